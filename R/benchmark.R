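#' Run one seeded phantom segmentation trial
#'
#' Reproducibility harness used by the noise-robustness and ablation
#' experiments: generates the default brain phantom for the trial seed,
#' corrupts it with salt-and-pepper noise of the given intensity, runs
#' the requested segmentation, and evaluates the binary tumor mask
#' (brightest-center cluster) against the generating partition. The
#' phantom noise, impulse-noise placement and clustering initialization
#' each draw from a sub-seed derived from `seed`, so a trial is fully
#' determined by `(seed, noise, method, flags)`.
#'
#' @param seed integer trial seed.
#' @param noise salt-and-pepper intensity in \[0, 0.5\] (the study grid
#'   is 0, 0.005, 0.01, 0.02).
#' @param method `"ifcm_ms"` or `"fcm"`.
#' @param spec a [phantom_spec()]; its `seed` is replaced by the trial
#'   sub-seed. Default: the standard 128 x 128 phantom.
#' @param use_ifs,use_transfer,use_similarity ablation switches passed to
#'   [ifcm_config()] (ignored for `method = "fcm"`).
#' @param clusters cluster count; defaults to the phantom's class count.
#' @param max_iter iteration cap.
#' @param ... further arguments to [ifcm_config()].
#' @return A list with `indices` (the four evaluation indices),
#'   `accuracy`, the `result`, the noisy `image` and the `truth` mask.
#' @export
phantom_trial <- function(seed, noise = 0.02,
                          method = c("ifcm_ms", "fcm"),
                          spec = phantom_spec(),
                          use_ifs = TRUE, use_transfer = TRUE,
                          use_similarity = TRUE, clusters = NULL,
                          max_iter = 100, ...) {
  method <- match.arg(method)
  spec$seed <- as.integer(seed)
  ph <- make_phantom(spec)
  img <- salt_and_pepper(ph$image, noise, seed = seed + 10000L)
  if (is.null(clusters)) clusters <- length(spec$class_means)
  res <- if (method == "fcm") {
    fcm(img, clusters = clusters, max_iter = max_iter, seed = seed + 20000L)
  } else {
    cfg <- ifcm_config(clusters = clusters, seed = seed + 20000L,
                       use_ifs = use_ifs, use_transfer = use_transfer,
                       use_similarity = use_similarity,
                       max_iter = max_iter, ...)
    ifcm_ms(img, cfg)
  }
  truth <- ph$mask == ph$tumor_label
  idx <- seg_indices(confusion(tumor_mask(res), truth))
  list(indices = idx, accuracy = unname(idx["accuracy"]), result = res,
       image = img, truth = truth)
}

#' Mean tumor accuracy over a grid of seeds
#'
#' @param seeds integer vector of trial seeds.
#' @param ... arguments forwarded to [phantom_trial()].
#' @return Numeric vector of per-seed tumor accuracies (mean it for the
#'   study summary).
#' @export
phantom_accuracy_sweep <- function(seeds, ...) {
  vapply(seeds, function(s) phantom_trial(seed = s, ...)$accuracy,
         numeric(1))
}
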