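#' Fuzzy-complement generator parameters
#'
#' An intuitionistic fuzzy set (IFS) extends an ordinary fuzzy membership
#' \eqn{\mu} with a nonmembership \eqn{\nu} and a hesitation degree
#' \eqn{\pi} such that \eqn{\mu + \nu + \pi = 1} pointwise. The
#' nonmembership is obtained from \eqn{\mu} through a fuzzy-complement
#' generator:
#' \describe{
#'   \item{Sugeno}{\eqn{\nu = (1 - \mu) / (1 + \lambda \mu)} with
#'     \eqn{\lambda > 0}.}
#'   \item{Yager}{\eqn{\nu = (1 - \mu^\alpha)^{1/\alpha}} with
#'     \eqn{\alpha \in (0, 1)}. Exponents \eqn{\alpha \ge 1} would make the
#'     hesitation negative and are rejected.}
#' }
#'
#' @param family `"sugeno"` or `"yager"`.
#' @param param generator parameter (Sugeno \eqn{\lambda > 0}; Yager
#'   \eqn{\alpha} in (0, 1)).
#' @return An object of class `generator_params`.
#' @examples
#' generator_params("sugeno", 2)
#' @export
generator_params <- function(family = c("sugeno", "yager"), param = 2) {
  family <- match.arg(family)
  if (length(param) != 1 || !is.finite(param)) {
    stop("`param` must be a single finite number", call. = FALSE)
  }
  if (family == "sugeno" && param <= 0) {
    stop("Sugeno generator requires lambda > 0", call. = FALSE)
  }
  if (family == "yager" && (param <= 0 || param >= 1)) {
    stop("Yager generator requires alpha in (0, 1); alpha >= 1 yields ",
         "negative hesitation and is not a valid IFS generator here",
         call. = FALSE)
  }
  structure(list(family = family, param = as.numeric(param)),
            class = "generator_params")
}

#' Build an intuitionistic fuzzy triple from a membership stack
#'
#' Computes the nonmembership \eqn{\nu} with the chosen generator and the
#' hesitation \eqn{\pi = 1 - \mu - \nu}, for every pixel and cluster of a
#' membership stack. For valid generator parameters \eqn{\pi \ge 0}
#' everywhere and \eqn{\mu + \nu + \pi = 1} to machine precision.
#'
#' @param mu membership values in \[0, 1\]: an H x W x c array (a
#'   membership stack), matrix or vector.
#' @param gen a [generator_params()] object.
#' @return A list of class `ifs_triple` with components `mu`, `nu`, `pi`,
#'   each shaped like `mu`.
#' @examples
#' tr <- intuitionify(c(0, 0.5, 1), generator_params("sugeno", 2))
#' tr$nu  # 1, 0.25, 0
#' @export
intuitionify <- function(mu, gen = generator_params()) {
  if (!inherits(gen, "generator_params")) {
    stop("`gen` must be created with generator_params()", call. = FALSE)
  }
  if (min(mu) < 0 || max(mu) > 1) {
    stop("membership values must lie in [0, 1]", call. = FALSE)
  }
  nu <- switch(gen$family,
    sugeno = (1 - mu) / (1 + gen$param * mu),
    yager  = (1 - mu^gen$param)^(1 / gen$param)
  )
  pi <- 1 - mu - nu
  if (min(pi) < -1e-12) {
    stop("generator produced negative hesitation; parameters are outside ",
         "the valid IFS domain", call. = FALSE)
  }
  pi[pi < 0] <- 0
  structure(list(mu = mu, nu = nu, pi = pi), class = "ifs_triple")
}

#' Intuitionistic fuzzy entropy of a hesitation map
#'
#' The entropy term monitored alongside the clustering objective:
#' \deqn{\sum_i \pi'_i e^{1 - \pi'_i}, \qquad
#'       \pi'_i = \frac{1}{n}\sum_k \pi_{ik},}
#' where \eqn{\pi_{ik}} is the hesitation of pixel \eqn{k} toward cluster
#' \eqn{i} and \eqn{n} the pixel count. Nonnegative, and zero exactly when
#' every hesitation vanishes.
#'
#' @param pi hesitation values in \[0, 1\]: an H x W x c array, or a
#'   matrix/vector treated as a single cluster.
#' @return A single nonnegative number.
#' @examples
#' hesitation_entropy(array(0, c(4, 4, 2)))  # 0
#' @export
hesitation_entropy <- function(pi) {
  if (min(pi) < 0 || max(pi) > 1) {
    stop("hesitation values must lie in [0, 1]", call. = FALSE)
  }
  d <- dim(pi)
  pbar <- if (!is.null(d) && length(d) == 3) {
    colMeans(matrix(pi, d[1] * d[2], d[3]))
  } else {
    mean(pi)
  }
  sum(pbar * exp(1 - pbar))
}

# Intuitionistic membership used by the clustering driver: u' is the
# per-pixel renormalization of u + pi(u). (u + pi cannot itself satisfy
# the sum-to-one constraint unless all hesitations are zero.)
intuitionistic_membership <- function(u, gen) {
  tr <- intuitionify(u, gen)
  normalize_stack(u + tr$pi, zero_to_uniform = FALSE)
}
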