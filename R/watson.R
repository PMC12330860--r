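#' Sample axial fiber orientations from a Watson distribution
#'
#' Draws unit vectors from the bipolar Watson density
#' `f(x) ~ exp(kappa * (mode . x)^2)` on the sphere.  The density is
#' antipodally symmetric, matching the sign ambiguity of diffusion-tensor
#' principal eigenvectors.  `kappa = 0` gives the uniform axial law;
#' `kappa = Inf` returns the mode for every draw.
#'
#' Sampling uses vectorized rejection with a uniform envelope on
#' `c = mode . x`, which is adequate for the moderate concentrations
#' (`kappa` up to a few hundred) used in the phantom.
#'
#' @param tract A [tract_spec()] supplying `orientation_mode` and
#'   `orientation_kappa`; alternatively pass `mode`/`kappa` directly.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param mode,kappa Direct parameter interface overriding `tract`.
#' @return An `n x 3` matrix of unit row vectors.
#' @examples
#' v <- sample_orientations(n = 5, seed = 1, mode = c(0, 0, 1), kappa = 50)
#' @export
sample_orientations <- function(tract = NULL, n, seed = NULL,
                                mode = tract$orientation_mode,
                                kappa = tract$orientation_kappa) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  mode <- as.numeric(unit_rows(mode))
  check_number(n, "n", 1)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop_gesse("'kappa' must be a single number >= 0")
  n <- as.integer(n)
  if (is.infinite(kappa))
    return(matrix(mode, nrow = n, ncol = 3, byrow = TRUE))
  cosines <- numeric(0)
  while (length(cosines) < n) {
    m <- max(2L * (n - length(cosines)), 64L)
    c_try <- runif(m, -1, 1)
    acc <- runif(m) < exp(kappa * (c_try^2 - 1))
    cosines <- c(cosines, c_try[acc])
  }
  cosines <- cosines[seq_len(n)]
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - cosines^2))
  B <- basis_from_mode(mode)
  cbind(s * cos(phi), s * sin(phi), cosines) %*% t(B)
}
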