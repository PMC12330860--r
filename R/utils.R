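MS_PER_S <- 1000

ms_to_s <- function(te_ms) te_ms / MS_PER_S

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gesse <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gesse(sprintf("'%s' must be a single finite number", name))
  ok <- if (strict) x > min else x >= min
  if (!ok)
    stop_gesse(sprintf("'%s' must be %s %s (got %g)", name,
                       if (strict) ">" else ">=", format(min), x))
  invisible(x)
}

#' Normalize a 3-vector (or the rows of an n x 3 matrix) to unit length
#' @noRd
unit_rows <- function(v) {
  m <- if (is.matrix(v)) v else matrix(v, ncol = 3L)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12))
    stop_gesse("zero-length direction vector")
  m / nrm
}

#' Build an orthonormal basis whose third column is `mode`
#' @noRd
basis_from_mode <- function(mode) {
  w <- as.numeric(unit_rows(mode))
  helper <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- helper - sum(helper * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}
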