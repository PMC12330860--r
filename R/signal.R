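#' Per-voxel echo series
#'
#' A light container for the magnitude signal of one voxel across a train of
#' gradient echoes.
#'
#' @param values Magnitude per echo (arbitrary units, >= 0).
#' @param echo_TEs Echo times, ms; same length as `values`.
#' @param section Character label per echo in `{"fid","rephase","dephase"}`.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(values, echo_TEs, section) {
  values <- as.numeric(values); echo_TEs <- as.numeric(echo_TEs)
  if (length(values) != length(echo_TEs) || length(values) != length(section))
    stop_gesse("'values', 'echo_TEs' and 'section' must have matching lengths")
  if (any(!is.finite(echo_TEs)))
    stop_gesse("echo times must be finite")
  if (!all(section %in% c("fid", "rephase", "dephase")))
    stop_gesse("unknown section label")
  structure(list(values = values, echo_TEs = echo_TEs,
                 section = as.character(section)),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat(sprintf("echo_series: %d echoes, TE %.1f-%.1f ms (%s)\n",
              length(x$values), min(x$echo_TEs), max(x$echo_TEs),
              paste(unique(x$section), collapse = "+")))
  invisible(x)
}

#' Two-rate spin-echo signal model
#'
#' Evaluates `S(TE) = M0 * exp(-R2*TE - R2'*|TE - sTE|)` (times converted to
#' seconds internally) on echoes of the rephasing/dephasing sections.  At the
#' spin-echo top the reversible decay is fully refocused, so
#' `S(sTE) = M0 * exp(-R2*sTE)` regardless of R2'.
#'
#' @param tissue A [tissue_params()].
#' @param TEs Echo times to evaluate, ms; must lie within the
#'   rephasing/dephasing window of `spec`.  Defaults to all spin-echo-section
#'   echoes of `spec`.
#' @param spec An [echo_train_spec()] supplying `sTE`.
#' @return An [echo_series()] of noiseless model magnitudes.
#' @examples
#' ts <- tissue_params(1000, 25, 5)
#' simulate_se_signal(ts, TEs = 40, spec = echo_train_spec())$values
#' @export
simulate_se_signal <- function(tissue,
                               TEs = echo_times(spec, c("rephase", "dephase")),
                               spec = echo_train_spec()) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(spec, "echo_train_spec"))
  TEs <- as.numeric(TEs)
  lo <- min(spec$rephase_TEs); hi <- max(spec$dephase_TEs)
  if (any(TEs < lo - 1e-9) || any(TEs > hi + 1e-9))
    stop_gesse(sprintf("TEs must lie within the spin-echo window [%.2f, %.2f] ms",
                       lo, hi))
  te_s <- ms_to_s(TEs)
  ste_s <- ms_to_s(spec$sTE)
  vals <- tissue$M0 * exp(-tissue$R2 * te_s - tissue$R2prime * abs(te_s - ste_s))
  echo_series(vals, TEs, ifelse(TEs < spec$sTE, "rephase", "dephase"))
}

#' FID signal model
#'
#' The free induction decay before the refocusing pulse decays at the total
#' rate `R2* = R2 + R2'`: `S(TE) = M0 * exp(-(R2 + R2') * TE)`.
#'
#' @param tissue A [tissue_params()].
#' @param TEs Echo times, ms; must precede the rephasing section of `spec`.
#' @param spec An [echo_train_spec()] used only to bound admissible TEs.
#' @return An [echo_series()] with section `"fid"`.
#' @export
simulate_fid_signal <- function(tissue, TEs = spec$fid_TEs,
                                spec = echo_train_spec()) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(spec, "echo_train_spec"))
  TEs <- as.numeric(TEs)
  if (any(TEs < 0) || any(TEs >= min(spec$rephase_TEs) - 1e-9))
    stop_gesse("FID TEs must be non-negative and precede the rephasing section")
  vals <- tissue$M0 * exp(-tissue$R2star * ms_to_s(TEs))
  echo_series(vals, TEs, rep("fid", length(TEs)))
}

#' Add magnitude noise to an echo series
#'
#' The default `"rician"` model reproduces magnitude MRI noise: the noiseless
#' signal is placed on the real axis, independent Gaussian noise of standard
#' deviation `sigma` is added to both quadrature channels, and the modulus is
#' taken.  The `"gaussian"` model adds real Gaussian noise and clips at zero;
#' it is exact for analytic checks at high SNR.
#'
#' @param series An [echo_series()] (or any numeric vector, returned as such).
#' @param sigma Per-channel noise standard deviation, signal units (>= 0).
#' @param model `"rician"` or `"gaussian"`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Same type as `series`, with noisy non-negative values.
#' @export
add_magnitude_noise <- function(series, sigma, model = c("rician", "gaussian"),
                                seed = NULL) {
  model <- match.arg(model)
  check_number(sigma, "sigma", 0)
  vals <- if (inherits(series, "echo_series")) series$values else as.numeric(series)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- length(vals)
    vals <- switch(model,
      rician   = sqrt((vals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2),
      gaussian = pmax(vals + rnorm(n, 0, sigma), 0))
  }
  if (inherits(series, "echo_series")) {
    out <- series; out$values <- vals; out
  } else vals
}
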