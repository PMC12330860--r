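#' Multi-voxel echo stack
#'
#' Magnitude signal for many voxels across one echo train: a numeric matrix
#' with one row per voxel and one column per echo.  This is the in-memory
#' stand-in for a 4-D echo-train volume; [read_echo_volume()] /
#' [write_echo_volume()] convert to and from NIfTI plus an echo-time sidecar.
#'
#' @param values Numeric matrix, voxels x echoes.
#' @param echo_TEs Echo times (ms), one per column.
#' @param section Section label per column.
#' @param dim Optional spatial dimensions of the voxel grid (prod == nrow).
#' @return An object of class `echo_stack`.
#' @export
echo_stack <- function(values, echo_TEs, section, dim = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(echo_TEs) || ncol(values) != length(section))
    stop_gesse("number of echo columns must match 'echo_TEs' and 'section'")
  if (!is.null(dim) && prod(dim) != nrow(values))
    stop_gesse("prod(dim) must equal the number of voxel rows")
  structure(list(values = values, echo_TEs = as.numeric(echo_TEs),
                 section = as.character(section), dim = dim),
            class = "echo_stack")
}

#' Rate maps container
#'
#' @param R2 Numeric vector/array of R2 estimates, 1/s.
#' @param R2star,R2prime Optional companion maps; where all three are present
#'   and valid they must satisfy `R2star = R2 + R2prime` to within 1e-9.
#' @param valid_mask Logical map of voxels with trustworthy estimates.
#' @return An object of class `rate_maps`.
#' @export
rate_maps <- function(R2, R2star = NULL, R2prime = NULL,
                      valid_mask = rep(TRUE, length(R2))) {
  if (!is.null(R2star) && !is.null(R2prime)) {
    ok <- valid_mask & is.finite(R2) & is.finite(R2star) & is.finite(R2prime)
    if (any(abs(R2star[ok] - R2[ok] - R2prime[ok]) > 1e-9))
      stop_gesse("R2star must equal R2 + R2prime on valid voxels")
  }
  structure(list(R2 = R2, R2star = R2star, R2prime = R2prime,
                 valid_mask = valid_mask),
            class = "rate_maps")
}

#' Model-free R2 from one symmetric gradient-echo pair
#'
#' For echoes acquired at `sTE - n*delta_TE` and `sTE + n*delta_TE`, the
#' reversible (R2') attenuation is identical on both sides of the spin echo
#' and cancels in the ratio, leaving
#' `R2 = ln(S_minus / S_plus) / (2 * n * delta_TE)`.  The estimate is exact
#' on noiseless two-rate signals for any M0 and R2'.
#'
#' @param S_minus,S_plus Magnitudes at `sTE - n*delta_TE` and
#'   `sTE + n*delta_TE`; strictly positive (vectorized).
#' @param n Integer pair index, >= 1.
#' @param delta_TE Echo spacing, ms.
#' @return R2 in 1/s.
#' @examples
#' r2_from_pair(2, 1, n = 10, delta_TE = 1.3)  # ln 2 / 0.026 s
#' @export
r2_from_pair <- function(S_minus, S_plus, n, delta_TE) {
  if (any(S_minus <= 0) || any(S_plus <= 0))
    stop_gesse("pair magnitudes must be strictly positive")
  check_number(n, "n", 1)
  check_number(delta_TE, "delta_TE", 0, strict = TRUE)
  log(S_minus / S_plus) / (2 * n * ms_to_s(delta_TE))
}

#' Pair-average R2 map
#'
#' Computes the per-pair R2 estimate for every `n` in `n_range` and averages
#' the per-n maps voxelwise with equal weight.  Voxels for which any pair
#' member is non-positive or non-finite are marked invalid rather than
#' clipped.
#'
#' @param stack An [echo_stack()] containing the spin-echo sections.
#' @param spec The [echo_train_spec()] that generated `stack`.
#' @param n_range Integer pair indices to average (default 6:11, the range
#'   with usable contrast-to-noise in the reference protocol).
#' @return A [rate_maps()] with fields `R2` and `valid_mask`.
#' @export
r2_map_pair_average <- function(stack, spec, n_range = 6:11) {
  stopifnot(inherits(stack, "echo_stack"), inherits(spec, "echo_train_spec"))
  n_range <- as.integer(n_range)
  if (length(n_range) == 0L) stop_gesse("'n_range' must be non-empty")
  if (!all(n_range %in% spec$pair_ns))
    stop_gesse("all pair indices in 'n_range' must be available in 'spec'")
  nvox <- nrow(stack$values)
  acc <- matrix(NA_real_, nvox, length(n_range))
  valid <- rep(TRUE, nvox)
  for (k in seq_along(n_range)) {
    te <- pair_te(spec, n_range[k])
    i_minus <- which(abs(stack$echo_TEs - te[1]) < 1e-6)[1]
    i_plus  <- which(abs(stack$echo_TEs - te[2]) < 1e-6)[1]
    if (is.na(i_minus) || is.na(i_plus))
      stop_gesse(sprintf("echo stack lacks the n=%d pair echoes", n_range[k]))
    sm <- stack$values[, i_minus]; sp <- stack$values[, i_plus]
    ok <- is.finite(sm) & is.finite(sp) & sm > 0 & sp > 0
    valid <- valid & ok
    acc[ok, k] <- log(sm[ok] / sp[ok]) /
      (2 * n_range[k] * ms_to_s(spec$delta_TE))
  }
  r2 <- rowMeans(acc)
  r2[!valid] <- NA_real_
  out <- rate_maps(R2 = r2, valid_mask = valid)
  if (!is.null(stack$dim)) {
    out$R2 <- array(out$R2, stack$dim)
    out$valid_mask <- array(out$valid_mask, stack$dim)
  }
  out
}

se_design <- function(series, spec) {
  keep <- series$section != "fid"
  te_s <- ms_to_s(series$echo_TEs[keep])
  list(y = series$values[keep], te = te_s, ste = ms_to_s(spec$sTE),
       dev = abs(te_s - ms_to_s(spec$sTE)))
}

#' Log-linear fit of the two-rate spin-echo model
#'
#' Ordinary least squares of `ln S` on the regressors `{1, -TE, -|TE - sTE|}`.
#' Exact on noiseless model data; in noise the log transform is used as-is
#' (no Rician bias correction), matching the model-free processing chain.
#'
#' @param series An [echo_series()] spanning both sides of `sTE`.
#' @param spec An [echo_train_spec()].
#' @return List with `M0`, `R2`, `R2prime` (1/s) and `converged = TRUE`.
#' @export
fit_loglinear <- function(series, spec = echo_train_spec()) {
  stopifnot(inherits(series, "echo_series"))
  d <- se_design(series, spec)
  if (length(d$y) < 4L)
    stop_gesse("need at least 4 spin-echo-section echoes")
  if (any(d$y <= 0))
    stop_gesse("log-linear fit requires strictly positive magnitudes")
  if (!any(d$te < d$ste - 1e-12) || !any(d$te > d$ste + 1e-12))
    stop_gesse("echoes on only one side of sTE: TE and |TE - sTE| are collinear")
  X <- cbind(1, -d$te, -d$dev)
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop_gesse("rank-deficient design for log-linear fit")
  b <- qr.coef(qrX, log(d$y))
  list(M0 = exp(b[[1]]), R2 = b[[2]], R2prime = b[[3]], converged = TRUE)
}

#' Nonlinear least-squares fit of the two-rate spin-echo model
#'
#' Signal-domain least squares of `S(TE) = M0 exp(-R2*TE - R2'*|TE - sTE|)`
#' with analytic gradient, box constraints `M0 > 0`, `R2 >= 0`, `R2' >= 0`,
#' and starting values from [fit_loglinear()] (projected into the feasible
#' region).
#'
#' @inheritParams fit_loglinear
#' @param control Passed to [stats::nlminb()]; defaults request a 1e-10
#'   relative tolerance.
#' @return List with `M0`, `R2`, `R2prime`, `converged`, `message`.
#' @export
fit_exponential <- function(series, spec = echo_train_spec(),
                            control = list(rel.tol = 1e-10, iter.max = 500L,
                                           eval.max = 1000L)) {
  stopifnot(inherits(series, "echo_series"))
  d <- se_design(series, spec)
  if (length(d$y) < 4L)
    stop_gesse("need at least 4 spin-echo-section echoes")
  start <- tryCatch({
    ll <- fit_loglinear(series, spec)
    c(max(ll$M0, 1e-8), max(ll$R2, 0), max(ll$R2prime, 0))
  }, error = function(e) c(max(d$y), 1, 1))
  obj <- function(p) {
    mu <- p[1] * exp(-p[2] * d$te - p[3] * d$dev)
    sum((d$y - mu)^2)
  }
  grad <- function(p) {
    mu <- p[1] * exp(-p[2] * d$te - p[3] * d$dev)
    r <- mu - d$y
    2 * c(sum(r * mu / p[1]),
          -sum(r * mu * d$te),
          -sum(r * mu * d$dev))
  }
  fit <- nlminb(start, obj, gradient = grad,
                lower = c(1e-12, 0, 0), control = control)
  list(M0 = fit$par[1], R2 = fit$par[2], R2prime = fit$par[3],
       converged = fit$convergence == 0L, message = fit$message)
}

#' R2* from the FID section
#'
#' Log-linear mono-exponential fit of the FID echoes:
#' `ln S = ln M0 - R2* TE`.  With exactly two echoes this reduces to the
#' two-point formula `ln(S1/S2)/(TE2 - TE1)`.  A negative estimate flags the
#' voxel invalid instead of being clamped.
#'
#' @param series An [echo_series()] whose `"fid"` echoes are used (other
#'   sections are ignored; pure FID series are accepted as-is).
#' @return List with `M0`, `R2star` (1/s) and `valid`.
#' @export
fit_r2star_fid <- function(series) {
  stopifnot(inherits(series, "echo_series"))
  keep <- if (any(series$section == "fid")) series$section == "fid"
          else rep(TRUE, length(series$values))
  y <- series$values[keep]; te <- ms_to_s(series$echo_TEs[keep])
  if (length(y) < 2L) stop_gesse("need at least 2 FID echoes")
  if (any(y <= 0)) return(list(M0 = NA_real_, R2star = NA_real_, valid = FALSE))
  b <- qr.coef(qr(cbind(1, -te)), log(y))
  list(M0 = exp(b[[1]]), R2star = b[[2]], valid = b[[2]] >= 0)
}

#' Combine a pair-average R2 map with a FID R2* map into R2'
#'
#' @param r2_maps A [rate_maps()] with `R2`.
#' @param r2star Numeric map of R2* (1/s), same geometry.
#' @return A [rate_maps()] with all three rates; `R2prime = R2star - R2`.
#' @export
combine_r2prime <- function(r2_maps, r2star) {
  stopifnot(inherits(r2_maps, "rate_maps"))
  r2p <- r2star - r2_maps$R2
  valid <- r2_maps$valid_mask & is.finite(r2star) & is.finite(r2p) & r2p >= 0
  rate_maps(R2 = r2_maps$R2, R2star = r2star, R2prime = r2p,
            valid_mask = valid)
}
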