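#' Angle between fiber orientation and the main field
#'
#' `alpha = arccos(|PEV . b0|)` in degrees, in `[0, 90]`.  The absolute
#' value makes the angle invariant under the sign ambiguity of the
#' principal eigenvector.
#'
#' @param pev Unit 3-vector or `n x 3` matrix of fiber directions
#'   (normalized internally; zero vectors are an error).
#' @param b0 Unit 3-vector of the main field (default grid +z).
#' @return Angle(s) in degrees.
#' @examples
#' compute_alpha(c(0, 0, 1), c(0, 0, 1))  # 0
#' compute_alpha(c(1, 0, 0), c(0, 0, 1))  # 90
#' @export
compute_alpha <- function(pev, b0 = c(0, 0, 1)) {
  p <- unit_rows(pev)
  b <- as.numeric(unit_rows(b0))
  ct <- pmin(1, abs(p %*% b))
  as.numeric(acos(ct) * 180 / pi)
}

#' Orientation regressor sin^4(alpha)
#' @param alpha_deg Angle in degrees.
#' @return `sin(alpha)^4`.
#' @export
sin4_alpha <- function(alpha_deg) sin(alpha_deg * pi / 180)^4

#' Select analyzable white-matter voxels
#'
#' Keeps voxels with `FA > fa_min` and `tract_prob > prob_min` (strict
#' inequalities), i.e. voxels dominated by a single well-defined tract.
#'
#' @param table A [fiber_voxel_table()].
#' @param fa_min FA threshold (default 0.4).
#' @param prob_min Tract-probability threshold (default 0.25).
#' @param verbose Report the survivor count.
#' @return The filtered [fiber_voxel_table()].
#' @export
select_voxels <- function(table, fa_min = 0.4, prob_min = 0.25,
                          verbose = FALSE) {
  stopifnot(inherits(table, "fiber_voxel_table"))
  keep <- table$FA > fa_min & table$tract_prob > prob_min
  out <- table[keep, , drop = FALSE]
  if (verbose)
    message(sprintf("select_voxels: %d of %d voxels retained (FA > %g, p > %g)",
                    nrow(out), nrow(table), fa_min, prob_min))
  fiber_voxel_table(out)
}

#' Voxel-count-weighted mean tract diameter
#'
#' `dbar = sum_t(d_t * n_t) / sum_t(n_t)` over the tracts present in the
#' table, with n_t the tract's voxel count.  Because d is constant within a
#' tract this equals the per-voxel mean of d.
#'
#' @param table A [fiber_voxel_table()] (typically after [select_voxels()]).
#' @return Weighted mean diameter, micrometres.
#' @export
compute_dbar <- function(table) {
  stopifnot(inherits(table, "fiber_voxel_table"))
  if (nrow(table) == 0L) stop_gesse("empty voxel table")
  per <- aggregate(d ~ tract_id, data = as.data.frame(table),
                   FUN = function(x) x[1])
  n <- as.numeric(table(factor(table$tract_id, levels = per$tract_id)))
  sum(per$d * n) / sum(n)
}

#' Bin voxels by sin^4(alpha) within each tract
#'
#' Voxels of each tract are categorized into ten bins of width 0.1 on
#' `sin^4(alpha)` -- `[0, 0.1), ..., [0.9, 1.0]` with the last bin closed --
#' to remove the heavy weighting of near-parallel/near-perpendicular fibers
#' induced by the supine head pose.  Empty bins are omitted.
#'
#' @param table A [fiber_voxel_table()].
#' @param b0 Main-field direction used for the angle computation.
#' @return data.frame of class `binned_observations` with columns
#'   `tract_id`, `bin_index` (0--9), `bin_sin4_mean`, `R2_mean`, `R2_se`
#'   (sample SD / sqrt(n); `NA` for singleton bins), `n_members`, `d`.
#' @export
bin_by_sin4 <- function(table, b0 = c(0, 0, 1)) {
  stopifnot(inherits(table, "fiber_voxel_table"))
  alpha <- compute_alpha(as.matrix(table[, c("pev_x", "pev_y", "pev_z")]), b0)
  s4 <- sin4_alpha(alpha)
  bin <- pmin(floor(s4 * 10), 9L)
  key <- interaction(table$tract_id, bin, drop = TRUE)
  split_idx <- split(seq_len(nrow(table)), key)
  obs <- do.call(rbind, lapply(split_idx, function(i) {
    data.frame(tract_id = table$tract_id[i[1]],
               bin_index = as.integer(bin[i[1]]),
               bin_sin4_mean = mean(s4[i]),
               R2_mean = mean(table$R2[i]),
               R2_se = if (length(i) > 1) sd(table$R2[i]) / sqrt(length(i)) else NA_real_,
               n_members = length(i),
               d = table$d[i[1]])
  }))
  obs <- obs[order(obs$tract_id, obs$bin_index), ]
  rownames(obs) <- NULL
  class(obs) <- c("binned_observations", "data.frame")
  obs
}

#' Fit the multi-linear orientation/diameter model to binned observations
#'
#' Unweighted ordinary least squares of the binned mean R2 on
#' `a0 + a1 (d - dbar) + a2 s4 + a3 (d - dbar) s4`, where the orientation
#' regressor `s4` is the within-bin mean of `sin^4(alpha)` (not the bin
#' centre).  Reduced models are obtained by removing terms.
#'
#' @param obs A [bin_by_sin4()] result.
#' @param d_bar Voxel-count-weighted mean diameter, micrometres, as from
#'   [compute_dbar()] on the selected table.
#' @param terms Character subset of `c("a1", "a2", "a3")` to include beside
#'   the intercept.
#' @param weighted If `TRUE`, weight observations by their member counts
#'   (off by default: the binning exists precisely to undo the orientation
#'   weighting of the voxel population).
#' @param robust_se Report heteroscedasticity-consistent (HC3) standard
#'   errors (default).  Binned means carry unequal sampling variance
#'   (SD/sqrt(n) per bin), so classical OLS standard errors are
#'   anti-conservative; HC3 restores nominal confidence-interval coverage.
#'   Ignored (classical) for weighted fits.
#' @return An object of class `gesse_fit`: coefficients `a0`--`a3` (`NA`
#'   where excluded), standard errors, `R2_stat`, `adjR2_stat`, `n_obs`,
#'   `d_bar`, `included_terms`.
#' @export
fit_orientation_model <- function(obs, d_bar, terms = c("a1", "a2", "a3"),
                                  weighted = FALSE, robust_se = TRUE) {
  stopifnot(inherits(obs, "data.frame"))
  terms <- if (length(terms)) match.arg(terms, c("a1", "a2", "a3"),
                                        several.ok = TRUE) else character(0)
  if ("a3" %in% terms && !all(c("a1", "a2") %in% c(terms)) )
    terms <- union(terms, c("a1", "a2"))   # interaction implies main effects
  df <- data.frame(y = obs$R2_mean, dc = obs$d - d_bar,
                   s4 = obs$bin_sin4_mean, w = obs$n_members)
  p <- length(terms)
  if (nrow(df) <= p + 1L)
    stop_gesse("need more binned observations than free coefficients")
  rhs <- c("1", if ("a1" %in% terms) "dc", if ("a2" %in% terms) "s4",
           if ("a3" %in% terms) "dc:s4")
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- if (weighted) lm(fml, data = df, weights = df$w) else lm(fml, data = df)
  if (fit$rank < p + 1L)
    stop_gesse("rank-deficient design (e.g. a single tract cannot identify a diameter effect)")
  sm <- summary(fit)
  cf <- sm$coefficients
  if (robust_se && !weighted) {
    X <- stats::model.matrix(fit)
    u <- stats::residuals(fit)
    h <- stats::hatvalues(fit)
    XtXi <- solve(crossprod(X))
    meat <- crossprod(X * (u / (1 - h)))
    cf[, 2] <- sqrt(diag(XtXi %*% meat %*% XtXi))
  }
  pick <- function(label) {
    if (label %in% rownames(cf)) cf[label, 1:2] else c(NA_real_, NA_real_)
  }
  a  <- rbind(a0 = pick("(Intercept)"), a1 = pick("dc"),
              a2 = pick("s4"), a3 = pick("dc:s4"))
  structure(list(a0 = a["a0", 1], a1 = a["a1", 1], a2 = a["a2", 1],
                 a3 = a["a3", 1],
                 se = setNames(a[, 2], rownames(a)),
                 included_terms = terms,
                 R2_stat = sm$r.squared, adjR2_stat = sm$adj.r.squared,
                 n_obs = nrow(df), d_bar = d_bar, weighted = weighted,
                 lm_fit = fit),
            class = "gesse_fit")
}

#' @export
print.gesse_fit <- function(x, digits = 4, ...) {
  cat("Orientation/diameter model fit (binned OLS)\n")
  co <- c(a0 = x$a0, a1 = x$a1, a2 = x$a2, a3 = x$a3)
  for (nm in names(co)) {
    if (!is.na(co[nm]))
      cat(sprintf("  %s = %s (SE %s)\n", nm, format(co[nm], digits = digits),
                  format(x$se[nm], digits = digits)))
  }
  cat(sprintf("  R^2 = %.3f, adjusted R^2 = %.3f, n = %d, d_bar = %.3f um\n",
              x$R2_stat, x$adjR2_stat, x$n_obs, x$d_bar))
  invisible(x)
}

#' Nested model comparison for the orientation/diameter model
#'
#' Fits the four standard variants -- orientation only (`a2`), diameter only
#' (`a1`), both main effects (`a1 + a2`), and the full model with
#' interaction -- and tabulates coefficients, R^2 and adjusted R^2.
#'
#' @inheritParams fit_orientation_model
#' @return data.frame with one row per variant (`fit` 1--4) plus an
#'   attribute `"fits"` holding the `gesse_fit` objects.
#' @export
model_comparison <- function(obs, d_bar, weighted = FALSE) {
  variants <- list(`1` = "a2", `2` = "a1", `3` = c("a1", "a2"),
                   `4` = c("a1", "a2", "a3"))
  fits <- lapply(variants, fit_orientation_model, obs = obs, d_bar = d_bar,
                 weighted = weighted)
  tab <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(fit = as.integer(k), a0 = f$a0, a1 = f$a1, a2 = f$a2,
               a3 = f$a3, R2_stat = f$R2_stat, adjR2_stat = f$adjR2_stat,
               n_obs = f$n_obs)
  }))
  attr(tab, "fits") <- fits
  attr(tab, "d_bar") <- d_bar
  tab
}

#' Field-strength scaling of the orientation-dependence amplitude
#'
#' Compares the amplitude of the sin^4(alpha) orientation dependence
#' measured at two field strengths with the ratio of the fields themselves;
#' an approximately matching pair of ratios indicates close-to-linear
#' scaling of the orientation effect with B0.
#'
#' @param amp_high,amp_low Orientation-dependence amplitudes (1/s) at the
#'   higher and lower field.
#' @param b_high,b_low Field strengths, Tesla.
#' @param digits Rounding applied to both ratios (default 2).
#' @return List with `amplitude_ratio` and `field_ratio`.
#' @examples
#' orientation_field_scaling(5.34, 2.2)  # 2.43 vs 7/3 = 2.33
#' @export
orientation_field_scaling <- function(amp_high, amp_low, b_high = 7,
                                      b_low = 3, digits = 2) {
  check_number(amp_high, "amp_high", 0, strict = TRUE)
  check_number(amp_low, "amp_low", 0, strict = TRUE)
  list(amplitude_ratio = round(amp_high / amp_low, digits),
       field_ratio = round(b_high / b_low, digits))
}
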