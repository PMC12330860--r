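#' Echo-train timing specification
#'
#' Describes the gradient-echo timing of a GESFIDE/GESSE acquisition: a
#' free-induction-decay (FID) section after excitation, a rephasing section
#' before the spin-echo top at `sTE`, and a dephasing section after it.
#' Gradient-echo pairs symmetric about `sTE` (`sTE - n*delta_TE`,
#' `sTE + n*delta_TE`) are indexed by the integer `n` and drive the
#' model-free R2 estimator.
#'
#' The default construction mirrors a whole-brain 7 T protocol: spin echo at
#' 40 ms, echo spacing 1.30 ms, 6 FID echoes starting at 7.0 ms, 11
#' rephasing echoes (25.7--38.7 ms) and 30 dephasing echoes (41.3--79.0 ms).
#' Note that the rephasing/dephasing grids are laid out literally as
#' `sTE - n*delta_TE` / `sTE + n*delta_TE`, which is the convention required
#' for exact pairing; published per-section end points of nominally
#' equivalent protocols are not always consistent with a single uniform
#' spacing, and no attempt is made to reproduce such rounding.
#'
#' @param sTE Spin-echo time, ms.
#' @param delta_TE Gradient-echo spacing, ms.
#' @param n_fid,fid_start Number of FID echoes and the first FID echo time
#'   (ms); the FID grid is `fid_start + (0:(n_fid-1)) * delta_TE`.
#' @param n_rephase Number of rephasing echoes at `sTE - (n_rephase:1)*delta_TE`.
#' @param n_dephase Number of dephasing echoes at `sTE + (1:n_dephase)*delta_TE`.
#' @param fid_TEs,rephase_TEs,dephase_TEs Optional explicit echo-time grids
#'   (ms); when supplied they override the regular grids above.
#' @param pair_ns Integer pair indices available symmetrically about `sTE`;
#'   defaults to every `n` for which both pair members exist.
#' @return An object of class `echo_train_spec`.
#' @examples
#' spec <- echo_train_spec()
#' pair_te(spec, 8)   # c(29.6, 50.4)
#' @export
echo_train_spec <- function(sTE = 40, delta_TE = 1.3,
                            n_fid = 6, fid_start = 7.0,
                            n_rephase = 11, n_dephase = 30,
                            fid_TEs = NULL, rephase_TEs = NULL,
                            dephase_TEs = NULL, pair_ns = NULL) {
  check_number(sTE, "sTE", 0, strict = TRUE)
  check_number(delta_TE, "delta_TE", 0, strict = TRUE)
  if (is.null(fid_TEs))     fid_TEs     <- fid_start + (seq_len(n_fid) - 1L) * delta_TE
  if (is.null(rephase_TEs)) rephase_TEs <- sTE - rev(seq_len(n_rephase)) * delta_TE
  if (is.null(dephase_TEs)) dephase_TEs <- sTE + seq_len(n_dephase) * delta_TE
  if (is.null(pair_ns)) {
    ns <- seq_len(max(1L, length(dephase_TEs)))
    pair_ns <- ns[vapply(ns, function(n) {
      any(abs(rephase_TEs - (sTE - n * delta_TE)) < 1e-6) &&
        any(abs(dephase_TEs - (sTE + n * delta_TE)) < 1e-6)
    }, logical(1))]
  }
  spec <- structure(
    list(sTE = sTE, delta_TE = delta_TE,
         fid_TEs = as.numeric(fid_TEs),
         rephase_TEs = as.numeric(rephase_TEs),
         dephase_TEs = as.numeric(dephase_TEs),
         pair_ns = as.integer(pair_ns)),
    class = "echo_train_spec")
  validate_echo_train_spec(spec)
}

validate_echo_train_spec <- function(spec) {
  with(spec, {
    for (nm in c("fid_TEs", "rephase_TEs", "dephase_TEs")) {
      v <- spec[[nm]]
      if (length(v) && any(diff(v) <= 0))
        stop_gesse(sprintf("'%s' must be strictly increasing", nm))
    }
    if (length(fid_TEs) && length(rephase_TEs) &&
        max(fid_TEs) >= min(rephase_TEs))
      stop_gesse("FID echoes must all precede the rephasing section")
    if (length(rephase_TEs) && max(rephase_TEs) > sTE + 1e-9)
      stop_gesse("rephasing echoes must not exceed sTE")
    if (length(dephase_TEs) && min(dephase_TEs) < sTE - 1e-9)
      stop_gesse("dephasing echoes must not precede sTE")
    for (n in pair_ns) {
      if (!any(abs(rephase_TEs - (sTE - n * delta_TE)) < 1e-6) ||
          !any(abs(dephase_TEs - (sTE + n * delta_TE)) < 1e-6))
        stop_gesse(sprintf("pair index n=%d has no matching echo pair", n))
    }
  })
  spec
}

#' @export
print.echo_train_spec <- function(x, ...) {
  cat(sprintf("GESSE echo-train spec: sTE %.2f ms, delta_TE %.3f ms\n",
              x$sTE, x$delta_TE))
  cat(sprintf("  FID:       %d echoes (%.1f-%.1f ms)\n", length(x$fid_TEs),
              min(x$fid_TEs), max(x$fid_TEs)))
  cat(sprintf("  rephasing: %d echoes (%.1f-%.1f ms)\n", length(x$rephase_TEs),
              min(x$rephase_TEs), max(x$rephase_TEs)))
  cat(sprintf("  dephasing: %d echoes (%.1f-%.1f ms)\n", length(x$dephase_TEs),
              min(x$dephase_TEs), max(x$dephase_TEs)))
  cat(sprintf("  pair indices n: %s\n", paste(range(x$pair_ns), collapse = "-")))
  invisible(x)
}

#' Echo times of the symmetric pair with index `n`
#'
#' @param spec An [echo_train_spec()].
#' @param n Integer pair index.
#' @return `c(minus, plus)` echo times in ms.
#' @export
pair_te <- function(spec, n) {
  stopifnot(inherits(spec, "echo_train_spec"))
  if (!n %in% spec$pair_ns)
    stop_gesse(sprintf("pair index n=%d not available in this spec", n))
  c(spec$sTE - n * spec$delta_TE, spec$sTE + n * spec$delta_TE)
}

#' All sampled echo times of a spec, in acquisition order
#' @param spec An [echo_train_spec()].
#' @param sections Which sections to include.
#' @return Numeric vector of echo times (ms) with a `section` attribute.
#' @export
echo_times <- function(spec, sections = c("fid", "rephase", "dephase")) {
  stopifnot(inherits(spec, "echo_train_spec"))
  sections <- match.arg(sections, c("fid", "rephase", "dephase"),
                        several.ok = TRUE)
  te <- numeric(0); sec <- character(0)
  if ("fid" %in% sections)     { te <- c(te, spec$fid_TEs);     sec <- c(sec, rep("fid", length(spec$fid_TEs))) }
  if ("rephase" %in% sections) { te <- c(te, spec$rephase_TEs); sec <- c(sec, rep("rephase", length(spec$rephase_TEs))) }
  if ("dephase" %in% sections) { te <- c(te, spec$dephase_TEs); sec <- c(sec, rep("dephase", length(spec$dephase_TEs))) }
  structure(te, section = sec)
}

#' Tissue relaxation parameters
#'
#' @param M0 Steady-state signal magnitude (arbitrary units, >= 0).
#' @param R2 Irreversible transverse rate, 1/s (>= 0).
#' @param R2prime Reversible transverse rate R2' = R2* - R2, 1/s (>= 0).
#' @return An object of class `tissue_params` with derived field `R2star`.
#' @examples
#' tissue_params(1000, 25, 5)$R2star  # 30
#' @export
tissue_params <- function(M0, R2, R2prime = 0) {
  check_number(M0, "M0", 0)
  check_number(R2, "R2", 0)
  check_number(R2prime, "R2prime", 0)
  structure(list(M0 = M0, R2 = R2, R2prime = R2prime,
                 R2star = R2 + R2prime),
            class = "tissue_params")
}

#' Serialize / deserialize an echo-train spec
#'
#' The on-disk form uses the keys `sTE_ms`, `delta_TE_ms`, `fid_TEs_ms`,
#' `rephase_TEs_ms`, `dephase_TEs_ms`, `pair_ns` and can be JSON or YAML
#' (chosen by file extension).
#'
#' @param spec An [echo_train_spec()].
#' @param path Output (input) file ending in `.json`, `.yaml` or `.yml`.
#' @return `write_echo_spec` returns `path` invisibly; `read_echo_spec`
#'   returns an `echo_train_spec`.
#' @export
write_echo_spec <- function(spec, path) {
  stopifnot(inherits(spec, "echo_train_spec"))
  obj <- list(sTE_ms = spec$sTE, delta_TE_ms = spec$delta_TE,
              fid_TEs_ms = spec$fid_TEs, rephase_TEs_ms = spec$rephase_TEs,
              dephase_TEs_ms = spec$dephase_TEs, pair_ns = spec$pair_ns)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_echo_spec
#' @export
read_echo_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  echo_train_spec(sTE = obj$sTE_ms, delta_TE = obj$delta_TE_ms,
                  fid_TEs = unlist(obj$fid_TEs_ms),
                  rephase_TEs = unlist(obj$rephase_TEs_ms),
                  dephase_TEs = unlist(obj$dephase_TEs_ms),
                  pair_ns = unlist(obj$pair_ns))
}
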