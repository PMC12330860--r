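#' White-matter tract specification
#'
#' One entry of the tract table used by the synthetic-data generator: an id,
#' a human-readable name, the tract's apparent axonal diameter index (the
#' per-tract diffusion-derived summary statistic, micrometres), a mean R2
#' offset applied inside the bundle on the image grid, the dominant fiber
#' direction, the Watson concentration of per-voxel orientations around it,
#' and the number of voxels the tract contributes.
#'
#' @param tract_id Positive integer id.
#' @param name Tract name.
#' @param diameter_index Diameter index d, micrometres (> 0).
#' @param orientation_mode Unit 3-vector, dominant fiber direction.
#' @param orientation_kappa Watson concentration (>= 0, may be `Inf`).
#' @param n_voxels Voxels contributed by this tract.
#' @param mean_R2_offset Mean R2 offset inside the bundle, 1/s (grid path).
#' @return An object of class `tract_spec`.
#' @export
tract_spec <- function(tract_id, name, diameter_index, orientation_mode,
                       orientation_kappa = 8, n_voxels = 2500,
                       mean_R2_offset = 0) {
  check_number(tract_id, "tract_id", 1)
  check_number(diameter_index, "diameter_index", 0, strict = TRUE)
  check_number(n_voxels, "n_voxels", 1)
  mode <- as.numeric(unit_rows(orientation_mode))
  structure(list(tract_id = as.integer(tract_id), name = as.character(name),
                 diameter_index = diameter_index,
                 orientation_mode = mode,
                 orientation_kappa = orientation_kappa,
                 n_voxels = as.integer(n_voxels),
                 mean_R2_offset = mean_R2_offset),
            class = "tract_spec")
}

#' Default set of 20 bilateral white-matter tracts
#'
#' Ten left/right tract pairs emulating a head-first supine pose: most
#' dominant directions lie close to parallel (projection fibers) or close to
#' perpendicular (association and commissural fibers) to the scanner +z
#' axis, which concentrates `sin^4 alpha` near 0 and 1, with a few oblique
#' bundles populating the intermediate bins.  Diameter indices span
#' 3--6.5 micrometres, interleaved between hemispheres so that diameter and
#' orientation are not confounded across tracts.
#'
#' @param n_voxels Voxels per tract.
#' @param kappa Watson concentration shared by all tracts.
#' @param diameters Optional length-20 vector of diameter indices
#'   (micrometres) overriding the default `seq(3, 6.5, length.out = 20)`
#'   interleaved assignment.
#' @return A list of 20 [tract_spec()] objects.
#' @export
default_tract_set <- function(n_voxels = 2500, kappa = 8, diameters = NULL) {
  pairs <- data.frame(
    name  = c("cst", "scr", "atr", "unc", "cgc",
              "slf", "ilf", "ifo", "fma", "fmi"),
    polar = c(8, 18, 38, 48, 58, 70, 78, 84, 89, 89),
    azim  = c(10, 40, 70, 100, 130, 20, 50, 80, 0, 180))
  d_grid <- if (is.null(diameters)) seq(3, 6.5, length.out = 20) else diameters
  if (length(d_grid) != 20L) stop_gesse("'diameters' must have length 20")
  tracts <- vector("list", 20L)
  for (i in seq_len(10L)) {
    th <- pairs$polar[i] * pi / 180
    for (side in 1:2) {
      az <- (pairs$azim[i] + if (side == 2) 180 else 0) * pi / 180
      id <- 2L * (i - 1L) + side
      d  <- if (side == 1) d_grid[i] else d_grid[21L - i]
      tracts[[id]] <- tract_spec(
        tract_id = id,
        name = paste0(pairs$name[i], c("_l", "_r")[side]),
        diameter_index = d,
        orientation_mode = c(sin(th) * cos(az), sin(th) * sin(az), cos(th)),
        orientation_kappa = kappa, n_voxels = n_voxels)
    }
  }
  tracts
}

#' Default tissue-class table of the digital phantom
#'
#' Gray- and white-matter R2 values sit in the 22--28 1/s band typical of
#' 7 T, with elevated rates in the iron-rich subcortical nuclei and a larger
#' reversible component (R2') in white matter and nuclei.
#'
#' @return A data.frame with columns `class`, `label`, `M0`, `R2`, `R2prime`.
#' @export
default_tissue_table <- function() {
  data.frame(
    class   = c("background", "csf", "cortex", "swm", "dwm",
                "caudate", "putamen", "pallidus", "thalamus"),
    label   = c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    M0      = c(0, 1200, 1000, 950, 900, 950, 950, 900, 950),
    R2      = c(0, 4, 24, 26, 23, 28, 30, 36, 27),
    R2prime = c(0, 1, 4, 5, 6, 9, 11, 15, 7))
}

CC_LABEL <- 90L
TRACT_LABEL_BASE <- 100L

#' Phantom configuration
#'
#' @param seed Mandatory integer seed; every stochastic element of the
#'   phantom is reproducible from it.
#' @param dim Grid shape (3 integers).
#' @param voxel_size_mm Voxel size, mm.
#' @param tissue_table Tissue-class table as from [default_tissue_table()].
#' @param tracts List of [tract_spec()] bundles hosted on the grid.
#' @param noise_sigma Magnitude-noise SD used by the echo-simulation stage.
#' @param b0_direction Unit 3-vector of the main field in grid coordinates.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(seed, dim = c(48, 56, 40), voxel_size_mm = c(2, 2, 2),
                           tissue_table = default_tissue_table(),
                           tracts = default_tract_set(n_voxels = 150)[1:8],
                           noise_sigma = 0, b0_direction = c(0, 0, 1)) {
  if (missing(seed)) stop_gesse("'seed' is mandatory for phantom_config")
  check_number(seed, "seed")
  if (length(dim) != 3L || any(dim < 16))
    stop_gesse("'dim' must be 3 integers, each >= 16")
  check_number(noise_sigma, "noise_sigma", 0)
  structure(list(seed = as.integer(seed), dim = as.integer(dim),
                 voxel_size_mm = voxel_size_mm, tissue_table = tissue_table,
                 tracts = tracts, noise_sigma = noise_sigma,
                 b0_direction = as.numeric(unit_rows(b0_direction))),
            class = "phantom_config")
}

#' Build the digital brain phantom
#'
#' Constructs a labelled 3-D volume: an ellipsoidal brain with a cortical
#' ribbon, superficial and deep white matter, a central CSF cavity, four
#' bilateral subcortical nuclei with elevated R2, a midsagittal
#' corpus-callosum arch pre-divided into four tip-to-tip sections, and
#' rectangular tract bundles carved into deep white matter with exactly the
#' requested voxel counts.  Per-voxel M0/R2/R2' follow the tissue table;
#' tract voxels additionally carry FA, tract probability, a Watson-sampled
#' principal eigenvector, and the tract's `mean_R2_offset`.
#'
#' The build is fully deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return An object of class `gesse_phantom`: list with `labels`,
#'   `cc_section`, `M0`, `R2`, `R2prime`, `tract_id`, `tract_prob`, `FA`
#'   (arrays of `config$dim`), `pev` (4-D array, last dim 3), and `config`.
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  dm <- config$dim
  ctr <- (dm + 1) / 2
  ax <- dm / 2 - 2                      # brain ellipsoid semi-axes (voxels)
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  dx <- g$x - ctr[1]; dy <- g$y - ctr[2]; dz <- g$z - ctr[3]
  r <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2 + (dz / ax[3])^2)

  tt <- config$tissue_table
  lab_of <- function(cls) tt$label[match(cls, tt$class)]
  labels <- array(lab_of("background"), dm)
  labels[r <= 1]    <- lab_of("cortex")
  labels[r <= 0.88] <- lab_of("swm")
  labels[r <= 0.78] <- lab_of("dwm")
  labels[sqrt((dx / 3)^2 + (dy / 5)^2 + (dz / 2.5)^2) <= 1] <- lab_of("csf")

  nuclei <- list(caudate  = list(off = c(5, 8, 3),  rad = 3),
                 putamen  = list(off = c(9, 3, 1),  rad = 3),
                 pallidus = list(off = c(6, 1, -1), rad = 2.5),
                 thalamus = list(off = c(5, -5, 2), rad = 3.5))
  for (nm in names(nuclei)) {
    nu <- nuclei[[nm]]
    for (sgn in c(-1, 1)) {
      o <- nu$off * c(sgn, 1, 1)
      inside <- sqrt((dx - o[1])^2 + (dy - o[2])^2 + (dz - o[3])^2) <= nu$rad
      labels[inside] <- lab_of(nm)
    }
  }

  # midsagittal corpus-callosum arch (central 3 sagittal slices), four
  # tip-to-tip sections anterior -> posterior
  cc_section <- array(0L, dm)
  cc_a <- min(12, ax[2] * 0.55); cc_b <- min(8, ax[3] * 0.5)
  rho <- sqrt((dy / cc_a)^2 + (dz / cc_b)^2)
  phi <- atan2(dz / cc_b, dy / cc_a)    # 0 at anterior (+y) tip, pi posterior
  in_cc <- abs(dx) <= 1 & rho >= 0.72 & rho <= 1.04 & phi >= -0.1 &
    phi <= pi + 0.1 & labels[cbind(g$x, g$y, g$z)] %in%
      lab_of(c("swm", "dwm"))
  sec <- pmin(pmax(ceiling(4 * pmin(pmax(phi, 0), pi) / pi), 1L), 4L)
  labels[in_cc] <- CC_LABEL
  cc_section[cbind(g$x, g$y, g$z)[in_cc, , drop = FALSE]] <- sec[in_cc]

  # tract bundles: exact-count rectangular boxes packed into a lattice in
  # the lower deep-white-matter region
  tract_id_map <- array(0L, dm)
  n_tr <- length(config$tracts)
  if (n_tr > 0) {
    h <- floor(ax * 0.78 / sqrt(3))     # half-extent of inscribed dwm box
    if (any(h < 4)) stop_gesse("grid too small to host requested structures")
    max_n <- max(vapply(config$tracts, function(t) t$n_voxels, integer(1)))
    cw <- if (max_n >= 50) 5L else 3L
    blen <- ceiling(max_n / cw^2)
    cell <- c(cw + 1L, cw + 1L, blen + 1L)
    lo <- floor(ctr - h); span <- 2 * h
    slots <- floor(span / cell)
    if (prod(slots) < n_tr)
      stop_gesse("grid too small to host requested structures")
    slot_idx <- 0L
    for (tr in config$tracts) {
      sx <- slot_idx %% slots[1]
      sy <- (slot_idx %/% slots[1]) %% slots[2]
      sz <- slot_idx %/% (slots[1] * slots[2])
      slot_idx <- slot_idx + 1L
      orig <- lo + c(sx, sy, sz) * cell + 1L
      cells <- as.matrix(expand.grid(x = orig[1] + 0:(cw - 1L),
                                     y = orig[2] + 0:(cw - 1L),
                                     z = orig[3] + 0:(blen - 1L)))
      cells <- cells[seq_len(tr$n_voxels), , drop = FALSE]
      tract_id_map[cells] <- tr$tract_id
      labels[cells] <- TRACT_LABEL_BASE + tr$tract_id
    }
  }

  M0map <- array(tt$M0[match(labels, tt$label)], dm)
  R2map <- array(tt$R2[match(labels, tt$label)], dm)
  R2pmap <- array(tt$R2prime[match(labels, tt$label)], dm)
  # corpus callosum and tract bundles carry deep-white-matter tissue values
  wm_like <- labels == CC_LABEL | labels >= TRACT_LABEL_BASE
  M0map[wm_like]  <- tt$M0[tt$class == "dwm"]
  R2map[wm_like]  <- tt$R2[tt$class == "dwm"]
  R2pmap[wm_like] <- tt$R2prime[tt$class == "dwm"]
  # section-wise R2 offsets emulating the inverse association of R2 with
  # effective fiber diameter (genu: small fibers, high R2; isthmus: large
  # fibers, low R2)
  cc_offsets <- c(2, 0.5, -1.5, -0.5)
  ccv <- labels == CC_LABEL
  R2map[ccv] <- R2map[ccv] + cc_offsets[cc_section[ccv]]

  FAmap <- array(0, dm); probmap <- array(0, dm)
  pev <- array(0, c(dm, 3L))
  brain <- labels > 0
  FAmap[brain] <- runif(sum(brain), 0.05, 0.3)
  for (tr in config$tracts) {
    idx <- which(tract_id_map == tr$tract_id)
    n <- length(idx)
    ori <- sample_orientations(tr, n = n)
    FAmap[idx] <- runif(n, 0.45, 0.9)
    probmap[idx] <- runif(n, 0.35, 1)
    R2map[idx] <- R2map[idx] + tr$mean_R2_offset
    nvx <- prod(dm)
    pev[idx] <- ori[, 1]; pev[idx + nvx] <- ori[, 2]; pev[idx + 2 * nvx] <- ori[, 3]
  }

  structure(list(labels = labels, cc_section = cc_section, M0 = M0map,
                 R2 = R2map, R2prime = R2pmap, tract_id = tract_id_map,
                 tract_prob = probmap, FA = FAmap, pev = pev,
                 config = config),
            class = "gesse_phantom")
}

#' @export
print.gesse_phantom <- function(x, ...) {
  cat(sprintf("gesse_phantom: %s grid, %d tract bundles, seed %d\n",
              paste(x$config$dim, collapse = "x"),
              length(x$config$tracts), x$config$seed))
  invisible(x)
}

#' Simulate the echo-train acquisition of a phantom
#'
#' Evaluates the two-rate signal model (and the R2* FID model for the FID
#' section) for every grid voxel and optionally adds magnitude noise.
#'
#' @param phantom A [build_phantom()] result.
#' @param spec An [echo_train_spec()].
#' @param sections Echo sections to simulate.
#' @param sigma Noise SD (signal units); 0 disables noise.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param seed Integer seed for the noise.
#' @return An [echo_stack()] with `dim` set to the phantom grid.
#' @export
simulate_echo_stack <- function(phantom, spec = echo_train_spec(),
                                sections = c("rephase", "dephase"),
                                sigma = phantom$config$noise_sigma,
                                noise_model = "rician",
                                seed = phantom$config$seed + 1L) {
  stopifnot(inherits(phantom, "gesse_phantom"))
  te <- echo_times(spec, sections)
  sec <- attr(te, "section")
  te_s <- ms_to_s(as.numeric(te)); ste_s <- ms_to_s(spec$sTE)
  m0 <- as.numeric(phantom$M0); r2 <- as.numeric(phantom$R2)
  r2p <- as.numeric(phantom$R2prime)
  vals <- matrix(0, length(m0), length(te_s))
  for (j in seq_along(te_s)) {
    rate_te <- if (sec[j] == "fid") (r2 + r2p) * te_s[j]
               else r2 * te_s[j] + r2p * abs(te_s[j] - ste_s)
    vals[, j] <- m0 * exp(-rate_te)
  }
  stk <- echo_stack(vals, as.numeric(te), sec, dim = phantom$config$dim)
  if (sigma > 0) {
    set.seed(as.integer(seed))
    n <- length(stk$values)
    stk$values <- if (noise_model == "rician")
      sqrt((stk$values + rnorm(n, 0, sigma))^2 + matrix(rnorm(n, 0, sigma), nrow(stk$values))^2)
    else pmax(stk$values + rnorm(n, 0, sigma), 0)
  }
  stk
}

#' Fiber-voxel table constructor/validator
#'
#' One row per white-matter voxel: estimated R2, FA, tract id and
#' probability, principal-eigenvector components, and the tract diameter
#' index d.
#'
#' @param df data.frame with columns `voxel`, `R2`, `FA`, `tract_id`,
#'   `tract_prob`, `pev_x`, `pev_y`, `pev_z`, `d`.
#' @return The validated table with class `fiber_voxel_table`.
#' @export
fiber_voxel_table <- function(df) {
  need <- c("voxel", "R2", "FA", "tract_id", "tract_prob",
            "pev_x", "pev_y", "pev_z", "d")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_gesse("missing fiber_voxel_table columns: ", paste(miss, collapse = ", "))
  if (any(df$FA < 0 | df$FA > 1)) stop_gesse("FA must lie in [0, 1]")
  if (any(df$tract_prob < 0 | df$tract_prob > 1))
    stop_gesse("tract_prob must lie in [0, 1]")
  if (any(df$d <= 0)) stop_gesse("diameter index d must be positive")
  nrm <- sqrt(df$pev_x^2 + df$pev_y^2 + df$pev_z^2)
  if (any(abs(nrm - 1) > 1e-6)) stop_gesse("PEV rows must be unit vectors")
  class(df) <- unique(c("fiber_voxel_table", class(df)))
  df
}

#' Generate a synthetic fiber-voxel table under the orientation model
#'
#' Forward-simulates the multi-linear orientation/diameter model
#' `R2 = a0 + a1 (d - dbar) + a2 sin^4(alpha) + a3 (d - dbar) sin^4(alpha)`
#' plus Gaussian rate noise, on Watson-distributed per-voxel orientations.
#' `dbar` is the voxel-count-weighted mean diameter computed on the
#' generated table itself with [compute_dbar()], i.e. exactly the quantity
#' the downstream fit recomputes.  By default in-tract FA is drawn above
#' 0.4 and tract probability above 0.25, so the default table passes the
#' standard voxel selection unchanged.
#'
#' @param coeffs Numeric `c(a0, a1, a2, a3)` in 1/s (a1, a3 per micrometre).
#'   The default is a representative white-matter fit at 7 T.
#' @param tracts List of [tract_spec()]; at least 2 distinct diameters are
#'   required when `a1 != 0` or `a3 != 0`.
#' @param sigma Gaussian rate-noise SD, 1/s.
#' @param seed Integer seed (mandatory).
#' @param b0 Unit 3-vector of the main field.
#' @param fa_range,prob_range Uniform draw ranges for FA and tract
#'   probability of in-tract voxels.
#' @return A [fiber_voxel_table()].
#' @export
generate_voxel_table <- function(coeffs = c(a0 = 22.08, a1 = -6.06,
                                            a2 = 3.49, a3 = 0),
                                 tracts = default_tract_set(),
                                 sigma = 1.5, seed, b0 = c(0, 0, 1),
                                 fa_range = c(0.4, 0.95),
                                 prob_range = c(0.3, 1)) {
  if (missing(seed)) stop_gesse("'seed' is mandatory for generate_voxel_table")
  check_number(sigma, "sigma", 0)
  if (length(coeffs) != 4L) stop_gesse("'coeffs' must be c(a0, a1, a2, a3)")
  d_all <- vapply(tracts, function(t) t$diameter_index, numeric(1))
  if ((coeffs[2] != 0 || coeffs[4] != 0) && length(unique(d_all)) < 2L)
    stop_gesse("diameter effect is unidentifiable with fewer than 2 distinct tract diameters")
  set.seed(as.integer(seed))
  b0 <- as.numeric(unit_rows(b0))
  rows <- lapply(tracts, function(tr) {
    n <- tr$n_voxels
    ori <- sample_orientations(tr, n = n)
    data.frame(tract_id = tr$tract_id, d = tr$diameter_index,
               FA = runif(n, fa_range[1], fa_range[2]),
               tract_prob = runif(n, prob_range[1], prob_range[2]),
               pev_x = ori[, 1], pev_y = ori[, 2], pev_z = ori[, 3])
  })
  tab <- do.call(rbind, rows)
  tab$voxel <- seq_len(nrow(tab))
  alpha <- compute_alpha(as.matrix(tab[, c("pev_x", "pev_y", "pev_z")]), b0)
  s4 <- sin(alpha * pi / 180)^4
  dbar <- sum(tab$d) / nrow(tab)        # == compute_dbar on this table
  dc <- tab$d - dbar
  tab$R2 <- coeffs[1] + coeffs[2] * dc + coeffs[3] * s4 +
    coeffs[4] * dc * s4 + rnorm(nrow(tab), 0, sigma)
  fiber_voxel_table(tab[, c("voxel", "R2", "FA", "tract_id", "tract_prob",
                            "pev_x", "pev_y", "pev_z", "d")])
}

#' Write / read a fiber-voxel table as TSV
#'
#' @param table A [fiber_voxel_table()].
#' @param path TSV path.
#' @return `write_voxel_table` returns `path` invisibly; `read_voxel_table`
#'   the validated table.
#' @export
write_voxel_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path) {
  fiber_voxel_table(read.table(path, header = TRUE, sep = "\t"))
}
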