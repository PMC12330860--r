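#' Fiber-diameter histogram
#'
#' @param diameter_um Fiber diameters, micrometres (> 0).
#' @param frequency Counts or proportions (>= 0, not all zero).
#' @return An object of class `diameter_histogram`.
#' @export
diameter_histogram <- function(diameter_um, frequency) {
  diameter_um <- as.numeric(diameter_um); frequency <- as.numeric(frequency)
  if (length(diameter_um) != length(frequency) || length(diameter_um) == 0L)
    stop_gesse("'diameter_um' and 'frequency' must be matching non-empty vectors")
  if (any(diameter_um <= 0)) stop_gesse("diameters must be positive")
  if (any(frequency < 0) || all(frequency == 0))
    stop_gesse("frequencies must be >= 0 with at least one positive entry")
  structure(list(diameter_um = diameter_um, frequency = frequency),
            class = "diameter_histogram")
}

#' Read diameter histograms from CSV
#'
#' Expected columns: `diameter_um`, `frequency`, and optionally `section`;
#' with a `section` column one histogram per section is returned.
#'
#' @param path CSV file.
#' @return A `diameter_histogram`, or a named list of them per section.
#' @export
read_diameter_histogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("diameter_um", "frequency") %in% names(df)))
    stop_gesse("histogram CSV needs columns 'diameter_um' and 'frequency'")
  if ("section" %in% names(df)) {
    lapply(split(df, df$section),
           function(s) diameter_histogram(s$diameter_um, s$frequency))
  } else {
    diameter_histogram(df$diameter_um, df$frequency)
  }
}

#' Effective fiber diameter of a histogram
#'
#' The mean diameter weighted by cross-sectional area:
#' `d_eff = sum(f_i d_i^3) / sum(f_i d_i^2)`.  It is invariant to rescaling
#' of the frequencies, equivariant under rescaling of the diameters, and
#' bounded by the smallest and largest diameter present.
#'
#' @param hist A [diameter_histogram()], or a numeric vector of diameters
#'   when `frequency` is given separately.
#' @param frequency Optional frequencies matching a bare diameter vector.
#' @return Effective diameter, micrometres.
#' @examples
#' effective_diameter(diameter_histogram(c(1, 2), c(10, 10)))  # 1.8
#' @export
effective_diameter <- function(hist, frequency = NULL) {
  if (!inherits(hist, "diameter_histogram"))
    hist <- diameter_histogram(hist, frequency)
  sum(hist$frequency * hist$diameter_um^3) /
    sum(hist$frequency * hist$diameter_um^2)
}

encode3 <- function(m, base) {
  (m[, 1] - 1) + base[1] * ((m[, 2] - 1) + base[2] * (m[, 3] - 1))
}

mask_graph <- function(coords, base) {
  # 8-connected (2-D embedded in 3-D with flat third axis) lattice graph
  # with Euclidean edge weights
  key <- encode3(coords, base)
  idx <- seq_len(nrow(coords))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ed_from <- integer(0); ed_to <- integer(0); ed_w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, c(offs[k, 1], offs[k, 2], offs[k, 3]), "+")
    hit <- match(encode3(nb, base), key)
    ok <- !is.na(hit) & hit > idx        # each undirected edge once
    ed_from <- c(ed_from, idx[ok]); ed_to <- c(ed_to, hit[ok])
    ed_w <- c(ed_w, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
  }
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed_from, ed_to))
  igraph::E(g)$weight <- ed_w
  g
}

chamfer_dt <- function(m2) {
  # two-pass chamfer distance to the background (outside the matrix counts
  # as background); adequate for tip refinement on small masks
  nr <- nrow(m2) + 2L; nc <- ncol(m2) + 2L
  d <- matrix(0, nr, nc)
  d[2:(nr - 1), 2:(nc - 1)][m2] <- 1e9
  s2 <- sqrt(2)
  for (j in 2:(nc - 1)) for (i in 2:(nr - 1)) {
    if (d[i, j] == 0) next
    d[i, j] <- min(d[i, j], d[i - 1, j] + 1, d[i, j - 1] + 1,
                   d[i - 1, j - 1] + s2, d[i + 1, j - 1] + s2)
  }
  for (j in (nc - 1):2) for (i in (nr - 1):2) {
    if (d[i, j] == 0) next
    d[i, j] <- min(d[i, j], d[i + 1, j] + 1, d[i, j + 1] + 1,
                   d[i + 1, j + 1] + s2, d[i - 1, j + 1] + s2)
  }
  d[2:(nr - 1), 2:(nc - 1)]
}

#' Tip-to-tip four-section division of a corpus-callosum mask
#'
#' Divides a midsagittal corpus-callosum mask into four sections of equal
#' arc length along its medial curve, ordered anterior to posterior: genu,
#' anterior body, isthmus, splenium.  The two tips are found as the
#' endpoints of the geodesic diameter of the 8-connected voxel graph
#' (Euclidean edge weights); every voxel is assigned the normalized
#' geodesic coordinate `t = d_A / (d_A + d_P)` between the anterior (A) and
#' posterior (P) tips and sectioned at t = 0.25 / 0.5 / 0.75.  This
#' operationalizes "equal length" as equal medial arc length rather than
#' equal voxel count; an `equal_extent` alternative cuts the
#' anterior-posterior bounding extent into quarters instead.
#'
#' The first array dimension of the mask is taken as the anterior-posterior
#' axis (low index = anterior).  A 3-D mask is collapsed across its third
#' dimension (sagittal slice stack) and the 2-D sectioning is replicated on
#' every slice.
#'
#' @param mask Logical 2-D matrix or 3-D array; must form a single
#'   8-connected component and not degenerate to a line.
#' @param method `"arc_length"` (default) or `"equal_extent"`.
#' @return Object of class `callosum_sectioning`: `section` (integer array
#'   like `mask`, 1 = genu ... 4 = splenium, 0 outside), `labels`,
#'   `arc_length` (voxel units), `tips` (2 x 2 matrix of tip coordinates),
#'   `method`.
#' @export
section_callosum <- function(mask, method = c("arc_length", "equal_extent")) {
  method <- match.arg(method)
  dm <- dim(mask)
  collapse <- length(dm) == 3L
  m2 <- if (collapse) apply(mask, c(1, 2), any) else mask
  if (!any(m2)) stop_gesse("empty mask")
  coords2 <- which(m2, arr.ind = TRUE)
  if (nrow(coords2) < 8L)
    stop_gesse("mask too small to section")
  cc <- sweep(coords2, 2, colMeans(coords2))
  if (min(svd(cc)$d) < 1e-6)
    stop_gesse("degenerate (line-like) mask cannot be sectioned")
  coords <- cbind(coords2, 1L)
  base <- c(max(coords2[, 1]) + 2L, max(coords2[, 2]) + 2L, 2L)
  g <- mask_graph(coords, base)
  if (igraph::components(g)$no != 1L)
    stop_gesse("mask must be a single connected component")

  d0 <- igraph::distances(g, v = 1)[1, ]
  v1 <- which.max(d0)
  d1 <- igraph::distances(g, v = v1)[1, ]
  v2 <- which.max(d1)
  d2 <- igraph::distances(g, v = v2)[1, ]
  # refine each geodesic-diameter endpoint to the most interior voxel of
  # its end region, so tips sit on the medial curve rather than on corners
  dtv <- chamfer_dt(m2)[coords2]
  delta <- max(2, max(dtv))
  refine <- function(d_other, anchor) {
    cand <- which(d_other >= d_other[anchor] - delta)
    cand[which.max(dtv[cand])]
  }
  v1 <- refine(d2, v1)
  v2 <- refine(d1, v2)
  d1 <- igraph::distances(g, v = v1)[1, ]
  d2 <- igraph::distances(g, v = v2)[1, ]
  # anterior tip = lower index along the anterior-posterior (first) axis
  if (coords2[v1, 1] <= coords2[v2, 1]) {
    tipA <- v1; tipP <- v2; dA <- d1; dP <- d2
  } else {
    tipA <- v2; tipP <- v1; dA <- d2; dP <- d1
  }
  arc <- dA[tipP]
  tcoord <- switch(method,
    arc_length = dA / (dA + dP),
    equal_extent = {
      ap <- coords2[, 1]
      (ap - min(ap)) / max(1e-12, diff(range(ap)))
    })
  sec2 <- findInterval(tcoord, c(0.25, 0.5, 0.75)) + 1L

  section <- array(0L, dim = dm)
  if (collapse) {
    sec_plane <- matrix(0L, dm[1], dm[2])
    sec_plane[coords2] <- sec2
    for (k in seq_len(dm[3])) {
      sl <- mask[, , k]
      section[, , k][sl] <- sec_plane[sl]
    }
  } else {
    section[coords2] <- sec2
  }
  structure(list(section = section,
                 labels = c("genu", "anterior_body", "isthmus", "splenium"),
                 arc_length = arc,
                 tips = coords2[c(tipA, tipP), , drop = FALSE],
                 t = tcoord, method = method),
            class = "callosum_sectioning")
}

#' Per-section R2 statistics and association with effective diameter
#'
#' Summarizes an R2 map over the four callosum sections (optionally over a
#' selection of central sagittal slices) and, when per-section effective
#' diameters are supplied, reports the Pearson and Spearman association of
#' the section means with d_eff.
#'
#' @param R2_map Numeric array matching the geometry of
#'   `sectioning$section`, or a 3-D array from which `slices` along the
#'   third dimension are analyzed with a 2-D sectioning.
#' @param sectioning A [section_callosum()] result.
#' @param d_eff Optional numeric vector of effective diameters
#'   (micrometres), one per section in anterior-to-posterior order.
#' @param slices Optional slice indices (third dimension) to include when
#'   `R2_map` is 3-D and the sectioning is 2-D; defaults to the central 3.
#' @return List with `stats` (data.frame: section, label, n, mean, sd) and
#'   `association` (`pearson`, `spearman`, `defined`) when `d_eff` given.
#' @export
section_stats <- function(R2_map, sectioning, d_eff = NULL, slices = NULL) {
  stopifnot(inherits(sectioning, "callosum_sectioning"))
  sec <- sectioning$section
  if (length(dim(R2_map)) == 3L && length(dim(sec)) == 2L) {
    nz <- dim(R2_map)[3]
    if (is.null(slices)) {
      mid <- ceiling(nz / 2)
      slices <- intersect((mid - 1):(mid + 1), seq_len(nz))
    }
    R2_map <- R2_map[, , slices, drop = FALSE]
    sec <- array(rep(sec, length(slices)), dim = dim(R2_map))
  }
  if (!all(dim(R2_map) == dim(sec)))
    stop_gesse("R2 map and sectioning geometries do not match")
  stats <- do.call(rbind, lapply(1:4, function(s) {
    v <- R2_map[sec == s]
    v <- v[is.finite(v)]
    data.frame(section = s, label = sectioning$labels[s], n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }))
  out <- list(stats = stats)
  if (!is.null(d_eff)) {
    if (length(d_eff) != 4L) stop_gesse("'d_eff' must have one value per section")
    m <- stats$mean
    defined <- all(is.finite(m)) && sd(m) > 1e-12 && sd(d_eff) > 1e-12
    out$association <- list(
      pearson = if (defined) cor(m, d_eff, method = "pearson") else NA_real_,
      spearman = if (defined) cor(m, d_eff, method = "spearman") else NA_real_,
      defined = defined)
  }
  out
}
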