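# Shared fixture builders and independent oracles (built in code, no files).

default_spec <- echo_train_spec()

# manual fiber-voxel table with orientations at prescribed alpha (degrees)
table_from_alpha <- function(alpha_deg, R2, tract_id = 1L, d = 4,
                             FA = 0.8, prob = 0.9) {
  n <- length(alpha_deg)
  a <- alpha_deg * pi / 180
  fiber_voxel_table(data.frame(
    voxel = seq_len(n), R2 = rep_len(R2, n), FA = rep_len(FA, n),
    tract_id = rep_len(tract_id, n), tract_prob = rep_len(prob, n),
    pev_x = sin(a), pev_y = 0, pev_z = cos(a), d = rep_len(d, n)))
}

# independent Bellman-Ford geodesic distances on an 8-connected 2-D mask
# (deliberately naive; used only as an oracle on tiny masks)
brute_geodesic <- function(mask, source_rc) {
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  dist <- rep(Inf, n)
  src <- which(coords[, 1] == source_rc[1] & coords[, 2] == source_rc[2])
  dist[src] <- 0
  edges <- NULL
  for (i in seq_len(n)) {
    dd <- abs(sweep(coords, 2, coords[i, ]))
    nb <- which(dd[, 1] <= 1 & dd[, 2] <= 1 & (dd[, 1] + dd[, 2]) > 0)
    edges <- rbind(edges, cbind(i, nb, sqrt(dd[nb, 1]^2 + dd[nb, 2]^2)))
  }
  repeat {
    relaxed <- dist[edges[, 1]] + edges[, 3]
    new <- pmin(dist, tapply(c(relaxed, dist), c(edges[, 2], seq_len(n)), min)[as.character(seq_len(n))])
    if (all(abs(new - dist) < 1e-12)) break
    dist <- as.numeric(new)
  }
  list(coords = coords, dist = dist)
}

# random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# closed-form CDF of sin^4(alpha) for uniformly random axial directions:
# |cos(alpha)| ~ U(0,1) so P(sin^4 <= y) = 1 - sqrt(1 - sqrt(y))
sin4_uniform_cdf <- function(y) 1 - sqrt(pmax(0, 1 - sqrt(y)))
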