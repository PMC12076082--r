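# Independent brute-force oracles used to cross-check the package's
# optimised implementations.

# All-pairs intermolecular contact enumeration under the minimum-image
# convention (strict < cutoff), via full n x n distance matrices.
brute_contact_pairs <- function(xyz, mol, box, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(xyz[, k], xyz[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  hit <- d2 < cutoff^2 & outer(mol, mol, "!=") & upper.tri(d2)
  idx <- which(hit, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  matrix(as.integer(idx), ncol = 2L)
}

# Exhaustive Triangle threshold: histogram, peak-to-farthest-tail line,
# per-bin perpendicular point-line distance, written from the geometric
# definition.
brute_triangle <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  idx <- pmin(n_bins, pmax(1L, findInterval(v, breaks,
                                            rightmost.closed = TRUE)))
  h <- tabulate(idx, nbins = n_bins)
  centres <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  peak <- which.max(h)
  ne <- which(h > 0L)
  tail_bin <- if ((ne[length(ne)] - peak) >= (peak - ne[1L])) {
    ne[length(ne)]
  } else {
    ne[1L]
  }
  p1 <- c(peak, h[peak]); p2 <- c(tail_bin, h[tail_bin])
  best <- NA_integer_; best_d <- -Inf
  for (b in seq(min(peak, tail_bin), max(peak, tail_bin))) {
    num <- abs((p2[2] - p1[2]) * (b - p1[1]) -
                 (p2[1] - p1[1]) * (h[b] - p1[2]))
    d <- num / sqrt(sum((p2 - p1)^2))
    if (d > best_d) { best_d <- d; best <- b }
  }
  centres[best]
}

# Deterministic synthetic trajectory builders for hand-checked frames.
toy_trajectory <- function(frames, mol, box = c(100, 100, 100),
                           mass = NULL, temperature = 300) {
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1L]])
  if (is.null(mass)) mass <- rep(110, n)
  slab_trajectory(frames, mol = mol, mass = mass, box = box,
                  temperature = temperature)
}
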