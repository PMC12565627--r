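# Independent brute-force oracles, deliberately naive.

# Exhaustive peak finder: strict-neighbour local maxima (left-most index of a
# plateau), prominence by exhaustive valley search to the nearest strictly
# higher point on each side, then greedy min-distance pruning by descending
# height. O(n^2); independent of find_peaks_core's run-length/greedy code.
oracle_peaks <- function(y, prominence_min = 0, min_distance = 1L) {
  n <- length(y)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] <= y[i - 1]) next
    # walk a potential plateau to the right
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    if (j < n && y[j + 1] < y[i]) cand <- c(cand, i)
  }
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    hi_l <- which(left > h)
    lmin <- if (length(hi_l)) min(left[(max(hi_l) + 1):(i - 1)]) else min(left)
    right <- y[(i + 1):n]
    hi_r <- which(right > h)
    rmin <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence_min
  cand <- cand[keep]; prom <- prom[keep]
  ord <- order(-y[cand], -prom, cand)
  kept <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - cand[kept]) >= min_distance)) kept <- c(kept, j)
  }
  sort(cand[kept])
}

# Hand step-up BH for cross-checking
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Write a 2-D matrix as a 16-bit TIFF of integer intensities (0..65535)
write_test_tiff <- function(m, path) {
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16, compression = "none")
  path
}

make_sidecar <- function(path, px = NULL, py = NULL, shape = NULL) {
  meta <- list()
  if (!is.null(px)) meta$pixel_size_x_um <- px
  if (!is.null(py)) meta$pixel_size_y_um <- py
  if (!is.null(shape)) meta$shape <- shape
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
}
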