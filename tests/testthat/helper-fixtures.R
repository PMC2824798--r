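# Small rasters and pattern fixtures built in code.

# raster from a dense 0/1 matrix given as rows of strings, e.g. "0101"
raster_from_strings <- function(rows) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  raster_from_matrix(m)
}

# random binary pattern matrix with nonempty rows
random_patterns <- function(n, d, p = 0.2, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * d, 1, p), n, d)
    if (all(rowSums(m) > 0)) return(m)
  }
}

# similarity matrix with two planted perfect blocks, rows interleaved
interleaved_two_block_patterns <- function(per_block = 4, d = 40) {
  a <- c(rep(1L, d / 2), rep(0L, d / 2))
  b <- c(rep(0L, d / 2), rep(1L, d / 2))
  rows <- vector("list", 2 * per_block)
  for (i in seq_len(per_block)) {
    rows[[2 * i - 1]] <- a
    rows[[2 * i]] <- b
  }
  do.call(rbind, rows)
}

# direct, loop-based Jaccard for use as an independent oracle
jaccard_oracle <- function(x, y) {
  inter <- sum(x == 1 & y == 1)
  uni <- sum(x == 1 | y == 1)
  inter / uni
}

# direct cell-averaging contrast oracle (diagonal inside boxes)
contrast_oracle <- function(s, starts, ends) {
  n <- nrow(s)
  inside <- matrix(FALSE, n, n)
  for (b in seq_along(starts)) {
    idx <- starts[b]:ends[b]
    inside[idx, idx] <- TRUE
  }
  d_in <- mean(s[inside])
  d_out <- if (any(!inside)) mean(s[!inside]) else 0
  d_in - d_out
}
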