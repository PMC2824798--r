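#' Channel-to-grid coordinate map
#'
#' Channels index the 60 electrodes of an 8 x 8 array whose four corners are
#' absent. Channel `c` (0-based) occupies the `(c+1)`-th non-corner position
#' of the grid in row-major order; the returned value is the 0-based
#' position in the unfolded 1 x 64 frame vector.
#'
#' @param n_channels number of channels; 60 uses the corner-free 8 x 8 map,
#'   other values fall back to an identity map padded to the next multiple
#'   of 64 only when <= 64.
#' @return Integer vector: 0-based unfolded coordinate per channel.
#' @export
grid_coordinates <- function(n_channels = 60) {
  if (n_channels == 60L || n_channels == 60) {
    corners <- c(0L, 7L, 56L, 63L)
    setdiff(0:63, corners)
  } else if (n_channels <= 64) {
    seq_len(n_channels) - 1L
  } else {
    stop("grid map defined for at most 64 channels", call. = FALSE)
  }
}

#' Unfold an avalanche into a binary pattern vector
#'
#' Each 8 x 8 frame becomes a 1 x 64 row-major vector (corner coordinates
#' always zero); an avalanche of length L concatenates its L frame vectors
#' into one binary vector of length 64 L, frame order preserved.
#'
#' @param avalanches an [find_avalanches()] result.
#' @param id avalanche id.
#' @return Integer 0/1 vector of length `64 * length`; its sum equals the
#'   avalanche size.
#' @export
unfold <- function(avalanches, id) {
  stopifnot(inherits(avalanches, "avalanche_set"))
  row <- avalanches[avalanches$id == id, ]
  if (!nrow(row)) stop("unknown avalanche id", call. = FALSE)
  ev <- attr(avalanches, "events")
  ev <- ev[ev$id == id, ]
  coords <- grid_coordinates(attr(avalanches, "n_channels"))
  v <- integer(64L * row$length)
  frame <- ev$bin - row$start_bin
  v[frame * 64L + coords[ev$channel + 1L] + 1L] <- 1L
  v
}

#' Pattern matrix for all avalanches of one length
#'
#' @param avalanches an [find_avalanches()] result.
#' @param length avalanche length L to select.
#' @param ids optional subset of avalanche ids (all of that length if NULL).
#' @return Binary integer matrix, one unfolded avalanche per row; rownames
#'   are avalanche ids.
#' @export
pattern_matrix <- function(avalanches, length, ids = NULL) {
  stopifnot(inherits(avalanches, "avalanche_set"))
  sel <- avalanches[avalanches$length == length, ]
  if (!is.null(ids)) sel <- sel[sel$id %in% ids, ]
  ev <- attr(avalanches, "events")
  build_pattern_matrix(sel, ev[ev$id %in% sel$id, ], length,
                       attr(avalanches, "n_channels"))
}

# sel: avalanche rows of one length; ev: exactly their events
build_pattern_matrix <- function(sel, ev, length, n_channels) {
  n <- nrow(sel)
  coords <- grid_coordinates(n_channels)
  m <- matrix(0L, n, 64L * length, dimnames = list(sel$id, NULL))
  if (!n) return(m)
  rowi <- match(ev$id, sel$id)
  frame <- ev$bin - sel$start_bin[rowi]
  m[cbind(rowi, frame * 64L + coords[ev$channel + 1L] + 1L)] <- 1L
  m
}

#' Boolean (Jaccard) similarity of two binary pattern vectors
#'
#' `S(X, Y) = <X,Y> / (<X,X> + <Y,Y> - <X,Y>)`: the size of the
#' intersection of the two active-coordinate sets divided by the size of
#' their union. Ranges from 0 (disjoint) to 1 (identical support).
#'
#' @param x,y binary vectors of equal length, not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
boolean_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("pattern vectors must have equal dimension", call. = FALSE)
  inter <- sum(x * y)
  union <- sum(x * x) + sum(y * y) - inter
  if (union == 0)
    stop("similarity undefined for two all-zero vectors", call. = FALSE)
  inter / union
}

#' All-pairs similarity matrix for equal-length patterns
#'
#' @param patterns binary matrix, one pattern per row (>= 2 rows).
#' @return Symmetric N x N matrix of class `similarity_matrix` with unit
#'   diagonal and entries in `[0, 1]`.
#' @export
similarity_matrix <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L)
    stop("need at least 2 patterns", call. = FALSE)
  a <- tcrossprod(patterns * 1.0)          # <X_i, X_j>
  sz <- diag(a)
  if (any(sz == 0))
    stop("all-zero pattern row: similarity undefined", call. = FALSE)
  s <- a / (outer(sz, rep(1, length(sz))) + outer(rep(1, length(sz)), sz) - a)
  dimnames(s) <- dimnames(a)
  class(s) <- c("similarity_matrix", class(s))
  s
}

pattern_hclust <- function(s) {
  stats::hclust(stats::as.dist(1 - unclass(s)), method = "average")
}

#' Order a similarity matrix by hierarchical clustering
#'
#' Average-linkage agglomerative clustering on distance `1 - S`; the
#' returned permutation is the dendrogram leaf order, which places mutually
#' similar avalanches adjacently so groups appear as dark diagonal blocks.
#' Deterministic (ties broken by merge order of `stats::hclust`).
#'
#' @param s a [similarity_matrix()].
#' @return Integer permutation of `1..N`.
#' @export
order_matrix <- function(s) {
  pattern_hclust(s)$order
}

check_boxes <- function(boxes, n) {
  boxes <- boxes[order(boxes$start), , drop = FALSE]
  if (boxes$start[1] != 1L || boxes$end[nrow(boxes)] != n ||
      any(boxes$start > boxes$end) ||
      (nrow(boxes) > 1L && any(boxes$start[-1] != boxes$end[-nrow(boxes)] + 1L)))
    stop("boxes must be a contiguous partition of 1..N", call. = FALSE)
  boxes
}

#' Contrast of a box grouping
#'
#' For contiguous index ranges ("boxes") partitioning the ordered matrix,
#' `D_in` is the mean similarity over all cells `(r, c)` with `r` and `c` in
#' the same box (diagonal included), `D_out` the mean over all remaining
#' cells (0 when no cell lies outside), and the contrast is `D_in - D_out`.
#' Maximal when boxes are dark and the surround is light.
#'
#' @param s an (ordered) [similarity_matrix()].
#' @param boxes data frame with columns `start`, `end` (1-based, inclusive)
#'   forming a contiguous partition of `1..N`.
#' @return List with `d_in`, `d_out`, `contrast`.
#' @export
contrast <- function(s, boxes) {
  s <- unclass(s)
  n <- nrow(s)
  boxes <- check_boxes(boxes, n)
  s_in <- 0; c_in <- 0
  for (b in seq_len(nrow(boxes))) {
    idx <- boxes$start[b]:boxes$end[b]
    s_in <- s_in + sum(s[idx, idx])
    c_in <- c_in + length(idx)^2
  }
  tot <- sum(s)
  c_out <- n^2 - c_in
  d_in <- s_in / c_in
  d_out <- if (c_out > 0) (tot - s_in) / c_out else 0
  list(d_in = d_in, d_out = d_out, contrast = d_in - d_out)
}

# Summed-area table: sat[i+1, j+1] = sum(s[1:i, 1:j]); block sums in O(1).
make_sat <- function(s) {
  n <- nrow(s)
  sat <- matrix(0, n + 1L, n + 1L)
  sat[-1L, -1L] <- t(apply(apply(s, 2L, cumsum), 1L, cumsum))
  sat
}

block_sum <- function(sat, r0, r1, c0, c1) {
  sat[r1 + 1L, c1 + 1L] - sat[r0, c1 + 1L] - sat[r1 + 1L, c0] + sat[r0, c0]
}


#' Contrast-maximizing grouping of an ordered similarity matrix
#'
#' Candidate partitions are those induced by cutting the average-linkage
#' dendrogram at each merge level (every cluster of such a cut is contiguous
#' in the leaf order), plus the trivial one-box partition. Boxes smaller
#' than `min_box` are merged with their more similar neighbor before
#' scoring. The candidate maximizing the contrast function is returned;
#' exhaustive enumeration of all contiguous partitions is available for
#' small N via `exhaustive = TRUE`.
#'
#' @param s a [similarity_matrix()] (unordered; ordering is computed here so
#'   that the dendrogram and leaf order are mutually consistent).
#' @param min_box smallest allowed box (default 2: singleton boxes are
#'   degenerate under a contrast whose interiors include the diagonal).
#' @param exhaustive if TRUE (N <= 14), score every contiguous partition of
#'   the leaf order instead of only dendrogram cuts.
#' @return List of class `grouping`: `order` (leaf permutation), `boxes`
#'   (data frame `start`, `end`, `n_members`, `mean_similarity` — the mean
#'   pairwise off-diagonal similarity within the box, in ordered
#'   coordinates), `member_ids` (list of original row indices per box),
#'   `d_in`, `d_out`, `contrast`.
#' @export
best_grouping <- function(s, min_box = 2, exhaustive = FALSE) {
  su <- unclass(s)
  n <- nrow(su)
  hc <- pattern_hclust(s)
  ord <- hc$order
  so <- su[ord, ord]
  sat <- make_sat(so)

  cand <- list(n)                           # trivial one-box partition
  if (exhaustive) {
    if (n > 14L) stop("exhaustive search limited to N <= 14", call. = FALSE)
    for (mask in seq_len(2^(n - 1L)) - 1L) {
      cutpts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
      cand[[length(cand) + 1L]] <- c(cutpts, n)
    }
  } else {
    memb <- stats::cutree(hc, k = seq_len(n))[ord, , drop = FALSE]
    for (k in seq(2L, length.out = max(0L, n - 1L))) {
      mo <- memb[, k]
      cand[[length(cand) + 1L]] <- c(which(mo[-1L] != mo[-n]), n)
    }
  }

  best <- best_candidate_cpp(sat, cand, as.integer(min_box))
  bounds <- list(start = best$start, end = best$end)
  mean_sim <- vapply(seq_along(bounds$start), function(b) {
    m <- bounds$end[b] - bounds$start[b] + 1L
    if (m < 2L) return(NA_real_)
    (block_sum(sat, bounds$start[b], bounds$end[b],
               bounds$start[b], bounds$end[b]) - m) / (m * (m - 1L))
  }, numeric(1))
  member_ids <- lapply(seq_along(bounds$start), function(b)
    ord[bounds$start[b]:bounds$end[b]])
  boxes <- data.frame(start = bounds$start, end = bounds$end,
                      n_members = bounds$end - bounds$start + 1L,
                      mean_similarity = mean_sim)
  structure(list(order = ord, boxes = boxes, member_ids = member_ids,
                 d_in = best$d_in, d_out = best$d_out,
                 contrast = best$contrast),
            class = "grouping")
}

#' @export
print.grouping <- function(x, ...) {
  cat(sprintf("grouping: %d boxes over %d patterns, contrast %.4f (D_in %.4f, D_out %.4f)\n",
              nrow(x$boxes), length(x$order), x$contrast, x$d_in, x$d_out))
  invisible(x)
}
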