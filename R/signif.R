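#' Shuffle-test configuration
#'
#' @param n_shuffles number of surrogate data sets (default 20; a data group
#'   beating all of them corresponds to p < 0.05).
#' @param seed integer seed for the surrogate generator.
#' @return List of class `shuffle_config`.
#' @export
shuffle_config <- function(n_shuffles = 20, seed = 1L) {
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  structure(list(n_shuffles = n_shuffles, seed = as.integer(seed)),
            class = "shuffle_config")
}

#' Constrained shuffle of an event raster
#'
#' The most stringent surrogate scheme: activity on a given channel may move
#' only to another time bin on the same channel, and only to bins where at
#' least one *other* channel was active in the original raster. This
#' preserves each channel's event count exactly and (approximately) the
#' network's temporal burst profile. Target bins are sampled without
#' replacement per channel; if a channel has more events than eligible bins,
#' the surplus events keep their original bins.
#'
#' @param raster an [event_raster()].
#' @param seed integer seed.
#' @return A shuffled [event_raster()] of the same dimensions.
#' @export
constrained_shuffle <- function(raster, seed = NULL) {
  stopifnot(inherits(raster, "event_raster"))
  if (!length(raster$bin)) return(raster)
  if (!is.null(seed)) set.seed(seed)
  new_bin <- integer(length(raster$bin))
  # eligible bins for channel e: active bins minus those where e was the
  # only active channel (the raster is binary, so a channel contributes at
  # most one event per bin)
  active <- unique(raster$bin)
  n_in_bin <- tabulate(match(raster$bin, active), nbins = length(active))
  multi <- active[n_in_bin > 1L]
  single_idx <- match(raster$bin, active) %in% which(n_in_bin == 1L)
  single_bin <- raster$bin[single_idx]
  single_ch <- raster$channel[single_idx]
  for (ch in sort(unique(raster$channel))) {
    mine <- which(raster$channel == ch)
    eligible <- c(multi, single_bin[single_ch != ch])
    n_ev <- length(mine)
    if (length(eligible) >= n_ev) {
      new_bin[mine] <- eligible[sample.int(length(eligible), n_ev)]
    } else {
      # fill every eligible bin; surplus events stay in place, drawn from
      # events whose original bin is not eligible so no collision arises
      keepable <- mine[!(raster$bin[mine] %in% eligible)]
      n_surplus <- n_ev - length(eligible)
      kept <- keepable[sample.int(length(keepable), n_surplus)]
      placed <- setdiff(mine, kept)
      new_bin[placed] <- eligible[sample.int(length(eligible))]
      new_bin[kept] <- raster$bin[kept]
    }
  }
  event_raster(new_bin, raster$channel, raster$n_channels, raster$n_bins,
               raster$bin_ms)
}

# Per-length grouping of one raster: returns, for each length in `lengths`
# with >= 2 avalanches, the best grouping plus the selected avalanche ids.
group_by_length <- function(raster, lengths, min_box, cap, seed = NULL) {
  av <- find_avalanches(raster)
  ev <- attr(av, "events")
  ev_len <- av$length[ev$id]            # ids are consecutive 1..nrow(av)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (L in lengths) {
    ids <- av$id[av$length == L]
    if (length(ids) < 2L) next
    capped <- FALSE
    ev_sub <- ev[ev_len == L, ]
    if (is.finite(cap) && length(ids) > cap) {
      ids <- sort(ids[sample.int(length(ids), cap)])
      capped <- TRUE
      ev_sub <- ev_sub[ev_sub$id %in% ids, ]
    }
    pm <- build_pattern_matrix(av[match(ids, av$id), ], ev_sub, L,
                               attr(av, "n_channels"))
    s <- similarity_matrix(pm)
    g <- best_grouping(s, min_box = min_box)
    out[[as.character(L)]] <- list(length = L, grouping = g, ids = ids,
                                   n_avalanches = length(ids), capped = capped)
  }
  out
}

#' Detect statistically significant groups of repeating avalanches
#'
#' Runs the full pattern pipeline (unfold, Jaccard similarity matrix,
#' dendrogram ordering, contrast-maximizing grouping) on the data raster and
#' on `n_shuffles` constrained-shuffle surrogates, separately for each
#' avalanche length. A data group is flagged significant when its mean
#' pairwise similarity strictly exceeds that of *every* group of the same
#' length found in *all* surrogate sets (with 20 surrogates, p < 0.05); ties
#' are not significant.
#'
#' @param raster an [event_raster()].
#' @param lengths avalanche lengths to analyze (default 2:9).
#' @param shuffle_cfg a [shuffle_config()].
#' @param min_box smallest allowed group (see [best_grouping()]).
#' @param cap per-length random subsample ceiling on the number of patterns
#'   entering the N x N computation (default 500; `Inf` disables). Applied
#'   identically to data and surrogates.
#' @return Data frame of class `significance_report` with one row per data
#'   group: `length`, `group`, `n_members`, `mean_similarity`,
#'   `shuffle_max`, `significant`; attribute `groupings` holds the per-length
#'   data groupings (with member avalanche ids), attribute `seeds` the
#'   surrogate seeds used.
#' @export
significant_groups <- function(raster, lengths = 2:9,
                               shuffle_cfg = shuffle_config(),
                               min_box = 2, cap = 500) {
  stopifnot(inherits(raster, "event_raster"),
            inherits(shuffle_cfg, "shuffle_config"))
  set.seed(shuffle_cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      2L * shuffle_cfg$n_shuffles + 1L)
  data_groups <- group_by_length(raster, lengths, min_box, cap,
                                 seed = seeds[1L])

  # pooled shuffle-group mean similarities per length
  shuffle_sims <- stats::setNames(
    replicate(length(lengths), numeric(0), simplify = FALSE),
    as.character(lengths))
  for (s in seq_len(shuffle_cfg$n_shuffles)) {
    sr <- constrained_shuffle(raster, seed = seeds[2L * s])
    sg <- group_by_length(sr, lengths, min_box, cap, seed = seeds[2L * s + 1L])
    for (nm in names(sg)) {
      ms <- sg[[nm]]$grouping$boxes$mean_similarity
      shuffle_sims[[nm]] <- c(shuffle_sims[[nm]], ms[!is.na(ms)])
    }
  }

  rows <- list()
  for (nm in names(data_groups)) {
    g <- data_groups[[nm]]$grouping
    thr <- if (length(shuffle_sims[[nm]])) max(shuffle_sims[[nm]]) else -Inf
    for (b in seq_len(nrow(g$boxes))) {
      ms <- g$boxes$mean_similarity[b]
      if (is.na(ms)) next
      rows[[length(rows) + 1L]] <- data.frame(
        length = as.integer(nm), group = b,
        n_members = g$boxes$n_members[b],
        mean_similarity = ms, shuffle_max = thr,
        significant = ms > thr)
    }
  }
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(length = integer(), group = integer(), n_members = integer(),
               mean_similarity = numeric(), shuffle_max = numeric(),
               significant = logical())
  structure(rep, groupings = data_groups, seeds = seeds,
            class = c("significance_report", "data.frame"))
}

#' Write a significance report as delimited text
#'
#' @param report a [significant_groups()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_significance_report <- function(report, path) {
  stopifnot(inherits(report, "significance_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
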