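#' Extract neuronal avalanches from an event raster
#'
#' An avalanche is a maximal run of consecutively active frames (time bins
#' with at least one event) preceded and terminated by a blank frame. Runs
#' touching the first or last bin of the raster are discarded because their
#' bounding blank frame is unobserved. Length is the number of frames, size
#' the total number of events.
#'
#' @param raster an [event_raster()].
#' @return A data frame of class `avalanche_set` with one row per avalanche
#'   (`id`, `start_bin`, `length`, `size`) and attributes `events` (the
#'   events belonging to each avalanche: `bin`, `channel`, `id`) and
#'   `n_channels`. Empty rasters give zero rows.
#' @export
find_avalanches <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  empty <- function() {
    structure(data.frame(id = integer(), start_bin = integer(),
                         length = integer(), size = integer()),
              events = data.frame(bin = integer(), channel = integer(),
                                  id = integer()),
              n_channels = raster$n_channels, class = c("avalanche_set", "data.frame"))
  }
  if (!length(raster$bin)) return(empty())
  active <- unique(raster$bin)            # sorted: events are bin-ordered
  counts <- tabulate(match(raster$bin, active), nbins = length(active))
  run_start <- c(TRUE, diff(active) > 1L)
  run_id <- cumsum(run_start)
  starts <- active[run_start]
  ends <- active[c(run_start[-1], TRUE)]
  keep <- starts > 0L & ends < raster$n_bins - 1L  # edge truncation
  lens <- (ends - starts + 1L)
  sizes <- as.integer(rowsum(counts, run_id, reorder = TRUE))
  kept <- which(keep)
  if (!length(kept)) return(empty())
  av <- data.frame(id = seq_along(kept),
                   start_bin = starts[kept],
                   length = lens[kept],
                   size = sizes[kept])
  # map each event to its run, then to the kept avalanche id (0 = dropped)
  ev_run <- run_id[match(raster$bin, active)]
  id_of_run <- integer(max(run_id))
  id_of_run[kept] <- seq_along(kept)
  ev_id <- id_of_run[ev_run]
  evs <- data.frame(bin = raster$bin[ev_id > 0L],
                    channel = raster$channel[ev_id > 0L],
                    id = ev_id[ev_id > 0L])
  structure(av, events = evs, n_channels = raster$n_channels,
            class = c("avalanche_set", "data.frame"))
}

#' Frames of one avalanche
#'
#' @param avalanches an [find_avalanches()] result.
#' @param id avalanche id.
#' @return List of integer vectors, one per frame, each the sorted 0-based
#'   channels active in that frame.
#' @export
avalanche_frames <- function(avalanches, id) {
  stopifnot(inherits(avalanches, "avalanche_set"))
  row <- avalanches[avalanches$id == id, ]
  if (!nrow(row)) stop("unknown avalanche id", call. = FALSE)
  ev <- attr(avalanches, "events")
  ev <- ev[ev$id == id, ]
  lapply(seq_len(row$length) - 1L, function(f)
    sort(ev$channel[ev$bin == row$start_bin + f]))
}

#' Empirical avalanche size distribution
#'
#' @param avalanches an [find_avalanches()] result with at least one row.
#' @return A data frame (`size`, `probability`) of class `size_distribution`;
#'   probabilities sum to 1.
#' @export
size_distribution <- function(avalanches) {
  stopifnot(inherits(avalanches, "avalanche_set"))
  if (!nrow(avalanches))
    stop("no avalanches: cannot form a size distribution", call. = FALSE)
  tab <- table(avalanches$size)
  out <- data.frame(size = as.integer(names(tab)),
                    probability = as.numeric(tab) / sum(tab))
  class(out) <- c("size_distribution", "data.frame")
  out
}

#' Log-log least-squares slope of a size distribution
#'
#' Fits `log10 P(S) ~ log10 S` by ordinary least squares over the support
#' restricted to `[s_min, s_max]`, the straight-line regime below the
#' finite-size cutoff of the 60-channel array. A critical branching process
#' gives a slope near -3/2.
#'
#' @param dist a [size_distribution()].
#' @param s_min,s_max inclusive size window for the fit (defaults 3 and 30).
#' @return The fitted slope (a real number).
#' @export
powerlaw_slope <- function(dist, s_min = 3, s_max = 30) {
  stopifnot(inherits(dist, "size_distribution"))
  sel <- dist$size >= s_min & dist$size <= s_max & dist$probability > 0
  if (sum(sel) < 3L)
    stop("need at least 3 support points with positive mass in [s_min, s_max]",
         call. = FALSE)
  fit <- stats::lm(log10(probability) ~ log10(size), data = dist[sel, ])
  unname(stats::coef(fit)[2])
}

#' Detect threshold crossings in continuous multichannel traces
#'
#' Per channel, the threshold is `mean - threshold_sd * sd` of that channel's
#' signal. Each maximal contiguous sub-threshold excursion yields one event
#' at the time of its most negative sample; event times are assigned to
#' `bin_ms` bins.
#'
#' @param traces numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz.
#' @param threshold_sd threshold in channel standard deviations (default 3).
#' @param bin_ms bin width in milliseconds (default 4).
#' @return An [event_raster()] with `ceiling(samples / samples_per_bin)`
#'   bins.
#' @export
detect_threshold_events <- function(traces, sample_rate, threshold_sd = 3,
                                    bin_ms = 4) {
  traces <- as.matrix(traces)
  if (!length(traces) || !all(is.finite(traces)))
    stop("traces must be a non-empty finite numeric matrix", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  samples_per_bin <- sample_rate * bin_ms / 1000
  n_bins <- as.integer(ceiling(ncol(traces) / samples_per_bin))
  bins <- integer(); chans <- integer()
  for (ch in seq_len(nrow(traces))) {
    x <- traces[ch, ]
    thr <- mean(x) - threshold_sd * stats::sd(x)
    below <- x < thr
    if (!any(below)) next
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(r$values)) {
      i0 <- starts[seg]; i1 <- ends[seg]
      peak <- i0 + which.min(x[i0:i1]) - 1L
      b <- as.integer(floor((peak - 1L) / samples_per_bin))
      bins <- c(bins, b); chans <- c(chans, ch - 1L)
    }
  }
  event_raster(bins, chans, n_channels = nrow(traces), n_bins = n_bins,
               bin_ms = bin_ms)
}
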