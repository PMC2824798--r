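#' Synthetic LFP traces with known event times
#'
#' Generates continuous multichannel voltage traces as Gaussian baseline
#' noise plus injected negative half-cosine peaks of the kind produced by
#' near-synchronous population spikes (about 20 ms wide), together with the
#' ground-truth event raster, so the threshold detector can be validated
#' end to end.
#'
#' @param event_schedule data frame with columns `channel` (0-based) and
#'   `time_s` (peak center, seconds).
#' @param duration_s trace duration in seconds.
#' @param noise_sd baseline noise standard deviation.
#' @param peak_amp peak depth (positive number; the peak reaches
#'   `-peak_amp`).
#' @param peak_width_ms full width of the half-cosine peak (default 20).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param n_channels number of channels (default 60).
#' @param bin_ms bin width for the ground-truth raster.
#' @param seed noise seed.
#' @return List with `traces` (channels x samples matrix) and `truth` (an
#'   [event_raster()] holding one event per scheduled peak, in the bin of
#'   the peak minimum).
#' @export
gen_lfp_traces <- function(event_schedule, duration_s, noise_sd = 1,
                           peak_amp = 10, peak_width_ms = 20,
                           sample_rate = 1000, n_channels = 60, bin_ms = 4,
                           seed = 1L) {
  n_samples <- as.integer(round(duration_s * sample_rate))
  if (nrow(event_schedule) &&
      (any(event_schedule$time_s < 0) || any(event_schedule$time_s > duration_s)))
    stop("scheduled times must lie within the trace duration", call. = FALSE)
  half_w <- peak_width_ms / 2000            # half width in seconds
  if (nrow(event_schedule)) {
    o <- order(event_schedule$channel, event_schedule$time_s)
    es <- event_schedule[o, ]
    same <- diff(es$time_s) < 2 * half_w & diff(es$channel) == 0
    if (any(same))
      stop("overlapping peaks on one channel closer than the peak width",
           call. = FALSE)
  }
  set.seed(seed)
  traces <- matrix(stats::rnorm(n_channels * n_samples, sd = noise_sd),
                   n_channels, n_samples)
  w_samples <- max(3L, as.integer(round(peak_width_ms / 1000 * sample_rate)))
  shape <- -peak_amp * 0.5 * (1 - cos(2 * pi * seq_len(w_samples) / (w_samples + 1L)))
  bins <- integer(); chans <- integer()
  for (i in seq_len(nrow(event_schedule))) {
    ch <- event_schedule$channel[i] + 1L
    center <- as.integer(round(event_schedule$time_s[i] * sample_rate))
    i0 <- max(1L, center - w_samples %/% 2L)
    i1 <- min(n_samples, i0 + w_samples - 1L)
    traces[ch, i0:i1] <- traces[ch, i0:i1] + shape[seq_len(i1 - i0 + 1L)]
    peak <- i0 + which.min(traces[ch, i0:i1]) - 1L
    bins <- c(bins, as.integer(floor((peak - 1L) / (sample_rate * bin_ms / 1000))))
    chans <- c(chans, ch - 1L)
  }
  n_bins <- as.integer(ceiling(n_samples / (sample_rate * bin_ms / 1000)))
  list(traces = traces,
       truth = event_raster(bins, chans, n_channels, n_bins, bin_ms))
}

#' Specification for a planted-template raster
#'
#' @param n_templates number of distinct avalanche templates.
#' @param template_length frames per template.
#' @param template_size total events per template.
#' @param n_repeats noisy copies planted per template.
#' @param flip_prob probability that each template event is relocated to a
#'   random empty cell of its own frame in a given copy (in `[0, 0.5)`);
#'   event count and frame occupancy are preserved.
#' @param background_p_spont spontaneous rate of the critical background
#'   model whose cascades fill the gaps between planted copies.
#' @param total_bins raster length in bins.
#' @param n_channels channels (default 60).
#' @param seed integer seed.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(n_templates = 3, template_length = 4,
                       template_size = 12, n_repeats = 20, flip_prob = 0.02,
                       background_p_spont = 0.005, total_bins = 20000,
                       n_channels = 60, seed = 1L) {
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must lie in [0, 0.5)", call. = FALSE)
  if (template_size < template_length)
    stop("template_size must be >= template_length (nonempty frames)",
         call. = FALSE)
  structure(list(n_templates = as.integer(n_templates),
                 template_length = as.integer(template_length),
                 template_size = as.integer(template_size),
                 n_repeats = as.integer(n_repeats),
                 flip_prob = flip_prob,
                 background_p_spont = background_p_spont,
                 total_bins = as.integer(total_bins),
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

# one template: length x n_channels 0/1 matrix, every frame nonempty
draw_template <- function(len, size, n_channels) {
  m <- matrix(0L, len, n_channels)
  # one event per frame first, remainder spread at random
  for (f in seq_len(len)) m[f, sample.int(n_channels, 1L)] <- 1L
  free <- which(m == 0L)
  extra <- size - len
  if (extra > 0L) m[free[sample.int(length(free), extra)]] <- 1L
  m
}

# Each template event relocates, with probability flip_prob, to a uniformly
# chosen empty cell of its own frame; size and frame occupancy are
# preserved, so copies share general (not exact) resemblance.
noisy_copy <- function(template, flip_prob) {
  copy <- template
  for (f in seq_len(nrow(copy))) {
    evs <- which(copy[f, ] == 1L)
    move <- evs[stats::runif(length(evs)) < flip_prob]
    for (ch in move) {
      free <- which(copy[f, ] == 0L)
      if (!length(free)) next
      copy[f, ch] <- 0L
      copy[f, free[sample.int(length(free), 1L)]] <- 1L
    }
  }
  copy
}

#' Generate a raster with planted, noisily repeated avalanche templates
#'
#' Plants `n_repeats` noisy copies of each of `n_templates` avalanche
#' templates at random positions, each flanked by blank guard bins so the
#' avalanche detector recovers it with known boundaries, amid background
#' cascades drawn from the critical branching model (sigma = 1). Returns the
#' member-to-template labels for end-to-end ground-truth checks.
#'
#' @param spec a [plant_spec()].
#' @return List with `raster` (an [event_raster()]) and `labels` (data frame
#'   `start_bin`, `template`, one row per planted copy).
#' @export
gen_planted_raster <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  n_cop <- spec$n_templates * spec$n_repeats
  slot_len <- spec$template_length + 2L      # copy plus blank guards
  if (n_cop * slot_len * 2L > spec$total_bins)
    stop("total_bins too small for the requested planted content",
         call. = FALSE)
  templates <- lapply(seq_len(spec$n_templates), function(i)
    draw_template(spec$template_length, spec$template_size, spec$n_channels))

  # background from the critical branching model
  bg_cfg <- model_config(n_units = spec$n_channels,
                         p_spont = spec$background_p_spont,
                         n_steps = spec$total_bins,
                         seed = spec$seed + 1L)
  bg_net <- build_network(bg_cfg)
  bg <- simulate_network(bg_net, bg_cfg, seed = spec$seed + 2L)
  m <- raster_matrix(bg)

  # non-overlapping slots for the copies
  n_slots <- spec$total_bins %/% slot_len
  slots <- sort(sample.int(n_slots, n_cop))
  labels <- data.frame(start_bin = integer(n_cop), template = integer(n_cop))
  k <- 0L
  for (tpl in seq_len(spec$n_templates)) {
    for (rep_i in seq_len(spec$n_repeats)) {
      k <- k + 1L
      lo <- (slots[k] - 1L) * slot_len + 1L   # 1-based slot start
      copy <- noisy_copy(templates[[tpl]], spec$flip_prob)
      m[, lo:(lo + slot_len - 1L)] <- 0L      # guard bins blank out background
      m[, (lo + 1L):(lo + spec$template_length)] <- t(copy)
      labels$start_bin[k] <- lo               # 0-based bin of first frame
      labels$template[k] <- tpl
    }
  }
  list(raster = raster_from_matrix(m), labels = labels)
}

#' Declining stand-in reference group-length distribution
#'
#' An exponentially declining distribution `P(L) proportional to
#' exp(-decay (L - 2))` over L = 2..9, emulating the observed decline in the
#' probability of significant groups with avalanche length. Serves as the
#' shipped reference when no user-supplied (L, probability) table is given.
#'
#' @param decay positive decay rate per unit length.
#' @return A [group_length_distribution()], strictly decreasing.
#' @export
gen_reference_distribution <- function(decay) {
  if (length(decay) != 1L || is.na(decay) || decay <= 0)
    stop("decay must be a single positive number", call. = FALSE)
  group_length_distribution(exp(-decay * (0:7)))
}
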