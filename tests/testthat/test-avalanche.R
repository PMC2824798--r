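test_that("avalanche extraction matches the worked frame example (length 5, size 9)", {
  # blank, then frames with 2,3,1,2,1 active channels, then blank
  m <- matrix(0L, 8, 7)
  m[1:2, 2] <- 1L; m[3:5, 3] <- 1L; m[6, 4] <- 1L; m[c(2, 7), 5] <- 1L; m[8, 6] <- 1L
  av <- find_avalanches(raster_from_matrix(m))
  expect_equal(nrow(av), 1L)
  expect_equal(av$length, 5L)
  expect_equal(av$size, 9L)
  expect_equal(av$start_bin, 1L)
})

test_that("avalanche extraction partitions interior events and drops edge-touching runs", {
  expect_equal(nrow(find_avalanches(event_raster(integer(), integer(), 8, 20))), 0L)

  set.seed(42)
  for (trial in 1:20) {
    m <- matrix(rbinom(10 * 60, 1, 0.12), 10, 60)
    r <- raster_from_matrix(m)
    av <- find_avalanches(r)
    # brute-force oracle: runs of nonempty columns, interior only
    col_active <- colSums(m) > 0
    runs <- rle(col_active)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    keep <- runs$values & starts > 1L & ends < ncol(m)
    expect_equal(nrow(av), sum(keep))
    expect_equal(av$length, unname(ends - starts + 1L)[keep])
    expect_equal(av$size,
                 unname(vapply(which(keep), function(k)
                   sum(m[, starts[k]:ends[k]]), numeric(1))))
    # conservation: interior events equal the sum of avalanche sizes
    interior <- sum(vapply(which(keep), function(k)
      sum(m[, starts[k]:ends[k]]), numeric(1)))
    expect_equal(sum(av$size), interior)
    # every nonempty interior column belongs to exactly one avalanche
    ev <- attr(av, "events")
    cols <- unique(ev$bin)
    owner <- tapply(ev$id, ev$bin, function(x) length(unique(x)))
    expect_true(all(owner == 1L))
  }
})

test_that("size distribution is a normalized empirical pmf", {
  av <- structure(data.frame(id = 1:3, start_bin = c(1L, 5L, 9L),
                             length = c(1L, 1L, 2L), size = c(3L, 3L, 5L)),
                  events = data.frame(bin = integer(), channel = integer(),
                                      id = integer()),
                  n_channels = 60, class = c("avalanche_set", "data.frame"))
  d <- size_distribution(av)
  expect_equal(d$probability[d$size == 3], 2 / 3)
  expect_equal(d$probability[d$size == 5], 1 / 3)
  expect_equal(sum(d$probability), 1)
  expect_error(size_distribution(find_avalanches(event_raster(integer(), integer(), 8, 20))))
})

test_that("power-law slope recovers exact exponents", {
  s <- 1:30
  exact <- data.frame(size = s, probability = s^(-1.5) / sum(s^(-1.5)))
  class(exact) <- c("size_distribution", "data.frame")
  expect_equal(powerlaw_slope(exact), -1.5, tolerance = 1e-10)
  unif <- data.frame(size = 1:10, probability = rep(0.1, 10))
  class(unif) <- c("size_distribution", "data.frame")
  expect_equal(powerlaw_slope(unif, 1, 10), 0, tolerance = 1e-10)
  few <- data.frame(size = c(3, 5), probability = c(0.5, 0.5))
  class(few) <- c("size_distribution", "data.frame")
  expect_error(powerlaw_slope(few))
})

test_that("lower branching parameter yields smaller avalanches (subcritical ordering)", {
  mean_size <- function(sigma, seed) {
    cfg <- model_config(sigma_target = sigma, n_steps = 30000, seed = seed)
    net <- build_network(cfg)
    av <- find_avalanches(simulate_network(net, cfg, seed = seed + 1000L))
    mean(av$size)
  }
  sizes <- vapply(1:10, function(s) c(mean_size(0.8, s), mean_size(1.0, s)),
                  numeric(2))
  expect_true(all(sizes[1, ] < sizes[2, ]))
})

test_that("threshold detector finds injected peaks and ignores quiet traces", {
  # flat zero trace with one injected negative half-cosine 20 ms peak
  tr <- matrix(0, 1, 1000)
  shape <- -10 * 0.5 * (1 - cos(2 * pi * (1:20) / 21))
  tr[1, 301:320] <- shape
  r <- detect_threshold_events(tr, sample_rate = 1000)
  expect_equal(length(r$bin), 1L)
  peak_sample <- 300 + which.min(shape)
  expect_equal(r$bin, as.integer(floor((peak_sample - 1) / 4)))

  # trace never crossing threshold: pure mild noise has excursions, but a
  # constant trace has none
  expect_length(detect_threshold_events(matrix(1, 2, 500), 1000)$bin, 0L)

  # two-channel synthetic traces: recovered events match generator truth
  sched <- data.frame(channel = c(0L, 0L, 1L),
                      time_s = c(0.25, 0.61, 0.40))
  g <- gen_lfp_traces(sched, duration_s = 1, noise_sd = 0.5, peak_amp = 10,
                      n_channels = 2, seed = 9)
  det <- detect_threshold_events(g$traces, sample_rate = 1000)
  expect_identical(det$bin, g$truth$bin)
  expect_identical(det$channel, g$truth$channel)
})
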