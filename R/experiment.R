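#' Run the model repeatedly at one weighting exponent
#'
#' Builds `n_runs` independent networks at exponent `B`, simulates each, and
#' extracts significant groups at avalanche lengths 2-9. Topology and
#' dynamics use separate seeds derived from `seed` so each run is fully
#' reproducible. Length-1 avalanches have no temporal extent and are
#' excluded; significant groups longer than 9 frames are not observed at
#' these scales.
#'
#' @param B weighting-function exponent.
#' @param n_runs independent runs (the full protocol uses 10).
#' @param config a [model_config()]; its `exponent_B` is overridden by `B`.
#' @param shuffle_cfg a [shuffle_config()]; its seed is re-derived per run.
#' @param lengths avalanche lengths analyzed (default 2:9).
#' @param cap per-length pattern subsample ceiling (see
#'   [significant_groups()]).
#' @param min_box smallest allowed group.
#' @param seed master seed for the condition.
#' @return List of per-run [significant_groups()] reports (class
#'   `condition_result`), with `B` and the per-run seeds as attributes.
#' @export
run_condition <- function(B, n_runs = 10, config = model_config(),
                          shuffle_cfg = shuffle_config(),
                          lengths = 2:9, cap = 500, min_box = 2,
                          seed = config$seed) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_runs),
                      ncol = 3L, dimnames = list(NULL, c("topology", "dynamics", "shuffle")))
  reports <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$exponent_B <- B
    cfg$seed <- run_seeds[r, "topology"]
    net <- build_network(cfg)
    raster <- simulate_network(net, cfg, seed = run_seeds[r, "dynamics"])
    sc <- shuffle_cfg
    sc$seed <- run_seeds[r, "shuffle"]
    reports[[r]] <- significant_groups(raster, lengths = lengths,
                                       shuffle_cfg = sc, min_box = min_box,
                                       cap = cap)
  }
  structure(reports, B = B, seeds = run_seeds, class = "condition_result")
}

#' Group-length distribution pooled over runs
#'
#' Counts significant groups per avalanche length L = 2..9, pooled over all
#' reports, and normalizes to probabilities. With zero significant groups
#' the distribution is all-zero and carries attribute `empty = TRUE`.
#'
#' @param reports a [run_condition()] result or list of
#'   [significant_groups()] reports.
#' @return A [group_length_distribution()] with attribute `n_groups` (total
#'   significant groups).
#' @export
length_distribution <- function(reports) {
  if (inherits(reports, "significance_report")) reports <- list(reports)
  counts <- stats::setNames(numeric(8L), as.character(2:9))
  for (rep in reports) {
    sig <- rep[rep$significant, , drop = FALSE]
    if (!nrow(sig)) next
    tab <- table(factor(sig$length, levels = 2:9))
    counts <- counts + as.numeric(tab)
  }
  out <- group_length_distribution(counts)
  attr(out, "n_groups") <- sum(counts)
  out
}

#' Sum-of-squares error between two group-length distributions
#'
#' @param p,q distributions over the same support L = 2..9.
#' @return `sum((p - q)^2)`, non-negative, zero iff identical.
#' @export
sse <- function(p, q) {
  if (length(p) != length(q))
    stop("distributions must share the same support", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("distributions must share the same support", call. = FALSE)
  sum((as.numeric(p) - as.numeric(q))^2)
}

#' Sweep the weighting exponent B
#'
#' For each B: run the model `n_runs` times, pool significant groups into a
#' group-length distribution, compare it to `reference` by sum-of-squares
#' error, and count the total significant groups. Reports the good-fit set
#' (SSE at or below `fit_threshold`, the intrinsic variability of paired
#' reference data sets), the best-fit B (minimum SSE) and the optimal B
#' (maximum total groups; smallest B on ties, all tied values listed).
#'
#' @param B_values exponents to test (default 0.4 to 4.0 in steps of 0.4).
#' @param reference a [group_length_distribution()] over L = 2..9, e.g. from
#'   [read_reference()] or [gen_reference_distribution()].
#' @param fit_threshold good-fit SSE ceiling (default 0.016).
#' @param config base [model_config()].
#' @param n_runs runs per B.
#' @param shuffle_cfg a [shuffle_config()].
#' @param cap per-length pattern subsample ceiling.
#' @param min_box smallest allowed group.
#' @param seed master seed; per-B seeds are derived from it.
#' @return Data frame of class `sweep_result`: one row per B with `B`,
#'   `n_groups`, `sse`, `good_fit` and `P2`..`P9` (the pooled group-length
#'   probabilities). Attributes: `best_fit_B`, `optimal_B` (smallest
#'   maximizer), `optimal_B_all` (all maximizers), `good_fit_B`,
#'   `reference`, `n_runs`, `n_steps`, `seeds`.
#' @export
sweep_exponent <- function(B_values = seq(0.4, 4.0, by = 0.4), reference,
                           fit_threshold = 0.016, config = model_config(),
                           n_runs = 10, shuffle_cfg = shuffle_config(),
                           cap = 500, min_box = 2, seed = config$seed) {
  if (missing(reference) || is.null(reference))
    stop("a reference group-length distribution is required", call. = FALSE)
  if (length(B_values) < 2L)
    stop("need at least two B values to sweep", call. = FALSE)
  reference <- group_length_distribution(as.numeric(reference))
  set.seed(seed)
  b_seeds <- sample.int(.Machine$integer.max - 1L, length(B_values))
  rows <- vector("list", length(B_values))
  for (i in seq_along(B_values)) {
    reports <- run_condition(B_values[i], n_runs = n_runs, config = config,
                             shuffle_cfg = shuffle_cfg, cap = cap,
                             min_box = min_box, seed = b_seeds[i])
    dist <- length_distribution(reports)
    rows[[i]] <- data.frame(B = B_values[i],
                            n_groups = attr(dist, "n_groups"),
                            sse = sse(dist, reference),
                            t(as.numeric(dist)))
  }
  out <- do.call(rbind, rows)
  names(out)[seq(4L, 11L)] <- paste0("P", 2:9)
  out$good_fit <- out$sse <= fit_threshold
  maxima <- out$B[out$n_groups == max(out$n_groups)]
  structure(out,
            best_fit_B = out$B[which.min(out$sse)],
            optimal_B = min(maxima),
            optimal_B_all = maxima,
            good_fit_B = out$B[out$good_fit],
            reference = reference,
            fit_threshold = fit_threshold,
            n_runs = n_runs, n_steps = config$n_steps,
            seeds = b_seeds,
            class = c("sweep_result", "data.frame"))
}

#' Write a sweep result and its manifest
#'
#' Writes the per-B table as CSV and a JSON manifest (seeds, protocol sizes,
#' reference distribution, headline B values) from which the sweep can be
#' reproduced exactly.
#'
#' @param x a [sweep_exponent()] result.
#' @param dir output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_sweep_result <- function(x, dir) {
  stopifnot(inherits(x, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab_path <- file.path(dir, "sweep.csv")
  utils::write.csv(as.data.frame(x), tab_path, row.names = FALSE)
  manifest <- list(
    n_runs = attr(x, "n_runs"), n_steps = attr(x, "n_steps"),
    fit_threshold = attr(x, "fit_threshold"),
    seeds = attr(x, "seeds"),
    reference = as.numeric(attr(x, "reference")),
    best_fit_B = attr(x, "best_fit_B"),
    optimal_B = attr(x, "optimal_B"),
    optimal_B_all = attr(x, "optimal_B_all"),
    good_fit_B = attr(x, "good_fit_B"))
  man_path <- file.path(dir, "sweep_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tab_path, man_path))
}
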