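#' Configuration for the branching network model
#'
#' The model represents a 60-electrode array as 60 binary units. Each unit
#' connects to `out_degree` other units; the probabilities on those
#' connections follow an exponentially skewed profile controlled by
#' `exponent_B` (see [weight_profile()]) and are scaled so that every unit's
#' branching parameter equals `sigma_target` (1 = critical). Units fire
#' spontaneously with probability `p_spont` per bin and are refractory for
#' `refractory_steps` bins after firing. One simulated hour at 4-ms bins is
#' 900,000 steps.
#'
#' @param n_units number of units/channels (default 60).
#' @param out_degree outgoing connections per unit (default 10).
#' @param exponent_B non-negative skew exponent of the weighting function;
#'   0 gives a homogeneous profile.
#' @param p_spont per-unit per-bin spontaneous activation probability.
#' @param refractory_steps bins of enforced silence after an activation.
#' @param sigma_target branching parameter per unit, in `[0, out_degree]`.
#' @param n_steps number of 4-ms bins to simulate.
#' @param bin_ms bin width in milliseconds (metadata).
#' @param seed integer seed for network construction.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_units = 60, out_degree = 10, exponent_B = 0,
                         p_spont = 0.005, refractory_steps = 5,
                         sigma_target = 1, n_steps = 900000, bin_ms = 4,
                         seed = 1L) {
  cfg <- list(n_units = as.integer(n_units), out_degree = as.integer(out_degree),
              exponent_B = exponent_B, p_spont = p_spont,
              refractory_steps = as.integer(refractory_steps),
              sigma_target = sigma_target, n_steps = as.integer(n_steps),
              bin_ms = bin_ms, seed = as.integer(seed))
  if (cfg$p_spont < 0 || cfg$p_spont > 1)
    stop("p_spont must lie in [0, 1]", call. = FALSE)
  if (cfg$out_degree >= cfg$n_units)
    stop("out_degree must be smaller than n_units", call. = FALSE)
  if (cfg$out_degree < 1L) stop("out_degree must be >= 1", call. = FALSE)
  if (cfg$refractory_steps < 0L)
    stop("refractory_steps must be >= 0", call. = FALSE)
  if (cfg$n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  if (cfg$exponent_B < 0) stop("exponent_B must be >= 0", call. = FALSE)
  if (cfg$sigma_target < 0 || cfg$sigma_target > cfg$out_degree)
    stop("sigma_target must lie in [0, out_degree]", call. = FALSE)
  class(cfg) <- "model_config"
  cfg
}

#' Exponential connection-weight profile
#'
#' Assigns a unit's `k` outgoing transmission probabilities by rank:
#' `w_r = exp(-B r) / sum_m exp(-B m)`, `r = 1..k`. At `B = 0` the profile is
#' homogeneous (`1/k`); larger `B` concentrates mass on a few strong
#' connections. The profile always sums to 1; [build_network()] rescales it
#' by the target branching parameter.
#'
#' @param B non-negative skew exponent.
#' @param k number of connections (>= 1).
#' @return Numeric vector of `k` probabilities summing to 1, non-increasing
#'   in rank (strictly decreasing when `B > 0`).
#' @examples
#' weight_profile(0, 10)     # ten 0.1s
#' weight_profile(1.6, 2)    # c(0.832, 0.168) approximately
#' @export
weight_profile <- function(B, k) {
  if (length(B) != 1L || is.na(B) || B < 0)
    stop("B must be a single non-negative number", call. = FALSE)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single integer >= 1", call. = FALSE)
  # subtract B so exp() stays in range for large B; normalization cancels it
  w <- exp(-B * (seq_len(k) - 1))
  w / sum(w)
}

#' Build a fixed random weighted network
#'
#' Every unit receives `out_degree` distinct, non-self targets chosen
#' uniformly at random. Its outgoing probabilities are
#' `weight_profile(exponent_B, out_degree) * sigma_target`, assigned to the
#' targets in random order, then fixed. Deterministic given `config$seed`.
#'
#' @param config a [model_config()].
#' @return A list of class `weighted_network` with integer matrix `targets`
#'   (n_units x out_degree, 0-based) and numeric matrix `probs`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "model_config"))
  n <- config$n_units
  k <- config$out_degree
  w <- weight_profile(config$exponent_B, k) * config$sigma_target
  if (any(w > 1))
    stop("sigma_target too large: a transmission probability would exceed 1",
         call. = FALSE)
  targets <- matrix(0L, n, k)
  probs <- matrix(0, n, k)
  set.seed(config$seed)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    targets[i, ] <- cand[sample.int(length(cand), k)] - 1L
    probs[i, ] <- w[sample.int(k)]
  }
  structure(list(targets = targets, probs = probs,
                 n_units = n, out_degree = k,
                 exponent_B = config$exponent_B,
                 sigma_target = config$sigma_target),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d units, out-degree %d, B = %g, sigma = %g\n",
              x$n_units, x$out_degree, x$exponent_B, x$sigma_target))
  invisible(x)
}

#' Branching parameter of a unit
#'
#' The sum of transmission probabilities leaving unit `unit`: the expected
#' number of descendants an isolated activation of that unit produces.
#'
#' @param network a [build_network()] result.
#' @param unit 1-based unit index.
#' @return The branching parameter, a value in `[0, out_degree]`.
#' @export
branching_parameter <- function(network, unit) {
  stopifnot(inherits(network, "weighted_network"))
  unit <- as.integer(unit)
  if (length(unit) != 1L || is.na(unit) || unit < 1L || unit > network$n_units)
    stop("unknown unit index", call. = FALSE)
  sum(network$probs[unit, ])
}

#' Simulate the stochastic branching dynamics
#'
#' Runs the network for `config$n_steps` 4-ms bins. At every step each
#' non-refractory unit activates spontaneously with probability `p_spont` or
#' if any incoming connection from a unit active at the previous step
#' transmits (`rand <= p_ij`, independent draws, OR rule). Activation at `t`
#' makes the unit refractory during `t+1 .. t+refractory_steps`. The initial
#' state is all-inactive unless `init_active` forces units on at bin 0.
#'
#' @param network a [build_network()] result.
#' @param config a [model_config()] with matching `n_units`.
#' @param seed dynamics seed (independent of the topology seed so topology
#'   can be held fixed across dynamical replicates); defaults to
#'   `config$seed + 1`.
#' @param init_active integer vector of 1-based units forced active at bin 0.
#' @return An [event_raster()] of `n_units x n_steps`.
#' @export
simulate_network <- function(network, config, seed = NULL,
                             init_active = integer()) {
  stopifnot(inherits(network, "weighted_network"),
            inherits(config, "model_config"))
  if (network$n_units != config$n_units)
    stop("network and config disagree on n_units", call. = FALSE)
  if (is.null(seed)) seed <- config$seed + 1L
  init0 <- as.integer(init_active) - 1L
  if (length(init0) && (min(init0) < 0L || max(init0) >= config$n_units))
    stop("init_active out of range", call. = FALSE)
  set.seed(seed)
  ev <- simulate_branching_cpp(network$targets, network$probs,
                               config$n_steps, config$p_spont,
                               config$refractory_steps, init0)
  r <- event_raster(ev$bin, ev$channel,
                    n_channels = config$n_units, n_bins = config$n_steps,
                    bin_ms = config$bin_ms)
  attr(r, "seed") <- as.integer(seed)
  r
}
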