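# Agent-based Monte Carlo simulation with random sequential updating. The
# compiled inner loop performs N elementary updates per Monte Carlo step;
# the reported order parameter for finite populations is <|m|> because
# symmetry-restoring flips drive <m> itself to zero over long runs.

#' Simulation configuration
#'
#' Bundles model parameters with run-control settings and a seed. The seed
#' drives four independent substreams (target choice, response kind, panel
#' sampling, independence coin), so runs are reproducible and the mirror
#' symmetry of the dynamics is preserved draw-for-draw.
#'
#' @param params A `"qv_params"` object with finite `N`.
#' @param m0 Initial magnetization; `N * (1 + m0) / 2` must be an integer.
#'   Ignored when `opinions` is supplied.
#' @param opinions Optional explicit initial opinion vector of length `N`.
#' @param duration Run length in Monte Carlo steps (N elementary updates each).
#' @param burn_in MCS discarded before sampling; default 20% of `duration`.
#' @param thin Record one sample every `thin` MCS.
#' @param seed Single integer seed.
#' @return Object of class `"qv_sim_config"`.
#' @export
simulation_config <- function(params, m0 = 1, opinions = NULL,
                              duration = 1000, burn_in = NULL, thin = 1,
                              seed = 1) {
  stopifnot(inherits(params, "qv_params"))
  if (!is.finite(params$N))
    stop("'params' must have a finite population size N for simulation", call. = FALSE)
  if (is.null(burn_in)) burn_in <- floor(0.2 * duration)
  if (burn_in < 0 || duration <= burn_in)
    stop("'duration' must exceed 'burn_in' and 'burn_in' must be >= 0", call. = FALSE)
  if (thin < 1 || thin != round(thin))
    stop("'thin' must be a positive integer", call. = FALSE)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (is.null(opinions)) {
    opinions <- configuration_from_m(params$N, m0)
  } else {
    opinions <- new_configuration(opinions)
    if (length(opinions) != params$N)
      stop("'opinions' must have length N", call. = FALSE)
  }
  structure(list(params = params, opinions = as.integer(opinions),
                 m0 = magnetization(attr(opinions, "n_up"), params$N),
                 duration = duration, burn_in = burn_in, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "qv_sim_config")
}

#' One elementary update (reference implementation)
#'
#' Pure-R single elementary step used for unit-level validation of the
#' compiled engine: picks a uniform target, draws the response kind with
#' probabilities `(1-p, p(1-z), pz)`, samples a panel of `q` distinct
#' non-target agents when needed, and applies [apply_response()]. Uses R's
#' global RNG.
#'
#' @param config A `"qv_config"` opinion vector.
#' @param params A `"qv_params"` object with finite `N`.
#' @return The updated `"qv_config"`.
#' @export
step_opinion <- function(config, params) {
  stopifnot(inherits(config, "qv_config"), inherits(params, "qv_params"))
  N <- params$N
  target <- sample.int(N, 1)
  u_kind <- stats::runif(1)
  kind <- if (u_kind < 1 - params$p) "conformity"
          else if (u_kind < 1 - params$p * params$z) "anticonformity"
          else "independence"
  new_op <- if (kind == "independence") {
    apply_response(config[target], integer(0), "independence",
                   u = stats::runif(1))
  } else {
    panel_idx <- sample(setdiff(seq_len(N), target), params$q)
    apply_response(config[target], as.integer(config)[panel_idx], kind,
                   r = params$r, w = params$w)
  }
  if (new_op != config[target]) {
    ops <- as.integer(config)
    ops[target] <- new_op
    new_configuration(ops)
  } else config
}

#' Run a Monte Carlo simulation
#'
#' Executes the compiled agent-based dynamics: `duration` Monte Carlo steps
#' of `N` elementary updates each, recording the magnetization after burn-in
#' at the thinning interval and (optionally) the visited-state histogram.
#' Deterministic given the seed in the configuration.
#'
#' @param config A `"qv_sim_config"` object.
#' @param record_histogram If `TRUE`, also tally how many post-burn-in MCS
#'   end in each up count `n = 0..N`.
#' @param mirror_independence Internal testing switch: mirrors the
#'   independence coin (`u -> 1 - u`), which together with a negated initial
#'   configuration reproduces the globally flipped trajectory exactly.
#' @return Object of class `"qv_trajectory"`: a data frame with columns
#'   `t_mcs`, `m`, and attributes `config` (full echo including seed),
#'   `final_opinions`, and `histogram` (when recorded).
#' @examples
#' pp <- model_params(3, 3, 3, p = 0.1, z = 1, N = 50)
#' tr <- run_simulation(simulation_config(pp, m0 = 1, duration = 200, seed = 7))
#' @export
run_simulation <- function(config, record_histogram = FALSE,
                           mirror_independence = FALSE) {
  stopifnot(inherits(config, "qv_sim_config"))
  pp <- config$params
  res <- .mc_run_cpp(config$opinions, pp$q, pp$r, pp$w, pp$p, pp$z,
                     config$duration, config$burn_in, config$thin,
                     config$seed, record_histogram, mirror_independence)
  out <- data.frame(t_mcs = res$t_mcs, m = res$m)
  attr(out, "config") <- config
  attr(out, "final_opinions") <- res$final_opinions
  if (record_histogram) {
    h <- res$histogram
    names(h) <- 0:pp$N
    attr(out, "histogram") <- h
  }
  class(out) <- c("qv_trajectory", "data.frame")
  out
}

#' Order-parameter estimate from a trajectory
#'
#' Batch-means estimate of the stationary order parameter `<|m|>` with an
#' autocorrelation-aware standard error: post-burn-in samples are split into
#' `n_batches` contiguous batches and the standard error is computed from
#' the spread of the batch means.
#'
#' @param trajectory A `"qv_trajectory"` (or data frame with `t_mcs`, `m`).
#' @param burn_in Additional burn-in in MCS applied on top of whatever the
#'   run already discarded (default 0).
#' @param n_batches Number of batches, at least 20.
#' @return Named list with `mean` (`<|m|>`), `se`, and `n` (samples used).
#' @export
estimate_order_parameter <- function(trajectory, burn_in = 0, n_batches = 20) {
  if (n_batches < 20) stop("'n_batches' must be >= 20", call. = FALSE)
  keep <- trajectory$t_mcs > burn_in
  x <- abs(trajectory$m[keep])
  if (length(x) < n_batches)
    stop(sprintf("too few post-burn-in samples (%d) for %d batches",
                 length(x), n_batches), call. = FALSE)
  batch <- cut(seq_along(x), n_batches, labels = FALSE)
  means <- tapply(x, batch, mean)
  list(mean = mean(x),
       se = stats::sd(means) / sqrt(n_batches),
       n = length(x))
}

#' Empirical one-step flip frequencies
#'
#' Performs repeated independent single elementary updates from a fixed
#' configuration with `n_up` up agents and counts down-moves, no-changes and
#' up-moves, for validation of the analytic one-step rates.
#'
#' @param params A `"qv_params"` object with finite `N`.
#' @param n_up Up count of the fixed starting configuration.
#' @param trials Number of independent one-step trials.
#' @param seed Integer seed.
#' @return Named integer vector with components `down`, `stay`, `up`.
#' @export
step_frequencies <- function(params, n_up, trials = 1e5, seed = 1) {
  stopifnot(inherits(params, "qv_params"))
  if (!is.finite(params$N)) stop("finite N required", call. = FALSE)
  .mc_step_trials_cpp(n_up, params$N, params$q, params$r, params$w,
                      params$p, params$z, as.integer(trials), as.integer(seed))
}

#' @export
print.qv_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Monte Carlo trajectory: N = %d, %d samples, seed = %d\n",
              cfg$params$N, nrow(x), cfg$seed))
  cat(sprintf("  duration = %g MCS (burn-in %g, thin %d), m0 = %g\n",
              cfg$duration, cfg$burn_in, cfg$thin, cfg$m0))
  invisible(x)
}
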