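# Exact finite-population treatment. On the complete graph the up count
# n = N_up performs a birth-death Markov chain on {0..N}: each elementary
# step moves n up with lambda+(n), down with lambda-(n), or stays. The chain
# is reversible, so its stationary distribution (when it exists) has the
# product form pi(n+1)/pi(n) = lambda+(n)/lambda-(n+1).

#' Build the birth-death chain for a finite population
#'
#' Tabulates the exact one-elementary-step rates `lambda+(n)`, `lambda-(n)`,
#' `lambda0(n)` for every up count `n = 0..N` from the finite-population
#' response rates.
#'
#' @param params A `"qv_params"` object with finite `N`.
#' @return Object of class `"qv_chain"`: list with `N`, `params`, and numeric
#'   vectors `lambda_plus`, `lambda_minus`, `lambda_zero` indexed by
#'   `n = 0..N` (element `i` is state `n = i - 1`).
#' @examples
#' ch <- build_chain(model_params(3, 2, 2, p = 0.3, z = 0.5, N = 30))
#' @export
build_chain <- function(params) {
  stopifnot(inherits(params, "qv_params"))
  if (!is.finite(params$N))
    stop("'params' must have a finite population size N", call. = FALSE)
  N <- params$N
  lp <- numeric(N + 1)
  lm <- numeric(N + 1)
  for (n in 0:N) {
    tr <- total_rates(finite_rates(n, N, params$q, params$r, params$w),
                      params$p, params$z)
    lp[n + 1] <- tr$lambda_plus
    lm[n + 1] <- tr$lambda_minus
  }
  structure(list(N = N, params = params, lambda_plus = lp, lambda_minus = lm,
                 lambda_zero = 1 - lp - lm),
            class = "qv_chain")
}

#' @export
print.qv_chain <- function(x, ...) {
  cat(sprintf("Birth-death chain on n_up = 0..%d (threshold q-voter model)\n", x$N))
  print(x$params)
  invisible(x)
}

# states from which the chain can never leave (both flip channels closed)
absorbing_states <- function(chain) {
  which(chain$lambda_plus == 0 & chain$lambda_minus == 0) - 1L
}

#' Stationary distribution of the finite-population chain
#'
#' Exact product-form solution of the reversible birth-death chain:
#' `pi(n+1)/pi(n) = lambda+(n)/lambda-(n+1)`, accumulated in log space and
#' normalized. Requires an irreducible chain (every up-move and down-move
#' probability strictly positive in the interior); with absorbing states
#' (e.g. pure conformity, `p = 0`) no unique stationary distribution exists
#' and an error names them - use [absorption_probabilities()] instead.
#'
#' @param chain A `"qv_chain"` object.
#' @return Object of class `"qv_dist"`: numeric probability vector over
#'   `n = 0..N` with attributes `N` and `m` (the magnetization grid).
#' @examples
#' ch <- build_chain(model_params(3, 2, 2, p = 0.3, z = 0.5, N = 30))
#' pi_n <- stationary_distribution(ch)
#' sum(pi_n) # 1
#' @export
stationary_distribution <- function(chain) {
  stopifnot(inherits(chain, "qv_chain"))
  N <- chain$N
  up <- chain$lambda_plus[1:N]        # lambda+(0..N-1)
  down <- chain$lambda_minus[2:(N + 1)] # lambda-(1..N)
  if (any(up == 0) || any(down == 0)) {
    abs_states <- absorbing_states(chain)
    stop(sprintf("chain is not irreducible; no unique stationary distribution (absorbing or unreachable structure%s)",
                 if (length(abs_states))
                   paste0("; absorbing states: n = ",
                          paste(abs_states, collapse = ", "))
                 else ""), call. = FALSE)
  }
  log_pi <- c(0, cumsum(log(up) - log(down)))
  log_pi <- log_pi - max(log_pi)
  pi_n <- exp(log_pi)
  pi_n <- pi_n / sum(pi_n)
  structure(pi_n, N = N, m = magnetization(0:N, N), class = "qv_dist")
}

#' Absorption probabilities for reducible chains
#'
#' For parameter sets with absorbing consensus states (e.g. `p = 0`),
#' computes the probability of eventually absorbing at `n = N` (all-up
#' consensus) from every starting state, by first-step analysis of the
#' embedded jump chain (the classical ruin recursion with ratios
#' `lambda-/lambda+`).
#'
#' @param chain A `"qv_chain"` object absorbing only at `n = 0` and `n = N`
#'   (every interior state must be able to move in at least one direction).
#' @return Numeric vector `h(n)`, `n = 0..N`: probability of all-up consensus.
#' @export
absorption_probabilities <- function(chain) {
  stopifnot(inherits(chain, "qv_chain"))
  N <- chain$N
  up <- chain$lambda_plus[2:N]    # lambda+(1..N-1)
  down <- chain$lambda_minus[2:N] # lambda-(1..N-1)
  if (any(up + down == 0))
    stop("interior states with both flip channels closed; absorption probabilities are ill-defined",
         call. = FALSE)
  # first-step analysis: (lambda+ + lambda-) h(n) =
  #   lambda+ h(n+1) + lambda- h(n-1), h(0) = 0, h(N) = 1
  k <- N - 1
  A <- diag(up + down, k)
  for (n in seq_len(k - 1)) {
    A[n, n + 1] <- -up[n]
    A[n + 1, n] <- -down[n + 1]
  }
  b <- numeric(k)
  b[k] <- up[k]
  h <- c(0, solve(A, b), 1)
  names(h) <- 0:N
  h
}

#' Evolve a state distribution through the master equation
#'
#' Applies the exact one-elementary-step stochastic matrix of the chain
#' `N * t` times (an integer number of elementary steps; `t` is measured in
#' Monte Carlo steps of `N` elementary updates each). Probability mass moves
#' as `P'(n) = P(n-1) lambda+(n-1) + P(n) lambda0(n) + P(n+1) lambda-(n+1)`.
#'
#' @param chain A `"qv_chain"` object.
#' @param P0 Initial probability vector over `n = 0..N` (any numeric vector
#'   summing to 1, e.g. from [delta_distribution()]).
#' @param t Duration in MCS, `t >= 0`; `N * t` is rounded to an integer
#'   number of elementary steps.
#' @return A `"qv_dist"` probability vector at time `t`.
#' @examples
#' ch <- build_chain(model_params(3, 2, 2, p = 0.3, z = 0.5, N = 20))
#' P <- evolve_distribution(ch, delta_distribution(ch, 10), t = 5)
#' @export
evolve_distribution <- function(chain, P0, t) {
  stopifnot(inherits(chain, "qv_chain"))
  N <- chain$N
  if (length(P0) != N + 1) stop("'P0' must have length N + 1", call. = FALSE)
  if (any(P0 < 0) || abs(sum(P0) - 1) > 1e-9)
    stop("'P0' must be a probability vector (nonnegative, summing to 1)", call. = FALSE)
  if (t < 0) stop("'t' must be nonnegative", call. = FALSE)
  n_steps <- round(N * t)
  P <- as.numeric(P0)
  lp <- chain$lambda_plus
  lm <- chain$lambda_minus
  l0 <- chain$lambda_zero
  for (s in seq_len(n_steps)) {
    P <- P * l0 +
      c(0, (P * lp)[1:N]) +        # inflow from n - 1
      c((P * lm)[2:(N + 1)], 0)    # inflow from n + 1
  }
  P <- P / sum(P) # renormalize away accumulated rounding
  structure(P, N = N, m = magnetization(0:N, N), t = t, class = "qv_dist")
}

#' Point-mass initial distribution
#'
#' @param chain A `"qv_chain"` object.
#' @param n0 Up count carrying all initial mass.
#' @return Probability vector over `n = 0..N`.
#' @export
delta_distribution <- function(chain, n0) {
  N <- chain$N
  if (n0 < 0 || n0 > N) stop("'n0' must lie in 0..N", call. = FALSE)
  P <- numeric(N + 1)
  P[n0 + 1] <- 1
  P
}

#' @export
print.qv_dist <- function(x, ...) {
  N <- attr(x, "N")
  cat(sprintf("State distribution over n_up = 0..%d (mean m = %.6g)\n",
              N, sum(attr(x, "m") * as.numeric(x))))
  invisible(x)
}
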