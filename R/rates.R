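# Exact per-elementary-step transition probabilities for the aggregate state.
#
# One elementary step (duration 1/N Monte Carlo steps) picks a uniformly
# random target and a response kind; the up count can increase by one,
# decrease by one, or stay. The six response-resolved probabilities
# (alpha, beta, gamma for conformity, anticonformity, independence; +/- for
# up/down moves) are exact binomial tails in the infinite-population limit
# and hypergeometric tails (panel drawn without replacement from the N - 1
# non-target agents) at finite N.

# upper binomial tail P(Bin(q, prob) >= k)
btail <- function(k, q, prob) {
  stats::pbinom(k - 1, q, prob, lower.tail = FALSE)
}

# upper hypergeometric tail P(H >= k), H = number of "successes" in a draw of
# q from a pool of n_succ successes and n_fail failures, without replacement
htail <- function(k, n_succ, n_fail, q) {
  stats::phyper(k - 1, n_succ, n_fail, q, lower.tail = FALSE)
}

new_response_rates <- function(alpha_plus, alpha_minus, beta_plus, beta_minus,
                               gamma_plus, gamma_minus) {
  structure(list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                 beta_plus = beta_plus, beta_minus = beta_minus,
                 gamma_plus = gamma_plus, gamma_minus = gamma_minus),
            class = "qv_response_rates")
}

#' @export
print.qv_response_rates <- function(x, ...) {
  cat("Response-resolved transition rates\n")
  cat(sprintf("  conformity      alpha+ = %-12.10g alpha- = %-12.10g\n",
              x$alpha_plus, x$alpha_minus))
  cat(sprintf("  anticonformity  beta+  = %-12.10g beta-  = %-12.10g\n",
              x$beta_plus, x$beta_minus))
  cat(sprintf("  independence    gamma+ = %-12.10g gamma- = %-12.10g\n",
              x$gamma_plus, x$gamma_minus))
  invisible(x)
}

#' Response-resolved rates in the infinite-population limit
#'
#' With up fraction `x = (1 + m)/2` and down fraction `v = (1 - m)/2`, the
#' probabilities that a single elementary step moves the magnetization up or
#' down through each response channel are
#' \deqn{\alpha^+ = v\,P(\mathrm{Bin}(q, x) \ge r),\quad
#'       \alpha^- = x\,P(\mathrm{Bin}(q, v) \ge r),}
#' \deqn{\beta^+  = v\,P(\mathrm{Bin}(q, v) \ge w),\quad
#'       \beta^-  = x\,P(\mathrm{Bin}(q, x) \ge w),}
#' \deqn{\gamma^+ = v/2,\quad \gamma^- = x/2.}
#' The first factor is the probability that the target currently holds the
#' losing (for `+`) or winning (for `-`) opinion; the tail is the probability
#' that the sampled panel meets the relevant threshold.
#'
#' @param m Magnetization in `[-1, 1]`.
#' @param q Panel size.
#' @param r Conformity threshold.
#' @param w Anticonformity threshold.
#' @return A `"qv_response_rates"` object with fields `alpha_plus`,
#'   `alpha_minus`, `beta_plus`, `beta_minus`, `gamma_plus`, `gamma_minus`.
#' @examples
#' infinite_rates(0, q = 2, r = 2, w = 2) # all alpha, beta = 1/8; gamma = 1/4
#' @export
infinite_rates <- function(m, q, r, w) {
  if (length(m) != 1L || is.na(m) || abs(m) > 1)
    stop("'m' must be a single value in [-1, 1]", call. = FALSE)
  x <- (1 + m) / 2
  v <- (1 - m) / 2
  new_response_rates(
    alpha_plus  = v * btail(r, q, x),
    alpha_minus = x * btail(r, q, v),
    beta_plus   = v * btail(w, q, v),
    beta_minus  = x * btail(w, q, x),
    gamma_plus  = v / 2,
    gamma_minus = x / 2)
}

#' Response-resolved rates for a finite population
#'
#' Exact finite-N analogue of [infinite_rates()]: the panel of `q` agents is
#' drawn uniformly without replacement from the `N - 1` agents other than the
#' target, so binomial tails become hypergeometric tails. For example
#' `alpha_plus = (N_down / N) * P(H >= r)` where `H` counts up-agents in a
#' panel drawn from the remaining `N_up` ups and `N_down - 1` downs, given a
#' down target. Independence rates are `gamma_plus = N_down / (2N)`,
#' `gamma_minus = N_up / (2N)`. As `N` grows at fixed magnetization these
#' converge to the infinite-population rates.
#'
#' @param n_up Number of up agents, in `0..N`.
#' @param N Population size.
#' @inheritParams infinite_rates
#' @return A `"qv_response_rates"` object.
#' @examples
#' finite_rates(2, N = 4, q = 3, r = 2, w = 2)
#' @export
finite_rates <- function(n_up, N, q, r, w) {
  if (q > N - 1)
    stop("'q' must satisfy q <= N - 1 (cannot sample the panel without replacement)",
         call. = FALSE)
  if (n_up < 0 || n_up > N) stop("'n_up' must lie in 0..N", call. = FALSE)
  n_down <- N - n_up
  # tails conditioned on the target's state; guarded so that a zero
  # target-state probability never multiplies an undefined tail
  tail_given_down <- function(k, count_succ_up) {
    if (n_down == 0) return(0)
    if (count_succ_up) htail(k, n_up, n_down - 1, q)
    else htail(k, n_down - 1, n_up, q)
  }
  tail_given_up <- function(k, count_succ_up) {
    if (n_up == 0) return(0)
    if (count_succ_up) htail(k, n_up - 1, n_down, q)
    else htail(k, n_down, n_up - 1, q)
  }
  new_response_rates(
    alpha_plus  = (n_down / N) * tail_given_down(r, TRUE),
    alpha_minus = (n_up / N)   * tail_given_up(r, FALSE),
    beta_plus   = (n_down / N) * tail_given_down(w, FALSE),
    beta_minus  = (n_up / N)   * tail_given_up(w, TRUE),
    gamma_plus  = n_down / (2 * N),
    gamma_minus = n_up / (2 * N))
}

#' Aggregate one-step transition rates
#'
#' Mixes the response-resolved rates with the response probabilities:
#' \deqn{\lambda^+ = (1-p)\alpha^+ + p(1-z)\beta^+ + pz\gamma^+,}
#' and analogously for \eqn{\lambda^-}; \eqn{\lambda^0 = 1 - \lambda^+ -
#' \lambda^-} is the probability that the elementary step changes nothing
#' (uniformity/congruence, sub-threshold panels, or an independence draw that
#' confirms the current opinion).
#'
#' @param rr A `"qv_response_rates"` object.
#' @param p Probability of nonconformity.
#' @param z Conditional probability of independence given nonconformity.
#' @return A named list of class `"qv_total_rates"` with `lambda_plus`,
#'   `lambda_minus`, `lambda_zero`, summing to 1.
#' @examples
#' total_rates(infinite_rates(0, 2, 2, 2), p = 0.5, z = 0.5)
#' @export
total_rates <- function(rr, p, z) {
  stopifnot(inherits(rr, "qv_response_rates"))
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]", call. = FALSE)
  if (z < 0 || z > 1) stop("'z' must lie in [0, 1]", call. = FALSE)
  lp <- (1 - p) * rr$alpha_plus  + p * (1 - z) * rr$beta_plus  + p * z * rr$gamma_plus
  lm <- (1 - p) * rr$alpha_minus + p * (1 - z) * rr$beta_minus + p * z * rr$gamma_minus
  structure(list(lambda_plus = lp, lambda_minus = lm,
                 lambda_zero = 1 - lp - lm),
            class = "qv_total_rates")
}

#' @export
print.qv_total_rates <- function(x, ...) {
  cat(sprintf("lambda+ = %.10g, lambda- = %.10g, lambda0 = %.10g\n",
              x$lambda_plus, x$lambda_minus, x$lambda_zero))
  invisible(x)
}
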