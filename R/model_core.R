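#' Model parameters for the threshold q-voter model
#'
#' Bundles and validates the full parameter set of the generalized threshold
#' q-voter model with all four Willis-Nail social responses. A randomly chosen
#' target agent responds to a randomly sampled influence group ("panel") of
#' `q` other agents with one of three state-changing responses: conformity
#' (probability `1 - p`), anticonformity (probability `p * (1 - z)`) or
#' independence (probability `p * z`); uniformity/congruence (agreeing with
#' the panel already) changes nothing. Conformity flips the target when at
#' least `r` panel members oppose its current opinion; anticonformity flips it
#' when at least `w` panel members share its current opinion; independence
#' redraws the opinion at random with flip probability `f = 1/2`.
#'
#' @param q Influence-group (panel) size, positive integer.
#' @param r Conformity threshold: minimum number of panel members holding the
#'   opinion opposite to the target's that is needed for the target to adopt
#'   it. Integer in `1..q`.
#' @param w Anticonformity threshold: minimum number of panel members sharing
#'   the target's current opinion that is needed for the target to rebel and
#'   flip. Integer in `1..q`.
#' @param p Probability of nonconformity in `[0, 1]`.
#' @param z Conditional probability of independence given nonconformity, in
#'   `[0, 1]`. `z = 1` is the conformity+independence model, `z = 0` the
#'   conformity+anticonformity model.
#' @param N Population size: a positive integer with `q <= N - 1` (the panel
#'   is drawn without replacement from the other agents), or `Inf` for the
#'   mean-field (infinite population) limit. Default `Inf`.
#' @param f Independence flip probability. Fixed at `1/2`, the only value
#'   under which the independence rates take their standard symmetric form;
#'   any other value is rejected.
#'
#' @return An object of class `"qv_params"`: a validated named list with
#'   fields `q`, `r`, `w`, `p`, `z`, `N`, `f`.
#' @examples
#' model_params(q = 3, r = 3, w = 3, p = 0.2, z = 1, N = 100)
#' @export
model_params <- function(q, r, w, p, z, N = Inf, f = 0.5) {
  check_count <- function(x, name, min = 1L) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
      stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
    as.integer(x)
  }
  q <- check_count(q, "q")
  r <- check_count(r, "r")
  w <- check_count(w, "w")
  if (r > q) stop("'r' must satisfy 1 <= r <= q", call. = FALSE)
  if (w > q) stop("'w' must satisfy 1 <= w <= q", call. = FALSE)
  check_prob <- function(x, name) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a single probability in [0, 1]", name), call. = FALSE)
    as.numeric(x)
  }
  p <- check_prob(p, "p")
  z <- check_prob(z, "z")
  if (length(f) != 1L || !is.numeric(f) || f != 0.5)
    stop("'f' is fixed at 1/2 in this model", call. = FALSE)
  if (length(N) != 1L || !is.numeric(N) || is.na(N) || N < 1)
    stop("'N' must be a positive integer or Inf", call. = FALSE)
  if (is.finite(N)) {
    if (N != as.integer(N)) stop("'N' must be a positive integer or Inf", call. = FALSE)
    N <- as.integer(N)
    if (q > N - 1L)
      stop("'q' must satisfy q <= N - 1 (panel drawn without replacement from the other agents)",
           call. = FALSE)
  }
  structure(list(q = q, r = r, w = w, p = p, z = z, N = N, f = 0.5),
            class = "qv_params")
}

#' @export
print.qv_params <- function(x, ...) {
  nn <- if (is.finite(x$N)) format(x$N) else "Inf (mean field)"
  cat("Threshold q-voter model parameters\n")
  cat(sprintf("  q = %d, r = %d, w = %d, p = %g, z = %g, N = %s, f = 1/2\n",
              x$q, x$r, x$w, x$p, x$z, nn))
  invisible(x)
}

#' Opinion configuration of a finite population
#'
#' Wraps a vector of +1/-1 opinions and caches the up count. On the complete
#' graph the pair `(n_up, N)` is a sufficient description of the state.
#'
#' @param opinions Integer or numeric vector with entries in `{-1, +1}`.
#' @return Object of class `"qv_config"`: the opinion vector with attributes
#'   `n_up` and `N`.
#' @examples
#' cfg <- new_configuration(c(1, 1, -1, 1))
#' attr(cfg, "n_up")
#' @export
new_configuration <- function(opinions) {
  opinions <- as.integer(opinions)
  if (length(opinions) < 1L || !all(opinions %in% c(-1L, 1L)))
    stop("'opinions' must be a non-empty vector of +1/-1 values", call. = FALSE)
  structure(opinions, n_up = sum(opinions == 1L), N = length(opinions),
            class = "qv_config")
}

#' Construct a configuration with a prescribed magnetization
#'
#' Builds an opinion vector of length `N` whose magnetization is exactly
#' `m0` (which requires `N * m0` to have the parity of `N`, so that the up
#' count `n_up = N (1 + m0) / 2` is an integer). The up agents occupy the
#' first positions; on the complete graph the labelling is immaterial.
#'
#' @param N Population size.
#' @param m0 Target magnetization in `[-1, 1]`.
#' @return A `"qv_config"` object.
#' @export
configuration_from_m <- function(N, m0) {
  if (abs(m0) > 1) stop("'m0' must lie in [-1, 1]", call. = FALSE)
  n_up <- N * (1 + m0) / 2
  if (abs(n_up - round(n_up)) > 1e-9)
    stop(sprintf("'m0' = %g is not realizable for N = %d: N*(1+m0)/2 must be an integer (N*m0 must have the parity of N)",
                 m0, N), call. = FALSE)
  n_up <- as.integer(round(n_up))
  new_configuration(c(rep(1L, n_up), rep(-1L, N - n_up)))
}

#' Magnetization (order parameter)
#'
#' The population-level opinion imbalance `m = (N_up - N_down) / N
#' = (2 n_up - N) / N`, the order parameter of the order-disorder transition.
#'
#' @param n_up Number of agents holding opinion +1, in `0..N`.
#' @param N Population size, `N >= 1`.
#' @return Magnetization in `[-1, 1]`.
#' @examples
#' magnetization(75, 100) # 0.5
#' @export
magnetization <- function(n_up, N) {
  if (any(N < 1)) stop("'N' must be >= 1", call. = FALSE)
  if (any(n_up < 0 | n_up > N)) stop("'n_up' must lie in 0..N", call. = FALSE)
  (2 * n_up - N) / N
}

#' Integer threshold from a fractional majority
#'
#' Converts a majority fraction `a` of the panel size `q` into the integer
#' threshold `ceiling(a * q)`, the convention used when thresholds are swept
#' as fractions (the source of the saw-tooth structure of phase diagrams at
#' fractional thresholds).
#'
#' @param a Fraction in `(0, 1]`.
#' @param q Panel size.
#' @return Integer threshold in `1..q`.
#' @examples
#' threshold_count(0.75, 10) # 8
#' @export
threshold_count <- function(a, q) {
  if (any(a <= 0 | a > 1)) stop("'a' must lie in (0, 1]", call. = FALSE)
  if (any(q < 1)) stop("'q' must be >= 1", call. = FALSE)
  as.integer(ceiling(a * q))
}

#' Single-agent social response
#'
#' Applies one Willis-Nail response of the target to a sampled panel:
#' * `"conformity"`: if at least `r` panel members hold the opinion opposite
#'   to the target's, the target adopts that opposite opinion; otherwise it
#'   keeps its opinion (uniformity/congruence).
#' * `"anticonformity"`: if at least `w` panel members share the target's
#'   current opinion, the target flips against them; otherwise no change.
#' * `"independence"`: the panel is ignored and the new opinion is `+1` if
#'   `u < 1/2`, else `-1` (flip probability `f = 1/2`).
#'
#' Only the opinion opposite to the target is tested for conformity, and only
#' the target's own opinion for anticonformity; this matches the event
#' decomposition behind the aggregate transition rates and keeps the rule
#' single-valued even for sub-majority thresholds. In the tie case `r = q/2`
#' with a half-half panel the target flips (the threshold "at least r" is met).
#'
#' @param target_opinion `+1` or `-1`.
#' @param panel Vector of `q` opinions in `{-1, +1}`.
#' @param kind One of `"conformity"`, `"anticonformity"`, `"independence"`.
#' @param r,w Thresholds (only the one relevant to `kind` is consulted).
#' @param u Uniform random draw in `[0, 1)`, used only for independence.
#' @return The target's new opinion, `+1` or `-1`.
#' @examples
#' apply_response(-1, c(1, 1, 1), "conformity", r = 3) # +1
#' @export
apply_response <- function(target_opinion, panel, kind, r = NULL, w = NULL,
                           u = NULL) {
  if (!target_opinion %in% c(-1, 1))
    stop("'target_opinion' must be +1 or -1", call. = FALSE)
  if (!all(panel %in% c(-1, 1)))
    stop("'panel' must contain only +1/-1 values", call. = FALSE)
  kind <- match.arg(kind, c("conformity", "anticonformity", "independence"))
  switch(kind,
    conformity = {
      if (is.null(r)) stop("'r' is required for conformity", call. = FALSE)
      n_opposite <- sum(panel == -target_opinion)
      if (n_opposite >= r) -target_opinion else target_opinion
    },
    anticonformity = {
      if (is.null(w)) stop("'w' is required for anticonformity", call. = FALSE)
      n_same <- sum(panel == target_opinion)
      if (n_same >= w) -target_opinion else target_opinion
    },
    independence = {
      if (is.null(u)) u <- stats::runif(1)
      if (u < 0.5) 1 else -1
    })
}
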