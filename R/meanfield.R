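# Mean-field stationary analysis.
#
# In the infinite-population limit the stationarity condition lambda+ =
# lambda- is linear in p and yields p = A / (A - C) with
#   A(m) = alpha+ - alpha-                 (ordering drive of conformity)
#   C(m) = (1-z) (beta+ - beta-) - z m/2   (disordering drive of nonconformity)
# Both A and C are odd polynomials in m. The m -> 0 limit of p(m) is the
# lower spinodal p*, and the sign of the quadratic coefficient p2 of the
# expansion p(m) = p* + p2 m^2 + p4 m^4 + ... classifies the transition:
# p2 < 0 (p(m) has a maximum at m = 0) -> continuous; p2 > 0 -> discontinuous
# (an interior maximum of p(m), the upper spinodal, appears). When p2 = 0 the
# quartic term decides; only if both vanish is the point tricritical.
#
# The series coefficients are obtained in closed form from derivatives of the
# binomial tail T(x) = P(Bin(q, x) >= r) at x = 1/2, using
# T'(x) = r C(q, r) x^(r-1) (1-x)^(q-r). All quantities involved are exactly
# representable in double precision up to q = 50 and beyond, so no numerical
# differentiation across the m = 0 singularity of m(p) is ever needed.

# t_k = T^(k)(1/2) / k! for k = 0..5, T(x) = P(Bin(q, x) >= r); cached.
.qv_cache <- new.env(parent = emptyenv())

tail_derivs_half <- function(q, r) {
  key <- paste0(q, ":", r)
  hit <- .qv_cache[[key]]
  if (!is.null(hit)) return(hit)
  dfall <- function(a, j) if (j == 0) 1 else prod(a - 0:(j - 1))
  t <- numeric(6)
  t[1] <- btail(r, q, 0.5)
  rc <- r * choose(q, r)
  gk <- function(k) { # k-th derivative of x^(r-1)(1-x)^(q-r) at 1/2
    s <- 0
    for (j in 0:k) {
      c1 <- dfall(r - 1, j)
      c2 <- dfall(q - r, k - j)
      if (c1 == 0 || c2 == 0) next
      s <- s + choose(k, j) * c1 * c2 * (-1)^(k - j) * 0.5^(q - 1 - k)
    }
    s
  }
  for (k in 1:5) t[k + 1] <- rc * gk(k - 1) / factorial(k)
  .qv_cache[[key]] <- t
  t
}

# odd series coefficients (orders m, m^3, m^5) of A(m) and B(m) about m = 0
odd_series <- function(q, r, w) {
  t <- tail_derivs_half(q, r)
  u <- tail_derivs_half(q, w)
  list(a = c((t[2] - 2 * t[1]) / 2, (t[4] - 2 * t[3]) / 8, (t[6] - 2 * t[5]) / 32),
       b = c(-(u[2] + 2 * u[1]) / 2, -(u[4] + 2 * u[3]) / 8, -(u[6] + 2 * u[5]) / 32))
}

# p*, p2, p4 for one (q, r, w) and a vector of z values; vectorized over z.
# Returns a list of numeric vectors. p* outside (0, 1) means there is no
# order-disorder transition at positive nonconformity (flagged by `physical`).
expansion_coefficients <- function(q, r, w, z) {
  s <- odd_series(q, r, w)
  a1 <- s$a[1]; a3 <- s$a[2]; a5 <- s$a[3]
  c1 <- (1 - z) * s$b[1] - z / 2
  c3 <- (1 - z) * s$b[2]
  c5 <- (1 - z) * s$b[3]
  d1 <- a1 - c1; d3 <- a3 - c3; d5 <- a5 - c5
  p_star <- a1 / d1
  u <- a3 / a1; v <- a5 / a1
  sdl <- d3 / d1; tdl <- d5 / d1
  list(p_star = p_star,
       p2 = p_star * (u - sdl),
       p4 = p_star * (v - u * sdl + sdl^2 - tdl),
       physical = is.finite(p_star) & p_star > 0 & p_star < 1)
}

#' Stationary relation p(m)
#'
#' Solves the mean-field stationarity condition (rate of opinion growth equal
#' to rate of decay) for the nonconformity probability `p` at a given
#' magnetization: `p = A / (A - C)` with `A = alpha+ - alpha-` and
#' `C = (1 - z)(beta+ - beta-) + z (gamma+ - gamma-)`. Magnetizations whose
#' root falls outside `[0, 1]` have no physical stationary `p` and yield `NA`.
#'
#' @param m Magnetization value(s) in `[-1, 1]`, nonzero (the disordered
#'   branch `m = 0` is stationary for every `p`). The relation is even in `m`.
#' @param q,r,w Panel size and thresholds.
#' @param z Conditional independence probability.
#' @return Numeric vector of stationary `p` values (`NA` where no root lies
#'   in `[0, 1]`).
#' @examples
#' stationary_p(0.5, q = 3, r = 3, w = 3, z = 1) # 3/11
#' @export
stationary_p <- function(m, q, r, w, z) {
  if (any(abs(m) > 1)) stop("'m' must lie in [-1, 1]", call. = FALSE)
  if (any(m == 0)) stop("'m' must be nonzero; use critical_p() for the m -> 0 limit",
                        call. = FALSE)
  vapply(m, function(mi) {
    rr <- infinite_rates(mi, q, r, w)
    A <- rr$alpha_plus - rr$alpha_minus
    C <- (1 - z) * (rr$beta_plus - rr$beta_minus) +
      z * (rr$gamma_plus - rr$gamma_minus)
    denom <- A - C
    if (abs(denom) < 1e-300)
      stop("degenerate stationarity condition: A - C = 0 at m = ", mi, call. = FALSE)
    p <- A / denom
    if (is.finite(p) && p >= 0 && p <= 1) p else NA_real_
  }, numeric(1))
}

#' Critical nonconformity p* (lower spinodal)
#'
#' The limit of the stationary relation `p(m)` as `m -> 0+`: the nonconformity
#' level below which the disordered state `m = 0` is unstable. Computed from
#' the linear series coefficients of the odd polynomials `A(m)` and `C(m)`
#' (both vanish at `m = 0`; their ratio is finite), not by numerical limits.
#'
#' @inheritParams stationary_p
#' @return The critical value `p*`. Values outside `(0, 1)` are returned
#'   as-is with a warning: they indicate that disorder is stable at every
#'   positive nonconformity level (no order-disorder transition).
#' @examples
#' critical_p(q = 3, r = 3, w = 3, z = 1) # 1/3
#' @export
critical_p <- function(q, r, w, z) {
  ec <- expansion_coefficients(q, r, w, z)
  if (!is.finite(ec$p_star))
    stop("no finite m -> 0 limit of p(m): linear coefficients of A and C coincide",
         call. = FALSE)
  if (!ec$physical)
    warning(sprintf("p* = %g lies outside (0, 1): no order-disorder transition at these parameters",
                    ec$p_star), call. = FALSE)
  ec$p_star
}

#' Classify the order-disorder transition
#'
#' Expands `p(m) = p* + p2 m^2 + p4 m^4 + ...` using exact series
#' coefficients. `p2 < 0` (maximum of `p(m)` at `m = 0`) means the ordered
#' branch exists only below `p*`: a continuous transition. `p2 > 0` means
#' `p(m)` initially rises, creating an interior maximum (the upper spinodal)
#' and a coexistence region: a discontinuous transition. If `p2` vanishes the
#' quartic coefficient decides; if both vanish the parameters sit exactly at
#' a tricritical point.
#'
#' @inheritParams stationary_p
#' @param tol Tolerance below which a series coefficient is treated as zero.
#' @return Object of class `"qv_phase"`: list with `transition_type`
#'   (`"continuous"`, `"discontinuous"`, `"tricritical"`, or `"none"` when
#'   `p*` is not in `(0, 1)`), `p_star`, `p_upper` (upper spinodal; equals
#'   `p_star` for continuous transitions), and the coefficients `p2`, `p4`.
#' @examples
#' classify_transition(q = 6, r = 6, w = 6, z = 1)$transition_type # discontinuous
#' @export
classify_transition <- function(q, r, w, z, tol = 1e-10) {
  ec <- expansion_coefficients(q, r, w, z)
  if (!ec$physical) {
    return(structure(list(transition_type = "none", p_star = ec$p_star,
                          p_upper = NA_real_, p2 = ec$p2, p4 = ec$p4,
                          q = q, r = r, w = w, z = z),
                     class = "qv_phase"))
  }
  type <-
    if (abs(ec$p2) > tol) {
      if (ec$p2 < 0) "continuous" else "discontinuous"
    } else if (abs(ec$p4) > tol) {
      if (ec$p4 < 0) "continuous" else "discontinuous"
    } else "tricritical"
  p_upper <- if (type == "discontinuous") {
    upper_spinodal(q, r, w, z, ec$p_star)
  } else ec$p_star
  structure(list(transition_type = type, p_star = ec$p_star,
                 p_upper = p_upper, p2 = ec$p2, p4 = ec$p4,
                 q = q, r = r, w = w, z = z),
            class = "qv_phase")
}

#' @export
print.qv_phase <- function(x, ...) {
  cat(sprintf("Order-disorder transition at q = %d, r = %d, w = %d, z = %g\n",
              x$q, x$r, x$w, x$z))
  cat(sprintf("  type: %s\n  p* (lower spinodal): %.10g\n", x$transition_type, x$p_star))
  if (identical(x$transition_type, "discontinuous"))
    cat(sprintf("  upper spinodal: %.10g\n", x$p_upper))
  invisible(x)
}

# maximum of p(m) over m in (0, 1]: grid scan then local refinement
upper_spinodal <- function(q, r, w, z, p_star, n_grid = 2001) {
  grid <- seq(1 / n_grid, 1, length.out = n_grid)
  pv <- suppressWarnings(stationary_p(grid, q, r, w, z))
  pv[is.na(pv)] <- -Inf
  i <- which.max(pv)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(function(mm) {
    val <- suppressWarnings(stationary_p(mm, q, r, w, z))
    if (is.na(val)) -Inf else val
  }, lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  max(opt$objective, pv[i], p_star)
}

#' Spinodal pair
#'
#' The two stability limits of the transition: `p_lower = p*` (below it the
#' disordered state is unstable) and `p_upper` (above it no ordered state
#' survives; the maximum of the stationary relation `p(m)`). They coincide
#' when the transition is continuous; the gap between them is the coexistence
#' (hysteresis) region of a discontinuous transition.
#'
#' @inheritParams stationary_p
#' @return Named numeric vector `c(p_lower, p_upper)`.
#' @examples
#' spinodals(q = 6, r = 6, w = 6, z = 1)
#' @export
spinodals <- function(q, r, w, z) {
  cl <- classify_transition(q, r, w, z)
  if (identical(cl$transition_type, "none"))
    stop("no order-disorder transition at these parameters (p* outside (0, 1))",
         call. = FALSE)
  c(p_lower = cl$p_star, p_upper = cl$p_upper)
}

#' Stationary curve p(m) on a magnetization grid
#'
#' Tabulates the stationary relation for plotting or export; only the
#' positive branch is stored (the relation is even in `m`).
#'
#' @inheritParams stationary_p
#' @param m_grid Grid of magnetizations in `(0, 1]`.
#' @return A data frame with columns `m` and `p` and the parameters attached
#'   as attributes.
#' @export
stationary_curve <- function(q, r, w, z, m_grid = seq(0.005, 1, by = 0.005)) {
  if (any(m_grid <= 0)) stop("'m_grid' must lie in (0, 1]", call. = FALSE)
  out <- data.frame(m = m_grid,
                    p = suppressWarnings(stationary_p(m_grid, q, r, w, z)))
  attr(out, "params") <- list(q = q, r = r, w = w, z = z)
  out
}

#' Effective force and potential profile
#'
#' The drift `F(m) = lambda+ - lambda-` and the effective (Landau) potential
#' `V(m) = -integral of F`, fixed by `V(0) = 0` and computed by trapezoidal
#' quadrature on the supplied grid. Stable stationary states are local minima
#' of `V`; in the coexistence region of a discontinuous transition `V` has
#' three local minima (`m = 0` and a symmetric ordered pair).
#'
#' @param m_grid Symmetric grid on `[-1, 1]` containing 0.
#' @param q,r,w,p,z Model parameters.
#' @return Data frame with columns `m`, `F`, `V`.
#' @examples
#' pp <- potential_profile(seq(-1, 1, by = 0.01), q = 3, r = 3, w = 3,
#'                         p = 0.2, z = 1)
#' @export
potential_profile <- function(m_grid, q, r, w, p, z) {
  m_grid <- sort(m_grid)
  if (max(abs(m_grid + rev(m_grid))) > 1e-12 || !any(m_grid == 0))
    stop("'m_grid' must be symmetric about 0 and contain 0", call. = FALSE)
  F_vals <- vapply(m_grid, function(mm) {
    tr <- total_rates(infinite_rates(mm, q, r, w), p, z)
    tr$lambda_plus - tr$lambda_minus
  }, numeric(1))
  i0 <- which(m_grid == 0)
  V <- numeric(length(m_grid))
  if (i0 < length(m_grid)) {
    dm <- diff(m_grid[i0:length(m_grid)])
    incr <- -dm * (F_vals[i0:(length(m_grid) - 1)] + F_vals[(i0 + 1):length(m_grid)]) / 2
    V[(i0 + 1):length(m_grid)] <- cumsum(incr)
  }
  if (i0 > 1) {
    dm <- diff(m_grid[1:i0])
    incr <- dm * (F_vals[1:(i0 - 1)] + F_vals[2:i0]) / 2
    V[(i0 - 1):1] <- cumsum(rev(incr))
  }
  data.frame(m = m_grid, F = F_vals, V = V)
}

#' Deterministic mean-field trajectory
#'
#' Integrates the rate equation `dm/dt = 2 F(m)` (expected magnetization
#' change per Monte Carlo step: `N` elementary steps each moving `m` by
#' `2/N` with net probability `lambda+ - lambda-`) with a fourth-order
#' Runge-Kutta scheme. The trajectory converges to a stable root of `F`.
#'
#' @param m0 Initial magnetization in `[-1, 1]`.
#' @param q,r,w,p,z Model parameters.
#' @param t_max Duration in Monte Carlo steps.
#' @param dt Integration step in MCS.
#' @return Data frame with columns `t` and `m`.
#' @examples
#' tr <- meanfield_trajectory(0.9, q = 3, r = 3, w = 3, p = 0.1, z = 1,
#'                            t_max = 50)
#' @export
meanfield_trajectory <- function(m0, q, r, w, p, z, t_max = 100, dt = 0.01) {
  if (abs(m0) > 1) stop("'m0' must lie in [-1, 1]", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  force <- function(mm) {
    mm <- max(-1, min(1, mm))
    tr <- total_rates(infinite_rates(mm, q, r, w), p, z)
    2 * (tr$lambda_plus - tr$lambda_minus)
  }
  n_steps <- ceiling(t_max / dt)
  tt <- numeric(n_steps + 1)
  mm <- numeric(n_steps + 1)
  mm[1] <- m0
  for (i in seq_len(n_steps)) {
    k1 <- force(mm[i])
    k2 <- force(mm[i] + dt * k1 / 2)
    k3 <- force(mm[i] + dt * k2 / 2)
    k4 <- force(mm[i] + dt * k3)
    mm[i + 1] <- max(-1, min(1, mm[i] + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6))
    tt[i + 1] <- i * dt
  }
  data.frame(t = tt, m = mm)
}

#' Critical independence fraction z*
#'
#' Locates the value of `z` separating continuous from discontinuous
#' transitions at fixed `(q, r, w)`. A coarse scan over `z` detects the sign
#' structure of the classification; a single boundary is then refined by
#' bisection. Returns 1 when the transition is continuous for every `z`
#' (no discontinuity anywhere on the segment) and 0 when it is discontinuous
#' for every `z`.
#'
#' @inheritParams stationary_p
#' @param dz Coarse scan step.
#' @param tol Bisection tolerance on `z`.
#' @return The critical `z*` in `[0, 1]`, with attribute `direction` set to
#'   `"discontinuous_above"` (the usual case: continuous for `z < z*`) or
#'   `"discontinuous_below"` for inverted pockets.
#' @examples
#' critical_z(q = 6, r = 6, w = 6) # strictly below 1
#' @export
critical_z <- function(q, r, w, dz = 0.02, tol = 1e-6) {
  zs <- seq(0, 1, by = dz)
  disc <- vapply(zs, function(z)
    identical(classify_transition(q, r, w, z)$transition_type, "discontinuous"),
    logical(1))
  if (!any(disc)) return(structure(1, direction = "discontinuous_above"))
  if (all(disc)) return(structure(0, direction = "discontinuous_above"))
  changes <- which(diff(disc) != 0)
  if (length(changes) > 1)
    stop(sprintf("multiple continuous/discontinuous boundaries detected in z for q = %d, r = %d, w = %d (near z = %s); refusing to bisect a non-monotone classification",
                 q, r, w, paste(signif(zs[changes], 3), collapse = ", ")),
         call. = FALSE)
  lo <- zs[changes]
  hi <- zs[changes + 1]
  f_lo <- disc[changes]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    d_mid <- identical(classify_transition(q, r, w, mid)$transition_type,
                       "discontinuous")
    if (d_mid == f_lo) lo <- mid else hi <- mid
  }
  zstar <- (lo + hi) / 2
  structure(zstar,
            direction = if (f_lo) "discontinuous_below" else "discontinuous_above")
}

# does any z in the open unit interval give a discontinuous transition?
# vectorized over the z grid via the closed-form expansion coefficients
discontinuity_exists <- function(q, r, w, z_grid = seq(0.005, 0.995, by = 0.005),
                                 tol = 1e-10) {
  ec <- expansion_coefficients(q, r, w, z_grid)
  disc <- ec$physical &
    ((ec$p2 > tol) | (abs(ec$p2) <= tol & ec$p4 > tol))
  any(disc)
}

#' Critical conformity majority r*
#'
#' The smallest conformity threshold `r` in the majority domain
#' `r > q/2` at which a discontinuous order-disorder transition occurs for
#' some `z` in `(0, 1)`. Below `r*` the transition is continuous for every
#' anticonformity threshold `w` and every `z` (`z* = 1` everywhere).
#'
#' Two policies are offered for aggregating over `w`:
#' * `"every_w"` (default): `r` qualifies only if a discontinuity exists at
#'   **every** `w` in `w_set`. This reproduces the published critical
#'   majorities (e.g. `r*(10) = 8`); near `q = 50` the anticonformity
#'   threshold is not perfectly irrelevant and a weak-discontinuity pocket at
#'   `w` near `q/2` makes the policies differ (see the package vignette).
#' * `"any_w"`: `r` qualifies if a discontinuity exists at **some** `w`.
#'
#' @param q Panel size, `q >= 2`.
#' @param w_policy Aggregation over the anticonformity threshold, see above.
#' @param w_set Set of `w` values scanned; defaults to `1:q`.
#' @param z_grid Grid of interior `z` values scanned for a discontinuity.
#' @return Integer `r*` (or `NA` if no majority threshold qualifies), with
#'   attribute `per_w`: a logical matrix `[r, w]` recording where a
#'   discontinuity exists, so both policies can be audited.
#' @examples
#' critical_r(10) # 8
#' @export
critical_r <- function(q, w_policy = c("every_w", "any_w"), w_set = NULL,
                       z_grid = seq(0.005, 0.995, by = 0.005)) {
  if (q < 2) stop("'q' must be >= 2", call. = FALSE)
  w_policy <- match.arg(w_policy)
  if (is.null(w_set)) w_set <- seq_len(q)
  r_set <- seq.int(floor(q / 2) + 1L, q)
  per_w <- matrix(FALSE, length(r_set), length(w_set),
                  dimnames = list(r = r_set, w = w_set))
  agg <- if (w_policy == "every_w") all else any
  r_star <- NA_integer_
  for (i in seq_along(r_set)) {
    for (j in seq_along(w_set))
      per_w[i, j] <- discontinuity_exists(q, r_set[i], w_set[j], z_grid)
    if (is.na(r_star) && agg(per_w[i, ])) r_star <- r_set[i]
  }
  structure(r_star, per_w = per_w, w_policy = w_policy)
}

#' Tricritical panel size q*
#'
#' With thresholds given as fixed fractions of the panel size
#' (`r = ceiling(a_r q)`, `w = ceiling(a_w q)`), finds the smallest panel
#' size whose order-disorder transition is discontinuous. For smaller `q`
#' only continuous transitions occur; at `q*` the spinodals separate.
#'
#' @param a_r,a_w Threshold fractions in `(0, 1]`.
#' @param z Conditional independence probability.
#' @param q_max Scan bound.
#' @return The smallest discontinuous `q` as an integer, or `NA_integer_`
#'   if none exists in `2..q_max`.
#' @examples
#' tricritical_q(1, 1, z = 1) # 6
#' @export
tricritical_q <- function(a_r, a_w, z, q_max = 50) {
  for (q in 2:q_max) {
    cl <- classify_transition(q, threshold_count(a_r, q), threshold_count(a_w, q), z)
    if (identical(cl$transition_type, "discontinuous")) return(as.integer(q))
  }
  NA_integer_
}

#' Phase diagram over a range of panel sizes
#'
#' Tabulates the spinodal pair and transition type for `q` in a range, with
#' thresholds either fixed integers or fractions of `q`.
#'
#' @param q_range Integer vector of panel sizes.
#' @param a_r,a_w Threshold fractions in `(0, 1]` (resolved per `q` via
#'   [threshold_count()]).
#' @param z Conditional independence probability.
#' @return Data frame with columns `q`, `r`, `w`, `p_lower`, `p_upper`,
#'   `type`.
#' @export
phase_diagram <- function(q_range, a_r, a_w, z) {
  rows <- lapply(q_range, function(q) {
    r <- threshold_count(a_r, q)
    w <- threshold_count(a_w, q)
    cl <- classify_transition(q, r, w, z)
    data.frame(q = q, r = r, w = w, p_lower = cl$p_star,
               p_upper = cl$p_upper, type = cl$transition_type)
  })
  do.call(rbind, rows)
}
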