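# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: rates come from brute-force enumeration of every
# (target, panel) draw, mean-field closed forms from hand-reduced algebra.

# Exhaustive enumeration of all N * choose(N-1, q) equally likely
# (target, panel) draws for a configuration with n_up up agents. Pure
# counting; no binomial/hypergeometric functions involved.
enum_rates <- function(n_up, N, q, r, w) {
  ops <- c(rep(1L, n_up), rep(-1L, N - n_up))
  counts <- c(ap = 0, am = 0, bp = 0, bm = 0)
  total <- 0
  for (i in seq_len(N)) {
    others <- setdiff(seq_len(N), i)
    panels <- if (length(others) == 1) matrix(others, 1, 1)
              else utils::combn(others, q)
    for (k in seq_len(ncol(panels))) {
      total <- total + 1
      n_up_panel <- sum(ops[panels[, k]] == 1L)
      if (ops[i] == -1L) {
        if (n_up_panel >= r) counts["ap"] <- counts["ap"] + 1
        if (q - n_up_panel >= w) counts["bp"] <- counts["bp"] + 1
      } else {
        if (q - n_up_panel >= r) counts["am"] <- counts["am"] + 1
        if (n_up_panel >= w) counts["bm"] <- counts["bm"] + 1
      }
    }
  }
  list(alpha_plus = counts[["ap"]] / total, alpha_minus = counts[["am"]] / total,
       beta_plus = counts[["bp"]] / total, beta_minus = counts[["bm"]] / total,
       gamma_plus = (N - n_up) / (2 * N), gamma_minus = n_up / (2 * N))
}

# Hand-reduced closed forms for q = 3, unanimity thresholds r = w = 3:
# conformity + independence (z = 1) and conformity + anticonformity (z = 0).
p_closed_q3_z1 <- function(m) (1 - m^2) / (3 - m^2)
p_closed_q3_z0 <- function(m) (1 - m^2) / (3 + m^2)

# For unanimity thresholds r = w = q the conformity drive reduces to
# A(m) = v x^q - x v^q with x = (1+m)/2, v = (1-m)/2; with z = 1 the
# stationary relation is p = A / (A + m/2).
p_closed_unanimity_z1 <- function(m, q) {
  x <- (1 + m) / 2
  v <- (1 - m) / 2
  A <- v * x^q - x * v^q
  A / (A + m / 2)
}

# m -> 0 limits of the unanimity closed forms
p_star_unanimity_z1 <- function(q) (q - 1) / (q - 1 + 2^(q - 1))
p_star_unanimity_z0 <- function(q) (q - 1) / (2 * q)

# dense left-eigenvector oracle for the stationary distribution of the
# one-elementary-step birth-death transition matrix
eigen_stationary <- function(chain) {
  N <- chain$N
  M <- diag(chain$lambda_zero)
  for (n in 0:(N - 1)) M[n + 1, n + 2] <- chain$lambda_plus[n + 1]
  for (n in 1:N) M[n + 1, n] <- chain$lambda_minus[n + 1]
  e <- eigen(t(M))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

total_variation <- function(p1, p2) 0.5 * sum(abs(as.numeric(p1) - as.numeric(p2)))
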