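# Independent oracles used to validate the package's own implementations.
# Each is deliberately naive (fine-grid quadrature, ODE integration,
# explicit formula arithmetic, enumeration) and shares no code with the
# implementation it checks.

# Tofts convolution by brute-force fine-grid trapezoid quadrature of
# C_t(t) = Ktrans int_0^t Ca(u) exp(-Ktrans/ve (t-u)) du  (+ vp Ca(t)).
# aif_fun must be vectorized over time (s); rates in /min.
oracle_tofts_conv <- function(ktrans, ve, vp, aif_fun, times, dt_fine = 0.01) {
  kt <- ktrans / 60
  kep <- kt / ve
  vapply(times, function(t) {
    if (t <= 0) return(vp * aif_fun(t))
    u <- seq(0, t, by = dt_fine)
    if (u[length(u)] < t) u <- c(u, t)
    integrand <- aif_fun(u) * exp(-kep * (t - u))
    kt * sum(diff(u) * (integrand[-1] + integrand[-length(u)]) / 2) +
      vp * aif_fun(t)
  }, numeric(1))
}

# Brix relative signal by numerical integration of the two-compartment
# infusion ODE system (plasma with constant unit-rate infusion over tau,
# tissue exchanging with plasma). Rates /min, tau and times in s.
oracle_brix_ode <- function(a_brix, kep, kel, tau, times) {
  tau_m <- tau / 60
  rhs <- function(t, y, parms) {
    r <- if (t < tau_m) 1 else 0
    list(c(r - kel * y[1], y[1] - kep * y[2]))
  }
  tm <- sort(unique(c(0, pmax(times, 0) / 60, tau_m)))
  sol <- deSolve::ode(c(cp = 0, ct = 0), tm, rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  ct <- stats::approx(sol[, 1], sol[, 3], xout = pmax(times, 0) / 60)$y
  # amplitude convention: A multiplies the unit-infusion-rate tissue curve
  1 + a_brix * ct
}

# ICC(A,1) by explicit two-way ANOVA sum-of-squares arithmetic written out
# long-hand (cell-by-cell loops), independent of the implementation.
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_r <- 0
  for (i in seq_len(n)) ss_r <- ss_r + k * (sum(m[i, ]) / k - grand)^2
  ss_c <- 0
  for (j in seq_len(k)) ss_c <- ss_c + n * (sum(m[, j]) / n - grand)^2
  ss_t <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_t <- ss_t + (m[i, j] - grand)^2
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- (ss_t - ss_r - ss_c) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Lin CCC by direct formula arithmetic with population denominators.
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Exact Mann-Whitney p by full enumeration of all group assignments.
oracle_mwu_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_stat <- function(ga, gb) {
    sum(vapply(ga, function(x) sum(x > gb) + 0.5 * sum(x == gb), numeric(1)))
  }
  u_obs <- u_stat(a, b)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  # two-sided p: fraction of assignments at least as extreme as observed
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Pearson r by direct covariance/SD arithmetic.
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small ready-made study configs used across tests
tiny_config <- function(artery_jitter = 0, ...) {
  study_config(dim = c(12, 12, 4), n_artery = 60, lesion_size = 25,
               artery_jitter = artery_jitter, ...)
}
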