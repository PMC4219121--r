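# Independent brute-force oracles. Each is written from the definition with
# scalar loops (or a derivative-free root search on the written-out
# likelihood) and stays independent of the code paths it checks.

# Product-limit estimator, tabulated by hand at each distinct event time.
oracle_km <- function(times, events) {
  ev_t <- sort(unique(times[events == 1]))
  surv <- numeric(length(ev_t))
  s <- 1
  for (k in seq_along(ev_t)) {
    t <- ev_t[k]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ev_t, survival = surv)
}

# Two-group log-rank chi-square from the per-event-time hypergeometric
# tabulation (O - E and variance summed over event times).
oracle_logrank_chisq <- function(time, event, x) {
  ev_t <- sort(unique(time[event == 1]))
  OmE <- 0
  V <- 0
  for (t in ev_t) {
    at_risk <- time >= t
    nR <- sum(at_risk)
    n1R <- sum(at_risk & x == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & x == 1)
    OmE <- OmE + d1 - d * n1R / nR
    if (nR > 1) {
      V <- V + d * (n1R / nR) * (1 - n1R / nR) * (nR - d) / (nR - 1)
    }
  }
  OmE^2 / V
}

# The Efron-tie-corrected Cox log partial likelihood, written out directly.
oracle_efron_loglik <- function(beta, time, event, x) {
  r <- exp(beta * x)
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    A <- sum(r[R])
    B <- sum(r[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(A - (l / d) * B)
    }
    ll <- ll + beta * sum(x[D])
  }
  ll
}

# Maximizer of the written-out partial likelihood: root of the central
# difference score, located by bisection-grade uniroot.
oracle_cox_beta <- function(time, event, x, h = 1e-5) {
  g <- function(b) {
    (oracle_efron_loglik(b + h, time, event, x) -
       oracle_efron_loglik(b - h, time, event, x)) / (2 * h)
  }
  lo <- -1
  hi <- 1
  while (g(lo) < 0 && lo > -20) lo <- lo * 2
  while (g(hi) > 0 && hi < 20) hi <- hi * 2
  if (g(lo) < 0 || g(hi) > 0) return(NA_real_) # monotone likelihood
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

# Harrell's C by O(n^2) pair enumeration: a pair is usable when the
# event-bearing sample has the strictly shorter time, or ties a censored
# sample's time; both-event time ties are unusable; risk ties count 1/2.
oracle_cindex <- function(risk, time, event) {
  usable <- 0
  score <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] == 1 && (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))) {
        usable <- usable + 1
        if (risk[i] > risk[j]) score <- score + 1
        if (risk[i] == risk[j]) score <- score + 0.5
      }
    }
  }
  score / usable
}

# Step-up BH from the definition: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Random survival instance with optional time ties (integer rounding) for
# exercising the tie-handling paths.
random_surv_instance <- function(n, tie = FALSE, cens = 0.3) {
  time <- rexp(n, 0.05)
  if (tie) time <- ceiling(time)
  event <- as.numeric(runif(n) > cens)
  if (sum(event) == 0) event[sample.int(n, 2)] <- 1
  x <- rbinom(n, 1, 0.5)
  if (sum(x) == 0) x[1] <- 1
  if (sum(x) == n) x[1] <- 0
  list(time = time, event = event, x = x)
}
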