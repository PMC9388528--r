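# Independent oracles and small constructors shared across tests.

# Exact HWE p-value via the direct conditional (multinomial/hypergeometric)
# probability formula -- an independent route from the package's
# normalized-enumeration implementation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  ks <- seq(na %% 2, min(na, 2 * n - na), 2)
  lp <- vapply(ks, function(k) {
    nr <- (na - k) / 2
    nc <- n - k - nr
    lgamma(n + 1) - lgamma(nr + 1) - lgamma(k + 1) - lgamma(nc + 1) +
      k * log(2) + lgamma(na + 1) + lgamma(2 * n - na + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(lp)
  po <- pr[match(n_Aa, ks)]
  min(1, sum(pr[pr <= po * (1 + 1e-12)]))
}

# Brute-force BH step-up: adj_i = min over j with p_(j) >= p_(i) rank of
# p_(j) * m / j, capped at 1, in the original order.
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k))
    adj[i] <- min(1, min(ps[i:k] * m / (i:k)))
  out <- numeric(k)
  out[o] <- adj
  out
}

# OLS via explicit normal equations.
ols_oracle <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% b
  s2 <- sum(r^2) / (nrow(X) - ncol(X))
  list(coef = drop(b), se = sqrt(diag(s2 * solve(crossprod(X)))))
}

# Hand-built recording: a stationary eye at (x0, y0) with one optional
# velocity profile injected, plus a minimal message log. Times in ms.
make_recording <- function(x, y = rep(0, length(x)), fs = 1000,
                           blink = rep(0L, length(x)),
                           messages = data.frame(time_ms = 0,
                                                 event = "TARGET_ON 0.00 0.00")) {
  dt <- 1000 / fs
  list(samples = data.frame(time_ms = seq(0, by = dt,
                                          length.out = length(x)),
                            x_deg = x, y_deg = y, blink = blink),
       messages = messages, sampling_rate = fs)
}

# Raised-cosine horizontal movement of given amplitude/peak velocity
# injected into a flat trace at t_start (ms); returns the x vector.
inject_saccade <- function(n, t_start, amplitude, peak_velocity, x0 = 0,
                           fs = 1000) {
  dur <- 2 * abs(amplitude) / peak_velocity * 1000
  tms <- seq(0, by = 1000 / fs, length.out = n)
  u <- (tms - t_start) / dur
  x <- rep(x0, n)
  mid <- u >= 0 & u < 1
  x[mid] <- x0 + amplitude * (u[mid] - sin(2 * pi * u[mid]) / (2 * pi))
  x[u >= 1] <- x0 + amplitude
  x
}

# Per-trial metrics row in the shape produced by process_saccade_session.
metric_row <- function(trial, valid = TRUE, direction_correct = TRUE,
                       corrected = NA, latency = 200, gain = 95,
                       err = 5, pv = 360) {
  data.frame(trial = trial, side = "right", latency = latency,
             amplitude = gain / 100 * 9.63, amplitude_gain = gain,
             spatial_error = err, peak_velocity = pv,
             adj_peak_velocity = pv / (gain / 100 * 9.63),
             direction_correct = direction_correct, corrected = corrected,
             valid = valid,
             invalid_reason = ifelse(valid, "", "no_saccade"),
             stringsAsFactors = FALSE)
}
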