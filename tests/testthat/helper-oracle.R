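# Independent fixed-step RK4 integration of the three-state
# glucose-insulin core (no exercise subsystem), used as a reference for
# the event-driven solver. Shares nothing with the package's integrator.
bergman3_reference <- function(schedule, params, dt = 0.05,
                               horizon = 1440) {
  h <- if (is.na(params$h)) params$Gb else params$h
  meal_t <- schedule$meals$t0
  rhs <- function(t, y) {
    d <- meal_rate(t, schedule$meals, params)
    past <- meal_t[meal_t <= t]
    t_ref <- if (length(past)) t - max(past) else 0
    c(-params$eta * (y[1] - params$Ib) +
        params$gamma * max(y[3] - h, 0) * t_ref,
      -params$p2 * y[2] + params$p3 * (y[1] - params$Ib),
      -params$p1 * (y[3] - params$Gb) - y[2] * y[3] + d)
  }
  n <- round(horizon / dt)
  y <- c(params$Ib, 0, params$Gb)
  keep_every <- round(1 / dt)
  out <- matrix(NA_real_, nrow = horizon + 1L, ncol = 3L)
  out[1L, ] <- y
  for (i in seq_len(n)) {
    t <- (i - 1L) * dt
    k1 <- rhs(t, y)
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% keep_every == 0L) out[i / keep_every + 1L, ] <- y
  }
  data.frame(t = 0:horizon, I = out[, 1L], X = out[, 2L], G = out[, 3L])
}

# Closed-form mean/SD of a normal truncated to [lo, hi].
tnorm_moments <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  Z <- pnorm(b) - pnorm(a)
  mu <- m + s * (dnorm(a) - dnorm(b)) / Z
  v <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = mu, sd = sqrt(v))
}

# Truncation interval actually used by the generator for each factor.
generator_bounds <- function(field, ms, trunc_sd = 3) {
  lo <- ms[1] - trunc_sd * ms[2]; hi <- ms[1] + trunc_sd * ms[2]
  switch(field,
         age = c(max(20, lo), min(75, hi)),
         basal_glucose = c(max(60, lo), min(130, hi)),
         bmi = c(max(15, lo), hi),
         height = c(max(1.2, lo), hi),
         cho_total = c(max(50, lo), hi),
         c(lo, hi))
}
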