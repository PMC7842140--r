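# Independent brute-force oracles and small data builders used across the
# suite. These deliberately avoid the package's own code paths (and the
# survival package) so agreement is a genuine cross-check.

# Product-limit estimator by direct risk-set counting.
oracle_km <- function(time, event) {
  s <- 1
  out <- data.frame(time = 0, survival = 1)
  for (tt in sort(unique(time[event == 1]))) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = tt, survival = s))
  }
  out
}

# Mantel-Haenszel log-rank chi-square by explicit risk-table enumeration,
# hypergeometric variance, ties pooled per distinct event time.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(0:1, c(length(time_a), length(time_b)))
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 0)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 0)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(NA_real_)
  (O - E)^2 / V
}

# Noise-free volume points on a dose x time grid from given parameters.
exact_volume_points <- function(params, doses = c(40, 60, 80),
                                times = c(2, 5, 9, 14, 20, 26)) {
  pts <- expand.grid(dose = doses, t = times)
  pts$volume <- predict_volume(pts$dose, pts$t, params,
                               warn_pre_onset = FALSE)
  pts$mouse_id <- paste0("m", seq_len(nrow(pts)))
  pts
}

# Onset observations lying exactly on the onset line of `params`.
exact_onsets <- function(params, doses = c(40, 60, 80)) {
  data.frame(mouse_id = paste0("m", seq_along(doses)), dose = doses,
             onset_week = onset_time(doses, params))
}
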