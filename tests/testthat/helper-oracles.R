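# Independent brute-force oracles, kept free of the package's code paths.

# Two-group log-rank by explicit 2x2 hypergeometric tables at each distinct
# event time. Returns the chi-square statistic and the O - E excess of the
# first group.
logrank_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  excess <- O - E
  stat <- if (V > 0) excess^2 / V else 0
  list(statistic = stat, excess_first = excess, first_group = g1)
}

# Type-7 (linear interpolation between order statistics) sample quantile,
# written from the order-statistics definition.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Product-limit estimator computed directly from its definition.
km_oracle <- function(time, event, at_times) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(at_times))
  for (i in seq_along(at_times)) {
    s <- 1
    for (t in ts[ts <= at_times[i]]) {
      n <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s <- s * (1 - d / n)
    }
    out[i] <- s
  }
  out
}
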