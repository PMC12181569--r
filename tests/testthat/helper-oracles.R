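# Independent brute-force oracles, kept deliberately naive: they recompute
# risk sets by direct counting at every step and never call the package's
# own survival code (nor the survival package).

# product-limit estimator by direct risk-set counting
km_oracle <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  nrisk <- integer(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    d <- sum(events == 1 & times == ts[i])
    nrisk[i] <- sum(times >= ts[i])
    s <- s * (1 - d / nrisk[i])
    surv[i] <- s
  }
  med <- if (any(surv <= 0.5)) ts[which(surv <= 0.5)[1]] else NA_real_
  list(event_times = ts, surv = surv, n_at_risk = nrisk, median = med)
}

# two-group log-rank: observed-minus-expected with hypergeometric variance
logrank_oracle <- function(times, events, group) {
  group <- as.logical(group)
  ts <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & group)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & group)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  list(chi_square = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# exhaustive enumeration of every quartile-bounded split, log-rank p at each
scan_oracle <- function(scores, times, events, probs = c(0.25, 0.75)) {
  qb <- quantile(scores, probs = probs, names = FALSE)
  cand <- sort(unique(scores[scores >= qb[1] & scores <= qb[2]]))
  p <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    high <- scores > cand[i]
    if (sum(high) == 0 || sum(!high) == 0) next
    p[i] <- logrank_oracle(times, events, high)$p
  }
  list(cutoffs = cand, p = p, selected_index = which.min(p))
}

# one random survival fixture with continuous times (no ties, unique min p)
random_surv_fixture <- function(n, event_prob = 0.6) {
  list(scores = rlnorm(n, log(1000), 0.4),
       times = round(rexp(n, 1 / 40) + runif(n), 3),
       events = rbinom(n, 1, event_prob))
}
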