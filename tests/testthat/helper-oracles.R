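# Independent oracles the implementation is checked against.

# Brute-force expectation for one stratum pathway by enumerating all 2^k
# quit/not-quit outcome vectors: element j says whether the person would
# quit at stage j if they attempted it (probability quit[j], independent).
# A person attempts stages until their first success; counselling costs
# are incurred by everyone, pharmacotherapy costs only on stages attempted.
oracle_stratum <- function(quit, cost, kind) {
  k <- length(quit)
  counselling_cost <- sum(cost[kind == "counselling"])
  if (k == 0L) return(list(quit_rate = 0, cost_per_person = counselling_cost))
  exp_quit <- 0
  exp_cost <- 0
  for (mask in 0:(2^k - 1)) {
    b <- as.integer(intToBits(mask))[seq_len(k)]
    p <- prod(ifelse(b == 1, quit, 1 - quit))
    first <- which(b == 1)[1]
    reached <- if (is.na(first)) seq_len(k) else seq_len(first)
    path_cost <- counselling_cost +
      sum(cost[reached][kind[reached] == "pharmacotherapy"])
    exp_quit <- exp_quit + p * (!is.na(first))
    exp_cost <- exp_cost + p * path_cost
  }
  list(quit_rate = exp_quit, cost_per_person = exp_cost)
}

# Frontier oracle: a strategy is on the cost-effectiveness frontier iff it
# maximizes net monetary benefit lambda * effect - cost for some positive
# willingness to pay. Probing the midpoints between all pairwise slopes
# (plus values below and above the whole range) finds every maximizer.
oracle_frontier <- function(totals) {
  e <- totals$quitters
  c_ <- totals$cost_inr
  n <- length(e)
  slopes <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (e[j] != e[i]) {
        s <- (c_[j] - c_[i]) / (e[j] - e[i])
        if (s > 0) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(unique(slopes))
  lambdas <- if (length(slopes) == 0L) {
    # no positive trade-off anywhere: one strategy wins at every lambda
    c(1e-9, 1)
  } else {
    c(slopes[1] / 2, (slopes[-1] + slopes[-length(slopes)]) / 2,
      2 * slopes[length(slopes)])
  }
  retained <- character(0)
  for (l in lambdas) {
    nmb <- l * e - c_
    win <- which(nmb == max(nmb))
    if (length(win) > 1) win <- win[which.min(c_[win])]
    retained <- union(retained, totals$strategy[win])
  }
  sort(retained)
}
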