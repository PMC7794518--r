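# Independent oracles, kept free of the implementation paths they check.

# Largest p with P(X >= k | Binomial(n, p)) <= 1 - level, by bisection on
# the binomial survival function (monotone increasing in p). Vectorized
# over k and n.
bisect_lower_bound <- function(k, n, level = 0.95, iter = 60) {
  m <- max(length(k), length(n))
  k <- rep_len(k, m); n <- rep_len(n, m)
  lo <- numeric(m); hi <- rep(1, m)
  alpha <- 1 - level
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    surv <- stats::pbinom(k - 1, n, mid, lower.tail = FALSE)
    up <- surv <= alpha
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  out <- (lo + hi) / 2
  out[k == 0] <- 0
  out
}

# Two-sided Fisher p by brute-force enumeration: all tables with the
# observed margins, probabilities from binomial coefficients, summing
# those no more likely than the observed table (relative tolerance for
# floating-point ties).
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- prob[match(a, xs)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Small helper: truth class lookup for kept variants of one cohort.
truth_class_lookup <- function(cohort) {
  muts <- do.call(rbind, lapply(cohort$truth, function(t) {
    data.frame(patient_id = t$patient_id,
               variant_id = t$mutations$mutation_id,
               class = t$mutations$class, stringsAsFactors = FALSE)
  }))
  rownames(muts) <- NULL
  muts
}
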