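# Independent brute-force oracles and small record builders shared by the
# tests. The oracles deliberately avoid the package's own code paths.

# grid posterior computed from the raw binomial formula (no dbinom),
# uniform prior; returns point estimate and central 95% interval
brute_ccf_oracle <- function(alt, depth, purity, total_cn = 2,
                             multiplicity = 1) {
  grid <- seq(0.01, 1, length.out = 100)
  f <- purity * grid * multiplicity /
    (purity * total_cn + (1 - purity) * 2)
  loglik <- alt * log(f) + (depth - alt) * log1p(-f)
  if (alt == 0) loglik <- (depth - alt) * log1p(-f)
  if (alt == depth) loglik <- alt * log(f)
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  cum <- cumsum(post)
  list(point = grid[which.max(post)],
       ci_low = grid[min(which(cum >= 0.025))],
       ci_high = grid[min(which(cum >= 0.975))])
}

# minimum read support by direct tail scan (oracle for min_detectable_reads)
brute_kstar <- function(depth, error, fpr) {
  tail_p <- function(k) sum(stats::dbinom(k:depth, depth, error))
  for (k in 1:depth) if (tail_p(k) <= fpr) return(k)
  NA_integer_
}

# two-sided Fisher p by exhaustive enumeration of 2x2 tables with the
# observed margins (oracle for fisher.test-based operations)
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney pairwise concordance with ties counted 1/2 (AUC oracle)
concordance_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# MutationRecord rows for hand-built rescue scenarios
mut_rec <- function(sample, pos, alt_reads, depth, bq = 35, mq = 60,
                    patient = "PT1") {
  data.frame(patient = patient, sample = sample, chrom = "chr1", pos = pos,
             ref = "A", alt = "T", gene = sprintf("G%d", pos),
             coding = TRUE, alt_reads = alt_reads, depth = depth,
             base_quality = bq, map_quality = mq, stringsAsFactors = FALSE)
}

# driver presence matrix: t truncal drivers plus extras with given
# harboring-lesion index sets
driver_presence <- function(n_lesions, n_truncal, extra_sets = list()) {
  rows <- c(replicate(n_truncal, rep(TRUE, n_lesions), simplify = FALSE),
            lapply(extra_sets, function(s) seq_len(n_lesions) %in% s))
  do.call(rbind, rows)
}
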