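test_that("ploidy-relative CNA classes are exclusive and exhaustive", {
  for (ploidy in seq(1.5, 5, by = 0.5)) {
    for (total in 0:12) {
      minor <- sample(0:(total %/% 2), 1)
      seg <- data.frame(major = total - minor, minor = minor)
      cl <- classify_cna(seg, ploidy)
      # re-derive the class from the inequality definitions
      expected <- if (total == 0) "homozygous_del"
      else if (total >= 3 * ploidy) "high_amp"
      else if (total >= 2 * ploidy) "gain"
      else if (total < ploidy / 2) "partial_del"
      else "neutral"
      expect_equal(cl$class, expected)
      expect_equal(cl$loh, minor == 0 && total > 0)
    }
  }
  expect_error(classify_cna(data.frame(major = -1, minor = 0), 2),
               "negative")
})

test_that("canonical amplification and gain examples classify correctly", {
  segs <- data.frame(major = c(5, 3, 0), minor = c(1, 1, 0))
  cl <- classify_cna(segs, ploidy = 2)
  expect_equal(cl$class, c("high_amp", "gain", "homozygous_del"))
})

test_that("CIN equals the brute-force per-base altered fraction", {
  expect_equal(cin(data.frame(chrom = "chr1", start = 1, end = 1000,
                              major = 1, minor = 1), 2, 1000), 0)
  expect_equal(cin(data.frame(chrom = "chr1", start = 1, end = 1000,
                              major = 3, minor = 1), 2, 1000), 1)
  expect_equal(cin(data.frame(chrom = "chr1", start = 1, end = 900e6,
                              major = 2, minor = 2), 2, 3000e6), 0.3)
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    bounds <- sort(sample(1:999, n))
    starts <- c(1, bounds + 1)
    ends <- c(bounds, 1000)
    segs <- data.frame(chrom = "chr1", start = starts, end = ends,
                       major = sample(0:3, n + 1, replace = TRUE),
                       minor = 0)
    segs$minor <- pmin(segs$major, sample(0:1, n + 1, replace = TRUE))
    got <- cin(segs, 2, 1000)
    per_base <- rep(FALSE, 1000)
    for (i in seq_len(nrow(segs))) {
      tot <- segs$major[i] + segs$minor[i]
      if (tot != 2 || (segs$minor[i] == 0 && tot > 0))
        per_base[segs$start[i]:segs$end[i]] <- TRUE
    }
    expect_equal(got, mean(per_base))
  }
})

test_that("SCNA similarity is base-level with event-class matching", {
  amp <- data.frame(chrom = "chr1", start = 1, end = 100, major = 5,
                    minor = 1)
  neutral <- data.frame(chrom = "chr1", start = 1, end = 100, major = 1,
                        minor = 1)
  expect_equal(scna_jaccard(amp, amp), 1)
  expect_true(is.na(scna_jaccard(neutral, neutral)))
  # disjoint altered regions
  amp2 <- data.frame(chrom = "chr1", start = 101, end = 200, major = 5,
                     minor = 1)
  expect_equal(scna_jaccard(rbind(amp, data.frame(chrom = "chr1",
                                                  start = 101, end = 200,
                                                  major = 1, minor = 1)),
                            rbind(neutral, amp2)), 0)
  # same interval but different event class contributes only to the union
  del <- data.frame(chrom = "chr1", start = 1, end = 100, major = 0,
                    minor = 0)
  expect_equal(scna_jaccard(amp, del), 0)
  # breakpoint jitter: half-overlapping identical gains
  a <- data.frame(chrom = "chr1", start = 1, end = 100, major = 3, minor = 1)
  b <- data.frame(chrom = "chr1", start = 51, end = 150, major = 3,
                  minor = 1)
  expect_equal(scna_jaccard(a, b), 50 / 150)
})

test_that("mutation-loss detection follows the three-condition rule", {
  calls <- mut_rec("A", c(100, 200, 300), 40, 100)
  pileup <- rbind(calls,
                  mut_rec("B", c(100, 200, 300), 0, 100),
                  mut_rec("C", c(100, 200, 300), 0, 100))
  pm <- classify_mutations(rescue_mutations(calls, pileup))
  expect_equal(unique(pm$class), "private")
  loh <- matrix(FALSE, 3, 3, dimnames = dimnames(pm$status))
  # mut 1: absent lesions both LOH -> loss event
  loh[1, c("B", "C")] <- TRUE
  # mut 2: one absent lesion lacks LOH -> removed from consideration
  loh[2, "B"] <- TRUE
  # mut 3: no LOH anywhere -> not evaluable either
  res <- detect_mutation_loss(pm, loh)
  expect_equal(res$loss_event, c(TRUE, FALSE, FALSE))
  expect_equal(res$evaluable, c(TRUE, FALSE, FALSE))
})

test_that("mutation observed only under LOH is not a loss event", {
  calls <- mut_rec("A", 100, 40, 100)
  pileup <- rbind(calls, mut_rec("B", 100, 0, 100))
  pm <- classify_mutations(rescue_mutations(calls, pileup))
  loh <- matrix(TRUE, 1, 2, dimnames = dimnames(pm$status))
  res <- detect_mutation_loss(pm, loh)
  expect_false(res$loss_event)  # condition (i) fails: mutation sits on LOH
})

test_that("loss-free simulated patients yield zero loss events", {
  co <- simulate_cohort(sim_config(n_patients = 1, lesions_per_patient = 5,
                                   seed = 41))
  tp <- co$tissue
  pm <- classify_mutations(power_filter(
    rescue_mutations(tp[tp$called, ], tp), co$sample_sheet))
  loh <- matrix(FALSE, nrow(pm$status), ncol(pm$status),
                dimnames = dimnames(pm$status))
  res <- detect_mutation_loss(pm, loh)
  expect_equal(sum(res$loss_event), 0)
})
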