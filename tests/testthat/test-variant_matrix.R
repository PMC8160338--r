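test_that("rescue scores support above threshold and respects qualities", {
  calls <- mut_rec("A", 100, 40, 100)
  pileup <- rbind(mut_rec("A", 100, 40, 100),
                  mut_rec("B", 100, 3, 90),            # rescued
                  mut_rec("C", 100, 2, 95),            # below threshold
                  mut_rec("D", 100, 5, 95, mq = 40),   # fails mapping quality
                  mut_rec("E", 100, 5, 95, bq = 20))   # fails base quality
  pm <- rescue_mutations(calls, pileup)
  st <- pm$status[1, ]
  expect_equal(unname(st[c("A", "B", "C", "D", "E")]),
               c("called", "rescued", "absent", "absent", "absent"))
})

test_that("missing pileup yields unpowered cells and calls are kept", {
  calls <- rbind(mut_rec("A", 100, 40, 100), mut_rec("A", 200, 30, 80))
  pileup <- rbind(mut_rec("A", 100, 40, 100), mut_rec("B", 100, 3, 90))
  pm <- rescue_mutations(calls, pileup)
  expect_equal(pm$status["chr1:200:A:T", "B"], "unpowered")
  expect_equal(pm$status["chr1:200:A:T", "A"], "called")
  # read support from the call backfills the matrix when pileup lacks it
  expect_equal(pm$alt["chr1:200:A:T", "A"], 30)
})

test_that("rescue is monotone and idempotent on simulated patients", {
  co <- simulate_cohort(sim_config(n_patients = 2, lesions_per_patient = 6,
                                   seed = 14))
  for (p in unique(co$truth$patient)) {
    tp <- co$tissue[co$tissue$patient == p, ]
    calls <- tp[tp$called, ]
    pm <- rescue_mutations(calls, tp)
    pres_after <- colSums(pm$status == "called" | pm$status == "rescued")
    pres_before <- vapply(pm$lesions, function(l)
      sum(calls$sample == l & calls$mut_id %in% pm$muts$mut_id), numeric(1))
    expect_true(all(pres_after >= pres_before))
    expect_identical(rescue_mutations(calls, tp)$status, pm$status)
  }
})

test_that("power filter applies the binomial detection-probability rule", {
  calls <- mut_rec("A", 100, 40, 100)
  sheet <- data.frame(sample = c("A", "B"), patient = "PT1",
                      purity = c(0.5, 0.5), ploidy = 2)
  # d=100, purity 0.5 (expected VAF 0.25): essentially certain detection
  pm <- power_filter(rescue_mutations(calls, rbind(
    calls, mut_rec("B", 100, 0, 100))), sheet)
  expect_true(pm$powered[1])
  # d=3 with expected VAF 0.1 (purity 0.2): P(X>=3) = 0.001
  sheet$purity <- c(0.2, 0.2)
  pm <- power_filter(rescue_mutations(calls, rbind(
    calls, mut_rec("B", 100, 0, 3))), sheet)
  expect_false(pm$powered[1])
  # purity 1, d=30 (VAF 0.5): powered
  sheet$purity <- c(1, 1)
  pm <- power_filter(rescue_mutations(calls, rbind(
    calls, mut_rec("B", 100, 0, 30))), sheet)
  expect_true(pm$powered[1])
  # zero depth is never powered
  sheet$purity <- c(1, 1)
  pm <- power_filter(rescue_mutations(calls, rbind(
    calls, mut_rec("B", 100, 0, 0))), sheet)
  expect_false(pm$powered[1])
})

test_that("classes partition powered mutations into truncal/branch/private", {
  co <- simulate_cohort(sim_config(n_patients = 3, seed = 31))
  for (p in unique(co$truth$patient)) {
    tp <- co$tissue[co$tissue$patient == p, ]
    pm <- rescue_mutations(tp[tp$called, ], tp)
    pm <- power_filter(pm, co$sample_sheet)
    pm <- classify_mutations(pm)
    cls <- pm$class
    expect_equal(sum(cls %in% c("truncal", "branch", "private")),
                 sum(pm$powered))
    npres <- rowSums(pm$status == "called" | pm$status == "rescued")
    N <- length(pm$lesions)
    expect_true(all(npres[cls == "truncal"] == N))
    expect_true(all(npres[cls == "private"] == 1))
    expect_true(all(npres[cls == "branch"] >= 2 &
                      npres[cls == "branch"] < N))
  }
})

test_that("undetectable truncal mutations in an underpowered lesion are excluded, not misclassified", {
  # lesion C is low purity and shallow: a truly truncal mutation reads as
  # absent there; without the power filter it is (wrongly) branch
  calls <- rbind(mut_rec("A", 100, 40, 100), mut_rec("B", 100, 38, 100))
  pileup <- rbind(calls, mut_rec("C", 100, 0, 10))
  sheet <- data.frame(sample = c("A", "B", "C"), patient = "PT1",
                      purity = c(0.6, 0.6, 0.1), ploidy = 2)
  naive <- classify_mutations(rescue_mutations(calls, pileup))
  expect_equal(naive$class[1], "branch")
  strict <- classify_mutations(power_filter(rescue_mutations(calls, pileup),
                                            sheet))
  expect_equal(strict$class[1], "unclassifiable")
})

test_that("jaccard matches explicit set arithmetic and brute force", {
  calls <- rbind(mut_rec("A", c(100, 200, 300), 40, 100),
                 mut_rec("B", c(200, 300, 400), 40, 100))
  pileup <- rbind(calls, mut_rec("A", 400, 0, 100),
                  mut_rec("B", 100, 0, 100))
  pm <- rescue_mutations(calls, pileup)
  j <- jaccard_similarity(pm)
  expect_equal(j$matrix["A", "B"], 0.5)  # {100,200,300} vs {200,300,400}
  expect_true(isSymmetric(j$matrix))
  expect_equal(unname(diag(j$matrix)), c(1, 1))
  # brute force over random presence matrices
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:8, 1); m <- sample(5:30, 1)
    pres <- matrix(runif(n * m) < 0.5, m, n)
    pm2 <- pm
    pm2$status <- ifelse(pres, "called", "absent")
    dimnames(pm2$status) <- list(sprintf("m%d", 1:m), sprintf("L%d", 1:n))
    pm2$alt <- pm2$depth <- matrix(100, m, n, dimnames = dimnames(pm2$status))
    pm2$lesions <- sprintf("L%d", 1:n)
    pm2$powered <- rep(TRUE, m)
    jm <- jaccard_similarity(pm2)$matrix
    for (i in 1:(n - 1)) for (k in (i + 1):n) {
      un <- sum(pres[, i] | pres[, k])
      expected <- if (un == 0) NA_real_ else sum(pres[, i] & pres[, k]) / un
      expect_equal(jm[i, k], expected)
    }
  }
})

test_that("TMB counts filtered coding mutations per powered megabase", {
  rec <- data.frame(coding = TRUE, alt_reads = rep(10, 60),
                    depth = rep(100, 60))
  expect_equal(tmb(rec, powered_coding_bases = 30e6), 2.0)
  low_vaf <- data.frame(coding = TRUE, alt_reads = 1, depth = 200)  # 0.005
  expect_equal(tmb(low_vaf, 1e6), 0)
  shallow <- data.frame(coding = TRUE, alt_reads = 10, depth = 25)
  expect_equal(tmb(shallow, 1e6), 0)
  expect_error(tmb(rec, 0), "positive")
})

test_that("MAD is the unscaled median absolute deviation", {
  expect_equal(dispersion_mad(c(1, 1, 1)), 0)
  expect_equal(dispersion_mad(c(1, 2, 3, 4, 100)), 1)
  expect_equal(dispersion_mad(5), 0)
  expect_error(dispersion_mad(numeric(0)), "empty")
})

test_that("lesion downsampling reproduces the full median at full size", {
  co <- simulate_cohort(sim_config(n_patients = 1, lesions_per_patient = 6,
                                   seed = 17))
  tp <- co$tissue
  pm <- classify_mutations(power_filter(
    rescue_mutations(tp[tp$called, ], tp), co$sample_sheet))
  full <- jaccard_similarity(pm)$median
  reps <- downsample_jaccard(pm, n_lesions = 6, n_reps = 5, seed = 2)
  expect_equal(reps, rep(full, 5))
  expect_identical(downsample_jaccard(pm, 3, 10, seed = 4),
                   downsample_jaccard(pm, 3, 10, seed = 4))
  expect_error(downsample_jaccard(pm, 1, 5), ">= 2")
  expect_error(downsample_jaccard(pm, 7, 5), "exceeds")
  # an all-truncal matrix has median similarity 1 at any subset size
  pm$status[] <- "called"
  pm$powered <- rep(TRUE, nrow(pm$status))
  expect_equal(unique(downsample_jaccard(pm, 3, 10, seed = 1)), 1)
})
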