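test_that("error-controlled read threshold matches the brute-force scan", {
  m <- power_model()
  expect_equal(min_detectable_reads(1000, m), 10L)
  expect_equal(min_detectable_reads(1000, m),
               brute_kstar(1000, m$per_base_error, m$fpr))
  # degenerate bounds: huge tolerated FPR or vanishing error rate
  expect_equal(min_detectable_reads(500, power_model(fpr = 0.999)), 1L)
  expect_equal(min_detectable_reads(500,
                                    power_model(per_base_error = 1e-12)), 1L)
  expect_error(min_detectable_reads(2, power_model(per_base_error = 0.4)),
               "too low")
})

test_that("k* is monotone over the (fpr, error, depth) lattice", {
  for (d in c(200, 800, 2000)) {
    for (err in c(5e-4, 1e-3, 3e-3)) {
      for (fpr in c(1e-8, 5e-7, 1e-5)) {
        k <- min_detectable_reads(d, power_model(fpr = fpr,
                                                 per_base_error = err))
        expect_equal(k, brute_kstar(d, err, fpr))
        # non-increasing in fpr
        expect_gte(k, min_detectable_reads(
          d, power_model(fpr = fpr * 10, per_base_error = err)))
        # non-decreasing in error rate
        expect_gte(min_detectable_reads(
          d, power_model(fpr = fpr, per_base_error = err * 2)), k)
      }
    }
  }
})

test_that("detection power is monotone in CCF and saturates", {
  pow <- suppressWarnings(
    detection_power(seq(0.05, 1, by = 0.05), tumor_fraction = 0.3,
                    depth = 1200))
  expect_true(all(diff(pow) >= 0))
  expect_gt(detection_power(1, tumor_fraction = 1, depth = 1000), 0.999)
  # low CCFs whose expected VAF sits at the error floor are flagged
  expect_warning(p <- detection_power(0.005, tumor_fraction = 0.3,
                                      depth = 1200), "unreliable")
  expect_true(attr(p, "unreliable"))
})

test_that("minimum detectable CCF inverts the power curve consistently", {
  for (tf in c(0.1, 0.3)) {
    cc <- min_detectable_ccf(tf, depth = 1200)
    expect_gte(detection_power(cc, tf, 1200), 0.9)
    expect_lt(suppressWarnings(detection_power(cc - 0.01, tf, 1200)), 0.9)
  }
  expect_warning(res <- min_detectable_ccf(0.005, depth = 100), "below")
  expect_true(is.na(res))
})

test_that("plasma detection rescues at three reads and filters de novo variants", {
  ts <- data.frame(mut_id = c("m1", "m2", "m3", "m4"),
                   class = c("truncal", "branch", "private", "branch"),
                   k = c(5, 3, 1, 2), max_ccf = 1)
  plasma <- data.frame(
    mut_id = c("m1", "m2", "m3", "d1", "d2"),
    alt_reads = c(3, 0, 600, 5, 12),
    depth = c(1200, 1200, 1200, 1250, 1200))
  det <- detect_in_cfdna(ts, plasma, tumor_fraction = 0.3)
  expect_equal(det$detected, c(TRUE, FALSE, TRUE, NA))
  expect_true(is.na(det$ctdna_ccf[2]))
  # VAF 0.5/0.15 -> CCF 1 for m3 at tumor fraction 0.3
  expect_equal(det$ctdna_ccf[3], 1)
  denovo <- attr(det, "plasma_only")
  expect_equal(denovo$mut_id, "d2")  # d1 VAF 0.004 filtered, d2 0.01 kept
})

test_that("detection model recovers odds ratios and flags degeneracies", {
  set.seed(33)
  n <- 600
  k <- sample(1:10, n, replace = TRUE)
  detected <- runif(n) < plogis(-2.5 + log(2) * k)
  rec <- data.frame(detected = detected, k = k, max_ccf = runif(n))
  fit <- detection_model(rec)
  expect_false(fit$separation)
  expect_gt(fit$ci["k", "lower"], 1)      # positive lesion-count effect
  expect_true(fit$ci["k", "lower"] < 2 & fit$ci["k", "upper"] > 2)
  # constant k: coefficient undefined
  expect_error(detection_model(data.frame(detected = rep(c(TRUE, FALSE), 10),
                                          k = 3, max_ccf = runif(20))),
               "constant")
  # one outcome class only
  expect_error(detection_model(data.frame(detected = TRUE, k = 1:10,
                                          max_ccf = runif(10))),
               "both detected and undetected")
  # complete separation triggers the penalized fallback
  sep <- data.frame(detected = rep(c(FALSE, TRUE), each = 20),
                    k = rep(c(1, 9), each = 20),
                    max_ccf = runif(40))
  expect_warning(sfit <- detection_model(sep), "separation")
  expect_true(sfit$separation)
  expect_true(is.finite(sfit$coef["k"]) && sfit$coef["k"] > 0)
})

test_that("CCF-versus-lesions slope is exact on noiseless mixtures", {
  N <- 12
  rec <- data.frame(detected = TRUE, k = rep(1:11, each = 3))
  rec$ctdna_ccf <- rec$k / N
  fit <- suppressWarnings(ccf_vs_lesions_model(rec))  # exact fit
  expect_equal(fit$slope, 1 / N)
  flat <- data.frame(detected = TRUE, k = 1:10, ctdna_ccf = 0.4)
  expect_equal(suppressWarnings(ccf_vs_lesions_model(flat))$slope, 0)
  expect_error(ccf_vs_lesions_model(rec[1, ]), "at least 3")
})

test_that("branch/private contrast matches the enumeration oracle", {
  rec <- data.frame(class = rep(c("branch", "private"), c(10, 10)),
                    detected = rep(c(TRUE, FALSE, TRUE, FALSE),
                                   c(5, 5, 5, 5)))
  res <- branch_vs_private_test(rec)
  expect_equal(res$p_value, 1)
  set.seed(4)
  for (rep in 1:10) {
    cl <- sample(c("branch", "private"), 40, replace = TRUE)
    de <- runif(40) < ifelse(cl == "branch", 0.8, 0.2)
    if (length(unique(cl)) < 2) next
    r <- branch_vs_private_test(data.frame(class = cl, detected = de))
    expect_equal(r$p_value, enum_fisher_p(unclass(r$table)),
                 tolerance = 1e-7)
  }
  expect_error(branch_vs_private_test(
    data.frame(class = "branch", detected = TRUE)), "both")
})
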