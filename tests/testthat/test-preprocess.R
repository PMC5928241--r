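make_intensities <- function(M, U, det = NULL) {
  dimnames(M) <- dimnames(U) <-
    list(sprintf("cg%03d", seq_len(nrow(M))),
         sprintf("s%02d", seq_len(ncol(M))))
  if (is.null(det)) det <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  else dimnames(det) <- dimnames(M)
  intensity_matrix(M, U, det)
}

test_that("joint quantile normalization matches the order-statistic oracle", {
  # 2 probes x 2 samples; stacked M/U vectors are (1,3,2,4) and (5,7,6,8)
  x <- make_intensities(M = cbind(c(1, 3), c(5, 7)),
                        U = cbind(c(2, 4), c(6, 8)))
  qn <- quantile_normalize_signals(x)
  # brute force: sorted columns (1,2,3,4) and (5,6,7,8) -> means (3,4,5,6),
  # reassigned by within-sample rank
  expect_equal(unname(qn$M), cbind(c(3, 5), c(3, 5)))
  expect_equal(unname(qn$U), cbind(c(4, 6), c(4, 6)))

  # identical samples are a fixed point
  x2 <- make_intensities(M = cbind(c(10, 40), c(10, 40)),
                         U = cbind(c(20, 5), c(20, 5)))
  qn2 <- quantile_normalize_signals(x2)
  expect_equal(qn2$M, x2$M)
  expect_equal(qn2$U, x2$U)
})

test_that("normalized samples share a distribution and keep their ranks", {
  set.seed(41)
  x <- make_intensities(M = matrix(rexp(60, 1e-3), 20, 3),
                        U = matrix(rexp(60, 2e-3), 20, 3))
  qn <- quantile_normalize_signals(x)
  stacked <- rbind(qn$M, qn$U)
  sorted <- apply(stacked, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 1], sorted[, 3])
  raw <- rbind(x$M, x$U)
  for (j in 1:3)
    expect_equal(order(stacked[, j]), order(raw[, j]))
  expect_error(quantile_normalize_signals(
    make_intensities(M = matrix(1:4, 4, 1), U = matrix(1:4, 4, 1))),
    "at least 2 samples")
})

test_that("beta computation follows M/(M+U) with missing at zero total", {
  x <- make_intensities(M = cbind(c(100, 0, 50), c(0, 300, 7)),
                        U = cbind(c(300, 0, 50), c(0, 100, 7)))
  b <- compute_beta(x)
  expect_equal(unname(b[1, ]), c(0.25, NA))
  expect_equal(unname(b[2, ]), c(NA, 0.75))
  expect_equal(unname(b[3, ]), c(0.5, 0.5))
})

test_that("detection masking hits exactly the planted coordinates", {
  set.seed(42)
  det <- matrix(0, 5, 4)
  fails <- rbind(c(1, 2), c(3, 3), c(5, 1))
  det[fails] <- 0.5
  x <- make_intensities(M = matrix(100, 5, 4), U = matrix(100, 5, 4), det)
  b0 <- compute_beta(x)
  b <- mask_detection_failures(b0, x$detection_p)
  expect_equal(sum(is.na(b)), 3)
  expect_true(all(is.na(b[fails])))
  expect_equal(b[!is.na(b)], b0[!is.na(b)]) # surviving values untouched
  expect_identical(mask_detection_failures(b0, matrix(0, 5, 4)), b0)
  expect_true(all(is.na(mask_detection_failures(b0, matrix(1, 5, 4)))))
  expect_error(mask_detection_failures(b0, matrix(0, 4, 4)), "dimensions")
})

test_that("probe filter uses a strict 10% missingness boundary", {
  b <- matrix(0.5, 3, 10,
              dimnames = list(c("keep0", "keep1", "drop2"), NULL))
  b["keep1", 1] <- NA          # 10% missing: retained (strict >)
  b["drop2", 1:2] <- NA        # 20% missing: dropped
  f <- filter_probes(b)
  expect_identical(rownames(f$beta), c("keep0", "keep1"))
  expect_identical(f$removed_probes, "drop2")
  expect_identical(filter_probes(f$beta)$removed_probes, character(0))
})

test_that("sample filter applies call-rate, intensity and median rules", {
  # 50 probes x 10 samples; sample 1: call rate 0.90; sample 2: intensity
  # 40% of the median; all others healthy
  M <- matrix(3000, 50, 10)
  U <- matrix(3000, 50, 10)
  det <- matrix(0, 50, 10)
  det[1:5, 1] <- 0.5                  # call rate 45/50 = 0.90 < 0.95
  M[, 2] <- 1200; U[, 2] <- 1200      # avg 1200 < 0.5 * median(≈3000)
  x <- make_intensities(M, U, det)
  b <- compute_beta(x)
  f <- filter_samples(x, b)
  expect_equal(sum(f$report$excluded), 2)
  expect_true(f$report$fail_call_rate[1])
  expect_false(f$report$fail_min_intensity[1])
  expect_true(f$report$fail_median_frac[2])
  expect_true(f$report$fail_min_intensity[2]) # 1200 < 2000 AU too
  expect_equal(ncol(f$beta), 8)

  # median rule alone: intensity above 2000 AU but below half the median
  M2 <- matrix(6000, 50, 10); U2 <- matrix(6000, 50, 10)
  M2[, 3] <- 2300; U2[, 3] <- 2300    # avg 2300 > 2000, < 0.5 * 6000
  x2 <- make_intensities(M2, U2)
  f2 <- filter_samples(x2, compute_beta(x2))
  expect_equal(which(f2$report$excluded), 3L)
  expect_false(f2$report$fail_min_intensity[3])
  expect_true(f2$report$fail_median_frac[3])

  # healthy identical samples: none excluded
  x3 <- make_intensities(matrix(3000, 10, 4), matrix(3000, 10, 4))
  expect_equal(sum(filter_samples(x3, compute_beta(x3))$report$excluded), 0)

  # everything failing raises with the report attached
  x4 <- make_intensities(matrix(10, 5, 3), matrix(10, 5, 3))
  expect_error(filter_samples(x4, compute_beta(x4)), "all samples excluded")
})

test_that("per-sample mean methylation is mask-aware", {
  b <- cbind(a = c(0.4, 0.4, 0.4), b = c(0.2, 0.8, NA), c = c(NA, NA, NA))
  expect_warning(m <- mean_sample_methylation(b), "all-missing")
  expect_equal(unname(m), c(0.4, 0.5, NA))
})

test_that("the full preprocessing chain reconciles and is idempotent", {
  cfg <- small_config(n_probes = 300, detection_fail_rate = 0.02,
                      seed = 44)
  sheet <- generate_sample_sheet(cfg)
  x <- generate_intensities(cfg, sheet, probe_manifest(cfg))
  pp <- preprocess_pipeline(x)
  expect_equal(pp$n$probes_in, pp$n$probes_out + pp$n$probes_removed)
  expect_equal(pp$n$samples_in, pp$n$samples_out + pp$n$samples_removed)
  expect_equal(pp$n$samples_removed, 0) # fail rate well above call cutoff
  expect_true(all(pp$beta >= 0 & pp$beta <= 1, na.rm = TRUE))
  # filters are no-ops on their own output
  again <- filter_probes(pp$beta)
  expect_equal(length(again$removed_probes), 0)
  expect_identical(again$beta, pp$beta)
})
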