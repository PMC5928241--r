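ewas_fixture <- function(seed = 51, ...) {
  cfg <- small_config(n_probes = 60, seed = seed, ...)
  sheet <- generate_sample_sheet(cfg)
  probes <- probe_manifest(cfg)
  beta <- compute_beta(generate_intensities(cfg, sheet, probes))
  list(cfg = cfg, sheet = sheet, probes = probes, beta = beta,
       design = ewas_design(sheet))
}

test_that("forcing chip variance to zero reproduces the OLS oracle", {
  fx <- ewas_fixture(chip_sd = 0)
  X <- model.matrix(~ dose + time + row, fx$design)
  for (i in 1:20) {
    y <- fx$beta[i, ]
    got <- fit_probe_mixed_model(y, fx$design, "dose", engine = "ols")
    want <- ols_oracle(y, X, "dose")
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_identical(got$method, "ols")
    # singular auto fits fall back to the same numbers
    auto <- fit_probe_mixed_model(y, fx$design, "dose")
    if (identical(auto$method, "ols"))
      expect_equal(auto$slope, want$slope, tolerance = 1e-10)
  }
})

test_that("degenerate responses and designs are flagged, not fitted", {
  fx <- ewas_fixture()
  const <- fit_probe_mixed_model(rep(0.5, nrow(fx$design)), fx$design,
                                 "dose")
  expect_identical(const$flag, "constant_response")
  expect_true(is.na(const$p))
  one_dose <- fx$sheet[fx$sheet$dose == 0, ]
  expect_error(run_ewas(fx$beta[, one_dose$sample_id], one_dose, "dose"),
               "single level")
  expect_error(fit_probe_mixed_model(c(0.1, 0.2), fx$design, "dose"),
               "match")
})

test_that("the mixed model covers a planted slope at nominal rate", {
  # 95% Wald interval should cover the true slope in roughly 95% of
  # replicates when chip effects are present
  cfg <- small_config(n_probes = 1, seed = 52, chip_sd = 0.05)
  sheet <- generate_sample_sheet(cfg)
  design <- ewas_design(sheet)
  true_slope <- 0.05
  covered <- vapply(1:300, function(r) {
    y <- withr::with_seed(1e6 + r, {
      chip_eff <- rnorm(4, 0, 0.05)[as.integer(design$chip)]
      0.3 + true_slope * design$dose + chip_eff + rnorm(48, 0, 0.02)
    })
    f <- fit_probe_mixed_model(y, design, "dose")
    crit <- qt(0.975, df = f$df)
    (f$slope - crit * f$se) <= true_slope &&
      true_slope <= (f$slope + crit * f$se)
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("holm and BH adjustments match their textbook forms", {
  expect_equal(holm_adjust(0.005), 0.005)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.04, 0.5))
  expect_equal(holm_adjust(c(0.6, 0.7)), c(1, 1))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.32), 0.32)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # NA entries are excluded from m and preserved in place
  p <- c(0.01, NA, 0.02, 0.5)
  expect_equal(holm_adjust(p), c(0.03, NA, 0.04, 0.5))
  # order equivariance
  set.seed(53)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  expect_equal(fdr_adjust(p)[perm], fdr_adjust(p[perm]))
})

test_that("ewas recovers planted dose effects with correct direction", {
  cfg <- small_config(n_probes = 500, n_dose_probes = 60,
                      dose_effect = 0.05, residual_sd = 0.02, seed = 54)
  sheet <- generate_sample_sheet(cfg)
  probes <- probe_manifest(cfg)
  beta <- compute_beta(generate_intensities(cfg, sheet, probes))
  tab <- run_ewas(beta, sheet, "dose")
  planted <- tab$probe_id %in% probes$probe_id[probes$is_dose]
  hit <- planted & !is.na(tab$p) & tab$p < 0.001
  expect_gt(mean(tab$p[planted] < 0.001, na.rm = TRUE), 0.9)
  expect_true(all(tab$direction[hit] == "hyper"))
  # fe-like planting targets low-baseline sites
  expect_lt(mean(tab$baseline_beta[planted]), 0.35)
  # table invariants
  ok <- !is.na(tab$p)
  expect_true(all(tab$holm_p[ok] >= tab$p[ok]))
  expect_true(all(tab$fdr_q[ok] >= tab$p[ok]))
  expect_identical(tab$direction[ok], ifelse(tab$slope[ok] > 0,
                                             "hyper", "hypo"))
})

test_that("a time-targeted ewas recovers drift probes symmetrically", {
  cfg <- small_config(n_probes = 400, n_drift_probes = 60,
                      drift_rate = 0.002, residual_sd = 0.02, seed = 55)
  sheet <- generate_sample_sheet(cfg)
  probes <- probe_manifest(cfg)
  beta <- compute_beta(generate_intensities(cfg, sheet, probes))
  tab <- run_ewas(beta, sheet, "time")
  drifted <- tab$probe_id %in% probes$probe_id[probes$is_drift]
  expect_gt(mean(tab$p[drifted] < 0.001, na.rm = TRUE), 0.9)
  expect_lt(mean(tab$p[!drifted] < 0.001, na.rm = TRUE), 0.01)
  # recovered sign matches each probe's drift direction
  sig <- drifted & !is.na(tab$p) & tab$p < 0.001
  want <- ifelse(probes$drift_sign[match(tab$probe_id, probes$probe_id)] > 0,
                 "hyper", "hypo")
  expect_true(all(tab$direction[sig] == want[sig]))
})

test_that("dose/time site classification follows set algebra", {
  mk <- function(ids, sig) {
    data.frame(probe_id = ids, p = ifelse(ids %in% sig, 1e-5, 0.5))
  }
  ids <- letters[1:6]
  d <- mk(ids, c("a", "b", "c"))
  t <- mk(ids, c("c", "d"))
  cls <- classify_dose_time_sites(d, t)
  expect_setequal(cls$dose_only, c("a", "b"))
  expect_setequal(cls$time_only, "d")
  expect_setequal(cls$both, "c")
  # disjoint significant sets leave 'both' empty
  cls2 <- classify_dose_time_sites(mk(ids, "a"), mk(ids, "b"))
  expect_length(cls2$both, 0)
  expect_error(classify_dose_time_sites(d, mk(letters[2:7], "c")),
               "universe")
  # headline arithmetic: 935 dose-significant sites of which 91 are also
  # time-significant leave 844 dose-only
  all_ids <- sprintf("cg%04d", 1:2000)
  dose_sig <- all_ids[1:935]
  time_sig <- all_ids[c(845:935, 1500:1700)] # 91 overlapping
  cls3 <- classify_dose_time_sites(mk(all_ids, dose_sig),
                                   mk(all_ids, time_sig))
  expect_length(cls3$dose_only, 844)
  expect_length(cls3$both, 91)
})

test_that("the global trend test recovers a planted mean-beta slope", {
  sheet <- generate_sample_sheet(small_config(seed = 56))
  # zero-noise linear means: exact recovery
  mb <- 0.4 + 0.01 * sheet$dose + 0.0002 * sheet$time
  names(mb) <- sheet$sample_id
  got <- suppressWarnings(global_trend_test(mb, sheet)) # zero-noise fit
  expect_equal(got$slope, 0.01, tolerance = 1e-9)
  expect_lt(got$p_value, 1e-12)
  expect_error(global_trend_test(mb[1:2], sheet[1:2, ]), "3 samples")
  # power under noise across seeds
  hits <- vapply(1:100, function(r) {
    noisy <- withr::with_seed(2e6 + r, mb + rnorm(48, 0, 0.002))
    names(noisy) <- sheet$sample_id
    g <- global_trend_test(noisy, sheet)
    g$slope > 0 && g$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # shuffled dose: null p roughly uniform
  pnull <- vapply(1:100, function(r) {
    withr::with_seed(3e6 + r, {
      sh2 <- sheet
      sh2$dose <- sample(sh2$dose)
      noisy <- 0.4 + rnorm(48, 0, 0.002)
      names(noisy) <- sh2$sample_id
      global_trend_test(noisy, sh2)$p_value
    })
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pnull, "punif")$p.value), 0.01)
})

test_that("persistence deltas are centered and track planted persistence", {
  cfg <- small_config(n_probes = 200, n_dose_probes = 50,
                      dose_effect = 0.1, residual_sd = 0.01,
                      chip_sd = 0, row_sd = 0, doses = c(0, 1),
                      seed = 57)
  sheet <- generate_sample_sheet(cfg)
  probes <- probe_manifest(cfg)
  beta <- compute_beta(generate_intensities(cfg, sheet, probes))
  ps <- persistence_summary(beta, sheet,
                            probes = probes$probe_id[probes$is_dose])
  ref <- ps[ps$dose == 0 & ps$time == min(sheet$time), ]
  expect_lt(abs(ref$median), 0.02)
  dosed <- ps[ps$dose == 1, ]
  # non-decaying planted effect: median delta near +0.1 at every time
  expect_true(all(abs(dosed$median - 0.1) < 0.02))
  expect_error(persistence_summary(beta, sheet[sheet$dose > 0, ]),
               "unexposed")
})
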