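test_that("Mosteller BSA evaluates the printed formula and depends only on the product", {
  expect_equal(bsa_mosteller(3600 / 175, 175), 1.0)
  expect_equal(bsa_mosteller(80, 175), sqrt(80 * 175 / 3600))
  expect_equal(bsa_mosteller(80, 175), 1.972, tolerance = 1e-3)
  expect_equal(bsa_mosteller(76.5, 176), 1.934, tolerance = 1e-3)
  # symmetric in the weight x height product
  expect_equal(bsa_mosteller(50, 200), bsa_mosteller(200, 50))
  expect_error(bsa_mosteller(0, 175), "positive")
  expect_error(bsa_mosteller(80, -1), "positive")
})

test_that("MDRD eGFR matches direct evaluation and scales as the printed power law", {
  expect_equal(egfr_mdrd(1.0, 60, "male"), 175 * 60^(-0.203),
               tolerance = 1e-10)
  expect_equal(egfr_mdrd(1.0, 60, "male"), 76.2, tolerance = 1e-3)
  expect_equal(egfr_mdrd(1.0, 60, "female"),
               egfr_mdrd(1.0, 60, "male") * 0.742)
  expect_equal(egfr_mdrd(1.0, 60, "female"), 56.6, tolerance = 1e-3)
  # doubling creatinine divides the estimate by 2^1.154
  expect_equal(egfr_mdrd(2, 60, "male") / egfr_mdrd(1, 60, "male"),
               2^(-1.154))
  # strictly decreasing in serum creatinine
  scr <- seq(0.4, 6, by = 0.2)
  expect_true(all(diff(egfr_mdrd(scr, 55, "male")) < 0))
  expect_error(egfr_mdrd(0, 60, "male"), "positive")
})

test_that("CKD-EPI 2009 equation reproduces hand-computed values", {
  # male, scr above kappa: 141 * (scr/0.9)^-1.209 * 0.993^age
  expect_equal(egfr_ckdepi(1.2, 50, "male"),
               141 * (1.2 / 0.9)^(-1.209) * 0.993^50, tolerance = 1e-12)
  # female, scr below kappa: alpha branch with the 1.018 factor
  expect_equal(egfr_ckdepi(0.5, 40, "female"),
               141 * (0.5 / 0.7)^(-0.329) * 0.993^40 * 1.018,
               tolerance = 1e-12)
  scr <- seq(0.4, 6, by = 0.2)
  expect_true(all(diff(egfr_ckdepi(scr, 55, "female")) < 0))
})

test_that("relative-to-absolute eGFR conversion uses individual BSA", {
  expect_equal(egfr_relative_to_absolute(77, 1.73), 77)
  expect_equal(egfr_relative_to_absolute(48.4, 1.96), 48.4 * 1.96 / 1.73)
  expect_equal(egfr_relative_to_absolute(48.4, 1.96), 54.84,
               tolerance = 1e-3)
  expect_equal(egfr_relative_to_absolute(0, 2.1), 0)
})

test_that("Cockcroft-Gault clearance matches the formula with the female factor", {
  expect_equal(ecrcl_cg(1.0, 40, 72, "male"), 100.0)
  expect_equal(ecrcl_cg(1.0, 40, 72, "female"), 85.0)
  expect_equal(ecrcl_cg(1.0, 140, 72, "male"), 0)
  scr <- seq(0.4, 6, by = 0.2)
  expect_true(all(diff(ecrcl_cg(scr, 55, 80, "male")) < 0))
})

test_that("KDIGO categories honour printed boundaries and partition [0, Inf)", {
  expect_equal(as.character(classify_kdigo(14.9)), "<15")
  expect_equal(as.character(classify_kdigo(29)), "15-29")
  expect_equal(as.character(classify_kdigo(30)), "30-44")
  expect_equal(as.character(classify_kdigo(44.5)), "30-44")
  expect_equal(as.character(classify_kdigo(59)), "45-59")
  expect_equal(as.character(classify_kdigo(90)), ">=90")
  # no gaps or overlaps over a fine grid
  grid <- seq(0, 200, by = 0.01)
  cats <- classify_kdigo(grid)
  expect_false(anyNA(cats))
  expect_equal(nlevels(droplevels(cats)), 6)
  expect_true(!is.unsorted(as.integer(cats)))
  expect_error(classify_kdigo(-1), "non-negative")
})

test_that("anuria is a strict < 100 mL cut on 24-h urine output", {
  expect_true(is_anuric(0))
  expect_true(is_anuric(99))
  expect_false(is_anuric(100))
  expect_false(is_anuric(2400))
})

test_that("covariate imputation carries forward within subject and uses cohort medians", {
  tab <- data.frame(
    ID = c(1, 1, 1, 2, 2, 3, 3),
    TIME = c(0, 8, 24, 0, 8, 0, 8),
    SCR = c(1.2, NA, 1.5, 2.0, NA, NA, NA),
    HT = c(170, 170, 170, 180, 180, NA, NA))
  out <- impute_covariates(tab, columns = c("SCR", "HT"))
  expect_equal(out$SCR[1:3], c(1.2, 1.2, 1.5))      # gap filled by LOCF
  expect_equal(out$SCR[4:5], c(2.0, 2.0))
  # subject 3 entirely missing: cohort median of baselines (1.2, 2.0)
  expect_equal(out$SCR[6:7], c(1.6, 1.6))
  expect_equal(out$HT[6:7], c(175, 175))
  # idempotent and identity on complete tables
  expect_identical(impute_covariates(out, columns = c("SCR", "HT")), out)
  expect_error(impute_covariates(transform(tab, HT = NA_real_),
                                 columns = "HT"), "HT")
})
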