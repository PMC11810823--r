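test_that("fold assignment partitions cages evenly and reproducibly", {
  cages <- sprintf("C%04d", 1:100)
  fa <- assign_folds(cages, k = 10, seed = 1)
  expect_setequal(fa$cage_id, cages)
  expect_equal(unname(table(fa$fold)), rep(10L, 10), ignore_attr = TRUE)
  expect_identical(fa, assign_folds(cages, k = 10, seed = 1))
  expect_false(identical(fa, assign_folds(cages, k = 10, seed = 2)))

  # uneven counts differ by at most one
  fa2 <- assign_folds(sprintf("c%d", 1:104), k = 10, seed = 3)
  expect_lte(diff(range(table(fa2$fold))), 1)
  expect_error(assign_folds(cages, k = 1), "invalid k")
  expect_error(assign_folds(cages[1:5], k = 10), "fewer cages")
})

test_that("pre-correction returns fixed-effect residuals of cage means", {
  # no fixed-effect variation: residual = cage mean - grand mean
  cg <- data.frame(cage_id = sprintf("c%d", 1:20),
                   mean_fs_BACK45 = rnorm(20, 12),
                   rt_number = "RT1", fdc = "f", feather_gene = "fast",
                   stringsAsFactors = FALSE)
  pr <- precorrect(cg, "BACK45")
  expect_equal(pr$y_obs, cg$mean_fs_BACK45 - mean(cg$mean_fs_BACK45))
  expect_equal(mean(pr$y_obs), 0, tolerance = 1e-12)

  # fixed effects explain everything: all residuals zero
  cg2 <- cg
  cg2$rt_number <- rep(c("RT1", "RT2"), 10)
  cg2$mean_fs_BACK45 <- ifelse(cg2$rt_number == "RT1", 11, 14)
  expect_equal(precorrect(cg2, "BACK45")$y_obs, rep(0, 20),
               tolerance = 1e-12)

  # missing cage means give missing proxies
  cg$mean_fs_BACK45[3] <- NA
  expect_true(is.na(precorrect(cg, "BACK45")$y_obs[3]))
})

test_that("proxies recover the non-fixed part of simulated cage means", {
  # few fixed-effect levels so their estimation error is negligible
  sim <- simulate_rt_data(sim_config(n_sires = 300, seed = 17,
                                     n_rt_numbers = 4, farms_per_batch = 3,
                                     crosses_per_batch = 1),
                          keep_liability = TRUE)
  pr <- precorrect(sim$cages, "liab_45")
  tr <- sim$truth$cages
  # survivor-mean residual+cage+sire deviation, reconstructed from truth
  dev <- sim$cages$mean_liab_45 -
    tr$offset[match(sim$cages$cage_id, tr$cage_id)]
  expect_gte(cor(pr$y_obs, dev, use = "complete.obs"), 0.99)
})

test_that("r(s1, Ybar_obs) matches hand evaluation and limits", {
  expect_equal(r_true_proxy(1, 0.25, 2, 9), sqrt(0.25 / 0.8055556),
               tolerance = 1e-6)
  expect_equal(r_true_proxy(1, 0, 2, 1e12), 1, tolerance = 1e-5)
  expect_equal(r_true_proxy(0, 0.3, 1, 10), 0)
  expect_error(r_true_proxy(0, 0, 0, 5), "undefined")
  expect_error(r_true_proxy(-1, 0.3, 1, 10), "non-negative")
})

test_that("expected accuracy reproduces the model-family formulas", {
  # cage-level sire models, hand-evaluated
  vc <- list(G0 = matrix(0.25), R0 = matrix(1))
  expect_equal(expected_accuracy("CUSiM", vc, m = 6),
               sqrt(0.25 / (0.25 + 1 / 6)), tolerance = 1e-12)
  expect_equal(expected_accuracy("CUSiM", vc, m = 6), sqrt(0.6),
               tolerance = 1e-12)
  # CUAM with sigma2_A = 1, sigma2_e = 2, m = 6
  vca <- list(G0 = matrix(1), R0 = matrix(2))
  expect_equal(expected_accuracy("CUAM", vca, m = 6),
               sqrt(0.25 / (0.25 + 2.75 / 6)), tolerance = 1e-12)
  # IBAM/IUAM formula, hand-evaluated at d=20, n=53, m=6
  vcb <- list(G0 = matrix(1), C0 = matrix(0.5), R0 = matrix(2.5))
  hand <- 0.25 / (0.25 + 0.25 / 20 + 0.5 / 53 + 2.5 / 53 + 0.5 / 6)
  expect_equal(expected_accuracy("IUAM", vcb), sqrt(hand),
               tolerance = 1e-12)
  # IBSiM formula and its validity constraint
  vcs <- list(G0 = matrix(0.25), C0 = matrix(0.5), R0 = matrix(2.5))
  hand_s <- 0.25 / (0.25 + 0.25 / 20 + 0.5 / 53 + (2.5 - 0.75) / 53 + 0.5 / 6)
  expect_equal(expected_accuracy("IBSiM", vcs), sqrt(hand_s),
               tolerance = 1e-12)
  expect_error(expected_accuracy("IBSiM", list(G0 = matrix(1),
                                               C0 = matrix(0.1),
                                               R0 = matrix(2.5))),
               "inconsistent")
  # accuracy approaches 1 as noise vanishes and families grow
  vc1 <- list(G0 = matrix(1), C0 = matrix(1e-9), R0 = matrix(1e-9))
  expect_equal(expected_accuracy("IBAM", vc1, d = 1e9, n = 1e9, m = 1e9), 1,
               tolerance = 1e-5)
  # monotone non-decreasing in m
  accs <- sapply(2:12, function(m) expected_accuracy("CUSiM", vc, m = m))
  expect_true(all(diff(accs) > 0))
  expect_error(expected_accuracy("CUSiM", vc, m = 0), "positive")
})

test_that("total heritable variance ratio follows the definitions", {
  f_sire <- list(varcomp = list(G0 = matrix(0.25), R0 = matrix(1)),
                 spec = model_spec("CUSiM"))
  expect_equal(total_heritable_ratio(f_sire), 0.8)
  f_an <- list(varcomp = list(G0 = matrix(1), C0 = matrix(0.5),
                              R0 = matrix(2.5)),
               spec = model_spec("IUAM"))
  expect_equal(total_heritable_ratio(f_an), 0.25)
  f_null <- list(varcomp = list(G0 = matrix(0), R0 = matrix(1)),
                 spec = model_spec("CUSiM"))
  expect_equal(total_heritable_ratio(f_null), 0)
})

test_that("fold accuracy and dispersion behave on constructed cases", {
  set.seed(1)
  prox <- data.frame(cage_id = sprintf("c%d", 1:40),
                     sire_id = rep(sprintf("s%d", 1:20), each = 2),
                     y_obs = rnorm(40))
  # perfect estimates: correlation 1, identity regression slope 1
  one <- data.frame(sire_id = sprintf("s%d", 1:20),
                    s_hat = prox$y_obs[seq(1, 39, 2)])
  sub <- prox[seq(1, 39, 2), ]
  expect_equal(fold_accuracy(one, sub), 1)
  expect_equal(dispersion_slope(one, sub), 1)
  # halving the estimates doubles the slope; doubling halves it
  half <- transform(one, s_hat = s_hat / 2)
  expect_equal(dispersion_slope(half, sub), 2)
  dbl <- transform(one, s_hat = s_hat * 2)
  expect_equal(dispersion_slope(dbl, sub), 0.5)
  # randomly permuted estimates carry no information
  set.seed(42)
  perm_cors <- replicate(200, {
    shp <- transform(one, s_hat = sample(s_hat))
    fold_accuracy(shp, sub)
  })
  expect_lt(abs(mean(perm_cors)), 0.05)
  # degenerate inputs are skipped
  expect_true(is.na(fold_accuracy(one, sub[1:2, ])))
  expect_true(is.na(dispersion_slope(transform(one, s_hat = 1), sub)))
})

test_that("oracle substitution of true sire effects gives accuracy near 1", {
  sim <- simulate_rt_data(sim_config(n_sires = 300, seed = 19),
                          keep_liability = TRUE)
  pr <- precorrect(sim$cages, "liab_45")
  pr$sire_id <- sim$cages$sire_id[match(pr$cage_id, sim$cages$cage_id)]
  tr <- sim$truth$sires
  sh <- data.frame(sire_id = tr$sire_id, s_hat = tr$s_fs)
  r_shat <- fold_accuracy(sh, pr)
  cfg <- sim$config
  # realized sire variance (the test sires are related through the sire
  # line, so it sits below the nominal sigma2_S; fitted components would
  # reflect the same realized quantity)
  v_s <- var(tr$s_fs)
  r_s1 <- r_true_proxy(4 * v_s, cfg$sigma2_c,
                       cfg$sigma2_e - 3 * v_s,
                       mean(sim$cages$n_original))
  expect_equal(r_shat / r_s1, 1, tolerance = 0.1)
})

test_that("marginal-mean comparison detects injected model differences", {
  # single model: EMMEAN equals the arithmetic fold mean
  folds <- data.frame(model = "CUSiM", fold = 1:10,
                      r_shat = seq(0.5, 0.68, by = 0.02))
  em <- emmean_compare(folds, "r_shat")
  expect_equal(em$emmean, mean(folds$r_shat))

  # identical models share a letter; zero contrast
  two <- rbind(transform(folds, model = "A"), transform(folds, model = "B"))
  em2 <- suppressWarnings(emmean_compare(two, "r_shat"))  # perfect fit
  expect_equal(diff(em2$emmean), 0, tolerance = 1e-12)
  expect_equal(em2$group[1], em2$group[2])

  # a constant offset delta is recovered as the contrast and separates
  # the letter groups despite shared fold-level noise
  set.seed(3)
  base <- rnorm(10, 0.6, 0.05)
  delta <- 0.12
  inj <- rbind(data.frame(model = "A", fold = 1:10, r_shat = base),
               data.frame(model = "B", fold = 1:10,
                          r_shat = base + delta + rnorm(10, 0, 0.005)))
  em3 <- emmean_compare(inj, "r_shat")
  expect_equal(em3$emmean[em3$model == "B"] - em3$emmean[em3$model == "A"],
               delta, tolerance = 0.02)
  expect_false(em3$group[1] == em3$group[2])

  # one-sample contrast against a null value (dispersion use-case)
  disp <- data.frame(model = "CUSiM", fold = 1:10,
                     slope = rnorm(10, 1, 0.001) + 2)
  emd <- emmean_compare(disp, "slope", null = 1)
  expect_lt(emd$p_vs_null, 0.001)
})

test_that("cross-validation wires folds, masking and metrics together", {
  sim <- simulate_rt_data(sim_config(n_sires = 60, seed = 23))
  cv <- cross_validate(sim, c("CUSiM", "CUAM"), "BACK45", k = 5, seed = 11,
                       vc_source = "fit")
  expect_s3_class(cv, "rt_validation")
  expect_equal(nrow(cv$folds), 2 * 5)
  expect_setequal(unique(cv$folds$model), c("CUSiM", "CUAM"))
  # equivalent parameterizations give near-identical validation metrics
  a <- cv$folds[cv$folds$model == "CUSiM", ]
  b <- cv$folds[cv$folds$model == "CUAM", ]
  expect_equal(a$r_shat, b$r_shat, tolerance = 0.02)
  expect_true(all(cv$folds$t2 >= 0))
  expect_true(all(cv$folds$r_s1 > 0 & cv$folds$r_s1 < 1))
  expect_equal(cv$accuracy$accuracy,
               cv$accuracy$r_shat / cv$accuracy$r_s1)
  # same seed reruns identically
  cv2 <- cross_validate(sim, c("CUSiM", "CUAM"), "BACK45", k = 5, seed = 11,
                        vc_source = "fit")
  expect_identical(cv$folds, cv2$folds)
})
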