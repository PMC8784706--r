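test_that("effective dose respects the 30-day lag and cumulates other drugs", {
  expect_identical(effective_dose(NULL, 9),
                   c(metformin_dose = 0, other_dose = 0, insulin = 0))
  meds <- data.frame(subject_id = "S1",
                     drug_class = c("other_oral", "other_oral"),
                     drug = c("sulfonylurea", "dpp4"),
                     dose_fraction = c(0.5, 0.5),
                     start_day = c(0, 0), stop_day = Inf)
  expect_equal(effective_dose(meds, 9)[["other_dose"]], 1.0)
  dup <- data.frame(subject_id = "S1", drug_class = "metformin",
                    dose_fraction = c(0.5, 0.7),
                    start_day = c(0, 100), stop_day = c(200, Inf))
  expect_error(effective_dose(dup, 12), "overlapping")
})

test_that("conditional transform centers within subject and ignores level shifts", {
  cfg <- cohort_config(25, seed = 61)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg)
  d <- conditional_transform(hb)
  sums <- tapply(d$hba1c_c, d$subject_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  # shifting one subject's HbA1c leaves the transform unchanged
  hb2 <- hb
  first <- hb2$visits$subject_id == hb2$visits$subject_id[1]
  hb2$visits$hba1c[first] <- hb2$visits$hba1c[first] + 25
  d2 <- conditional_transform(hb2)
  expect_equal(d$hba1c_c, d2$hba1c_c, tolerance = 1e-12)
  # two-visit subject: centered values are +/- half the difference
  hb3 <- list(visits = data.frame(subject_id = "A", month = c(0, 9),
                                  hba1c = c(46, 50)),
              medications = hb$medications[0, ])
  d3 <- conditional_transform(hb3)
  expect_equal(d3$hba1c_c, c(-2, 2))
  # subjects with one visit are excluded
  hb4 <- list(visits = rbind(hb$visits,
                             data.frame(subject_id = "LONE", month = 0,
                                        hba1c = 44, assay_delay = 0, bmi = 30)),
              medications = hb$medications)
  expect_message(d4 <- conditional_transform(hb4), "excluding")
  expect_false("LONE" %in% d4$subject_id)
})

test_that("noiseless untreated trajectories return exact slopes", {
  cfg <- cohort_config(30, seed = 62)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg, residual_sd = 0,
                       effects = list(metformin_a = 0, metformin_b = 0,
                                      otherdrug_a = 0, otherdrug_b = 0,
                                      insulin = 0, bmi = 0, delay = 0),
                       treated_fraction = 0)
  fit <- fit_progression(conditional_transform(hb))
  truth <- co$truth$slopes[match(names(fit$subject_slopes),
                                 rownames(co$truth$weights))]
  expect_equal(unname(fit$subject_slopes), unname(truth), tolerance = 1e-6)
})

test_that("slope recovery on a realistic synthetic cohort", {
  cfg <- cohort_config(500, seed = 63)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg, residual_sd = 2)
  fit <- fit_progression(conditional_transform(hb))
  expect_true(fit$converged)
  truth <- co$truth$slopes[match(names(fit$subject_slopes),
                                 rownames(co$truth$weights))]
  # with 5 visits the attainable correlation is information-bounded by
  # sigma_s / sqrt(sigma_s^2 + sigma^2 / sum(t_centered^2)); require the
  # estimator to come close to that oracle bound
  u2 <- sum(scale(c(0, 9, 18, 27, 36), scale = FALSE)^2)
  bound <- sd(truth) / sqrt(var(truth) + 2^2 / u2)
  expect_gt(cor(fit$subject_slopes, truth), 0.85 * bound)
  expect_equal(fit$sigma_slope, sd(truth), tolerance = 0.25)
  expect_equal(fit$residual_sd, 2, tolerance = 0.1)
  expect_lt(abs(fit$mu_slope - mean(truth)),
            2 * sd(truth) / sqrt(length(truth)) + 0.01)
  # recovered signs honor the constraints
  fx <- fit$fixed_effects
  expect_lte(fx[["met_dose"]], 0)
  expect_lte(fx[["insulin_ind"]], 0)
  expect_gte(fx[["bmi"]], 0)
})

test_that("a constraint-violating generative effect lands on the boundary", {
  cfg <- cohort_config(120, seed = 64)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg, residual_sd = 1,
                       effects = list(metformin_a = 2, metformin_b = 3,
                                      otherdrug_a = 0, otherdrug_b = 0,
                                      insulin = 0, bmi = 0.1, delay = 0),
                       treated_fraction = 0.6)
  fit <- fit_progression(conditional_transform(hb))
  expect_true(all(c("met_ind", "met_dose") %in% fit$boundary))
  expect_equal(unname(fit$fixed_effects[["met_dose"]]), 0)
  # lifting the constraints recovers the positive sign
  fit_u <- fit_progression(conditional_transform(hb), constrain = FALSE)
  expect_gt(fit_u$fixed_effects[["met_dose"]] +
              fit_u$fixed_effects[["met_ind"]], 0)
})

test_that("likelihood is invariant to per-subject level shifts", {
  cfg <- cohort_config(60, seed = 65)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg)
  f1 <- fit_progression(conditional_transform(hb))
  hb$visits$hba1c <- hb$visits$hba1c +
    10 * as.numeric(factor(hb$visits$subject_id))
  f2 <- fit_progression(conditional_transform(hb))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$subject_slopes, f2$subject_slopes, tolerance = 2e-2)
})

test_that("slope-score regressions find a planted archetype effect", {
  set.seed(66)
  n <- 500
  W <- etioscope:::dirichlet_rows(n, 4, 0.5)
  colnames(W) <- LETTERS[1:4]
  rownames(W) <- sprintf("S%04d", 1:n)
  slopes <- 0.04 * W[, "D"] + rnorm(n, sd = 0.02)
  names(slopes) <- rownames(W)
  tab <- slopes_vs_scores(slopes, W)
  bD <- tab[tab$archetype == "D", ]
  bB <- tab[tab$archetype == "B", ]
  expect_gt(bD$estimate, 0)
  expect_lt(bD$p, 1e-6)
  expect_gt(bB$p, 1e-6)
  # permuted scores lose the signal
  perm <- W[sample(n), ]
  rownames(perm) <- rownames(W)
  tabp <- slopes_vs_scores(slopes, perm)
  expect_lt(abs(tabp$estimate[tabp$archetype == "D"]), abs(bD$estimate))
  # strata of an unstratified effect agree within sampling error
  strata <- setNames(rep(c("u", "t"), length.out = n), rownames(W))
  tabs <- slopes_vs_scores(slopes, W, strata = strata)
  du <- tabs[tabs$stratum == "u" & tabs$archetype == "D", ]
  dt_ <- tabs[tabs$stratum == "t" & tabs$archetype == "D", ]
  expect_lt(abs(du$estimate - dt_$estimate),
            3 * sqrt(du$se^2 + dt_$se^2))
})
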