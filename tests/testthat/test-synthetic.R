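test_that("cohort weights lie on the simplex and the generator is deterministic", {
  co <- small_cohort(100, seed = 3)
  W <- co$truth$weights
  expect_true(all(W >= 0))
  expect_true(all(abs(rowSums(W) - 1) <= 1e-10))
  co2 <- small_cohort(100, seed = 3)
  expect_identical(co$phenotypes$values, co2$phenotypes$values)
  expect_identical(co$truth$weights, co2$truth$weights)
  co3 <- small_cohort(100, seed = 4)
  expect_false(identical(co$phenotypes$values, co3$phenotypes$values))
})

test_that("noiseless phenotype rows are exact convex combinations of the profiles", {
  co <- generate_cohort(cohort_config(60, noise_sd = 0, seed = 5))
  X_hat <- co$truth$weights %*% co$truth$archetype_profiles
  expect_equal(unname(co$phenotypes$values), unname(X_hat), tolerance = 1e-12)
})

test_that("smaller Dirichlet alpha concentrates weights near the vertices", {
  frac_extreme <- function(alpha) {
    co <- generate_cohort(cohort_config(1000, dirichlet_alpha = alpha, seed = 9))
    mean(apply(co$truth$weights, 1, max) > 0.6)
  }
  expect_gt(frac_extreme(0.05), frac_extreme(5))
})

test_that("cohort config validates its arguments", {
  expect_error(cohort_config(3, k_true = 4), "n_subjects")
  expect_error(cohort_config(10, dirichlet_alpha = 0), "dirichlet_alpha")
  expect_error(cohort_config(10, noise_sd = -1), "noise_sd")
})

test_that("MMTT generator is reproducible and respects steady state", {
  # constant basal glucose, flat potentiation, no noise: C-peptide constant
  tp <- beta_cell_truth(glucose_rise = 0, potentiation_ratio = 1,
                        rate_sensitivity = 0)
  rec <- generate_mmtt(tp, noise_glucose = 0, noise_cpeptide = 0)
  expect_equal(diff(range(rec$cpeptide)), 0, tolerance = 1e-8)
  # and t = 0 equals the independent closed-form steady state
  kin <- cpeptide_kinetics()
  expect_equal(rec$cpeptide[1], tp$basal_secretion * kin$integral,
               tolerance = 1e-8)
  r1 <- generate_mmtt(beta_cell_truth(), seed = 2)
  r2 <- generate_mmtt(beta_cell_truth(), seed = 2)
  expect_identical(r1$cpeptide, r2$cpeptide)
})

test_that("doubling glucose sensitivity increases total 2-h secretion", {
  tot <- function(gs) {
    rec <- generate_mmtt(beta_cell_truth(glucose_sensitivity = gs),
                         noise_glucose = 0, noise_cpeptide = 0)
    tr <- attr(rec, "truth")
    sum(diff(tr$grid) * (head(tr$isr, -1) + tail(tr$isr, -1)) / 2)
  }
  expect_gt(tot(168), tot(84))
})

test_that("MMTT generator rejects bad sampling grids and noise", {
  expect_error(generate_mmtt(beta_cell_truth(), sampling_minutes = c(0, 60)),
               "120")
  expect_error(generate_mmtt(beta_cell_truth(), sampling_minutes = c(10, 60, 120)),
               "from 0")
  expect_error(generate_mmtt(beta_cell_truth(), noise_glucose = -0.1), ">= 0")
})

test_that("noiseless untreated HbA1c slopes equal truth exactly", {
  cfg <- cohort_config(30, seed = 21)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg, residual_sd = 0,
                       effects = list(metformin_a = 0, metformin_b = 0,
                                      otherdrug_a = 0, otherdrug_b = 0,
                                      insulin = 0, bmi = 0, delay = 0),
                       treated_fraction = 0)
  for (id in unique(hb$visits$subject_id)[1:10]) {
    v <- hb$visits[hb$visits$subject_id == id, ]
    slope <- coef(lm(hba1c ~ month, v))[2]
    i <- match(id, rownames(co$truth$weights))
    expect_equal(unname(slope), unname(co$truth$slopes[i]), tolerance = 1e-8)
  }
})

test_that("medication started within 30 days does not affect the visit", {
  meds <- data.frame(subject_id = "S1", drug_class = "metformin",
                     dose_fraction = 0.5,
                     start_day = 9 * 30.4375 - 10, stop_day = Inf)
  dd <- effective_dose(meds, month = 9)
  expect_identical(unname(dd["metformin_dose"]), 0)
  dd31 <- effective_dose(transform(meds, start_day = 9 * 30.4375 - 31), 9)
  expect_identical(unname(dd31["metformin_dose"]), 0.5)
})

test_that("negative drug effects lower treated visits below the untreated line", {
  cfg <- cohort_config(40, seed = 31)
  co <- generate_cohort(cfg)
  hb <- generate_hba1c(co$truth, cfg, residual_sd = 0, treated_fraction = 1)
  v <- hb$visits
  for (id in unique(v$subject_id)[1:8]) {
    sv <- v[v$subject_id == id, ]
    i <- match(id, rownames(co$truth$weights))
    sub_meds <- hb$medications[hb$medications$subject_id == id, ]
    doses <- vapply(sv$month, function(mo)
      effective_dose(sub_meds, mo)[["metformin_dose"]], 1.0)
    if (!any(doses > 0)) next
    # counterfactual without treatment, same slope/bmi/delay terms
    untreated <- sv$hba1c[1] - (hb$effects$metformin_a * (doses[1] > 0) +
                                  hb$effects$metformin_b * doses[1]) +
      co$truth$slopes[i] * (sv$month - sv$month[1]) +
      hb$effects$bmi * (sv$bmi - sv$bmi[1]) +
      hb$effects$delay * (sv$assay_delay - sv$assay_delay[1])
    expect_true(all(sv$hba1c[doses > 0] <= untreated[doses > 0] + 1e-9))
  }
})

test_that("omics generator plants loadings on single archetypes", {
  co <- small_cohort(2000, seed = 41, dirichlet_alpha = 0.5)
  om <- generate_omics(co$truth, n_features = 60, n_null = 20,
                       effect_sd = 1, seed = 7)
  expect_equal(sum(om$is_null), 20)
  W <- co$truth$weights
  sig <- which(!om$is_null)
  for (f in sig[1:10]) {
    a <- which(om$loadings[f, ] != 0)
    cors <- abs(cor(om$features[, f], W))
    expect_equal(which.max(cors), a)
  }
  om0 <- generate_omics(co$truth, 30, 0, effect_sd = 0, seed = 7)
  expect_true(all(om0$is_null))
  om2 <- generate_omics(co$truth, 60, 20, 1, seed = 7)
  expect_identical(om$features, om2$features)
})

test_that("genotype dosages follow the binomial model with six partitions", {
  g <- generate_genotypes(5000, 40, seed = 13)
  expect_true(all(g$dosages %in% 0:2))
  for (j in 1:10) {
    p <- g$weights$freq[j]
    se <- sqrt(2 * p * (1 - p) / 5000)
    expect_lt(abs(mean(g$dosages[, j]) - 2 * p), 3 * se + 1e-12)
  }
  expect_setequal(unique(g$weights$partition),
                  c("IS1", "IS2", "IA", "BMI", "LIPID", "MIX"))
  g0 <- generate_genotypes(200, 3, freq_range = c(0, 0), seed = 1)
  expect_true(all(g0$dosages == 0))
})
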