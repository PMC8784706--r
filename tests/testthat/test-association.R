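test_that("score-phenotype OLS recovers identity and matches normal equations", {
  set.seed(70)
  W <- etioscope:::dirichlet_rows(200, 4, 0.5)
  colnames(W) <- LETTERS[1:4]
  res <- suppressWarnings(score_phenotype_association(W, W[, "A"]))
  a <- res[res$archetype == "A", ]
  expect_equal(a$estimate, 1, tolerance = 1e-10)
  expect_lt(a$p, 1e-100)
  # 5-point hand-worked OLS vs the normal-equations oracle
  s5 <- cbind(A = c(0.9, 0.7, 0.5, 0.3, 0.1))
  s5 <- cbind(s5, B = 1 - s5[, 1], C = 0, D = 0)
  y5 <- c(2.1, 1.6, 1.8, 0.9, 0.7)
  res5 <- score_phenotype_association(s5, y5)
  X <- cbind(1, s5[, "A"])
  beta_or <- solve(crossprod(X), crossprod(X, y5))[2]
  expect_equal(res5$estimate[res5$archetype == "A"], beta_or,
               tolerance = 1e-10)
  expect_error(score_phenotype_association(W, rep(1, 200)), "variance")
})

test_that("null outcomes give calibrated type-I error", {
  set.seed(71)
  W <- etioscope:::dirichlet_rows(1000, 4, 0.5)
  colnames(W) <- LETTERS[1:4]
  hits <- replicate(500, {
    y <- rnorm(1000)
    m <- lm(y ~ W[, 1])
    summary(m)$coefficients[2, 4] < 0.05
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("extreme-group tests detect planted shifts with correct direction", {
  set.seed(72)
  labels <- rep(c("A", "B", "C", "D", "MIX"), each = 50)
  y <- rnorm(250)
  y[labels == "A"] <- y[labels == "A"] + 2
  out <- extreme_group_tests(labels, y)
  gA <- out$groups[out$groups$group == "A", ]
  expect_lt(gA$mann_whitney_p, 1e-6)
  expect_gt(gA$rank_biserial, 0)
  expect_lt(out$kruskal_p, 1e-6)
  # label exchange under the null leaves KW calibrated
  p_null <- replicate(200, {
    extreme_group_tests(sample(labels), rnorm(250))$kruskal_p
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
})

test_that("medication odds ratios match the 2x2 cross-product and detect effects", {
  set.seed(73)
  # binary score column reduces the logistic model to a 2x2 table
  x <- rep(c(0, 1), each = 100)
  status <- c(rbinom(100, 1, 0.3), rbinom(100, 1, 0.6))
  S <- cbind(A = x, B = 1 - x)
  out <- medication_odds(S, status)
  tab <- table(x, status)
  or_hand <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_equal(out$or[out$archetype == "A"], or_hand, tolerance = 1e-6)
  # planted effect on archetype D
  W <- etioscope:::dirichlet_rows(700, 4, 0.5)
  colnames(W) <- LETTERS[1:4]
  st <- as.numeric(W[, "D"] + rnorm(700, sd = 0.15) > 0.5)
  res <- medication_odds(W, st)
  d <- res[res$archetype == "D", ]
  expect_gt(d$or, 1)
  expect_lt(d$p, 1e-4)
})

test_that("null odds ratios cover one at the nominal rate", {
  set.seed(74)
  W <- etioscope:::dirichlet_rows(300, 4, 0.5)
  colnames(W) <- LETTERS[1:4]
  covered <- replicate(200, {
    st <- rbinom(300, 1, 0.4)
    r <- medication_odds(W[, 1, drop = FALSE] |>
                           (\(x) cbind(A = x[, 1], B = 1 - x[, 1]))(), st)[1, ]
    r$ci_lo <= 1 && r$ci_hi >= 1
  })
  expect_gte(mean(covered), 0.93)
})

test_that("separation triggers the penalized fallback", {
  x <- c(rep(0.1, 30), rep(0.9, 30))
  S <- cbind(A = x, B = 1 - x)
  status <- as.numeric(x > 0.5)
  out <- suppressWarnings(medication_odds(S, status))
  expect_true(out$penalized[out$archetype == "A"])
  expect_true(is.finite(out$or[out$archetype == "A"]))
})

test_that("BH q-values reproduce the step-up oracle and preserve order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(75)
  for (i in 1:20) {
    p <- round(runif(sample(3:8, 1)), 3)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("omics screen controls FDR on nulls and finds planted features", {
  set.seed(76)
  co <- small_cohort(700, seed = 77)
  W <- co$truth$weights
  # realized FDR over replicates with half null features
  fdr <- replicate(30, {
    om <- generate_omics(co$truth, 300, 150, effect_sd = 0.8,
                         seed = sample.int(1e6, 1))
    scr <- omics_screen(W, om$features)
    hit <- scr$q < 0.05
    if (!any(hit)) return(0)
    false_feat <- colnames(om$features)[om$is_null]
    sum(hit & scr$feature %in% false_feat) / sum(hit)
  })
  expect_lte(mean(fdr), 0.05 + 2 * sd(fdr) / sqrt(length(fdr)) + 0.02)
  # power on clearly planted features
  om <- generate_omics(co$truth, 200, 150, effect_sd = 1.5, seed = 78)
  scr <- omics_screen(W, om$features)
  planted <- colnames(om$features)[!om$is_null]
  found <- unique(scr$feature[scr$q < 0.05])
  expect_gte(mean(planted %in% found), 0.8)
  # metformin covariate mode with an irrelevant covariate changes little
  met <- rbinom(700, 1, 0.4)
  scr_adj <- omics_screen(W, om$features, "covariate", metformin = met)
  j <- order(scr$feature, scr$archetype)
  ja <- order(scr_adj$feature, scr_adj$archetype)
  expect_lt(max(abs(scr$estimate[j] - scr_adj$estimate[ja]) /
                  pmax(scr$se[j], 1e-12)), 1)
})

test_that("the collinearity guard refuses a joint all-scores model", {
  W <- etioscope:::dirichlet_rows(50, 4, 0.5)
  expect_error(score_phenotype_association(W, rnorm(50), joint = TRUE),
               "rank deficient")
})

test_that("genetic risk scores are the stated weighted sums", {
  dos <- matrix(c(0, 1, 2, 2, 0, 1), 2, 3,
                dimnames = list(c("s1", "s2"), c("snp_a", "snp_b", "snp_c")))
  w <- data.frame(snp = c("snp_a", "snp_b", "snp_c"),
                  weight = c(0.1, 0.2, 0.3),
                  partition = c("IS1", "IS1", "BMI"))
  # subject dosage rows: s1 = (0, 2, 0), s2 = (1, 2, 1)
  expect_equal(unname(compute_grs(dos, w)),
               c(0.1 * 0 + 0.2 * 2 + 0.3 * 0, 0.1 * 1 + 0.2 * 2 + 0.3 * 1))
  expect_equal(unname(compute_grs(dos, w, "IS1")), c(0.4, 0.5))
  expect_equal(unname(compute_grs(dos * 0, w)), c(0, 0))
  w1 <- transform(w, weight = 1)
  expect_equal(unname(compute_grs(dos, w1)), unname(rowSums(dos)))
  expect_error(compute_grs(dos[, 1:2], w), "absent")
  g <- generate_genotypes(50, 12, seed = 9)
  tabl <- grs_table(g$dosages, g$weights)
  expect_identical(sort(setdiff(names(tabl), "T2D")),
                   sort(c("IS1", "IS2", "IA", "BMI", "LIPID", "MIX")))
  expect_equal(tabl$T2D, unname(compute_grs(g$dosages, g$weights)))
})
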