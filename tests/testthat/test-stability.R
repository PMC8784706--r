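test_that("adjusted Rand index matches hand counting, symmetry and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(letters[1:4], letters[1:4]), 1)
  # degenerate partitions
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(2, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1, 1), c(1, 1, 2, 2)), 0)
  set.seed(20)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "lengths differ")
})

test_that("threshold labelling follows the strict-inequality rule", {
  s <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.4, 0.3, 0.2, 0.1),
             c(0.25, 0.25, 0.25, 0.25))
  expect_identical(assign_labels(s, 0.6), c("A", "mixed", "mixed"))
  expect_identical(assign_labels(s, 0), c("A", "A", "A"))
  expect_error(assign_labels(rbind(c(0.5, 0.4)), 0.5), "simplex")
})

test_that("archetype matching recovers permutations and is scale invariant", {
  set.seed(21)
  Z <- matrix(rnorm(4 * 8), 4, 8)
  p <- c(3, 1, 4, 2)
  mm <- match_archetypes(Z, Z[p, ])
  expect_identical(mm$permutation, order(p))  # inverse permutation
  expect_equal(unname(Z[p, ][mm$permutation, ]), unname(Z), tolerance = 1e-12)
  expect_true(all(mm$similarity > 1 - 1e-10))
  mm2 <- match_archetypes(Z, 3.7 * Z[p, ])
  expect_identical(mm2$permutation, mm$permutation)
  expect_equal(mm2$similarity, mm$similarity, tolerance = 1e-12)
  # noisy permuted copy vs exhaustive-permutation oracle
  Zn <- Z[p, ] + matrix(rnorm(32, sd = 0.1), 4, 8)
  mm3 <- match_archetypes(Z, Zn)
  S <- etioscope:::cosine_similarity_matrix(Z, Zn)
  perms <- etioscope:::permutations_of(4)
  totals <- apply(perms, 1, function(q) sum(S[cbind(1:4, q)]))
  expect_identical(mm3$permutation, perms[which.max(totals), ])
  expect_error(match_archetypes(Z, Z[1:3, ]), "differ")
})

test_that("scree RSS is non-increasing and hits machine zero on exact mixtures", {
  # exact mixtures of 4 vertices, vertices included in the data
  co <- generate_cohort(cohort_config(150, noise_sd = 0, seed = 22))
  Z <- co$truth$archetype_profiles
  X <- unname(rbind(Z, co$truth$weights %*% Z))
  sc <- scree(X, 1:5, n_restarts = 3, seed = 5, robust = FALSE)
  expect_true(all(diff(sc$rss) <= 1e-8))
  expect_equal(sc$rss[1], sum(scale(X, scale = FALSE)^2), tolerance = 1e-6)
  expect_lt(sc$rss[4], 1e-6 * sum(X^2))
  expect_gt(sc$rss[3], 100 * sc$rss[4])
  sc2 <- scree(X, 1:5, n_restarts = 3, seed = 5, robust = FALSE)
  expect_equal(sc$rss, sc2$rss)
})

test_that("subsampling stability is reproducible and degenerate at fraction ~ 1", {
  co <- small_cohort(150, seed = 23)
  X <- co$phenotypes$values
  st <- stability_by_subsampling(X, 4, fraction = 0.9, replicates = 3,
                                 thresholds = c(0, 0.3, 0.6), seed = 31,
                                 ref_restarts = 4, replicate_restarts = 2)
  st2 <- stability_by_subsampling(X, 4, fraction = 0.9, replicates = 3,
                                  thresholds = c(0, 0.3, 0.6), seed = 31,
                                  ref_restarts = 4, replicate_restarts = 2)
  expect_identical(st$ari, st2$ari)
  expect_true(all(st$ari$ari >= -1 & st$ari$ari <= 1, na.rm = TRUE))
  expect_error(stability_by_subsampling(X, 4, fraction = 0.01, replicates = 1),
               "smaller than k")
})

test_that("structured data are more stable than pure noise under the same protocol", {
  co <- small_cohort(250, seed = 24)
  X <- co$phenotypes$values
  st_struct <- stability_by_subsampling(X, 4, replicates = 8, seed = 41,
                                        thresholds = 0, ref_restarts = 5,
                                        replicate_restarts = 3)
  set.seed(25)
  Xn <- matrix(rnorm(length(X)), nrow(X), ncol(X))
  st_noise <- stability_by_subsampling(Xn, 4, replicates = 8, seed = 41,
                                       thresholds = 0, ref_restarts = 5,
                                       replicate_restarts = 3)
  expect_gt(st_struct$median_ari[["0"]], st_noise$median_ari[["0"]])
})

test_that("minimal-parameter-set search removes duplicates and keeps similarity", {
  set.seed(26)
  co <- small_cohort(250, seed = 27, n_phenotypes = 5, k_true = 3,
                     noise_sd = 1.2)  # noise keeps raw inter-column |r| < 0.9
  X <- co$phenotypes$values
  expect_lt(max(abs(cor(X)) - diag(5)), 0.9)
  dup <- X + matrix(rnorm(length(X), sd = 0.05), nrow(X), ncol(X))
  colnames(dup) <- paste0(colnames(X), "_dup")
  Xd <- cbind(X, dup)
  res <- find_minimal_parameter_set(Xd, cutoffs = c(0.95, 0.9), k = 3,
                                    seed = 51, n_restarts = 5)
  expect_true(res$satisfied)
  expect_length(res$retained, 5)
  expect_true(all(res$similarities > 0.99))
  # uncorrelated columns: the full set survives with similarity 1
  set.seed(27)
  Xu <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, letters[1:4]))
  res_u <- find_minimal_parameter_set(Xu, cutoffs = c(0.8, 0.6), k = 2,
                                      seed = 52, n_restarts = 5)
  expect_identical(res_u$retained, letters[1:4])
  expect_true(all(res_u$similarities > 1 - 1e-6))
  expect_error(find_minimal_parameter_set(Xu, cutoffs = c(0.2, 0.8), k = 2),
               "descending")
})
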