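#' Configuration for the synthetic cohort generator
#'
#' Bundles the knobs of the generator: cohort size, number of phenotypes,
#' number of latent archetypes, Dirichlet concentration of the archetype
#' weights, noise level (as a fraction of the spread of the archetype
#' profiles), the visit schedule and the number of recruitment centers.
#'
#' @param n_subjects number of subjects.
#' @param n_phenotypes number of phenotype columns (default 32).
#' @param k_true number of latent archetypes (default 4).
#' @param dirichlet_alpha symmetric Dirichlet concentration of the weight
#'   rows; small values place subjects near the vertices.
#' @param noise_sd i.i.d. Gaussian noise SD as a fraction of the SD of the
#'   archetype-profile entries.
#' @param seed integer seed.
#' @param visit_months schedule of visits in months from baseline.
#' @param centers number of recruitment centers.
#' @param covariate_sd SD of additive center/sex-genotype offsets on the
#'   phenotypes (0 by default so noiseless rows stay in the archetype hull).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects, n_phenotypes = 32, k_true = 4,
                          dirichlet_alpha = 0.5, noise_sd = 0.3, seed = 1,
                          visit_months = c(0, 9, 18, 27, 36), centers = 4,
                          covariate_sd = 0) {
  if (n_subjects < k_true) stopf("n_subjects must be >= k_true")
  if (n_phenotypes < 1 || k_true < 1) stopf("dimensions must be positive")
  if (dirichlet_alpha <= 0) stopf("dirichlet_alpha must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_phenotypes = as.integer(n_phenotypes),
                 k_true = as.integer(k_true),
                 dirichlet_alpha = dirichlet_alpha, noise_sd = noise_sd,
                 seed = as.integer(seed), visit_months = visit_months,
                 centers = as.integer(centers), covariate_sd = covariate_sd),
            class = "cohort_config")
}

#' Reference archetype phenotype profiles
#'
#' Returns the bundled table of four synthetic archetype profiles over the
#' 32 clinical phenotypes, expressed in standardized (z-score-like) units:
#' archetype A is lean and insulin deficient, B obese and insulin sensitive,
#' C obese and insulin resistant, D globally severe (high glycaemia, low
#' glucose sensitivity).  Used as the default latent profiles of
#' [generate_cohort()] so downstream labels are interpretable.
#'
#' @return k x m numeric matrix with archetype rows A-D and named phenotype
#'   columns.
#' @export
default_archetype_profiles <- function() {
  path <- system.file("extdata", "archetype_profiles_synthetic.csv",
                      package = "etioscope", mustWork = TRUE)
  tab <- utils::read.csv(path)
  Z <- t(as.matrix(tab[, c("A", "B", "C", "D")]))
  colnames(Z) <- tab$phenotype
  rownames(Z) <- c("A", "B", "C", "D")
  Z
}

# Per-archetype ground-truth beta-cell parameter anchors (units as in
# beta_cell_params); order A, B, C, D.
archetype_secretion_anchors <- function() {
  list(glucose_sensitivity = c(80, 71, 135, 34),
       rate_sensitivity = c(950, 773, 1715, 852),
       potentiation_ratio = c(1.76, 1.15, 1.29, 1.13),
       basal_secretion = c(93, 87, 203, 166),
       basal_glucose = c(6.8, 6.2, 6.9, 9.5),
       glucose_rise = c(2.5, 1.8, 3.0, 6.0))
}

dirichlet_rows <- function(n, k, alpha) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Generate a synthetic phenotype cohort with ground truth
#'
#' Draws per-subject archetype weights from a symmetric Dirichlet, forms the
#' phenotype matrix as convex mixtures of latent archetype profiles plus
#' i.i.d. Gaussian noise (\code{X = W Z + E}), attaches sex-genotype and
#' recruitment-center covariates, and returns both the observable
#' \code{phenotype_matrix} and a \code{synthetic_truth} record (profiles,
#' weights, HbA1c slopes, per-subject secretion parameters) for recovery
#' tests.  With the default \code{k_true = 4} and 32 phenotypes the latent
#' profiles are the bundled interpretable set
#' ([default_archetype_profiles()]); other shapes use seeded random profiles.
#'
#' Subject HbA1c slopes (mmol/mol per month) are generated with loadings on
#' the severe (D, positive) and insulin-deficient (A, negative) weights, and
#' secretion parameters interpolate per-archetype anchors with lognormal
#' between-subject variation.
#'
#' @param config a [cohort_config()].
#' @return list with elements \code{phenotypes} (a \code{phenotype_matrix})
#'   and \code{truth} (class \code{synthetic_truth}).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    k <- config$k_true; m <- config$n_phenotypes; n <- config$n_subjects
    if (k == 4L && m == 32L) {
      Z <- default_archetype_profiles()
    } else {
      Z <- matrix(stats::rnorm(k * m, sd = 1.4), k, m)
      colnames(Z) <- sprintf("phen_%02d", seq_len(m))
      rownames(Z) <- LETTERS[seq_len(k)]
    }
    W <- dirichlet_rows(n, k, config$dirichlet_alpha)
    colnames(W) <- rownames(Z)
    rownames(W) <- sprintf("S%04d", seq_len(n))
    sigma <- config$noise_sd * stats::sd(as.vector(Z))
    X <- W %*% Z
    if (sigma > 0) X <- X + matrix(stats::rnorm(n * m, sd = sigma), n, m)

    sex <- ifelse(stats::runif(n) < 0.41, "XX", "XY")
    center <- sample.int(config$centers, n, replace = TRUE)
    if (config$covariate_sd > 0) {
      center_eff <- matrix(stats::rnorm(config$centers * m,
                                        sd = config$covariate_sd),
                           config$centers, m)
      sex_eff <- stats::rnorm(m, sd = config$covariate_sd)
      X <- X + center_eff[center, ] + outer(sex == "XX", sex_eff)
    }
    rownames(X) <- sprintf("S%04d", seq_len(n))

    # ground-truth HbA1c slopes: severe archetype progresses fastest,
    # insulin-deficient slowest
    slopes <- 0.05 + 0.04 * (W[, min(k, 4L)] - 1 / k) -
      0.03 * (W[, 1L] - 1 / k) + stats::rnorm(n, sd = 0.045)
    names(slopes) <- rownames(W)

    anchors <- archetype_secretion_anchors()
    Wk <- if (k == 4L) W else {
      pad <- matrix(0, n, 4L); pad[, seq_len(min(k, 4L))] <-
        W[, seq_len(min(k, 4L))]
      pad / pmax(rowSums(pad), 1e-12)
    }
    jitter_ln <- function(x, cv) x * exp(stats::rnorm(n, sd = cv))
    secretion <- data.frame(
      subject_id = rownames(X),
      glucose_sensitivity = jitter_ln(drop(Wk %*% anchors$glucose_sensitivity), 0.15),
      rate_sensitivity = jitter_ln(drop(Wk %*% anchors$rate_sensitivity), 0.15),
      potentiation_ratio = jitter_ln(drop(Wk %*% anchors$potentiation_ratio), 0.05),
      basal_secretion = jitter_ln(drop(Wk %*% anchors$basal_secretion), 0.10),
      basal_glucose = jitter_ln(drop(Wk %*% anchors$basal_glucose), 0.05),
      glucose_rise = jitter_ln(drop(Wk %*% anchors$glucose_rise), 0.15),
      body_surface_area = stats::rnorm(n, 2.07, 0.23))

    truth <- structure(list(archetype_profiles = Z, weights = W,
                            slopes = slopes, secretion_params = secretion,
                            omics_loadings = NULL, config = config),
                       class = "synthetic_truth")
    phen <- phenotype_matrix(X,
      covariates = data.frame(subject_id = rownames(X),
                              sex_genotype = sex, center = factor(center)),
      transform_state = "rank_normal")
    list(phenotypes = phen, truth = truth)
  })
}

#' Ground-truth beta-cell parameter set for MMTT simulation
#'
#' Assembles the parameters of the two-component secretion model used by
#' [generate_mmtt()]: a linear dose response with slope
#' \code{glucose_sensitivity} anchored so that the basal steady state holds,
#' a geometric potentiation factor with 2h/baseline ratio
#' \code{potentiation_ratio} normalized to average one over the test, and a
#' rate-sensitivity term acting on positive glucose derivatives.
#'
#' @param glucose_sensitivity mean dose-response slope,
#'   pmol min^-1 m^-2 L mmol^-1.
#' @param rate_sensitivity pmol m^-2 L mmol^-1.
#' @param potentiation_ratio dimensionless P(120)/P(0).
#' @param basal_secretion pmol min^-1 m^-2 at basal glucose.
#' @param basal_glucose fasting glucose, mmol/L.
#' @param glucose_rise peak postprandial rise above basal, mmol/L.
#' @param body_surface_area m^2.
#' @param insulin_clearance L min^-1 m^-2, used to emit the insulin curve.
#' @return object of class \code{beta_cell_truth}.
#' @export
beta_cell_truth <- function(glucose_sensitivity = 84,
                            rate_sensitivity = 1100,
                            potentiation_ratio = 1.4,
                            basal_secretion = 136,
                            basal_glucose = 7.1,
                            glucose_rise = 4,
                            body_surface_area = 2.07,
                            insulin_clearance = 0.9) {
  structure(as.list(environment()), class = "beta_cell_truth")
}

# Potentiation factor P(t) = P0 * ratio^(t/T): geometric in time, and P0 is
# chosen in closed form so that the time average over [0, T] is exactly 1.
potentiation_curve <- function(t, ratio, t_end = 120) {
  if (abs(ratio - 1) < 1e-12) return(rep(1, length(t)))
  p0 <- log(ratio) / (ratio - 1)
  p0 * ratio^(t / t_end)
}

# Smooth postprandial glucose excursion: basal plus a log-normal-shaped bump
# peaking between 30 and 60 min, still elevated at 120 min.
glucose_excursion <- function(t, basal, rise, t_peak = 45, shape = 0.8) {
  bump <- ifelse(t <= 0, 0, exp(-(log(t / t_peak))^2 / (2 * shape^2)))
  basal + rise * bump
}

# True secretion rate of the two-component model on grid t (dG/dt by central
# differences of the noiseless glucose curve).
true_isr_curve <- function(t, params, kin) {
  G <- glucose_excursion(t, params$basal_glucose, params$glucose_rise)
  dG <- c(0, diff(G) / diff(t))
  P <- potentiation_curve(t, params$potentiation_ratio, max(t))
  f_basal <- params$basal_secretion / P[1L]
  f <- pmax(f_basal + params$glucose_sensitivity * (G - params$basal_glucose), 1)
  P * f + params$rate_sensitivity * pmax(dG, 0)
}

#' Simulate a mixed-meal tolerance test record
#'
#' Generates glucose, C-peptide and insulin curves for one subject from
#' known ground-truth secretion parameters.  Glucose follows a smooth
#' postprandial excursion; C-peptide is obtained by forward convolution of
#' the true secretion rate with the two-exponential kinetics kernel,
#' starting from the basal steady state; insulin is the secretion rate
#' divided by a constant clearance.  Multiplicative log-normal measurement
#' noise is applied at the given fractions (defaults mirror assay precision
#' of about 1% for glucose and 4% for C-peptide).
#'
#' @param truth_params a [beta_cell_truth()].
#' @param sampling_minutes strictly increasing sample times starting at 0 and
#'   spanning at least 120 min.
#' @param noise_glucose,noise_cpeptide multiplicative noise fractions.
#' @param seed integer seed.
#' @param kinetics a [cpeptide_kinetics()] kernel.
#' @param subject_id identifier stored on the record.
#' @return object of class \code{mmtt_record} with the sampled curves; the
#'   noiseless truth (fine-grid ISR and concentrations) is attached as
#'   attribute \code{"truth"}.
#' @export
generate_mmtt <- function(truth_params,
                          sampling_minutes = seq(0, 120, by = 5),
                          noise_glucose = 0.01, noise_cpeptide = 0.04,
                          seed = 1, kinetics = cpeptide_kinetics(),
                          subject_id = "S0001") {
  stopifnot(inherits(truth_params, "beta_cell_truth"))
  if (noise_glucose < 0 || noise_cpeptide < 0)
    stopf("noise fractions must be >= 0")
  if (sampling_minutes[1L] != 0 || any(diff(sampling_minutes) <= 0))
    stopf("sampling_minutes must be strictly increasing from 0")
  if (max(sampling_minutes) < 120) stopf("sampling must span at least 120 min")

  grid <- seq(0, max(sampling_minutes), by = 1)
  isr <- true_isr_curve(grid, truth_params, kinetics)
  cp <- simulate_cpeptide(isr, kinetics, grid = grid)
  G <- glucose_excursion(grid, truth_params$basal_glucose,
                         truth_params$glucose_rise)
  ins <- isr / truth_params$insulin_clearance

  idx <- match(sampling_minutes, grid)
  with_seed(seed, {
    ln_noise <- function(x, cv) if (cv == 0) x else
      x * exp(stats::rnorm(length(x), sd = cv))
    rec <- structure(list(
      subject_id = subject_id, minutes = sampling_minutes,
      glucose = ln_noise(G[idx], noise_glucose),
      cpeptide = ln_noise(cp[idx], noise_cpeptide),
      insulin = ln_noise(ins[idx], noise_cpeptide),
      body_surface_area = truth_params$body_surface_area),
      class = "mmtt_record")
    attr(rec, "truth") <- list(grid = grid, isr = isr, cpeptide = cp,
                               glucose = G, insulin = ins,
                               params = truth_params)
    rec
  })
}

#' Generate longitudinal HbA1c series with medication records
#'
#' Builds per-visit HbA1c values as baseline + slope x month + treatment
#' effects + Gaussian residual, using the ground-truth slopes from
#' [generate_cohort()].  Medication effects follow the sign conventions of
#' the progression model (glucose-lowering drugs lower HbA1c; BMI raises
#' it), and medication start days are generated so the 30-day effectiveness
#' lag is exercised.  A drug contributes \code{a + b * dose} only at visits
#' at least 30 days after its start.
#'
#' @param truth a \code{synthetic_truth}.
#' @param config the [cohort_config()] (visit schedule).
#' @param residual_sd Gaussian residual SD, mmol/mol.
#' @param effects named list of true effect sizes (all drug terms <= 0,
#'   \code{bmi} >= 0).
#' @param treated_fraction fraction of subjects on metformin.
#' @return list of class \code{hba1c_collection} with data.frames
#'   \code{visits} (subject_id, month, hba1c, assay_delay, bmi) and
#'   \code{medications} (subject_id, drug_class, dose_fraction, start_day,
#'   stop_day), plus the truth effects used.
#' @export
generate_hba1c <- function(truth, config, residual_sd = 2,
                           effects = list(metformin_a = -1.5, metformin_b = -2.5,
                                          otherdrug_a = -1, otherdrug_b = -2,
                                          insulin = -3, bmi = 0.15,
                                          delay = 0.02),
                           treated_fraction = 0.4) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(truth$slopes)
  ids <- rownames(truth$weights)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  months <- config$visit_months
  with_seed(config$seed + 1L, {
    base <- stats::rnorm(n, 46.4, 5.7)
    base_bmi <- stats::rnorm(n, 30.4, 4.9)

    meds <- list()
    for (i in seq_len(n)) {
      if (stats::runif(1) < treated_fraction)
        meds[[length(meds) + 1L]] <- data.frame(
          subject_id = ids[i], drug_class = "metformin",
          dose_fraction = round(stats::runif(1, 0.2, 0.8), 2),
          start_day = round(stats::runif(1, -300, 600)), stop_day = Inf)
      if (stats::runif(1) < 0.10)
        meds[[length(meds) + 1L]] <- data.frame(
          subject_id = ids[i], drug_class = "other_oral",
          dose_fraction = round(stats::runif(1, 0.2, 0.6), 2),
          start_day = round(stats::runif(1, 0, 800)), stop_day = Inf)
      if (stats::runif(1) < 0.05)
        meds[[length(meds) + 1L]] <- data.frame(
          subject_id = ids[i], drug_class = "insulin", dose_fraction = 1,
          start_day = round(stats::runif(1, 100, 900)), stop_day = Inf)
    }
    medications <- if (length(meds)) do.call(rbind, meds) else
      data.frame(subject_id = character(), drug_class = character(),
                 dose_fraction = numeric(), start_day = numeric(),
                 stop_day = numeric())

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      delay <- round(stats::runif(length(months), 0, 14))
      bmi <- base_bmi[i] + stats::rnorm(length(months), 0, 0.5)
      sub_meds <- medications[medications$subject_id == ids[i], , drop = FALSE]
      treat <- vapply(months, function(mo) {
        dd <- effective_dose(sub_meds, mo)
        effects$metformin_a * (dd[["metformin_dose"]] > 0) +
          effects$metformin_b * dd[["metformin_dose"]] +
          effects$otherdrug_a * (dd[["other_dose"]] > 0) +
          effects$otherdrug_b * dd[["other_dose"]] +
          effects$insulin * dd[["insulin"]]
      }, numeric(1))
      value <- base[i] + truth$slopes[i] * months + effects$bmi * bmi +
        effects$delay * delay + treat +
        stats::rnorm(length(months), 0, residual_sd)
      rows[[i]] <- data.frame(subject_id = ids[i], month = months,
                              hba1c = value, assay_delay = delay, bmi = bmi)
    }
    structure(list(visits = do.call(rbind, rows), medications = medications,
                   effects = effects, residual_sd = residual_sd),
              class = "hba1c_collection")
  })
}

#' Generate omics features with linear loadings on archetype weights
#'
#' The first \code{n_features - n_null} features load linearly on the
#' ground-truth archetype weights (each non-null feature loads on one
#' randomly chosen archetype with coefficient drawn at SD \code{effect_sd});
#' the remaining \code{n_null} features are pure standard-normal noise.
#' Which features are null is recorded for FDR-calibration tests.
#'
#' @param truth a \code{synthetic_truth}.
#' @param n_features total number of features.
#' @param n_null number of pure-noise features (<= n_features).
#' @param effect_sd SD of the non-null loading coefficients.
#' @param seed integer seed.
#' @return list: \code{features} (subjects x features matrix),
#'   \code{loadings} (features x k), \code{is_null} logical vector.
#' @export
generate_omics <- function(truth, n_features, n_null, effect_sd, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_null > n_features) stopf("n_null must be <= n_features")
  W <- truth$weights
  n <- nrow(W); k <- ncol(W)
  with_seed(seed, {
    L <- matrix(0, n_features, k)
    n_sig <- n_features - n_null
    if (n_sig > 0 && effect_sd > 0) {
      which_arch <- sample.int(k, n_sig, replace = TRUE)
      L[cbind(seq_len(n_sig), which_arch)] <- stats::rnorm(n_sig, sd = effect_sd)
    }
    F <- W %*% t(L) + matrix(stats::rnorm(n * n_features), n, n_features)
    colnames(F) <- sprintf("feat_%05d", seq_len(n_features))
    rownames(F) <- rownames(W)
    is_null <- rowSums(L != 0) == 0
    list(features = F, loadings = L, is_null = is_null)
  })
}

#' Generate biallelic genotype dosages and a risk-allele weight table
#'
#' Dosages are drawn binomially (2 trials) at per-SNP allele frequencies
#' uniform over \code{freq_range}.  The weight table carries per-SNP positive
#' effect sizes and a partition label from the six mechanism classes
#' (IS1, IS2, IA, BMI, LIPID, MIX) used for partitioned genetic risk scores;
#' every class is represented when \code{n_snps >= 6}.
#'
#' @param n_subjects,n_snps dimensions.
#' @param freq_range risk-allele frequency interval, subset of (0, 1).
#' @param seed integer seed.
#' @return list: \code{dosages} (subjects x SNPs, values 0/1/2),
#'   \code{weights} data.frame (snp, freq, weight, partition).
#' @export
generate_genotypes <- function(n_subjects, n_snps,
                               freq_range = c(0.05, 0.95), seed = 1) {
  if (freq_range[1L] < 0 || freq_range[2L] > 1 ||
      freq_range[1L] > freq_range[2L])
    stopf("freq_range must be an interval inside (0, 1)")
  classes <- c("IS1", "IS2", "IA", "BMI", "LIPID", "MIX")
  with_seed(seed, {
    freq <- stats::runif(n_snps, freq_range[1L], freq_range[2L])
    D <- vapply(freq, function(p) stats::rbinom(n_subjects, 2L, p),
                integer(n_subjects))
    if (n_subjects == 1L) D <- matrix(D, 1L, n_snps)
    colnames(D) <- sprintf("snp_%04d", seq_len(n_snps))
    rownames(D) <- sprintf("S%04d", seq_len(n_subjects))
    weights <- data.frame(
      snp = colnames(D), freq = freq,
      weight = abs(stats::rnorm(n_snps, 0.1, 0.05)),
      partition = sample(rep_len(classes, n_snps)))
    list(dosages = D, weights = weights)
  })
}
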