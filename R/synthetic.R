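#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of the classic longitudinal heart-study
#' cohort the methodology was developed for: about five thousand adults in
#' small nuclear families plus unrelated singletons, mean age at entry 37
#' (SD 9, minimum 18), 55 percent female, 64 percent ever-smokers, BMI
#' 25.0 (SD 4.1), additive marker effects tuned to a narrow-sense
#' heritability of years of life of 0.25, covariate effects of about +3.1
#' years (female vs male) and -4.1 years (ever- vs never-smoker), expected
#' years of life maximal for BMI near 22.5, and administrative
#' right-censoring (a stylized uniform enrollment window of 1958-1982 with
#' survival ascertained through 2007, calibrated so that roughly two
#' thirds of records are censored).
#'
#' @param n_founders unrelated singleton individuals.
#' @param n_families nuclear families (two founder parents each).
#' @param offspring_per_family offspring per family.
#' @param p number of markers.
#' @param maf_range range of ancestral minor-allele frequencies.
#' @param n_subpops,fst number of subpopulations and their
#'   Balding-Nichols divergence (fst = 0 gives an unstructured cohort).
#' @param h2 target narrow-sense heritability of years of life, in [0, 1).
#' @param causal_frac fraction of markers carrying (Gaussian) effects.
#' @param var_ge variance of the genetic-plus-residual component (years^2).
#' @param yl_base expected years of life of a never-smoking male at the
#'   BMI optimum.
#' @param sex_effect,smoking_effect additive covariate effects (years).
#' @param bmi_optimum,bmi_curvature BMI at maximal expected YL and the
#'   quadratic penalty (years per (kg/m^2)^2) away from it.
#' @param entry_age_mean,entry_age_sd age-at-entry distribution (truncated
#'   at 18 years).
#' @param enroll_start,enroll_end,study_end_year enrollment window and
#'   administrative end of follow-up (drives the censoring fraction).
#' @param prop_female,prop_smoker,bmi_mean,bmi_sd covariate distributions.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 1900, n_families = 800,
                       offspring_per_family = 2, p = 10000,
                       maf_range = c(0.05, 0.5), n_subpops = 1, fst = 0,
                       h2 = 0.25, causal_frac = 0.1, var_ge = 110,
                       yl_base = 83, sex_effect = 3.1, smoking_effect = -4.1,
                       bmi_optimum = 22.5, bmi_curvature = 0.043,
                       entry_age_mean = 37, entry_age_sd = 9,
                       enroll_start = 1958, enroll_end = 1982,
                       study_end_year = 2007,
                       prop_female = 0.55, prop_smoker = 0.64,
                       bmi_mean = 25.0, bmi_sd = 4.1, seed = 1) {
  if (h2 < 0 || h2 >= 1) stop_config("h2 must lie in [0, 1)")
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stop_config("maf_range must be within (0, 0.5]")
  if (fst < 0) stop_config("fst must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotypes with optional structure and families
#'
#' Founder allele frequencies are drawn per subpopulation with the
#' Balding-Nichols construction (Beta around an ancestral frequency with
#' divergence `fst`); founders are in Hardy-Weinberg equilibrium within
#' their subpopulation, and offspring genotypes descend by Mendelian gene
#' dropping (each parent transmits each allele independently with
#' probability dosage/2, valid for unlinked loci).  Families are couples
#' of founders drawn from the same subpopulation.
#'
#' @param config a [sim_config] (the caller controls the RNG seed).
#' @return list with `genotypes` (n x p dosage matrix with ids/marker
#'   names), `subpop` (integer labels), `pedigree` (data.frame),
#'   `sex` (0/1, offspring parents are one of each).
#' @export
simulate_genotypes <- function(config) {
  p <- config$p
  n_sing <- config$n_founders
  n_fam <- config$n_families
  n_off <- config$offspring_per_family
  n_founder_tot <- n_sing + 2 * n_fam
  n <- n_founder_tot + n_fam * n_off

  anc <- runif(p, config$maf_range[1], config$maf_range[2])
  K <- config$n_subpops
  freqs <- matrix(anc, K, p, byrow = TRUE)
  if (config$fst > 0 && K > 1) {
    a <- anc * (1 - config$fst) / config$fst
    b <- (1 - anc) * (1 - config$fst) / config$fst
    for (k in seq_len(K)) freqs[k, ] <- rbeta(p, a, b)
  }

  ids <- sprintf("ind%05d", seq_len(n))
  G <- matrix(0, n, p, dimnames = list(ids, sprintf("snp%05d", seq_len(p))))
  subpop <- integer(n)

  # founders: singletons then family parents, balanced over subpopulations
  founder_pop <- rep_len(seq_len(K), n_sing)
  fam_pop <- rep_len(seq_len(K), n_fam)
  for (i in seq_len(n_sing)) {
    k <- founder_pop[i]
    G[i, ] <- rbinom(p, 2, freqs[k, ])
    subpop[i] <- k
  }
  father <- rep(NA_character_, n); mother <- rep(NA_character_, n)
  sex <- rbinom(n, 1, config$prop_female)
  for (f in seq_len(n_fam)) {
    k <- fam_pop[f]
    i_pat <- n_sing + 2 * f - 1
    i_mat <- n_sing + 2 * f
    G[i_pat, ] <- rbinom(p, 2, freqs[k, ])
    G[i_mat, ] <- rbinom(p, 2, freqs[k, ])
    subpop[c(i_pat, i_mat)] <- k
    sex[i_pat] <- 0; sex[i_mat] <- 1
  }
  off0 <- n_founder_tot
  for (f in seq_len(n_fam)) {
    i_pat <- n_sing + 2 * f - 1
    i_mat <- n_sing + 2 * f
    for (o in seq_len(n_off)) {
      i <- off0 + (f - 1) * n_off + o
      G[i, ] <- rbinom(p, 1, G[i_pat, ] / 2) + rbinom(p, 1, G[i_mat, ] / 2)
      subpop[i] <- fam_pop[f]
      father[i] <- ids[i_pat]
      mother[i] <- ids[i_mat]
    }
  }
  pedigree <- data.frame(id = ids, father = father, mother = mother,
                         stringsAsFactors = FALSE)
  list(genotypes = G, subpop = subpop, pedigree = pedigree, sex = sex)
}

#' Simulate covariates
#' @param n number of individuals.
#' @param config a [sim_config].
#' @param sex optional pre-assigned 0/1 sex vector (families fix parents').
#' @return data.frame `sex`, `smoking`, `bmi`.
#' @export
simulate_covariates <- function(n, config, sex = NULL) {
  if (is.null(sex)) sex <- rbinom(n, 1, config$prop_female)
  data.frame(sex = sex,
             smoking = rbinom(n, 1, config$prop_smoker),
             bmi = pmax(rnorm(n, config$bmi_mean, config$bmi_sd), 14))
}

#' Simulate years of life with administrative censoring
#'
#' Years of life are generated on the scale of the analysis model itself:
#' YL_i = yl_base + sex_effect * female_i + smoking_effect * smoker_i -
#' bmi_curvature * (bmi_i - bmi_optimum)^2 + g_i + e_i, with the genetic
#' value g_i = sum_j x_ij beta_j rescaled so var(g) = h2 * var_ge and the
#' residual e_i drawn from N(0, (1 - h2) * var_ge) truncated so that every
#' individual survives at least to their (independently drawn) age at
#' entry.  Enrollment years are uniform over the enrollment window;
#' individuals whose death year falls after `study_end_year` are
#' right-censored at the age attained then.  The censoring time therefore
#' depends on entry year and entry age only, never on g or e.
#'
#' @param genotypes dosage matrix.
#' @param covariates data.frame from [simulate_covariates].
#' @param config a [sim_config].
#' @return list with `outcomes` (data.frame as in [cohort_data]) and
#'   `truth` (marker effects, genetic values, realized h2, causal ids,
#'   covariate surface and censoring parameters).
#' @export
simulate_phenotypes <- function(genotypes, covariates, config) {
  n <- nrow(genotypes); p <- ncol(genotypes)
  if (config$h2 >= 1) stop_config("h2 must be < 1")

  var_g <- config$h2 * config$var_ge
  var_e <- (1 - config$h2) * config$var_ge
  g <- numeric(n)
  beta <- numeric(p)
  causal <- integer(0)
  if (var_g > 0 && p > 0) {
    n_causal <- max(1L, ceiling(config$causal_frac * p))
    causal <- sort(sample.int(p, n_causal))
    beta[causal] <- rnorm(n_causal)
    Xc <- sweep(genotypes[, causal, drop = FALSE], 2,
                colMeans(genotypes[, causal, drop = FALSE]))
    g_raw <- as.vector(Xc %*% beta[causal])
    sc <- if (var(g_raw) > 0) sqrt(var_g / var(g_raw)) else 0
    beta <- beta * sc
    g <- g_raw * sc
  }

  surface <- config$yl_base + config$sex_effect * covariates$sex +
    config$smoking_effect * covariates$smoking -
    config$bmi_curvature * (covariates$bmi - config$bmi_optimum)^2

  age_entry <- rtruncnorm(n, config$entry_age_mean, config$entry_age_sd,
                          lower = 18)
  entry_year <- runif(n, config$enroll_start, config$enroll_end)

  # residual truncated so YL >= age at entry (subjects are alive at entry)
  e <- rtruncnorm(n, 0, sqrt(var_e), lower = age_entry - surface - g)
  yl <- surface + g + e

  death_year <- entry_year + (yl - age_entry)
  cens_age <- age_entry + (config$study_end_year - entry_year)
  censored <- death_year > config$study_end_year

  ids <- rownames(genotypes)
  outcomes <- data.frame(
    id = ids, age_entry = age_entry,
    status = ifelse(censored, "right", "observed"),
    yl_lower = ifelse(censored, cens_age, yl),
    yl_upper = ifelse(censored, Inf, yl),
    stringsAsFactors = FALSE)

  truth <- list(beta = setNames(beta, colnames(genotypes)),
                causal = colnames(genotypes)[causal],
                g = setNames(g, ids), yl = setNames(yl, ids),
                h2_target = config$h2,
                h2_realized = var(g) / var(g + e),
                censored_fraction = mean(censored),
                surface = list(yl_base = config$yl_base,
                               sex_effect = config$sex_effect,
                               smoking_effect = config$smoking_effect,
                               bmi_optimum = config$bmi_optimum,
                               bmi_curvature = config$bmi_curvature),
                censoring = list(enroll_start = config$enroll_start,
                                 enroll_end = config$enroll_end,
                                 study_end_year = config$study_end_year),
                entry_year = setNames(entry_year, ids))
  list(outcomes = outcomes, truth = truth)
}

#' Simulate a complete cohort with ground truth
#'
#' Runs [simulate_genotypes], [simulate_covariates] and
#' [simulate_phenotypes] under one seed and assembles a [cohort_data].
#'
#' @param config a [sim_config].
#' @return list with `cohort` (a [cohort_data]), `truth`, `subpop`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  gen <- simulate_genotypes(config)
  n <- nrow(gen$genotypes)
  covs <- simulate_covariates(n, config, sex = gen$sex)
  covs$id <- rownames(gen$genotypes)
  phen <- simulate_phenotypes(gen$genotypes, covs, config)
  cohort <- cohort_data(phen$outcomes, covs, gen$genotypes, gen$pedigree)
  list(cohort = cohort, truth = phen$truth, subpop = gen$subpop)
}

#' Write a simulated cohort as a reusable fixture
#'
#' Emits the [write_cohort] files plus `truth.json` (generating
#' parameters, causal markers, genetic values) into `out_dir`.  Files are
#' byte-reproducible from the simulation seed.
#'
#' @param sim result of [simulate_cohort].
#' @param out_dir output directory.
#' @return invisibly, the vector of paths written.
#' @export
write_fixture <- function(sim, out_dir) {
  paths <- write_cohort(sim$cohort, out_dir)
  tpath <- file.path(out_dir, "truth.json")
  tr <- sim$truth
  tr$entry_year <- NULL
  jsonlite::write_json(tr, tpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, truth = tpath))
}
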