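# Independent oracles and small fixture builders used across the suite.

# Closed-form inverse-Gaussian CDF (Chhikara & Folks), used to check the
# hand-rolled sampler without relying on it.
pinvgauss_oracle <- function(q, mean, shape) {
  a <- sqrt(shape / q)
  pnorm(a * (q / mean - 1)) +
    exp(2 * shape / mean) * pnorm(-a * (q / mean + 1))
}

# Brute-force pairwise AUC: P(case scored riskier) + 1/2 ties, risk being
# minus the predicted years of life.
brute_auc <- function(predicted_yl, indicator) {
  ok <- !is.na(indicator)
  p <- predicted_yl[ok]; y <- indicator[ok]
  cases <- p[y == 1]; controls <- p[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(cases) * length(controls))
}

# Monte-Carlo allele-dropping estimate of the additive relationship
# matrix: founders receive unique alleles, offspring inherit one random
# allele per parent per replicate; A_ij = 2 * P(random allele of i is IBD
# to a random allele of j), estimated over `reps` replicates.
A_allele_drop <- function(pedigree, reps = 2e5) {
  id <- as.character(pedigree$id)
  fa <- as.character(pedigree$father); fa[fa %in% c("0", "") | is.na(fa)] <- NA
  mo <- as.character(pedigree$mother); mo[mo %in% c("0", "") | is.na(mo)] <- NA
  n <- length(id)
  fi <- match(fa, id); mi <- match(mo, id)
  # parents-first order (pedigrees in tests are generated parents-first,
  # but re-sort defensively)
  ord <- integer(0); placed <- logical(n)
  while (length(ord) < n) {
    ready <- !placed & (is.na(fi) | placed[pmax(fi, 1)]) &
                       (is.na(mi) | placed[pmax(mi, 1)])
    ord <- c(ord, which(ready)); placed[ready] <- TRUE
  }
  al1 <- matrix(0L, n, reps); al2 <- matrix(0L, n, reps)
  next_allele <- 1L
  for (i in ord) {
    if (is.na(fi[i])) {
      al1[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(reps) < 0.5
      al1[i, ] <- ifelse(pick, al1[fi[i], ], al2[fi[i], ])
    }
    if (is.na(mi[i])) {
      al2[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(reps) < 0.5
      al2[i, ] <- ifelse(pick, al1[mi[i], ], al2[mi[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in i:n) {
    phi <- (mean(al1[i, ] == al1[j, ]) + mean(al1[i, ] == al2[j, ]) +
            mean(al2[i, ] == al1[j, ]) + mean(al2[i, ] == al2[j, ])) / 4
    A[i, j] <- A[j, i] <- 2 * phi
  }
  A
}

# random acyclic pedigree: founders first, later individuals may draw
# parents among earlier ones
random_pedigree <- function(n, n_founders = max(2, n %/% 3)) {
  id <- sprintf("p%02d", seq_len(n))
  fa <- rep(NA_character_, n); mo <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pool <- seq_len(i - 1)
    if (length(pool) >= 2 && runif(1) < 0.9) {
      pick <- sample(pool, 2)
      fa[i] <- id[pick[1]]; mo[i] <- id[pick[2]]
    }
  }
  data.frame(id = id, father = fa, mother = mo, stringsAsFactors = FALSE)
}

# small cohort without genotypes: observed/censored outcomes + covariates
make_test_cohort <- function(n, seed = 1, cens_frac = 0.3, mu = 80, sdv = 10,
                             genotypes = NULL) {
  set.seed(seed)
  y <- rnorm(n, mu, sdv)
  age <- pmin(rtruncnorm(n, 37, 9, lower = 18), y - 1)
  cens <- runif(n) < cens_frac
  cage <- pmax(age + 1, y - rexp(n, 1 / 10))
  cens <- cens & (cage < y)
  out <- data.frame(id = sprintf("i%04d", seq_len(n)), age_entry = age,
                    status = ifelse(cens, "right", "observed"),
                    yl_lower = ifelse(cens, cage, y),
                    yl_upper = ifelse(cens, Inf, y))
  cov <- data.frame(id = out$id, sex = rbinom(n, 1, 0.5),
                    smoking = rbinom(n, 1, 0.5),
                    bmi = rnorm(n, 25, 4))
  cohort_data(out, cov, genotypes)
}

# Tobit fixture: intercept-only outcome with fixed-point right censoring
make_tobit_cohort <- function(n = 500, mu = 75, sdv = 10, cpoint = 75,
                              seed = 42, ignore_censoring = FALSE) {
  set.seed(seed)
  y <- rnorm(n, mu, sdv)
  cens <- y > cpoint
  if (ignore_censoring) {
    yl_lower <- ifelse(cens, cpoint, y); status <- "observed"
    yl_upper <- yl_lower
  } else {
    status <- ifelse(cens, "right", "observed")
    yl_lower <- ifelse(cens, cpoint, y)
    yl_upper <- ifelse(cens, Inf, y)
  }
  out <- data.frame(id = sprintf("t%04d", seq_len(n)), age_entry = 20,
                    status = status, yl_lower = yl_lower, yl_upper = yl_upper)
  cov <- data.frame(id = out$id, sex = rbinom(n, 1, 0.5),
                    smoking = rbinom(n, 1, 0.5), bmi = rnorm(n, 25, 4))
  cohort_data(out, cov)
}

intercept_model <- function() model_spec(covariates = character(0), name = "intercept")

quick_chain <- function(n_iter = 2000, burn_in = 500, thin = 2, seed = 1)
  chain_control(n_iter, burn_in, thin, seed)
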