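#' Bayesian LASSO hyper-parameters
#'
#' Prior settings for the censored Bayesian LASSO: a scaled-inverse-chi^2
#' prior on the residual variance (degrees of freedom `df`, scale `S`) and
#' a Gamma prior on the regularization parameter lambda^2 (shape `s`, rate
#' `delta`).  `S` and `delta` left NULL are resolved from the data at fit
#' time following the weakly-informative guideline of centering the prior
#' on a plausible variance partition: the prior mode of the residual
#' variance is set to (1 - h0^2) times the sample variance of uncensored
#' years of life, and the prior mode of lambda^2 to
#' 2 (1 - h0^2) / h0^2 * sum_j var(x_j), with h0^2 = 0.25 (the classical
#' heritability of human lifespan).
#'
#' @param df,S residual-variance prior degrees of freedom and scale.
#' @param s,delta shape and rate of the Gamma prior on lambda^2.
#' @param h0_sq prior heritability used to resolve `S` and `delta`.
#' @export
bl_hyper <- function(df = 5, S = NULL, s = 1.1, delta = NULL, h0_sq = 0.25) {
  if (df <= 0 || s <= 0) stop_config("hyper-parameters df and s must be positive")
  if (!is.null(S) && S <= 0) stop_config("S must be positive")
  if (!is.null(delta) && delta <= 0) stop_config("delta must be positive")
  structure(list(df = df, S = S, s = s, delta = delta, h0_sq = h0_sq),
            class = "bl_hyper")
}

#' Gibbs chain settings
#'
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded before retention; `burn_in < n_iter`.
#' @param thin retain every `thin`-th sweep after burn-in.
#' @param seed integer RNG seed; the chain is bit-reproducible from it.
#' @export
chain_control <- function(n_iter = 30000, burn_in = 5000, thin = 10, seed = 1) {
  if (burn_in >= n_iter) stop_config("burn_in must be smaller than n_iter")
  if (thin < 1) stop_config("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_control")
}

# --- internal pieces of the Gibbs cycle -----------------------------------

# Encode the outcome table into parallel vectors used in the hot loop:
# code 0 = observed, 1 = right-, 2 = left-, 3 = interval-censored.
encode_outcomes <- function(out) {
  code <- match(out$status, c("observed", "right", "left", "interval")) - 1L
  list(code = code, lo = out$yl_lower, hi = out$yl_upper,
       censored = which(code > 0L), observed = which(code == 0L))
}

# Initial latent outcome: the observed value, or a point inside the bounds.
init_latent <- function(enc) {
  y <- ifelse(enc$code == 0L, enc$lo,
       ifelse(enc$code == 1L, enc$lo + 5,
       ifelse(enc$code == 2L, enc$hi - 5, (enc$lo + enc$hi) / 2)))
  y
}

# Truncated-normal augmentation of censored records.  eta is the current
# linear predictor; returns the full latent outcome vector.
.augment_outcomes <- function(eta, sigma2e, enc, y_latent) {
  ci <- enc$censored
  if (length(ci)) {
    y_latent[ci] <- rtruncnorm(length(ci), mean = eta[ci],
                               sd = sqrt(sigma2e),
                               lower = enc$lo[ci], upper = enc$hi[ci])
  }
  y_latent
}

# Park-Casella full conditional of the reciprocal marker variances:
# 1/tau^2_j ~ inverse-Gaussian(sqrt(lambda^2 sigma^2_e / beta_j^2), lambda^2),
# with a ceiling guarding the division when beta_j underflows.
.update_tau2 <- function(beta, lambda2, sigma2e, ceiling = 1e12) {
  if (lambda2 <= 0) stop_config("lambda2 must be positive")
  b2 <- beta^2
  tiny <- b2 < lambda2 * sigma2e / ceiling^2
  mu_star <- sqrt(lambda2 * sigma2e / pmax(b2, lambda2 * sigma2e / ceiling^2))
  inv <- rinvgauss(length(beta), mean = mu_star, shape = lambda2)
  inv <- pmin(inv, ceiling)
  inv[tiny] <- ceiling
  1 / inv
}

# Gamma full conditional of the regularization parameter.
.update_lambda2 <- function(tau2, s, delta) {
  rgamma(1, shape = length(tau2) + s, rate = sum(tau2) / 2 + delta)
}

# Scaled-inverse-chi^2 draw: (S0 + ss) / chi^2_{df0 + m}.
.draw_scaled_inv_chisq <- function(df0, S0, ss, m) {
  (S0 + ss) / rchisq(1, df = df0 + m)
}

# Observed-data deviance: -2 log likelihood using the normal density for
# observed records and normal tail/CDF/interval probabilities for censored
# ones.  This is the deviance DIC is built from.
observed_deviance <- function(eta, sigma2e, enc) {
  sdv <- sqrt(sigma2e)
  ll <- numeric(length(eta))
  o <- enc$code == 0L
  ll[o] <- dnorm(enc$lo[o], mean = eta[o], sd = sdv, log = TRUE)
  rt <- enc$code == 1L
  ll[rt] <- pnorm(enc$lo[rt], mean = eta[rt], sd = sdv,
                  lower.tail = FALSE, log.p = TRUE)
  lf <- enc$code == 2L
  ll[lf] <- pnorm(enc$hi[lf], mean = eta[lf], sd = sdv, log.p = TRUE)
  iv <- enc$code == 3L
  if (any(iv)) {
    pr <- pnorm(enc$hi[iv], eta[iv], sdv) - pnorm(enc$lo[iv], eta[iv], sdv)
    ll[iv] <- log(pmax(pr, 1e-300))
  }
  -2 * sum(ll)
}

resolve_hyper <- function(hyper, enc, Xc) {
  obs <- enc$code == 0L
  vy <- if (sum(obs) >= 2) var(enc$lo[obs]) else var(enc$lo[is.finite(enc$lo)])
  if (!is.finite(vy) || vy <= 0) vy <- 1
  h0 <- hyper$h0_sq
  if (is.null(hyper$S)) hyper$S <- (1 - h0) * vy * (hyper$df + 2)
  if (is.null(hyper$delta)) {
    sum_vx <- if (!is.null(Xc) && ncol(Xc) > 0)
      sum(colMeans(Xc^2) - colMeans(Xc)^2) else 1
    lambda0_sq <- max(2 * (1 - h0) / h0 * sum_vx, 1e-8)
    hyper$delta <- if (hyper$s > 1) (hyper$s - 1) / lambda0_sq
                   else hyper$s / lambda0_sq
  }
  hyper$V_y <- vy
  hyper
}

#' Fit the censored Bayesian LASSO whole-genome regression
#'
#' Runs the Gibbs sampler for the model
#' \deqn{y_i = \mu + w_i' \beta_F + \sum_j x_{ij} \beta_j + u_i + \epsilon_i}
#' where `y_i` is years of life (latent for censored records and imputed
#' from its truncated-normal full conditional each sweep), the fixed
#' effects (intercept, sex, smoking, spline terms, PCs) carry flat priors,
#' marker effects carry the Park-Casella Bayesian LASSO prior
#' beta_j ~ N(0, tau^2_j sigma^2_e) with exponential mixing on tau^2_j,
#' and the optional pedigree effect u ~ N(0, A sigma^2_u) is parameterized
#' through the Cholesky factor of the additive relationship matrix A.
#' Each sweep cycles: outcome augmentation, location effects (fixed,
#' marker, pedigree), tau^2, lambda^2, variances.
#'
#' @param cohort a [cohort_data] object.
#' @param model a [model_spec].
#' @param hyper a [bl_hyper]; NULL scales are resolved from the data.
#' @param chain a [chain_control].
#' @param pcs principal-component score matrix (rows aligned to the
#'   cohort) when the model includes PC covariates.
#' @param A additive relationship matrix for the cohort ids when the model
#'   includes a pedigree effect; computed from `cohort$pedigree` if NULL.
#' @param verbose print progress.
#' @return an object of class `wgp_fit` holding the retained chain
#'   (scalars and fixed effects per draw, with the per-draw observed-data
#'   deviance), posterior means of all location parameters, fitted values,
#'   the stored design/spline/centering information needed for prediction,
#'   and bookkeeping (seed, bounds violations).
#' @export
fit_wgp <- function(cohort, model, hyper = bl_hyper(), chain = chain_control(),
                    pcs = NULL, A = NULL, verbose = FALSE) {
  set.seed(chain$seed)
  n <- length(cohort$ids)
  enc <- encode_outcomes(cohort$outcomes)

  if (model$n_pcs > 0 && is.null(pcs)) {
    if (is.null(cohort$genotypes))
      stop_data("PC covariates requested but cohort has no genotypes")
    pcs <- genotype_pca(cohort$genotypes, model$n_pcs)$scores
  }
  design <- build_fixed_design(cohort, model, pcs = pcs)
  W <- design$X
  q <- ncol(W)
  WtW <- crossprod(W)
  cholW <- tryCatch(chol(WtW), error = function(e)
    stop_numerical("singular fixed-effect normal equations; check the design matrix rank"))

  has_markers <- !is.null(model$markers) && length(model$markers) > 0
  Xm <- NULL; centers <- NULL; xtx <- NULL; p_act <- 0L; active <- logical(0)
  if (has_markers) {
    if (is.null(cohort$genotypes)) stop_data("model includes markers but cohort has no genotypes")
    Xm <- cohort$genotypes[, model$markers, drop = FALSE]
    storage.mode(Xm) <- "double"
    centers <- colMeans(Xm)
    Xm <- sweep(Xm, 2, centers)
    xtx <- colSums(Xm^2)
    active <- xtx > 1e-12
    xtx[!active] <- 0
    p_act <- sum(active)
  }
  hyper <- resolve_hyper(hyper, enc, Xm)

  has_ped <- isTRUE(model$pedigree)
  L <- NULL; Ltx <- NULL
  if (has_ped) {
    if (is.null(A)) {
      if (is.null(cohort$pedigree)) stop_data("pedigree effect requested but cohort has no pedigree")
      Afull <- pedigree_A(cohort$pedigree)
      A <- Afull$A[cohort$ids, cohort$ids]
    }
    L <- t(chol(A + diag(1e-8, n)))
    Ltx <- colSums(L^2)
  }
  dfu <- 5; Su <- 0.25 * hyper$V_y * (dfu + 2)

  # state
  y_lat <- init_latent(enc)
  bF <- as.vector(solve(WtW, crossprod(W, y_lat)))
  beta <- numeric(if (has_markers) ncol(Xm) else 0)
  aa <- numeric(if (has_ped) n else 0)
  tau2 <- rep(1, length(beta))
  lambda2 <- if (hyper$s > 1) (hyper$s - 1) / hyper$delta + 1 else hyper$s / hyper$delta
  sigma2e <- max(hyper$V_y / 2, 1e-4)
  sigma2u <- 0.1 * hyper$V_y
  r <- y_lat - as.vector(W %*% bF)

  n_keep <- (chain$n_iter - chain$burn_in) %/% chain$thin
  draws <- data.frame(sigma2e = numeric(n_keep), lambda2 = numeric(n_keep),
                      sigma2u = numeric(n_keep), deviance = numeric(n_keep))
  draws_bF <- matrix(NA_real_, n_keep, q, dimnames = list(NULL, design$labels))
  eta_sum <- numeric(n); beta_sum <- numeric(length(beta))
  u_sum <- numeric(n); bF_sum <- numeric(q)
  bounds_violations <- 0L
  keep_i <- 0L

  for (it in seq_len(chain$n_iter)) {
    eta <- y_lat - r
    # 1. augment censored outcomes
    y_new <- .augment_outcomes(eta, sigma2e, enc, y_lat)
    r <- r + (y_new - y_lat)
    y_lat <- y_new
    # 2. fixed effects (flat prior Gaussian full conditional)
    rW <- r + as.vector(W %*% bF)
    mean_bF <- as.vector(solve(WtW, crossprod(W, rW)))
    bF <- mean_bF + sqrt(sigma2e) * backsolve(cholW, rnorm(q))
    r <- rW - as.vector(W %*% bF)
    # 3. marker effects (single-site sweep, running residual)
    if (has_markers)
      .gibbs_coef_sweep(Xm, r, beta, xtx, tau2 * sigma2e, sigma2e)
    # 4. pedigree effect through u = L a
    if (has_ped) {
      .gibbs_coef_sweep(L, r, aa, Ltx, rep(sigma2u, n), sigma2e)
      sigma2u <- .draw_scaled_inv_chisq(dfu, Su, sum(aa^2), n)
    }
    # 5-6. shrinkage hierarchy
    if (p_act > 0) {
      tau2[active] <- .update_tau2(beta[active], lambda2, sigma2e)
      lambda2 <- .update_lambda2(tau2[active], hyper$s, hyper$delta)
    }
    # 7. residual variance (includes the marker contribution because the
    # marker prior variance is scaled by sigma2_e)
    ssb <- if (p_act > 0) sum(beta[active]^2 / tau2[active]) else 0
    sigma2e <- .draw_scaled_inv_chisq(hyper$df, hyper$S, sum(r^2) + ssb,
                                      n + p_act)
    if (!is.finite(sigma2e) || anyNA(r))
      stop_numerical("non-finite sampler state at iteration %d", it)

    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0) {
      keep_i <- keep_i + 1L
      eta <- y_lat - r
      draws$sigma2e[keep_i] <- sigma2e
      draws$lambda2[keep_i] <- lambda2
      draws$sigma2u[keep_i] <- if (has_ped) sigma2u else NA_real_
      draws$deviance[keep_i] <- observed_deviance(eta, sigma2e, enc)
      draws_bF[keep_i, ] <- bF
      eta_sum <- eta_sum + eta
      bF_sum <- bF_sum + bF
      if (has_markers) beta_sum <- beta_sum + beta
      if (has_ped) u_sum <- u_sum + as.vector(L %*% aa)
      if (any(y_lat < enc$lo - 1e-8) || any(y_lat > enc$hi + 1e-8))
        bounds_violations <- bounds_violations + 1L
    }
    if (verbose && it %% 5000 == 0)
      message(sprintf("  iter %d / %d", it, chain$n_iter))
  }

  post <- list(beta_F = setNames(bF_sum / n_keep, design$labels),
               beta_M = if (has_markers)
                 setNames(beta_sum / n_keep,
                          cohort$marker_ids[model$markers]) else NULL,
               u = if (has_ped) u_sum / n_keep else NULL,
               fitted = eta_sum / n_keep,
               sigma2e = mean(draws$sigma2e),
               lambda2 = mean(draws$lambda2),
               sigma2u = if (has_ped) mean(draws$sigma2u) else NULL)

  ped_weights <- NULL
  if (has_ped) {
    ped_weights <- as.vector(solve(A + diag(1e-8, n), post$u))
  }

  structure(list(chain = draws, draws_beta_F = draws_bF, posterior = post,
                 model = model, hyper = hyper, control = chain,
                 design = design,
                 marker_ids = if (has_markers)
                   cohort$marker_ids[model$markers] else NULL,
                 marker_centers = centers,
                 ped_weights = ped_weights, train_ids = cohort$ids,
                 outcomes_enc = enc, n = n,
                 bounds_violations = bounds_violations),
            class = "wgp_fit")
}

#' @export
print.wgp_fit <- function(x, ...) {
  cat(sprintf("wgp_fit '%s': n = %d, %d retained draws\n",
              x$model$name, x$n, nrow(x$chain)))
  cat(sprintf("  posterior mean residual variance: %.2f\n", x$posterior$sigma2e))
  if (!is.null(x$posterior$beta_M))
    cat(sprintf("  markers: %d\n", length(x$posterior$beta_M)))
  invisible(x)
}

#' Predict expected years of life
#'
#' Posterior-mean linear predictor for new individuals.  The stored spline
#' specifications, covariate coding and marker centering from training are
#' reused, so fold-held-out predictions are exact reproductions of the
#' training-time basis.  Pedigree effects contribute only through
#' relationships to training individuals, supplied as the cross
#' relationship block `A_cross` (rows = new individuals, columns =
#' training individuals); without it they contribute zero.
#'
#' @param object a [fit_wgp] result.
#' @param cohort a [cohort_data] of individuals to predict; NULL returns
#'   the training fitted values.
#' @param pcs PC scores for the new individuals when the model has PC
#'   covariates (must come from the same PCA as training).
#' @param A_cross relationship block between new and training individuals.
#' @param ... unused.
#' @return numeric vector of expected years of life.
#' @export
predict.wgp_fit <- function(object, cohort = NULL, pcs = NULL,
                            A_cross = NULL, ...) {
  if (is.null(cohort)) return(object$posterior$fitted)
  design <- build_fixed_design(cohort, object$model, pcs = pcs,
                               spline_specs = object$design$spline_specs)
  eta <- as.vector(design$X %*% object$posterior$beta_F)
  if (!is.null(object$marker_ids)) {
    if (is.null(cohort$genotypes)) stop_data("cohort has no genotypes")
    miss <- setdiff(object$marker_ids, colnames(cohort$genotypes))
    if (length(miss))
      stop_data("markers absent from cohort: %s",
                paste(head(miss, 5), collapse = ", "))
    Xn <- cohort$genotypes[, object$marker_ids, drop = FALSE]
    Xn <- sweep(Xn, 2, object$marker_centers)
    eta <- eta + as.vector(Xn %*% object$posterior$beta_M)
  }
  if (!is.null(object$ped_weights)) {
    if (is.null(A_cross)) {
      message("predict.wgp_fit: no A_cross supplied; pedigree effect set to 0")
    } else {
      eta <- eta + as.vector(A_cross %*% object$ped_weights)
    }
  }
  eta
}

#' Deviance information criterion of a fitted chain
#'
#' DIC = mean deviance + pD, with pD = mean deviance minus the deviance at
#' the posterior means (posterior-mean linear predictor and posterior-mean
#' residual variance plugged into the observed-data likelihood: normal
#' density for observed records, normal tail/interval probabilities for
#' censored ones).  Smaller is better.
#'
#' @param fit a [fit_wgp] result.
#' @return list with `DIC`, `pD` and `mean_deviance`.
#' @export
dic <- function(fit) {
  if (nrow(fit$chain) < 10)
    stop_config("DIC needs at least 10 retained draws (have %d)", nrow(fit$chain))
  dbar <- mean(fit$chain$deviance)
  dhat <- observed_deviance(fit$posterior$fitted, fit$posterior$sigma2e,
                            fit$outcomes_enc)
  pd <- dbar - dhat
  list(DIC = dbar + pd, pD = pd, mean_deviance = dbar)
}
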