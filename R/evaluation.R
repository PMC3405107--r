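#' Percent of variance explained from two residual variances
#'
#' The summary used when comparing nested model fits: the percent
#' reduction of the (posterior-mean) residual variance of a richer model
#' relative to a reference model, 100 * (1 - v_model / v_reference).
#' Applied, e.g., to the intercept-only variance versus the entry-age +
#' sex model, or to a marker model versus its covariate-only counterpart.
#'
#' @param v_model residual variance of the richer model.
#' @param v_reference residual variance of the reference model.
#' @return percent reduction (may be negative).
#' @export
pct_variance_explained <- function(v_model, v_reference) {
  if (any(v_model <= 0) || any(v_reference <= 0))
    stop_config("variances must be positive")
  100 * (1 - v_model / v_reference)
}

#' Cross-validation fold assignment
#'
#' Balanced random partition of individuals (or whole families) into `k`
#' folds.  In family mode, families are the connected components of the
#' pedigree graph (parent-offspring edges), so every family lands intact
#' in one fold and held-out individuals have no direct relatives in
#' training.
#'
#' @param ids character vector of individual ids.
#' @param k number of folds, >= 2.
#' @param unit `"individual"` or `"family"`.
#' @param seed RNG seed; the assignment is deterministic given it.
#' @param pedigree pedigree data.frame, required in family mode.
#' @return object of class `cv_plan`: list with `k`, `unit`, `seed` and
#'   `assignment` (named integer vector id -> fold).
#' @export
make_folds <- function(ids, k, unit = c("individual", "family"), seed = 1,
                       pedigree = NULL) {
  unit <- match.arg(unit)
  if (k < 2) stop_config("need at least 2 folds")
  set.seed(seed)
  if (unit == "individual") {
    if (k > length(ids)) stop_config("more folds than individuals")
    fold <- sample(rep_len(seq_len(k), length(ids)))
    names(fold) <- ids
  } else {
    if (is.null(pedigree))
      stop_config("family-unit folds require a pedigree")
    fam <- pedigree_components(pedigree, ids)
    ufam <- unique(fam)
    if (k > length(ufam)) stop_config("more folds than families")
    fam_fold <- setNames(sample(rep_len(seq_len(k), length(ufam))), ufam)
    fold <- fam_fold[fam]
    names(fold) <- ids
  }
  structure(list(k = k, unit = unit, seed = seed, assignment = fold),
            class = "cv_plan")
}

# connected components of the parent-offspring graph, labelled per cohort id;
# ids absent from the pedigree are singleton families
pedigree_components <- function(pedigree, ids) {
  pid <- as.character(pedigree$id)
  fa <- normalize_parent(pedigree$father)
  mo <- normalize_parent(pedigree$mother)
  all_ids <- unique(c(pid, fa[!is.na(fa)], mo[!is.na(mo)], ids))
  parent <- seq_along(all_ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  idx <- setNames(seq_along(all_ids), all_ids)
  for (r in seq_along(pid)) {
    if (!is.na(fa[r])) unite(idx[[pid[r]]], idx[[fa[r]]])
    if (!is.na(mo[r])) unite(idx[[pid[r]]], idx[[mo[r]]])
  }
  roots <- vapply(idx[ids], find, integer(1))
  paste0("fam", roots)
}

#' Cross-validation R-squared against the entry-age baseline
#'
#' R^2_cv = 1 - sum_dead (y_i - yhat_i)^2 / sum_dead (y_i - ybar_i)^2,
#' where the sums run over uncensored subjects only, yhat are out-of-fold
#' predictions from the model of interest and ybar are out-of-fold
#' predictions from the baseline model (intercept + entry-age effect).
#' The statistic is the proportion of inter-individual differences in
#' years of life accounted for beyond the baseline; it can be negative.
#'
#' @param observed_yl observed years of life (only entries with
#'   `uncensored_mask` TRUE are used).
#' @param predictions,baseline_predictions aligned prediction vectors.
#' @param uncensored_mask logical vector marking observed deaths.
#' @return scalar R^2_cv.
#' @export
cv_r_squared <- function(observed_yl, predictions, baseline_predictions,
                         uncensored_mask) {
  u <- which(uncensored_mask)
  if (!length(u)) stop_data("no uncensored subjects; R^2_cv is undefined")
  y <- observed_yl[u]
  num <- sum((y - predictions[u])^2)
  den <- sum((y - baseline_predictions[u])^2)
  1 - num / den
}

#' Survival status indicators at a ladder of age thresholds
#'
#' For each individual and threshold tau: 1 if the individual died before
#' tau, 0 if known to be alive at tau (observed death at or after tau, or
#' censored at or after tau), and undetermined (NA) if censored before
#' tau.  Left/interval records are classified when their bounds decide the
#' status and undetermined otherwise.
#'
#' @param outcomes outcome data.frame as in [cohort_data].
#' @param thresholds ages tau (default 60, 65, ..., 95).
#' @return list with `indicators` (n x length(thresholds) matrix of
#'   0/1/NA) and `determined` (named count of non-missing entries per
#'   threshold).
#' @export
survival_indicators <- function(outcomes, thresholds = seq(60, 95, by = 5)) {
  n <- nrow(outcomes)
  M <- matrix(NA_real_, n, length(thresholds),
              dimnames = list(outcomes$id, paste0("tau", thresholds)))
  lo <- outcomes$yl_lower
  hi <- outcomes$yl_upper
  st <- outcomes$status
  for (j in seq_along(thresholds)) {
    tau <- thresholds[j]
    v <- rep(NA_real_, n)
    obs <- st == "observed"
    v[obs] <- as.numeric(lo[obs] < tau)
    rt <- st == "right"
    v[rt & lo >= tau] <- 0                  # alive at tau
    lf <- st == "left"
    v[lf & hi <= tau] <- 1                  # died before the bound <= tau
    iv <- st == "interval"
    v[iv & hi <= tau] <- 1
    v[iv & lo >= tau] <- 0
    M[, j] <- v
  }
  list(indicators = M,
       determined = setNames(colSums(!is.na(M)), colnames(M)))
}

#' Longitudinal AUC at a survival threshold
#'
#' AUC(tau) = P(risk_case > risk_control) + 0.5 P(tie) with risk score
#' equal to minus the predicted years of life (shorter predicted life =
#' higher early-death risk), cases the individuals who died before tau and
#' controls those alive at tau; undetermined records are excluded.  Equals
#' the Mann-Whitney statistic normalized by n_case * n_control; computed
#' with the trapezoidal (tie = 1/2) convention via \pkg{pROC}.
#'
#' @param predicted_yl predicted years of life.
#' @param indicators 0/1/NA survival indicator vector at the threshold
#'   (see [survival_indicators]).
#' @return scalar AUC, or NA with a warning when there is no case or no
#'   control among the determined records.
#' @export
longitudinal_auc <- function(predicted_yl, indicators) {
  ok <- !is.na(indicators)
  y <- indicators[ok]; p <- predicted_yl[ok]
  if (!any(y == 1) || !any(y == 0)) {
    warning("longitudinal_auc: need at least one case and one control; returning NA")
    return(NA_real_)
  }
  # direction ">": controls (alive) have larger predicted YL than cases
  as.numeric(pROC::auc(response = y, predictor = p,
                       levels = c(0, 1), direction = ">", quiet = TRUE))
}

#' Absolute prediction error profile by years-of-life bin
#'
#' Mean absolute out-of-fold prediction error among uncensored subjects,
#' grouped into the bins YL <= 65, (65, 70], ..., (90, 95], YL > 95, with
#' standard errors and 95 percent confidence intervals (mean +/- 1.96 SE).
#' Bins with fewer than two subjects get an NA standard error; empty bins
#' are NA throughout.
#'
#' @param observed_yl observed years of life.
#' @param predictions aligned predictions.
#' @param uncensored_mask logical mask of observed deaths.
#' @return data.frame with one row per bin: `bin`, `n`, `mean_abs_error`,
#'   `se`, `ci_lower`, `ci_upper`.
#' @export
abs_error_profile <- function(observed_yl, predictions, uncensored_mask) {
  u <- which(uncensored_mask)
  y <- observed_yl[u]; e <- abs(y - predictions[u])
  brk <- c(-Inf, seq(65, 95, by = 5), Inf)
  labs <- c("<=65", "(65,70]", "(70,75]", "(75,80]", "(80,85]",
            "(85,90]", "(90,95]", ">95")
  g <- cut(y, breaks = brk, labels = labs)
  res <- data.frame(bin = labs, n = 0L, mean_abs_error = NA_real_,
                    se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
  for (i in seq_along(labs)) {
    ei <- e[g == labs[i]]
    m <- length(ei)
    res$n[i] <- m
    if (m >= 1) res$mean_abs_error[i] <- mean(ei)
    if (m >= 2) {
      res$se[i] <- sd(ei) / sqrt(m)
      res$ci_lower[i] <- res$mean_abs_error[i] - 1.96 * res$se[i]
      res$ci_upper[i] <- res$mean_abs_error[i] + 1.96 * res$se[i]
    }
  }
  res
}

#' Cross-validated evaluation of a model ladder
#'
#' For each model in the ladder and each fold of the plan: fit on the
#' remaining folds, predict the held-out individuals, and pool the
#' out-of-fold predictions.  The baseline model (intercept + 4-df
#' entry-age spline) is refit inside the same training folds, so the
#' R^2_cv denominator never sees held-out data.  Reports overall and
#' per-fold R^2_cv, longitudinal AUC at each threshold, and the
#' absolute-error profile.  PC covariates are by default computed once
#' from the full genotype panel before splitting (the leakage this
#' implies is flagged in the report); `pc_mode = "fold"` recomputes them
#' within each training fold instead.
#'
#' @param cohort a [cohort_data].
#' @param models named list of [model_spec]s (see [model_ladder]).
#' @param cv_plan a [make_folds] plan.
#' @param hyper,chain passed to [fit_wgp] (the chain seed is offset per
#'   fold so folds are independent but reproducible).
#' @param thresholds AUC thresholds.
#' @param pc_mode `"full"` (PCs from all genotypes, as in a whole-cohort
#'   analysis) or `"fold"` (PCs refit per training fold, no leakage).
#' @param baseline a [model_spec] for the R^2_cv baseline.
#' @param verbose print per-fold progress.
#' @return object of class `cv_report`: list with `predictions` (matrix,
#'   one column per model plus the baseline), `r2` (data.frame of overall
#'   and per-fold R^2_cv), `auc` (models x thresholds), `auc_fold`
#'   (models x thresholds x folds), `error_profile` (list per model),
#'   `folds`, `pc_leakage`.
#' @export
run_cv_experiment <- function(cohort, models, cv_plan, hyper = bl_hyper(),
                              chain = chain_control(),
                              thresholds = seq(60, 95, by = 5),
                              pc_mode = c("full", "fold"),
                              baseline = model_spec(covariates = "age_spline",
                                                    name = "baseline"),
                              verbose = FALSE) {
  pc_mode <- match.arg(pc_mode)
  n <- length(cohort$ids)
  fold <- cv_plan$assignment[cohort$ids]
  if (anyNA(fold)) stop_config("cv plan does not cover all cohort ids")

  any_pcs <- any(vapply(models, function(m) m$n_pcs > 0, logical(1)))
  pcs_full <- NULL
  if (any_pcs && pc_mode == "full") {
    kmax <- max(vapply(models, function(m) m$n_pcs, numeric(1)))
    pcs_full <- genotype_pca(cohort$genotypes, kmax)$scores
  }
  any_ped <- any(vapply(models, function(m) isTRUE(m$pedigree), logical(1)))
  A_full <- NULL
  if (any_ped) {
    if (is.null(cohort$pedigree)) stop_config("pedigree model in ladder but cohort has no pedigree")
    A_full <- pedigree_A(cohort$pedigree)$A[cohort$ids, cohort$ids]
  }

  model_names <- names(models)
  preds <- matrix(NA_real_, n, length(models) + 1,
                  dimnames = list(cohort$ids, c(model_names, ".baseline")))
  r2_fold <- matrix(NA_real_, length(models), cv_plan$k,
                    dimnames = list(model_names, paste0("fold", seq_len(cv_plan$k))))

  obs <- cohort$outcomes$status == "observed"
  yl <- ifelse(obs, cohort$outcomes$yl_lower, NA_real_)

  for (f in seq_len(cv_plan$k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (!length(test)) next
    tr <- subset_cohort(cohort, train)
    te <- subset_cohort(cohort, test)
    fold_chain <- chain
    fold_chain$seed <- chain$seed + 1000L * f
    if (verbose) message(sprintf("fold %d / %d (n_train = %d)", f, cv_plan$k, length(train)))

    base_fit <- fit_wgp(tr, baseline, hyper = hyper, chain = fold_chain)
    preds[test, ".baseline"] <- predict(base_fit, te)

    pcs_tr_fold <- NULL
    for (mi in seq_along(models)) {
      m <- models[[mi]]
      pcs_tr <- NULL; pcs_te <- NULL
      if (m$n_pcs > 0) {
        if (pc_mode == "full") {
          pcs_tr <- pcs_full[train, , drop = FALSE]
          pcs_te <- pcs_full[test, , drop = FALSE]
        } else {
          if (is.null(pcs_tr_fold)) {
            pca_tr <- genotype_pca(tr$genotypes, m$n_pcs)
            pcs_tr_fold <- pca_tr
          }
          pcs_tr <- pcs_tr_fold$scores
          # project held-out genotypes on the training loadings
          Gte <- te$genotypes[, colnames(tr$genotypes)[apply(tr$genotypes, 2, sd) > 0], drop = FALSE]
          Gtr <- tr$genotypes[, colnames(Gte), drop = FALSE]
          mu <- colMeans(Gtr); sdv <- apply(Gtr, 2, sd)
          pcs_te <- scale(Gte, center = mu, scale = sdv) %*% pcs_tr_fold$loadings
        }
      }
      A_tt <- NULL; A_cross <- NULL
      if (isTRUE(m$pedigree)) {
        A_tt <- A_full[train, train, drop = FALSE]
        A_cross <- A_full[test, train, drop = FALSE]
      }
      fit <- fit_wgp(tr, m, hyper = hyper, chain = fold_chain,
                     pcs = pcs_tr, A = A_tt)
      preds[test, mi] <- predict(fit, te, pcs = pcs_te, A_cross = A_cross)
      if (any(obs[test]))
        r2_fold[mi, f] <- cv_r_squared(yl[test], preds[test, mi],
                                       preds[test, ".baseline"], obs[test])
    }
  }

  r2_overall <- vapply(model_names, function(mn)
    cv_r_squared(yl, preds[, mn], preds[, ".baseline"], obs), numeric(1))
  r2 <- data.frame(model = model_names, overall = r2_overall, r2_fold,
                   check.names = FALSE, row.names = NULL)

  si <- survival_indicators(cohort$outcomes, thresholds)
  auc <- matrix(NA_real_, length(models), length(thresholds),
                dimnames = list(model_names, paste0("tau", thresholds)))
  auc_fold <- array(NA_real_, c(length(models), length(thresholds), cv_plan$k),
                    dimnames = list(model_names, paste0("tau", thresholds),
                                    paste0("fold", seq_len(cv_plan$k))))
  for (mn in model_names)
    for (j in seq_along(thresholds)) {
      auc[mn, j] <- suppressWarnings(
        longitudinal_auc(preds[, mn], si$indicators[, j]))
      for (f in seq_len(cv_plan$k)) {
        tf <- which(fold == f)
        auc_fold[mn, j, f] <- suppressWarnings(
          longitudinal_auc(preds[tf, mn], si$indicators[tf, j]))
      }
    }

  profiles <- lapply(model_names, function(mn)
    abs_error_profile(yl, preds[, mn], obs))
  names(profiles) <- model_names

  structure(list(predictions = preds, r2 = r2, auc = auc,
                 auc_fold = auc_fold,
                 error_profile = profiles, determined = si$determined,
                 folds = cv_plan,
                 pc_leakage = any_pcs && pc_mode == "full"),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold (%s units)\n", x$folds$k, x$folds$unit))
  print(x$r2[, c("model", "overall")], row.names = FALSE)
  if (isTRUE(x$pc_leakage))
    cat("  note: PC covariates computed on the full panel before splitting\n")
  invisible(x)
}
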