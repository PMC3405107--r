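test_that("fold assignment is balanced, deterministic and family-coherent", {
  ids <- sprintf("i%03d", 1:100)
  plan <- make_folds(ids, 10, "individual", seed = 4)
  expect_equal(as.vector(table(plan$assignment)), rep(10L, 10))
  plan2 <- make_folds(ids, 10, "individual", seed = 4)
  expect_identical(plan$assignment, plan2$assignment)
  expect_false(identical(plan$assignment,
                         make_folds(ids, 10, "individual", seed = 5)$assignment))
  expect_error(make_folds(ids[1:5], 10), "folds")
  # 30 trios stay intact within folds
  ids3 <- character(0); fa <- character(0); mo <- character(0)
  for (t in 1:30) {
    trio <- sprintf("t%02d_%s", t, c("f", "m", "o"))
    ids3 <- c(ids3, trio); fa <- c(fa, NA, NA, trio[1]); mo <- c(mo, NA, NA, trio[2])
  }
  ped <- data.frame(id = ids3, father = fa, mother = mo)
  planf <- make_folds(ids3, 10, "family", seed = 6, pedigree = ped)
  for (t in 1:30) {
    trio <- sprintf("t%02d_%s", t, c("f", "m", "o"))
    expect_equal(length(unique(planf$assignment[trio])), 1L)
  }
  expect_equal(as.vector(table(planf$assignment)), rep(9L, 10))
  expect_error(make_folds(ids3, 10, "family"), "pedigree")
})

test_that("cross-validation R-squared matches its definition", {
  y <- c(70, 80, 90); base <- c(80, 80, 80)
  expect_equal(cv_r_squared(y, c(72, 80, 88), base, rep(TRUE, 3)), 0.96)
  expect_equal(cv_r_squared(y, base, base, rep(TRUE, 3)), 0)
  expect_equal(cv_r_squared(y, y, base, rep(TRUE, 3)), 1)
  # order invariance
  set.seed(8)
  n <- 40; yy <- rnorm(n, 80, 10); pp <- yy + rnorm(n, 0, 5)
  bb <- rnorm(n, 80, 2); msk <- runif(n) < 0.6
  perm <- sample(n)
  expect_equal(cv_r_squared(yy, pp, bb, msk),
               cv_r_squared(yy[perm], pp[perm], bb[perm], msk[perm]))
  expect_error(cv_r_squared(yy, pp, bb, rep(FALSE, n)), "uncensored")
})

test_that("survival indicators implement the determined/undetermined rules", {
  out <- data.frame(id = c("d58", "c70", "c55", "d80"),
                    age_entry = 30,
                    status = c("observed", "right", "right", "observed"),
                    yl_lower = c(58, 70, 55, 80),
                    yl_upper = c(58, Inf, Inf, 80))
  si <- survival_indicators(out, thresholds = c(60, 75))
  expect_equal(unname(si$indicators[, "tau60"]), c(1, 0, NA, 0))
  expect_equal(unname(si$indicators[, "tau75"]), c(1, NA, NA, 0))
  expect_equal(unname(si$determined), c(3L, 2L))
  # determined records at tau exclude exactly those censored below tau
  set.seed(9)
  co <- make_test_cohort(120, seed = 9, cens_frac = 0.5)
  si2 <- survival_indicators(co$outcomes)
  for (j in seq_along(si2$determined)) {
    tau <- c(seq(60, 95, 5))[j]
    cens_below <- co$outcomes$status == "right" & co$outcomes$yl_lower < tau
    expect_equal(unname(si2$determined[j]), sum(!cens_below))
  }
})

test_that("longitudinal AUC equals exhaustive pairwise enumeration", {
  # perfect separation and all-ties
  expect_equal(longitudinal_auc(c(60, 65, 85, 90), c(1, 1, 0, 0)), 1.0)
  expect_equal(longitudinal_auc(rep(70, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # random instances up to n = 30, including ties and undetermined records
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    pred <- sample(seq(60, 90, 2.5), n, replace = TRUE)
    ind <- sample(c(0, 1, NA), n, replace = TRUE, prob = c(.4, .4, .2))
    if (sum(ind == 1, na.rm = TRUE) == 0 || sum(ind == 0, na.rm = TRUE) == 0) next
    expect_equal(longitudinal_auc(pred, ind), brute_auc(pred, ind))
  }
  expect_warning(auc_na <- longitudinal_auc(c(70, 80), c(1, 1)), "case")
  expect_true(is.na(auc_na))
})

test_that("absolute-error profile bins and intervals are correct", {
  y <- c(60, 63, 67, 68, 72, 81, 97)
  p <- c(62, 60, 67, 70, 75, 81, 90)
  res <- abs_error_profile(y, p, rep(TRUE, 7))
  expect_equal(res$mean_abs_error[res$bin == "<=65"], mean(c(2, 3)))
  expect_equal(res$mean_abs_error[res$bin == "(65,70]"], mean(c(0, 2)))
  expect_equal(res$mean_abs_error[res$bin == "(70,75]"], 3)
  expect_true(is.na(res$se[res$bin == "(70,75]"]))     # single subject
  expect_equal(res$mean_abs_error[res$bin == ">95"], 7)
  expect_true(is.na(res$mean_abs_error[res$bin == "(85,90]"]))  # empty bin
  expect_equal(res$n[res$bin == "(75,80]"], 0L)
  # exact predictions give all-zero bin means
  res0 <- abs_error_profile(y, y, rep(TRUE, 7))
  expect_true(all(res0$mean_abs_error[res0$n > 0] == 0))
  # SE construction: mean +/- 1.96 SE
  i65 <- which(res$bin == "<=65")
  expect_equal(res$ci_upper[i65],
               res$mean_abs_error[i65] + 1.96 * sd(c(2, 3)) / sqrt(2))
})

test_that("a small cross-validated ladder runs end to end and is self-consistent", {
  cfg <- sim_config(n_founders = 100, n_families = 30, p = 80, h2 = 0.3,
                    causal_frac = 0.3, seed = 61)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  models <- list(
    "A-0" = model_spec(c("sex", "age_spline"), name = "A-0"),
    "B-80" = model_spec(c("sex", "age_spline", "smoking", "bmi_spline"),
                        markers = 1:80, name = "B-80"))
  plan <- make_folds(co$ids, 3, "individual", seed = 2)
  rep <- run_cv_experiment(co, models, plan, chain = quick_chain(900, 300, 3, seed = 3),
                           thresholds = c(70, 80))
  # overall R2 equals recomputation from the pooled prediction matrix
  obs <- co$outcomes$status == "observed"
  yl <- co$outcomes$yl_lower
  r2_manual <- cv_r_squared(yl, rep$predictions[, "B-80"],
                            rep$predictions[, ".baseline"], obs)
  expect_equal(rep$r2$overall[rep$r2$model == "B-80"], r2_manual)
  expect_false(any(is.na(rep$predictions)))
  expect_equal(dim(rep$auc), c(2L, 2L))
  expect_equal(dim(rep$auc_fold), c(2L, 2L, 3L))
  # per-fold AUCs scatter around the pooled value
  expect_lt(abs(mean(rep$auc_fold["B-80", "tau80", ], na.rm = TRUE) -
                  rep$auc["B-80", "tau80"]), 0.25)
  expect_equal(nrow(rep$error_profile[["A-0"]]), 8L)
})
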