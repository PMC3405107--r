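#' Natural cubic spline basis with reproducible knots
#'
#' Wraps [splines::ns()].  When fitted (no `spec`), a `df`-column natural
#' cubic spline basis is built with interior knots at equally spaced
#' sample percentiles (for `df = 4`: the 25th, 50th and 75th percentiles)
#' and boundary knots at the sample range.  The knot specification is
#' returned so the identical basis can be evaluated on new data — required
#' when predicting held-out cross-validation folds.  Natural splines are
#' linear beyond the boundary knots, so out-of-range evaluation is well
#' defined (a message notes it).
#'
#' @param x numeric vector.
#' @param df basis dimension, >= 2.
#' @param spec a stored spec (as returned in `$spec`) to re-evaluate a
#'   fitted basis on new `x`; overrides `df`.
#' @return list with `basis` (length(x) x df matrix) and `spec` (list of
#'   `df`, `knots`, `boundary`).
#' @export
natural_spline_basis <- function(x, df = 4, spec = NULL) {
  if (is.null(spec)) {
    if (df < 2) stop_config("natural spline needs df >= 2")
    if (length(unique(x)) < df)
      stop_data("too few distinct values (%d) for a %d-df spline",
                length(unique(x)), df)
    basis <- splines::ns(x, df = df)
    spec <- list(df = df,
                 knots = as.numeric(attr(basis, "knots")),
                 boundary = as.numeric(attr(basis, "Boundary.knots")))
  } else {
    if (any(x < spec$boundary[1] | x > spec$boundary[2]))
      message("natural_spline_basis: evaluating beyond boundary knots (linear extrapolation)")
    basis <- splines::ns(x, knots = spec$knots, Boundary.knots = spec$boundary)
  }
  list(basis = unclass(basis)[, , drop = FALSE], spec = spec)
}

#' Specify the terms of a whole-genome regression model
#'
#' A model spec names which fixed-effect covariates enter the linear
#' predictor, which markers (if any), how many genotype principal
#' components, and whether a pedigree random effect is included.
#'
#' @param covariates character subset of `"sex"`, `"age_spline"`,
#'   `"smoking"`, `"bmi_spline"` (the intercept is always present).
#' @param markers integer vector of marker indices, or NULL for none.
#' @param n_pcs number of genotype principal components appended as fixed
#'   covariates.
#' @param pedigree logical: include an additive infinitesimal (pedigree)
#'   random effect.
#' @param name optional label used in reports.
#' @export
model_spec <- function(covariates = c("sex", "age_spline"), markers = NULL,
                       n_pcs = 0, pedigree = FALSE, name = NULL) {
  allowed <- c("sex", "age_spline", "smoking", "bmi_spline")
  bad <- setdiff(covariates, allowed)
  if (length(bad))
    stop_config("unknown covariate term(s): %s", paste(bad, collapse = ", "))
  structure(list(covariates = covariates, markers = markers,
                 n_pcs = n_pcs, pedigree = isTRUE(pedigree),
                 name = name %||% "model"),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a ladder-style model name into a spec
#'
#' Names follow the `<A|B>-<suffix>` convention: `A` = intercept + sex +
#' 4-df entry-age spline; `B` = `A` + smoking + 4-df BMI spline.  The
#' suffix is `0` (no markers), a marker count such as `250` or `2.5K`
#' (thinned evenly over the map), `GWPC` (no markers, first two genotype
#' principal components), or `PED` (no markers, pedigree random effect).
#'
#' @param name model name, e.g. `"B-80K"`.
#' @param p total number of markers available (needed for marker subsets).
#' @return a [model_spec].
#' @export
parse_model_name <- function(name, p = NULL) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !(parts[1] %in% c("A", "B")))
    stop_config("cannot parse model name '%s'", name)
  covs <- if (parts[1] == "A") c("sex", "age_spline")
          else c("sex", "age_spline", "smoking", "bmi_spline")
  suf <- parts[2]
  markers <- NULL; n_pcs <- 0; pedigree <- FALSE
  if (suf == "GWPC") {
    n_pcs <- 2
  } else if (suf == "PED") {
    pedigree <- TRUE
  } else {
    k <- if (grepl("K$", suf)) 1000 * as.numeric(sub("K$", "", suf))
         else as.numeric(suf)
    if (is.na(k)) stop_config("cannot parse model name '%s'", name)
    if (k > 0) {
      if (is.null(p)) stop_config("marker ladder '%s' needs the panel size p", name)
      markers <- select_evenly_spaced(p, as.integer(k))
    }
  }
  model_spec(covariates = covs, markers = markers, n_pcs = n_pcs,
             pedigree = pedigree, name = name)
}

#' A ladder of model specs from names
#' @param names character vector of ladder names (see [parse_model_name]).
#' @param p total marker count.
#' @return named list of [model_spec] objects.
#' @export
model_ladder <- function(names, p = NULL) {
  setNames(lapply(names, parse_model_name, p = p), names)
}

#' Build the fixed-effects design matrix
#'
#' Assembles the non-genetic part of the linear predictor: intercept, 0/1
#' sex dummy (female vs male), 4-df natural spline of age at entry, 0/1
#' smoking dummy (ever vs never), 4-df natural spline of BMI, and optional
#' genotype principal-component columns.  Spline knots are stored in the
#' result; pass `spline_specs` from a fitted design to evaluate the same
#' basis on new individuals.
#'
#' @param cohort a [cohort_data] object.
#' @param spec a [model_spec].
#' @param pcs matrix of principal-component scores (rows aligned to the
#'   cohort) when `spec$n_pcs > 0`.
#' @param spline_specs stored spline specs from a previous design.
#' @param spline_df spline degrees of freedom (default 4).
#' @return object of class `fixed_design`: list with `X` (n x q matrix,
#'   first column the intercept), `labels`, `spline_specs`.
#' @export
build_fixed_design <- function(cohort, spec, pcs = NULL, spline_specs = NULL,
                               spline_df = 4) {
  n <- length(cohort$ids)
  cols <- list(`(Intercept)` = rep(1, n))
  specs_out <- list()
  cv <- cohort$covariates
  terms <- spec$covariates

  if ("sex" %in% terms) {
    if (is.null(cv$sex)) stop_data("cohort lacks the sex covariate")
    cols$sexF <- as.numeric(cv$sex)
  }
  if ("age_spline" %in% terms) {
    ns_age <- natural_spline_basis(cohort$outcomes$age_entry, df = spline_df,
                                   spec = spline_specs$age_entry)
    b <- ns_age$basis
    colnames(b) <- paste0("ns(age_entry)", seq_len(ncol(b)))
    cols$age <- b
    specs_out$age_entry <- ns_age$spec
  }
  if ("smoking" %in% terms) {
    if (is.null(cv$smoking)) stop_data("cohort lacks the smoking covariate")
    cols$smokingEver <- as.numeric(cv$smoking)
  }
  if ("bmi_spline" %in% terms) {
    if (is.null(cv$bmi)) stop_data("cohort lacks the bmi covariate")
    ns_bmi <- natural_spline_basis(cv$bmi, df = spline_df,
                                   spec = spline_specs$bmi)
    b <- ns_bmi$basis
    colnames(b) <- paste0("ns(bmi)", seq_len(ncol(b)))
    cols$bmi <- b
    specs_out$bmi <- ns_bmi$spec
  }
  if (spec$n_pcs > 0) {
    if (is.null(pcs)) stop_data("model requests %d PCs but none supplied", spec$n_pcs)
    pcs <- as.matrix(pcs)[, seq_len(spec$n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    cols$pcs <- pcs
  }

  X <- do.call(cbind, lapply(names(cols), function(nm) {
    m <- cols[[nm]]
    if (is.null(dim(m))) { m <- matrix(m, ncol = 1); colnames(m) <- nm }
    m
  }))
  structure(list(X = X, labels = colnames(X), spline_specs = specs_out),
            class = "fixed_design")
}
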