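#' Assemble a cohort object
#'
#' Aligns phenotype (censoring-typed outcome), covariate, genotype and
#' optional pedigree information into a single validated container.  The
#' phenotype ids are the master list; individuals missing genotypes, any
#' covariate, or outcome fields are dropped with a logged count.  Missing
#' dosages are mean-imputed per marker; markers left with zero variance are
#' flagged as monomorphic (the sampler pins their effects at zero).
#'
#' @param outcomes data.frame with columns `id`, `age_entry`, `status`
#'   (one of `"observed"`, `"right"`, `"left"`, `"interval"`), `yl_lower`,
#'   `yl_upper`.  For observed records the two bounds are equal to the
#'   known years of life; right censoring has `yl_upper = Inf`, left
#'   censoring `yl_lower = -Inf`.
#' @param covariates data.frame with columns `id`, `sex` (0 = male,
#'   1 = female), `smoking` (0 = never, 1 = ever), `bmi` (kg/m^2, > 0).
#' @param genotypes numeric matrix of minor-allele dosages in {0, 1, 2} or
#'   NA, with rownames = ids and colnames = marker ids in genomic map
#'   order, or NULL.
#' @param pedigree optional data.frame `id`, `father`, `mother` (NA, `""`
#'   or `"0"` for unknown parents).
#' @param verbose print a message with the exclusion count.
#' @return an object of class `cohort_data`: a list with elements `ids`,
#'   `outcomes`, `covariates`, `genotypes`, `marker_ids`, `pedigree`,
#'   `monomorphic` (logical per marker) and `n_dropped`.
#' @export
cohort_data <- function(outcomes, covariates, genotypes = NULL,
                        pedigree = NULL, verbose = FALSE) {
  req <- c("id", "age_entry", "status", "yl_lower", "yl_upper")
  if (!all(req %in% names(outcomes)))
    stop_data("outcomes must have columns %s", paste(req, collapse = ", "))
  outcomes$id <- as.character(outcomes$id)
  if (anyDuplicated(outcomes$id))
    stop_data("duplicate ids in phenotype table: %s",
              paste(unique(outcomes$id[duplicated(outcomes$id)]), collapse = ", "))
  covariates$id <- as.character(covariates$id)
  if (anyDuplicated(covariates$id))
    stop_data("duplicate ids in covariate table")

  n_in <- nrow(outcomes)
  keep <- rep(TRUE, n_in)

  # outcome completeness / validity
  ok_status <- outcomes$status %in% c("observed", "right", "left", "interval")
  keep <- keep & ok_status & is.finite(outcomes$age_entry)

  # covariate completeness
  ci <- match(outcomes$id, covariates$id)
  cov_ok <- !is.na(ci)
  cc <- covariates[ifelse(is.na(ci), 1L, ci), c("sex", "smoking", "bmi")]
  cov_ok <- cov_ok & is.finite(cc$sex) & is.finite(cc$smoking) & is.finite(cc$bmi)
  keep <- keep & cov_ok

  if (!is.null(genotypes)) {
    if (is.null(rownames(genotypes)))
      stop_data("genotype matrix must carry ids as rownames")
    gi <- match(outcomes$id, rownames(genotypes))
    keep <- keep & !is.na(gi)
  }

  if (!any(keep)) stop_data("no individuals shared across input tables")
  n_dropped <- sum(!keep)
  if (verbose && n_dropped > 0)
    message(sprintf("cohort_data: dropped %d of %d individuals with incomplete records",
                    n_dropped, n_in))

  ids <- outcomes$id[keep]
  out <- outcomes[keep, req]
  rownames(out) <- NULL
  validate_outcomes(out)

  cov <- covariates[match(ids, covariates$id), c("id", "sex", "smoking", "bmi")]
  rownames(cov) <- NULL
  if (any(cov$bmi <= 0)) stop_data("bmi must be positive")

  mono <- NULL
  marker_ids <- NULL
  if (!is.null(genotypes)) {
    g <- genotypes[match(ids, rownames(genotypes)), , drop = FALSE]
    bad <- !(g %in% c(0, 1, 2) | is.na(g))
    if (any(bad)) {
      j <- which(bad, arr.ind = TRUE)[1, 2]
      stop_data("dosage outside {0,1,2} at marker %s", colnames(g)[j])
    }
    storage.mode(g) <- "double"
    if (anyNA(g)) {
      cm <- colMeans(g, na.rm = TRUE)
      nai <- which(is.na(g), arr.ind = TRUE)
      g[nai] <- cm[nai[, 2]]
    }
    mono <- apply(g, 2, function(x) max(x) == min(x))
    marker_ids <- colnames(g)
    genotypes <- g
  }

  if (!is.null(pedigree)) {
    pedigree$id <- as.character(pedigree$id)
    pedigree$father <- normalize_parent(pedigree$father)
    pedigree$mother <- normalize_parent(pedigree$mother)
  }

  structure(list(ids = ids, outcomes = out, covariates = cov,
                 genotypes = genotypes, marker_ids = marker_ids,
                 pedigree = pedigree, monomorphic = mono,
                 n_dropped = n_dropped),
            class = "cohort_data")
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

validate_outcomes <- function(out) {
  obs <- out$status == "observed"
  if (any(obs & (out$yl_lower != out$yl_upper)))
    stop_data("observed records must have yl_lower == yl_upper")
  if (any(out$status == "right" & !is.infinite(out$yl_upper)))
    stop_data("right-censored records must have yl_upper = Inf")
  if (any(out$status == "left" & !is.infinite(out$yl_lower)))
    stop_data("left-censored records must have yl_lower = -Inf")
  iv <- out$status == "interval"
  if (any(iv & !(is.finite(out$yl_lower) & is.finite(out$yl_upper) &
                 out$yl_lower < out$yl_upper)))
    stop_data("interval records need finite yl_lower < yl_upper")
  fin_lo <- is.finite(out$yl_lower)
  if (any(fin_lo & out$yl_lower < out$age_entry - 1e-8))
    stop_data("finite outcome bounds must be >= age at entry")
  invisible(out)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data: %d individuals", length(x$ids)))
  if (!is.null(x$genotypes))
    cat(sprintf(", %d markers (%d monomorphic)",
                ncol(x$genotypes), sum(x$monomorphic)))
  cat("\n")
  tab <- table(x$outcomes$status)
  cat("  outcomes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$pedigree))
    cat(sprintf("  pedigree: %d rows\n", nrow(x$pedigree)))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d individuals dropped on input)\n", x$n_dropped))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param x a `cohort_data` object.
#' @export
n_individuals <- function(x) length(x$ids)

#' Read cohort inputs from files
#'
#' Reads a genotype file (PLINK `.raw` layout auto-detected by its
#' `FID IID PAT MAT SEX PHENOTYPE` header, otherwise a headerless
#' delimited dosage matrix with sidecar `<path>.ids` and `<path>.markers`
#' files), a phenotype table, a covariate table, and an optional pedigree,
#' and aligns them into a [cohort_data] object.
#'
#' The phenotype table (CSV/TSV) has columns `id`, `age_entry`, `event`
#' (1 = died, 0 = censored) and `age_last` (age at death or censoring);
#' optional `yl_lower`/`yl_upper` columns encode left- or
#' interval-censored records and take precedence where non-missing.
#'
#' @param genotype_path,phenotype_path,covariate_path,pedigree_path file
#'   paths; `genotype_path` and `pedigree_path` may be NULL.
#' @param verbose log exclusion counts.
#' @return a [cohort_data] object.
#' @export
read_cohort <- function(genotype_path, phenotype_path, covariate_path,
                        pedigree_path = NULL, verbose = TRUE) {
  for (p in c(genotype_path, phenotype_path, covariate_path, pedigree_path))
    if (!is.null(p) && !file.exists(p)) stop_data("file not found: %s", p)

  phen <- as.data.frame(data.table::fread(phenotype_path))
  need <- c("id", "age_entry", "event", "age_last")
  if (!all(need %in% names(phen)))
    stop_data("phenotype table must have columns %s", paste(need, collapse = ", "))
  outcomes <- outcomes_from_event_table(phen)

  covs <- as.data.frame(data.table::fread(covariate_path))

  genotypes <- if (!is.null(genotype_path)) read_genotypes(genotype_path) else NULL

  pedigree <- NULL
  if (!is.null(pedigree_path)) {
    pedigree <- as.data.frame(data.table::fread(pedigree_path,
                                                colClasses = "character"))
    names(pedigree)[1:3] <- c("id", "father", "mother")
  }

  cohort_data(outcomes, covs, genotypes, pedigree, verbose = verbose)
}

# Translate (age_entry, event, age_last [, yl_lower, yl_upper]) rows into
# the censoring-typed outcome encoding.
outcomes_from_event_table <- function(phen) {
  n <- nrow(phen)
  status <- ifelse(phen$event == 1, "observed", "right")
  lo <- phen$age_last
  hi <- ifelse(phen$event == 1, phen$age_last, Inf)
  if (all(c("yl_lower", "yl_upper") %in% names(phen))) {
    rich <- is.finite(phen$yl_lower) | is.finite(phen$yl_upper)
    rich[is.na(rich)] <- FALSE
    if (any(rich)) {
      l <- phen$yl_lower[rich]; u <- phen$yl_upper[rich]
      l[is.na(l)] <- -Inf; u[is.na(u)] <- Inf
      status[rich] <- ifelse(l == u, "observed",
                      ifelse(!is.finite(u), "right",
                      ifelse(!is.finite(l), "left", "interval")))
      lo[rich] <- l; hi[rich] <- u
    }
  }
  data.frame(id = as.character(phen$id), age_entry = phen$age_entry,
             status = status, yl_lower = lo, yl_upper = hi,
             stringsAsFactors = FALSE)
}

read_genotypes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^FID\\s+IID\\s", first) || grepl("^FID[,\t]IID", first)) {
    raw <- as.data.frame(data.table::fread(path))
    ids <- as.character(raw$IID)
    g <- as.matrix(raw[, -(1:6), drop = FALSE])
    storage.mode(g) <- "double"
    rownames(g) <- ids
    # strip PLINK's _<counted allele> suffix from marker names if present
    colnames(g) <- sub("_[ACGT0-9]+$", "", colnames(g))
    g
  } else {
    ids_f <- paste0(path, ".ids")
    mk_f <- paste0(path, ".markers")
    if (!file.exists(ids_f) || !file.exists(mk_f))
      stop_data("headerless genotype matrix needs sidecar files %s and %s",
                ids_f, mk_f)
    g <- as.matrix(data.table::fread(path, header = FALSE))
    storage.mode(g) <- "double"
    rownames(g) <- readLines(ids_f)
    colnames(g) <- readLines(mk_f)
    g
  }
}

#' Write a cohort to files
#'
#' Emits the four input files in the formats [read_cohort] accepts:
#' `genotypes.raw` (PLINK `.raw` layout), `phenotypes.csv`,
#' `covariates.csv` and (when present) `pedigree.csv`.
#'
#' @param cohort a [cohort_data] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  out <- cohort$outcomes
  phen <- data.frame(id = out$id, age_entry = out$age_entry,
                     event = as.integer(out$status == "observed"),
                     age_last = ifelse(out$status == "observed",
                                       out$yl_upper, out$yl_lower),
                     yl_lower = ifelse(out$status %in% c("left", "interval"),
                                       out$yl_lower, NA_real_),
                     yl_upper = ifelse(out$status %in% c("left", "interval"),
                                       out$yl_upper, NA_real_))
  # left-censored: age_last column is not meaningful, store the upper bound
  lc <- out$status == "left"
  phen$age_last[lc] <- out$yl_upper[lc]
  paths["phenotypes"] <- file.path(dir, "phenotypes.csv")
  data.table::fwrite(phen, paths["phenotypes"])

  paths["covariates"] <- file.path(dir, "covariates.csv")
  data.table::fwrite(cohort$covariates, paths["covariates"])

  if (!is.null(cohort$genotypes)) {
    fid <- cohort$ids
    sex_code <- ifelse(cohort$covariates$sex == 1, 2L, 1L)
    raw <- data.frame(FID = fid, IID = cohort$ids, PAT = 0L, MAT = 0L,
                      SEX = sex_code, PHENOTYPE = -9L,
                      cohort$genotypes, check.names = FALSE)
    paths["genotypes"] <- file.path(dir, "genotypes.raw")
    data.table::fwrite(raw, paths["genotypes"], sep = " ")
  }

  if (!is.null(cohort$pedigree)) {
    ped <- cohort$pedigree
    ped$father[is.na(ped$father)] <- "0"
    ped$mother[is.na(ped$mother)] <- "0"
    paths["pedigree"] <- file.path(dir, "pedigree.csv")
    data.table::fwrite(ped, paths["pedigree"])
  }
  invisible(paths)
}

#' Evenly spaced marker subset
#'
#' Selects `k` marker indices approximately uniform over genomic map
#' order: index_j = floor(j * p / k) for j = 0, ..., k-1 (returned
#' 1-based).  This is how nested marker ladders (2.5K, 5K, ... markers)
#' are thinned from the full panel.
#'
#' @param marker_ids character vector of marker ids in map order (or a
#'   single integer, the panel size).
#' @param k number of markers to select, 1 <= k <= p.
#' @return strictly increasing integer vector of length `k`.
#' @examples
#' select_evenly_spaced(letters[1:10], 5)  # 1 3 5 7 9
#' @export
select_evenly_spaced <- function(marker_ids, k) {
  p <- if (is.numeric(marker_ids) && length(marker_ids) == 1) marker_ids
       else length(marker_ids)
  if (k <= 0) stop_config("k must be positive")
  if (k > p) stop_config("k = %d exceeds the number of markers (%d)", k, p)
  floor((0:(k - 1)) * p / k) + 1L
}

#' Restrict a cohort to a subset of individuals
#'
#' @param cohort a [cohort_data] object.
#' @param idx integer or logical index, or character ids.
#' @return a [cohort_data] with the selected individuals (pedigree rows are
#'   kept in full so relationships to ancestors survive subsetting).
#' @export
subset_cohort <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort$ids)
  ids <- cohort$ids[idx]
  structure(list(ids = ids,
                 outcomes = cohort$outcomes[idx, , drop = FALSE],
                 covariates = cohort$covariates[idx, , drop = FALSE],
                 genotypes = if (!is.null(cohort$genotypes))
                   cohort$genotypes[idx, , drop = FALSE] else NULL,
                 marker_ids = cohort$marker_ids,
                 pedigree = cohort$pedigree,
                 monomorphic = cohort$monomorphic,
                 n_dropped = 0L),
            class = "cohort_data")
}

#' Restrict a cohort to a subset of markers
#' @param cohort a [cohort_data] object with genotypes.
#' @param j integer indices into the marker map.
#' @export
subset_markers <- function(cohort, j) {
  if (is.null(cohort$genotypes)) stop_data("cohort has no genotypes")
  cohort$genotypes <- cohort$genotypes[, j, drop = FALSE]
  cohort$marker_ids <- cohort$marker_ids[j]
  cohort$monomorphic <- cohort$monomorphic[j]
  cohort
}
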