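#' Additive relationship matrix from a pedigree
#'
#' Computes the expected additive (numerator) relationship matrix A by the
#' tabular method: individuals are sorted parents-first, the diagonal is
#' 1 + half the relationship between the parents (inbreeding), and each
#' off-diagonal entry is the mean of the relationships of the earlier
#' individual to the two parents; unknown parents contribute zero.
#'
#' @param pedigree data.frame with columns `id`, `father`, `mother`
#'   (`NA`, `""` or `"0"` for unknown parents; parents not listed as ids
#'   are added as founders).
#' @return list with `ids` (in the internal parents-first order) and `A`
#'   (symmetric positive-semidefinite matrix with dimnames).
#' @export
pedigree_A <- function(pedigree) {
  id <- as.character(pedigree$id)
  fa <- normalize_parent(pedigree$father)
  mo <- normalize_parent(pedigree$mother)
  if (anyDuplicated(id)) stop_data("duplicate ids in pedigree")
  # parents that never appear as ids become founders
  extra <- setdiff(c(fa, mo), c(id, NA))
  if (length(extra)) {
    id <- c(extra, id)
    fa <- c(rep(NA_character_, length(extra)), fa)
    mo <- c(rep(NA_character_, length(extra)), mo)
  }
  n <- length(id)
  fi <- match(fa, id); mi <- match(mo, id)

  # topological sort: repeatedly place individuals whose parents are placed
  order_out <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- !placed & (is.na(fi) | placed[ifelse(is.na(fi), 1L, fi)]) &
                       (is.na(mi) | placed[ifelse(is.na(mi), 1L, mi)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop_data("pedigree cycle detected involving individual %s",
              id[which(!placed)[1]])

  A <- matrix(0, n, n)
  pos <- integer(n)  # position of individual i in the tabular order
  for (k in seq_len(n)) {
    i <- order_out[k]
    pos[i] <- k
    f <- fi[i]; m <- mi[i]
    fk <- if (is.na(f)) 0L else pos[f]
    mk <- if (is.na(m)) 0L else pos[m]
    if (k > 1) {
      prev <- seq_len(k - 1)
      af <- if (fk > 0) A[prev, fk] else numeric(k - 1)
      am <- if (mk > 0) A[prev, mk] else numeric(k - 1)
      A[prev, k] <- A[k, prev] <- 0.5 * (af + am)
    }
    A[k, k] <- 1 + if (fk > 0 && mk > 0) 0.5 * A[fk, mk] else 0
  }
  ids_sorted <- id[order_out]
  dimnames(A) <- list(ids_sorted, ids_sorted)
  list(ids = ids_sorted, A = A)
}

#' Principal components of a genotype matrix
#'
#' Standard ancestry PCA: marker columns are centered and scaled to unit
#' variance (monomorphic columns dropped), and the top-k left singular
#' vectors scaled by their singular values give the PC scores.  Signs are
#' fixed so the largest-magnitude marker loading of each component is
#' positive, making scores reproducible across column permutations.
#'
#' @param genotypes n x p dosage matrix.
#' @param k number of components.
#' @return list with `scores` (n x k), `loadings` (p_used x k),
#'   `explained` (fractions of variance, non-increasing).
#' @export
genotype_pca <- function(genotypes, k) {
  if (k < 1) stop_config("k must be >= 1")
  G <- genotypes
  storage.mode(G) <- "double"
  svals <- apply(G, 2, sd)
  use <- svals > 0
  G <- G[, use, drop = FALSE]
  G <- scale(G, center = TRUE, scale = TRUE)
  if (k > min(dim(G))) stop_config("k = %d exceeds the matrix rank bound", k)
  sv <- svd(G, nu = k, nv = k)
  if (k > sum(sv$d > 1e-10)) stop_config("k = %d exceeds the rank of the genotype matrix", k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loads <- sv$v
  for (j in seq_len(k)) {
    s <- sign(loads[which.max(abs(loads[, j])), j])
    if (s < 0) { loads[, j] <- -loads[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(scores) <- colnames(loads) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(genotypes)
  list(scores = scores, loadings = loads,
       explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

# direct relatives (father, mother, offspring, full sib) of every id
direct_relatives <- function(pedigree) {
  id <- as.character(pedigree$id)
  fa <- normalize_parent(pedigree$father)
  mo <- normalize_parent(pedigree$mother)
  rel <- setNames(vector("list", length(id)), id)
  for (i in seq_along(id)) {
    r <- c(fa[i], mo[i])
    r <- c(r, id[which((!is.na(fa) & fa == id[i]) | (!is.na(mo) & mo == id[i]))])
    sib <- if (!is.na(fa[i]) && !is.na(mo[i]))
      id[which(!is.na(fa) & !is.na(mo) & fa == fa[i] & mo == mo[i] & id != id[i])]
      else character(0)
    rel[[i]] <- setdiff(unique(c(r, sib)), NA)
  }
  rel
}

#' Count close relatives available for prediction across CV folds
#'
#' For every individual, counts the direct relatives (father, mother,
#' offspring, full sib — full sibs share both known parents) assigned to a
#' different cross-validation fold, i.e. available in the training set
#' when the individual is predicted; optionally also the count restricted
#' to uncensored relatives.  Summary fractions report the share of
#' individuals predicted with no direct relative (and no uncensored
#' direct relative) in training.
#'
#' @param pedigree pedigree data.frame (`id`, `father`, `mother`).
#' @param fold_assignment named integer vector: id -> fold.
#' @param uncensored optional named logical vector: id -> observed death.
#' @return data.frame (`id`, `fold`, `n_relatives`,
#'   `n_uncensored_relatives`) with attribute `summary` (the fractions,
#'   in percent).
#' @export
count_training_relatives <- function(pedigree, fold_assignment,
                                     uncensored = NULL) {
  ids <- names(fold_assignment)
  if (is.null(ids)) stop_config("fold_assignment must be a named vector")
  ped_ids <- as.character(pedigree$id)
  missing_ids <- setdiff(ids, ped_ids)
  if (length(missing_ids))
    message(sprintf("count_training_relatives: %d ids absent from pedigree treated as founders",
                    length(missing_ids)))
  rel <- direct_relatives(pedigree)
  n_rel <- integer(length(ids)); n_unc <- integer(length(ids))
  for (i in seq_along(ids)) {
    r <- rel[[ids[i]]]
    r <- r[r %in% ids]                       # only cohort members can train
    other <- r[fold_assignment[r] != fold_assignment[ids[i]]]
    n_rel[i] <- length(other)
    n_unc[i] <- if (is.null(uncensored)) NA_integer_
                else sum(uncensored[other], na.rm = TRUE)
  }
  res <- data.frame(id = ids, fold = unname(fold_assignment[ids]),
                    n_relatives = n_rel, n_uncensored_relatives = n_unc)
  attr(res, "summary") <- c(
    pct_without_relative = 100 * mean(n_rel == 0),
    pct_without_uncensored_relative =
      if (is.null(uncensored)) NA_real_ else 100 * mean(n_unc == 0))
  res
}
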