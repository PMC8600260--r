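## TMM normalization and logCPM, written from the definition: per-sample
## trimmed, precision-weighted mean of gene-wise log2 ratios against a
## reference sample, rescaled to geometric mean 1.

# Upper-quartile count fraction of each sample (used to pick the reference).
.uq_fraction <- function(counts) {
  lib <- colSums(counts)
  apply(counts, 2, function(y) quantile(y, 0.75)) / lib
}

# TMM factor of one sample against the reference, from the definition:
# M = log2 relative expression ratio, A = average log2 abundance; drop genes
# with a zero in either sample; doubly trim (30% of M, 5% of A, two-sided);
# inverse-variance weights from the delta-method binomial variance of M.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.3, abs_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  p_obs <- obs / lib_obs
  p_ref <- ref / lib_ref
  M <- log2(p_obs / p_ref)
  A <- 0.5 * log2(p_obs * p_ref)
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1;      hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  f <- 2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors. The reference sample is the one
#' whose upper-quartile count fraction is closest to the mean upper-quartile
#' fraction; each sample's factor is the precision-weighted mean of gene-wise
#' log2 expression ratios against the reference after trimming the 30% most
#' extreme M-values and the 5% most extreme A-values (two-sided), excluding
#' genes with a zero count in either sample. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts count matrix (genes x samples), >= 2 samples, every sample
#'   with a positive total.
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- validate_counts(counts)
  if (ncol(counts) < 2) stop("TMM needs >=2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          colnames(counts)[which(lib == 0)[1]])
  uq <- .uq_fraction(counts)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    .tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref],
              logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' log2 counts-per-million with a library-size-scaled prior count
#'
#' `logcpm[g,s] = log2((y[g,s] + prior_s) / (lib_s + 2 * prior_s) * 1e6)`
#' where `lib_s` is the effective library size (raw total x TMM factor) and
#' `prior_s = prior * lib_s / mean(lib)` scales the prior count by relative
#' library size so that the offset is comparable across samples.
#'
#' @param counts count matrix.
#' @param factors per-sample normalization factors; computed by
#'   [tmm_factors()] when `NULL`.
#' @param prior positive prior count (default 0.5).
#' @return a `normalized_table`: list with `logcpm` matrix, `norm_factors`,
#'   `lib_sizes`, `effective_lib_sizes`, `gene_ids`, `sample_ids`, and an
#'   `all_zero` flag vector marking genes with zero counts in every sample
#'   (kept in the table, excluded later from DE testing).
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  counts <- validate_counts(counts)
  if (prior <= 0) stop("prior count must be positive")
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (any(factors <= 0)) stop("normalization factors must be positive")
  lib <- colSums(counts)
  eff <- lib * factors
  prior_s <- prior * eff / mean(eff)
  logcpm <- log2(sweep(sweep(counts, 2, prior_s, "+"), 2, eff + 2 * prior_s, "/") * 1e6)
  structure(list(gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 logcpm = logcpm,
                 norm_factors = factors,
                 lib_sizes = lib,
                 effective_lib_sizes = eff,
                 all_zero = rowSums(counts) == 0),
            class = "normalized_table")
}

#' Per-gene group-mean logCPM for the three strain roles
#'
#' @param norm a `normalized_table` from [log_cpm()].
#' @param sheet sample sheet covering all samples; all three roles must be
#'   present.
#' @return matrix genes x 3 with columns `mean_W`, `mean_KM`, `mean_ZERO`.
#' @export
group_mean_logcpm <- function(norm, sheet) {
  stopifnot(inherits(norm, "normalized_table"))
  sheet <- validate_samples(sheet, require_pairs = FALSE)
  idx <- match(norm$sample_ids, sheet$sample_id)
  if (anyNA(idx)) stop("samples without group assignment: ",
                       paste(norm$sample_ids[is.na(idx)], collapse = ", "))
  grp <- sheet$group[idx]
  out <- do.call(cbind, lapply(GROUP_ROLES, function(r) {
    cols <- which(grp == r)
    if (length(cols) == 0) stop("role with zero samples: ", r)
    rowMeans(norm$logcpm[, cols, drop = FALSE])
  }))
  colnames(out) <- paste0("mean_", GROUP_ROLES)
  rownames(out) <- norm$gene_ids
  out
}
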