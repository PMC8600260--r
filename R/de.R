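## Negative-binomial quasi-likelihood differential expression, self-contained:
## per-gene dispersion by Cox-Reid adjusted profile likelihood on a log-spaced
## grid, abundance trend by loess, empirical-Bayes squeezing, and a deviance-
## based quasi-likelihood F-test with moderated QL dispersions.
##
## NB parameterization: var = mu + phi * mu^2 (phi = 1/size).

#' Negative-binomial deviance
#'
#' `2 * sum(y log(y/mu) - (y + 1/phi) log((1 + phi y)/(1 + phi mu)))`,
#' reducing to the Poisson deviance at `phi = 0`.
#'
#' @param y observed counts (vector).
#' @param mu fitted means (vector, positive).
#' @param phi dispersion (scalar >= 0).
#' @return scalar deviance.
#' @export
nb_deviance <- function(y, mu, phi = 0) {
  t1 <- y * (log(pmax(y, 1e-300)) - log(mu))
  if (phi < 1e-10) {
    2 * sum(t1 - (y - mu))
  } else {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

# Row-wise deviance for a genes x samples block; phi scalar or per-gene
# vector (recycled down columns, matching rows).
.nb_dev_rows <- function(Y, MU, phi) {
  t1 <- Y * (log(pmax(Y, 1e-300)) - log(MU))
  phi <- rep_len(phi, nrow(Y))
  pois <- phi < 1e-10
  out <- numeric(nrow(Y))
  if (any(pois)) {
    out[pois] <- 2 * rowSums(t1[pois, , drop = FALSE] -
                               (Y[pois, , drop = FALSE] - MU[pois, , drop = FALSE]))
  }
  if (any(!pois)) {
    Yn <- Y[!pois, , drop = FALSE]; MUn <- MU[!pois, , drop = FALSE]
    ph <- phi[!pois]
    t2 <- (Yn + 1 / ph) * log((1 + ph * Yn) / (1 + ph * MUn))
    out[!pois] <- 2 * rowSums(t1[!pois, , drop = FALSE] - t2)
  }
  out
}

# Fisher-scoring fit of a per-gene intercept: mu = exp(beta_g + off_s).
# Y genes x samples, off per-sample, phi scalar or per-gene vector.
# Solves the NB score equation sum_s (y - mu)/(1 + phi mu) = 0, which is the
# deviance minimizer for fixed phi. Returns per-gene beta.
.fit_intercept_rows <- function(Y, off, phi, tol = 1e-10, max_iter = 100L) {
  G <- nrow(Y)
  phi <- rep_len(phi, G)
  tot <- rowSums(Y)
  beta <- log(pmax(rowMeans(sweep(Y, 2, exp(off), "/")), 1e-13))
  zero <- tot == 0
  beta[zero] <- -30
  active <- !zero
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    mu <- exp(outer(beta[active], off, "+"))
    denom <- 1 + mu * phi[active]
    score <- rowSums((Y[active, , drop = FALSE] - mu) / denom)
    info <- pmax(rowSums(mu / denom), 1e-12)
    step <- pmin(pmax(score / info, -5), 5)
    beta[active] <- beta[active] + step
    conv <- abs(step) < tol
    idx <- which(active)
    active[idx[conv]] <- FALSE
  }
  beta
}

#' Fit a negative-binomial log-linear GLM for one gene
#'
#' Iteratively reweighted least squares with a log link, known dispersion
#' and per-observation offsets (log effective library sizes). Convergence
#' is declared when the relative deviance change falls below `1e-8`.
#'
#' @param y counts for one gene.
#' @param design model matrix (rows = samples).
#' @param offsets per-sample offsets on the log scale.
#' @param phi NB dispersion (>= 0; 0 gives the Poisson fit).
#' @return list with `coefficients`, `fitted` (means), `deviance`,
#'   `converged`, `iterations`.
#' @export
fit_nb_glm <- function(y, design, offsets = rep(0, length(y)), phi = 0) {
  stopifnot(phi >= 0, nrow(design) == length(y), length(offsets) == length(y))
  X <- as.matrix(design)
  beta <- tryCatch(qr.coef(qr(X), log(pmax(y, 0.5)) - offsets),
                   error = function(e) rep(0, ncol(X)))
  beta[!is.finite(beta)] <- 0
  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta) + offsets
    eta <- pmin(pmax(eta, -45), 45)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offsets) + (y - mu) / mu
    fit <- tryCatch(qr.coef(qr(X * sqrt(w)), sqrt(w) * z),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) break
    beta <- fit
    dev <- nb_deviance(y, exp(pmin(pmax(drop(X %*% beta) + offsets, -45), 45)), phi)
    if (is.finite(dev) && abs(dev_old - dev) / (abs(dev) + 0.1) < 1e-8) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(X %*% beta) + offsets, -45), 45)
  mu <- exp(eta)
  list(coefficients = beta, fitted = mu,
       deviance = nb_deviance(y, mu, phi),
       converged = converged, iterations = it)
}

#' Expression filter: keep genes with CPM above a floor in enough samples
#'
#' @param counts count matrix.
#' @param sheet sample sheet for the samples in `counts` (used for the
#'   default `min_samples` = smallest group size).
#' @param min_cpm CPM floor (raw library sizes, no prior).
#' @param min_samples minimum number of samples at or above the floor;
#'   default is the smallest group size.
#' @return logical vector over genes (TRUE = keep).
#' @export
filter_expressed <- function(counts, sheet, min_cpm = 1, min_samples = NULL) {
  counts <- validate_counts(counts)
  sheet <- validate_samples(sheet, counts, require_pairs = FALSE)
  if (is.null(min_samples)) {
    grp <- sheet$group[match(colnames(counts), sheet$sample_id)]
    min_samples <- min(table(grp))
  }
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  rowSums(cpm >= min_cpm) >= min_samples
}

# Quadratic interpolation of the maximizer on an equally spaced grid.
.interp_peak <- function(x, y) {
  k <- which.max(y)
  n <- length(y)
  if (k == 1L || k == n) return(x[k])
  d2 <- y[k - 1] - 2 * y[k] + y[k + 1]
  if (!is.finite(d2) || d2 >= 0) return(x[k])
  h <- x[k + 1] - x[k]
  xv <- x[k] + 0.5 * h * (y[k - 1] - y[k + 1]) / d2
  min(max(xv, x[k - 1]), x[k + 1])
}

#' Estimate NB dispersions for a two-group design
#'
#' Per-gene dispersion maximizes the Cox-Reid adjusted profile likelihood
#' (profile log-likelihood minus half the log determinant of the Fisher
#' information of the mean parameters) evaluated on a log-spaced grid
#' `phi in [1e-4, 10]` of 41 points with quadratic interpolation at the
#' peak. A loess trend of log dispersion on average logCPM is fitted, and
#' per-gene values are squeezed toward the trend by empirical Bayes with a
#' moment-matched prior df, giving `squeezed_phi` between `phi` and
#' `trend_phi`.
#'
#' @param counts count matrix (already filtered to tested genes).
#' @param group two-level factor/character over the samples.
#' @param offsets per-sample log effective library sizes; defaults to
#'   TMM-derived offsets computed from `counts`.
#' @param ave_logcpm per-gene average logCPM used for the trend; computed
#'   from `counts` when `NULL`.
#' @param grid_range,grid_length dispersion grid (log-spaced).
#' @return list with per-gene `phi`, `trend_phi`, `squeezed_phi`, scalar
#'   `prior_df`, and `ave_logcpm`.
#' @export
estimate_dispersions <- function(counts, group, offsets = NULL,
                                 ave_logcpm = NULL,
                                 grid_range = c(1e-4, 10), grid_length = 41L) {
  Y <- counts
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("estimate_dispersions expects exactly two groups")
  if (min(table(group)) < 2) stop("each group needs >=2 samples")
  if (is.null(offsets)) {
    norm <- log_cpm(Y)
    offsets <- log(norm$effective_lib_sizes)
    if (is.null(ave_logcpm)) ave_logcpm <- rowMeans(norm$logcpm)
  }
  if (is.null(ave_logcpm)) ave_logcpm <- rowMeans(log_cpm(Y)$logcpm)
  colsA <- which(group == lev[1]); colsB <- which(group == lev[2])
  log_grid <- seq(log10(grid_range[1]), log10(grid_range[2]),
                  length.out = grid_length)
  grid <- 10^log_grid
  G <- nrow(Y)
  apl <- matrix(-Inf, G, grid_length)
  for (k in seq_len(grid_length)) {
    phi <- grid[k]
    betaA <- .fit_intercept_rows(Y[, colsA, drop = FALSE], offsets[colsA], phi)
    betaB <- .fit_intercept_rows(Y[, colsB, drop = FALSE], offsets[colsB], phi)
    muA <- exp(outer(betaA, offsets[colsA], "+"))
    muB <- exp(outer(betaB, offsets[colsB], "+"))
    ll <- rowSums(dnbinom(Y[, colsA, drop = FALSE], size = 1 / phi, mu = muA, log = TRUE)) +
      rowSums(dnbinom(Y[, colsB, drop = FALSE], size = 1 / phi, mu = muB, log = TRUE))
    cr <- 0.5 * (log(pmax(rowSums(muA / (1 + phi * muA)), 1e-300)) +
                   log(pmax(rowSums(muB / (1 + phi * muB)), 1e-300)))
    apl[, k] <- ll - cr
  }
  phi_hat <- vapply(seq_len(G), function(g) 10^.interp_peak(log_grid, apl[g, ]),
                    numeric(1))
  # abundance trend of the dispersion
  if (G >= 50) {
    lo <- loess(log(phi_hat) ~ ave_logcpm, span = 0.5, degree = 1,
                family = "symmetric")
    trend <- exp(predict(lo, ave_logcpm))
    trend[!is.finite(trend)] <- exp(median(log(phi_hat)))
  } else {
    trend <- rep(exp(median(log(phi_hat))), G)
  }
  trend <- pmin(pmax(trend, 1e-6), grid_range[2])
  df1 <- length(group) - 2
  d0 <- fit_f_dist(phi_hat / trend, df1)$df2
  squeezed <- if (is.finite(d0)) (df1 * phi_hat + d0 * trend) / (df1 + d0) else trend
  list(phi = phi_hat, trend_phi = trend, squeezed_phi = squeezed,
       prior_df = d0, ave_logcpm = ave_logcpm)
}

#' Quasi-likelihood F-test between two strain groups
#'
#' The full pipeline for one contrast: expression filtering, TMM/logCPM
#' normalization over the contrast's samples, grid Cox-Reid dispersion
#' estimation with trend and empirical-Bayes squeezing, per-group NB fits,
#' and a deviance-based quasi-likelihood F-test. For each tested gene the
#' full-vs-reduced deviance difference `D` is referred to a moderated
#' gene-wise QL dispersion `s2` (residual deviance / residual df, squeezed
#' with an inverse-chi-square prior whose df come from moment matching):
#' `F = D / s2_post` on `df1 = 1` and `df2 = residual df + prior df`.
#' Benjamini-Hochberg FDR is computed over tested genes.
#'
#' Log fold changes are `roleB` over `roleA` (log2).
#'
#' @param counts count matrix over all samples.
#' @param sheet sample sheet.
#' @param roleA,roleB strain roles to contrast (e.g. `"W"`, `"KM"`).
#' @param min_cpm,min_samples expression-filter parameters
#'   (see [filter_expressed()]).
#' @param prior prior count for logCPM.
#' @return a `de_result` data.frame over all genes with columns `gene`,
#'   `logFC`, `ave_logcpm`, `F`, `df1`, `df2`, `p`, `fdr`, `tested`;
#'   untested genes carry NA statistics.
#' @export
qlf_test <- function(counts, sheet, roleA, roleB,
                     min_cpm = 1, min_samples = NULL, prior = 0.5) {
  counts <- validate_counts(counts)
  sheet <- validate_samples(sheet, counts, require_pairs = FALSE)
  stopifnot(roleA %in% GROUP_ROLES, roleB %in% GROUP_ROLES, roleA != roleB)
  grp_all <- sheet$group[match(colnames(counts), sheet$sample_id)]
  use <- grp_all %in% c(roleA, roleB)
  if (sum(grp_all == roleA) < 2 || sum(grp_all == roleB) < 2)
    stop("both roles need >=2 samples (", roleA, ": ", sum(grp_all == roleA),
         ", ", roleB, ": ", sum(grp_all == roleB), ")")
  Y_all <- counts[, use, drop = FALSE]
  grp <- grp_all[use]
  sub_sheet <- data.frame(sample_id = colnames(Y_all), group = grp,
                          stringsAsFactors = FALSE)
  keep <- filter_expressed(Y_all, sub_sheet, min_cpm, min_samples)
  if (!any(keep)) stop("all genes removed by the expression filter")
  Y <- Y_all[keep, , drop = FALSE]
  norm <- log_cpm(Y, prior = prior)
  offsets <- log(norm$effective_lib_sizes)
  ave <- rowMeans(norm$logcpm)
  disp <- estimate_dispersions(Y, grp, offsets, ave)
  # GLM fits use the trended dispersion; gene-specific departures from the
  # trend are absorbed by the quasi-likelihood dispersion s2 below, which
  # keeps the F-test calibrated at small replicate numbers.
  phi <- disp$trend_phi
  colsA <- which(grp == roleA); colsB <- which(grp == roleB)
  betaA <- .fit_intercept_rows(Y[, colsA, drop = FALSE], offsets[colsA], phi)
  betaB <- .fit_intercept_rows(Y[, colsB, drop = FALSE], offsets[colsB], phi)
  muA <- exp(outer(betaA, offsets[colsA], "+"))
  muB <- exp(outer(betaB, offsets[colsB], "+"))
  dev_full <- .nb_dev_rows(Y[, colsA, drop = FALSE], muA, phi) +
    .nb_dev_rows(Y[, colsB, drop = FALSE], muB, phi)
  beta0 <- .fit_intercept_rows(Y, offsets, phi)
  mu0 <- exp(outer(beta0, offsets, "+"))
  dev_red <- .nb_dev_rows(Y, mu0, phi)
  D <- pmax(dev_red - dev_full, 0)
  df_resid <- length(grp) - 2
  s2 <- pmax(dev_full / df_resid, 1e-8)
  sq <- squeeze_var(s2, df_resid)
  df_total <- min(df_resid + sq$prior_df, df_resid * nrow(Y))
  Fstat <- D / sq$value
  p <- pf(Fstat, df1 = 1, df2 = df_total, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(counts),
                    logFC = NA_real_, ave_logcpm = NA_real_,
                    F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_, fdr = NA_real_,
                    tested = keep, stringsAsFactors = FALSE)
  out$logFC[keep] <- (betaB - betaA) / log(2)
  out$ave_logcpm[keep] <- ave
  out$F[keep] <- Fstat
  out$df1[keep] <- 1
  out$df2[keep] <- df_total
  out$p[keep] <- p
  out$fdr[keep] <- fdr
  attr(out, "contrast") <- c(roleA = roleA, roleB = roleB)
  attr(out, "prior_df") <- sq$prior_df
  attr(out, "dispersion_prior_df") <- disp$prior_df
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select differentially expressed genes
#'
#' Genes with `p < p_threshold` and, when `min_fold` is given,
#' `|logFC| > log2(min_fold)`; each gene is tagged `up` or `down` by the
#' sign of its log fold change.
#'
#' @param result a `de_result` from [qlf_test()].
#' @param p_threshold raw p-value threshold (the headline DEG lists use raw
#'   p; FDR is carried alongside).
#' @param min_fold optional fold-change floor on the natural scale (e.g.
#'   1.5), applied as `|logFC| > log2(min_fold)`.
#' @return data.frame with `gene`, `logFC`, `p`, `fdr`, `direction`.
#' @export
select_degs <- function(result, p_threshold = 0.05, min_fold = NULL) {
  ok <- !is.na(result$p) & result$p < p_threshold
  if (!is.null(min_fold)) ok <- ok & abs(result$logFC) > log2(min_fold)
  sel <- result[which(ok), c("gene", "logFC", "p", "fdr"), drop = FALSE]
  sel$direction <- ifelse(sel$logFC >= 0, "up", "down")
  rownames(sel) <- NULL
  sel
}
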