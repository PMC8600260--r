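## The per-gene compensation-coefficient statistic on group-mean logCPM,
## its classification, concordance between contrasts, coefficient density
## and heat-map-ready summaries.

#' Compensation coefficient (percent)
#'
#' `100 * (mean_km - mean_zero) / (mean_km - mean_w)` on the logCPM scale.
#' 100 means the back-selected strain is fully restored to the progenitor
#' level; 0 means it remains at the derived-strain level; values above 100
#' are overcompensation and values at or below 0 no compensation. The
#' coefficient is undefined (NA) when the denominator magnitude
#' `|mean_km - mean_w|` does not exceed `eps`.
#'
#' @param mean_km,mean_zero,mean_w group-mean logCPM values (vectorized).
#' @param eps denominator guard (logCPM units).
#' @return numeric vector of percentages; NA where undefined.
#' @export
compensation_coefficient <- function(mean_km, mean_zero, mean_w, eps = 1e-6) {
  denom <- mean_km - mean_w
  out <- 100 * (mean_km - mean_zero) / denom
  out[abs(denom) <= eps] <- NA_real_
  out
}

#' Classify a compensation coefficient
#'
#' `compensated` for coefficients in (0, 100], `overcompensated` above 100,
#' `uncompensated` at or below 0; NA coefficients map to `"undefined"`.
#'
#' @param coefficient numeric vector of percentages (NA allowed).
#' @return character vector of classes.
#' @export
classify_compensation <- function(coefficient) {
  out <- rep("undefined", length(coefficient))
  ok <- !is.na(coefficient)
  out[ok & coefficient > 100] <- "overcompensated"
  out[ok & coefficient > 0 & coefficient <= 100] <- "compensated"
  out[ok & coefficient <= 0] <- "uncompensated"
  out
}

#' Per-gene compensation table
#'
#' Combines group-mean logCPMs, the compensation coefficient, its class and
#' the KM-vs-W differential-expression p-value into one record per gene.
#'
#' @param norm a `normalized_table` over all samples (see [log_cpm()]).
#' @param sheet sample sheet with all three roles.
#' @param de_km_w `de_result` for the KM-vs-W contrast.
#' @param eps denominator guard for [compensation_coefficient()].
#' @return data.frame with `gene`, `mean_w`, `mean_km`, `mean_zero`,
#'   `coefficient`, `comp_class`, `de_p_km_w`.
#' @export
compensation_table <- function(norm, sheet, de_km_w, eps = 1e-6) {
  gm <- group_mean_logcpm(norm, sheet)
  p <- de_km_w$p[match(rownames(gm), de_km_w$gene)]
  coef <- compensation_coefficient(gm[, "mean_KM"], gm[, "mean_ZERO"],
                                   gm[, "mean_W"], eps)
  data.frame(gene = rownames(gm),
             mean_w = gm[, "mean_W"],
             mean_km = gm[, "mean_KM"],
             mean_zero = gm[, "mean_ZERO"],
             coefficient = coef,
             comp_class = classify_compensation(coef),
             de_p_km_w = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of DEGs with compensated expression
#'
#' Among genes with `de_p_km_w < p_threshold` and a defined coefficient,
#' the proportion whose coefficient lies in `(lower, 100]`. The default
#' `lower = 0` treats the whole positive range up to 100 as compensated;
#' `lower = 1` reproduces a literal "between 1 and 100" reading.
#'
#' @param records compensation table (see [compensation_table()]).
#' @param p_threshold DEG threshold on the KM-vs-W p-value.
#' @param lower lower bound (exclusive) of the compensated interval.
#' @return list with `fraction`, `n` (qualifying genes) and `defined`
#'   (FALSE when no gene qualifies; `fraction` is then NA).
#' @export
fraction_compensated <- function(records, p_threshold = 0.01, lower = 0) {
  ok <- !is.na(records$de_p_km_w) & records$de_p_km_w < p_threshold &
    !is.na(records$coefficient)
  if (!any(ok)) return(list(fraction = NA_real_, n = 0L, defined = FALSE))
  coefs <- records$coefficient[ok]
  list(fraction = mean(coefs > lower & coefs <= 100),
       n = sum(ok), defined = TRUE)
}

#' Log-fold-change concordance between two contrasts
#'
#' Spearman rank correlation (average-rank method) and the fraction of
#' genes whose log fold changes have strictly opposite signs (exact zeros
#' count as non-opposite) over a gene subset.
#'
#' @param fc_a,fc_b named or aligned numeric vectors of log2 fold changes.
#' @param subset optional index/logical/character vector selecting the
#'   genes to use (applied to both vectors).
#' @param description free-text descriptor of how the subset was defined.
#' @return list with `spearman_rho`, `n_genes`, `opposite_fraction`,
#'   `description`.
#' @export
concordance <- function(fc_a, fc_b, subset = NULL, description = "") {
  if (length(fc_a) != length(fc_b) && is.null(names(fc_a)))
    stop("fc_a and fc_b must align")
  if (!is.null(names(fc_a)) && !is.null(names(fc_b)))
    fc_b <- fc_b[match(names(fc_a), names(fc_b))]
  if (!is.null(subset)) {
    fc_a <- fc_a[subset]; fc_b <- fc_b[subset]
  }
  ok <- is.finite(fc_a) & is.finite(fc_b)
  fc_a <- fc_a[ok]; fc_b <- fc_b[ok]
  if (length(fc_a) < 3) stop("concordance needs >=3 genes")
  list(spearman_rho = cor(fc_a, fc_b, method = "spearman"),
       n_genes = length(fc_a),
       opposite_fraction = mean(fc_a * fc_b < 0),
       description = description)
}

#' Gaussian kernel density of compensation coefficients
#'
#' Kernel density estimate with a Gaussian kernel on an evenly spaced grid
#' spanning `[min - 3h, max + 3h]`. The default bandwidth is Silverman's
#' rule (`stats::bw.nrd0`); degenerate inputs (all values equal, bandwidth
#' 0) fall back to `h = max(1e-6 * range, 1e-6)`.
#'
#' @param coefficients numeric vector (>= 2 defined values).
#' @param bandwidth `"silverman"` or a positive number.
#' @param n grid size.
#' @return list with `grid`, `density`, `bandwidth`.
#' @export
coefficient_density <- function(coefficients, bandwidth = "silverman", n = 512) {
  x <- coefficients[is.finite(coefficients)]
  if (length(x) < 2) stop("need >=2 defined coefficients for a density")
  h <- if (is.numeric(bandwidth)) bandwidth else tryCatch(bw.nrd0(x), error = function(e) 0)
  if (!is.finite(h) || h <= 0) h <- max(1e-6 * diff(range(x)), 1e-6)
  d <- density(x, bw = h, kernel = "gaussian", n = n, cut = 3)
  list(grid = d$x, density = d$y, bandwidth = h)
}

#' Partition DEGs by compensation coefficient and rank by significance
#'
#' Among KM-vs-W DEGs with a defined coefficient, splits genes into those
#' above and those at or below `cutoff` percent compensation, keeps the `k`
#' most significant (smallest KM-vs-W p) in each, and orders each list from
#' the highest p-value at the top to the lowest at the bottom — the layout
#' used for the paired heat maps.
#'
#' @param records compensation table (see [compensation_table()]).
#' @param k number of genes kept per partition.
#' @param cutoff coefficient cutoff in percent.
#' @param p_threshold DEG threshold on the KM-vs-W p-value.
#' @return list of two data.frames, `compensated` (`coefficient > cutoff`)
#'   and `uncompensated` (`coefficient <= cutoff`), each ordered by
#'   descending p.
#' @export
top_partition <- function(records, k = 50, cutoff = 50, p_threshold = 0.05) {
  stopifnot(k >= 1)
  ok <- !is.na(records$de_p_km_w) & records$de_p_km_w < p_threshold &
    !is.na(records$coefficient)
  degs <- records[ok, , drop = FALSE]
  take <- function(sub) {
    sub <- sub[order(sub$de_p_km_w), , drop = FALSE]
    sub <- head(sub, k)
    sub <- sub[order(sub$de_p_km_w, decreasing = TRUE), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  }
  list(compensated = take(degs[degs$coefficient > cutoff, , drop = FALSE]),
       uncompensated = take(degs[degs$coefficient <= cutoff, , drop = FALSE]))
}

#' Z-transform logCPM rows for heat-map display
#'
#' Per selected gene, `(x - row mean) / row sd` with the sample standard
#' deviation (denominator n-1). Constant rows become all-zero and are
#' flagged in the `constant` attribute.
#'
#' @param norm a `normalized_table`.
#' @param genes character vector of gene ids to include (order preserved).
#' @return matrix of Z-scores with a logical `constant` attribute.
#' @export
zscore_rows <- function(norm, genes) {
  stopifnot(inherits(norm, "normalized_table"))
  idx <- match(genes, norm$gene_ids)
  if (anyNA(idx)) stop("genes absent from the normalized table: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  m <- norm$logcpm[idx, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s < 1e-12
  s[const] <- 1
  z <- (m - mu) / s
  z[const, ] <- 0
  rownames(z) <- genes
  attr(z, "constant") <- const
  z
}
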