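## Gene-set procedures: Fisher's exact over-representation of up/down DEG
## lists, DEG-restricted set analysis, and Venn partitions of DEG sets.

#' Fisher's exact test of a gene set against a gene list
#'
#' Builds the 2x2 table (in set & in list, in set & not, in list & not,
#' neither) over `universe`, after intersecting the set with the universe,
#' and computes the exact hypergeometric p-value by direct summation.
#' Two-sided (default): sum of probabilities of all tables with point
#' probability at most that of the observed table; `"greater"` gives the
#' one-sided over-representation tail.
#'
#' @param set_genes character vector (the gene set).
#' @param list_genes character vector (e.g. upregulated DEGs); must be a
#'   subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return list with `overlap`, `table` (2x2 matrix), `p`.
#' @export
fisher_set_test <- function(set_genes, list_genes, universe,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  set_genes <- intersect(unique(set_genes), universe)
  list_genes <- unique(list_genes)
  if (!all(list_genes %in% universe))
    stop("list genes outside the universe: ",
         paste(head(setdiff(list_genes, universe), 3), collapse = ", "))
  N <- length(universe)
  m <- length(set_genes)
  k <- length(list_genes)
  q <- length(intersect(set_genes, list_genes))
  tab <- matrix(c(q, m - q, k - q, N - m - k + q), 2, 2,
                dimnames = list(c("in_set", "not_set"), c("in_list", "not_list")))
  support <- max(0, m + k - N):min(m, k)
  probs <- dhyper(support, m, N - m, k)
  p_obs <- dhyper(q, m, N - m, k)
  p <- if (alternative == "two.sided") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    sum(probs[support >= q])
  }
  list(overlap = q, table = tab, p = min(p, 1))
}

#' Up/down enrichment of every set in a collection
#'
#' Runs [fisher_set_test()] for the up- and downregulated DEG lists against
#' each set, applies Benjamini-Hochberg correction across sets within each
#' direction, and calls a dominant direction per set (the direction with
#' the smaller p-value among those below `alpha`; `"none"` otherwise).
#' When `logfc` is supplied, each set's member genes (in the universe) are
#' returned sorted by decreasing log2 fold change for display.
#'
#' @param sets named list of character vectors (see [read_gmt()]).
#' @param up,down disjoint character vectors of up/down DEGs.
#' @param universe character vector of all tested genes.
#' @param logfc optional named numeric vector of log2 fold changes.
#' @param alpha significance level for the direction call.
#' @param alternative sidedness of the Fisher tests (see
#'   [fisher_set_test()]). Note that when `up` and `down` together exhaust
#'   the universe the two direction tables are complementary and a
#'   two-sided p is identical for both; direction-specific testing then
#'   needs `"greater"`.
#' @return data.frame with one row per set: `set`, `n_set_in_universe`,
#'   `n_up_overlap`, `n_down_overlap`, `p_up`, `p_down`, `fdr_up`,
#'   `fdr_down`, `direction_call`, and `members_by_logfc` (comma-joined)
#'   when `logfc` is given.
#' @export
enrich_all <- function(sets, up, down, universe, logfc = NULL, alpha = 0.05,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(intersect(up, down)) > 0)
    stop("up and down lists overlap: ",
         paste(head(intersect(up, down), 3), collapse = ", "))
  universe <- unique(universe)
  res <- lapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    tu <- fisher_set_test(genes, up, universe, alternative)
    td <- fisher_set_test(genes, down, universe, alternative)
    data.frame(set = nm,
               n_set_in_universe = length(intersect(unique(genes), universe)),
               n_up_overlap = tu$overlap, n_down_overlap = td$overlap,
               p_up = tu$p, p_down = td$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_up <- p.adjust(out$p_up, method = "BH")
  out$fdr_down <- p.adjust(out$p_down, method = "BH")
  out$direction_call <- ifelse(
    pmin(out$p_up, out$p_down) >= alpha, "none",
    ifelse(out$p_up <= out$p_down, "up", "down"))
  if (!is.null(logfc)) {
    out$members_by_logfc <- vapply(names(sets), function(nm) {
      mem <- intersect(unique(sets[[nm]]), universe)
      mem <- mem[order(logfc[mem], decreasing = TRUE)]
      paste(mem, collapse = ",")
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' DEG-restricted gene-set analysis
#'
#' Restricts the universe to differentially expressed genes at
#' `p_threshold` (and `min_fold`, when given), partitions them by
#' direction, and applies [enrich_all()] with one-sided
#' (over-representation) Fisher tests. One-sided tails are required here:
#' the up and down DEG lists exhaust the restricted universe, so their 2x2
#' tables are complementary and a two-sided p-value could not distinguish
#' the directions.
#'
#' @param de_result a `de_result` from [qlf_test()].
#' @param sets named list of gene sets.
#' @param p_threshold,min_fold DEG thresholds (see [select_degs()]).
#' @return an enrichment data.frame as in [enrich_all()]; when no gene
#'   passes the threshold, a zero-row data.frame with attribute
#'   `empty = TRUE`.
#' @export
deg_gsea_lite <- function(de_result, sets, p_threshold = 0.05, min_fold = NULL) {
  degs <- select_degs(de_result, p_threshold, min_fold)
  if (nrow(degs) == 0) {
    out <- data.frame(set = character(0), n_set_in_universe = integer(0),
                      n_up_overlap = integer(0), n_down_overlap = integer(0),
                      p_up = numeric(0), p_down = numeric(0),
                      fdr_up = numeric(0), fdr_down = numeric(0),
                      direction_call = character(0), stringsAsFactors = FALSE)
    attr(out, "empty") <- TRUE
    return(out)
  }
  logfc <- setNames(degs$logFC, degs$gene)
  enrich_all(sets,
             up = degs$gene[degs$direction == "up"],
             down = degs$gene[degs$direction == "down"],
             universe = degs$gene, logfc = logfc,
             alternative = "greater")
}

#' Exact Venn partition of two or three gene lists
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive region counts (names built
#'   from the labels, e.g. `A_only`, `A_and_B`, `A_and_B_and_C`), with a
#'   `union_size` attribute.
#' @export
venn <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("venn needs a named list of gene vectors")
  n <- length(sets)
  if (n < 2 || n > 3) stop("venn supports 2 or 3 sets, got ", n)
  labels <- names(sets)
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes), ncol = n)
  code <- apply(member, 1, function(row) paste(which(row), collapse = "&"))
  code <- as.character(code)
  regions <- character(0)
  combos <- unlist(lapply(seq_len(n), function(k)
    combn(seq_len(n), k, function(ix) paste(ix, collapse = "&"))), use.names = FALSE)
  counts <- vapply(combos, function(cc) sum(code == cc), integer(1))
  names(counts) <- vapply(strsplit(combos, "&", fixed = TRUE), function(ix)
    paste(labels[as.integer(ix)],
          collapse = "_and_"), character(1))
  only <- !grepl("_and_", names(counts))
  names(counts)[only] <- paste0(names(counts)[only], "_only")
  attr(counts, "union_size") <- length(all_genes)
  counts
}
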