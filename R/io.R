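## Count matrices, sample sheets, GMT gene sets and result tables.
##
## Orientation convention used everywhere in this package: genes in rows,
## samples in columns. Gene and sample identifiers are opaque strings.

#' Validate a gene x sample count matrix
#'
#' Checks the invariants every count matrix in the pipeline must satisfy:
#' integer, non-negative entries, unique gene and sample identifiers, and
#' dimnames present on both margins.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return the validated matrix (storage mode integer-compatible doubles are
#'   accepted and returned unchanged), invisibly usable in place.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ", paste(unique(rownames(counts)[duplicated(rownames(counts))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ", paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count at gene '%s', sample '%s': %s (must be a non-negative integer)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, 1], bad[1, 2]])))
  }
  counts
}

#' Read a gene-level count matrix
#'
#' Two dialects are supported. `"tsv"`: a plain tab-separated table with a
#' header row of sample ids and the first column holding gene ids. `"mtx"`:
#' a MatrixMarket sparse matrix accompanied by two sidecar files of row
#' (gene) and column (sample) identifiers, one id per line.
#'
#' @param path file path; for `"mtx"` the `.mtx` file.
#' @param dialect `"tsv"` (default) or `"mtx"`.
#' @param genes_path,samples_path sidecar id files for the mtx dialect;
#'   default `<path>.genes` and `<path>.samples`.
#' @return validated integer count matrix, genes x samples.
#' @export
read_counts <- function(path, dialect = c("tsv", "mtx"),
                        genes_path = paste0(path, ".genes"),
                        samples_path = paste0(path, ".samples")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("count TSV needs a gene-id column plus >=1 sample column")
    genes <- as.character(tab[[1]])
    sample_ids <- colnames(tab)[-1]   # before data.frame subsetting mangles duplicates
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric count value in ", path)
    rownames(m) <- genes
    colnames(m) <- sample_ids
  } else {
    if (!file.exists(genes_path)) stop("missing gene id sidecar: ", genes_path)
    if (!file.exists(samples_path)) stop("missing sample id sidecar: ", samples_path)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(samples_path)
  }
  validate_counts(m)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; the TSV dialect writes a `gene` id column
#' followed by one column per sample.
#'
#' @inheritParams read_counts
#' @param counts validated count matrix.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "mtx"),
                         genes_path = paste0(path, ".genes"),
                         samples_path = paste0(path, ".samples")) {
  dialect <- match.arg(dialect)
  counts <- validate_counts(counts)
  if (dialect == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), genes_path)
    writeLines(colnames(counts), samples_path)
  }
  invisible(path)
}

#' Canonical strain-group roles
#'
#' The three roles of the design: progenitor (`"W"`), derived (`"KM"`) and
#' back-selected (`"ZERO"`, written `"0"` in some tables and accepted as an
#' alias on input).
#' @export
GROUP_ROLES <- c("W", "KM", "ZERO")

#' Validate a sample sheet against a count matrix
#'
#' @param sheet data.frame with columns `sample_id` and `group`.
#' @param counts optional count matrix; when given, every sample column must
#'   be assigned a role.
#' @param require_pairs require >=2 samples per present role (needed before
#'   any dispersion estimation or contrast).
#' @return the sheet with `group` normalised to `GROUP_ROLES`.
#' @export
validate_samples <- function(sheet, counts = NULL, require_pairs = TRUE) {
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns 'sample_id' and 'group'")
  sheet$sample_id <- as.character(sheet$sample_id)
  grp <- as.character(sheet$group)
  grp[grp == "0"] <- "ZERO"
  bad <- setdiff(unique(grp), GROUP_ROLES)
  if (length(bad) > 0)
    stop("unknown group role(s): ", paste(bad, collapse = ", "),
         " (expected W, KM, ZERO)")
  sheet$group <- grp
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet")
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), sheet$sample_id)
    if (length(missing) > 0)
      stop("samples without group assignment: ", paste(missing, collapse = ", "))
  }
  if (require_pairs) {
    n <- table(sheet$group)
    if (any(n < 2))
      stop("each present role needs >=2 samples; got ",
           paste(names(n), n, sep = "=", collapse = ", "))
  }
  sheet
}

#' Read a sample sheet (TSV: sample_id, group)
#' @inheritParams validate_samples
#' @param path TSV file with header columns `sample_id` and `group`.
#' @export
read_samples <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sheet <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character")
  validate_samples(sheet, counts)
}

#' Write a sample sheet
#' @param sheet validated sample sheet.
#' @param path output TSV path.
#' @export
write_samples <- function(sheet, path) {
  write.table(sheet[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line; tab-separated fields are the set name,
#' a free-text description, then the member gene ids. Duplicate members
#' within a set are removed, keeping first occurrence order.
#'
#' @param path GMT file path.
#' @return named list of character vectors (the sets), with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member", i, length(f)))
    name <- f[[1]]
    if (name %in% names(sets)) stop("duplicate set name '", name, "' at line ", i)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("GMT line ", i, " has no members")
    sets[[name]] <- members
    desc[name] <- f[[2]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a result table as TSV at full precision
#'
#' All pipeline result tables go through this writer: TSV with a header row
#' and numeric columns formatted to 15 significant digits so p-values and
#' coefficients round-trip essentially exactly.
#'
#' @param table non-empty data.frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) stop("write_results expects a data.frame")
  if (nrow(table) == 0) stop("refusing to write an empty result table")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path TSV path.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}
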