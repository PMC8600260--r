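## End-to-end orchestration: simulate (or load) -> normalize -> DE (both
## contrasts) -> compensation -> enrichment -> report. Every stage is a pure
## function over files/objects, so each step is individually re-runnable.

#' Build a pipeline configuration
#'
#' Exactly one of `paths` (real data: `counts`, `samples`, optional `gmt`)
#' or `simulation` (a [sim_config()]) must be supplied. Threshold defaults
#' follow the study's printed analysis choices: DEG lists at p < 0.05 with
#' a 1.5-fold floor for set-level analyses, the compensation analysis at
#' p < 0.01, and a 50% coefficient cutoff for the top-gene partition.
#'
#' @param paths named list with `counts`, `samples` and optionally `gmt`
#'   file paths.
#' @param simulation a [sim_config()].
#' @param de_p DEG p-value threshold for DEG counts/enrichment/Venn.
#' @param comp_p p-value threshold for the compensation and concordance
#'   analyses.
#' @param min_fold fold-change floor for enrichment/Venn DEG lists.
#' @param comp_cutoff compensation-coefficient cutoff (percent) for
#'   [top_partition()].
#' @param top_k genes kept per heat-map partition.
#' @param seed integer seed for the run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, simulation = NULL,
                            de_p = 0.05, comp_p = 0.01, min_fold = 1.5,
                            comp_cutoff = 50, top_k = 50, seed = 1L) {
  if (is.null(paths) == is.null(simulation))
    stop("supply exactly one of 'paths' or 'simulation'")
  if (!is.null(paths) && !all(c("counts", "samples") %in% names(paths)))
    stop("paths needs 'counts' and 'samples'")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    stop("simulation must be a sim_config")
  stopifnot(de_p > 0, de_p <= 1, comp_p > 0, comp_p <= 1,
            is.null(min_fold) || min_fold >= 1, top_k >= 1)
  structure(list(paths = paths, simulation = simulation,
                 de_p = de_p, comp_p = comp_p, min_fold = min_fold,
                 comp_cutoff = comp_cutoff, top_k = top_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default synthetic-run configuration
#'
#' The package's demonstration scale: 2,000 genes with library sizes of
#' 1.5-2.2 million reads (the study design scaled down tenfold), replicates
#' W=4 / KM=3 / ZERO=4, 10% DE genes at 4-fold effects, and a 70/20/10
#' compensated/uncompensated/overcompensated class mix.
#'
#' @param seed integer seed (also seeds the simulation).
#' @param gmt optional GMT path for the enrichment stage.
#' @return a `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, gmt = NULL) {
  cfg <- pipeline_config(
    simulation = sim_config(n_genes = 2000,
                            lib_size_range = c(1.5e6, 2.2e6),
                            seed = seed),
    seed = seed)
  cfg$paths <- if (is.null(gmt)) NULL else list(gmt = gmt)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulation`
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim_args <- raw$simulation
    for (nm in c("replicates", "class_proportions"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    for (nm in c("baseline_logmean_range", "dispersion_params", "lib_size_range"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- as.numeric(unlist(sim_args[[nm]]))
    sim <- do.call(sim_config, sim_args)
  }
  args <- raw[setdiff(names(raw), "simulation")]
  args$simulation <- sim
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full compensation analysis
#'
#' Executes every stage and writes all result tables plus a
#' machine-readable `run_summary.json`, a `report.md` and a `run_log.txt`
#' under `out_dir`. Deterministic given the configuration (including its
#' seed).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output and returns results only.
#' @return (invisibly) list with `summary`, `de_km_w`, `de_zero_km`,
#'   `compensation`, `concordance`, `density`, `top`, `enrichment`,
#'   `venn`, `norm`, `counts`, `samples`, `truth` (NULL for real data).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(tab, file) {
    if (!is.null(out_dir)) write_results(tab, file.path(out_dir, file))
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- .stage("simulate", simulate_counts(config$simulation))
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    if (!is.null(out_dir)) {
      write_counts(counts, file.path(out_dir, "counts.tsv"))
      write_samples(samples, file.path(out_dir, "samples.tsv"))
      emit(truth, "truth.tsv")
    }
  } else {
    counts <- .stage("load", read_counts(config$paths$counts))
    samples <- .stage("load", read_samples(config$paths$samples, counts))
  }

  norm <- .stage("normalize", log_cpm(counts))
  de_km_w <- .stage("de_km_w", qlf_test(counts, samples, "W", "KM"))
  de_zero_km <- .stage("de_zero_km", qlf_test(counts, samples, "KM", "ZERO"))
  emit(de_km_w, "de_km_w.tsv"); emit(de_zero_km, "de_zero_km.tsv")

  comp <- .stage("compensation", compensation_table(norm, samples, de_km_w))
  emit(comp, "compensation.tsv")
  frac <- fraction_compensated(comp, config$comp_p, lower = 0)
  frac_1 <- fraction_compensated(comp, config$comp_p, lower = 1)

  conc <- .stage("concordance", {
    fa <- setNames(de_km_w$logFC, de_km_w$gene)
    fb <- setNames(de_zero_km$logFC, de_zero_km$gene)
    sig <- (!is.na(de_km_w$p) & de_km_w$p < config$comp_p) |
      (!is.na(de_zero_km$p) & de_zero_km$p < config$comp_p)
    concordance(fa, fb, subset = which(sig),
                description = sprintf("genes with p < %g in either contrast",
                                      config$comp_p))
  })
  emit(data.frame(spearman_rho = conc$spearman_rho, n_genes = conc$n_genes,
                  opposite_fraction = conc$opposite_fraction,
                  subset = conc$description), "concordance.tsv")

  dens <- .stage("density", {
    ok <- !is.na(comp$de_p_km_w) & comp$de_p_km_w < config$comp_p &
      !is.na(comp$coefficient)
    if (sum(ok) >= 2) coefficient_density(comp$coefficient[ok]) else NULL
  })
  if (!is.null(dens))
    emit(data.frame(coefficient = dens$grid, density = dens$density), "density.tsv")

  top <- .stage("top_partition",
                top_partition(comp, k = config$top_k,
                              cutoff = config$comp_cutoff,
                              p_threshold = config$de_p))
  if (nrow(top$compensated) > 0) emit(top$compensated, "top_compensated.tsv")
  if (nrow(top$uncompensated) > 0) emit(top$uncompensated, "top_uncompensated.tsv")
  zs <- lapply(top, function(part) {
    if (nrow(part) == 0) return(NULL)
    zscore_rows(norm, part$gene)
  })
  if (!is.null(out_dir)) {
    for (nm in names(zs)) {
      if (is.null(zs[[nm]])) next
      df <- data.frame(gene = rownames(zs[[nm]]), zs[[nm]], check.names = FALSE)
      write_results(df, file.path(out_dir, paste0("zscores_", nm, ".tsv")))
    }
  }

  degs_a <- select_degs(de_km_w, config$de_p, config$min_fold)
  degs_b <- select_degs(de_zero_km, config$de_p, config$min_fold)
  vn <- .stage("venn", venn(list(KM_vs_W = degs_a$gene,
                                 ZERO_vs_KM = degs_b$gene)))
  emit(data.frame(region = names(vn), count = as.integer(vn)), "venn.tsv")

  enr <- NULL
  if (!is.null(config$paths$gmt)) {
    enr <- .stage("enrichment", {
      if (!file.exists(config$paths$gmt))
        stop("no such GMT file: ", config$paths$gmt)
      sets <- read_gmt(config$paths$gmt)
      deg_gsea_lite(de_km_w, sets, config$de_p, config$min_fold)
    })
    if (nrow(enr) > 0) emit(enr, "enrichment_km_w.tsv")
  }

  summary <- list(
    seed = config$seed,
    thresholds = list(de_p = config$de_p, comp_p = config$comp_p,
                      min_fold = config$min_fold,
                      comp_cutoff = config$comp_cutoff, top_k = config$top_k),
    n_tested_km_w = sum(de_km_w$tested),
    n_tested_zero_km = sum(de_zero_km$tested),
    n_deg_km_w = sum(!is.na(de_km_w$p) & de_km_w$p < config$de_p),
    n_deg_zero_km = sum(!is.na(de_zero_km$p) & de_zero_km$p < config$de_p),
    fraction_compensated = frac$fraction,
    n_compensation_degs = frac$n,
    fraction_compensated_1_100 = frac_1$fraction,
    spearman_rho = conc$spearman_rho,
    opposite_fraction = conc$opposite_fraction,
    concordance_n_genes = conc$n_genes)

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("comprev %s | R %s.%s", as.character(utils::packageVersion("comprev")),
              R.version$major, R.version$minor),
      sprintf("seed: %d", config$seed),
      sprintf("thresholds: de_p=%g comp_p=%g min_fold=%s comp_cutoff=%g top_k=%d",
              config$de_p, config$comp_p,
              ifelse(is.null(config$min_fold), "none", format(config$min_fold)),
              config$comp_cutoff, config$top_k),
      sprintf("input: %s", if (is.null(config$simulation)) config$paths$counts
              else sprintf("simulated (%d genes, seed %d)",
                           config$simulation$n_genes, config$simulation$seed))),
      file.path(out_dir, "run_log.txt"))
    make_report(summary, top, file.path(out_dir, "report.md"))
  }

  invisible(list(summary = summary, de_km_w = de_km_w, de_zero_km = de_zero_km,
                 compensation = comp, concordance = conc, density = dens,
                 top = top, enrichment = enr, venn = vn, norm = norm,
                 counts = counts, samples = samples, truth = truth))
}

#' Write the human-readable run report
#'
#' Markdown summary of the run's headline quantities: DEG counts per
#' contrast, compensated fraction(s), concordance, and the top compensated
#' genes. Regenerating the report from the same summary is idempotent.
#'
#' @param summary the `summary` list from [run_pipeline()] (or the parsed
#'   `run_summary.json`).
#' @param top optional [top_partition()] result for the top-gene listing.
#' @param path optional output path.
#' @return the report text (character vector of lines), invisibly when
#'   written to `path`.
#' @export
make_report <- function(summary, top = NULL, path = NULL) {
  need <- c("n_deg_km_w", "n_deg_zero_km", "fraction_compensated",
            "spearman_rho", "opposite_fraction")
  missing <- setdiff(need, names(summary))
  if (length(missing) > 0)
    stop("summary missing fields: ", paste(missing, collapse = ", "))
  fmt_frac <- function(x) if (is.na(x)) "undefined" else sprintf("%.1f%%", 100 * x)
  lines <- c(
    "# Compensation analysis report",
    "",
    sprintf("- DEGs, KM vs W (p < %g): **%d** of %d tested",
            summary$thresholds$de_p, summary$n_deg_km_w, summary$n_tested_km_w),
    sprintf("- DEGs, ZERO vs KM (p < %g): **%d** of %d tested",
            summary$thresholds$de_p, summary$n_deg_zero_km, summary$n_tested_zero_km),
    sprintf("- Compensated fraction among KM-vs-W DEGs at p < %g (coefficient in (0,100]): **%s** (n = %d)",
            summary$thresholds$comp_p, fmt_frac(summary$fraction_compensated),
            summary$n_compensation_degs),
    sprintf("- Same fraction with the coefficient restricted to (1,100]: %s",
            fmt_frac(summary$fraction_compensated_1_100)),
    sprintf("- logFC concordance (KM-vs-W against ZERO-vs-KM): Spearman rho = **%.3f**, opposite-direction fraction = %s over %d genes",
            summary$spearman_rho, fmt_frac(summary$opposite_fraction),
            summary$concordance_n_genes))
  if (!is.null(top) && nrow(top$compensated) > 0) {
    shown <- utils::tail(top$compensated, 10)  # lowest p at the bottom
    lines <- c(lines, "",
               sprintf("Top compensated genes (most significant %d shown, coefficient > cutoff):",
                       nrow(shown)),
               sprintf("  %s (coefficient %.1f%%, p = %.3g)",
                       shown$gene, shown$coefficient, shown$de_p_km_w))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
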