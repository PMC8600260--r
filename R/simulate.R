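## Negative-binomial count simulator with the three-strain design and known
## per-gene compensation classes. NB parameterization throughout the package:
## var = mu + phi * mu^2 (phi = 1/size).

#' Simulation configuration
#'
#' Defaults mirror the study design this package models: ~20,000 genes,
#' replicates W=4 / KM=3 / ZERO=4, library sizes of 15-22 million reads, a
#' minority of genes differentially expressed between the derived strain (KM)
#' and its progenitor (W), and most of those DEGs compensated back toward the
#' progenitor level in the back-selected strain (ZERO).
#'
#' @param n_genes number of genes.
#' @param replicates named integer vector of replicates per role (`W`, `KM`,
#'   `ZERO`); each must be >= 2.
#' @param baseline_logmean_range interval for the per-gene natural-log
#'   baseline relative expression `b_g` (uniform draw).
#' @param dispersion_params `c(phi0, scale)`: per-gene NB dispersion follows
#'   the decreasing abundance trend `phi_g = phi0 + scale / exp(b_g)`.
#' @param lib_size_range interval of library sizes (reads per sample,
#'   uniform integer draw).
#' @param de_fraction fraction of genes differentially expressed KM vs W.
#' @param effect_size_logfc magnitude (log2) of the true KM-vs-W effect
#'   `beta_g`; signs are Rademacher (+/-1 with equal probability).
#' @param class_proportions probabilities over the compensation classes
#'   `compensated`, `uncompensated`, `overcompensated`; must sum to 1.
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 20000,
                       replicates = c(W = 4, KM = 3, ZERO = 4),
                       baseline_logmean_range = c(1, 10),
                       dispersion_params = c(phi0 = 0.05, scale = 1),
                       lib_size_range = c(15e6, 22e6),
                       de_fraction = 0.1,
                       effect_size_logfc = 2,
                       class_proportions = c(compensated = 0.7,
                                             uncompensated = 0.2,
                                             overcompensated = 0.1),
                       seed = 1L) {
  stopifnot(n_genes >= 1,
            length(replicates) == 3,
            all(c("W", "KM", "ZERO") %in% names(replicates)),
            length(baseline_logmean_range) == 2,
            diff(baseline_logmean_range) >= 0,
            length(dispersion_params) == 2,
            dispersion_params[[1]] >= 0, dispersion_params[[2]] >= 0,
            length(lib_size_range) == 2, all(lib_size_range > 0),
            diff(lib_size_range) >= 0,
            de_fraction >= 0, de_fraction <= 1,
            effect_size_logfc > 0,
            length(class_proportions) == 3,
            all(c("compensated", "uncompensated", "overcompensated") %in%
                  names(class_proportions)),
            all(class_proportions >= 0))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(replicates < 2))
    stop("each role needs >=2 replicates for any contrast to be testable")
  structure(list(n_genes = as.integer(n_genes),
                 replicates = replicates[c("W", "KM", "ZERO")],
                 baseline_logmean_range = baseline_logmean_range,
                 dispersion_params = unname(dispersion_params),
                 lib_size_range = lib_size_range,
                 de_fraction = de_fraction,
                 effect_size_logfc = effect_size_logfc,
                 class_proportions = class_proportions[c("compensated",
                                                         "uncompensated",
                                                         "overcompensated")],
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw the per-gene truth: baseline, dispersion, effects and classes.
# delta (true ZERO-vs-W log2 effect) per class, as a multiple of beta:
#   compensated      delta = u*beta, u ~ U[0, 0.3)   -> coefficient in (70, 100]
#   uncompensated    delta = v*beta, v ~ U[1.0, 1.5] -> coefficient in [-50, 0]
#   overcompensated  delta = -w*beta, w ~ U(0, 0.5]  -> coefficient in (100, 150]
# where true_coefficient = 100*(beta - delta)/beta for DE genes.
.draw_truth <- function(config) {
  n <- config$n_genes
  b <- runif(n, config$baseline_logmean_range[1], config$baseline_logmean_range[2])
  phi <- config$dispersion_params[1] + config$dispersion_params[2] / exp(b)
  n_de <- round(config$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE
  beta <- delta <- numeric(n)
  true_class <- rep("null", n)
  if (n_de > 0) {
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    beta[is_de] <- sign * config$effect_size_logfc
    cls <- sample(names(config$class_proportions), n_de, replace = TRUE,
                  prob = config$class_proportions)
    true_class[is_de] <- cls
    mult <- numeric(n_de)
    comp <- cls == "compensated"
    unco <- cls == "uncompensated"
    over <- cls == "overcompensated"
    mult[comp] <- runif(sum(comp), 0, 0.3)
    mult[unco] <- runif(sum(unco), 1.0, 1.5)
    mult[over] <- -runif(sum(over), .Machine$double.eps, 0.5)
    delta[is_de] <- mult * beta[is_de]
  }
  coef <- rep(NA_real_, n)
  coef[is_de] <- 100 * (beta[is_de] - delta[is_de]) / beta[is_de]
  data.frame(gene = sprintf("g%05d", seq_len(n)),
             baseline = b, dispersion = phi,
             beta = beta, delta = delta, is_de = is_de,
             true_class = true_class, true_coefficient = coef,
             stringsAsFactors = FALSE)
}

#' Simulate three-strain RNA-seq counts with known compensation truth
#'
#' Counts are drawn gene-by-sample as NB(mu, phi_g) with
#' `mu_gs = L_s * q_gs`, where the expected expression proportions
#' `q_gs = exp(b_g + ln(2) * (beta_g I\[s in KM\] + delta_g I\[s in ZERO\]))`
#' are renormalised to sum to 1 within each sample, `L_s` is the sample's
#' library size, and `var = mu + phi mu^2`.
#'
#' @param config a [sim_config()].
#' @param truth optional truth table overriding the random per-gene draw
#'   (same columns as the returned `truth`); used for controlled
#'   experiments, e.g. forcing exact full compensation `delta = 0`.
#' @return list with `counts` (integer matrix genes x samples), `samples`
#'   (sample sheet data.frame) and `truth` (per-gene truth table).
#' @export
simulate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(truth)) {
    truth <- .draw_truth(config)
  } else {
    need <- c("gene", "baseline", "dispersion", "beta", "delta", "is_de",
              "true_class", "true_coefficient")
    if (!all(need %in% names(truth))) stop("truth override missing columns")
    if (nrow(truth) != config$n_genes) stop("truth override has wrong n_genes")
  }
  reps <- config$replicates
  groups <- rep(c("W", "KM", "ZERO"), times = reps[c("W", "KM", "ZERO")])
  sample_ids <- unlist(lapply(c("W", "KM", "ZERO"),
                              function(r) paste0(r, seq_len(reps[[r]]))))
  sheet <- data.frame(sample_id = sample_ids, group = groups,
                      stringsAsFactors = FALSE)
  L <- round(runif(length(sample_ids), config$lib_size_range[1],
                   config$lib_size_range[2]))
  # expected relative expression per group, renormalised per sample
  log_q <- matrix(truth$baseline, nrow = config$n_genes, ncol = length(groups)) +
    log(2) * (outer(truth$beta, as.numeric(groups == "KM")) +
              outer(truth$delta, as.numeric(groups == "ZERO")))
  q <- exp(log_q)
  q <- sweep(q, 2, colSums(q), "/")
  mu <- sweep(q, 2, L, "*")
  phi <- truth$dispersion
  counts <- matrix(0L, nrow = config$n_genes, ncol = length(sample_ids),
                   dimnames = list(truth$gene, sample_ids))
  pois <- phi <= 0
  for (s in seq_along(sample_ids)) {
    y <- numeric(config$n_genes)
    if (any(pois)) y[pois] <- rpois(sum(pois), mu[pois, s])
    if (any(!pois)) y[!pois] <- rnbinom(sum(!pois), size = 1 / phi[!pois],
                                        mu = mu[!pois, s])
    counts[, s] <- as.integer(y)
  }
  list(counts = validate_counts(counts), samples = sheet, truth = truth)
}

#' Compare estimated compensation classes against simulation truth
#'
#' Restricted to genes detected as KM-vs-W DEGs (`de_p_km_w < p_threshold`
#' with a defined coefficient), builds the confusion matrix of true vs
#' estimated compensation class and compares the estimated compensated
#' fraction with the true fraction among those detected genes.
#'
#' @param truth truth table from [simulate_counts()].
#' @param records compensation table (see [compensation_table()]) with
#'   columns `gene`, `coefficient`, `comp_class`, `de_p_km_w`.
#' @param p_threshold DEG threshold on the KM-vs-W p-value.
#' @return list with `confusion` (true x estimated class table over detected
#'   DEGs), `n_detected`, `estimated_fraction`, `true_fraction` (fraction of
#'   detected DEGs whose true class is compensated), and `empty` flag.
#' @export
truth_recovery_report <- function(truth, records, p_threshold = 0.01) {
  if (!all(records$gene %in% truth$gene))
    stop("records contain gene ids absent from truth")
  m <- merge(truth, records, by = "gene")
  det <- m[!is.na(m$de_p_km_w) & m$de_p_km_w < p_threshold &
             !is.na(m$coefficient), , drop = FALSE]
  if (nrow(det) == 0) {
    return(list(confusion = table(character(0), character(0)),
                n_detected = 0L, estimated_fraction = NA_real_,
                true_fraction = NA_real_, empty = TRUE))
  }
  lev_true <- c("null", "compensated", "uncompensated", "overcompensated")
  lev_est <- c("compensated", "uncompensated", "overcompensated", "undefined")
  confusion <- table(true = factor(det$true_class, levels = lev_true),
                     estimated = factor(det$comp_class, levels = lev_est))
  list(confusion = confusion,
       n_detected = nrow(det),
       estimated_fraction = mean(det$comp_class == "compensated"),
       true_fraction = mean(det$true_class == "compensated"),
       empty = FALSE)
}
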