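# Shared fixtures and independent oracles used across the suite.

# Desk-scale simulation: the study design with library sizes scaled down
# tenfold so whole-pipeline tests run in seconds.
desk_config <- function(n_genes = 500, seed = 1, ...) {
  sim_config(n_genes = n_genes, lib_size_range = c(1.5e6, 2.2e6),
             seed = seed, ...)
}

# Small deterministic count matrix with dimnames.
tiny_counts <- function(values, n_genes, n_samples,
                        genes = sprintf("g%d", seq_len(n_genes)),
                        samples = sprintf("s%d", seq_len(n_samples))) {
  matrix(as.numeric(values), n_genes, n_samples,
         dimnames = list(genes, samples))
}

# Golden-section minimizer (unimodal f on [lo, hi]).
golden_min <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

# Independent two-group NB deviance minimum: each group's intercept found by
# golden-section search on the deviance directly.
oracle_two_group_deviance <- function(y, group_b, offsets, phi) {
  dev_group <- function(yg, og) {
    f <- function(beta) nb_deviance(yg, exp(beta + og), phi)
    bhat <- log((sum(yg) + 0.5) / sum(exp(og)))
    beta <- golden_min(f, bhat - 8, bhat + 8)
    f(beta)
  }
  dev_group(y[!group_b], offsets[!group_b]) +
    dev_group(y[group_b], offsets[group_b])
}
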