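# Small fixture builders shared across the test files. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# A hand-specified decay model (bypasses the random generator) for cases
# where exact baselines and rates matter.
manual_model <- function(baseline, lambda, gene_id = NULL,
                         decay_class = NULL, biotype = NULL) {
  n <- length(baseline)
  df <- data.frame(
    gene_id = gene_id %||% sprintf("G%05d", seq_len(n)),
    baseline_abundance = baseline,
    decay_rate = lambda,
    decay_class = decay_class %||% rep("background", n),
    biotype = biotype %||% rep("protein_coding", n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("decay_model", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny count experiment built directly from a counts matrix.
manual_experiment <- function(counts, pmi_hours) {
  stopifnot(ncol(counts) == length(pmi_hours))
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  reps <- stats::ave(pmi_hours, pmi_hours, FUN = seq_along)
  sheet <- data.frame(sample_id = colnames(counts), species = "mouse",
                      tissue = "retina", pmi_hours = pmi_hours,
                      replicate = as.integer(reps),
                      stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = rownames(counts), biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  count_experiment(counts, sheet, ann)
}

# Global-null experiment: every gene decays at the same rate, so relative
# abundance is constant and any DE call is a false positive.
null_experiment <- function(n_genes = 1500, lambda = 0.02,
                            pmi_hours = c(0, 24), replicates = 4,
                            library_size = 1e6, bcv = 0.1, seed = 1) {
  m <- generate_decay_model(
    n_genes, class_proportions = c(stable = 0, background = 1, fast = 0),
    rate_ranges = list(stable = c(0, 0), background = c(lambda, lambda),
                       fast = c(lambda + 1, lambda + 1)),
    seed = seed)
  d <- sim_design(pmi_hours = pmi_hours, replicates = replicates,
                  library_size = library_size, bcv = bcv, seed = seed + 1)
  list(model = m, experiment = simulate_counts(m, d))
}

# Planted experiment: a fraction of fast-decay genes against a non-decaying
# background; `fold` is the absolute decay of the planted genes by `t_max`.
planted_experiment <- function(n_genes = 2000, frac_fast = 0.1, fold = 4,
                               t_max = 24, replicates = 4,
                               library_size = 1e6, bcv = 0.1, seed = 1) {
  lam <- log(fold) / t_max
  m <- generate_decay_model(
    n_genes,
    class_proportions = c(stable = 0, background = 1 - frac_fast,
                          fast = frac_fast),
    rate_ranges = list(stable = c(0, 0), background = c(0, 0),
                       fast = c(lam, lam)),
    seed = seed)
  d <- sim_design(pmi_hours = c(0, t_max), replicates = replicates,
                  library_size = library_size, bcv = bcv, seed = seed + 1)
  list(model = m, experiment = simulate_counts(m, d))
}
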