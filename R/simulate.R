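#' Describe a simulated sequencing experiment
#'
#' Holds the design of one simulated post-mortem time course: the species
#' and tissue labels, the harvesting grid in hours, replication, sequencing
#' depth, and the replicate biological coefficient of variation (BCV). The
#' defaults mirror a mouse time course: harvests at 0, 0.25, 0.5, 0.75, 1,
#' 3, 6, 12 and 24 h with four animals per interval, roughly forty million
#' reads per library, and BCV 0.1 as is typical for genetically identical
#' model organisms.
#'
#' @param species_label,tissue_label Labels copied into the sample sheet.
#' @param pmi_hours Non-negative harvest times in hours; must contain 0
#'   (the baseline group every contrast is tested against).
#' @param replicates Replicates per time point (>= 2, otherwise replicate
#'   dispersion is inestimable).
#' @param library_size Expected reads per sample.
#' @param bcv Biological coefficient of variation between replicates;
#'   `bcv = 0` selects an exact Poisson observation model.
#' @param seed Integer seed, or `NULL`.
#' @return A `sim_design` list.
#' @export
sim_design <- function(species_label = "mouse", tissue_label = "retina",
                       pmi_hours = c(0, 0.25, 0.5, 0.75, 1, 3, 6, 12, 24),
                       replicates = 4L, library_size = 4e7, bcv = 0.1,
                       seed = NULL) {
  if (!is.numeric(pmi_hours) || any(pmi_hours < 0)) {
    stop("'pmi_hours' must be non-negative", call. = FALSE)
  }
  if (!any(pmi_hours == 0)) {
    stop("'pmi_hours' must contain 0 (baseline group)", call. = FALSE)
  }
  if (anyDuplicated(pmi_hours)) {
    stop("'pmi_hours' must be distinct", call. = FALSE)
  }
  if (replicates < 2) {
    stop("'replicates' must be >= 2", call. = FALSE)
  }
  if (library_size < 1) stop("'library_size' must be positive", call. = FALSE)
  if (bcv < 0) stop("'bcv' must be non-negative", call. = FALSE)
  structure(list(species_label = species_label, tissue_label = tissue_label,
                 pmi_hours = sort(pmi_hours),
                 replicates = as.integer(replicates),
                 library_size = library_size, bcv = bcv, seed = seed),
            class = "sim_design")
}

#' Simulate a post-mortem RNA-seq count experiment
#'
#' Draws gene-level counts under the compositional observation model: at
#' time \eqn{t} each sample sequences an expected `library_size` reads, and
#' gene \eqn{g} receives a negative-binomial count with mean
#' \eqn{\mu_g = L \, p_g(t)} (see [expected_proportions()]) and variance
#' \eqn{\mu_g + \phi \mu_g^2} where \eqn{\phi = \mathrm{BCV}^2}. With
#' `bcv = 0` counts are exactly Poisson.
#'
#' @param model A `decay_model`.
#' @param design A [sim_design()].
#' @param gene_bcv Optional per-gene BCV vector overriding `design$bcv`,
#'   for simulations with gene-specific replicate variability.
#' @return A [count_experiment()] whose annotations carry the simulation
#'   truth (`true_lambda`, `true_class`).
#' @examples
#' m <- generate_decay_model(50, seed = 1)
#' d <- sim_design(pmi_hours = c(0, 24), replicates = 2,
#'                 library_size = 1e5, seed = 2)
#' x <- simulate_counts(m, d)
#' dim(x$counts)
#' @export
simulate_counts <- function(model, design, gene_bcv = NULL) {
  stopifnot(inherits(model, "decay_model"), inherits(design, "sim_design"))
  n_genes <- nrow(model)
  if (is.null(gene_bcv)) {
    phi <- rep(design$bcv^2, n_genes)
  } else {
    if (length(gene_bcv) != n_genes || any(gene_bcv < 0)) {
      stop("'gene_bcv' must be a non-negative vector of length n_genes",
           call. = FALSE)
    }
    phi <- gene_bcv^2
  }
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      pmi_hours = design$pmi_hours)
  grid <- grid[order(grid$pmi_hours, grid$replicate), , drop = FALSE]
  sample_id <- sprintf("%s_%s_pmi%g_rep%d", design$species_label,
                       design$tissue_label, grid$pmi_hours, grid$replicate)
  L <- design$library_size
  pois <- phi == 0

  counts <- with_seed(design$seed, {
    cols <- lapply(seq_len(nrow(grid)), function(i) {
      mu <- L * expected_proportions(model, grid$pmi_hours[i])
      y <- numeric(n_genes)
      if (any(pois)) y[pois] <- stats::rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        y[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                   size = 1 / phi[!pois])
      }
      y
    })
    do.call(cbind, cols)
  })
  dimnames(counts) <- list(model$gene_id, sample_id)

  sample_sheet <- data.frame(sample_id = sample_id,
                             species = design$species_label,
                             tissue = design$tissue_label,
                             pmi_hours = grid$pmi_hours,
                             replicate = grid$replicate,
                             stringsAsFactors = FALSE)
  annotations <- data.frame(gene_id = model$gene_id,
                            biotype = model$biotype,
                            true_lambda = model$decay_rate,
                            true_class = model$decay_class,
                            stringsAsFactors = FALSE)
  count_experiment(counts, sample_sheet, annotations)
}

#' Simulate a qRT-PCR Ct panel over post-mortem intervals
#'
#' Emulates a qRT-PCR assay of selected marker genes: the cycle threshold
#' is linear in the negative log2 template abundance,
#' \eqn{Ct = c_0 - \log_2(a_g e^{-\lambda_g t}) + \epsilon}, with Gaussian
#' measurement noise and amplification efficiency fixed at 2 (one cycle per
#' doubling). One animal is generated per (interval, replicate) pair.
#'
#' @param model A `decay_model`.
#' @param panel_genes Character vector of marker gene ids (must exist in
#'   the model).
#' @param pmi_hours Assayed post-mortem intervals in hours.
#' @param replicates Animals per interval.
#' @param ct_noise_sd Measurement noise SD in cycles (>= 0).
#' @param seed Integer seed, or `NULL`.
#' @param c0 Calibration constant in cycles for unit template abundance.
#' @return A long-format [ct_panel()] with columns `gene_id`, `animal_id`,
#'   `pmi_hours`, `ct`.
#' @export
simulate_ct_panel <- function(model, panel_genes,
                              pmi_hours = c(0, 6, 12, 18, 24),
                              replicates = 4L, ct_noise_sd = 0.25,
                              seed = NULL, c0 = 30) {
  stopifnot(inherits(model, "decay_model"))
  missing <- setdiff(panel_genes, model$gene_id)
  if (length(missing)) {
    stop("panel genes not in model: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0", call. = FALSE)
  idx <- match(panel_genes, model$gene_id)
  a <- model$baseline_abundance[idx]
  lam <- model$decay_rate[idx]

  animals <- expand.grid(replicate = seq_len(replicates),
                         pmi_hours = pmi_hours)
  animals <- animals[order(animals$pmi_hours, animals$replicate), ,
                     drop = FALSE]
  animals$animal_id <- sprintf("a%02d", seq_len(nrow(animals)))

  df <- with_seed(seed, {
    recs <- lapply(seq_len(nrow(animals)), function(i) {
      t <- animals$pmi_hours[i]
      ct <- c0 - log2(a) + lam * t / log(2) +
        stats::rnorm(length(a), 0, ct_noise_sd)
      data.frame(gene_id = panel_genes, animal_id = animals$animal_id[i],
                 pmi_hours = t, ct = ct, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  rownames(df) <- NULL
  ct_panel(df)
}

#' Simulate a homolog map with unmapped and multi-mapped sources
#'
#' Generates a source-to-target gene id map of the kind produced by
#' ortholog lookup: a configurable fraction of source genes have no target
#' homolog, a fraction map to two targets, and the remainder map uniquely.
#' Target ids carry a sortable numeric suffix so that lowest-id resolution
#' (see [resolve_homologs()]) is well defined.
#'
#' @param source_genes Character vector of source gene ids.
#' @param frac_unmapped,frac_multimapped Proportions of sources with zero
#'   and with two targets; must satisfy `frac_unmapped + frac_multimapped <= 1`.
#' @param seed Integer seed, or `NULL`.
#' @return A `homolog_map` data frame (`source_id`, `target_id`), one row
#'   per pair.
#' @export
simulate_homolog_map <- function(source_genes, frac_unmapped = 0.11,
                                 frac_multimapped = 0.05, seed = NULL) {
  if (frac_unmapped < 0 || frac_multimapped < 0 ||
      frac_unmapped + frac_multimapped > 1) {
    stop("'frac_unmapped' + 'frac_multimapped' must be proportions summing to <= 1",
         call. = FALSE)
  }
  n <- length(source_genes)
  with_seed(seed, {
    status <- sample(c("none", "multi", "single"), n, replace = TRUE,
                     prob = c(frac_unmapped, frac_multimapped,
                              1 - frac_unmapped - frac_multimapped))
    n_targets <- c(none = 0L, single = 1L, multi = 2L)[status]
    total <- sum(n_targets)
    suffix <- sample.int(9999999L, total)
    df <- data.frame(
      source_id = rep(source_genes, n_targets),
      target_id = sprintf("HOMT%07d", suffix),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$source_id, df$target_id), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("homolog_map", "data.frame")
    df
  })
}
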