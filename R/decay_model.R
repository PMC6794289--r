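#' Generate a per-gene post-mortem decay model
#'
#' Defines the ground truth for the simulator: each gene carries a baseline
#' abundance \eqn{a_g} (arbitrary molecule units) and a first-order decay
#' rate \eqn{\lambda_g} (per hour), so that its true abundance at
#' post-mortem time \eqn{t} is \eqn{a_g e^{-\lambda_g t}}. No synthesis term
#' is included: transcription is assumed to stop at death, so transcript
#' pools can only shrink. Genes fall into three kinetic classes --
#' `stable`, `background` and `fast` -- with class-specific rate ranges.
#'
#' Default rate ranges correspond to half-lives of hundreds of hours
#' (stable), roughly 14--70 h (background) and 2.3--8.7 h (fast), a
#' realistic spread for mammalian mRNA turnover that yields both relatively
#' preserved and relatively degraded genes within a 24 h post-mortem
#' interval.
#'
#' @param n_genes Number of genes to generate (>= 1).
#' @param class_proportions Named numeric vector of proportions for the
#'   classes `stable`, `background`, `fast`; must sum to 1.
#' @param rate_ranges Named list of length-2 numeric ranges (per hour) for
#'   each class. Ranges must be non-negative and ordered
#'   stable <= background <= fast without overlap (shared endpoints are
#'   allowed, so degenerate `c(0, 0)` ranges are valid).
#' @param baseline_log_sd Standard deviation of log baseline abundance;
#'   baselines are log-normal.
#' @param biotype_proportions Named proportions for `protein_coding`,
#'   `lncRNA`, `pseudogene`; must sum to 1.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A `decay_model` data frame with columns `gene_id`,
#'   `baseline_abundance`, `decay_rate`, `decay_class`, `biotype`.
#' @examples
#' m <- generate_decay_model(100, seed = 1)
#' table(m$decay_class)
#' @export
generate_decay_model <- function(n_genes,
                                 class_proportions = c(stable = 0.1,
                                                       background = 0.8,
                                                       fast = 0.1),
                                 rate_ranges = list(stable = c(0, 0.002),
                                                    background = c(0.01, 0.05),
                                                    fast = c(0.08, 0.3)),
                                 baseline_log_sd = 1,
                                 biotype_proportions = c(protein_coding = 0.8,
                                                         lncRNA = 0.15,
                                                         pseudogene = 0.05),
                                 seed = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    stop("'n_genes' must be a single integer >= 1", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  classes <- c("stable", "background", "fast")
  biotypes <- c("protein_coding", "lncRNA", "pseudogene")
  class_proportions <- class_proportions[classes]
  biotype_proportions <- biotype_proportions[biotypes]
  if (anyNA(class_proportions) || anyNA(biotype_proportions)) {
    stop("class/biotype proportions must be named for all three levels",
         call. = FALSE)
  }
  check_simplex(class_proportions, "class_proportions")
  check_simplex(biotype_proportions, "biotype_proportions")
  if (!all(classes %in% names(rate_ranges))) {
    stop("'rate_ranges' must name all of stable, background, fast",
         call. = FALSE)
  }
  rr <- lapply(rate_ranges[classes], function(r) sort(as.numeric(r)))
  if (any(vapply(rr, length, 1L) != 2L) || any(unlist(rr) < 0)) {
    stop("each rate range must be two non-negative numbers", call. = FALSE)
  }
  if (rr$stable[2] > rr$background[1] || rr$background[2] > rr$fast[1]) {
    stop("rate ranges must be ordered stable <= background <= fast without overlap",
         call. = FALSE)
  }
  if (baseline_log_sd < 0) {
    stop("'baseline_log_sd' must be non-negative", call. = FALSE)
  }

  with_seed(seed, {
    decay_class <- sample(classes, n_genes, replace = TRUE,
                          prob = class_proportions)
    decay_rate <- numeric(n_genes)
    for (cl in classes) {
      idx <- decay_class == cl
      decay_rate[idx] <- stats::runif(sum(idx), rr[[cl]][1], rr[[cl]][2])
    }
    baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = baseline_log_sd)
    biotype <- sample(biotypes, n_genes, replace = TRUE,
                      prob = biotype_proportions)
    model <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      baseline_abundance = baseline,
      decay_rate = decay_rate,
      decay_class = decay_class,
      biotype = biotype,
      stringsAsFactors = FALSE
    )
    attr(model, "rate_ranges") <- rr
    attr(model, "seed") <- seed
    class(model) <- c("decay_model", "data.frame")
    model
  })
}

#' Expected relative transcript abundance at a post-mortem time
#'
#' Under a fixed sequencing depth only relative abundance is observable:
#' uniform decay cancels entirely under renormalization, and a gene decaying
#' more slowly than the transcriptome average rises in relative abundance
#' even though its absolute copy number falls. This function returns the
#' expected proportion of the library occupied by each gene,
#' \deqn{p_g(t) = a_g e^{-\lambda_g t} / \sum_h a_h e^{-\lambda_h t}.}
#'
#' @param model A `decay_model`.
#' @param t Non-negative time(s) in hours.
#' @return If `t` is scalar, a named proportion vector summing to 1;
#'   otherwise a genes x times matrix with each column summing to 1.
#' @examples
#' m <- generate_decay_model(5, seed = 1)
#' colSums(expected_proportions(m, c(0, 24)))
#' @export
expected_proportions <- function(model, t) {
  stopifnot(inherits(model, "decay_model") || is.data.frame(model))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be non-negative and finite", call. = FALSE)
  }
  a <- model$baseline_abundance
  lam <- model$decay_rate
  out <- vapply(t, function(tt) {
    # subtract the min exponent for numerical stability at large lambda*t
    logw <- log(a) - lam * tt
    w <- exp(logw - max(logw))
    w / sum(w)
  }, numeric(nrow(model)))
  if (length(t) == 1L) {
    out <- drop(out)
    names(out) <- model$gene_id
  } else {
    dimnames(out) <- list(model$gene_id, paste0("t", t))
  }
  out
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("Decay model: %d genes\n", nrow(x)))
  print(table(class_by_biotype = x$decay_class, x$biotype))
  rng <- range(x$decay_rate)
  cat(sprintf("decay rates: %.4g to %.4g per hour\n", rng[1], rng[2]))
  invisible(x)
}
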