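# Preserved/degraded classification of genes at each post-mortem interval.

#' Negative-binomial likelihood-ratio test against the 0 h baseline
#'
#' Tests, gene by gene, whether the relative abundance at `contrast_pmi`
#' differs from the 0 h group, holding the (tagwise, if available)
#' dispersion fixed. The full model fits one proportion per group with
#' effective library sizes as offsets; the null forces a shared proportion.
#' Twice the log-likelihood difference is referred to a chi-square with one
#' degree of freedom.
#'
#' The log2 fold change is computed on the CPM scale from effective
#' library sizes with a pseudocount of 0.5 CPM in both groups, so zero
#' groups stay finite. By default effective library sizes include
#' robust clipped-mean normalization factors ([norm_factors()]): under a fixed
#' sequencing depth the decay of part of the transcriptome inflates every
#' other gene's relative abundance, and re-centring on the typical gene
#' keeps unchanged genes near logFC 0. Set `normalize = "none"` for pure
#' library-size offsets.
#'
#' @param experiment A [count_experiment()] (expressed genes).
#' @param contrast_pmi Post-mortem interval (hours) to test against 0 h;
#'   must exist in the sample sheet along with a 0 h group.
#' @param dispersion A `dispersion_estimate` from
#'   [estimate_common_dispersion()] or [estimate_tagwise_dispersion()].
#' @param normalize `"clipped_mean"` (default), `"median_ratio"` or `"none"`.
#' @param pseudocount CPM-scale pseudocount for fold changes (default 0.5).
#' @return Data frame with `gene_id`, `logFC`, `logCPM`, `p_value`, and
#'   attribute `contrast_pmi`.
#' @export
nb_test_vs_baseline <- function(experiment, contrast_pmi, dispersion,
                                normalize = c("clipped_mean", "median_ratio", "none"),
                                pseudocount = 0.5) {
  stopifnot(inherits(experiment, "count_experiment"),
            inherits(dispersion, "dispersion_estimate"))
  normalize <- match.arg(normalize)
  ss <- experiment$sample_sheet
  base_cols <- which(ss$pmi_hours == 0)
  trt_cols <- which(ss$pmi_hours == contrast_pmi)
  if (!length(base_cols)) stop("no 0 h baseline group", call. = FALSE)
  if (!length(trt_cols) || contrast_pmi == 0) {
    stop(sprintf("no samples at PMI %g h", contrast_pmi), call. = FALSE)
  }
  cols <- c(base_cols, trt_cols)
  y <- experiment$counts[, cols, drop = FALSE]
  grp <- factor(rep(c("baseline", "contrast"),
                    c(length(base_cols), length(trt_cols))),
                levels = c("baseline", "contrast"))
  lib <- colSums(experiment$counts)[cols] *
    norm_factors(y, normalize, group = grp)

  phi <- dispersion$tagwise_phi
  if (is.null(phi)) {
    phi <- rep(dispersion$common_phi, nrow(y))
  } else if (!is.null(names(phi))) {
    phi <- phi[rownames(y)]
    if (anyNA(phi)) {
      stop("tagwise dispersions missing for some genes", call. = FALSE)
    }
  }
  phi <- unname(pmax(phi, 1e-10))

  ll_for <- function(g) {
    fit <- nb_fit_group_means(y, lib, g, phi)
    mu <- fit$mu
    rowSums(ifelse(mu == 0 & y == 0, 0,
                   stats::dnbinom(y, size = 1 / phi,
                                  mu = pmax(mu, 1e-300), log = TRUE)))
  }
  ll_full <- ll_for(grp)
  ll_null <- ll_for(factor(rep("all", length(cols))))
  stat <- pmax(2 * (ll_full - ll_null), 0)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  cpm_eff <- sweep(y, 2L, lib, "/") * 1e6
  m0 <- rowMeans(cpm_eff[, grp == "baseline", drop = FALSE])
  m1 <- rowMeans(cpm_eff[, grp == "contrast", drop = FALSE])
  out <- data.frame(
    gene_id = rownames(y),
    logFC = log2((m1 + pseudocount) / (m0 + pseudocount)),
    logCPM = log2(rowMeans(cpm_eff) + pseudocount),
    p_value = p,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "contrast_pmi") <- contrast_pmi
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j} clipped at 1, applied via
#' [stats::p.adjust()] after validating that all p-values lie in (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Classify genes as preserved, degraded or not DE
#'
#' A gene is `preserved` (relatively upregulated) when `q <= alpha` and
#' `logFC > 0`, `degraded` (relatively downregulated) when `q <= alpha`
#' and `logFC < 0`, and `not_de` otherwise.
#'
#' @param de Data frame with `logFC` and either `q_value` or `p_value`
#'   (q-values are computed by [bh_adjust()] when absent).
#' @param alpha Significance threshold on q (default 0.05; the boundary is
#'   inclusive).
#' @return The input with `q_value` and `status` columns, classed
#'   `de_result`; status counts are attached as attribute `counts`.
#' @export
classify_de <- function(de, alpha = 0.05) {
  stopifnot(is.data.frame(de), "logFC" %in% names(de))
  if (!"q_value" %in% names(de)) {
    if (!"p_value" %in% names(de)) {
      stop("'de' needs a q_value or p_value column", call. = FALSE)
    }
    de$q_value <- bh_adjust(de$p_value)
  }
  status <- rep("not_de", nrow(de))
  status[de$q_value <= alpha & de$logFC > 0] <- "preserved"
  status[de$q_value <= alpha & de$logFC < 0] <- "degraded"
  de$status <- factor(status, levels = c("preserved", "degraded", "not_de"))
  attr(de, "alpha") <- alpha
  attr(de, "counts") <- table(de$status)
  class(de) <- unique(c("de_result", class(de)))
  de
}

#' Run all baseline contrasts of an experiment
#'
#' Convenience wrapper: estimates (tagwise) dispersion, runs
#' [nb_test_vs_baseline()] for every requested post-mortem interval,
#' applies Benjamini-Hochberg adjustment within each contrast, and
#' classifies genes.
#'
#' @inheritParams nb_test_vs_baseline
#' @param contrasts Intervals to test; defaults to every non-zero PMI in
#'   the sample sheet.
#' @param alpha q-value threshold (default 0.05).
#' @param prior_df Shrinkage prior for tagwise dispersion (default 10).
#' @param dispersion Optional precomputed `dispersion_estimate`.
#' @return A `de_analysis` list: `results` (named list of `de_result`
#'   frames), `counts_table`, `dispersion`, `alpha`.
#' @export
de_analysis <- function(experiment, contrasts = NULL, alpha = 0.05,
                        prior_df = 10, normalize = c("clipped_mean", "median_ratio", "none"),
                        dispersion = NULL) {
  stopifnot(inherits(experiment, "count_experiment"))
  normalize <- match.arg(normalize)
  pmis <- sort(unique(experiment$sample_sheet$pmi_hours))
  contrasts <- contrasts %||% pmis[pmis > 0]
  missing <- setdiff(contrasts, pmis)
  if (length(missing)) {
    stop("PMIs absent from the sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_tagwise_dispersion(experiment,
                                              prior_df = prior_df)
  }
  results <- lapply(contrasts, function(t) {
    de <- nb_test_vs_baseline(experiment, t, dispersion, normalize)
    de$q_value <- bh_adjust(de$p_value)
    classify_de(de, alpha)
  })
  names(results) <- sprintf("pmi%g", contrasts)
  structure(list(results = results,
                 counts_table = de_count_table(results, contrasts),
                 dispersion = dispersion, alpha = alpha),
            class = "de_analysis")
}

#' Per-interval preserved/degraded/not-DE counts
#'
#' Summarizes a set of baseline contrasts as one row per post-mortem
#' interval with the number of preserved, degraded and unaffected genes;
#' the three counts sum to the number of genes tested.
#'
#' @param de_list A `de_analysis`, or a list of classified `de_result`
#'   frames.
#' @param pmi_hours Optional interval labels for a plain list.
#' @return Data frame with `pmi_hours`, `n_preserved`, `n_degraded`,
#'   `n_not_de`.
#' @export
de_count_table <- function(de_list, pmi_hours = NULL) {
  if (inherits(de_list, "de_analysis")) return(de_list$counts_table)
  if (inherits(de_list, "de_result")) de_list <- list(de_list)
  pmi_hours <- pmi_hours %||%
    vapply(de_list, function(d) attr(d, "contrast_pmi") %||% NA_real_, 1)
  rows <- lapply(de_list, function(d) {
    tab <- table(d$status)
    data.frame(n_preserved = as.integer(tab["preserved"]),
               n_degraded = as.integer(tab["degraded"]),
               n_not_de = as.integer(tab["not_de"]))
  })
  out <- cbind(pmi_hours = pmi_hours, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Mean-difference (MD) plot data
#'
#' One record per tested gene: average log2 CPM across both groups of the
#' contrast (A), the log2 fold change (M), and the preserved/degraded
#' status for colouring.
#'
#' @param de A classified `de_result`.
#' @return Data frame with `gene_id`, `logCPM`, `logFC`, `status`.
#' @export
md_plot_data <- function(de) {
  stopifnot(inherits(de, "de_result"))
  out <- de[, c("gene_id", "logCPM", "logFC", "status")]
  attr(out, "contrast_pmi") <- attr(de, "contrast_pmi")
  out
}

#' MD plot of one baseline contrast
#'
#' @param de A classified `de_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data.
#' @export
plot_md <- function(de, ...) {
  d <- md_plot_data(de)
  cols <- c(preserved = "#d73027", degraded = "#4575b4", not_de = "grey60")
  graphics::plot(d$logCPM, d$logFC, pch = 16, cex = 0.4,
                 col = cols[as.character(d$status)],
                 xlab = "Average log2 CPM", ylab = "log2 fold change",
                 main = sprintf("PMI %g h vs 0 h",
                                attr(d, "contrast_pmi") %||% NA), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(d)
}

#' @export
print.de_analysis <- function(x, ...) {
  cat(sprintf("DE analysis vs 0 h (q <= %g), BCV = %.4g\n",
              x$alpha, x$dispersion$bcv))
  print(x$counts_table, row.names = FALSE)
  invisible(x)
}
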