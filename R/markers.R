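# Candidate marker-gene selection from Z-score timelines.

#' Z-score timelines of per-interval expression
#'
#' For each gene, computes the mean `log2(CPM + 0.5)` over replicates at
#' each post-mortem interval, standardizes the interval means to Z-scores
#' (mean 0, sample SD 1 with the n-1 denominator; a constant timeline maps
#' to all-zero Z), and fits an ordinary least-squares line of Z against
#' hours to summarize the trajectory by a slope and R-squared.
#'
#' @param experiment A [count_experiment()].
#' @param gene_ids Genes to include (default: all).
#' @param timepoints Intervals (hours) to use; at least 3 required.
#'   Defaults to every interval in the sample sheet.
#' @return A `z_timeline` data frame with `gene_id`, `slope` (Z per hour),
#'   `r2`, plus attributes `z` (genes x timepoints matrix) and
#'   `timepoints`.
#' @export
zscore_timeline <- function(experiment, gene_ids = NULL, timepoints = NULL) {
  stopifnot(inherits(experiment, "count_experiment"))
  ss <- experiment$sample_sheet
  timepoints <- sort(timepoints %||% unique(ss$pmi_hours))
  if (length(timepoints) < 3L) {
    stop("at least 3 timepoints are needed for a slope", call. = FALSE)
  }
  missing <- setdiff(timepoints, ss$pmi_hours)
  if (length(missing)) {
    stop("timepoints absent from the experiment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lc <- log2(cpm(experiment) + 0.5)
  if (!is.null(gene_ids)) {
    bad <- setdiff(gene_ids, rownames(lc))
    if (length(bad)) {
      stop("unknown genes: ", paste(utils::head(bad, 10L), collapse = ", "),
           call. = FALSE)
    }
    lc <- lc[gene_ids, , drop = FALSE]
  }
  means <- vapply(timepoints, function(t) {
    rowMeans(lc[, ss$pmi_hours == t, drop = FALSE])
  }, numeric(nrow(lc)))
  if (nrow(lc) == 1L) means <- matrix(means, nrow = 1L)
  mu <- rowMeans(means)
  sdv <- apply(means, 1L, stats::sd)
  z <- (means - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0

  tc <- timepoints - mean(timepoints)
  sxx <- sum(tc^2)
  slope <- as.numeric(z %*% tc) / sxx
  # z rows have SD 1 (n-1), so total sum of squares is fixed
  tss <- rowSums((z - rowMeans(z))^2)
  rss <- tss - slope^2 * sxx
  r2 <- ifelse(tss > 0, pmax(0, 1 - rss / tss), 0)

  out <- data.frame(gene_id = rownames(lc), slope = slope, r2 = r2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  dimnames(z) <- list(out$gene_id, paste0("t", timepoints))
  attr(out, "z") <- z
  attr(out, "timepoints") <- timepoints
  class(out) <- c("z_timeline", "data.frame")
  out
}

#' @export
plot.z_timeline <- function(x, genes = NULL, ...) {
  z <- attr(x, "z")
  tp <- attr(x, "timepoints")
  if (!is.null(genes)) z <- z[genes, , drop = FALSE]
  graphics::matplot(tp, t(z), type = "l", lty = 1, col = "grey40",
                    xlab = "PMI (h)", ylab = "Z-score of mean log2 CPM", ...)
  invisible(x)
}

#' Filter genes by per-interval replicate BCV
#'
#' Retains genes whose per-gene, per-interval BCV (square root of the
#' maximum-likelihood negative-binomial dispersion within that interval's
#' replicate group, no shrinkage) is below `max_bcv` at every listed
#' interval. This keeps only genes with consistently quiet replicates,
#' suitable for qRT-PCR follow-up.
#'
#' @param experiment A [count_experiment()].
#' @param timepoints Intervals (hours) at which the BCV must stay low;
#'   each needs at least 2 replicates.
#' @param max_bcv BCV upper bound, exclusive (default 0.075).
#' @return Character vector of retained gene ids; per-interval BCVs are
#'   attached as attribute `bcv` (genes x timepoints matrix).
#' @export
bcv_filter <- function(experiment, timepoints = c(0, 3, 6, 12, 24),
                       max_bcv = 0.075) {
  stopifnot(inherits(experiment, "count_experiment"))
  ss <- experiment$sample_sheet
  missing <- setdiff(timepoints, ss$pmi_hours)
  if (length(missing)) {
    stop("timepoints absent from the experiment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lib <- colSums(experiment$counts)
  bcv <- vapply(timepoints, function(t) {
    cols <- which(ss$pmi_hours == t)
    if (length(cols) < 2L) {
      stop(sprintf("timepoint %g h has fewer than 2 replicates", t),
           call. = FALSE)
    }
    groupwise_bcv(experiment$counts[, cols, drop = FALSE], lib[cols])
  }, numeric(nrow(experiment$counts)))
  if (nrow(experiment$counts) == 1L) bcv <- matrix(bcv, nrow = 1L)
  dimnames(bcv) <- list(rownames(experiment$counts),
                        paste0("t", timepoints))
  keep <- rowSums(bcv < max_bcv) == length(timepoints)
  out <- rownames(experiment$counts)[keep]
  attr(out, "bcv") <- bcv
  out
}

#' Select candidate marker genes by timeline slope
#'
#' From genes whose Z-timeline is well described by a line
#' (`r2 >= min_r2`), selects the `n_positive` steepest positive slopes and
#' the `n_negative` steepest negative slopes. Ties are broken by
#' lexicographic gene id, making the selection deterministic and
#' independent of input order.
#'
#' @param timelines A `z_timeline` from [zscore_timeline()].
#' @param n_positive,n_negative Number of rising / falling candidates
#'   (defaults 9 and 9).
#' @param min_r2 Minimum R-squared of the linear fit (default 0.8).
#' @return Data frame of the selected genes (`gene_id`, `slope`, `r2`,
#'   `sign`), positive slopes first, each block ordered by decreasing
#'   steepness.
#' @export
select_candidates <- function(timelines, n_positive = 9L, n_negative = 9L,
                              min_r2 = 0.8) {
  stopifnot(inherits(timelines, "z_timeline") || is.data.frame(timelines))
  elig <- timelines[timelines$r2 >= min_r2, , drop = FALSE]
  pos <- elig[elig$slope > 0, , drop = FALSE]
  neg <- elig[elig$slope < 0, , drop = FALSE]
  if (nrow(pos) < n_positive || nrow(neg) < n_negative) {
    stop(sprintf(paste0("insufficient eligible genes: %d positive ",
                        "(need %d), %d negative (need %d) at r2 >= %g"),
                 nrow(pos), n_positive, nrow(neg), n_negative, min_r2),
         call. = FALSE)
  }
  pos <- pos[order(-pos$slope, pos$gene_id), , drop = FALSE][seq_len(n_positive), ]
  neg <- neg[order(neg$slope, neg$gene_id), , drop = FALSE][seq_len(n_negative), ]
  pos$sign <- "positive"
  neg$sign <- "negative"
  out <- rbind(pos[, c("gene_id", "slope", "r2", "sign")],
               neg[, c("gene_id", "slope", "r2", "sign")])
  rownames(out) <- NULL
  out
}
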