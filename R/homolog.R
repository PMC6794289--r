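# Homolog resolution and gene-set overlap tables for cross-species and
# cross-tissue comparisons.

parse_target_key <- function(target_id) {
  m <- regmatches(target_id, regexpr("[0-9]+$", target_id))
  bad <- lengths(regmatches(target_id, gregexpr("[0-9]+$", target_id))) == 0L
  if (any(bad)) {
    stop("target id(s) without a numeric suffix: ",
         paste(utils::head(target_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  as.numeric(m)
}

#' Map a gene list into the homolog namespace
#'
#' Applies the resolution rules used for cross-species comparison: source
#' genes without a homolog are dropped, and a source gene with several
#' homologs contributes only the target with the lowest numeric id
#' suffix. The result is a set (duplicates collapse).
#'
#' @param gene_ids Source gene ids.
#' @param map A homolog map data frame with `source_id`, `target_id`
#'   columns (see [simulate_homolog_map()] / [read_homolog_map()]).
#' @return Sorted character vector of resolved target ids.
#' @export
resolve_homologs <- function(gene_ids, map) {
  stopifnot(all(c("source_id", "target_id") %in% names(map)))
  hit <- map[map$source_id %in% gene_ids, , drop = FALSE]
  if (!nrow(hit)) return(character())
  key <- parse_target_key(hit$target_id)
  ord <- order(hit$source_id, key, hit$target_id)
  hit <- hit[ord, , drop = FALSE]
  first <- !duplicated(hit$source_id)
  sort(unique(hit$target_id[first]))
}

#' Overlap between two gene sets
#'
#' Intersection and exclusive counts for two sets in a shared namespace,
#' satisfying `overlap + exclusive_a == length(unique(set_a))` and the
#' analogous identity for B.
#'
#' @param set_a,set_b Character vectors (coerced to sets).
#' @param label_a,label_b Labels carried into the result.
#' @return An `overlap_result` list with `overlap_count`,
#'   `exclusive_a_count`, `exclusive_b_count`, the labels, and the shared
#'   ids in `overlap`.
#' @export
overlap_sets <- function(set_a, set_b, label_a = "A", label_b = "B") {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  shared <- intersect(a, b)
  structure(list(overlap_count = length(shared),
                 exclusive_a_count = length(setdiff(a, b)),
                 exclusive_b_count = length(setdiff(b, a)),
                 label_a = label_a, label_b = label_b,
                 overlap = sort(shared)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %d | exclusively %s %d | exclusively %s %d\n",
              x$overlap_count, x$label_a, x$exclusive_a_count,
              x$label_b, x$exclusive_b_count))
  invisible(x)
}

#' Preserved/degraded counts broken down by gene biotype
#'
#' For one classified contrast, counts expressed (tested), preserved and
#' degraded genes within each biotype, with percentages of the expressed
#' genes rounded to one decimal.
#'
#' @param de A classified `de_result` (see [classify_de()]).
#' @param annotations Gene annotation data frame with `gene_id` and
#'   `biotype`; every tested gene must be annotated.
#' @return Data frame with one row per biotype: `biotype`, `n_expressed`,
#'   `n_preserved`, `n_degraded`, `pct_preserved`, `pct_degraded`.
#' @export
biotype_breakdown <- function(de, annotations) {
  stopifnot(is.data.frame(de), "status" %in% names(de))
  bt <- annotations$biotype[match(de$gene_id, annotations$gene_id)]
  if (anyNA(bt)) {
    stop("genes without biotype annotation: ",
         paste(utils::head(de$gene_id[is.na(bt)], 5L), collapse = ", "),
         call. = FALSE)
  }
  bt <- factor(bt)
  n_expr <- as.integer(table(bt))
  n_pres <- as.integer(table(bt[de$status == "preserved"]))
  n_degr <- as.integer(table(bt[de$status == "degraded"]))
  data.frame(biotype = levels(bt), n_expressed = n_expr,
             n_preserved = n_pres, n_degraded = n_degr,
             pct_preserved = round(100 * n_pres / n_expr, 1),
             pct_degraded = round(100 * n_degr / n_expr, 1),
             stringsAsFactors = FALSE)
}

#' Cross-comparison fold ratio of DE overlap counts
#'
#' Compares how strongly DE gene sets overlap within a species (between
#' its tissues) versus within a tissue (between species): the sum of
#' overlap counts across the intra-species strata divided by the sum
#' across the intra-tissue strata. A value above 1 indicates that RNA
#' metabolism is more species- than tissue-specific.
#'
#' @param overlaps_by_tissue `overlap_result` (or list of them) comparing
#'   tissues within a species (numerator strata).
#' @param overlaps_by_species `overlap_result` (or list of them) comparing
#'   species within a tissue (denominator strata).
#' @return A single fold ratio.
#' @export
cross_comparison_ratio <- function(overlaps_by_tissue, overlaps_by_species) {
  sum_overlaps <- function(x) {
    if (inherits(x, "overlap_result")) x <- list(x)
    if (!length(x)) stop("empty stratum list", call. = FALSE)
    sum(vapply(x, function(o) o$overlap_count, numeric(1)))
  }
  num <- sum_overlaps(overlaps_by_tissue)
  den <- sum_overlaps(overlaps_by_species)
  if (den == 0) {
    stop("intra-tissue overlap sum is zero; ratio undefined", call. = FALSE)
  }
  num / den
}

#' Read / write a homolog map TSV
#'
#' Two tab-separated columns, `source_id` and `target_id`, one row per
#' mapped pair; `#`-prefixed lines hold metadata.
#'
#' @param path File path.
#' @return [read_homolog_map()] returns a `homolog_map` data frame.
#' @export
read_homolog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_table_commented(path)
  stopifnot(all(c("source_id", "target_id") %in% names(df)))
  if (anyDuplicated(df)) df <- unique(df)
  class(df) <- c("homolog_map", "data.frame")
  df
}

#' @rdname read_homolog_map
#' @param map A homolog map data frame.
#' @param comments Metadata comment lines.
#' @export
write_homolog_map <- function(map, path, comments = character()) {
  write_table_commented(as.data.frame(map)[, c("source_id", "target_id")],
                        path, comments)
}
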