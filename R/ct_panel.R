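# qRT-PCR Ct panels and their internal normalization.

#' Construct a Ct panel
#'
#' Long-format qRT-PCR measurements: one row per (gene, animal) with the
#' animal's post-mortem interval and the cycle threshold. Each animal may
#' appear at one interval only, and each (gene, animal) pair at most once.
#'
#' @param df Data frame with columns `gene_id`, `animal_id`, `pmi_hours`,
#'   `ct`.
#' @return A `ct_panel` data frame (attribute `normalized = FALSE`).
#' @export
ct_panel <- function(df) {
  need <- c("gene_id", "animal_id", "pmi_hours", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("Ct panel missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$ct) || any(!is.finite(df$ct))) {
    stop("'ct' must be finite numeric", call. = FALSE)
  }
  if (anyDuplicated(df[, c("gene_id", "animal_id")])) {
    stop("duplicate (gene, animal) Ct records", call. = FALSE)
  }
  pmi_per_animal <- tapply(df$pmi_hours, df$animal_id,
                           function(v) length(unique(v)))
  if (any(pmi_per_animal != 1L)) {
    stop("each animal must have a single pmi_hours value", call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "normalized") <- FALSE
  class(df) <- unique(c("ct_panel", class(df)))
  df
}

is_normalized <- function(panel) isTRUE(attr(panel, "normalized"))

#' Internally normalize a Ct panel
#'
#' Subtracts, within each animal, the mean Ct over the full marker panel
#' from every gene's Ct, producing `delta_ct`. This removes animal-level
#' offsets (input amount, RT efficiency): adding a constant to one
#' animal's Cts leaves its delta-Ct values unchanged. Each animal must
#' have a complete panel, and a panel may only be normalized once.
#'
#' @param panel A [ct_panel()].
#' @return The panel with a `delta_ct` column and `normalized = TRUE`.
#' @export
normalize_ct <- function(panel) {
  stopifnot(inherits(panel, "ct_panel"))
  if (is_normalized(panel)) {
    stop("panel is already normalized", call. = FALSE)
  }
  genes <- unique(panel$gene_id)
  animals <- unique(panel$animal_id)
  have <- table(factor(panel$animal_id, animals),
                factor(panel$gene_id, genes))
  if (any(have == 0L)) {
    idx <- which(have == 0L, arr.ind = TRUE)
    pairs <- paste0("(", animals[idx[, 1]], ", ", genes[idx[, 2]], ")")
    stop("incomplete panel; missing: ",
         paste(utils::head(pairs, 10L), collapse = ", "), call. = FALSE)
  }
  panel$delta_ct <- panel$ct -
    stats::ave(panel$ct, panel$animal_id, FUN = mean)
  attr(panel, "normalized") <- TRUE
  panel
}

# Wide delta-Ct matrix (animals x genes) plus per-animal PMI, from a
# normalized panel.
panel_matrix <- function(panel) {
  stopifnot(inherits(panel, "ct_panel"))
  if (!is_normalized(panel)) panel <- normalize_ct(panel)
  genes <- sort(unique(panel$gene_id))
  animals <- unique(panel$animal_id)
  D <- matrix(NA_real_, length(animals), length(genes),
              dimnames = list(animals, genes))
  D[cbind(match(panel$animal_id, animals),
          match(panel$gene_id, genes))] <- panel$delta_ct
  pmi <- panel$pmi_hours[match(animals, panel$animal_id)]
  list(delta = D, pmi = pmi, animal_id = animals)
}

#' Read / write Ct panels as CSV
#'
#' Long-format CSV with columns `gene_id`, `animal_id`, `pmi_hours`,
#' `ct`; `#`-prefixed lines hold metadata.
#'
#' @param path File path.
#' @return [read_ct_panel()] returns a `ct_panel`.
#' @export
read_ct_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ct_panel(read_table_commented(path, sep = ","))
}

#' @rdname read_ct_panel
#' @param panel A [ct_panel()].
#' @param comments Metadata comment lines.
#' @export
write_ct_panel <- function(panel, path, comments = character()) {
  stopifnot(inherits(panel, "ct_panel"))
  cols <- intersect(c("gene_id", "animal_id", "pmi_hours", "ct"),
                    names(panel))
  write_table_commented(as.data.frame(panel)[, cols], path, comments,
                        sep = ",")
}
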