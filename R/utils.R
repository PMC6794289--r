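# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded generators do not disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive n sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Validate that a proportion vector lies on the simplex.
check_simplex <- function(p, what, tol = 1e-9) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("'%s' must be non-negative and finite", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.12g)", what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

# Write a data frame as TSV/CSV with '#'-prefixed metadata comment lines.
write_table_commented <- function(df, path, comments = character(),
                                  sep = "\t") {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_commented <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
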