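# PMI estimation from delta-Ct marker panels: an exhaustive three-gene
# multiple-regression ensemble with mean aggregation.

#' Enumerate all three-gene combinations
#'
#' Every unordered 3-subset of the marker genes, each sorted internally,
#' with the list in lexicographic order. With 18 markers this yields
#' choose(18, 3) = 816 candidate models.
#'
#' @param gene_ids Character vector of at least 3 gene ids.
#' @return A choose(n, 3) x 3 character matrix, one sorted triple per row.
#' @export
enumerate_triples <- function(gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) < 3L) {
    stop("at least 3 genes are required", call. = FALSE)
  }
  t(utils::combn(sort(gene_ids), 3L))
}

#' Fit the exhaustive three-gene PMI regression ensemble
#'
#' For every three-gene combination of the panel, fits an ordinary
#' least-squares regression of the known post-mortem interval on the three
#' internally normalized delta-Ct values,
#' \deqn{PMI_a = \beta_0 + \beta_1 \Delta Ct_{g_1,a} + \beta_2 \Delta
#' Ct_{g_2,a} + \beta_3 \Delta Ct_{g_3,a} + \varepsilon_a,}
#' records the overall F-test p-value and R-squared of each model, and
#' retains the models passing the p-value rule. Retained models are later
#' averaged by [predict.pmi_ensemble()]. Rank-deficient triples are
#' skipped with a warning rather than failing the fit.
#'
#' The retention rule defaults to `model_p <= p_threshold`
#' (`p_direction = "le"`); the reversed reading (`"ge"`) is available as
#' an option.
#'
#' @param panel A [ct_panel()] with known `pmi_hours`; normalized with
#'   [normalize_ct()] if it is not already.
#' @param p_threshold Model p-value threshold (default 0.05).
#' @param p_direction `"le"` to keep models with p at or below the
#'   threshold (default), `"ge"` for the reversed rule.
#' @return A `pmi_ensemble` object with elements `models` (all fitted
#'   models with coefficients, `r2`, `p_value`, `retained`), `gene_ids`,
#'   `p_threshold`, `p_direction`, `n_animals`, and the training data.
#' @examples
#' m <- generate_decay_model(20, seed = 1)
#' p <- simulate_ct_panel(m, m$gene_id[1:6], replicates = 4,
#'                        ct_noise_sd = 0.2, seed = 2)
#' fit <- pmi_ensemble(p)
#' fit
#' @export
pmi_ensemble <- function(panel, p_threshold = 0.05,
                         p_direction = c("le", "ge")) {
  p_direction <- match.arg(p_direction)
  pm <- panel_matrix(panel)
  D <- pm$delta
  pmi <- pm$pmi
  n <- nrow(D)
  if (n < 5L) {
    stop("at least 5 animals are required to fit 3-gene models",
         call. = FALSE)
  }
  if (anyNA(pmi)) stop("every animal needs a known pmi_hours", call. = FALSE)
  if (stats::var(pmi) == 0) {
    stop("all animals share one PMI; regression is undefined", call. = FALSE)
  }
  triples <- enumerate_triples(colnames(D))
  K <- nrow(triples)
  coefs <- matrix(NA_real_, K, 4L,
                  dimnames = list(NULL, c("intercept", "b1", "b2", "b3")))
  r2 <- p <- rep(NA_real_, K)
  singular <- logical(K)
  tss <- sum((pmi - mean(pmi))^2)
  df2 <- n - 4L
  for (k in seq_len(K)) {
    X <- cbind(1, D[, triples[k, ], drop = FALSE])
    qr_x <- qr(X)
    if (qr_x$rank < 4L) {
      singular[k] <- TRUE
      next
    }
    b <- qr.coef(qr_x, pmi)
    rss <- sum((pmi - drop(X %*% b))^2)
    coefs[k, ] <- b
    r2[k] <- 1 - rss / tss
    fstat <- (tss - rss) / 3 / (rss / df2)
    p[k] <- if (rss <= tss * 1e-12) 0 else
      stats::pf(fstat, 3, df2, lower.tail = FALSE)
  }
  if (any(singular)) {
    warning(sprintf("%d singular triple(s) skipped", sum(singular)))
  }
  retained <- !singular &
    if (p_direction == "le") p <= p_threshold else p >= p_threshold
  models <- data.frame(gene_1 = triples[, 1], gene_2 = triples[, 2],
                       gene_3 = triples[, 3], coefs, r2 = r2,
                       p_value = p, retained = retained,
                       stringsAsFactors = FALSE)
  if (!any(retained)) {
    warning("no models retained at the requested threshold")
  }
  structure(list(models = models, gene_ids = colnames(D),
                 p_threshold = p_threshold, p_direction = p_direction,
                 n_animals = n,
                 training = list(delta = D, pmi = pmi,
                                 animal_id = pm$animal_id),
                 call = match.call()),
            class = "pmi_ensemble")
}

#' Predict post-mortem intervals from a fitted ensemble
#'
#' Each retained three-gene model produces one PMI estimate per animal;
#' the final estimate is their unweighted mean. Estimates are not clipped,
#' so slightly negative values are possible and reported as-is.
#'
#' @param object A [pmi_ensemble()].
#' @param newdata A [ct_panel()] for new animals (normalized internally if
#'   needed), or `NULL` for the training animals.
#' @param per_model If `TRUE`, attach the animals x models estimate matrix
#'   as attribute `per_model`.
#' @param ... Unused.
#' @return Data frame with `animal_id`, `pmi_estimate` (hours) and
#'   `n_models`.
#' @export
predict.pmi_ensemble <- function(object, newdata = NULL,
                                 per_model = FALSE, ...) {
  mods <- object$models[object$models$retained, , drop = FALSE]
  if (!nrow(mods)) stop("ensemble is empty; nothing retained", call. = FALSE)
  if (is.null(newdata)) {
    D <- object$training$delta
    animals <- object$training$animal_id
  } else {
    pm <- panel_matrix(newdata)
    missing <- setdiff(object$gene_ids, colnames(pm$delta))
    if (length(missing)) {
      stop("new panel lacks model genes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    D <- pm$delta
    animals <- pm$animal_id
  }
  est <- vapply(seq_len(nrow(mods)), function(k) {
    g <- unlist(mods[k, c("gene_1", "gene_2", "gene_3")], use.names = FALSE)
    b <- unlist(mods[k, c("intercept", "b1", "b2", "b3")],
                use.names = FALSE)
    b[1] + D[, g, drop = FALSE] %*% b[2:4]
  }, numeric(nrow(D)))
  if (nrow(D) == 1L) est <- matrix(est, nrow = 1L)
  out <- data.frame(animal_id = animals,
                    pmi_estimate = unname(rowMeans(est)),
                    n_models = nrow(mods), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (per_model) {
    dimnames(est) <- list(animals, NULL)
    attr(out, "per_model") <- est
  }
  out
}

#' @export
fitted.pmi_ensemble <- function(object, ...) {
  p <- predict(object)
  structure(p$pmi_estimate, names = p$animal_id)
}

#' @export
residuals.pmi_ensemble <- function(object, ...) {
  object$training$pmi - fitted(object)
}

#' @export
coef.pmi_ensemble <- function(object, ...) {
  object$models[object$models$retained,
                c("gene_1", "gene_2", "gene_3", "intercept",
                  "b1", "b2", "b3"), drop = FALSE]
}

#' @export
print.pmi_ensemble <- function(x, ...) {
  cat(sprintf("PMI regression ensemble: %d three-gene models over %d genes\n",
              nrow(x$models), length(x$gene_ids)))
  cat(sprintf("  retained %d models (p %s %g), %d training animals\n",
              sum(x$models$retained),
              if (x$p_direction == "le") "<=" else ">=",
              x$p_threshold, x$n_animals))
  invisible(x)
}

#' @export
summary.pmi_ensemble <- function(object, ...) {
  mods <- object$models
  ret <- mods[mods$retained, , drop = FALSE]
  res <- residuals(object)
  out <- list(n_models = nrow(mods), n_retained = nrow(ret),
              p_threshold = object$p_threshold,
              p_direction = object$p_direction,
              r2_summary = summary(ret$r2),
              training_mae = mean(abs(res)),
              training_rmse = sqrt(mean(res^2)),
              top = utils::head(ret[order(ret$p_value, -ret$r2), ], 5L))
  class(out) <- "summary.pmi_ensemble"
  out
}

#' @export
print.summary.pmi_ensemble <- function(x, ...) {
  cat(sprintf("PMI ensemble: %d/%d models retained (p %s %g)\n",
              x$n_retained, x$n_models,
              if (x$p_direction == "le") "<=" else ">=", x$p_threshold))
  cat(sprintf("training MAE %.3f h, RMSE %.3f h\n",
              x$training_mae, x$training_rmse))
  cat("R-squared of retained models:\n")
  print(x$r2_summary)
  cat("best models:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pmi_ensemble <- function(x, ...) {
  p <- predict(x, per_model = TRUE)
  truth <- x$training$pmi
  graphics::plot(truth, p$pmi_estimate, pch = 19,
                 xlab = "true PMI (h)", ylab = "ensemble estimate (h)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(p)
}

#' Leave-one-animal-out evaluation of the PMI estimator
#'
#' For each animal, refits the whole ensemble on the remaining animals and
#' predicts the held-out one. Because the delta-Ct normalization is
#' strictly within-animal, no information leaks from the held-out animal
#' into training. Reports signed errors, the mean absolute error and the
#' root-mean-square error in hours.
#'
#' @inheritParams pmi_ensemble
#' @return A `pmi_loao` list: `per_animal` (data frame with `animal_id`,
#'   `pmi_true`, `pmi_estimate`, `error`, `n_models`), `mae`, `rmse`.
#' @export
evaluate_loao <- function(panel, p_threshold = 0.05,
                          p_direction = c("le", "ge")) {
  p_direction <- match.arg(p_direction)
  stopifnot(inherits(panel, "ct_panel"))
  if (!is_normalized(panel)) panel <- normalize_ct(panel)
  animals <- unique(panel$animal_id)
  if (length(animals) < 6L) {
    stop("at least 6 animals are required for leave-one-animal-out",
         call. = FALSE)
  }
  rows <- lapply(animals, function(a) {
    train <- panel[panel$animal_id != a, , drop = FALSE]
    test <- panel[panel$animal_id == a, , drop = FALSE]
    fit <- suppressWarnings(pmi_ensemble(train, p_threshold, p_direction))
    pred <- predict(fit, newdata = test)
    truth <- test$pmi_hours[1]
    data.frame(animal_id = a, pmi_true = truth,
               pmi_estimate = pred$pmi_estimate,
               error = pred$pmi_estimate - truth,
               n_models = pred$n_models, stringsAsFactors = FALSE)
  })
  per_animal <- do.call(rbind, rows)
  rownames(per_animal) <- NULL
  structure(list(per_animal = per_animal,
                 mae = mean(abs(per_animal$error)),
                 rmse = sqrt(mean(per_animal$error^2))),
            class = "pmi_loao")
}

#' @export
print.pmi_loao <- function(x, ...) {
  cat(sprintf("Leave-one-animal-out: %d animals, MAE %.3f h, RMSE %.3f h\n",
              nrow(x$per_animal), x$mae, x$rmse))
  invisible(x)
}
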