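# Internal Ct normalization, triple enumeration, the regression ensemble
# and its leave-one-animal-out evaluation.

# Build a normalized panel directly from a delta-Ct matrix and PMI vector
# by inventing raw Cts whose within-animal centring reproduces the matrix.
panel_from_delta <- function(D, pmi) {
  D <- D - rowMeans(D)  # enforce per-animal zero mean
  animals <- sprintf("a%02d", seq_len(nrow(D)))
  genes <- colnames(D) %||% sprintf("g%02d", seq_len(ncol(D)))
  df <- data.frame(
    gene_id = rep(genes, each = nrow(D)),
    animal_id = rep(animals, ncol(D)),
    pmi_hours = rep(pmi, ncol(D)),
    ct = as.vector(D) + 25,  # arbitrary per-animal offset
    stringsAsFactors = FALSE
  )
  ct_panel(df)
}

test_that("normalize_ct centres each animal and guards reuse", {
  df <- data.frame(gene_id = rep(c("g1", "g2", "g3"), 2),
                   animal_id = rep(c("a1", "a2"), each = 3),
                   pmi_hours = rep(c(0, 6), each = 3),
                   ct = c(20, 22, 24, 31, 30, 35))
  p <- normalize_ct(ct_panel(df))
  expect_equal(p$delta_ct[p$animal_id == "a1"], c(-2, 0, 2))
  means <- tapply(p$delta_ct, p$animal_id, mean)
  expect_equal(unname(c(means)), c(0, 0), tolerance = 1e-9)
  # shift invariance: +5 cycles on one animal changes nothing
  df2 <- df
  df2$ct[df2$animal_id == "a2"] <- df2$ct[df2$animal_id == "a2"] + 5
  p2 <- normalize_ct(ct_panel(df2))
  expect_equal(p2$delta_ct, p$delta_ct)
  # double normalization and incomplete panels are errors
  expect_error(normalize_ct(p), "already")
  expect_error(normalize_ct(ct_panel(df[-1, ])), "missing")
  # single-gene panel: all deltas zero
  p1 <- normalize_ct(ct_panel(df[df$gene_id == "g1", ]))
  expect_equal(p1$delta_ct, c(0, 0))
})

test_that("triple enumeration matches combinatorics and an exhaustive oracle", {
  expect_equal(nrow(enumerate_triples(sprintf("g%02d", 1:18))), 816)
  expect_equal(nrow(enumerate_triples(c("a", "b", "c"))), 1)
  expect_error(enumerate_triples(c("a", "b")), "at least 3")
  # brute-force oracle for small n: all index triples i<j<k
  for (n in 3:6) {
    ids <- sort(sprintf("x%d", seq_len(n)))
    oracle <- list()
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      oracle[[length(oracle) + 1]] <- c(ids[i], ids[j], ids[k])
    }
    got <- enumerate_triples(rev(ids))
    expect_equal(nrow(got), choose(n, 3))
    expect_equal(unname(split(got, seq_len(nrow(got)))), oracle)
  }
  for (n in 7:20) {
    expect_equal(nrow(enumerate_triples(sprintf("g%02d", 1:n))),
                 factorial(n) / (factorial(3) * factorial(n - 3)))
  }
})

test_that("an exact linear rule is recovered perfectly", {
  set.seed(71)
  D <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, sprintf("g%02d", 1:6)))
  D <- D - rowMeans(D)
  pmi <- 3 + 2 * D[, "g01"]
  panel <- panel_from_delta(D, pmi)
  fit <- pmi_ensemble(panel, p_threshold = 1e-8)
  mods <- fit$models
  with_g1 <- mods$gene_1 == "g01" | mods$gene_2 == "g01" |
    mods$gene_3 == "g01"
  # every model containing g01 is exact, with coefficient 2 on g01
  expect_true(all(mods$retained[with_g1]))
  expect_true(all(!mods$retained[!with_g1]))
  expect_equal(mods$r2[with_g1], rep(1, sum(with_g1)), tolerance = 1e-9)
  for (k in which(with_g1)) {
    genes <- unlist(mods[k, c("gene_1", "gene_2", "gene_3")])
    bs <- unlist(mods[k, c("b1", "b2", "b3")])
    expect_equal(unname(bs[genes == "g01"]), 2, tolerance = 1e-6)
    expect_equal(unname(bs[genes != "g01"]), c(0, 0), tolerance = 1e-6)
  }
  pred <- predict(fit, newdata = panel)
  expect_equal(pred$pmi_estimate, pmi, tolerance = 1e-6)
})

test_that("prediction is the unweighted mean over retained models", {
  set.seed(73)
  D <- matrix(rnorm(12 * 4), 12, 4,
              dimnames = list(NULL, sprintf("g%02d", 1:4)))
  pmi <- rep(c(0, 6, 12, 24), 3)
  panel <- panel_from_delta(D, pmi)
  fit <- pmi_ensemble(panel, p_threshold = 1)  # retain everything
  expect_equal(sum(fit$models$retained), choose(4, 3))
  pred <- predict(fit, per_model = TRUE)
  per <- attr(pred, "per_model")
  expect_equal(pred$pmi_estimate, unname(rowMeans(per)))
  # hand-check one animal against explicit model formulas
  Dc <- fit$training$delta
  est_hand <- vapply(seq_len(nrow(fit$models)), function(k) {
    b <- unlist(fit$models[k, c("intercept", "b1", "b2", "b3")])
    g <- unlist(fit$models[k, c("gene_1", "gene_2", "gene_3")])
    unname(b[1] + sum(b[2:4] * Dc[1, g]))
  }, numeric(1))
  expect_equal(unname(per[1, ]), est_hand)
  # single-model ensemble: the mean is that model's estimate
  one <- fit
  one$models$retained <- c(TRUE, rep(FALSE, nrow(fit$models) - 1))
  p_one <- predict(one, per_model = TRUE)
  expect_equal(p_one$pmi_estimate, unname(attr(p_one, "per_model")[, 1]))
})

test_that("pure-noise panels retain about the nominal fraction of models", {
  set.seed(75)
  fracs <- vapply(1:12, function(i) {
    D <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, sprintf("g%02d", 1:6)))
    pmi <- rep(c(0, 6, 12, 18, 24), each = 4)
    fit <- suppressWarnings(pmi_ensemble(panel_from_delta(D, pmi),
                                         p_threshold = 0.05))
    mean(fit$models$retained)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.04)
})

test_that("model and animal order do not affect predictions", {
  m <- generate_decay_model(30, seed = 77)
  m$baseline_abundance <- pmax(m$baseline_abundance, 1)
  panel <- simulate_ct_panel(m, m$gene_id[1:6], replicates = 4,
                             ct_noise_sd = 0.2, seed = 78)
  fit <- pmi_ensemble(panel)
  pred <- predict(fit)
  shuf <- as.data.frame(panel)[sample(nrow(panel)), ]
  pred2 <- predict(fit, newdata = ct_panel(shuf))
  ord <- match(pred$animal_id, pred2$animal_id)
  expect_equal(pred2$pmi_estimate[ord], pred$pmi_estimate,
               tolerance = 1e-12)
})

test_that("LOAO is near-exact without noise and degrades sanely with it", {
  # noise-free linear rule over delta-Ct: held-out predictions are exact.
  # (A zero-noise panel from the exponential model itself is collinear --
  # every delta-Ct is affine in time -- so full-rank data is constructed.)
  set.seed(81)
  D0 <- matrix(rnorm(20 * 5), 20, 5,
               dimnames = list(NULL, sprintf("g%02d", 1:5)))
  D0 <- D0 - rowMeans(D0)
  pmi0 <- 12 + 3 * D0[, "g01"]
  panel0 <- panel_from_delta(D0, pmi0)
  ev0 <- evaluate_loao(panel0, p_threshold = 1e-6)
  expect_lt(ev0$mae, 1e-6)
  # with noise, errors stay finite and beat the label-shuffled baseline
  set.seed(82)
  mm <- generate_decay_model(40, seed = 83)
  mm$decay_rate[1:9] <- 0
  mm$decay_rate[10:18] <- log(2) / 6
  panel <- simulate_ct_panel(mm, mm$gene_id[1:18],
                             pmi_hours = c(0, 6, 12, 18, 24),
                             replicates = 4, ct_noise_sd = 0.25, seed = 84)
  ev <- evaluate_loao(panel)
  expect_lt(ev$mae, 2)
  shuffled <- as.data.frame(panel)
  perm <- sample(unique(shuffled$animal_id))
  names(perm) <- unique(shuffled$animal_id)
  new_pmi <- tapply(shuffled$pmi_hours, shuffled$animal_id, unique)[
    perm[shuffled$animal_id]]
  shuffled$pmi_hours <- unname(new_pmi)
  # retain all models: with shuffled labels few pass any threshold
  ev_null <- evaluate_loao(ct_panel(shuffled), p_threshold = 1)
  grand_mean_mae <- mean(abs(panel$pmi_hours - mean(unique(
    tapply(panel$pmi_hours, panel$animal_id, unique)))))
  expect_gt(ev_null$mae, 0.5 * grand_mean_mae)
  expect_gt(ev_null$mae, ev$mae)
  expect_error(evaluate_loao(panel0[panel0$animal_id %in%
                                      unique(panel0$animal_id)[1:4], ]),
               "at least")
})
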