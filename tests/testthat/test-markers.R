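# Z-score timelines, the per-interval BCV filter and candidate selection.

test_that("z-scores standardize interval means with the sample SD", {
  # per-interval means 1, 2, 3 (sample SD 1) must map to z = -1, 0, 1
  f <- function(target_mean_log2cpm) {
    round(2^target_mean_log2cpm - 0.5)
  }
  # 4 genes so each column's library is dominated by a filler gene;
  # choose counts so gene g1 has CPM 2^k - 0.5 shape approximately
  counts <- rbind(
    g1 = c(100, 200, 400),
    filler = c(1e6, 1e6, 1e6) - c(100, 200, 400)
  )
  colnames(counts) <- c("s1", "s2", "s3")
  x <- manual_experiment(counts, pmi_hours = c(0, 12, 24))
  tl <- zscore_timeline(x)
  z <- attr(tl, "z")["g1", ]
  m <- log2(cpm(x)["g1", ] + 0.5)
  expect_equal(unname(z), unname((m - mean(m)) / stats::sd(m)))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
})

test_that("hand case: means in arithmetic progression give slope 1/12", {
  z <- c(-1, 0, 1)
  hours <- c(0, 12, 24)
  # closed form against the implementation on constructed data
  counts <- rbind(g1 = c(10, 20, 40), filler = rep(1e6, 3))
  x <- manual_experiment(counts, pmi_hours = hours)
  tl <- zscore_timeline(x)
  fit <- stats::lm(attr(tl, "z")["g1", ] ~ hours)
  expect_equal(tl$slope[1], unname(stats::coef(fit)[2]))
  expect_equal(tl$r2[1], summary(fit)$r.squared, tolerance = 1e-9)
})

test_that("constant timelines are flat and reversal negates the slope", {
  const <- rep(500L, 4)
  rise <- c(10L, 40L, 200L, 900L)
  counts <- rbind(const = const, rise = rise,
                  filler = 1000000L - const - rise)  # fixed library size
  hours <- c(0, 8, 16, 24)  # symmetric grid, so reversal reflects exactly
  x <- manual_experiment(counts, pmi_hours = hours)
  tl <- zscore_timeline(x)
  expect_equal(unname(attr(tl, "z")["const", ]), rep(0, 4))
  expect_equal(tl$slope[tl$gene_id == "const"], 0)
  x_rev <- manual_experiment(counts[, 4:1], pmi_hours = hours)
  tl_rev <- zscore_timeline(x_rev)
  expect_equal(tl_rev$slope[tl_rev$gene_id == "rise"],
               -tl$slope[tl$gene_id == "rise"], tolerance = 1e-12)
  expect_error(zscore_timeline(manual_experiment(counts[, 1:2],
                                                 hours[1:2])),
               "3 timepoints")
})

test_that("bcv_filter keeps quiet genes and drops noisy ones", {
  n <- 400
  m <- generate_decay_model(n,
    class_proportions = c(stable = 0, background = 1, fast = 0),
    rate_ranges = list(stable = c(0, 0), background = c(0, 0),
                       fast = c(1, 1)), seed = 61)
  gene_bcv <- rep(0.02, n)
  gene_bcv[1:40] <- 0.3  # planted noisy genes
  d <- sim_design(pmi_hours = c(0, 3, 6, 12, 24), replicates = 4,
                  library_size = 2e6, seed = 62)
  x <- simulate_counts(m, d, gene_bcv = gene_bcv)
  kept <- bcv_filter(x, timepoints = c(0, 3, 6, 12, 24), max_bcv = 0.075)
  noisy <- m$gene_id[1:40]
  expect_lt(mean(noisy %in% kept), 0.1)
  expect_gt(mean(setdiff(m$gene_id, noisy) %in% kept), 0.6)
  # degenerate threshold removes (nearly) everything
  expect_lt(length(bcv_filter(x, max_bcv = 1e-6)), 5)
  expect_error(bcv_filter(x, timepoints = c(0, 5)), "absent")
})

test_that("candidate selection honours counts, signs and the tie rule", {
  tl <- data.frame(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    slope = c(0.05, 0.04, 0.04, -0.05, -0.04, 0.001),
    r2 = c(0.9, 0.95, 0.9, 0.99, 0.85, 0.2))
  class(tl) <- c("z_timeline", "data.frame")
  sel <- select_candidates(tl, n_positive = 2, n_negative = 2, min_r2 = 0.8)
  expect_equal(sel$gene_id, c("a", "b", "d", "e"))
  # identical slope at the cutoff: lexicographically smaller id wins
  sel2 <- select_candidates(tl, n_positive = 3, n_negative = 2,
                            min_r2 = 0.8)
  expect_equal(sel2$gene_id[2:3], c("b", "c"))
  # order invariance
  sel3 <- select_candidates(tl[sample(6), ], 2, 2, 0.8)
  expect_equal(sel3, sel)
  expect_error(select_candidates(tl, 5, 2, 0.8), "insufficient")
})

test_that("selection recovers planted stable and fast markers", {
  n <- 800
  m <- generate_decay_model(n,
    class_proportions = c(stable = 0, background = 1, fast = 0),
    rate_ranges = list(stable = c(0, 0), background = c(0.02, 0.02),
                       fast = c(1, 1)), seed = 63)
  stable_idx <- 1:9
  fast_idx <- 10:18
  m$decay_rate[stable_idx] <- 0
  m$decay_class[stable_idx] <- "stable"
  m$decay_rate[fast_idx] <- 0.15
  m$decay_class[fast_idx] <- "fast"
  # markers are well-expressed genes, as qPCR assay design would require
  m$baseline_abundance[1:18] <-
    pmax(m$baseline_abundance[1:18], stats::median(m$baseline_abundance))
  gene_bcv <- rep(0.1, n)
  gene_bcv[1:18] <- 0.02  # markers are quiet replicators
  d <- sim_design(pmi_hours = c(0, 3, 6, 12, 24), replicates = 4,
                  library_size = 2e6, seed = 64)
  x <- simulate_counts(m, d, gene_bcv = gene_bcv)
  kept <- bcv_filter(x)
  tl <- zscore_timeline(x, kept)
  sel <- select_candidates(tl, 9, 9, min_r2 = 0.8)
  planted <- m$gene_id[1:18]
  expect_gte(sum(sel$gene_id %in% planted), 16)
  # positive-slope picks are enriched for the stable class
  pos <- sel$gene_id[sel$sign == "positive"]
  n_stable_pos <- sum(pos %in% m$gene_id[stable_idx])
  ph <- stats::phyper(n_stable_pos - 1, length(stable_idx),
                      n - length(stable_idx), length(pos),
                      lower.tail = FALSE)
  expect_lt(ph, 0.01)
})
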