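# NB likelihood-ratio testing, BH adjustment and preserved/degraded
# classification.

# Independent step-up oracle: the literal definition
# q_(i) = min over j with p_(j) >= p_(i) of m * p_(j) / j, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (ps[j] >= ps[i]) cand <- min(cand, m * ps[j] / j)
    }
    q[o[i]] <- min(cand, 1)
  }
  q
}

test_that("bh_adjust matches hand-derived cases and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.5, 100)), rep(0.5, 100))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("bh_adjust equals the exhaustive step-up oracle on all
          orderings of six p-values", {
  p_base <- c(0.001, 0.008, 0.039, 0.041, 0.5, 0.87)
  perms <- NULL
  # all 720 permutations, built recursively
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  for (p in permute(p_base)) {
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # and with ties present
  p_tied <- c(0.01, 0.01, 0.2, 0.2, 0.7, 1)
  expect_equal(bh_adjust(p_tied), bh_oracle(p_tied))
})

test_that("identical groups give logFC 0 and p 1", {
  counts <- matrix(rep(c(50L, 200L, 1000L), 8), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
  x <- manual_experiment(counts, pmi_hours = rep(c(0, 24), each = 4))
  disp <- estimate_common_dispersion(x)
  de <- nb_test_vs_baseline(x, 24, disp)
  expect_equal(de$logFC, rep(0, 3))
  expect_equal(de$p_value, rep(1, 3))
})

test_that("swapping group labels negates logFC and preserves p-values", {
  pl <- planted_experiment(n_genes = 400, seed = 51)
  x <- pl$experiment
  sheet_sw <- x$sample_sheet
  sheet_sw$pmi_hours <- ifelse(sheet_sw$pmi_hours == 0, 24, 0)
  x_sw <- count_experiment(x$counts, sheet_sw, x$gene_annotations)
  disp <- estimate_common_dispersion(x)
  de <- nb_test_vs_baseline(x, 24, disp)
  de_sw <- nb_test_vs_baseline(x_sw, 24, disp)
  expect_equal(de_sw$logFC, -de$logFC, tolerance = 1e-8)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-6)
})

test_that("a strongly decayed gene is detected with the right effect size", {
  # one 8-fold decayed gene in an otherwise null transcriptome
  n <- 2000
  m <- generate_decay_model(n,
    class_proportions = c(stable = 0, background = 1, fast = 0),
    rate_ranges = list(stable = c(0, 0), background = c(0, 0),
                       fast = c(1, 1)), seed = 53)
  m$decay_rate[1] <- log(8) / 24
  m$decay_class[1] <- "fast"
  m$baseline_abundance[1] <- stats::median(m$baseline_abundance) * 4
  d <- sim_design(pmi_hours = c(0, 24), replicates = 4,
                  library_size = 1e6, bcv = 0.1, seed = 54)
  x <- simulate_counts(m, d)
  disp <- estimate_common_dispersion(x)
  de <- nb_test_vs_baseline(x, 24, disp)
  expect_lt(de$p_value[1], 1e-4)
  expect_lt(abs(de$logFC[1] - (-3)), 0.3)
})

test_that("p-values are uniform under the global null (KS band)", {
  x <- null_experiment(n_genes = 3000, seed = 55)$experiment
  disp <- estimate_tagwise_dispersion(x, prior_df = 10)
  p <- nb_test_vs_baseline(x, 24, disp)$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.358 / sqrt(length(p)))
})

test_that("classification respects the q and logFC rules", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   logFC = c(2, -2, 3, 0),
                   q_value = c(0.04, 0.04, 0.5, 0.01))
  cl <- classify_de(de, alpha = 0.05)
  expect_equal(as.character(cl$status),
               c("preserved", "degraded", "not_de", "not_de"))
  expect_equal(unname(c(attr(cl, "counts"))), c(1L, 1L, 2L))
  # alpha = 0 silences everything
  cl0 <- classify_de(transform(de, q_value = pmax(q_value, 1e-12)),
                     alpha = 0)
  expect_true(all(cl0$status == "not_de"))
})

test_that("count table rows partition the tested genes", {
  pl <- planted_experiment(n_genes = 800, seed = 57)
  x <- pl$experiment
  da <- de_analysis(x, alpha = 0.05, prior_df = 10)
  tab <- de_count_table(da)
  expect_equal(tab$n_preserved + tab$n_degraded + tab$n_not_de,
               rep(nrow(x$counts), nrow(tab)))
  # planted fast genes at 24 h are recovered almost completely
  de24 <- da$results$pmi24
  fast <- pl$model$gene_id[pl$model$decay_class == "fast"]
  recovered <- de24$gene_id[de24$status == "degraded"]
  expect_gte(mean(fast %in% recovered), 0.9)
})

test_that("false discoveries are controlled under the global null", {
  # any call under a uniform-decay null is false; mean FDP over replicate
  # simulations must stay near the BH guarantee
  fdp <- vapply(1:20, function(s) {
    x <- null_experiment(n_genes = 600, seed = 500 + s)$experiment
    disp <- estimate_common_dispersion(x)
    de <- nb_test_vs_baseline(x, 24, disp)
    cl <- classify_de(transform(de, q_value = bh_adjust(p_value)))
    n_called <- sum(cl$status != "not_de")
    if (n_called > 0) 1 else 0
  }, numeric(1))
  mc_se <- stats::sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * mc_se + 1e-12)
})

test_that("md plot data is consistent with the classification", {
  counts <- matrix(c(100L, 10L, 0L, 100L, 12L, 0L,
                     400L, 10L, 0L, 380L, 11L, 0L), nrow = 3,
                   dimnames = list(c("up", "flat", "absent"), NULL))
  x <- manual_experiment(counts, pmi_hours = c(0, 0, 24, 24))
  # drop the all-zero gene before testing, as the expression filter would
  keep <- filter_expressed(x, min_cpm = 1, min_samples = 2)
  xk <- count_experiment(x$counts[keep, , drop = FALSE], x$sample_sheet,
                         x$gene_annotations[
                           x$gene_annotations$gene_id %in% keep, ])
  disp <- estimate_common_dispersion(xk, group_labels = rep(1, 4))
  de <- classify_de(nb_test_vs_baseline(xk, 24, disp, normalize = "none"))
  md <- md_plot_data(de)
  expect_false("absent" %in% md$gene_id)
  expect_equal(table(md$status), attr(de, "counts"))
  # arithmetic oracle for A and M with pseudocount 0.5 on plain CPM
  cp <- cpm(xk$counts)
  a_hand <- log2(rowMeans(cp) + 0.5)
  m_hand <- log2((rowMeans(cp[, 3:4]) + 0.5) / (rowMeans(cp[, 1:2]) + 0.5))
  expect_equal(md$logCPM, unname(a_hand))
  expect_equal(md$logFC, unname(m_hand))
})
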