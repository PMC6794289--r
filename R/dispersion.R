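# Negative-binomial dispersion estimation.
#
# The replicate variability model is var(y) = mu + phi * mu^2 with
# phi = BCV^2. Group means (one proportion per replicate group, with
# library sizes as offsets) are profiled out by Fisher scoring, and the
# profile log-likelihood carries a Cox-Reid adjustment of
# -1/2 * log(information) per estimated mean, without which the maximum
# likelihood dispersion is biased downward at small replicate numbers.

# Fisher scoring for per-gene, per-group log-mean proportions.
# counts: G x n; lib: length n effective library sizes; group: factor of
# length n; phi: scalar or length-G vector. Returns list(mu, info) where mu
# is the fitted G x n mean matrix and info a G x nlevels(group) matrix of
# observed Fisher information for each profiled mean (0 for all-zero groups).
nb_fit_group_means <- function(counts, lib, group, phi, iter = 30L) {
  group <- droplevels(as.factor(group))
  G <- nrow(counts)
  mu <- matrix(0, G, ncol(counts), dimnames = dimnames(counts))
  info <- matrix(0, G, nlevels(group))
  colnames(info) <- levels(group)
  for (j in seq_len(nlevels(group))) {
    cols <- which(group == levels(group)[j])
    y <- counts[, cols, drop = FALSE]
    l <- lib[cols]
    tot <- rowSums(y)
    ok <- tot > 0
    beta <- ifelse(ok, log(tot / sum(l)), -Inf)
    if (any(ok)) {
      b <- beta[ok]
      ys <- y[ok, , drop = FALSE]
      ph <- if (length(phi) == 1L) rep(phi, sum(ok)) else phi[ok]
      for (k in seq_len(iter)) {
        m <- exp(b) %o% l
        w <- 1 + ph * m
        U <- rowSums((ys - m) / w)
        J <- rowSums(m / w)
        step <- U / pmax(J, 1e-10)
        step <- pmin(pmax(step, -5), 5)  # damp early wild steps
        b <- b + step
        if (max(abs(step)) < 1e-10) break
      }
      beta[ok] <- b
      m <- exp(b) %o% l
      mu[ok, cols] <- m
      info[ok, j] <- rowSums(m / (1 + ph * m))
    }
  }
  list(mu = mu, info = info)
}

# Cox-Reid adjusted profile log-likelihood per gene at dispersion phi.
nb_apl <- function(counts, lib, group, phi) {
  fit <- nb_fit_group_means(counts, lib, group, phi)
  mu <- fit$mu
  if (length(phi) == 1L && phi == 0) {
    # all-zero groups contribute log P(0 | mu = 0) = 0
    ll <- rowSums(ifelse(mu == 0 & counts == 0, 0,
                         stats::dpois(counts, pmax(mu, 1e-300), log = TRUE)))
  } else {
    size <- 1 / phi  # scalar or per-gene, recycled down columns
    ll <- rowSums(ifelse(mu == 0 & counts == 0, 0,
                         stats::dnbinom(counts, size = size,
                                        mu = pmax(mu, 1e-300), log = TRUE)))
  }
  # adjustment only for groups where a mean was actually estimated
  adj <- rowSums(ifelse(fit$info > 0, log(pmax(fit$info, 1e-300)), 0)) / 2
  ll - adj
}

default_groups <- function(experiment, group_labels) {
  if (is.null(group_labels)) {
    group_labels <- factor(experiment$sample_sheet$pmi_hours)
  }
  group_labels <- droplevels(as.factor(group_labels))
  if (length(group_labels) != ncol(experiment$counts)) {
    stop("'group_labels' length must equal the number of samples",
         call. = FALSE)
  }
  if (!any(table(group_labels) >= 2)) {
    stop("dispersion inestimable: every group has a single sample",
         call. = FALSE)
  }
  group_labels
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the Cox-Reid adjusted profile log-likelihood summed over
#' genes, with one mean per replicate group (library sizes as offsets)
#' profiled out. The biological coefficient of variation is
#' \eqn{\sqrt{\hat\phi}}.
#'
#' @param experiment A [count_experiment()], ideally restricted to
#'   expressed genes.
#' @param group_labels Factor of replicate groups per sample; defaults to
#'   the sample sheet's `pmi_hours`.
#' @param phi_max Upper bound of the dispersion search (default 5).
#' @return A `dispersion_estimate` with elements `common_phi`, `bcv`,
#'   `tagwise_phi` (`NULL` here), `group_labels`.
#' @examples
#' m <- generate_decay_model(200, seed = 1)
#' d <- sim_design(pmi_hours = c(0, 24), replicates = 4,
#'                 library_size = 2e5, bcv = 0.2, seed = 2)
#' est <- estimate_common_dispersion(simulate_counts(m, d))
#' est$bcv
#' @export
estimate_common_dispersion <- function(experiment, group_labels = NULL,
                                       phi_max = 5) {
  stopifnot(inherits(experiment, "count_experiment"))
  group <- default_groups(experiment, group_labels)
  counts <- experiment$counts
  lib <- colSums(counts)
  f <- function(phi) sum(nb_apl(counts, lib, group, phi))
  opt <- stats::optimize(f, c(1e-8, phi_max), maximum = TRUE, tol = 1e-9)
  phi_hat <- opt$maximum
  if (f(0) >= opt$objective) phi_hat <- 0
  structure(list(common_phi = phi_hat, tagwise_phi = NULL,
                 bcv = sqrt(phi_hat), prior_df = NULL,
                 group_labels = group, phi_max = phi_max),
            class = "dispersion_estimate")
}

# Shared dispersion grid: zero (exact Poisson), a log-spaced ladder, plus
# any anchor values (e.g. the common estimate) inserted exactly.
phi_grid <- function(phi_max, anchors = numeric(), length_out = 80L) {
  g <- c(0, exp(seq(log(1e-5), log(phi_max), length.out = length_out)),
         anchors[anchors > 0 & anchors <= phi_max])
  sort(unique(g))
}

#' Estimate tagwise (per-gene) dispersions with shrinkage
#'
#' Per-gene dispersions maximize a weighted objective: the gene's own
#' Cox-Reid adjusted profile likelihood plus `prior_df` pseudo-observations
#' of the experiment-average likelihood, the weight being
#' `prior_df / residual df`. With `prior_df = 0` each gene is estimated on
#' its own; as `prior_df` grows all estimates shrink to the common value.
#' Maximization is over a dense dispersion grid that contains zero and the
#' common estimate exactly.
#'
#' @inheritParams estimate_common_dispersion
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @param common Optional precomputed result of
#'   [estimate_common_dispersion()]; computed if missing.
#' @return A `dispersion_estimate` with `tagwise_phi` (named per-gene
#'   vector) and `tagwise_bcv` filled in.
#' @export
estimate_tagwise_dispersion <- function(experiment, group_labels = NULL,
                                        prior_df = 10, common = NULL,
                                        phi_max = 5) {
  stopifnot(inherits(experiment, "count_experiment"))
  group <- default_groups(experiment, group_labels)
  if (is.null(common)) {
    common <- estimate_common_dispersion(experiment, group, phi_max)
  }
  counts <- experiment$counts
  lib <- colSums(counts)
  df_resid <- ncol(counts) - nlevels(group)
  if (df_resid < 1) {
    stop("no residual degrees of freedom for tagwise estimation",
         call. = FALSE)
  }
  grid <- phi_grid(phi_max, anchors = common$common_phi)
  apl <- vapply(grid, function(p) nb_apl(counts, lib, group, p),
                numeric(nrow(counts)))
  if (nrow(counts) == 1L) apl <- matrix(apl, nrow = 1L)
  shared <- colMeans(apl)
  prior_n <- prior_df / df_resid
  obj <- apl + matrix(prior_n * shared, nrow(apl), length(grid),
                      byrow = TRUE)
  tag <- grid[max.col(obj, ties.method = "first")]
  names(tag) <- rownames(counts)
  out <- common
  out$tagwise_phi <- tag
  out$tagwise_bcv <- sqrt(tag)
  out$prior_df <- prior_df
  out
}

# Per-gene ML dispersion (no shrinkage) within a single replicate group;
# used by the marker-selection BCV filter.
groupwise_bcv <- function(counts, lib, phi_max = 4) {
  grid <- phi_grid(phi_max, length_out = 120L)
  group <- factor(rep(1L, ncol(counts)))
  apl <- vapply(grid, function(p) nb_apl(counts, lib, group, p),
                numeric(nrow(counts)))
  if (nrow(counts) == 1L) apl <- matrix(apl, nrow = 1L)
  sqrt(grid[max.col(apl, ties.method = "first")])
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("NB dispersion estimate: common phi = %.5g (BCV = %.4g)\n",
              x$common_phi, x$bcv))
  if (!is.null(x$tagwise_phi)) {
    q <- stats::quantile(sqrt(x$tagwise_phi), c(0.25, 0.5, 0.75))
    cat(sprintf("  tagwise BCV quartiles (prior_df = %g): %.4g / %.4g / %.4g\n",
                x$prior_df, q[1], q[2], q[3]))
  }
  invisible(x)
}
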