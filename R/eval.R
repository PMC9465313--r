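# Evaluation statistics: per-gene correlations under the four model
# classes, significance counting, enrichment tests, the directional
# agreement probability and the time-point scrambling control.

#' Pearson correlation with undefined-correlation propagation
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return product-moment coefficient, or `NA` if either vector has zero
#'   variance.
#' @export
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3)
    stop("pearson needs two equal-length numeric vectors with >= 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pearson inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-gene correlation summary under four model classes
#'
#' For every gene/protein record the observed protein values on the paired
#' grid are correlated with (a) the summed splice-variant expression, (b)
#' the single splice variant with the largest absolute correlation (signed
#' value reported), (c) the cross-validated predictions of the static
#' multi-splice model (delay forced to zero), and (d) the cross-validated
#' predictions of the delayed multi-splice model.
#'
#' @inheritParams fit_dataset
#' @param oos_delayed named list of [double_cv_predict()] data frames for
#'   the delayed model, keyed by protein id (entries may be missing).
#' @param oos_static same, for the zero-delay model.
#' @return data.frame with columns `gene_id`, `protein_id`,
#'   `n_transcripts`, `rho_sum`, `rho_best_single`, `rho_static_multi`,
#'   `rho_delayed_multi`. Undefined correlations are `NA`.
#' @export
correlation_table <- function(dataset, oos_delayed = NULL,
                              oos_static = NULL) {
  rows <- lapply(dataset, function(rec) {
    al <- align_timepoints(rec$gene$times, rec$protein$y)
    tpair <- unclass(al$grid)
    obs <- al$protein$values
    Xp <- rec$gene$X[, match(tpair, rec$gene$times), drop = FALSE]
    rho_sum <- pearson(colSums(Xp), obs)
    tr_rhos <- apply(Xp, 1, pearson, y = obs)
    rho_best <- if (all(is.na(tr_rhos))) NA_real_ else
      tr_rhos[which.max(abs(tr_rhos))]
    oos_rho <- function(oos) {
      df <- oos[[rec$protein$protein_id]]
      if (is.null(df)) return(NA_real_)
      pearson(df$predicted, df$observed)
    }
    data.frame(gene_id = rec$gene$gene_id,
               protein_id = rec$protein$protein_id,
               n_transcripts = nrow(rec$gene$X),
               rho_sum = rho_sum,
               rho_best_single = unname(rho_best),
               rho_static_multi = if (is.null(oos_static)) NA_real_ else
                 oos_rho(oos_static),
               rho_delayed_multi = if (is.null(oos_delayed)) NA_real_ else
                 oos_rho(oos_delayed),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the four model classes over a dataset
#'
#' Convenience wrapper: computes double cross-validated predictions with
#' the full delay grid and with the delay forced to zero, then summarizes
#' with [correlation_table()].
#'
#' @inheritParams fit_dataset
#' @return list with `table` (the [correlation_table()] data frame) and
#'   `medians` (named vector of per-class median correlations).
#' @export
evaluate_models <- function(dataset, delays = build_delay_grid(200L, 24),
                            n_lams = 50L, eps = 1e-4) {
  oos_d <- list()
  oos_s <- list()
  for (rec in dataset) {
    pid <- rec$protein$protein_id
    oos_d[[pid]] <- double_cv_predict(rec$gene, rec$protein, delays = delays,
                                      n_lams = n_lams, eps = eps)
    oos_s[[pid]] <- double_cv_predict(rec$gene, rec$protein,
                                      delays = delay_grid(0),
                                      n_lams = n_lams, eps = eps)
  }
  tab <- correlation_table(dataset, oos_delayed = oos_d, oos_static = oos_s)
  meds <- vapply(c("rho_sum", "rho_best_single", "rho_static_multi",
                   "rho_delayed_multi"),
                 function(cl) stats::median(tab[[cl]], na.rm = TRUE),
                 numeric(1))
  list(table = tab, medians = meds, oos_delayed = oos_d, oos_static = oos_s)
}

#' Critical |rho| for a two-sided Pearson significance test
#'
#' From the t distribution with `n_points - 2` degrees of freedom.
#'
#' @param n_points number of paired observations (>= 3).
#' @param alpha two-sided significance level.
#' @return critical absolute correlation.
#' @export
significance_threshold <- function(n_points, alpha = 0.05) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 3)
    stop("n_points must be a single count >= 3")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  df <- n_points - 2
  tc <- stats::qt(1 - alpha / 2, df = df)
  tc / sqrt(df + tc^2)
}

#' Expected number of significant correlations under the null
#'
#' @param n_genes number of genes tested.
#' @param tail_prob per-gene tail probability (e.g. 0.025 for one
#'   direction at a two-sided alpha of 0.05).
#' @return expected count `n_genes * tail_prob`.
#' @export
expected_significant <- function(n_genes, tail_prob) {
  if (!is.numeric(n_genes) || n_genes < 0)
    stop("n_genes must be a non-negative count")
  if (!is.numeric(tail_prob) || tail_prob < 0 || tail_prob > 1)
    stop("tail_prob must be a probability")
  n_genes * tail_prob
}

#' Exact binomial enrichment test
#'
#' One-sided binomial tail probability, computed in log space so extreme
#' tails do not underflow; `log10_p` carries the exact bound even when
#' `p_value` underflows to zero.
#'
#' @param observed observed count of successes.
#' @param n number of trials.
#' @param p0 null success probability, in (0, 1).
#' @param direction `"greater"` (enrichment, upper tail) or `"less"`.
#' @return list of class `enrichment_result`: `observed`, `expected`, `n`,
#'   `p0`, `p_value`, `log10_p`, `odds_ratio`.
#' @export
binomial_enrichment <- function(observed, n, p0,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1)
    stop("p0 must be in (0, 1)")
  if (!is.numeric(observed) || !is.numeric(n) || observed < 0 ||
      observed > n)
    stop("need 0 <= observed <= n")
  logp <- if (direction == "greater") {
    stats::pbinom(observed - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  } else {
    stats::pbinom(observed, n, p0, lower.tail = TRUE, log.p = TRUE)
  }
  expected <- n * p0
  oratio <- if (observed < n && expected > 0 && expected < n) {
    (observed / (n - observed)) / (expected / (n - expected))
  } else {
    Inf
  }
  structure(list(observed = observed, expected = expected, n = n, p0 = p0,
                 p_value = exp(logp), log10_p = logp / log(10),
                 odds_ratio = oratio),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> observed %g of %g (expected %.4g), log10 p = %.4g, OR = %.3g\n",
    x$observed, x$n, x$expected, x$log10_p, x$odds_ratio))
  invisible(x)
}

#' Probability that all predicted directions agree by chance
#'
#' Product of per-protein chance-match probabilities; an empty input is the
#' empty product, 1.
#'
#' @param per_protein_match_probs vector of probabilities in (0, 1].
#' @return single probability.
#' @export
directional_agreement_p <- function(per_protein_match_probs) {
  if (length(per_protein_match_probs) == 0) return(1)
  p <- as.numeric(per_protein_match_probs)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("match probabilities must lie in (0, 1]")
  prod(p)
}

#' Time-point scrambling control
#'
#' Permutes the order of each protein's aligned measurements with a seeded
#' generator, reruns the delayed double cross-validation, and records the
#' median cross-validated correlation; repeated `n_perm` times this gives a
#' null distribution against which the observed median can be compared.
#'
#' @inheritParams fit_dataset
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return numeric vector of length `n_perm` of scrambled median
#'   correlations.
#' @export
scramble_control <- function(dataset, n_perm, seed,
                             delays = build_delay_grid(200L, 24),
                             n_lams = 50L, eps = 1e-4) {
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("n_perm must be >= 1")
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) {
    rhos <- vapply(dataset, function(rec) {
      al <- align_timepoints(rec$gene$times, rec$protein$y)
      obs <- al$protein$values
      perm <- sample.int(length(obs))
      p_perm <- protein_series(rec$protein$protein_id,
                               rec$protein$gene_id,
                               obs[perm], unclass(al$grid))
      oos <- double_cv_predict(rec$gene, p_perm, delays = delays,
                               n_lams = n_lams, eps = eps)
      pearson(oos$predicted, oos$observed)
    }, numeric(1))
    stats::median(rhos, na.rm = TRUE)
  }, numeric(1))
}
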