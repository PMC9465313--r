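# Differential predicted-protein (DEPP) screening of case/control cohorts:
# z-normalization, coefficient-weighted protein scores, Kruskal-Wallis
# tests, Benjamini-Hochberg FDR and the model-gain report.

#' Row-wise z-normalization of a cohort matrix
#'
#' Each transcript (row) is centered and scaled to unit population standard
#' deviation across samples; zero-variance rows map to all zeros.
#'
#' @param counts numeric matrix, transcripts x samples (>= 2 samples).
#' @return matrix of the same shape.
#' @export
znormalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stop("z-normalization needs at least 2 samples")
  if (any(!is.finite(counts)))
    stop("counts must be finite")
  mu <- rowMeans(counts)
  cc <- counts - mu
  s <- sqrt(rowMeans(cc^2))
  z <- cc / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Predicted-protein score for every cohort sample
#'
#' Per-sample weighted sum of z-normalized transcript rows, weights being
#' the fitted model coefficients. Transcripts with nonzero coefficients
#' that are absent from the cohort are dropped with a warning (their
#' z-score is treated as zero); if no nonzero-coefficient transcript
#' overlaps the cohort the protein is skipped (`NULL` with a warning).
#'
#' @param z z-normalized cohort matrix with transcript rownames (see
#'   [znormalize()]).
#' @param fit a `model_fit` (or any list with named `beta`).
#' @return named numeric score vector with attribute `n_transcripts_used`,
#'   or `NULL`.
#' @export
predict_protein_cohort <- function(z, fit) {
  b <- fit$beta[fit$beta != 0]
  if (length(b) == 0) {
    warning("model for ", fit$protein_id, " has no nonzero coefficients")
    return(NULL)
  }
  present <- intersect(names(b), rownames(z))
  missing <- setdiff(names(b), present)
  if (length(missing))
    warning("protein ", fit$protein_id, ": transcripts absent from cohort: ",
            paste(missing, collapse = ", "))
  if (length(present) == 0) {
    warning("protein ", fit$protein_id,
            ": no model transcript found in cohort, skipping")
    return(NULL)
  }
  score <- as.numeric(crossprod(z[present, , drop = FALSE], b[present]))
  names(score) <- colnames(z)
  attr(score, "n_transcripts_used") <- length(present)
  score
}

#' Kruskal-Wallis rank test
#'
#' Midrank-tied H statistic with tie correction and a chi-square p-value on
#' `groups - 1` degrees of freedom. All-tied inputs give `H = 0`, `p = 1`.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups, each with >= 2 members).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  g <- factor(groups)
  tab <- table(g)
  if (nlevels(g) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each")
  n <- length(values)
  df <- nlevels(g) - 1L
  if (all(values == values[1]))
    return(list(statistic = 0, p_value = 1, df = df))
  r <- rank(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / as.numeric(tab)) - 3 * (n + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / C
  list(statistic = H,
       p_value = stats::pchisq(H, df, lower.tail = FALSE),
       df = df)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return vector of q-values (monotone in the sorted order, capped at 1).
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Differential predicted-protein analysis of a cohort
#'
#' Per protein in the atlas: z-normalize the cohort, compute the
#' coefficient-weighted protein score, test it between groups with a
#' Kruskal-Wallis test, then adjust across all tested proteins with
#' Benjamini-Hochberg. Proteins without usable transcripts are skipped
#' (recorded in the `skipped` attribute).
#'
#' @param cohort a [cohort_matrix()].
#' @param atlas list of `model_fit` objects (see [fit_dataset()] or
#'   [atlas_from_truth()]).
#' @return data.frame of class `depp_result`, sorted by q then p, with
#'   columns `protein_id`, `kw_stat`, `p_value`, `q_value`,
#'   `n_transcripts_used`; attributes `scores` (proteins x samples matrix)
#'   and `skipped`.
#' @export
depp_analysis <- function(cohort, atlas) {
  if (!inherits(cohort, "cohort_matrix"))
    stop("cohort must be a cohort_matrix")
  z <- znormalize(cohort$counts)
  rows <- list()
  scores <- list()
  skipped <- character(0)
  for (fit in atlas) {
    sc <- withCallingHandlers(
      predict_protein_cohort(z, fit),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(sc)) {
      skipped <- c(skipped, fit$protein_id)
      next
    }
    kw <- kruskal_wallis(sc, cohort$group_labels)
    rows[[fit$protein_id]] <- data.frame(
      protein_id = fit$protein_id,
      kw_stat = kw$statistic,
      p_value = kw$p_value,
      n_transcripts_used = attr(sc, "n_transcripts_used"),
      stringsAsFactors = FALSE)
    scores[[fit$protein_id]] <- sc
  }
  if (length(rows) == 0) {
    out <- data.frame(protein_id = character(0), kw_stat = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      n_transcripts_used = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$q_value <- bh_fdr(out$p_value)
    out <- out[order(out$q_value, out$p_value, out$protein_id), ,
               drop = FALSE]
    out <- out[, c("protein_id", "kw_stat", "p_value", "q_value",
                   "n_transcripts_used")]
    rownames(out) <- NULL
  }
  attr(out, "scores") <- if (length(scores))
    do.call(rbind, scores) else NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("depp_result", class(out))
  out
}

#' Per-transcript Kruskal-Wallis tests for the transcripts entering models
#'
#' @inheritParams depp_analysis
#' @return named vector of nominal p-values, one per transcript with a
#'   nonzero coefficient in any atlas model that is present in the cohort.
#' @export
transcript_tests <- function(cohort, atlas) {
  used <- unique(unlist(lapply(atlas, function(f)
    names(f$beta)[f$beta != 0])))
  used <- intersect(used, rownames(cohort$counts))
  z <- znormalize(cohort$counts)
  vapply(used, function(tx)
    kruskal_wallis(z[tx, ], cohort$group_labels)$p_value, numeric(1))
}

#' Model-gain report: predicted proteins versus ingoing splice variants
#'
#' Compares the fraction of predicted proteins that are nominally
#' differentially expressed with the same fraction among the splice
#' variants entering the models, together with a binomial comparison of the
#' observed protein count against the transcript-level fraction.
#'
#' @param depp a `depp_result` from [depp_analysis()].
#' @param transcript_p named vector of per-transcript nominal p-values
#'   (see [transcript_tests()]).
#' @param alpha nominal significance level.
#' @return list with `fraction_protein`, `fraction_transcript`,
#'   `n_proteins`, `n_transcripts`, `alpha` and `enrichment` (a
#'   [binomial_enrichment()] result; the transcript fraction is clamped
#'   away from 0 and 1 by half a count when used as the null probability).
#' @export
model_gain <- function(depp, transcript_p, alpha = 0.05) {
  if (nrow(depp) == 0 || length(transcript_p) == 0)
    stop("model_gain needs non-empty protein and transcript test results")
  fp <- mean(depp$p_value < alpha)
  ft <- mean(transcript_p < alpha)
  nt <- length(transcript_p)
  p0 <- min(max(ft, 0.5 / nt), 1 - 0.5 / nt)
  list(fraction_protein = fp,
       fraction_transcript = ft,
       n_proteins = nrow(depp),
       n_transcripts = nt,
       alpha = alpha,
       enrichment = binomial_enrichment(sum(depp$p_value < alpha),
                                        nrow(depp), p0))
}
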