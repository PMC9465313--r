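#' One gene's splice-variant expression matrix on a time grid
#'
#' @param gene_id gene identifier.
#' @param transcript_ids character vector of transcript (splice-variant)
#'   identifiers, one per row of `X`.
#' @param X numeric matrix, transcripts x time points.
#' @param times sampling times (hours).
#' @return list of class `ts_gene`.
#' @export
ts_gene <- function(gene_id, transcript_ids, X, times) {
  times <- grid_times(times)
  X <- as.matrix(X)
  if (nrow(X) < 1 || nrow(X) != length(transcript_ids))
    stop("X needs one row per transcript id")
  if (ncol(X) != length(times))
    stop("X needs one column per time point")
  if (any(!is.finite(X)))
    stop("transcript abundances must be finite")
  storage.mode(X) <- "double"
  dimnames(X) <- list(as.character(transcript_ids), NULL)
  structure(list(gene_id = as.character(gene_id),
                 transcript_ids = as.character(transcript_ids),
                 X = X, times = times),
            class = "ts_gene")
}

#' @export
print.ts_gene <- function(x, ...) {
  cat(sprintf("<ts_gene> %s: %d transcripts x %d time points\n",
              x$gene_id, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' One protein's abundance trajectory
#'
#' @param protein_id protein identifier.
#' @param gene_id identifier of the encoding gene.
#' @param values protein abundance measurements.
#' @param times sampling times (hours).
#' @return list of class `protein_series` with a `series` in `$y`.
#' @export
protein_series <- function(protein_id, gene_id, values, times) {
  structure(list(protein_id = as.character(protein_id),
                 gene_id = as.character(gene_id),
                 y = series(values, times)),
            class = "protein_series")
}

#' @export
print.protein_series <- function(x, ...) {
  cat(sprintf("<protein_series> %s (gene %s): %d points\n",
              x$protein_id, x$gene_id, length(x$y$values)))
  invisible(x)
}

# internal constructor for a fitted per-protein model
model_fit <- function(protein_id, gene_id, beta, intercept, lambda, tau,
                      loocv_mse, n_points) {
  structure(list(protein_id = as.character(protein_id),
                 gene_id = as.character(gene_id),
                 beta = beta, intercept = intercept,
                 lambda = lambda, tau = tau,
                 loocv_mse = loocv_mse,
                 n_nonzero = sum(beta != 0),
                 n_points = n_points),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model_fit> %s (gene %s): tau = %.3g h, lambda = %.3g, %d/%d nonzero, LOO MSE = %.3g\n",
    x$protein_id, x$gene_id, x$tau, x$lambda, x$n_nonzero, length(x$beta),
    x$loocv_mse))
  invisible(x)
}

#' Transcripts-by-samples cohort with group labels
#'
#' @param counts numeric matrix, transcripts x samples (raw counts or
#'   abundances); rownames are transcript ids.
#' @param group_labels per-sample group labels (>= 2 groups, each with
#'   >= 2 samples).
#' @param sample_ids optional sample identifiers (default: column names).
#' @param transcript_ids optional transcript identifiers (default: row
#'   names).
#' @param gene_ids optional per-transcript gene identifiers.
#' @return list of class `cohort_matrix`.
#' @export
cohort_matrix <- function(counts, group_labels, sample_ids = NULL,
                          transcript_ids = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(transcript_ids)) transcript_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- colnames(counts)
  if (is.null(transcript_ids) || length(transcript_ids) != nrow(counts))
    stop("cohort needs one transcript id per row")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  if (length(sample_ids) != ncol(counts) ||
      length(group_labels) != ncol(counts))
    stop("sample ids and group labels must match the number of columns")
  if (any(!is.finite(counts)))
    stop("cohort abundances must be finite")
  tab <- table(group_labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("cohort needs >= 2 groups with >= 2 samples each")
  if (is.null(gene_ids)) gene_ids <- rep(NA_character_, nrow(counts))
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids must have one entry per transcript row")
  rownames(counts) <- transcript_ids
  colnames(counts) <- sample_ids
  structure(list(counts = counts,
                 transcript_ids = as.character(transcript_ids),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 group_labels = as.character(group_labels)),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  tab <- table(x$group_labels)
  cat(sprintf("<cohort_matrix> %d transcripts x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
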