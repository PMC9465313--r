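# TSV readers and writers. All tables are tab-separated with a header row;
# numeric values are written with 17 significant digits so write/read
# round-trips are lossless; identifiers are opaque strings.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("file ", path, " is missing required columns: ",
         paste(miss, collapse = ", "))
}

# Parse column labels like "0h", "30min", "0.5h", "5d" into hours.
# Returns NULL if any label is not temporal.
parse_time_labels <- function(labels) {
  m <- regmatches(labels,
                  regexec("^([0-9]*\\.?[0-9]+)(h|min|d)$", labels))
  if (any(vapply(m, length, integer(1)) != 3)) return(NULL)
  val <- as.numeric(vapply(m, `[`, character(1), 2))
  unit <- vapply(m, `[`, character(1), 3)
  unname(val * c(h = 1, min = 1 / 60, d = 24)[unit])
}

numeric_cells <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("file ", path, ": non-numeric value '", v[bad[1]],
             "' in column '", cl, "', row ", bad[1])
      v <- vn
    }
    if (any(is.na(v)))
      stop("file ", path, ": missing value in column '", cl, "'")
    df[[cl]] <- v
  }
  df
}

#' Read a transcript expression table
#'
#' Expects a TSV with header columns `gene_id`, `transcript_id`, followed
#' either by time-point columns (labels with an `h`, `min` or `d` suffix,
#' e.g. `0h`, `30min`, `5d`; converted to hours) or by sample-id columns.
#'
#' @param path path to the TSV file.
#' @return list with `type` (`"timecourse"` or `"cohort"`), `X`
#'   (transcripts x columns matrix with transcript rownames), `gene_ids`
#'   (per row), and either `times` (hours, columns sorted by time) or
#'   `sample_ids`.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("gene_id", "transcript_id"), path)
  value_cols <- setdiff(names(df), c("gene_id", "transcript_id"))
  if (length(value_cols) < 2)
    stop("file ", path, " needs at least two value columns")
  dup <- df$transcript_id[duplicated(df$transcript_id)]
  if (length(dup))
    stop("file ", path, ": duplicated transcript id(s): ",
         paste(unique(dup), collapse = ", "))
  df <- numeric_cells(df, value_cols, path)
  X <- as.matrix(df[, value_cols, drop = FALSE])
  rownames(X) <- df$transcript_id
  times <- parse_time_labels(value_cols)
  if (!is.null(times)) {
    o <- order(times)
    list(type = "timecourse", X = X[, o, drop = FALSE],
         gene_ids = df$gene_id, times = times[o])
  } else {
    list(type = "cohort", X = X, gene_ids = df$gene_id,
         sample_ids = value_cols)
  }
}

#' Read a protein abundance table
#'
#' TSV with columns `protein_id`, `gene_id`, then time-point columns
#' (`h`/`min`/`d` suffix).
#'
#' @param path path to the TSV file.
#' @return named list of [protein_series()], keyed by protein id.
#' @export
read_protein_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("protein_id", "gene_id"), path)
  value_cols <- setdiff(names(df), c("protein_id", "gene_id"))
  times <- parse_time_labels(value_cols)
  if (is.null(times))
    stop("file ", path, ": protein columns must be time points ",
         "(suffix h, min or d)")
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup))
    stop("file ", path, ": duplicated protein id(s): ",
         paste(unique(dup), collapse = ", "))
  df <- numeric_cells(df, value_cols, path)
  o <- order(times)
  out <- lapply(seq_len(nrow(df)), function(i)
    protein_series(df$protein_id[i], df$gene_id[i],
                   as.numeric(df[i, value_cols, drop = TRUE])[o],
                   times[o]))
  stats::setNames(out, df$protein_id)
}

#' Read a gene/transcript/protein mapping table
#'
#' @param path TSV with columns `gene_id`, `transcript_id`, `protein_id`.
#' @return validated data.frame; errors if a transcript id repeats within
#'   a gene or a protein maps to more than one gene.
#' @export
read_mapping <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("gene_id", "transcript_id", "protein_id"), path)
  dup <- duplicated(df[, c("gene_id", "transcript_id")])
  if (any(dup))
    stop("file ", path, ": transcript id(s) repeated within a gene: ",
         paste(unique(df$transcript_id[dup]), collapse = ", "))
  ng <- tapply(df$gene_id, df$protein_id,
               function(g) length(unique(g)))
  bad <- names(ng)[ng > 1]
  if (length(bad))
    stop("file ", path, ": protein(s) mapped to more than one gene: ",
         paste(bad, collapse = ", "))
  df[, c("gene_id", "transcript_id", "protein_id")]
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return data.frame with those two columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("sample_id", "group"), path)
  if (any(duplicated(df$sample_id)))
    stop("file ", path, ": duplicated sample id(s)")
  df[, c("sample_id", "group")]
}

#' Assemble gene/protein records from expression and protein tables
#'
#' Pairs each protein with the transcripts of its gene; proteins whose gene
#' has no expressed transcripts are dropped with a warning.
#'
#' @param expression result of [read_expression_table()] (type
#'   `"timecourse"`) or a path.
#' @param proteins result of [read_protein_table()] or a path.
#' @return list of records with elements `gene` and `protein`, the dataset
#'   format consumed by [fit_dataset()] and [evaluate_models()].
#' @export
read_dataset <- function(expression, proteins) {
  if (is.character(expression))
    expression <- read_expression_table(expression)
  if (is.character(proteins)) proteins <- read_protein_table(proteins)
  if (expression$type != "timecourse")
    stop("expression table must have time-point columns")
  recs <- list()
  skipped <- character(0)
  for (p in proteins) {
    rows <- which(expression$gene_ids == p$gene_id)
    if (length(rows) == 0) {
      skipped <- c(skipped, p$protein_id)
      next
    }
    g <- ts_gene(p$gene_id, rownames(expression$X)[rows],
                 expression$X[rows, , drop = FALSE], expression$times)
    recs[[p$protein_id]] <- list(gene = g, protein = p)
  }
  if (length(skipped))
    warning("proteins without expressed transcripts were skipped: ",
            paste(skipped, collapse = ", "))
  recs
}

#' Read a cohort (expression + sample sheet) for DEPP screening
#'
#' @param counts_path cohort expression TSV (sample-id value columns).
#' @param samples_path sample sheet TSV.
#' @return a [cohort_matrix()].
#' @export
read_cohort <- function(counts_path, samples_path) {
  ex <- read_expression_table(counts_path)
  if (ex$type != "cohort")
    stop("cohort table must have sample-id value columns")
  ss <- read_sample_sheet(samples_path)
  miss <- setdiff(ex$sample_ids, ss$sample_id)
  if (length(miss))
    stop("samples missing from sample sheet: ",
         paste(miss, collapse = ", "))
  grp <- ss$group[match(ex$sample_ids, ss$sample_id)]
  cohort_matrix(ex$X, grp, sample_ids = ex$sample_ids,
                gene_ids = ex$gene_ids)
}

time_labels <- function(times) paste0(fmt_num(times), "h")

#' Write a transcript expression table
#'
#' @param dataset list of gene/protein records (see [read_dataset()]), or a
#'   [cohort_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  if (inherits(dataset, "cohort_matrix")) {
    df <- data.frame(gene_id = dataset$gene_ids,
                     transcript_id = dataset$transcript_ids,
                     stringsAsFactors = FALSE)
    vals <- as.data.frame(apply(dataset$counts, 2, fmt_num),
                          stringsAsFactors = FALSE)
    names(vals) <- dataset$sample_ids
  } else {
    rows <- do.call(rbind, lapply(dataset, function(rec)
      cbind(gene_id = rec$gene$gene_id,
            transcript_id = rec$gene$transcript_ids,
            matrix(fmt_num(t(rec$gene$X)), nrow = nrow(rec$gene$X),
                   byrow = TRUE))))
    df <- data.frame(gene_id = rows[, 1], transcript_id = rows[, 2],
                     stringsAsFactors = FALSE)
    vals <- as.data.frame(rows[, -(1:2), drop = FALSE],
                          stringsAsFactors = FALSE)
    names(vals) <- time_labels(dataset[[1]]$gene$times)
  }
  write_tsv(cbind(df, vals), path)
  invisible(path)
}

#' Write a protein abundance table
#'
#' @inheritParams write_expression_table
#' @export
write_protein_table <- function(dataset, path) {
  rows <- do.call(rbind, lapply(dataset, function(rec)
    c(rec$protein$protein_id, rec$protein$gene_id,
      fmt_num(rec$protein$y$values))))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("protein_id", "gene_id",
                 time_labels(dataset[[1]]$protein$y$times))
  rownames(df) <- NULL
  write_tsv(df, path)
  invisible(path)
}

#' Write a sample sheet
#'
#' @param cohort a [cohort_matrix()].
#' @param path output TSV path.
#' @export
write_sample_sheet <- function(cohort, path) {
  write_tsv(data.frame(sample_id = cohort$sample_ids,
                       group = cohort$group_labels), path)
  invisible(path)
}

coef_string <- function(beta) {
  paste(sprintf("%s:%s", names(beta), fmt_num(beta)), collapse = ";")
}

parse_coef_string <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                  vapply(parts, `[`, character(1), 1))
}

#' Write a model atlas
#'
#' One row per fitted protein model: `protein_id`, `gene_id`, `tau_hours`,
#' `lambda`, `loocv_mse`, `intercept`, `n_nonzero`, and the per-transcript
#' coefficients as `transcript:beta` pairs joined with `;`.
#'
#' @param fits list of `model_fit` objects.
#' @param path output TSV path.
#' @export
write_model_atlas <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(protein_id = f$protein_id, gene_id = f$gene_id,
               tau_hours = fmt_num(f$tau), lambda = fmt_num(f$lambda),
               loocv_mse = fmt_num(f$loocv_mse),
               intercept = fmt_num(f$intercept),
               n_nonzero = f$n_nonzero,
               coefficients = coef_string(f$beta),
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(protein_id = character(0), gene_id = character(0),
                     tau_hours = character(0), lambda = character(0),
                     loocv_mse = character(0), intercept = character(0),
                     n_nonzero = integer(0), coefficients = character(0))
  write_tsv(df, path)
  invisible(path)
}

#' Read a model atlas written by [write_model_atlas()]
#'
#' @param path atlas TSV path.
#' @return named list of `model_fit` objects.
#' @export
read_model_atlas <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("protein_id", "gene_id", "tau_hours", "lambda",
                        "loocv_mse", "intercept", "coefficients"), path)
  fits <- lapply(seq_len(nrow(df)), function(i) {
    beta <- parse_coef_string(df$coefficients[i])
    model_fit(df$protein_id[i], df$gene_id[i], beta,
              as.numeric(df$intercept[i]), as.numeric(df$lambda[i]),
              as.numeric(df$tau_hours[i]), as.numeric(df$loocv_mse[i]),
              NA_integer_)
  })
  stats::setNames(fits, df$protein_id)
}

#' Write a DEPP result table
#'
#' @param results a `depp_result` from [depp_analysis()] (an empty result
#'   yields a valid header-only file).
#' @param path output TSV path.
#' @export
write_depp <- function(results, path) {
  df <- data.frame(protein_id = results$protein_id,
                   kw_stat = fmt_num(results$kw_stat),
                   p_value = fmt_num(results$p_value),
                   q_value = fmt_num(results$q_value),
                   n_transcripts_used = results$n_transcripts_used,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Default run configuration
#'
#' @return named list of the tunable pipeline settings: delay grid size and
#'   horizon, penalty path size and floor ratio, significance level, FDR
#'   threshold, interpolation/extrapolation policy, tie-break policy, seed.
#' @export
default_config <- function() {
  list(delay_n = 200L, delay_max = 24, n_lams = 50L, lambda_eps = 1e-4,
       alpha = 0.05, fdr = 0.05, extrapolation = "clamp",
       tie_break = "smallest-tau-largest-lambda", seed = 1L)
}

#' Read and validate a JSON run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path JSON file path.
#' @return validated configuration list (see [default_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  if (cfg$delay_n < 2 || cfg$delay_max <= 0 || cfg$n_lams < 2 ||
      cfg$lambda_eps <= 0 || cfg$lambda_eps >= 1 ||
      cfg$alpha <= 0 || cfg$alpha > 1 || cfg$fdr <= 0 || cfg$fdr > 1)
    stop("invalid configuration values in ", path)
  if (!cfg$extrapolation %in% "clamp")
    stop("unsupported extrapolation policy: ", cfg$extrapolation)
  cfg
}
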