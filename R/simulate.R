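# Ground-truth synthetic data: paired transcript/protein time courses
# generated as a delayed linear combination of smooth splice-variant
# trajectories plus noise, and case/control cohorts with isoform-level
# group effects.

# Strictly positive latent trajectory for one transcript: a log-normal
# baseline modulated by one or two saturating-rise or pulse response
# kernels on multi-hour timescales, evaluated at the mRNA sampling knots
# and linearly interpolated between them (constant before the first and
# after the last knot). The generated world therefore contains no dynamics
# below the resolution of the sampling design, matching the
# piecewise-linear assumption the models make. Consumes RNG.
draw_trajectory <- function(times) {
  baseline <- stats::rlnorm(1, meanlog = 3, sdlog = 0.7)
  kern <- function() {
    type <- sample(c("sat", "pulse"), 1)
    amp <- stats::runif(1, -1.5, 1.5)
    tc <- stats::runif(1, 0.5, 12)
    if (type == "sat") function(t) amp * t / (t + tc)
    else function(t) amp * (t / tc) * exp(1 - t / tc)
  }
  k1 <- kern()
  k2 <- if (stats::runif(1) < 0.5) kern() else function(t) 0
  knots <- baseline * exp(k1(times) + k2(times))
  stats::approxfun(times, knots, method = "linear", rule = 2)
}

#' Simulate one gene/protein pair from known ground truth
#'
#' Transcript trajectories are positive response curves sampled at the mRNA
#' knots and piecewise-linear between them; the protein measured at time
#' `s` equals the coefficient-weighted transcript combination evaluated at
#' `s - tau_true` (clamped at the trajectory boundaries) plus centered
#' Gaussian noise of standard deviation `sigma`.
#'
#' @param truth list with `gene_id`, `beta_true` (one coefficient per
#'   transcript, mixed signs allowed), `tau_true` (hours, >= 0) and
#'   `sigma` (noise sd, >= 0).
#' @param times mRNA sampling times (hours).
#' @param protein_times protein sampling times (hours).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `gene` (a [ts_gene()]), `protein` (a
#'   [protein_series()]), `noiseless` (protein values before noise) and
#'   `truth` (input truth augmented with `transcript_ids`).
#' @export
simulate_gene <- function(truth, times = c(0, 0.5, 1, 2, 6, 24),
                          protein_times = c(0, 1, 2, 6, 24, 120),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.numeric(truth$beta_true), length(truth$beta_true) >= 1,
            truth$tau_true >= 0, truth$sigma >= 0)
  k <- length(truth$beta_true)
  trajs <- replicate(k, draw_trajectory(times), simplify = FALSE)
  tx_ids <- paste0(truth$gene_id, ".t", seq_len(k))
  X <- t(vapply(trajs, function(f) f(times), numeric(length(times))))
  tq <- pmax(protein_times - truth$tau_true, 0)
  noiseless <- as.numeric(
    truth$beta_true %*%
      t(vapply(trajs, function(f) f(tq), numeric(length(tq)))))
  yv <- noiseless
  if (truth$sigma > 0)
    yv <- yv + stats::rnorm(length(yv), 0, truth$sigma)
  truth$transcript_ids <- tx_ids
  list(gene = ts_gene(truth$gene_id, tx_ids, X, times),
       protein = protein_series(paste0(truth$gene_id, ".prot"),
                                truth$gene_id, yv, protein_times),
       noiseless = noiseless,
       truth = truth)
}

#' Simulate a dataset of independent genes with known ground truth
#'
#' Genes get heterogeneous transcript counts, log-normal coefficient
#' magnitudes with optional sign flips (so anti-correlated isoform pairs
#' occur), delays drawn from a discrete distribution, and per-gene noise
#' scaled to the signal.
#'
#' @param n_genes number of genes (>= 1).
#' @param transcript_counts candidate transcript counts per gene.
#' @param transcript_probs sampling probabilities for `transcript_counts`.
#' @param delay_values candidate true delays in hours.
#' @param delay_probs sampling probabilities (default uniform).
#' @param sigma_rel protein noise sd as a fraction of the noiseless
#'   protein trajectory's (population) sd.
#' @param p_negative probability that a gene carries a negative
#'   coefficient (one randomly chosen transcript is flipped).
#' @param times,protein_times sampling grids (hours).
#' @param seed RNG seed.
#' @return list with `genes` (list of [simulate_gene()] records) and
#'   `truth` (list of per-gene truth records).
#' @export
simulate_dataset <- function(n_genes,
                             transcript_counts = 1:5,
                             transcript_probs = c(0.3, 0.3, 0.2, 0.15, 0.05),
                             delay_values = c(0, 2, 6),
                             delay_probs = NULL,
                             sigma_rel = 0.05,
                             p_negative = 0.3,
                             times = c(0, 0.5, 1, 2, 6, 24),
                             protein_times = c(0, 1, 2, 6, 24, 120),
                             seed = NULL) {
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("n_genes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  genes <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("g%04d", i)
    k <- if (length(transcript_counts) == 1) transcript_counts
         else sample(transcript_counts, 1, prob = transcript_probs)
    # one major isoform carries most of the translational weight; minor
    # isoforms modulate at roughly a third of its magnitude
    beta <- stats::rlnorm(k, meanlog = log(0.6), sdlog = 0.4)
    major <- sample.int(k, 1)
    beta[major] <- stats::rlnorm(1, meanlog = log(2), sdlog = 0.3)
    if (stats::runif(1) < p_negative) {
      flip <- sample.int(k, 1)
      beta[flip] <- -beta[flip]
    }
    tau <- if (length(delay_values) == 1) delay_values
           else sample(delay_values, 1, prob = delay_probs)
    # two-pass: draw the noiseless signal first, then scale the noise to it
    tr <- list(gene_id = gid, beta_true = beta, tau_true = tau, sigma = 0)
    rec <- simulate_gene(tr, times = times, protein_times = protein_times)
    s_sig <- sqrt(mean((rec$noiseless - mean(rec$noiseless))^2))
    sigma <- sigma_rel * s_sig
    yv <- rec$noiseless
    if (sigma > 0) yv <- yv + stats::rnorm(length(yv), 0, sigma)
    rec$protein <- protein_series(rec$protein$protein_id, gid, yv,
                                  protein_times)
    rec$truth$sigma <- sigma
    genes[[i]] <- rec
    truth[[i]] <- rec$truth
  }
  list(genes = genes, truth = truth)
}

#' Turn ground-truth coefficients into a model atlas
#'
#' Useful for exercising the cohort pipeline with exactly known models.
#'
#' @param truth list of truth records (from [simulate_dataset()]).
#' @return list of `model_fit` objects with `beta = beta_true`,
#'   `tau = tau_true` and `lambda = 0`.
#' @export
atlas_from_truth <- function(truth) {
  lapply(truth, function(tr) {
    beta <- stats::setNames(tr$beta_true, tr$transcript_ids)
    model_fit(paste0(tr$gene_id, ".prot"), tr$gene_id, beta, 0, 0,
              tr$tau_true, NA_real_, NA_integer_)
  })
}

#' Simulate a case/control cohort with isoform-level group effects
#'
#' Per gene, transcript abundances share a dominant latent factor across
#' samples (strong inter-subject covariation) plus independent noise. In
#' `effect_mode = "combination"` the group effect is injected along the
#' true coefficient direction, so the coefficient-weighted protein score
#' separates the groups while individual transcripts need not (the shared
#' factor cancels in anti-correlated combinations); in `"single"` only the
#' transcript with the largest absolute coefficient shifts. Abundances are
#' affine in the latent values (`100 + 10 * latent`), which row-wise
#' z-normalization removes exactly.
#'
#' @param truth list of truth records (see [simulate_dataset()]).
#' @param n_case,n_control group sizes (>= 2).
#' @param effect_size group shift in latent units along the effect
#'   direction.
#' @param effect_mode `"combination"` or `"single"`.
#' @param shared_sd sd of the per-gene latent factor shared by all
#'   transcripts of a gene.
#' @param noise_sd sd of the per-transcript independent noise.
#' @param seed RNG seed.
#' @return a [cohort_matrix()] (cases first) with attribute `truth`.
#' @export
simulate_cohort <- function(truth, n_case = 12, n_control = 12,
                            effect_size = 0.8,
                            effect_mode = c("combination", "single"),
                            shared_sd = 2, noise_sd = 0.4, seed = NULL) {
  effect_mode <- match.arg(effect_mode)
  if (n_case < 2 || n_control < 2)
    stop("each group needs >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  n <- n_case + n_control
  grp <- c(rep(1, n_case), rep(0, n_control))
  blocks <- lapply(truth, function(tr) {
    k <- length(tr$beta_true)
    w <- switch(effect_mode,
                combination = tr$beta_true / sqrt(sum(tr$beta_true^2)),
                single = {
                  w0 <- numeric(k)
                  w0[which.max(abs(tr$beta_true))] <- 1
                  w0
                })
    shared <- stats::rnorm(n, 0, shared_sd)
    latent <- matrix(shared, nrow = k, ncol = n, byrow = TRUE) +
      matrix(stats::rnorm(k * n, 0, noise_sd), nrow = k) +
      outer(w, grp * effect_size)
    m <- 100 + 10 * latent
    rownames(m) <- tr$transcript_ids
    m
  })
  counts <- do.call(rbind, blocks)
  colnames(counts) <- sprintf("S%03d", seq_len(n))
  ch <- cohort_matrix(counts,
                      group_labels = c(rep("case", n_case),
                                       rep("control", n_control)),
                      gene_ids = unlist(lapply(truth, function(tr)
                        rep(tr$gene_id, length(tr$beta_true)))))
  attr(ch, "truth") <- truth
  ch
}
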