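test_that("delayed_design shifts targets and lags regressors as documented", {
  pair <- make_pl_pair(beta = c(1.5, -0.5), tau = 0, seed = 3)
  d0 <- delayed_design(pair$gene, pair$protein, 0)
  expect_equal(d0$y, d0$protein_obs)
  expect_equal(unname(d0$Xq), unname(d0$X[, seq_along(d0$times)]),
               tolerance = 1e-12)

  # tau = 0.5 on the [0, 1, 2, 6, 24] grid: targets at [0.5, ..., 24.5],
  # the last clamped to the 24 h value
  d <- delayed_design(pair$gene, pair$protein, 0.5)
  al <- align_timepoints(pair$gene$times, pair$protein$y)
  expect_equal(d$y, interpolate_linear(al$protein,
                                       c(0.5, 1.5, 2.5, 6.5, 24.5)))
  expect_equal(d$y[5], al$protein$values[5])

  # piecewise-linear protein, tau inside a segment: manual oracle
  p <- protein_series("p", "g", c(0, 10, 10, 10, 10), c(0, 1, 2, 6, 24))
  dm <- delayed_design(pair$gene, p, 0.25)
  expect_equal(dm$y[1], 2.5)

  expect_error(delayed_design(pair$gene, pair$protein, -1), "non-negative")
})

test_that("loocv_mse equals an explicit per-fold oracle", {
  pair <- make_pl_pair(beta = c(1, -1), tau = 0, seed = 4, sigma = 0.5)
  g <- pair$gene; p <- pair$protein
  for (tau in c(0, 1.3)) {
    for (lam in c(0.3, 1.0)) {
      d <- delayed_design(g, p, tau)
      Xq <- t(d$Xq)
      errs <- sapply(seq_len(5), function(i) {
        f <- glmnet::glmnet(Xq[-i, ], d$protein_obs[-i], alpha = 1,
                            lambda = lam / 2, standardize = TRUE,
                            thresh = 1e-16, maxit = 1e7)
        (d$protein_obs[i] -
           as.numeric(predict(f, Xq[i, , drop = FALSE])))^2
      })
      expect_equal(loocv_mse(g, p, tau, lam), mean(errs),
                   tolerance = 1e-6)
    }
  }

  # null model: at lambda >= lambda_max each fold predicts its own
  # training mean, so the residuals are centered values scaled n/(n-1)
  obs <- align_timepoints(g$times, p$y)$protein$values
  n <- length(obs)
  big <- 10 * lambda_max(t(delayed_design(g, p, 0)$X), obs)
  expect_equal(loocv_mse(g, p, 0, big),
               mean(((obs - mean(obs)) * n / (n - 1))^2), tolerance = 1e-10)

  p3 <- protein_series("p", "g", c(1, 2), c(0, 1))
  g3 <- ts_gene("g", "t1", matrix(c(1, 2), 1), c(0, 1))
  expect_error(loocv_mse(g3, p3, 0, 0.1), "at least 3")
})

test_that("fit_protein_model selects the CV-optimal pair and recovers truth", {
  # single transcript, y = x, no noise
  tms <- c(0, 1, 2, 6, 24)
  x <- c(3, 8, 10, 6, 2)
  g <- ts_gene("g", "t1", matrix(x, 1), tms)
  p <- protein_series("p", "g", x, tms)
  fit <- fit_protein_model(g, p, delays = build_delay_grid(5, 8),
                           n_lams = 20)
  expect_equal(fit$tau, 0)
  expect_equal(unname(fit$beta), 1, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-5)

  # noiseless pair with the true delay on the grid: build_delay_grid(5, 8)
  # has delays [0, 0.5, 2, 4.5, 8]; the 12 h point keeps the delayed
  # response observable at more than one lagged time
  pair <- make_pl_pair(beta = c(2, -1), tau = 2,
                       times = c(0, 1, 2, 6, 12, 24), seed = 5)
  dg <- build_delay_grid(5, 8)
  fit2 <- fit_protein_model(pair$gene, pair$protein, delays = dg,
                            n_lams = 20)
  expect_equal(fit2$tau, 2)
  expect_equal(unname(fit2$beta), c(2, -1), tolerance = 1e-4)

  # the selected pair minimizes the (tau, lambda) CV surface
  surf <- sapply(dg$delays, function(tau)
    loocv_mse(pair$gene, pair$protein, tau, fit2$lambda))
  expect_lte(fit2$loocv_mse,
             min(surf) * (1 + 1e-5) + 1e-8 * (1 + min(surf)))
  expect_equal(fit2$loocv_mse,
               loocv_mse(pair$gene, pair$protein, fit2$tau, fit2$lambda),
               tolerance = 1e-8)

  # support bound at desk sample sizes
  set.seed(6)
  for (r in 1:5) {
    pr <- make_pl_pair(beta = rnorm(3), tau = 0, seed = 20 + r,
                       sigma = 0.3)
    f <- fit_protein_model(pr$gene, pr$protein, delays = dg, n_lams = 15)
    expect_lte(f$n_nonzero, f$n_points - 1)
    expect_equal(f$n_nonzero, sum(f$beta != 0))
    expect_true(f$tau %in% dg$delays)
  }
})

test_that("double_cv_predict is exact on noiseless linear data", {
  tms <- c(0, 1, 2, 6, 24)
  x <- c(3, 8, 10, 6, 2)
  g <- ts_gene("g", "t1", matrix(x, 1), tms)
  p <- protein_series("p", "g", 3 * x + 1, tms)
  oos <- double_cv_predict(g, p, delays = build_delay_grid(4, 8),
                           n_lams = 15)
  expect_equal(oos$predicted, oos$observed, tolerance = 1e-6)
  expect_equal(oos$heldout_index, 1:5)
})

test_that("double_cv_predict matches the nested-loop oracle", {
  dg <- build_delay_grid(4, 12)
  for (r in 1:3) {
    pair <- make_pl_pair(beta = c(1.2, -0.7), tau = 2, seed = 30 + r,
                         sigma = 0.4)
    mine <- double_cv_predict(pair$gene, pair$protein, delays = dg,
                              n_lams = 12, tol = 1e-12, maxit = 1000000L)
    orac <- oracle_double_cv(pair$gene, pair$protein, dg$delays, 12)
    expect_equal(mine$predicted, orac$predicted, tolerance = 1e-6)
    expect_equal(mine$tau_used, orac$tau_used)
  }
})

test_that("the held-out protein value cannot influence its own prediction", {
  pair <- make_pl_pair(beta = c(1, 0.5), tau = 0, seed = 7, sigma = 0.3)
  dg <- build_delay_grid(4, 8)
  base <- double_cv_predict(pair$gene, pair$protein, delays = dg,
                            n_lams = 12)
  for (i in c(1, 3, 5)) {
    vals <- pair$protein$y$values
    vals[i] <- vals[i] + 37
    p2 <- protein_series("p1", "g1", vals, pair$protein$y$times)
    pert <- double_cv_predict(pair$gene, p2, delays = dg, n_lams = 12)
    expect_equal(pert$predicted[i], base$predicted[i], tolerance = 1e-10)
  }
})

test_that("scaling the protein scales the cross-validated predictions", {
  pair <- make_pl_pair(beta = c(1, -0.6), tau = 0, seed = 8, sigma = 0.2)
  dg <- build_delay_grid(4, 8)
  o1 <- double_cv_predict(pair$gene, pair$protein, delays = dg, n_lams = 12)
  p2 <- protein_series("p1", "g1", 5 * pair$protein$y$values,
                       pair$protein$y$times)
  o2 <- double_cv_predict(pair$gene, p2, delays = dg, n_lams = 12)
  expect_equal(o2$predicted, 5 * o1$predicted, tolerance = 1e-6)
})

test_that("delayed models beat the zero-delay restriction when a delay exists", {
  set.seed(9)
  dg <- build_delay_grid(6, 12)
  ratios <- sapply(1:8, function(r) {
    pair <- make_pl_pair(beta = c(1.5, -0.8), tau = 4.5, seed = 40 + r,
                         times = c(0, 1, 2, 6, 12, 24),
                         sigma = 0.2)
    od <- double_cv_predict(pair$gene, pair$protein, delays = dg,
                            n_lams = 15)
    os <- double_cv_predict(pair$gene, pair$protein, delays = delay_grid(0),
                            n_lams = 15)
    c(median((od$predicted - od$observed)^2),
      median((os$predicted - os$observed)^2))
  })
  expect_lte(median(ratios[1, ]), median(ratios[2, ]))
})

test_that("fit_dataset skips unexpressed genes with a warning", {
  pair <- make_pl_pair(beta = 1, tau = 0, seed = 10)
  dead <- list(gene = ts_gene("g0", "t0", matrix(0, 1, 5),
                              c(0, 1, 2, 6, 24)),
               protein = protein_series("p0", "g0", rnorm(5),
                                        c(0, 1, 2, 6, 24)))
  expect_warning(
    fits <- fit_dataset(list(list(gene = pair$gene, protein = pair$protein),
                             dead),
                        delays = build_delay_grid(3, 8), n_lams = 10),
    "skipped")
  expect_named(fits, "p1")
})
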