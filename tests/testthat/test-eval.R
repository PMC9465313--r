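test_that("pearson matches the textbook formula and flags degeneracy", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  x <- c(1, 4, 2, 8, 5); y <- c(2, 3, 9, 1, 4)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), num / den, tolerance = 1e-12)
  expect_true(is.na(pearson(rep(2, 5), y)))
  expect_error(pearson(1:2, 1:2), ">= 3")
})

test_that("correlation_table computes the four model classes per gene", {
  # single-transcript gene: sum and best-single coincide
  pair <- make_pl_pair(beta = 2, tau = 0, seed = 11, sigma = 0.2)
  tab <- correlation_table(list(list(gene = pair$gene,
                                     protein = pair$protein)))
  expect_equal(tab$rho_sum, tab$rho_best_single)
  expect_true(is.na(tab$rho_delayed_multi))

  # protein equal to its single transcript: every class near 1
  tms <- c(0, 1, 2, 6, 24)
  x <- c(3, 8, 10, 6, 2)
  ds <- list(p1 = list(gene = ts_gene("g", "t1", matrix(x, 1), tms),
                       protein = protein_series("p1", "g", x, tms)))
  ev <- evaluate_models(ds, delays = build_delay_grid(3, 8), n_lams = 10)
  expect_true(all(abs(ev$table[, c("rho_sum", "rho_best_single",
                                   "rho_static_multi",
                                   "rho_delayed_multi")] - 1) < 1e-6))

  # signed best-single: pick the transcript with the largest |rho|
  X <- rbind(t1 = c(1, 2, 3, 4, 5), t2 = c(10, 8, 6, 4, 2.5))
  g2 <- ts_gene("g2", rownames(X), X, tms)
  p2 <- protein_series("p2", "g2", c(9, 8, 7, 6, 5), tms)
  tab2 <- correlation_table(list(list(gene = g2, protein = p2)))
  expect_lt(tab2$rho_best_single, 0)
})

test_that("significance_threshold comes from the t distribution", {
  expect_equal(significance_threshold(5, 0.05), 0.8783, tolerance = 1e-4)
  expect_lt(significance_threshold(5, 0.9999), 1e-4)
  ns <- c(4, 5, 8, 12, 30, 100)
  expect_true(all(diff(sapply(ns, significance_threshold)) < 0))
  expect_error(significance_threshold(2), ">= 3")
})

test_that("expected_significant is the null expectation", {
  expect_equal(expected_significant(4920, 0.025), 123)
  expect_equal(expected_significant(100, 0.025), 2.5)
  expect_equal(expected_significant(0, 0.4), 0)
})

test_that("binomial_enrichment matches exhaustive enumeration and survives extreme tails", {
  for (n in c(5, 10, 12)) {
    for (p0 in c(0.1, 0.4)) {
      for (obs in c(0, 2, n)) {
        e <- binomial_enrichment(obs, n, p0)
        brute <- sum(sapply(obs:n, function(k)
          choose(n, k) * p0^k * (1 - p0)^(n - k)))
        expect_equal(e$p_value, brute, tolerance = 1e-12)
        el <- binomial_enrichment(obs, n, p0, direction = "less")
        brute_l <- sum(sapply(0:obs, function(k)
          choose(n, k) * p0^k * (1 - p0)^(n - k)))
        expect_equal(el$p_value, brute_l, tolerance = 1e-12)
      }
    }
  }

  # observing the expectation is unremarkable
  e0 <- binomial_enrichment(round(400 * 0.3), 400, 0.3)
  expect_gte(e0$p_value, 0.4)

  # the study-scale enrichment stays resolvable in log space
  ep <- binomial_enrichment(407, 4920, 0.025)
  expect_lt(ep$log10_p, -93)
  expect_equal(ep$expected, 123)
  expect_equal(ep$odds_ratio,
               (407 / (4920 - 407)) / (123 / (4920 - 123)),
               tolerance = 1e-12)

  expect_error(binomial_enrichment(5, 10, 0), "p0")
  expect_error(binomial_enrichment(11, 10, 0.5), "observed")
})

test_that("directional_agreement_p is the product of chance-match probabilities", {
  dap <- directional_agreement_p(c(rep(56 / 92, 9), rep(2 / 4, 2)))
  expect_equal(signif(dap, 2), 2.9e-3)
  expect_equal(directional_agreement_p(numeric(0)), 1)

  set.seed(14)
  probs <- runif(6, 0.2, 0.9)
  expect_equal(directional_agreement_p(probs),
               directional_agreement_p(rev(probs)))
  expect_lte(directional_agreement_p(probs), min(probs))

  # Monte-Carlo oracle: frequency of all-match under independent draws
  nrep <- 200000
  hits <- colSums(matrix(runif(nrep * length(probs)) < probs,
                         nrow = length(probs))) == length(probs)
  phat <- mean(hits)
  se <- sqrt(phat * (1 - phat) / nrep)
  expect_lt(abs(phat - directional_agreement_p(probs)), 4 * se + 1e-4)

  expect_error(directional_agreement_p(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("scramble_control is seeded and detects real signal", {
  set.seed(15)
  ds <- lapply(1:8, function(r) {
    pair <- make_pl_pair(beta = c(1.5, -0.7), tau = 0, seed = 50 + r,
                         sigma = 0.1)
    list(gene = pair$gene, protein = pair$protein)
  })
  dg <- build_delay_grid(4, 8)
  null1 <- scramble_control(ds, n_perm = 10, seed = 99, delays = dg,
                            n_lams = 10)
  null2 <- scramble_control(ds, n_perm = 10, seed = 99, delays = dg,
                            n_lams = 10)
  expect_identical(null1, null2)
  expect_length(scramble_control(ds, 1, 7, delays = dg, n_lams = 10), 1)

  ev <- evaluate_models(ds, delays = dg, n_lams = 10)
  expect_gt(ev$medians[["rho_delayed_multi"]],
            stats::quantile(null1, 0.95))
})
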