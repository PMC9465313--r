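test_that("znormalize centers and scales rows, zero variance maps to zero", {
  m <- rbind(a = c(1, 2, 3, 6), b = rep(4, 4))
  z <- znormalize(m)
  expect_equal(z["a", ], (c(1, 2, 3, 6) - 3) / sqrt(3.5),
               ignore_attr = TRUE)
  expect_equal(z["b", ], rep(0, 4), ignore_attr = TRUE)

  set.seed(16)
  m2 <- matrix(rnorm(50), 5, 10)
  z2 <- znormalize(m2)
  expect_equal(rowMeans(z2), rep(0, 5), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z2^2)), rep(1, 5), tolerance = 1e-12)

  expect_error(znormalize(matrix(1, 3, 1)), "2 samples")
})

test_that("predict_protein_cohort is the coefficient-weighted z-score sum", {
  set.seed(17)
  m <- matrix(rexp(40, 0.1), 4, 10,
              dimnames = list(paste0("t", 1:4), paste0("S", 1:10)))
  z <- znormalize(m)
  fit1 <- list(protein_id = "pA", beta = c(t1 = 1, t2 = 0))
  expect_equal(unname(predict_protein_cohort(z, fit1)),
               unname(z["t1", ]), ignore_attr = TRUE)
  fit2 <- list(protein_id = "pB", beta = c(t1 = 1, t3 = -1))
  expect_equal(unname(predict_protein_cohort(z, fit2)),
               unname(z["t1", ] - z["t3", ]), ignore_attr = TRUE)

  # rescaling raw counts of a transcript leaves scores unchanged
  m3 <- m
  m3["t1", ] <- 7.3 * m3["t1", ]
  expect_equal(predict_protein_cohort(znormalize(m3), fit2),
               predict_protein_cohort(z, fit2), tolerance = 1e-12)

  # missing transcripts are dropped with a warning; no overlap skips
  fit3 <- list(protein_id = "pC", beta = c(t1 = 1, missing = 2))
  expect_warning(sc <- predict_protein_cohort(z, fit3), "absent")
  expect_equal(attr(sc, "n_transcripts_used"), 1)
  fit4 <- list(protein_id = "pD", beta = c(nope = 1))
  expect_warning(
    expect_warning(expect_null(predict_protein_cohort(z, fit4)),
                   "skipping"),
    "absent")
})

test_that("kruskal_wallis matches the rank formula and stats::kruskal.test", {
  kw <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)

  set.seed(18)
  for (r in 1:10) {
    v <- sample(c(rnorm(10), round(rnorm(8))))  # includes ties
    gl <- sample(rep(c("x", "y", "z"), c(6, 6, 6)))
    kw2 <- kruskal_wallis(v, gl)
    ref <- stats::kruskal.test(v, factor(gl))
    expect_equal(kw2$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw2$p_value, ref$p.value, tolerance = 1e-12)
    perm <- sample(18)
    kw3 <- kruskal_wallis(v[perm], gl[perm])
    expect_equal(kw3$statistic, kw2$statistic, tolerance = 1e-12)
  }

  # identical group distributions give H = 0
  kw4 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(kw4$statistic, 0, tolerance = 1e-12)

  kw5 <- kruskal_wallis(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(kw5$statistic, 0)
  expect_equal(kw5$p_value, 1)

  expect_error(kruskal_wallis(1:4, c("a", "a", "a", "b")), ">= 2")
})

test_that("bh_fdr reproduces the step-up recursion", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p_eq <- rep(0.2, 6)
  expect_equal(bh_fdr(p_eq), p_eq)

  set.seed(19)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-14))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_length(bh_fdr(numeric(0)), 0)
})

test_that("depp_analysis ranks an engineered separation first and is deterministic", {
  set.seed(20)
  n <- 16
  grp <- rep(c("case", "control"), each = n / 2)
  counts <- matrix(rnorm(8 * n, 100, 10), 8, n,
                   dimnames = list(paste0("t", 1:8), paste0("S", 1:n)))
  counts["t1", grp == "case"] <- counts["t1", grp == "case"] + 40
  ch <- cohort_matrix(counts, grp)
  atlas <- list(list(protein_id = "sep", beta = c(t1 = 1)),
                list(protein_id = "null1", beta = c(t3 = 1, t4 = -0.5)),
                list(protein_id = "null2", beta = c(t5 = 2)),
                list(protein_id = "gone", beta = c(zzz = 1)))
  d <- depp_analysis(ch, atlas)
  expect_equal(d$protein_id[1], "sep")
  expect_equal(attr(d, "skipped"), "gone")
  expect_true(all(d$q_value >= d$p_value - 1e-15))
  expect_true(!is.unsorted(d$q_value))  # results sorted by q
  d2 <- depp_analysis(ch, atlas)
  expect_identical(d, d2)

  empty <- depp_analysis(ch, list())
  expect_equal(nrow(empty), 0)
})

test_that("model_gain compares protein and transcript level fractions", {
  set.seed(21)
  n <- 20
  grp <- rep(c("case", "control"), each = n / 2)
  counts <- matrix(rnorm(6 * n, 50, 5), 6, n,
                   dimnames = list(paste0("t", 1:6), NULL))
  colnames(counts) <- paste0("S", 1:n)
  ch <- cohort_matrix(counts, grp)
  # identity single-transcript models degenerate to the transcript test
  atlas <- lapply(1:6, function(j)
    list(protein_id = paste0("p", j),
         beta = stats::setNames(1, paste0("t", j))))
  d <- depp_analysis(ch, atlas)
  tp <- transcript_tests(ch, atlas)
  gain <- model_gain(d, tp)
  expect_equal(gain$fraction_protein, gain$fraction_transcript)
  expect_equal(sort(d$p_value), sort(unname(tp)), tolerance = 1e-12)

  expect_error(model_gain(d[0, ], tp), "non-empty")
})
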