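test_that("Friedman statistic matches the closed form on ordered blocks", {
  m <- matrix(rep(c(1, 5, 9), each = 4), nrow = 4)   # same order every block
  fr <- friedman(m)
  expect_equal(fr$statistic, 8.0)
  expect_equal(fr$method, "exact permutation")
  expect_lt(fr$p_value, 0.05)

  expect_equal(friedman(matrix(1, 4, 3))$statistic, 0)
  expect_error(friedman(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "complete")
  expect_error(friedman(matrix(1:3, 1, 3)), "at least 2")
})

test_that("Friedman exact enumeration matches a Monte-Carlo permutation oracle", {
  mc_perm_p <- function(m, reps = 4000) {
    ranks <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    stat_of <- function(r) 12 / (n * k * (k + 1)) * sum(colSums(r)^2) -
      3 * n * (k + 1)
    obs <- stat_of(ranks)
    hits <- vapply(seq_len(reps), function(i) {
      r <- t(apply(ranks, 1, sample))
      stat_of(r) >= obs - 1e-9
    }, logical(1))
    mean(hits)
  }
  set.seed(31)
  for (i in 1:4) {
    m <- matrix(rnorm(9), 3, 3)
    expect_lt(abs(friedman(m)$p_value - mc_perm_p(m)), 0.06)
  }
  # the chi-square approximation is only coarse at these block counts;
  # sanity-bound the gap rather than expecting close agreement
  m_big <- matrix(rnorm(18), 6, 3)
  expect_equal(friedman(m_big)$method, "exact permutation")
  expect_lt(abs(friedman(m_big)$p_value -
                friedman(m_big, exact_limit = 0)$p_value), 0.1)
})

test_that("Friedman agrees with the reference implementation and is rank-invariant", {
  set.seed(32)
  m <- matrix(rnorm(40), 10, 4)
  ours <- friedman(m, exact_limit = 0)
  ref <- stats::friedman.test(m)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # invariant under monotone transformation within blocks
  expect_equal(friedman(exp(m), exact_limit = 0)$statistic, ours$statistic)
})

test_that("the KS screen separates uniform from normal samples", {
  set.seed(33)
  x_unif <- runif(1000)
  expect_lt(ks_normality(x_unif, reps = 400, seed = 1)$p_value, 0.05)

  # calibration: normal data should rarely be rejected
  rej <- vapply(1:20, function(i) {
    set.seed(100 + i)
    ks_normality(rnorm(200), reps = 200, seed = i)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)

  expect_error(ks_normality(rep(1, 50)), "degenerate")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
})

test_that("the KS statistic matches the reference Lilliefors statistic", {
  set.seed(34)
  for (i in 1:5) {
    x <- rgamma(60, 2)
    expect_equal(ks_normality(x, reps = 10, seed = 1)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  set.seed(35)
  g <- rep(c("A", "B", "C", "D"), each = 12)
  x <- rnorm(48) + (g == "A") * 2
  pw <- pairwise_bonferroni(x, g)
  expect_equal(nrow(pw), 6)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 6))
  expect_true(all(pw$p_adjusted >= pw$p_value))

  # identical groups cannot be distinguished
  y <- rep(1:10, 2)
  gid <- rep(c("A", "B"), each = 10)
  expect_equal(pairwise_bonferroni(y, gid)$p_adjusted, 1)

  expect_error(pairwise_bonferroni(1:5, rep("A", 5)), "2 groups")
  expect_error(pairwise_bonferroni(c(1, 2, 3, 4, 5), c("A", "A", "A", "B", "B"),
                                   kind = "paired"), "equal lengths")
})

test_that("rank-sum p-values match exact enumeration for small samples", {
  set.seed(36)
  for (i in 1:5) {
    x <- sample(seq(1, 40), 5)
    y <- sample(seq(41, 80), 6) / 2.3   # tie-free
    pw <- pairwise_bonferroni(c(x, y), rep(c("X", "Y"), c(5, 6)),
                              m_family = 1)
    expect_equal(pw$p_value, rank_sum_exact_p(x, y), tolerance = 1e-9)
  }
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7)), 0)
  # paired: mean difference over the SD of differences
  x <- c(1, 2, 4); y <- c(2, 3, 4)
  expect_equal(cohens_d(x, y, paired = TRUE),
               mean(x - y) / sd(x - y))
  expect_error(cohens_d(c(0, 0), c(0, 1e-20)), "zero pooled")
  expect_error(cohens_d(c(1), c(1, 2)), "n >= 2")
})

test_that("the full analysis battery reports the comparison families", {
  profs <- list(ID = test_profile("ID", dist = 1.1),
                ST = test_profile("ST", dist = 1.7))
  spec <- cohort_spec(profs, n_per_group = c(ID = 8, ST = 8), seed = 6)
  rec <- generate_cohort(spec, compute_validity = FALSE)
  rep <- analyze_cohort(rec, ks_reps = 100, seed = 2)
  expect_s3_class(rep, "mirror_report")
  expect_true(all(c("normality", "friedman", "pairwise_groups", "trials")
                  %in% names(rep)))
  pg <- rep$pairwise_groups
  expect_true(all(pg$comparison == "ID vs ST"))
  expect_equal(nrow(pg[pg$metric == "distance_mm", ]), 8)  # 4 teeth x 2 trials
  expect_true(any(rep$friedman$factor == "task"))
  expect_error(analyze_cohort(rec[rec$group == "ID", ]), "2 groups")
})

test_that("between-group power matches expectation at the reported effect size", {
  # offset means 1.1 vs 1.7 with SD ~ 0.5: the distance comparison should
  # be significant in nearly all repetitions at the study group sizes
  set.seed(37)
  hits <- vapply(1:25, function(i) {
    x <- rgamma(25, shape = (1.1 / 0.5)^2, scale = 0.5^2 / 1.1)
    y <- rgamma(21, shape = (1.7 / 0.5)^2, scale = 0.5^2 / 1.7)
    suppressWarnings(stats::wilcox.test(x, y)$p.value) * 6 < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
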