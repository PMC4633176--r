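test_that("Z-score classification flags shifted samples with an inclusive threshold", {
  set.seed(21)
  expr <- matrix(stats::rnorm(200 * 3), nrow = 200,
                 dimnames = list(sprintf("s%03d", 1:200), c("A", "B", "C")))
  ref_sd <- stats::sd(expr[, "A"])
  expr["s001", "A"] <- mean(expr[-1, "A"]) + 5 * ref_sd
  calls <- zscore_classify(expr, c("A", "B", "C"))
  expect_true(calls$altered[calls$sample_id == "s001"])
  expect_true("A" %in% calls$triggering_genes[[1]])

  # z of exactly 2.0 is altered: column c(0 x7, a, -a) has z = +/-2 exactly
  expr2 <- cbind(G = c(rep(0, 7), 3, -3))
  rownames(expr2) <- sprintf("s%d", 1:9)
  calls2 <- zscore_classify(expr2, "G")
  expect_equal(calls2$sample_id[calls2$altered], c("s8", "s9"))
})

test_that("degenerate and missing genes are skipped with warnings", {
  expr <- matrix(1, nrow = 10, ncol = 2,
                 dimnames = list(NULL, c("flat1", "flat2")))
  expect_warning(calls <- zscore_classify(expr, c("flat1", "flat2")),
                 "zero-variance")
  expect_false(any(calls$altered))
  expect_warning(zscore_classify(expr + stats::rnorm(20), c("flat1", "gone")),
                 "absent")
  expr3 <- matrix(stats::rnorm(30), nrow = 10,
                  dimnames = list(NULL, c("A", "B", "C")))
  none <- zscore_classify(expr3, character())
  expect_false(any(none$altered))
})

test_that("the altered fraction is invariant to affine rescaling of a gene", {
  set.seed(22)
  expr <- matrix(stats::rnorm(300), nrow = 100,
                 dimnames = list(NULL, c("A", "B", "C")))
  f1 <- attr(zscore_classify(expr, colnames(expr)), "fraction_altered")
  expr[, "B"] <- 7 * expr[, "B"] - 3
  f2 <- attr(zscore_classify(expr, colnames(expr)), "fraction_altered")
  expect_equal(f1, f2)
})

test_that("exact Mann-Whitney matches full enumeration and the textbook case", {
  res <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)  # 2 * 1/20 over all 20 labelings
  expect_equal(res$method, "exact")

  set.seed(23)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- sample(1:8, na, replace = TRUE)  # ties likely
    b <- sample(1:8, nb, replace = TRUE)
    expect_equal(mann_whitney_test(a, b)$p, oracle_mw_p(a, b))
  }
  # tie-free cases also agree with the classical exact distribution
  for (i in 1:10) {
    x <- sample(1:100, 10)
    a <- x[1:5]; b <- x[6:10]
    expect_equal(mann_whitney_test(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("the comparison is symmetric and gated on the KS normality check", {
  set.seed(24)
  a <- stats::rnorm(50); b <- stats::rnorm(50, 0.5)
  res <- compare_groups(a, b)
  expect_equal(res$test_used, "t_test")
  expect_equal(res$p, compare_groups(b, a)$p)

  skewed_a <- stats::rexp(80); skewed_b <- stats::rexp(80, 0.5)
  res2 <- compare_groups(skewed_a, skewed_b)
  expect_equal(res2$test_used, "mann_whitney")
  expect_equal(res2$p, compare_groups(skewed_b, skewed_a)$p)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")

  # Lilliefors variant runs and returns the same structure
  res3 <- compare_groups(a, b, lilliefors = TRUE)
  expect_true(res3$test_used %in% c("t_test", "mann_whitney"))
})

test_that("star codes follow the figure-legend convention", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.04, 0.05, 0.5)),
               c("***", "**", "*", "ns", "ns"))
})

test_that("product-limit estimates match hand computation and stay valid", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))

  flat <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(flat$survival == 1))

  one <- km_estimate(4, 1)
  expect_equal(one$survival, c(1, 0))

  expect_error(km_estimate(-1, 1), ">= 0")

  set.seed(25)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    km <- km_estimate(stats::rexp(n), stats::rbinom(n, 1, 0.7))
    expect_equal(km$survival[1], 1)
    expect_true(all(diff(km$survival) <= 0))
    expect_true(all(km$survival >= 0))
    # survival only drops where events occur
    drops <- which(diff(km$survival) < 0) + 1L
    expect_true(all(km$n_event[drops] > 0))
  }
})

test_that("log-rank matches a hand-worked observed/expected table", {
  # group a: events at 1, 2; group b: events at 3, 4; no censoring
  # chi-square = (2 - 5/6)^2 / (1/4 + 2/9) = 49/17
  res <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(res$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(res$p, stats::pchisq(49 / 17, 1, lower.tail = FALSE))

  ident <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6),
                        rep(c("a", "b"), each = 3))
  expect_equal(ident$chisq, 0, tolerance = 1e-12)
  expect_equal(ident$p, 1, tolerance = 1e-12)

  expect_warning(none <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(none$p, 1)
  expect_named(none$km_curves, c("a", "b"))
})
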