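test_that("chi-squared association matches the hand computation", {
  # perfect independence
  f <- rep(c("x", "y"), each = 20)
  g <- rep(c("a", "b"), times = 20)
  r <- chi_squared_assoc(f, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # perfect association: [[20,0],[0,20]] has sum (O-E)^2/E = 40 with all E = 10
  f2 <- rep(c("x", "y"), each = 20)
  g2 <- f2
  r2 <- chi_squared_assoc(f2, g2)
  expect_equal(r2$statistic, 40)
  expect_error(chi_squared_assoc(rep("x", 10), rep(c("a", "b"), 5)),
               "degenerate margin")
})

test_that("chi-squared equals brute-force sum (O-E)^2/E on random small tables", {
  set.seed(7)
  for (i in 1:25) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 8) + 1, r, cc)
    f <- rep(rep(paste0("f", seq_len(r)), cc), as.vector(tab))
    g <- rep(rep(paste0("g", seq_len(cc)), each = r), as.vector(tab))
    out <- chi_squared_assoc(f, g)
    expect_equal(out$statistic, chisq_brute(table(factor(f), factor(g))),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis matches the hand-ranked statistic and handles corners", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- kruskal_wallis_assoc(x, g)
  expect_equal(r$statistic, 7.2)     # no ties: 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  # all identical values
  r0 <- kruskal_wallis_assoc(rep(5, 9), g)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(kruskal_wallis_assoc(x[1:6], g[c(1:3, 4:6)]), "mann_whitney")
})

test_that("Kruskal-Wallis asymptotic p agrees with a permutation oracle", {
  set.seed(11)
  x <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  obs <- kruskal_wallis_assoc(x, g)$statistic
  perm <- replicate(2000, kruskal_wallis_assoc(x, sample(g))$statistic)
  p_perm <- mean(perm >= obs - 1e-12)
  p_asym <- kruskal_wallis_assoc(x, g)$p_value
  expect_lt(abs(p_perm - p_asym), 0.06)   # Monte-Carlo error margin
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  # a fully below b: U = 0 for a; exact two-sided p = 2 * 1/C(6,3) = 0.1
  r <- mann_whitney_assoc(c(1, 2, 3), c(10, 20, 30))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  # identical samples: U = nm/2, p near 1
  r2 <- mann_whitney_assoc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r2$statistic), 4.5)
  expect_gt(r2$p_value, 0.9)
  # Bonferroni cap
  r3 <- mann_whitney_assoc(c(1, 3, 2, 5), c(2, 4, 1, 6), m_comparisons = 3L)
  expect_equal(r3$p_adjusted, min(1, 3 * r3$p_value))
  expect_true(r3$p_adjusted >= r3$p_value)
  expect_error(mann_whitney_assoc(numeric(0), 1:3), "empty")
})

test_that("feature ranking selects tests by column type and orders by p-value", {
  set.seed(3)
  n <- 200L
  concern <- sample(c("most", "less", "no"), n, replace = TRUE)
  lab <- data.frame(key = paste0("k", 1:n), concern = concern,
                    label = binarize_concern(concern))
  planted <- ifelse(lab$label == 1L, rnorm(n, 2), rnorm(n))   # strong signal
  noise <- matrix(rnorm(n * 50), n)
  colnames(noise) <- sprintf("noise_%02d", 1:50)
  fm <- cbind(planted = planted, noise,
              flag = rbinom(n, 1, 0.5),            # categorical path
              constant = rep(1, n))
  rownames(fm) <- lab$key
  res <- suppressMessages(rank_features(fm, lab, scheme = "three_concern"))
  expect_identical(res$feature_name[1], "planted")
  expect_lt(res$p_value[1], min(res$p_value[res$feature_name != "planted"]))
  expect_identical(res$test[res$feature_name == "planted"], "kruskal_wallis")
  expect_identical(res$test[res$feature_name == "flag"], "chi_squared")
  expect_false("constant" %in% res$feature_name)   # skipped, not ranked
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # binary scheme sends continuous columns to Mann-Whitney
  res2 <- suppressMessages(rank_features(fm[, c("planted", "flag")], lab,
                                         scheme = "binary_label"))
  expect_identical(res2$test[res2$feature_name == "planted"], "mann_whitney")
  # pairwise scheme applies the Bonferroni multiplier for 3 contrasts
  res3 <- suppressMessages(rank_features(fm[, "planted", drop = FALSE], lab,
                                         scheme = "pairwise"))
  expect_equal(res3$p_adjusted, pmin(1, 3 * res3$p_value))
  # ranking is stable under row permutation
  perm <- sample(n)
  res_p <- suppressMessages(rank_features(fm[perm, ], lab, scheme = "three_concern"))
  expect_identical(res_p$feature_name, res$feature_name)
  expect_error(rank_features(fm, data.frame(key = "zz", concern = "most",
                                            label = 1L)),
               "no overlapping keys")
})
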