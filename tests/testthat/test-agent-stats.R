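test_that("the embedded crossover table loads and self-checks", {
  tab <- load_table1()
  expect_equal(nrow(tab), 27)
  expect_equal(tab$net_gadoteridol[1], 2660.6)
  expect_equal(tab$net_gadobutrol[1], 2355.5)
  expect_equal(tab$avg_gadoteridol[5] - tab$avg_gadobutrol[5], -0.047)
  expect_equal(tab$first_agent[8], "gadoteridol")
  expect_equal(tab$first_agent[23], "gadobutrol")

  # a corrupted difference column is caught by the integrity check
  bad <- tab
  bad$net_difference[3] <- bad$net_difference[3] + 5
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_table1(tmp), "integrity")
})

test_that("paired_t matches t.test and handles degenerate inputs", {
  set.seed(17)
  for (i in 1:5) {
    d <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    mine <- paired_t(d)
    ref <- t.test(d)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
    expect_equal(mine$ci95, as.numeric(ref$conf.int))
    expect_equal(mine$sd_diff, sd(d))
  }
  expect_equal(paired_t(rep(0, 10))$p, 1)
  expect_equal(paired_t(rep(2, 10))$p, 0)
  expect_error(paired_t(3), "at least 2")
})

test_that("correlation wrappers validate and agree with oracles", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r(x, 1:9), "equal length")

  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  set.seed(23)
  for (i in 1:10) {
    a <- sample(1:5, 30, replace = TRUE)   # heavy ties
    b <- a + sample(0:3, 30, replace = TRUE)
    expect_equal(spearman_rho(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  }
})

test_that("correlations are invariant to positive affine transforms", {
  set.seed(29)
  x <- rnorm(40); y <- x + rnorm(40)
  for (i in 1:5) {
    a <- runif(1, 0.1, 5); b <- runif(1, -10, 10)
    expect_equal(pearson_r(a * x + b, y), pearson_r(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, a * y + b), spearman_rho(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman limits are mean difference plus/minus exactly 2 SD", {
  x <- c(1, 2, 3, 4); y <- x
  ba0 <- bland_altman(x, y)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(diff(ba0$limits), 0)

  set.seed(37)
  d <- rnorm(1e4)
  ba <- bland_altman(d, rep(0, 1e4))
  expect_lt(abs(ba$limits[2] - 2) / 2, 0.03)
  expect_lt(abs(ba$limits[1] + 2) / 2, 0.03)
  expect_equal(ba$limits[2] - ba$mean_diff, 2 * ba$sd_diff)
})

test_that("preference counts partition the differences", {
  pc <- preference_counts(c(1, -1, 0))
  expect_equal(pc$count, c(1L, 1L, 1L))
  pc0 <- preference_counts(rep(0, 5))
  expect_equal(pc0$count[pc0$category == "zero"], 5L)
  expect_equal(sum(pc0$percent), 100)
})

test_that("percent difference uses the first examination as denominator", {
  f9 <- percent_difference(711.26, 695.47, "gadoteridol")
  expect_equal(f9$difference, 15.79, tolerance = 1e-12)
  expect_equal(round(f9$percent, 2), 2.22)
  f10 <- percent_difference(2102.98, 2119.53, "gadobutrol")
  expect_equal(f10$difference, 16.55, tolerance = 1e-12)
  expect_equal(round(f10$percent, 2), 0.79)
  expect_equal(percent_difference(100, 100)$percent, 0)
  expect_error(percent_difference(0, 5), "zero")
})

test_that("paired t direction agrees with a sign-flip permutation test", {
  tab <- load_table1()
  dn <- tab$net_gadoteridol - tab$net_gadobutrol
  t_res <- paired_t(dn)
  set.seed(41)
  perm_means <- replicate(2000, mean(dn * sample(c(-1, 1), length(dn),
                                                 replace = TRUE)))
  p_perm <- mean(abs(perm_means) >= abs(mean(dn)))
  expect_equal(sign(t_res$t), sign(mean(dn)))
  # both tests agree the effect is far from significant
  expect_gt(p_perm, 0.05)
  expect_gt(t_res$p, 0.05)
})

test_that("every printed difference column is consistent with its value columns", {
  tab <- load_table1()
  expect_lte(max(abs((tab$net_gadoteridol - tab$net_gadobutrol) -
                       tab$net_difference)), 0.1 + 1e-9)
  expect_lte(max(abs((tab$avg_gadoteridol - tab$avg_gadobutrol) -
                       tab$avg_difference)), 0.001 + 1e-9)
})
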