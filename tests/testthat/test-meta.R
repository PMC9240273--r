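test_that("Hedges g follows the closed form with its variance", {
  # n1=n2=10, mean diff 1, pooled sd 1: g = (1 - 3/71), v = 0.2 + g^2/40
  set.seed(2)
  x <- rnorm(10); x <- (x - mean(x)) / sd(x)        # mean 0, sd 1
  y <- x + 1                                        # identical sd, diff 1
  e <- hedges_g(x, y)
  g_exp <- (1 - 3 / 71)
  expect_equal(e$estimate, g_exp, tolerance = 1e-10)
  expect_equal(e$variance, 20 / 100 + g_exp^2 / 40, tolerance = 1e-10)
  # identical arms -> g = 0; swapping arms negates g, keeps v
  z <- rnorm(8)
  expect_equal(hedges_g(z, z)$estimate, 0)
  e1 <- hedges_g(x, y); e2 <- hedges_g(y, x)
  expect_equal(e1$estimate, -e2$estimate)
  expect_equal(e1$variance, e2$variance)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("Hedges g and its variance agree with the metafor reference", {
  skip_if_not_installed("metafor")
  set.seed(5)
  x <- rnorm(14); y <- rnorm(19, 0.6)
  e <- hedges_g(x, y)
  ref <- metafor::escalc(measure = "SMD", m1i = mean(y), m2i = mean(x),
                         sd1i = sd(y), sd2i = sd(x), n1i = 19, n2i = 14)
  expect_equal(e$estimate, as.numeric(ref$yi), tolerance = 1e-4)
  expect_equal(e$variance, as.numeric(ref$vi), tolerance = 1e-4)
})

test_that("DerSimonian-Laird pooling reproduces hand-computed cases", {
  # heterogeneous pair
  r <- dl_pool(data.frame(estimate = c(0, 2), variance = c(1, 1)))
  expect_equal(r$Q, 2); expect_equal(r$tau2, 1)
  expect_equal(r$mu, 1); expect_equal(r$se, 1)
  expect_equal(r$i2, 50)
  # homogeneous pair
  h <- dl_pool(data.frame(estimate = c(0.5, 0.5), variance = c(1, 1)))
  expect_equal(h$Q, 0); expect_equal(h$tau2, 0)
  expect_equal(h$mu, 0.5); expect_equal(h$i2, 0)
  # truncation branch: Q < df -> tau2 = 0, fixed-effect weights
  t <- dl_pool(data.frame(estimate = c(0, 1), variance = c(1, 1)))
  expect_equal(t$Q, 0.5); expect_equal(t$tau2, 0)
  expect_equal(t$mu, 0.5); expect_equal(t$se, sqrt(0.5))
  expect_error(dl_pool(data.frame(estimate = 1, variance = 1)), "two studies")
  expect_error(dl_pool(data.frame(estimate = c(1, 2), variance = c(1, 0))),
               "variances")
})

test_that("DL pooling matches metafor across random inputs", {
  skip_if_not_installed("metafor")
  set.seed(13)
  for (i in 1:5) {
    k <- sample(3:12, 1)
    y <- rnorm(k, 0.3, 0.4); v <- runif(k, 0.01, 0.4)
    a <- dl_pool(data.frame(estimate = y, variance = v))
    b <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(a$mu, as.numeric(b$beta), tolerance = 1e-10)
    expect_equal(a$tau2, b$tau2, tolerance = 1e-10)
    expect_equal(a$Q, b$QE, tolerance = 1e-10)
    expect_equal(a$i2, b$I2, tolerance = 1e-6)
    expect_equal(a$se, b$se, tolerance = 1e-10)
    expect_equal(a$p, b$pval, tolerance = 1e-10)
  }
})

test_that("tau2 = 0 reduces pooling to the inverse-variance fixed effect", {
  y <- c(0.2, 0.25, 0.22); v <- c(0.04, 0.05, 0.045)
  r <- dl_pool(data.frame(estimate = y, variance = v))
  expect_equal(r$tau2, 0)
  w <- 1 / v
  expect_equal(r$mu, sum(w * y) / sum(w), tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("Fisher z transform and correlation pooling compose correctly", {
  e <- fisher_z_effect(0, 103)
  expect_equal(e$estimate, 0); expect_equal(e$variance, 0.01)
  expect_equal(fisher_z_effect(0.5, 50)$estimate, 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z_effect(-0.5, 50)$estimate,
               -fisher_z_effect(0.5, 50)$estimate)
  expect_error(fisher_z_effect(1, 50), "< 1")
  expect_error(fisher_z_effect(0.5, 3), ">= 4")

  # all studies equal -> pooled r is that value
  eq <- pool_correlation(lapply(1:3, function(i) fisher_z_effect(0.5, 103)))
  expect_equal(eq$r, 0.5, tolerance = 1e-10)
  # r=(0.2, 0.6) at n=103: pooled r = tanh(DL mu of the z values)
  comp <- pool_correlation(list(fisher_z_effect(0.2, 103),
                                fisher_z_effect(0.6, 103)))
  oracle <- dl_pool(data.frame(estimate = atanh(c(0.2, 0.6)),
                               variance = c(0.01, 0.01)))
  expect_equal(comp$r, tanh(oracle$mu), tolerance = 1e-12)
  # unequal precision: se smaller than either single study
  two <- pool_correlation(list(fisher_z_effect(0.3, 50),
                               fisher_z_effect(0.3, 500)))
  expect_equal(two$r, 0.3, tolerance = 1e-10)
  expect_lt(two$pooled$se, 1 / sqrt(50 - 3))
})

test_that("correlation pooling is antisymmetric in the sign of r", {
  set.seed(3)
  r <- runif(5, -0.6, 0.6); n <- sample(30:200, 5)
  a <- pool_correlation(Map(fisher_z_effect, r, n))
  b <- pool_correlation(Map(fisher_z_effect, -r, n))
  expect_equal(a$r, -b$r, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.07, 4)), rep(0.07, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order restored
  p <- c(0.04, 0.01, 0.02)
  expect_equal(bh_adjust(p), c(0.04, 0.03, 0.03))
})

test_that("DL recovers planted mu and tau2 from generated summary effects", {
  set.seed(77)
  mus <- replicate(120, {
    seed <- sample.int(1e6, 1)
    se <- generate_summary_effects(0.3, 0.04, k = 50, n_per_arm = 100,
                                   seed = seed)
    re <- dl_pool(lapply(se, function(s) hedges_g(s$control, s$case)))
    c(re$mu, re$ci_lower <= 0.3 & 0.3 <= re$ci_upper)
  })
  expect_lt(abs(mean(mus[1, ]) - 0.3), 0.02)
  expect_gte(mean(mus[2, ]), 0.90)
})
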