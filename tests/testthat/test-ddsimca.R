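test_that("moment estimator recovers chi-square degrees of freedom", {
  set.seed(101)
  expect_equal(dof_estimate(7.3 * rchisq(1e4, df = 4)), 4L)
  expect_equal(dof_estimate(rexp(1e4, rate = 0.2)), 2L)
  expect_warning(N <- dof_estimate(rep(2, 10)), "constant")
  expect_equal(N, 250L)
  expect_error(dof_estimate(c(1, 2)), "at least 3")
})

test_that("score and orthogonal distances have the exact PCA geometry", {
  X <- gauss_matrix(60, 12, seed = 21)
  m <- ddsimca_fit(X, ncomp = 3)

  # the class center is distance-free
  d0 <- ddsimca_distances(m, matrix(m$center, 1))
  expect_equal(d0$h, 0, tolerance = 1e-18)
  expect_equal(d0$v, 0, tolerance = 1e-18)
  expect_equal(d0$c, 0, tolerance = 1e-16)

  # in-plane displacement along the first loading: v = 0, h = delta^2/lambda1
  delta <- 0.7
  d1 <- ddsimca_distances(m, matrix(m$center + delta * m$loadings[, 1], 1))
  expect_equal(d1$v, 0, tolerance = 1e-16)
  expect_equal(d1$h, delta^2 / m$eigenvalues[1], tolerance = 1e-10)

  # orthogonal displacement: h = 0, v = delta^2
  w <- rnorm(12)
  w <- w - m$loadings %*% crossprod(m$loadings, w)
  w <- w / sqrt(sum(w^2))
  d2 <- ddsimca_distances(m, matrix(m$center + delta * w, 1))
  expect_equal(d2$h, 0, tolerance = 1e-12)
  expect_equal(d2$v, delta^2, tolerance = 1e-10)

  # algebraic identity: with eigenvalues s^2/(n-1), training score
  # distances average to A*(n-1)/n
  expect_equal(mean(m$training$h), 3 * 59 / 60, tolerance = 1e-10)

  # total distance recombines h and v with the stated weights
  tr <- m$training
  expect_equal(tr$c, m$Nh * tr$h / m$h0 + m$Nv * tr$v / m$v0,
               tolerance = 1e-12)

  expect_error(ddsimca_distances(m, matrix(0, 1, 5)), "band count")
  expect_error(ddsimca_fit(X, ncomp = 60), "ncomp")
})

test_that("chi-square cutoffs match an independent quantile oracle", {
  m <- ddsimca_fit(gauss_matrix(80, 10, seed = 3), ncomp = 2,
                   alpha = 0.01, gamma = 0.01)
  k <- m$Nh + m$Nv
  expect_equal(m$c_crit, chisq_quantile_oracle(0.99, k), tolerance = 1e-6)
  expect_equal(m$c_out, chisq_quantile_oracle((1 - 0.01)^(1 / 80), k),
               tolerance = 1e-6)
  expect_gt(m$c_out, m$c_crit)
  # the worked chi-square value: 99th percentile at 5 dof
  expect_equal(chisq_quantile_oracle(0.99, 5), 15.08627, tolerance = 1e-4)
})

test_that("acceptance boundary is inclusive and monotone in both distances", {
  X <- gauss_matrix(60, 12, seed = 22)
  m <- ddsimca_fit(X, ncomp = 3)
  rec_on <- swirauth:::ddsimca_records(m, h = 0, v = 0, cdist = m$c_crit,
                                       ids = NULL, mode = "predict")
  expect_equal(rec_on$decision, "accepted")
  rec_over <- swirauth:::ddsimca_records(m, 0, 0, m$c_crit * (1 + 1e-12),
                                         NULL, "predict")
  expect_equal(rec_over$decision, "rejected")

  # scaling the orthogonal residual up never flips rejected -> accepted
  w <- rnorm(12)
  w <- w - m$loadings %*% crossprod(m$loadings, w)
  w <- w / sqrt(sum(w^2))
  scales <- seq(0.1, 3, by = 0.1)
  cs <- vapply(scales, function(s)
    ddsimca_distances(m, matrix(m$center + s * w, 1))$c, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("type-I error is calibrated on well-specified Gaussian data", {
  rates <- vapply(1:5, function(s) {
    train <- gauss_matrix(1000, 50, seed = 1000 + s)
    test <- gauss_matrix(1000, 50, seed = 2000 + s)
    m <- ddsimca_fit(train, ncomp = 5, alpha = 0.01)
    mean(ddsimca_classify(m, test)$decision == "rejected")
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.01), 0.01)

  # no seed produces a flood of training outliers (gamma protection)
  outl <- vapply(1:5, function(s) {
    m <- ddsimca_fit(gauss_matrix(200, 20, seed = 3000 + s), ncomp = 4)
    sum(m$training$decision == "outlier")
  }, numeric(1))
  expect_true(all(outl <= 0.01 * 200 + 3 * sqrt(0.01 * 200)))
})

test_that("decisions are invariant under a common orthogonal rotation", {
  X <- gauss_matrix(80, 15, seed = 31)
  Y <- gauss_matrix(40, 15, seed = 32) * 1.4
  Q <- qr.Q(qr(gauss_matrix(15, 15, seed = 33)))
  m1 <- ddsimca_fit(X, ncomp = 4)
  m2 <- ddsimca_fit(X %*% Q, ncomp = 4)
  d1 <- ddsimca_classify(m1, Y)
  d2 <- ddsimca_classify(m2, Y %*% Q)
  expect_equal(d1$c, d2$c, tolerance = 1e-8)
  expect_identical(d1$decision, d2$decision)
})

test_that("extreme plot counts are consistent with the classifier", {
  X <- gauss_matrix(100, 20, seed = 41)
  m <- ddsimca_fit(X, ncomp = 3, alpha = 0.05)
  ep <- extreme_plot_data(m, levels = c(0.01, 0.05, 0.1))
  expect_equal(ep$expected[2], 5)  # a = 0.05, n = 100
  # observed at a = alpha equals the extreme+outlier training count
  expect_equal(ep$observed[2],
               sum(m$training$decision %in% c("extreme", "outlier")))
  expect_equal(ep$envelope, 2 * sqrt(ep$level * 100 * (1 - ep$level)))

  # on well-specified data most grid points sit inside the envelope
  ep2 <- extreme_plot_data(m)
  inside <- abs(ep2$observed - ep2$expected) <= ep2$envelope
  expect_gte(mean(inside), 0.9)
})

test_that("factor selection recovers a 3-dimensional latent structure", {
  X <- latent3_matrix()
  expect_equal(ddsimca_select_factors(X, A_max = 6), 3L)
  expect_equal(ddsimca_select_factors(X, A_max = 1), 1L)
})

test_that("model round-trips through its YAML file", {
  X <- gauss_matrix(50, 10, seed = 51)
  m <- ddsimca_fit(X, ncomp = 2)
  path <- file.path(tempdir(), "model.ddsimca")
  save_ddsimca(m, path)
  back <- load_ddsimca(path)
  Y <- gauss_matrix(10, 10, seed = 52)
  expect_equal(ddsimca_distances(back, Y)$c, ddsimca_distances(m, Y)$c,
               tolerance = 1e-9)
  expect_equal(back$c_crit, m$c_crit, tolerance = 1e-12)
})
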