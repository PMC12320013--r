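test_that("standardize gives zero mean, unit population variance, and errors on constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  z <- standardize(rnorm(100, 5, 3))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(c(5, 5, 5)), "zero-variance")
  expect_error(standardize(3), "length")
})

test_that("window construction follows offsets, truncation and stride semantics", {
  ws <- build_window_set(1:10, 5, 5)
  expect_equal(ws$n_instances, 2)
  expect_equal(ws$values, rbind(1:5, 6:10))
  # trailing partial window discarded
  ws2 <- build_window_set(1:11, 5, 5)
  expect_equal(ws2$values, rbind(1:5, 6:10))
  # overlapping stride
  ws3 <- build_window_set(1:6, 5, 1)
  expect_equal(ws3$values, rbind(1:5, 2:6))
  expect_error(build_window_set(1:6, 5, 5), "insufficient")
})

test_that("alpha estimate is the pooled regression coefficient and recovers the population value", {
  x <- standardize(rnorm(1000))
  wx <- build_window_set(x, 5)
  wy <- build_window_set(0.5 * x, 5)
  expect_equal(estimate_alpha(wx, wy), 0.5, tolerance = 1e-12)
  wys <- build_window_set(standardize(0.5 * x), 5)
  expect_equal(estimate_alpha(wx, wys), 1.0, tolerance = 1e-10)
  # independent white noise: small pooled correlation
  set.seed(7)
  wa <- window_set(matrix(rnorm(10000), 2000, 5))
  wb <- window_set(matrix(rnorm(10000), 2000, 5))
  expect_lt(abs(estimate_alpha(wa, wb)), 0.05)
  # analytic lag-0 correlation of the coupled AR model
  p <- make_pair(n = 100000, alpha = 0.5, r = 0.8, seed = 11)
  vx <- 1 / (1 - 0.8^2); vd <- 1 / (1 - 0.2^2)
  rho_pop <- 0.5 * sqrt(vx) / sqrt(0.25 * vx + vd)
  wx2 <- build_window_set(standardize(p$x), 5)
  wy2 <- build_window_set(standardize(p$y), 5)
  expect_equal(estimate_alpha(wx2, wy2), rho_pop, tolerance = 0.02)
  expect_error(estimate_alpha(wx, window_set(matrix(0:5, 2, 3))), "mismatch")
})

test_that("residual windows invert the instantaneous regression exactly", {
  wx <- window_set(matrix(rnorm(50), 10, 5))
  wy <- window_set(0.7 * wx$values)
  expect_equal(residual_windows(wx, wy, 0.7)$values, matrix(0, 10, 5))
  expect_equal(residual_windows(wx, wy, 0)$values, wy$values)
  wz <- window_set(matrix(rnorm(50), 10, 5))
  rec <- residual_windows(wx, wz, 0.3)$values + 0.3 * wx$values
  expect_equal(rec, wz$values, tolerance = 1e-14)
})

test_that("window covariance uses divisor m and matches the AR(1) autocovariance", {
  expect_equal(window_covariance(window_set(rbind(c(1, 2), c(1, 2))))$matrix,
               matrix(0, 2, 2))
  expect_equal(window_covariance(window_set(rbind(c(1, -1), c(-1, 1))))$matrix,
               matrix(c(1, -1, -1, 1), 2))
  x <- standardize(simulate_ar(ar_spec(0.8), 100000, seed = 5))
  S <- window_covariance(build_window_set(x, 5))$matrix
  expect_equal(S, toeplitz(0.8^(0:4)), tolerance = 0.02)
  # toeplitz projection makes all diagonals constant
  St <- window_covariance(build_window_set(x, 5), toeplitz = TRUE)$matrix
  expect_equal(length(unique(round(St[row(St) - col(St) == 1], 12))), 1)
})

test_that("joint covariance has the right block structure", {
  set.seed(3)
  wa <- window_set(matrix(rnorm(5000), 1000, 5))
  wb <- window_set(matrix(rnorm(5000), 1000, 5))
  J <- joint_covariance(wa, wb)$matrix
  expect_equal(J[1:5, 1:5], window_covariance(wa)$matrix)
  expect_lt(max(abs(J[1:5, 6:10])), 3 / sqrt(1000))
  # duplicated variable: joint covariance singular before ridge
  Jdup <- joint_covariance(wa, wa)$matrix
  expect_lt(min(eigen(Jdup, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
})

test_that("Gaussian entropy matches closed forms", {
  expect_equal(gaussian_entropy(matrix(1)), 0.5 * (1 + log(2 * pi)))
  expect_equal(gaussian_entropy(diag(6)), 6 * 0.5 * (1 + log(2 * pi)))
  expect_equal(gaussian_entropy(matrix(c(1, .5, .5, 1), 2)),
               0.5 * log(0.75) + (1 + log(2 * pi)))
  expect_error(gaussian_entropy(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("Gaussian mutual information matches the scalar closed form and detects near-duplication", {
  # sample covariance shaped to exactly [[1, .6], [.6, 1]] at L = 1
  M <- exact_cov_instances(matrix(c(1, .6, .6, 1), 2), m = 50, seed = 2)
  I <- gaussian_mi(window_set(M[, 1, drop = FALSE]),
                   window_set(M[, 2, drop = FALSE]), ridge = 0)
  expect_equal(I, -0.5 * log(1 - 0.36), tolerance = 1e-10)
  # independent blocks: MI ~ 0 but never below -1e-8
  set.seed(9)
  wa <- window_set(matrix(rnorm(3000), 1000, 3))
  wb <- window_set(matrix(rnorm(3000), 1000, 3))
  expect_gte(gaussian_mi(wa, wb), -1e-8)
  expect_lt(gaussian_mi(wa, wb), 0.05)
  # near-duplication: MI diverges as the jitter vanishes
  wj <- window_set(wa$values + matrix(rnorm(3000, sd = 1e-3), 1000, 3))
  expect_gt(gaussian_mi(wa, wj), 5)
})

test_that("soc_decide recovers the simulated direction and reports consistent diagnostics", {
  hits <- vapply(1:50, function(s) {
    p <- make_pair(n = 10000, alpha = 0.7, r = 0.8, seed = s)
    soc_decide(p$x, p$y)$direction == "x_to_y"
  }, logical(1))
  expect_gte(sum(hits), 45)
  p <- make_pair(n = 5000, seed = 99)
  d <- soc_decide(p$x, p$y)
  expect_equal(d$criterion_C, 2 * d$mi_x_d - 2 * d$mi_y_e, tolerance = 1e-10)
  expect_gte(d$mi_x_d, -1e-8)
  expect_gte(d$mi_y_e, -1e-8)
})

test_that("soc_decide error paths: insufficient data, zero variance, singular residual", {
  expect_error(soc_decide(rnorm(60), rnorm(60)), "insufficient")
  expect_error(soc_decide(rep(1, 500), rnorm(500)), "zero-variance")
  x <- rnorm(500)
  expect_error(soc_decide(x, 2 * x), "singular")
})

test_that("criterion is antisymmetric under swap and invariant to affine rescaling", {
  for (s in 1:5) {
    p <- make_pair(n = 1000, alpha = 0.4, r = 0.7, seed = 100 + s)
    a <- soc_decide(p$x, p$y)
    b <- soc_decide(p$y, p$x)
    expect_equal(a$criterion_C, -b$criterion_C, tolerance = 1e-10)
    sc <- soc_decide(3.2 * p$x - 7, -0.5 * p$y + 2)
    expect_equal(sc$criterion_C, a$criterion_C, tolerance = 1e-10)
    expect_identical(sc$direction, a$direction)
  }
})

test_that("empirical criterion converges to the analytic population value", {
  pop <- soc_population_criterion(r = 0.8, alpha = 0.5, noise_coef = 0.2, L = 5)
  expect_lt(pop$C, 0)
  expect_equal(pop$mi_x_d, 0, tolerance = 1e-10)  # true-model residual is independent
  p <- make_pair(n = 50000, alpha = 0.5, r = 0.8, seed = 42)
  d <- soc_decide(p$x, p$y)
  expect_equal(d$criterion_C, pop$C, tolerance = 0.05)
})

test_that("population criterion is exactly zero at the identifiability boundary", {
  expect_equal(soc_population_criterion(r = 0.2, alpha = 0.5)$C, 0, tolerance = 1e-12)
  expect_equal(soc_population_criterion(r = 0.5, alpha = 0.7, noise_coef = 0.5)$C, 0,
               tolerance = 1e-12)
  # off the boundary the criterion favors the true direction
  for (r in c(0.4, 0.6, 0.9)) {
    expect_lt(soc_population_criterion(r = r, alpha = 0.5)$C, -1e-4)
  }
})

test_that("multi-instance input standardizes each time index across instances", {
  set.seed(21)
  m <- 300; L <- 5
  X <- matrix(rnorm(m * L), m, L)
  Y <- 0.6 * X + matrix(rnorm(m * L), m, L)
  d <- soc_decide(X, Y)
  expect_s3_class(d, "soc_decision")
  # per-column scaling of instances is absorbed
  d2 <- soc_decide(sweep(X, 2, c(2, 5, 1, 9, 3), `*`), Y)
  expect_equal(d2$criterion_C, d$criterion_C, tolerance = 1e-10)
})
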