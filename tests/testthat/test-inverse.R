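test_that("noise covariance estimation is consistent and shrinkable", {
  set.seed(111)
  X <- matrix(rnorm(4 * 20000), 4)
  C <- estimate_noise_cov(X, shrinkage = 0)
  expect_lt(max(abs(C$cov - diag(4))), 0.05)

  Cd <- estimate_noise_cov(X, shrinkage = 1)
  expect_equal(Cd$cov, diag(diag(stats::cov(t(X))), 4), tolerance = 1e-12)
})

test_that("a planted channel correlation is recovered", {
  set.seed(112)
  n <- 10000
  z <- rnorm(n)
  X <- rbind(0.6 * z + sqrt(1 - 0.36) * rnorm(n), z, rnorm(n))
  C <- estimate_noise_cov(X, shrinkage = 0)
  expect_equal(C$cov[1, 2], 0.6, tolerance = 0.05)
})

test_that("orthonormal lead field with tiny lambda recovers sources exactly", {
  G <- diag(5)[, 1:3]          # G'G = I, columns orthonormal
  C <- diag(5)
  inv <- make_inverse(G, C, lambda2 = 1e-10)
  s <- matrix(rnorm(3 * 20), 3)
  est <- apply_inverse(G %*% s, inv, normalize = FALSE)
  expect_lt(max(abs(est$data - s)), 1e-6)
})

test_that("strong regularization shrinks the kernel toward zero", {
  set.seed(113)
  G <- matrix(rnorm(6 * 3), 6)
  C <- diag(6)
  k_small <- make_inverse(G, C, lambda2 = 0.01)
  k_big <- make_inverse(G, C, lambda2 = 1e6)
  expect_lt(sum(k_big$kernel^2), 1e-6 * sum(k_small$kernel^2))
})

test_that("dSPM normalisation matches the brute-force matrix formula", {
  lf <- make_toy_lead_field(12, default_sources(), geometry_seed = 2)
  set.seed(114)
  A <- matrix(rnorm(12 * 12), 12)
  C <- crossprod(A) / 12 + diag(12) * 0.1
  inv <- make_inverse(lf, C, lambda2 = 1 / 9)
  M <- inv$kernel
  brute <- vapply(seq_len(nrow(M)), function(j)
    sqrt((M[j, , drop = FALSE] %*% C %*% t(M[j, , drop = FALSE]))[1, 1]), 0)
  expect_equal(inv$dspm_norm, brute, tolerance = 1e-10)
})

test_that("dSPM of pure covariance-matched noise has unit variance", {
  set.seed(115)
  lf <- make_toy_lead_field(10, default_sources(), geometry_seed = 5)
  A <- matrix(rnorm(10 * 10), 10)
  C <- crossprod(A) / 10 + diag(10) * 0.05
  inv <- make_inverse(lf, C, lambda2 = 1 / 9)
  L <- t(chol(C))
  noise <- L %*% matrix(rnorm(10 * 50000), 10)
  est <- apply_inverse(noise, inv, normalize = TRUE)
  v <- apply(est$data, 1, var)
  expect_equal(unname(v), rep(1, 3), tolerance = 0.05)
})

test_that("apply_inverse is linear and strict about channels", {
  lf <- make_toy_lead_field(8, default_sources(), geometry_seed = 7)
  inv <- make_inverse(lf, diag(8), lambda2 = 0.1)
  x <- matrix(rnorm(8 * 30), 8)
  e1 <- apply_inverse(x, inv, normalize = FALSE)$data
  e2 <- apply_inverse(2 * x, inv, normalize = FALSE)$data
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  expect_equal(apply_inverse(matrix(0, 8, 5), inv)$data, matrix(0, 3, 5))
  expect_error(apply_inverse(matrix(0, 7, 5), inv), "channel mismatch")
})

test_that("singular systems are refused with advice", {
  G <- matrix(1, 3, 2)  # rank-1 gain, zero lambda, singular C
  expect_error(make_inverse(G, matrix(0, 3, 3), lambda2 = 0), "singular")
})

test_that("ROI reduction implements mean and abs-mean as declared", {
  est <- structure(list(data = rbind(a = sin(1:50), b = -sin(1:50)),
                        source_labels = c("a", "b"), normalized = TRUE),
                   class = "source_estimate")
  m <- roi_timecourse(est, list(both = c("a", "b")), reduce = "mean")
  expect_lt(max(abs(m)), 1e-12)
  am <- roi_timecourse(est, list(both = c("a", "b")), reduce = "abs-mean")
  expect_equal(unname(am[1, ]), abs(sin(1:50)), tolerance = 1e-12)
  single <- roi_timecourse(est, list(solo = "a"))
  expect_equal(unname(single[1, ]), sin(1:50))
  expect_error(roi_timecourse(est, list(bad = "zz")), "unknown source")
})

test_that("single-trial ROI epochs feed the decoder", {
  spec <- small_spec()
  sim <- simulate_participant(spec, 17)
  ncov <- estimate_noise_cov(sim$noise_epochs, shrinkage = 0.1)
  inv <- make_inverse(spec$lead_field, ncov, lambda2 = 1 / 9)
  stc <- apply_inverse(sim$epochs, inv)
  roi_ep <- roi_timecourse(stc, list(
    parietal = c("left_supramarginal", "right_supramarginal"),
    frontal = "right_inferior_frontal"))
  expect_s3_class(roi_ep, "epochs")
  expect_equal(n_channels(roi_ep), 2)
  expect_equal(n_trials(roi_ep), n_trials(sim$epochs))
})

test_that("the summed decomposition commutes with the linear inverse", {
  spec <- small_spec()
  sim <- simulate_participant(spec, 19)
  ncov <- estimate_noise_cov(sim$noise_epochs, shrinkage = 0.1)
  inv <- make_inverse(spec$lead_field, ncov, lambda2 = 1 / 9)
  ep1 <- epochs(sim$epochs$data[1, , , drop = FALSE], spec$fs, spec$tmin_ms,
                sim$epochs$labels[1], sim$epochs$channel_ids)
  dec <- decompose_epochs(ep1, n_imfs = 6, drop_residual = FALSE)
  # inverse of the reconstruction equals sum of per-IMF inverses (linearity)
  per_imf <- lapply(seq_len(dim(dec$data)[1]), function(k)
    apply_inverse(matrix(dec$data[k, 1, , ], n_channels(ep1)), inv,
                  normalize = FALSE)$data)
  direct <- apply_inverse(matrix(ep1$data[1, , ], n_channels(ep1)), inv,
                          normalize = FALSE)$data
  expect_equal(Reduce(`+`, per_imf), direct, tolerance = 1e-8)
})
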