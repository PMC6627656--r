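test_that("coefficients of a constant image sit at the gradient floor", {
  cf <- compute_coefficients(matrix(500, 6, 6), diffusion_params())
  for (ck in cf[c("c1", "c2", "c3", "c4")])
    expect_true(all(ck == 0.001))
  expect_true(all(cf$s == 0.004))
})

test_that("the west coefficient across a vertical step matches the hand value", {
  # columns x < 2 (0-based) at 0, the rest at 100; pixel just right of the
  # step has axial difference 100 and zero tangential difference in the flat
  # column behind it: c1 = sqrt(100^2) + 0.001
  img <- make_step_edge(6, 6, 0, 100, 2)
  cf <- compute_coefficients(img, diffusion_params())
  expect_equal(cf$c1[3, 3], 100.001)
  expect_equal(cf$c1[3, 2], 0.001)    # flat region keeps the floor
})

test_that("adjacency symmetry holds exactly on a seeded random image", {
  set.seed(31)
  img <- matrix(runif(15 * 11, 0, 4095), 15, 11)
  cf <- compute_coefficients(img, diffusion_params(beta = 1))
  # c2 at (x-1, y) == c1 at (x, y); c4 at (x, y-1) == c3 at (x, y)
  expect_identical(cf$c2[, -ncol(img)], cf$c1[, -1])
  expect_identical(cf$c4[-nrow(img), ], cf$c3[-1, ])
  # beta = 2 goes through a different power but must keep the symmetry
  cf2 <- compute_coefficients(img, diffusion_params(beta = 2))
  expect_identical(cf2$c2[, -ncol(img)], cf2$c1[, -1])
})

test_that("coefficient_field validates positivity and adjacency symmetry", {
  one <- matrix(1, 4, 4)
  expect_s3_class(coefficient_field(one, one, one, one), "coefficient_field")
  expect_error(coefficient_field(one, one, one, 0 * one), "positive")
  bad <- one; bad[2, 2] <- 2
  expect_error(coefficient_field(bad, one, one, one), "adjacency")
})

test_that("apply_operator is the identity at alpha = 0 and on constants", {
  set.seed(5)
  img <- matrix(runif(64, 0, 100), 8, 8)
  cf <- compute_coefficients(img, diffusion_params())
  v <- matrix(rnorm(64), 8, 8)
  expect_identical(apply_operator(cf, 0, v), v)
  const <- matrix(3.7, 8, 8)
  expect_equal(apply_operator(cf, 0.2, const), const)
  expect_error(apply_operator(cf, 0.2, matrix(0, 4, 4)),
               class = "radusm_dim_error")
})

test_that("matrix-free operator matches dense assembly to machine precision", {
  set.seed(97)
  for (n in c(4L, 6L, 8L)) {
    img <- matrix(runif(n * n, 0, 4095), n, n)
    cf <- compute_coefficients(img, diffusion_params())
    A <- dense_rad_matrix(cf, 0.02)
    v <- matrix(rnorm(n * n), n, n)
    expect_equal(apply_operator(cf, 0.02, v),
                 matrix(A %*% as.vector(v), n, n), tolerance = 1e-13)
    expect_identical(max(abs(A - t(A))), 0)  # exactly symmetric
    # strictly diagonally dominant: excess is the identity's 1 (boundary rows more)
    excess <- diag(A) - (rowSums(abs(A)) - abs(diag(A)))
    expect_true(all(excess >= 1 - 1e-12))
  }
})

test_that("rad_smooth fixes constants, is exact at alpha = 0, and matches the dense solve", {
  const <- image2d(matrix(1234, 8, 8))
  expect_lt(max(abs(rad_smooth(const, diffusion_params()) - 1234)), 1e-6)
  set.seed(12)
  img <- image2d(matrix(runif(64, 0, 4095), 8, 8))
  expect_identical(pixels(rad_smooth(img, diffusion_params(alpha_diff = 0))),
                   pixels(img))
  p <- diffusion_params(alpha_diff = 0.02, solver_tol = 1e-12)
  cf <- compute_coefficients(img, p)
  oracle <- matrix(solve(dense_rad_matrix(cf, p$alpha_diff), as.vector(pixels(img))), 8, 8)
  expect_lt(rel_l2(pixels(rad_smooth(img, p)), oracle), 1e-6)
})

test_that("rad_smooth conserves the mean and obeys the maximum principle", {
  set.seed(88)
  cases <- list(std_phantom()$img,
                image2d(matrix(runif(32 * 32, 0, 4095), 32, 32)))
  for (img in cases) for (a in c(0.02, 0.2)) {
    sm <- rad_smooth(img, diffusion_params(alpha_diff = a))
    expect_lt(abs(mean(sm) - mean(img)) / abs(mean(img)), 1e-8)
    rng <- max(img) - min(img)
    expect_gte(min(sm), min(img) - 1e-6 * rng)
    expect_lte(max(sm), max(img) + 1e-6 * rng)
  }
})

test_that("smoothing distance grows monotonically with alpha_diff", {
  img <- std_phantom()$img
  d <- vapply(c(0.001, 0.02, 0.2), function(a)
    sqrt(sum((rad_smooth(img, diffusion_params(alpha_diff = a)) - img)^2)),
    numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("multiple lagged-diffusivity iterations run and keep the invariants", {
  img <- std_phantom()$img
  sm <- rad_smooth(img, diffusion_params(alpha_diff = 0.02, outer_iters = 3L))
  expect_length(attr(sm, "diagnostics"), 3L)
  expect_lt(abs(mean(sm) - mean(img)) / abs(mean(img)), 1e-8)
})

test_that("gaussian_smooth preserves constants, the mean, and realizes its kernel", {
  const <- image2d(matrix(321, 10, 10))
  expect_equal(pixels(gaussian_smooth(const, 5)), matrix(321, 10, 10))
  set.seed(2)
  img <- image2d(matrix(runif(40 * 40, 0, 4095), 40, 40))
  expect_lt(abs(mean(gaussian_smooth(img, 15)) - mean(img)) / mean(img), 1e-10)
  # impulse response equals the normalized truncated kernel
  z <- matrix(0, 31, 31); z[16, 16] <- 1
  out <- pixels(gaussian_smooth(image2d(z), kernel_size = 7, sigma = 7 / 6))
  k1 <- exp(-(-3:3)^2 / (2 * (7 / 6)^2)); k1 <- k1 / sum(k1)
  expect_equal(out[13:19, 13:19], outer(k1, k1), tolerance = 1e-12)
  expect_equal(sum(out), 1)
  expect_error(gaussian_smooth(img, 8), "odd")
})

test_that("perona_malik_smooth keeps constants and the mean, and rejects unstable steps", {
  const <- image2d(matrix(50, 8, 8))
  expect_equal(pixels(perona_malik_smooth(const, 30, 0.2, 5)), matrix(50, 8, 8))
  img <- std_phantom()$img
  sm <- perona_malik_smooth(img, kappa = 30, step = 0.2, n_steps = 10)
  expect_lt(abs(mean(sm) - mean(img)) / mean(img), 1e-8)
  expect_error(perona_malik_smooth(img, 30, step = 0.3, n_steps = 1),
               class = "radusm_stability_error")
})

test_that("RAD smooths edges more than impulses; the baselines do the reverse", {
  fx <- selectivity_fixture()
  rad <- selectivity_factors(rad_smooth(fx$img, diffusion_params(alpha_diff = 0.02)), fx)
  expect_gt(rad[["edge"]], rad[["impulse"]])
  gau <- selectivity_factors(gaussian_smooth(fx$img, 15), fx)
  expect_lt(gau[["edge"]], gau[["impulse"]])
  pm <- selectivity_factors(perona_malik_smooth(fx$img, kappa = 30, step = 0.2, n_steps = 10), fx)
  expect_lt(pm[["edge"]], pm[["impulse"]])
})

test_that("with constant coefficients one implicit step matches the matched Gaussian", {
  n <- 64
  g <- outer(seq_len(n), seq_len(n),
             function(y, x) 1000 * exp(-((y - 32)^2 + (x - 32)^2) / (2 * 8^2)))
  one <- matrix(1, n, n)
  cf <- coefficient_field(one, one, one, one)
  alpha <- 0.5                      # time alpha*c = 0.5 -> sigma = sqrt(2*0.5) = 1
  op <- function(v) apply_operator(cf, alpha, v)
  sol <- pbcg_solve(op, op, rhs = g, precond = jacobi_preconditioner(cf, alpha),
                    tol = 1e-12)$solution
  ref <- pixels(gaussian_smooth(image2d(g), kernel_size = 9, sigma = 1))
  expect_lt(rel_l2(sol, ref), 0.02)
})
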