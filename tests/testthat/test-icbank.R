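test_that("ICA recovers Laplacian sources mixed by a random matrix", {
  set.seed(13)
  n <- 2000
  S <- matrix(stats::rexp(n * 3) * sign(stats::runif(n * 3) - 0.5), n)
  A <- matrix(stats::rnorm(9), 3)
  X <- S %*% t(A)
  b <- fit_ica(X, 3, seed = 1)
  rec <- X %*% t(b$components)
  cc <- abs(stats::cor(rec, S))
  # permutation matching: every source has a dedicated component
  expect_true(all(apply(cc, 2, max) > 0.95))
  expect_true(all(apply(cc, 1, max) > 0.95))
  # recovered sources are uncorrelated
  g <- stats::cor(rec)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-6)
})

test_that("ICA is deterministic and reports PCA variance sensibly", {
  set.seed(14)
  X <- matrix(stats::rnorm(600 * 10), 600)
  # isotropic data has no unique rotation, so non-convergence is expected
  a <- suppressWarnings(fit_ica(X, 4, seed = 7))
  b <- suppressWarnings(fit_ica(X, 4, seed = 7))
  expect_identical(a$components, b$components)
  # isotropic Gaussian data: k of d components retain about k/d variance
  expect_lt(abs(a$variance_retained - 0.4), 0.08)
  expect_true(all(abs(rowSums(a$components^2) - 1) < 1e-10))
  expect_error(fit_ica(X[1:10, ], 4), "samples")
})

test_that("noiseless synthetic Gabor frames are recovered exactly", {
  pars <- random_gabor_pars(8, seed = 31)
  for (p in pars) {
    vol <- array(0, c(13, 13, 11))
    vol[, , 6] <- make_gabor_frame(p)
    f <- fit_gabor(vol, seed = 2, frames = "best")$summary
    expect_gt(f$r2, 0.999)
    expect_lt(abs(f$theta - p["theta"]), 2 * pi / 180)
    expect_lt(abs(f$sigma_x / p["sigma_x"] - 1), 0.05)
    expect_lt(abs(f$freq / p["freq"] - 1), 0.05)
    expect_lt(max(abs(c(f$x0, f$y0) - p[c("x0", "y0")])), 0.3)
    dphi <- abs(f$phi - p["phi"]) %% (2 * pi)
    expect_lt(min(dphi, 2 * pi - dphi), 0.1)
  }
})

test_that("all-zero frames are flagged degenerate", {
  vol <- array(0, c(13, 13, 11))
  vol[, , 3] <- make_gabor_frame(random_gabor_pars(1, 3)[[1]])
  f <- fit_gabor(vol, frames = "all")
  z <- f$frames[f$frames$frame == 6, ]
  expect_true(z$degenerate)
  expect_equal(z$r2, 0)
  expect_error(fit_gabor(array(0, c(13, 13, 11))), "zero energy")
})

test_that("canonicalization implements the stated Gabor symmetries", {
  p <- c(x0 = 7, y0 = 7, sigma_x = 3, sigma_y = 2, theta = 1.2 * pi,
         phi = 0.3, freq = 0.1)
  q <- canonicalize_gabor(p)
  expect_equal(unname(q["theta"]), 0.2 * pi, tolerance = 1e-12)
  expect_equal(unname(q["phi"]), 2 * pi - 0.3, tolerance = 1e-12)
  p2 <- c(x0 = 7, y0 = 7, sigma_x = 3, sigma_y = 2, theta = 0.4,
          phi = -0.5, freq = 0.1)
  expect_equal(unname(canonicalize_gabor(p2)["phi"]), 2 * pi - 0.5,
               tolerance = 1e-12)
  # idempotent on a batch of random parameters
  for (p in random_gabor_pars(6, 44)) {
    q1 <- canonicalize_gabor(p + c(0, 0, 0, 0, 3 * pi, -5, 0))
    expect_equal(canonicalize_gabor(q1), q1, tolerance = 1e-12)
    expect_true(q1["theta"] >= 0 && q1["theta"] < pi)
    expect_true(q1["phi"] >= 0 && q1["phi"] < 2 * pi)
    expect_true(q1["sigma_x"] >= q1["sigma_y"])
  }
  # (theta + pi, -phi) parameterizes the same Gabor and canonicalizes equally
  p3 <- random_gabor_pars(1, 45)[[1]]
  alt <- p3; alt["theta"] <- p3["theta"] + pi; alt["phi"] <- -p3["phi"]
  expect_equal(canonicalize_gabor(alt), canonicalize_gabor(p3),
               tolerance = 1e-12)
  expect_equal(max(abs(make_gabor_frame(alt) - make_gabor_frame(p3))), 0,
               tolerance = 1e-12)
})

test_that("IC clustering agrees with exhaustive 2-means on separated blobs", {
  set.seed(17)
  blob1 <- matrix(stats::rnorm(5 * 6, sd = 0.05), 5) +
    matrix(rep(c(2, 2, 1, 1, 0.3, 0.3), each = 5), 5)
  blob2 <- matrix(stats::rnorm(5 * 6, sd = 0.05), 5) +
    matrix(rep(c(8, 8, 2, 1, 2.5, 5), each = 5), 5)
  x <- rbind(blob1, blob2)
  fits <- tibble::as_tibble(as.data.frame(x))
  names(fits) <- c("x0", "y0", "sigma_x", "sigma_y", "theta", "phi")
  model <- cluster_ics(fits, 2, seed = 3)
  want <- oracle_two_means(x)
  same <- identical(model$assignment == model$assignment[1], want$grp == want$grp[1])
  expect_true(same)
  expect_equal(model$sse, want$sse, tolerance = 1e-8)
  # duplicates land in the same cluster; k = n gives zero SSE
  expect_equal(model$assignment[1], model$assignment[2])
  full <- cluster_ics(fits[c(1, 3, 6, 8), ], 4, seed = 5)
  expect_equal(full$sse, 0, tolerance = 1e-16)
  expect_error(cluster_ics(fits[rep(1, 5), ], 3), "distinct")
})
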