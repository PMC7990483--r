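# Strain kinematics and reduction to injury metrics.

# fake sim_result with uniaxial stretch histories lambda(t) per element
fake_result <- function(eps_fun, times, volumes = NULL, tissue = NULL) {
  En <- length(eps_fun)
  S <- length(times)
  Fh <- array(0, c(En, 9, S))
  for (s in seq_len(S)) {
    Fh[, 5, s] <- 1; Fh[, 9, s] <- 1
    for (e in seq_len(En)) {
      Fh[e, 1, s] <- sqrt(1 + 2 * eps_fun[[e]](times[s]))
    }
  }
  structure(list(times = times, F_hist = Fh,
                 element_volumes = volumes %||% rep(1, En),
                 hex_tissue = tissue %||% rep("grey", En),
                 hex_voxel = seq_len(En)),
            class = "sim_result")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Green-Lagrange strain matches closed forms and brute-force arithmetic", {
  expect_equal(green_lagrange(diag(3)), matrix(0, 3, 3))
  E <- green_lagrange(diag(c(1.2, 1, 1)))
  expect_equal(E[1, 1], 0.22, tolerance = 1e-12)
  expect_equal(E[2, 2], 0)
  F <- diag(3); F[1, 2] <- 0.5
  expect_equal(green_lagrange(F), (t(F) %*% F - diag(3)) / 2)
  expect_error(green_lagrange(diag(c(-1, 1, 1))), "non-invertible")
})

test_that("first principal strain agrees with dense eigensolves, scalar and vectorised", {
  expect_equal(first_principal(matrix(0, 3, 3)), 0)
  expect_equal(first_principal(diag(c(0.22, 0, 0))), 0.22)
  expect_error(first_principal(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")
  set.seed(5)
  for (i in 1:25) {
    A <- matrix(rnorm(9), 3); A <- (A + t(A)) / 2
    ref <- max(eigen(A, symmetric = TRUE)$values)
    expect_equal(first_principal(A), ref, tolerance = 1e-10)
    expect_equal(ccistrain:::.eigmax_sym6(A[1, 1], A[2, 2], A[3, 3],
                                          A[1, 2], A[1, 3], A[2, 3]),
                 ref, tolerance = 1e-10)
  }
})

test_that("history reduction recovers the analytic max strain and rate of a sine pulse", {
  times <- seq(0, 1, by = 0.01)
  res <- fake_result(list(function(t) 0.4 * sin(pi * t)), times)
  sf <- reduce_history(res)
  expect_equal(sf$max_strain, 0.4, tolerance = 1e-3)
  expect_equal(sf$max_rate, 0.4 * pi, tolerance = 2e-2)

  # subsampled history cannot exceed the full-history maximum
  sub <- fake_result(list(function(t) 0.4 * sin(pi * t)),
                     times[seq(1, length(times), by = 2)])
  expect_lte(reduce_history(sub)$max_strain, sf$max_strain + 1e-12)

  expect_error(reduce_history(fake_result(list(function(t) t),
                                          c(0, 0.01))),
               "insufficient history")
})

test_that("history reduction commutes with element reordering", {
  times <- seq(0, 1, by = 0.05)
  funs <- list(function(t) 0.1 * t, function(t) 0.3 * sin(pi * t),
               function(t) 0.2 * t^2)
  res <- fake_result(funs, times)
  sf <- reduce_history(res)
  perm <- c(3, 1, 2)
  resp <- res
  resp$F_hist <- res$F_hist[perm, , , drop = FALSE]
  resp$hex_tissue <- res$hex_tissue[perm]
  resp$hex_voxel <- res$hex_voxel[perm]
  resp$element_volumes <- res$element_volumes[perm]
  sfp <- reduce_history(resp)
  expect_equal(sfp$max_strain, sf$max_strain[perm], tolerance = 1e-12)
  expect_equal(sfp$max_rate, sf$max_rate[perm], tolerance = 1e-12)
})

test_that("rate-of-deformation variant agrees with the eps1 derivative for uniaxial stretch", {
  times <- seq(0, 1, by = 0.01)
  res <- fake_result(list(function(t) 0.2 * t), times)
  a <- reduce_history(res, rate_method = "eps1_dot")
  b <- reduce_history(res, rate_method = "rate_tensor")
  # with eps1 = 0.2 t: eps1dot = 0.2 exactly; max D11 = 0.2/lambda^2 -> 0.2
  # near t = 0, so both reductions give ~0.2 here
  expect_equal(a$max_rate, 0.2, tolerance = 1e-6)
  expect_equal(b$max_rate, 0.2, tolerance = 0.01)
})

test_that("exceedance volume fractions count brain tissue only and respect weights", {
  vols <- c(rep(1, 8), 5, 5)
  tiss <- c(rep("grey", 5), rep("white", 3), "csf", "ventricle")
  funs <- lapply(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.15, 0.25, 0.45, 0.9, 0.9),
                 function(a) function(t) a * t)
  res <- fake_result(funs, seq(0, 1, by = 0.1), volumes = vols, tissue = tiss)
  sf <- reduce_history(res)
  # thresholds below the minimum include everything
  expect_equal(volume_fraction_above(sf, "strain", 0), 1.0)
  # brute-force recount with brain elements only (csf/ventricle excluded)
  maxs <- vapply(funs, function(f) f(1), 0)[1:8]
  for (thr in c(0.18, 0.32, 0.42)) {
    expect_equal(volume_fraction_above(sf, "strain", thr),
                 sum(maxs > thr) / 8, tolerance = 1e-10)
  }
  # monotone non-increasing in threshold
  thr <- seq(0, 0.6, by = 0.05)
  fr <- vapply(thr, function(s) volume_fraction_above(sf, "strain", s), 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("equal-volume exceedance fraction is the simple count ratio", {
  funs <- lapply(c(rep(0.5, 3), rep(0.1, 7)), function(a) function(t) a * t)
  res <- fake_result(funs, seq(0, 1, by = 0.1))
  sf <- reduce_history(res)
  expect_equal(volume_fraction_above(sf, "strain", 0.3), 0.3)
})

test_that("RMSE of predictions reduces to hand arithmetic", {
  expect_equal(rmse_prediction(c(0.02, 0.05), 0.02),
               c(0, 0.03), tolerance = 1e-12)
  expect_equal(unname(rmse_prediction(cbind(c(0.05, 0.05)), 0.02)), 0.03,
               tolerance = 1e-12)
  a <- 0.01; b <- -0.03
  pred <- cbind(0.02 + c(a, b))
  expect_equal(unname(rmse_prediction(pred, 0.02)), sqrt((a^2 + b^2) / 2),
               tolerance = 1e-12)
  expect_error(rmse_prediction(cbind(1:3), c(0.1, 0.2)), "severity")
})
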