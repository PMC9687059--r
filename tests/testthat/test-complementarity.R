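test_that("atomic density terms follow the exponential model exactly", {
  params <- unit_params("H", rho_cnt = 1, zeta = 2)
  single <- mol("H", matrix(0, 1, 3))
  d <- molecular_density(single, params, c(1, 0, 0))
  expect_equal(d$rho, exp(-2), tolerance = 1e-12)
  expect_equal(d$atom, 1L)
  expect_equal(d$dist, 1, tolerance = 1e-12)

  # two identical atoms equidistant from the point: density doubles and
  # the argmax tie goes to the lower index
  pair <- mol(c("H", "H"), rbind(c(-1, 0, 0), c(1, 0, 0)))
  d2 <- molecular_density(pair, params, c(0, 0, 0))
  expect_equal(d2$rho, 2 * exp(-2), tolerance = 1e-12)
  expect_equal(d2$atom, 1L)

  noparams <- mol("S", matrix(0, 1, 3))
  expect_error(molecular_density(noparams, params, c(0, 0, 0)), "S")
})

test_that("argmax atom selection agrees with exhaustive search", {
  params <- default_density_params()
  set.seed(101)
  for (i in 1:1000) {
    n <- 20
    m <- mol(sample(c("C", "N", "O", "H", "S"), n, replace = TRUE),
             matrix(rnorm(3 * n, sd = 4), n))
    pt <- rnorm(3, sd = 6)
    d <- molecular_density(m, params, pt)
    # brute force: evaluate every atomic term independently
    terms <- vapply(seq_len(n), function(a) {
      p <- params[m$element[a], ]
      r <- sqrt(sum((coords(m)[a, ] - pt)^2))
      p$rho_cnt * exp(-p$zeta * r)
    }, 0)
    expect_equal(d$atom, which.max(terms))
    expect_equal(d$rho, sum(terms), tolerance = 1e-9)
  }
})

test_that("CF1 at a point is the symmetric sum of log-density terms", {
  p1 <- unit_params("H", 1, 2, 1)
  expect_equal(cf1_point(1, 1, p1, p1), 0, tolerance = 1e-12)
  expect_equal(cf1_point(exp(1), exp(1), p1, p1), 2, tolerance = 1e-12)
  pC <- unit_params("C", 100, 6, 6)
  expect_equal(cf1_point(0.3, 0.01, p1, pC), cf1_point(0.01, 0.3, pC, p1),
               tolerance = 1e-12)
  expect_error(cf1_point(0, 1, p1, p1), "positive")
})

test_that("intermolecular sampling respects the density band and grid", {
  params <- unit_params("C", rho_cnt = 100, zeta = 3, z = 6)
  a <- mol("C", matrix(c(-10, 0, 0), 1))
  b <- mol("C", matrix(c(10, 0, 0), 1))
  # 20 A apart: density midway is ~100*exp(-30); a band floored well
  # above that leaves nothing
  expect_warning(
    s0 <- sample_complementarity_points(a, b, params, spacing = 1,
                                        band = c(1e-4, 1e-1)),
    "no grid points")
  expect_equal(nrow(s0$points), 0L)

  close_a <- mol("C", matrix(c(-2, 0, 0), 1))
  close_b <- mol("C", matrix(c(2, 0, 0), 1))
  s1 <- sample_complementarity_points(close_a, close_b, params,
                                      spacing = 0.6, band = c(1e-6, 1e2),
                                      min_dist = 0.5)
  s2 <- sample_complementarity_points(close_a, close_b, params,
                                      spacing = 0.3, band = c(1e-6, 1e2),
                                      min_dist = 0.5)
  ratio <- nrow(s2$points) / nrow(s1$points)
  expect_gt(ratio, 8 * 0.8)
  expect_lt(ratio, 8 * 1.2)

  # mirror-symmetric system gives a mirror-symmetric point set
  lig_sym <- mol(c("C", "C"), rbind(c(-2, 0, 0), c(2, 0, 0)))
  prot_mid <- mol("C", matrix(0, 1, 3))
  ss <- sample_complementarity_points(prot_mid, lig_sym, params,
                                      spacing = 0.5, band = c(1e-6, 1e2),
                                      min_dist = 0.5)
  flip <- ss$points; flip[, 1] <- -flip[, 1]
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
  expect_equal(key(flip), key(ss$points))
})

test_that("single-atom pair realises the closed form CF1 = const - zeta*SUMRLRE", {
  zeta <- 2
  params <- unit_params("C", rho_cnt = 5, zeta = zeta, z = 6)
  prot <- mol("C", matrix(c(-1.5, 0, 0), 1))
  lig <- mol("C", matrix(c(1.5, 0, 0), 1))
  fit <- complementarity_profile(prot, lig, params, spacing = 0.5,
                                 band = c(1e-12, 1e3), min_dist = 1)
  expect_equal(fit$b_cf1, -zeta, tolerance = 1e-9)
  expect_equal(fit$rcor2, 1, tolerance = 1e-9)
  expect_equal(fit$a_cf1, 2 * log(5^2 / 6), tolerance = 1e-9)
  expect_equal(fit$n_points, nrow(fit$points))
  expect_equal(fit$min_sumrlre, min(fit$points$sumrlre))
  expect_equal(fit$max_cf1, max(fit$points$cf1))
})

test_that("regression recovers known coefficients and noise level", {
  # points drawn on CF1 = 6.4 - 4.0*SUMRLRE + N(0, 0.3^2)
  n <- 200
  stats <- t(vapply(1:200, function(s) {
    set.seed(s)
    sumrlre <- runif(n, 2.4, 4.0)
    cf1 <- 6.4 - 4.0 * sumrlre + rnorm(n, 0, 0.3)
    fit <- cf1_fit(sumrlre, cf1)
    se <- sqrt(diag(vcov(fit$model)))
    c(za = abs(fit$a_cf1 - 6.4) / se[1], zb = abs(fit$b_cf1 + 4.0) / se[2],
      sig = abs(fit$sigma - 0.3) / 0.3)
  }, c(za = 0, zb = 0, sig = 0)))
  expect_lt(median(stats[, "za"]), 3)
  expect_lt(median(stats[, "zb"]), 3)
  expect_lt(median(stats[, "sig"]), 0.10)
})

test_that("CF1 and SUMRLRE are rigid-transform and label-swap invariant", {
  params <- default_density_params()
  set.seed(5)
  cx <- sim_toy_complex(n_protein = 12, n_ligand = 5, separation = 3,
                        seed = 5)
  pts <- matrix(rnorm(30, sd = 2), 10)
  de <- molecular_density(cx$protein, params, pts)
  dl <- molecular_density(cx$ligand, params, pts)
  ep <- params[cx$protein$element[de$atom], ]
  lp <- params[cx$ligand$element[dl$atom], ]
  cf1 <- cf1_point(de$rho, dl$rho, ep, lp)
  sumrlre <- de$dist + dl$dist

  R <- random_rotation(); tr <- rnorm(3, sd = 8)
  pts_t <- pts %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
  de_t <- molecular_density(apply_rigid(cx$protein, R, tr), params, pts_t)
  dl_t <- molecular_density(apply_rigid(cx$ligand, R, tr), params, pts_t)
  cf1_t <- cf1_point(de_t$rho, dl_t$rho,
                     params[cx$protein$element[de_t$atom], ],
                     params[cx$ligand$element[dl_t$atom], ])
  expect_equal(cf1_t, cf1, tolerance = 1e-9)
  expect_equal(de_t$dist + dl_t$dist, sumrlre, tolerance = 1e-9)

  # swapping the enzyme/ligand roles leaves both quantities unchanged
  cf1_sw <- cf1_point(dl$rho, de$rho, lp, ep)
  expect_equal(cf1_sw, cf1, tolerance = 1e-12)
})

test_that("selection principles gate on correlation and overlap efficiency", {
  row <- list(rcor2 = 0.918, max_cf1 = -4.184, a_cf1 = 6.396, b_cf1 = -4.031)
  expect_true(assess_complementarity(row)$pass)
  bad_r2 <- assess_complementarity(list(rcor2 = 0.50, max_cf1 = -3))
  expect_false(bad_r2$pass)
  expect_match(bad_r2$reasons, "Rcor2")
  bad_cf1 <- assess_complementarity(list(rcor2 = 0.95, max_cf1 = -10))
  expect_false(bad_cf1$pass)
  expect_match(bad_cf1$reasons, "overlap efficiency")
  ref <- list(a_cf1 = 9.041, b_cf1 = -4.820)
  withref <- assess_complementarity(row, reference = ref)
  expect_equal(unname(withref$coef_delta["a"]), abs(6.396 - 9.041),
               tolerance = 1e-12)
})

test_that("profile errors on insufficient sampling", {
  expect_error(cf1_fit(c(1, 2), c(1, 2)), "insufficient sampling")
})
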