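fit_quiet <- function(...) suppressWarnings(suppressMessages(fit_reml(...)))

test_that("variance_at evaluates the quadratic form on the basis", {
  sch <- tiny_schedule()
  cf <- covariance_function(diag(2), sch)
  mid <- (250 + 1615) / 2
  expect_equal(variance_at(cf, mid), 1 / 2)  # phi_1(0) = 0
  cf1 <- covariance_function(matrix(3.2, 1, 1), sch)
  for (d in c(250, 700, 1615))
    expect_equal(variance_at(cf1, d), 3.2 / 2)
  expect_error(variance_at(cf, 2000), "outside")
  # symmetry and positivity for random PSD K on a day grid
  set.seed(71)
  K <- rand_psd(3)
  cf3 <- covariance_function(K, sch)
  days <- seq(250, 1615, length.out = 100)
  v <- vapply(days, function(d) variance_at(cf3, d), numeric(1))
  expect_true(all(v >= 0))
  expect_equal(variance_at(cf3, 400, 900), variance_at(cf3, 900, 400))
})

test_that("trajectories decompose the phenotypic variance and bound h2", {
  set.seed(73)
  sch <- tiny_schedule()
  cfg <- simulation_config(ng = 40, n_rep = 2, schedule = sch,
                           beta = c(25, 3, -2, 1, 0.5),
                           K_g = diag(c(10, 2)), K_p = matrix(3, 1, 1),
                           residual = "diagonal", R_params = rep(4, 5),
                           seed = 5)
  sim <- simulate_trial(cfg)
  fit <- fit_quiet(sim$table, sch, model_spec(2, 1, "diagonal"))
  tr <- trajectories(fit, seq(250, 1615, by = 15))
  expect_true(all(tr$var_genetic >= 0))
  expect_true(all(tr$h2 >= 0 & tr$h2 <= 1))
  expect_equal(tr$var_phenotypic,
               tr$var_genetic + tr$var_perm + tr$var_residual)
  expect_true(all(tr$var_phenotypic > tr$var_genetic))
  # order-1 permanent environment variance is flat over days
  expect_equal(diff(range(tr$var_perm)), 0)
  # excluding the permanent term raises h2
  tr2 <- trajectories(fit, seq(250, 1615, by = 15), include_perm_in_h2 = FALSE)
  expect_true(all(tr2$h2 >= tr$h2))
})

test_that("h2 approaches 1 when non-genetic variance vanishes in truth", {
  set.seed(79)
  sch <- tiny_schedule()
  cfg <- simulation_config(ng = 60, n_rep = 2, schedule = sch,
                           beta = c(25, 3, -2, 1, 0.5),
                           K_g = diag(c(10, 2)), K_p = matrix(1e-4, 1, 1),
                           residual = "homogeneous", R_params = 0.01,
                           seed = 6)
  sim <- simulate_trial(cfg)
  fit <- fit_quiet(sim$table, sch, model_spec(2, 1, "homogeneous"))
  tr <- trajectories(fit, measured_days(sch))
  expect_true(all(tr$h2 > 0.95))
})

test_that("genetic values reproduce the design-matrix genetic contribution", {
  set.seed(83)
  inst <- tiny_instance(ng = 6, n_rep = 2, n_days = 4, residual = "diagonal")
  fit <- fit_quiet(inst$table, inst$schedule, inst$spec,
                   control = reml_control(n_starts = 1))
  gv <- genetic_values(fit, measured_days(inst$schedule))
  d <- fit$design
  zg <- as.numeric(d$Z %*% as.vector(t(fit$alpha_hat[d$genotypes, ,
                                                     drop = FALSE])))
  for (k in seq_len(nrow(d$table))) {
    i <- d$table$genotype[k]
    j <- as.character(d$table$day[k])
    expect_equal(gv$values[i, j], zg[k], tolerance = 1e-10)
  }
  # zero coefficients give a flat zero curve
  fit0 <- fit
  fit0$alpha_hat[1, ] <- 0
  gv0 <- genetic_values(fit0, measured_days(inst$schedule))
  expect_equal(unname(gv0$values[1, ]), rep(0, 4))
})

test_that("accuracy endpoints: PEV of 0 gives 1, PEV of K_g gives 0", {
  set.seed(89)
  inst <- tiny_instance(ng = 6, n_rep = 2, n_days = 4, ma = 2,
                        residual = "homogeneous")
  fit <- fit_quiet(inst$table, inst$schedule, inst$spec,
                   control = reml_control(n_starts = 1))
  g1 <- fit$genotypes[1]
  fit$pev_blocks[[g1]] <- matrix(0, 2, 2)
  g2 <- fit$genotypes[2]
  fit$pev_blocks[[g2]] <- fit$params$K_g
  acc <- accuracy(fit, measured_days(inst$schedule))
  expect_equal(unname(acc[g1, ]), rep(1, 4))
  expect_equal(unname(acc[g2, ]), rep(0, 4), tolerance = 1e-6)
  expect_true(all(acc >= 0 & acc <= 1))
  lin <- accuracy(fit, measured_days(inst$schedule), form = "linear")
  expect_equal(lin, acc^2, tolerance = 1e-12)
})

test_that("eigenfunction proportions, orthonormality and sign convention", {
  sch <- tiny_schedule()
  ef <- eigenfunctions(diag(c(4, 1)), sch, grid = seq(250, 1615, by = 5))
  expect_equal(ef$proportions, c(80, 20))
  # leading eigenfunction of a diagonal K is proportional to phi_0: constant
  expect_lt(diff(range(ef$functions[, 1])), 1e-10)
  # rank-1 K
  v <- c(1, 2) / sqrt(5)
  ef1 <- eigenfunctions(4 * tcrossprod(v), sch)
  expect_equal(ef1$proportions, c(100, 0), tolerance = 1e-9)
  # random PSD K: trace partition, orthonormal eigenvectors, sum to 100
  set.seed(97)
  K <- rand_psd(4)
  ef2 <- eigenfunctions(K, sch)
  expect_equal(sum(ef2$values), sum(diag(K)))
  expect_equal(sum(ef2$proportions), 100, tolerance = 1e-9)
  expect_equal(crossprod(ef2$vectors), diag(4), tolerance = 1e-10)
  # sign convention: non-negative at the first day
  expect_true(all(ef2$functions[1, ] >= -1e-12))
  expect_error(eigenfunctions(matrix(1:4, 2), sch), "symmetric")
})

test_that("a phi0-dominated K yields a near-constant leading eigenfunction", {
  sch <- tiny_schedule()
  set.seed(101)
  K <- diag(c(8.6, 1.1, 0.27, 0.03)) + rand_psd(4, 0.01)
  ef <- eigenfunctions(K, sch)
  f1 <- ef$functions[, 1]
  expect_lt(diff(range(f1)), 0.10 * abs(mean(f1)))
})
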