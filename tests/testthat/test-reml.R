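fit_quiet <- function(...) suppressWarnings(suppressMessages(fit_reml(...)))

test_that("restricted_loglik matches the dense error-contrast oracle", {
  set.seed(101)
  for (res in c("homogeneous", "diagonal", "unstructured")) {
    for (rep in 1:3) {
      inst <- tiny_instance(ng = 3, n_rep = 2, n_days = 3, ma = 2, mp = 1,
                            residual = res)
      d <- suppressMessages(build_design(inst$table, inst$schedule, inst$spec))
      expect_equal(restricted_loglik(inst$params, d),
                   dense_restricted_loglik(inst$params, d),
                   tolerance = 1e-8)
    }
  }
})

test_that("zero random variances reduce REML to the fixed-model value", {
  set.seed(7)
  inst <- tiny_instance(ng = 4, n_rep = 2, n_days = 3, residual = "homogeneous")
  d <- suppressMessages(build_design(inst$table, inst$schedule, inst$spec))
  s2 <- 1.7
  par0 <- variance_parameters(matrix(0, 2, 2), matrix(0, 1, 1),
                              "homogeneous", s2)
  ll <- restricted_loglik(par0, d)
  X <- as.matrix(d$X)
  f <- lm.fit(X[, qr(X)$pivot[seq_len(qr(X)$rank)]], d$y)
  rss <- sum(f$residuals^2)
  n <- length(d$y); p <- f$rank
  expect_equal(ll, -0.5 * ((n - p) * log(2 * pi * s2) + rss / s2),
               tolerance = 1e-8)
})

test_that("REML log-likelihood obeys the analytic scale shift", {
  set.seed(21)
  inst <- tiny_instance(ng = 3, n_rep = 2, n_days = 3, residual = "diagonal")
  d <- suppressMessages(build_design(inst$table, inst$schedule, inst$spec))
  ll1 <- restricted_loglik(inst$params, d)
  cc <- 3
  scaled <- variance_parameters(inst$params$K_g * cc^2, inst$params$K_p * cc^2,
                                "diagonal", inst$params$R_params * cc^2)
  ll2 <- restricted_loglik(scaled, d, y = d$y * cc)
  X <- as.matrix(d$X)
  rank_X <- qr(X)$rank
  expect_equal(ll2 - ll1, -(length(d$y) - rank_X) * log(cc), tolerance = 1e-8)
})

test_that("restricted_loglik rejects mismatched parameters", {
  set.seed(3)
  inst <- tiny_instance()
  d <- suppressMessages(build_design(inst$table, inst$schedule, inst$spec))
  bad <- inst$params; bad$K_g <- diag(3)
  expect_error(restricted_loglik(bad, d), "dimensions")
  expect_error(variance_parameters(matrix(c(1, 2, 2, -5), 2), diag(1),
                                   "homogeneous", 1), "semi-definite")
})

test_that("fit recovers truth on a small trial and satisfies BLUP identities", {
  set.seed(31)
  sch <- tiny_schedule()
  cfg <- simulation_config(ng = 40, n_rep = 2, schedule = sch,
                           beta = c(25, 3, -2, 1, 0.5),
                           K_g = diag(c(8, 2)), K_p = matrix(2, 1, 1),
                           residual = "homogeneous", R_params = 4,
                           seed = 99)
  sim <- simulate_trial(cfg)
  fit <- fit_quiet(sim$table, sch, model_spec(2, 1, "homogeneous"))
  expect_true(fit$converged)
  # random effects centered under balanced data
  expect_lt(max(abs(colMeans(fit$alpha_hat))), 1e-6)
  # PSD of all returned covariances
  expect_silent(chol(fit$params$K_g + diag(1e-10, 2)))
  expect_silent(chol(fit$params$K_p + diag(1e-10, 1)))
  # shrinkage: K_g - PEV block is PSD for every genotype
  for (g in fit$genotypes) {
    ev <- eigen(fit$params$K_g - fit$pev_blocks[[g]], symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  # loose truth recovery (single replicate, generous band)
  expect_lt(abs(fit$params$K_g[1, 1] - 8) / 8, 0.8)
  # correlation of coefficient BLUPs with true coefficients
  expect_gt(cor(fit$alpha_hat[, 1], sim$truth$alpha[, 1]), 0.7)
})

test_that("record order does not change the estimates", {
  set.seed(17)
  inst <- tiny_instance(ng = 5, n_rep = 2, n_days = 4, residual = "diagonal")
  fit1 <- fit_quiet(inst$table, inst$schedule, inst$spec,
                    control = reml_control(n_starts = 1))
  perm <- sample(nrow(inst$table))
  fit2 <- fit_quiet(inst$table[perm, ], inst$schedule, inst$spec,
                    control = reml_control(n_starts = 1))
  expect_equal(fit1$logL, fit2$logL, tolerance = 1e-10)
  expect_equal(fit1$alpha_hat, fit2$alpha_hat, tolerance = 1e-8)
})

test_that("a genotype with no records gets zero BLUP and PEV = K_g", {
  set.seed(5)
  sch <- harvest_schedule(c(100L, 200L, 300L))
  df <- expand.grid(genotype = sprintf("g%02d", 1:12), replication = 1:2,
                    day = c(100L, 200L, 300L), stringsAsFactors = FALSE)
  df$yield <- 20 + rnorm(nrow(df), sd = 3)
  df$yield[df$genotype == "g07"] <- NA
  fit <- fit_quiet(df, sch, model_spec(2, 1, "homogeneous"))
  pg <- predict_genetic_coefficients(fit, "g07")
  expect_equal(unname(pg$coefficients), c(0, 0))
  expect_equal(pg$pev, fit$params$K_g, tolerance = 1e-10)
  expect_error(predict_genetic_coefficients(fit, "nope"), "unknown")
  # accuracy of the no-information genotype is 0 everywhere
  acc <- accuracy(fit, c(100, 200, 300))
  expect_equal(unname(acc["g07", ]), c(0, 0, 0), tolerance = 1e-6)
})

test_that("orders exceeding the measured harvests fail before optimization", {
  sch <- harvest_schedule(c(100L, 200L))
  df <- data.frame(genotype = c("a", "b"), replication = 1L,
                   day = 100L, yield = c(1, 2))
  expect_error(fit_reml(df, sch, model_spec(3, 1, "homogeneous")),
               "exceeds")
})
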