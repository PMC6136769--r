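test_that("time standardization maps anchors to -1/+1 and is affine", {
  sch <- tiny_schedule()
  expect_equal(standardize_time(250, sch), -1)
  expect_equal(standardize_time(1615, sch), 1)
  expect_equal(standardize_time(932.5, sch), 0)
  set.seed(11)
  a <- runif(50, 250, 1615); b <- runif(50, 250, 1615)
  expect_equal(standardize_time(a, sch) + standardize_time(b, sch),
               2 * standardize_time((a + b) / 2, sch))
  expect_error(standardize_time(100, sch), "outside")
  expect_error(standardize_time(2000, sch), "outside")
})

test_that("normalized Legendre basis matches closed-form values", {
  expect_equal(legendre_row(0, 2), c(sqrt(1 / 2), 0))
  expect_equal(legendre_row(1, 3), sqrt(c(1, 3, 5) / 2))
  expect_equal(legendre_row(-1, 2), c(sqrt(1 / 2), -sqrt(3 / 2)))
  expect_error(legendre_row(0, 0), "order")
  expect_error(legendre_row(1.5, 2), "\\[-1, 1\\]")
})

test_that("basis agrees with a closed-form Legendre oracle on a grid", {
  x <- seq(-1, 1, length.out = 101)
  B <- legendre_basis(x, 7)
  for (m in 0:6) {
    oracle <- sqrt((2 * m + 1) / 2) * legendre_closed_form(x, m)
    expect_equal(B[, m + 1], oracle, tolerance = 1e-12)
  }
})

test_that("normalized basis functions have unit L2 norm on [-1, 1]", {
  for (m in 0:5) {
    nrm <- integrate(function(x) legendre_basis(x, m + 1)[, m + 1]^2,
                     -1, 1, rel.tol = 1e-10)$value
    expect_equal(nrm, 1, tolerance = 1e-8)
  }
})

test_that("parameter counting reproduces the reference grid", {
  # 12-model grid: genetic {3,4} x perm {1,2} x residual {H,D,US}, 5 harvests
  grid <- default_model_grid()
  p <- vapply(grid, count_parameters, integer(1), n_measured_harvests = 5L)
  expect_identical(p, c(8L, 10L, 12L, 14L, 12L, 14L, 16L, 18L,
                        22L, 24L, 26L, 28L))
  expect_identical(count_parameters(model_spec(1, 1, "homogeneous"), 7L), 3L)
})

test_that("model spec labels round-trip", {
  for (s in default_model_grid())
    expect_equal(spec_label(parse_model_spec(spec_label(s))), spec_label(s))
  expect_error(parse_model_spec("Leg4.D"), "parse")
  expect_error(model_spec(0, 1), "orders")
  expect_error(model_spec(6, 1, fixed_order = 5), "exceed")
})

test_that("design matrices have the documented block dimensions", {
  sch <- harvest_schedule(c(100L, 200L))
  df <- expand.grid(genotype = c("g1", "g2"), replication = 1:2,
                    day = c(100L, 200L), stringsAsFactors = FALSE)
  df$yield <- runif(nrow(df), 10, 20)
  d <- build_design(df, sch, model_spec(2, 1, "homogeneous", fixed_order = 2))
  expect_equal(dim(d$Z), c(8, 4))
  expect_equal(dim(d$W), c(8, 4))
  # each record's W entry is phi_0 = sqrt(1/2)
  expect_equal(unique(d$W@x), sqrt(1 / 2))
  # each record's Z block row holds the Legendre row at its day
  r1 <- which(d$table$genotype == "g1" & d$table$day == 200 &
                d$table$replication == 1)
  expect_equal(as.numeric(d$Z[r1, 1:2]),
               legendre_row(standardize_time(200, sch), 2))
})

test_that("full-scale design has the expected column counts", {
  cfg <- elephantgrass_config()
  sim <- simulate_trial(cfg, seed = 42)
  sim$table$yield[is.na(sim$table$yield)] <- 1  # fill to count pre-removal size
  d <- build_design(sim$table, cfg$schedule, model_spec(4, 1, "diagonal"))
  expect_equal(dim(d$Z), c(1000, 400))
  expect_equal(dim(d$W), c(1000, 200))
  expect_equal(ncol(d$X), 2 + 5)
})

test_that("missing records are dropped and empty genotypes warned about", {
  sch <- harvest_schedule(c(100L, 200L))
  df <- data.frame(genotype = c("g1", "g1", "g2", "g2"),
                   replication = c(1L, 1L, 1L, 1L),
                   day = c(100L, 200L, 100L, 200L),
                   yield = c(5, 6, NA, NA))
  expect_warning(
    expect_message(d <- build_design(df, sch,
                                     model_spec(1, 1, "homogeneous",
                                                fixed_order = 2)),
                   "dropping 2"),
    "zero non-missing")
  expect_equal(nrow(d$table), 2)
  expect_false("g2" %in% d$genotypes)
  expect_true("g2" %in% d$all_genotypes)
})

test_that("duplicate plot-day records are a hard error", {
  sch <- harvest_schedule(c(100L, 200L))
  df <- data.frame(genotype = "g1", replication = 1L,
                   day = c(100L, 100L), yield = c(5, 6))
  expect_error(phenotype_table(df, sch), "duplicate")
})
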