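surface_from_matrix <- function(M, days, sch = NULL) {
  if (is.null(sch))
    sch <- harvest_schedule(range(days))
  structure(list(days = as.numeric(days), values = M, schedule = sch),
            class = "genetic_value_surface")
}

test_that("ideotype is the per-day maximum and is permutation invariant", {
  days <- 0:100
  t <- seq(-1, 1, length.out = length(days))
  M <- rbind(g1 = t, g2 = -t)
  gv <- surface_from_matrix(M, days)
  expect_equal(unname(ideotype(gv)), abs(t))
  # single dominant clone
  M2 <- rbind(a = rep(5, 101), b = rep(1, 101))
  expect_equal(unname(ideotype(surface_from_matrix(M2, days))), rep(5, 101))
  # permutation invariance
  gvp <- surface_from_matrix(M[c(2, 1), ], days)
  expect_equal(ideotype(gvp), ideotype(gv))
})

test_that("persistence normalizes to 100 and reproduces the 2-clone case", {
  days <- 250:1615
  n <- length(days)   # 1366 integer days, an even count
  # alternating leadership: A leads with gap h on even days, B with gap g on
  # odd days, so D_A = (n/2) g^2 and D_B = (n/2) h^2 exactly
  s <- rep(c(1, -1), length.out = n)
  g <- sqrt(2 / n); h <- sqrt(6 / n)
  M <- rbind(A = ifelse(s > 0, h, 0),
             B = ifelse(s > 0, 0, g))
  p <- persistence_index(surface_from_matrix(M, days))
  expect_equal(sum(p$persistence), 100, tolerance = 1e-9)
  expect_equal(p$D[p$genotype == "A"], 1, tolerance = 1e-9)
  expect_equal(p$D[p$genotype == "B"], 3, tolerance = 1e-9)
  expect_equal(p$persistence[p$genotype == "A"], 75, tolerance = 1e-9)
  expect_equal(p$persistence[p$genotype == "B"], 25, tolerance = 1e-9)
  expect_equal(p$rank[p$genotype == "A"], 1L)
})

test_that("identical clones share the index equally under the degenerate rule", {
  days <- 250:1615
  M <- matrix(7, nrow = 10, ncol = length(days),
              dimnames = list(sprintf("c%02d", 1:10), NULL))
  gv <- surface_from_matrix(M, days)
  expect_warning(p <- persistence_index(gv), "ideotype")
  expect_equal(p$persistence, rep(10, 10))
  expect_true(all(p$degenerate))
})

test_that("persistence is invariant to adding a constant to every curve", {
  set.seed(103)
  days <- 250:1615
  M <- matrix(rnorm(20 * length(days), 10, 2), nrow = 20,
              dimnames = list(sprintf("c%02d", 1:20), NULL))
  gv <- surface_from_matrix(M, days)
  gvs <- surface_from_matrix(M + 123.4, days)
  p1 <- persistence_index(gv); p2 <- persistence_index(gvs)
  expect_equal(p1$persistence, p2$persistence, tolerance = 1e-9)
  expect_equal(p1$genotype, p2$genotype)
})

test_that("shrinking one clone's deviation cannot lower its index", {
  set.seed(107)
  days <- 250:1615
  n <- length(days)
  base <- 10 + sin(seq(0, 3, length.out = n))
  M <- rbind(top = base + 2,
             mid = base,
             low = base - 3)
  gv <- surface_from_matrix(M, days)
  p_before <- suppressWarnings(persistence_index(gv))
  # move 'mid' halfway toward the ideotype (top stays the ideotype)
  M2 <- M
  M2["mid", ] <- (M["mid", ] + M["top", ]) / 2
  p_after <- suppressWarnings(persistence_index(surface_from_matrix(M2, days)))
  expect_gte(p_after$persistence[p_after$genotype == "mid"],
             p_before$persistence[p_before$genotype == "mid"])
})

test_that("the top-ranked clone has the smallest deviation sum (brute force)", {
  set.seed(109)
  days <- 250:1615
  M <- matrix(rnorm(15 * length(days), 12, 3), nrow = 15,
              dimnames = list(sprintf("c%02d", 1:15), NULL))
  gv <- surface_from_matrix(M, days)
  p <- persistence_index(gv)
  ideo <- apply(M, 2, max)
  D_brute <- apply(M, 1, function(g) sum((g - ideo)^2))
  expect_equal(p$genotype[1], names(which.min(D_brute)))
  expect_equal(sort(p$D), sort(unname(D_brute)), tolerance = 1e-10)
})

test_that("a clone dominating from mid-trajectory onward ranks first", {
  # emulate a late-dominant clone: modest early, clearly best from
  # mid-trajectory onward, against an early leader and mediocre competitors
  set.seed(113)
  sch <- tiny_schedule()
  days <- 250:1615
  t <- standardize_time(days, sch)
  n <- length(days)
  M <- matrix(0, 12, n, dimnames = list(sprintf("c%02d", 1:12), NULL))
  for (i in 2:11) M[i, ] <- runif(1, -1, 0) + runif(1, -0.5, 0.5) * t
  M[1, ] <- 2.5 - 2.5 * (t + 1)       # early leader, collapses later
  M[12, ] <- 0.5 + 3 * pmax(t, 0)     # surges after the middle of the range
  gv <- surface_from_matrix(M, days, sch)
  p <- persistence_index(gv)
  expect_equal(p$genotype[1], "c12")
})
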