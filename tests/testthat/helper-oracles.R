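# Shared fixtures and independent oracles for the test suite.

# Classical Legendre polynomial by the explicit closed form
#   P_m(x) = 2^-m sum_k C(m,k)^2 (x-1)^(m-k) (x+1)^k
# -- independent of the recurrence used by the package.
legendre_closed_form <- function(x, m) {
  k <- 0:m
  sapply(x, function(xi)
    2^(-m) * sum(choose(m, k)^2 * (xi - 1)^(m - k) * (xi + 1)^k))
}

rand_psd <- function(m, scale = 1) {
  A <- matrix(rnorm(m * m), m, m)
  crossprod(A) / m * scale + diag(1e-3 * scale, m)
}

tiny_schedule <- function() {
  harvest_schedule(c(250L, 500L, 815L, 1405L, 1615L))
}

# A small random model instance: data frame, schedule, spec and true
# variance parameters; sized for dense-oracle comparison.
tiny_instance <- function(ng = 3L, n_rep = 2L, n_days = 3L,
                          ma = 2L, mp = 1L,
                          residual = c("homogeneous", "diagonal",
                                       "unstructured")) {
  residual <- match.arg(residual)
  sch <- harvest_schedule(seq(100L, 400L, length.out = n_days))
  spec <- model_spec(ma, mp, residual, fixed_order = min(3L, n_days))
  Kg <- rand_psd(ma, 2)
  Kp <- rand_psd(mp, 1)
  Rp <- switch(residual,
               homogeneous = 0.5 + runif(1),
               diagonal = 0.5 + runif(n_days),
               unstructured = rand_psd(n_days, 0.8) + diag(0.3, n_days))
  cfg <- simulation_config(ng = ng, n_rep = n_rep, schedule = sch,
                           beta = rnorm(spec$fixed_order, sd = 2) + c(20, rep(0, spec$fixed_order - 1L)),
                           K_g = Kg, K_p = Kp, residual = residual,
                           R_params = Rp,
                           rep_effects = seq(-0.5, 0.5, length.out = n_rep),
                           seed = sample.int(1e6, 1))
  sim <- simulate_trial(cfg)
  list(table = sim$table, schedule = sch, spec = spec,
       params = variance_parameters(Kg, Kp, residual, Rp),
       truth = sim$truth)
}

# Brute-force REML log-likelihood: forms the full marginal covariance V and
# evaluates the density of an orthonormal basis of error contrasts.
dense_restricted_loglik <- function(params, design, y = design$y) {
  X <- as.matrix(design$X)
  Z <- as.matrix(design$Z)
  W <- as.matrix(design$W)
  ng <- length(design$genotypes)
  np <- length(design$plots)
  G <- kronecker(diag(ng), params$K_g)
  P <- kronecker(diag(np), params$K_p)
  n <- nrow(X)
  nh <- length(measured_days(design$schedule))
  R <- switch(params$residual,
              homogeneous = diag(rep(params$R_params, n)),
              diagonal = diag(params$R_params[design$harvest_index]),
              unstructured = {
                M <- matrix(0, n, n)
                for (rows in split(seq_len(n), design$table$plot)) {
                  h <- design$harvest_index[rows]
                  M[rows, rows] <- params$R_params[h, h]
                }
                M
              })
  V <- Z %*% G %*% t(Z) + W %*% P %*% t(W) + R
  sv <- svd(X)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  Q <- qr.Q(qr(X), complete = TRUE)[, (r + 1):n, drop = FALSE]
  z <- drop(crossprod(Q, y))
  S <- crossprod(Q, V %*% Q)
  cS <- chol(S)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(cS))) +
            sum(backsolve(cS, z, transpose = TRUE)^2))
}
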