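#' Configure a synthetic multi-harvest clone trial
#'
#' Describes a clone trial simulated exactly under the random regression
#' model that the package fits: genotype coefficient vectors drawn from
#' \eqn{N(0, K_g)}, plot permanent-environment coefficients from
#' \eqn{N(0, K_p)}, residuals from the chosen structure, a fixed mean
#' trajectory on the Legendre basis, small fixed replication offsets, and a
#' per-harvest plot death process that truncates a plot's records (dead
#' clones stop yielding data).
#'
#' @param ng Number of clonal genotypes.
#' @param n_rep Number of replications (plots per genotype).
#' @param schedule A [harvest_schedule()].
#' @param beta Fixed mean-curve coefficients on the normalized Legendre
#'   basis (length gives the fixed order).
#' @param K_g,K_p Genetic and permanent-environment coefficient
#'   covariances (orders taken from their dimensions).
#' @param residual Residual structure name.
#' @param R_params Residual parameters (see [variance_parameters()]).
#' @param rep_effects Fixed replication offsets, length `n_rep` (Mg/ha).
#' @param death_prob Per-harvest probability that a live plot dies before
#'   that harvest (applies from the second measured harvest on); records
#'   from the death harvest onward are missing.
#' @param dead_plot_as_zero Encode post-death records as 0 yield instead of
#'   missing.
#' @param seed Integer seed; simulation is bit-reproducible given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(ng, n_rep, schedule, beta, K_g, K_p,
                              residual = c("diagonal", "homogeneous",
                                           "unstructured"),
                              R_params,
                              rep_effects = c(-0.5, 0.5),
                              death_prob = 0,
                              dead_plot_as_zero = FALSE,
                              seed = 20180913L) {
  residual <- match.arg(residual)
  K_g <- as.matrix(K_g); K_p <- as.matrix(K_p)
  check_psd(K_g, "K_g"); check_psd(K_p, "K_p")
  if (residual == "unstructured") check_psd(as.matrix(R_params), "R_params")
  else if (any(R_params <= 0)) stop("residual variances must be > 0")
  if (death_prob < 0 || death_prob > 1) stop("death_prob must be in [0, 1]")
  if (length(rep_effects) != n_rep)
    stop("rep_effects must have length n_rep")
  structure(list(ng = as.integer(ng), n_rep = as.integer(n_rep),
                 schedule = schedule, beta = as.numeric(beta),
                 K_g = K_g, K_p = K_p, residual = residual,
                 R_params = R_params, rep_effects = as.numeric(rep_effects),
                 death_prob = death_prob,
                 dead_plot_as_zero = dead_plot_as_zero,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-harvest clone trial with known truth
#'
#' Draws a dataset from the random regression model described by a
#' [simulation_config()] and returns both the phenotype table and the
#' generating truth (coefficient vectors, the true genetic value surface on
#' the measured days, and the true variance trajectories), enabling
#' parameter-recovery and ranking-recovery studies.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `simulated_dataset`: `table` (a
#'   [phenotype_table()]), `truth` (list: `alpha`, `p`, `genetic_surface`,
#'   `trajectories`, `config`).
#' @export
simulate_trial <- function(config, seed = NULL) {
  if (!inherits(config, "simulation_config"))
    stop("`config` must be a simulation_config")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  sch <- config$schedule
  mdays <- measured_days(sch)
  nh <- length(mdays)
  tstar <- standardize_time(mdays, sch)
  Phi_b <- legendre_basis(tstar, length(config$beta))
  ma <- nrow(config$K_g); mp <- nrow(config$K_p)
  Phi_a <- legendre_basis(tstar, ma)
  Phi_p <- legendre_basis(tstar, mp)

  ng <- config$ng; nr <- config$n_rep
  La <- chol_psd(config$K_g); Lp <- chol_psd(config$K_p)
  alpha <- matrix(stats::rnorm(ng * ma), ng, ma) %*% t(La)
  rownames(alpha) <- sprintf("G%03d", seq_len(ng))
  np <- ng * nr
  pcoef <- matrix(stats::rnorm(np * mp), np, mp) %*% t(Lp)

  fixed_curve <- drop(Phi_b %*% config$beta)
  g_surface <- alpha %*% t(Phi_a)          # ng x nh true genetic values
  pe_vals <- pcoef %*% t(Phi_p)            # np x nh

  recs <- vector("list", np)
  k <- 0L
  for (i in seq_len(ng)) for (r in seq_len(nr)) {
    k <- k + 1L
    e <- switch(config$residual,
                homogeneous = stats::rnorm(nh, sd = sqrt(config$R_params)),
                diagonal = stats::rnorm(nh, sd = sqrt(config$R_params)),
                unstructured = drop(chol_psd(as.matrix(config$R_params)) %*%
                                      stats::rnorm(nh)))
    y <- fixed_curve + config$rep_effects[r] + g_surface[i, ] + pe_vals[k, ] + e
    y <- pmax(y, 0)   # biological floor: a plot can yield nothing, not less
    # death process: a live plot dies before harvest h with prob death_prob
    alive <- rep(TRUE, nh)
    if (config$death_prob > 0 && nh >= 2L) {
      died <- which(stats::runif(nh - 1L) < config$death_prob)
      if (length(died)) alive[(died[1L] + 1L):nh] <- FALSE
    }
    y[!alive] <- if (config$dead_plot_as_zero) 0 else NA_real_
    recs[[k]] <- data.frame(genotype = rownames(alpha)[i], replication = r,
                            day = mdays, yield = y, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  tab <- phenotype_table(df, sch)

  vg <- rowSums((Phi_a %*% config$K_g) * Phi_a)
  vp <- rowSums((Phi_p %*% config$K_p) * Phi_p)
  ve <- switch(config$residual,
               homogeneous = rep(config$R_params, nh),
               diagonal = as.numeric(config$R_params),
               unstructured = diag(as.matrix(config$R_params)))
  truth <- list(alpha = alpha, p = pcoef,
                genetic_surface = structure(
                  list(days = as.numeric(mdays), values = g_surface,
                       schedule = sch),
                  class = "genetic_value_surface"),
                trajectories = data.frame(day = mdays, var_genetic = vg,
                                          var_perm = vp, var_residual = ve,
                                          h2 = vg / (vg + vp + ve)),
                fixed_curve = fixed_curve,
                config = config)
  structure(list(table = tab, truth = truth), class = "simulated_dataset")
}

chol_psd <- function(M) {
  m <- nrow(M)
  if (m == 0L) return(M)
  L <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m)
  }
  L
}

#' Reference elephantgrass-style trial configuration
#'
#' A frozen simulation configuration emulating a multi-harvest
#' elephantgrass clone trial: 100 clones in 2 replications, five measured
#' harvests at 250, 500, 815, 1405 and 1615 days after the uniformity
#' harvest plus a prediction-only harvest at 1090 days. The quartic fixed
#' curve interpolates the harvest means 12.51, 29.60, 19.60, 15.28 and
#' 19.07 Mg/ha. The genetic coefficient covariance is diagonal on the
#' normalized basis with eigenvalue shares 86, 11, 2.74 and 0.26% of the
#' trace — a phi0-dominated spectrum whose leading eigenfunction is
#' constant over harvests — scaled so the mean genetic variance across
#' measured harvests is 20 (Mg/ha)^2. The permanent-environment term is an
#' order-1 (constant) regression with variance 2 (Mg/ha)^2, and the
#' diagonal residual variances are set so the true per-harvest
#' heritabilities are 0.75, 0.45, 0.70, 0.72 and 0.70 (the second harvest
#' deliberately the most environment-dominated). A small plot death
#' probability (0.005 per harvest transition) mimics occasional clone
#' death late in the trial.
#'
#' @param seed Seed stored in the configuration.
#' @return A [simulation_config()].
#' @export
elephantgrass_config <- function(seed = 20180913L) {
  sch <- harvest_schedule(c(250L, 500L, 815L, 1090L, 1405L, 1615L),
                          measured = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  mdays <- measured_days(sch)
  means <- c(12.51, 29.60, 19.60, 15.28, 19.07)
  Phi5 <- legendre_basis(standardize_time(mdays, sch), 5L)
  beta <- solve(Phi5, means)

  shares <- c(0.86, 0.11, 0.0274, 0.0026)
  Phi4 <- legendre_basis(standardize_time(mdays, sch), 4L)
  mean_unit_vg <- mean(rowSums((Phi4 %*% diag(shares)) * Phi4))
  Kg <- diag(shares * 20 / mean_unit_vg, 4L)

  var_pe <- 2
  Kp <- matrix(2 * var_pe, 1L, 1L)   # phi0^2 = 1/2

  h2 <- c(0.75, 0.45, 0.70, 0.72, 0.70)
  vg <- rowSums((Phi4 %*% Kg) * Phi4)
  ve <- vg * (1 - h2) / h2 - var_pe
  stopifnot(all(ve > 0))

  simulation_config(ng = 100L, n_rep = 2L, schedule = sch, beta = beta,
                    K_g = Kg, K_p = Kp, residual = "diagonal",
                    R_params = ve, rep_effects = c(-0.5, 0.5),
                    death_prob = 0.005, seed = seed)
}
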