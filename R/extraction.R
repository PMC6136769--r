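#' Covariance function on the original time scale
#'
#' A coefficient covariance matrix together with its Legendre basis order
#' and standardization anchors, evaluable as a (co)variance surface over
#' days: \eqn{\hat V(t_1, t_2) = \phi(t_1^*)' \hat K \phi(t_2^*)}.
#'
#' @param K Symmetric PSD coefficient covariance matrix.
#' @param schedule A [harvest_schedule()] supplying the anchors.
#' @return An object of class `covariance_function`.
#' @export
covariance_function <- function(K, schedule) {
  K <- as.matrix(K)
  check_psd(K, "K")
  structure(list(K = K, order = nrow(K), schedule = schedule),
            class = "covariance_function")
}

#' Evaluate a covariance function between two days
#'
#' @param cf A [covariance_function()].
#' @param day1,day2 Days within the standardization range (`day2` defaults
#'   to `day1`, giving a variance).
#' @return \eqn{\phi(t_1^*)' K \phi(t_2^*)}; symmetric in its arguments.
#' @export
variance_at <- function(cf, day1, day2 = day1) {
  f1 <- legendre_basis(standardize_time(day1, cf$schedule), cf$order)
  f2 <- legendre_basis(standardize_time(day2, cf$schedule), cf$order)
  drop(f1 %*% cf$K %*% t(f2))
}

#' Variance and heritability trajectories from a fitted model
#'
#' Evaluates the genetic and permanent-environment variance functions on a
#' day grid, attaches the residual variance (piecewise-constant: each day
#' inherits the residual variance of the nearest measured harvest), and
#' forms the phenotypic variance and heritability
#' \eqn{h^2(t) = \sigma^2_g(t) / (\sigma^2_g(t) + \sigma^2_{pe}(t) +
#' \sigma^2_e(t))}. Set `include_perm_in_h2 = FALSE` to exclude the
#' permanent-environment component from the denominator.
#'
#' @param fit An [fit_reml()] result.
#' @param grid Integer day grid (defaults to the schedule's full day range).
#' @param include_perm_in_h2 Include \eqn{\sigma^2_{pe}} in the phenotypic
#'   denominator (default `TRUE`).
#' @return A data frame of class `trajectory_set`: day, `var_genetic`,
#'   `var_perm`, `var_residual`, `var_phenotypic`, `h2`.
#' @export
trajectories <- function(fit, grid = NULL, include_perm_in_h2 = TRUE) {
  if (!fit$converged)
    warning("trajectories from a non-converged fit")
  sch <- fit$schedule
  if (is.null(grid)) grid <- seq(sch$day_min, sch$day_max)
  cfg <- covariance_function(fit$params$K_g, sch)
  cfp <- covariance_function(fit$params$K_p, sch)
  vg <- vapply(grid, function(d) variance_at(cfg, d), numeric(1))
  vp <- vapply(grid, function(d) variance_at(cfp, d), numeric(1))
  ve <- residual_variance_at(fit$params, sch, grid)
  vph <- vg + vp + ve
  denom <- vg + ve + if (include_perm_in_h2) vp else 0
  h2 <- ifelse(denom > 0, vg / denom, 0)
  structure(data.frame(day = grid, var_genetic = vg, var_perm = vp,
                       var_residual = ve, var_phenotypic = vph, h2 = h2),
            class = c("trajectory_set", "data.frame"))
}

# residual variance as a step function over harvests: each day takes the
# variance of the nearest measured harvest
residual_variance_at <- function(params, schedule, grid) {
  mdays <- measured_days(schedule)
  nearest <- vapply(grid, function(d) which.min(abs(mdays - d)), integer(1))
  switch(params$residual,
         homogeneous = rep(params$R_params, length(grid)),
         diagonal = params$R_params[nearest],
         unstructured = diag(params$R_params)[nearest])
}

#' Estimated genetic value surface
#'
#' Evaluates each genotype's genetic trajectory \eqn{\hat g_i(t) = \sum_m
#' \hat\alpha_{im} \phi_m(t^*)} on a day grid, including prediction-only
#' days for which no records exist.
#'
#' @param fit An [fit_reml()] result.
#' @param grid Integer day grid (default: the schedule's full day range).
#' @return An object of class `genetic_value_surface`: a list with `days`,
#'   matrix `values` (genotypes x days) and the schedule.
#' @export
genetic_values <- function(fit, grid = NULL) {
  sch <- fit$schedule
  if (is.null(grid)) grid <- seq(sch$day_min, sch$day_max)
  Phi <- legendre_basis(standardize_time(grid, sch), fit$spec$genetic_order)
  vals <- fit$alpha_hat %*% t(Phi)
  colnames(vals) <- as.character(grid)
  structure(list(days = as.numeric(grid), values = vals, schedule = sch),
            class = "genetic_value_surface")
}

#' @export
print.genetic_value_surface <- function(x, ...) {
  cat("Genetic value surface:", nrow(x$values), "genotypes x",
      length(x$days), "days (", min(x$days), "-", max(x$days), ")\n")
  invisible(x)
}

#' Prediction accuracy surface
#'
#' Accuracy of each genotype's predicted genetic value at each grid day,
#' from the prediction-error variance of its coefficient BLUPs:
#' \eqn{PEV_i(t) = \phi(t^*)' \, PEV_i \, \phi(t^*)} and
#' \eqn{\hat r_i(t) = \sqrt{1 - PEV_i(t)/\hat\sigma^2_g(t)}} (the standard
#' breeding-value accuracy; `form = "linear"` drops the square root).
#' Values are clipped into \eqn{[0, 1]}; days where the genetic variance
#' vanishes get accuracy 0 with a warning.
#'
#' @param fit An [fit_reml()] result.
#' @param grid Integer day grid.
#' @param form `"sqrt"` (default) or `"linear"`.
#' @return Matrix (genotypes x days) of accuracies in \eqn{[0, 1]}.
#' @export
accuracy <- function(fit, grid = NULL, form = c("sqrt", "linear")) {
  form <- match.arg(form)
  sch <- fit$schedule
  if (is.null(grid)) grid <- seq(sch$day_min, sch$day_max)
  Phi <- legendre_basis(standardize_time(grid, sch), fit$spec$genetic_order)
  cfg <- covariance_function(fit$params$K_g, sch)
  vg <- vapply(grid, function(d) variance_at(cfg, d), numeric(1))
  out <- matrix(0, nrow(fit$alpha_hat), length(grid),
                dimnames = list(rownames(fit$alpha_hat), as.character(grid)))
  zero_vg <- vg <= .Machine$double.eps * max(vg, 1)
  if (any(zero_vg))
    warning("genetic variance is zero at ", sum(zero_vg),
            " grid day(s); accuracy reported as 0 there")
  for (i in seq_len(nrow(out))) {
    pb <- fit$pev_blocks[[rownames(out)[i]]]
    pev <- rowSums((Phi %*% pb) * Phi)
    rel <- ifelse(zero_vg, 0, pmin(1, pmax(0, 1 - pev / vg)))
    out[i, ] <- if (form == "sqrt") sqrt(rel) else rel
  }
  out
}

#' Eigenfunctions of a genetic covariance function
#'
#' Eigendecomposition of the coefficient covariance matrix, each
#' eigenvector contracted with the normalized Legendre basis to give an
#' eigenfunction of the covariance function over time. Because the basis is
#' orthonormal on \eqn{[-1, 1]}, the eigenfunctions are orthonormal under
#' the same inner product and the eigenvalues partition the total
#' coefficient variance (the trace). Eigenvalues are sorted descending and
#' reported as percent of the trace; each eigenfunction's sign is fixed so
#' its value at the first day is positive (first nonzero value positive on
#' ties).
#'
#' @param K_g Symmetric PSD genetic coefficient covariance (or an `rr_fit`,
#'   from which it is taken).
#' @param schedule A [harvest_schedule()] (taken from the fit if omitted).
#' @param grid Integer day grid for the eigenfunction values.
#' @return An object of class `eigenfunction_set`: `values` (eigenvalues,
#'   descending), `proportions` (percent, summing to 100), `vectors`
#'   (columns are coefficient eigenvectors), `functions` (grid x n
#'   matrix of eigenfunction values), `days`.
#' @export
eigenfunctions <- function(K_g, schedule = NULL, grid = NULL) {
  if (inherits(K_g, "rr_fit")) {
    if (is.null(schedule)) schedule <- K_g$schedule
    K_g <- K_g$params$K_g
  }
  K_g <- as.matrix(K_g)
  if (!isSymmetric(unname(K_g), tol = 1e-8)) stop("K_g must be symmetric")
  if (is.null(schedule)) stop("a harvest schedule is required")
  if (is.null(grid)) grid <- seq(schedule$day_min, schedule$day_max)
  e <- eigen((K_g + t(K_g)) / 2, symmetric = TRUE)
  lambda <- e$values
  vecs <- e$vectors
  Phi <- legendre_basis(standardize_time(grid, schedule), nrow(K_g))
  funs <- Phi %*% vecs
  for (k in seq_len(ncol(funs))) {
    pivot <- funs[1L, k]
    if (abs(pivot) < 1e-12) {
      nz <- which(abs(funs[, k]) >= 1e-12)
      pivot <- if (length(nz)) funs[nz[1L], k] else 1
    }
    if (pivot < 0) { funs[, k] <- -funs[, k]; vecs[, k] <- -vecs[, k] }
  }
  tot <- sum(lambda)
  structure(list(values = lambda,
                 proportions = if (tot > 0) 100 * lambda / tot
                               else rep(0, length(lambda)),
                 vectors = vecs, functions = funs, days = grid),
            class = "eigenfunction_set")
}

#' @export
print.eigenfunction_set <- function(x, ...) {
  cat("Eigenfunctions of the genetic covariance function\n")
  cat("  proportional eigenvalues (%):",
      paste(sprintf("%.2f", x$proportions), collapse = ", "), "\n")
  invisible(x)
}
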