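#' Variance parameters of a random regression model
#'
#' Bundles the genetic coefficient covariance \eqn{K_g}, the
#' permanent-environment coefficient covariance \eqn{K_p} and the residual
#' parameters, validating symmetry and positive semi-definiteness.
#'
#' @param K_g Symmetric PSD matrix (`genetic_order` x `genetic_order`).
#' @param K_p Symmetric PSD matrix (`perm_order` x `perm_order`).
#' @param residual Residual structure: `"homogeneous"`, `"diagonal"` or
#'   `"unstructured"`.
#' @param R_params Residual parameters: a single variance, a vector of
#'   per-harvest variances, or a full symmetric PSD covariance matrix over
#'   the measured harvests.
#' @return An object of class `variance_parameters`.
#' @export
variance_parameters <- function(K_g, K_p,
                                residual = c("diagonal", "homogeneous", "unstructured"),
                                R_params) {
  residual <- match.arg(residual)
  K_g <- as.matrix(K_g); K_p <- as.matrix(K_p)
  check_psd(K_g, "K_g"); check_psd(K_p, "K_p")
  if (residual == "unstructured") {
    R_params <- as.matrix(R_params)
    check_psd(R_params, "unstructured residual covariance")
  } else {
    R_params <- as.numeric(R_params)
    if (residual == "homogeneous" && length(R_params) != 1L)
      stop("homogeneous residual takes a single variance")
    if (any(R_params <= 0)) stop("residual variances must be > 0")
  }
  structure(list(K_g = K_g, K_p = K_p, residual = residual, R_params = R_params),
            class = "variance_parameters")
}

check_psd <- function(M, what) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop(what, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) && min(ev) < -1e-8 * max(abs(ev), 1))
    stop(what, " must be positive semi-definite")
  invisible(TRUE)
}

# ---- log-Cholesky parameterization ------------------------------------------

chol_npar <- function(m) (m * (m + 1L)) %/% 2L

# theta: first m entries are log-diagonals of the lower Cholesky factor,
# the remaining m(m-1)/2 fill the strict lower triangle column-wise.
theta_to_cov <- function(theta, m) {
  L <- matrix(0, m, m)
  diag(L) <- exp(theta[seq_len(m)])
  if (m > 1L) L[lower.tri(L)] <- theta[-seq_len(m)]
  tcrossprod(L)
}

cov_to_theta <- function(K) {
  m <- nrow(K)
  L <- t(chol(K + diag(1e-12 * max(diag(K), 1), m)))
  c(log(diag(L)), L[lower.tri(L)])
}

# Pack/unpack the full REML parameter vector for a model spec.
# Layout: [K_g chol | K_p chol | residual], terms skipped when dropped.
theta_layout <- function(ma, mp, residual, nh) {
  ng <- if (ma > 0L) chol_npar(ma) else 0L
  np <- if (mp > 0L) chol_npar(mp) else 0L
  nr <- switch(residual, homogeneous = 1L, diagonal = nh, unstructured = chol_npar(nh))
  list(ng = ng, np = np, nr = nr, total = ng + np + nr,
       ma = ma, mp = mp, residual = residual, nh = nh)
}

theta_unpack <- function(theta, lay) {
  i <- 0L
  Kg <- if (lay$ma > 0L) theta_to_cov(theta[i + seq_len(lay$ng)], lay$ma)
        else matrix(0, 0, 0)
  i <- i + lay$ng
  Kp <- if (lay$mp > 0L) theta_to_cov(theta[i + seq_len(lay$np)], lay$mp)
        else matrix(0, 0, 0)
  i <- i + lay$np
  rp <- theta[i + seq_len(lay$nr)]
  if (lay$residual == "unstructured") {
    SigE <- theta_to_cov(rp, lay$nh); rvar <- diag(SigE)
  } else {
    SigE <- matrix(0, 0, 0); rvar <- exp(2 * rp)
  }
  list(Kg = Kg, Kp = Kp, rvar = rvar, SigE = SigE)
}

theta_pack <- function(Kg, Kp, residual, R_params, lay) {
  th <- numeric(0)
  if (lay$ma > 0L) th <- c(th, cov_to_theta(Kg))
  if (lay$mp > 0L) th <- c(th, cov_to_theta(Kp))
  th <- c(th,
          switch(residual,
                 homogeneous = 0.5 * log(R_params[1L]),
                 diagonal = 0.5 * log(rep_len(R_params, lay$nh)),
                 unstructured = cov_to_theta(as.matrix(R_params))))
  th
}

# ---- likelihood setup -------------------------------------------------------

# Groups the records of a design by genotype and by observation pattern so
# the C++ core can factor each distinct within-genotype covariance block once.
reml_setup <- function(design, include_genetic = TRUE, include_perm = TRUE) {
  spec <- design$spec
  Xd <- as.matrix(design$X)
  qrX <- qr(Xd, tol = 1e-10)
  rank_X <- qrX$rank
  keep <- qrX$pivot[seq_len(rank_X)]
  Xr <- Xd[, keep, drop = FALSE]
  logdetXtX <- as.numeric(determinant(crossprod(Xr), logarithm = TRUE)$modulus)

  tab <- design$table
  gi <- match(tab$genotype, design$genotypes)
  ord <- order(gi, tab$plot, tab$day)
  n_rec <- nrow(tab)

  ma <- if (include_genetic) spec$genetic_order else 0L
  mp <- if (include_perm) spec$perm_order else 0L
  tstar <- standardize_time(tab$day, design$schedule)
  Phi_a_all <- legendre_basis(tstar, spec$genetic_order)
  Phi_p_all <- legendre_basis(tstar, spec$perm_order)

  idx_by_g <- split(ord, gi[ord])
  keys <- character(length(idx_by_g))
  for (k in seq_along(idx_by_g)) {
    rows <- idx_by_g[[k]]
    slot <- match(tab$plot[rows], unique(tab$plot[rows]))
    keys[k] <- paste(c(slot, design$harvest_index[rows]), collapse = ",")
  }
  patterns <- lapply(split(seq_along(idx_by_g), keys), function(gs) {
    rows1 <- idx_by_g[[gs[1L]]]
    n <- length(rows1)
    Xs <- matrix(0, n * length(gs), rank_X)
    Y <- matrix(0, n, length(gs))
    for (j in seq_along(gs)) {
      rows <- idx_by_g[[gs[j]]]
      Xs[(j - 1L) * n + seq_len(n), ] <- Xr[rows, , drop = FALSE]
      Y[, j] <- tab$yield[rows]
    }
    list(phi_a = if (ma > 0L) Phi_a_all[rows1, , drop = FALSE] else matrix(0, n, 0),
         phi_p = if (mp > 0L) Phi_p_all[rows1, , drop = FALSE] else matrix(0, n, 0),
         plot = match(tab$plot[rows1], unique(tab$plot[rows1])),
         harvest = design$harvest_index[rows1],
         X = Xs, y = Y,
         genotype_index = as.integer(gs))
  })

  list(patterns = unname(patterns), n = n_rec, rank_X = rank_X,
       logdetXtX = logdetXtX, keep_cols = keep, Xr = Xr,
       lay = theta_layout(ma, mp, spec$residual,
                          sum(design$schedule$measured)))
}

block_loglik <- function(Kg, Kp, residual, rvar, SigE, setup) {
  rtype <- match(residual, c("homogeneous", "diagonal", "unstructured")) - 1L
  out <- reml_core(Kg, Kp, rtype, rvar,
                   if (length(SigE)) SigE else matrix(0, 0, 0), setup$patterns)
  if (!out$ok) return(-Inf)
  R <- tryCatch(chol(out$XtViX), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetXtViX <- 2 * sum(log(diag(R)))
  bhat <- backsolve(R, forwardsolve(t(R), out$XtViy))
  yPy <- out$ytViy - sum(out$XtViy * bhat)
  -0.5 * ((setup$n - setup$rank_X) * log(2 * pi) + out$logdetV +
            logdetXtViX - setup$logdetXtX + yPy)
}

#' Restricted (residual) log-likelihood of a random regression model
#'
#' Evaluates the REML log-likelihood of the data under marginal covariance
#' \eqn{V = Z (I \otimes K_g) Z' + W (I \otimes K_p) W' + R}, profiled over
#' the fixed effects. The value is the log-density of an orthonormal basis
#' of error contrasts, i.e. \eqn{-\tfrac12\,[(n - r_X)\log 2\pi + \log|V| +
#' \log|X'V^{-1}X| - \log|X'X| + y'Py]} with \eqn{X} reduced to full column
#' rank. Exploits the block-diagonal structure of \eqn{V} over genotypes.
#'
#' @param params A [variance_parameters()] object.
#' @param design A [build_design()] result.
#' @param y Optional response override (defaults to the design's response).
#' @return The REML log-likelihood (a scalar).
#' @export
restricted_loglik <- function(params, design, y = NULL) {
  if (!inherits(params, "variance_parameters"))
    stop("`params` must be a variance_parameters object")
  spec <- design$spec
  if (nrow(params$K_g) != spec$genetic_order ||
      nrow(params$K_p) != spec$perm_order)
    stop("parameter dimensions do not match the model spec")
  if (params$residual != spec$residual)
    stop("residual structure does not match the model spec")
  if (!is.null(y)) {
    if (length(y) != length(design$y)) stop("`y` not conformable with design")
    design$table$yield <- as.numeric(y)
    design$y <- as.numeric(y)
  }
  setup <- reml_setup(design)
  nh <- sum(design$schedule$measured)
  if (params$residual == "unstructured") {
    rvar <- diag(params$R_params); SigE <- params$R_params
  } else {
    rvar <- rep_len(params$R_params, if (params$residual == "homogeneous") 1L else nh)
    SigE <- matrix(0, 0, 0)
  }
  ll <- block_loglik(params$K_g, params$K_p, params$residual, rvar, SigE, setup)
  if (!is.finite(ll)) stop("singular marginal covariance V for these parameters")
  ll
}

#' REML fitting control options
#'
#' @param n_starts Number of optimizer starts (default 3: a
#'   phenotypic-variance-scaled start, a unit-matrix start, and a perturbed
#'   start). REML surfaces of high-order random regressions can be
#'   multimodal; extra starts trade time for robustness.
#' @param max_iter Maximum optimizer iterations per start.
#' @param rel_tol Relative log-likelihood convergence tolerance.
#' @param grad_tol Scaled gradient-norm threshold used to flag convergence.
#' @param seed Seed for the perturbed starts.
#' @param variance_floor Relative floor (times the phenotypic variance)
#'   applied to covariance eigenvalues that collapse onto the boundary.
#' @return A list of control settings.
#' @export
reml_control <- function(n_starts = 3L, max_iter = 500L, rel_tol = 1e-8,
                         grad_tol = 1e-4, seed = 20180913L,
                         variance_floor = 1e-10) {
  list(n_starts = as.integer(n_starts), max_iter = as.integer(max_iter),
       rel_tol = rel_tol, grad_tol = grad_tol, seed = as.integer(seed),
       variance_floor = variance_floor)
}

reml_starts <- function(lay, Vp, control) {
  starts <- list()
  mk <- function(kg_scale, kp_scale, r_scale) {
    # factor 2 maps a target variance onto the phi_0 coefficient scale
    Kg <- if (lay$ma > 0L) diag(2 * kg_scale * 0.6^(seq_len(lay$ma) - 1L),
                                lay$ma) else NULL
    Kp <- if (lay$mp > 0L) diag(2 * kp_scale * 0.6^(seq_len(lay$mp) - 1L),
                                lay$mp) else NULL
    Rp <- switch(lay$residual,
                 homogeneous = r_scale,
                 diagonal = rep(r_scale, lay$nh),
                 unstructured = diag(r_scale, lay$nh))
    theta_pack(Kg, Kp, lay$residual, Rp, lay)
  }
  starts[[1L]] <- mk(0.3 * Vp, 0.2 * Vp, 0.5 * Vp)
  if (control$n_starts >= 2L) starts[[2L]] <- mk(0.5, 0.5, 1)
  if (control$n_starts >= 3L) {
    set.seed(control$seed)
    for (s in 3L:control$n_starts)
      starts[[s]] <- starts[[1L]] + stats::rnorm(lay$total, sd = 0.3)
  }
  starts
}

#' Fit a random regression mixed model by REML
#'
#' Maximizes the restricted log-likelihood over a log-Cholesky
#' parameterization of \eqn{(K_g, K_p, R)} (which keeps every iterate
#' positive semi-definite), then solves the mixed model equations at the
#' optimum for the fixed effects, the genotype and plot coefficient BLUPs,
#' and the per-genotype prediction-error covariance (PEV) blocks.
#' Non-convergence is recorded in the returned object rather than raised:
#' model grids routinely contain specifications that fail to converge.
#'
#' @param table A [phenotype_table()] or raw data frame.
#' @param schedule A [harvest_schedule()].
#' @param spec A [model_spec()].
#' @param control A [reml_control()] list.
#' @param include_genetic,include_perm Set to `FALSE` to drop a random term
#'   entirely (used for the reduced models of likelihood ratio tests).
#' @return An object of class `rr_fit` with elements `spec`, `params`
#'   (a [variance_parameters()]), `beta`, `alpha_hat` (genotype coefficient
#'   BLUPs), `p_hat` (plot BLUPs), `logL`, `pev_blocks`, `n_records`,
#'   `rank_X`, `converged`, `boundary`, plus the schedule and index maps.
#' @export
fit_reml <- function(table, schedule, spec, control = reml_control(),
                     include_genetic = TRUE, include_perm = TRUE) {
  nh <- sum(schedule$measured)
  if (spec$genetic_order > nh || spec$perm_order > nh)
    stop("random regression order exceeds the number of measured harvests")
  design <- build_design(table, schedule, spec)
  p_count <- count_parameters(spec, nh)
  if (nrow(design$table) < 3L * p_count)
    warning("few records (", nrow(design$table), ") for ", p_count,
            " covariance parameters; estimates may be unstable")
  setup <- reml_setup(design, include_genetic, include_perm)
  lay <- setup$lay
  Vp <- stats::var(design$y)

  objective <- function(theta) {
    pr <- theta_unpack(theta, lay)
    ll <- block_loglik(pr$Kg, pr$Kp, lay$residual, pr$rvar, pr$SigE, setup)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # box constraints keep exp() in a sane range; off-diagonals are free
  lower <- rep(-Inf, lay$total); upper <- rep(Inf, lay$total)
  diag_pos <- diag_positions(lay)
  lower[diag_pos] <- 0.5 * log(1e-12 * max(Vp, 1e-8))
  upper[diag_pos] <- 0.5 * log(1e8 * max(Vp, 1e-8))

  starts <- reml_starts(lay, Vp, control)
  best <- NULL
  for (th0 in starts) {
    opt <- tryCatch(
      stats::nlminb(th0, objective, lower = lower, upper = upper,
                    control = list(iter.max = control$max_iter,
                                   eval.max = 20L * control$max_iter,
                                   rel.tol = control$rel_tol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("all optimizer starts failed for model ", spec_label(spec))

  logL <- -best$objective
  gr <- num_gradient(objective, best$par)
  converged <- is.finite(logL) && best$objective < 1e9 &&
    best$convergence == 0L &&
    sqrt(sum(gr^2)) < control$grad_tol * max(1, abs(logL))

  pr <- theta_unpack(best$par, lay)
  floor_val <- control$variance_floor * Vp
  bd <- FALSE
  if (lay$ma > 0L) { f <- floor_eigen(pr$Kg, floor_val); pr$Kg <- f$M; bd <- bd || f$floored }
  if (lay$mp > 0L) { f <- floor_eigen(pr$Kp, floor_val); pr$Kp <- f$M; bd <- bd || f$floored }
  if (lay$residual == "unstructured") {
    f <- floor_eigen(pr$SigE, floor_val); pr$SigE <- f$M; bd <- bd || f$floored
  }

  sol <- mme_solve(design, setup, pr, include_genetic, include_perm)

  params <- variance_parameters(
    K_g = if (lay$ma > 0L) pr$Kg else matrix(0, spec$genetic_order, spec$genetic_order),
    K_p = if (lay$mp > 0L) pr$Kp else matrix(0, spec$perm_order, spec$perm_order),
    residual = spec$residual,
    R_params = switch(spec$residual,
                      homogeneous = pr$rvar[1L],
                      diagonal = pr$rvar,
                      unstructured = pr$SigE))

  structure(
    list(spec = spec, schedule = schedule, params = params,
         beta = sol$beta, alpha_hat = sol$alpha, p_hat = sol$p,
         logL = logL,
         pev_blocks = sol$pev,
         n_records = setup$n, rank_X = setup$rank_X,
         converged = converged, boundary = bd,
         include_genetic = include_genetic, include_perm = include_perm,
         genotypes = design$all_genotypes, plots = design$plots,
         design = design, phenotypic_var = Vp,
         optimizer = list(par = best$par, iterations = best$iterations,
                          message = best$message, grad_norm = sqrt(sum(gr^2)))),
    class = "rr_fit")
}

diag_positions <- function(lay) {
  pos <- integer(0); i <- 0L
  if (lay$ma > 0L) { pos <- c(pos, i + seq_len(lay$ma)); i <- i + lay$ng }
  if (lay$mp > 0L) { pos <- c(pos, i + seq_len(lay$mp)); i <- i + lay$np }
  pos <- c(pos, i + seq_len(if (lay$residual == "unstructured") lay$nh else lay$nr))
  pos
}

num_gradient <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

floor_eigen <- function(M, floor_val) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  floored <- any(e$values < floor_val)
  v <- pmax(e$values, floor_val)
  list(M = e$vectors %*% (v * t(e$vectors)), floored = floored)
}

# Mixed model equations at the REML optimum: solutions and PEV blocks from
# the inverse coefficient matrix.
mme_solve <- function(design, setup, pr, include_genetic, include_perm) {
  spec <- design$spec
  tab <- design$table
  n <- nrow(tab)
  ng <- length(design$genotypes); np <- length(design$plots)
  ma <- spec$genetic_order; mp <- spec$perm_order

  Rinv <- residual_inverse(design, pr)
  Xr <- Matrix::Matrix(setup$Xr, sparse = TRUE)
  blocks <- list(Xr)
  if (include_genetic) blocks <- c(blocks, list(design$Z))
  if (include_perm) blocks <- c(blocks, list(design$W))
  M <- do.call(cbind, blocks)
  C <- as.matrix(Matrix::crossprod(M, Rinv %*% M))
  pX <- ncol(Xr)
  off <- pX
  if (include_genetic) {
    Kginv <- solve(pr$Kg)
    for (i in seq_len(ng)) {
      idx <- off + (i - 1L) * ma + seq_len(ma)
      C[idx, idx] <- C[idx, idx] + Kginv
    }
    off <- off + ng * ma
  }
  if (include_perm) {
    Kpinv <- solve(pr$Kp)
    for (i in seq_len(np)) {
      idx <- off + (i - 1L) * mp + seq_len(mp)
      C[idx, idx] <- C[idx, idx] + Kpinv
    }
  }
  rhs <- as.numeric(Matrix::crossprod(M, Rinv %*% design$y))
  Cinv <- solve(C)
  sol <- as.numeric(Cinv %*% rhs)

  beta <- sol[seq_len(pX)]
  names(beta) <- colnames(design$X)[setup$keep_cols]

  alpha <- matrix(0, length(design$all_genotypes), ma,
                  dimnames = list(design$all_genotypes,
                                  paste0("a", seq_len(ma) - 1L)))
  pev <- vector("list", length(design$all_genotypes))
  names(pev) <- design$all_genotypes
  if (include_genetic) {
    for (i in seq_len(ng)) {
      idx <- pX + (i - 1L) * ma + seq_len(ma)
      gname <- design$genotypes[i]
      alpha[gname, ] <- sol[idx]
      pev[[gname]] <- Cinv[idx, idx, drop = FALSE]
    }
    # genotypes present in the table but with no usable records: zero BLUP,
    # PEV equal to the full genetic covariance (no-information shrinkage)
    for (gname in setdiff(design$all_genotypes, design$genotypes))
      pev[[gname]] <- pr$Kg
  } else {
    for (gname in design$all_genotypes) pev[[gname]] <- matrix(0, ma, ma)
  }

  pmat <- matrix(0, np, mp, dimnames = list(design$plots,
                                            paste0("p", seq_len(mp) - 1L)))
  if (include_perm) {
    off <- pX + if (include_genetic) ng * ma else 0L
    pmat[] <- matrix(sol[off + seq_len(np * mp)], np, mp, byrow = TRUE)
  }
  list(beta = beta, alpha = alpha, p = pmat, pev = pev)
}

residual_inverse <- function(design, pr) {
  n <- length(design$y)
  if (length(pr$SigE)) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (rows in split(seq_len(n), design$table$plot)) {
      h <- design$harvest_index[rows]
      B <- solve(pr$SigE[h, h, drop = FALSE])
      ii <- c(ii, rep(rows, each = length(rows)))
      jj <- c(jj, rep(rows, times = length(rows)))
      xx <- c(xx, as.vector(B))
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  } else if (length(pr$rvar) == 1L) {
    Matrix::Diagonal(n, 1 / pr$rvar)
  } else {
    Matrix::Diagonal(n, 1 / pr$rvar[design$harvest_index])
  }
}

#' @export
print.rr_fit <- function(x, ...) {
  cat("Random regression REML fit:", spec_label(x$spec), "\n")
  cat(sprintf("  records: %d  rank(X): %d  logL: %.3f  converged: %s%s\n",
              x$n_records, x$rank_X, x$logL, x$converged,
              if (x$boundary) "  (boundary)" else ""))
  cat("  genetic coefficient variances:",
      paste(signif(diag(x$params$K_g), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.rr_fit <- function(object, ...) {
  structure(object$logL, df = count_parameters(object$spec,
                                               sum(object$schedule$measured)),
            class = "logLik")
}

#' Genotype coefficient BLUPs and their prediction-error covariance
#'
#' @param fit An [fit_reml()] result.
#' @param genotype_id A genotype identifier present in the fit.
#' @return A list with `coefficients` (length `genetic_order`) and `pev`
#'   (its prediction-error covariance block). A genotype known to the fit
#'   but carrying no records gets zero coefficients and `pev` equal to
#'   \eqn{\hat K_g}.
#' @export
predict_genetic_coefficients <- function(fit, genotype_id) {
  if (!genotype_id %in% fit$genotypes)
    stop("unknown genotype: ", genotype_id)
  list(coefficients = fit$alpha_hat[genotype_id, ],
       pev = fit$pev_blocks[[genotype_id]])
}
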