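#' Schwarz Bayesian information criterion for a REML fit
#'
#' \eqn{BIC = -2 \log L + p \log(n - r_X)} with natural logarithm, where
#' \eqn{p} counts the estimated (co)variance parameters, \eqn{n} the
#' records and \eqn{r_X} the rank of the fixed-effects incidence matrix
#' (the REML sample size is the number of error contrasts).
#'
#' @param logL REML log-likelihood.
#' @param p Number of estimated covariance parameters.
#' @param n Number of records.
#' @param rank_X Rank of the fixed-effects matrix.
#' @return The BIC value (smaller is better).
#' @export
bic <- function(logL, p, n, rank_X) {
  if (n <= rank_X) stop("n must exceed rank(X)")
  if (p < 0) stop("p must be >= 0")
  -2 * logL + p * log(n - rank_X)
}

#' Likelihood ratio test between nested REML fits
#'
#' Tests the contribution of a random term by comparing a full fit with a
#' reduced fit from which the genetic or the permanent-environment term was
#' omitted (same fixed effects and residual structure, so the REML
#' likelihoods are comparable). The statistic \eqn{2(\log L_{full} -
#' \log L_{red})} is clipped at zero and compared against the
#' \eqn{\chi^2_1} upper 1% critical value 6.63 — the conventional
#' single-threshold rule for variance-component LRTs in this literature.
#' The exact chi-squared mixture under a boundary null makes this threshold
#' conservative, so the degrees-of-freedom-matched critical value is also
#' reported for reference.
#'
#' @param full,reduced `rr_fit` objects; `reduced` must drop the genetic or
#'   the permanent-environment term of `full`.
#' @return A list with `statistic`, `significant_1pct` (6.63 threshold),
#'   `df` (covariance-parameter difference) and `critical_df_matched`.
#' @export
lrt <- function(full, reduced) {
  if (!inherits(full, "rr_fit") || !inherits(reduced, "rr_fit"))
    stop("lrt() expects two rr_fit objects")
  drops_genetic <- full$include_genetic && !reduced$include_genetic
  drops_perm <- full$include_perm && !reduced$include_perm
  if (!(drops_genetic || drops_perm))
    stop("`reduced` must omit the genetic or the permanent-environment term")
  if (!identical(full$spec$residual, reduced$spec$residual) ||
      full$spec$fixed_order != reduced$spec$fixed_order)
    stop("fits are not nested: fixed part and residual structure must match")
  stat <- max(0, 2 * (full$logL - reduced$logL))
  df <- count_parameters(full$spec, sum(full$schedule$measured)) -
    count_parameters_reduced(reduced)
  list(statistic = stat,
       significant_1pct = stat > chisq_crit_1pct(1L),
       df = df,
       critical_df_matched = chisq_crit_1pct(max(1L, df)))
}

count_parameters_reduced <- function(fit) {
  nh <- sum(fit$schedule$measured)
  p <- count_parameters(fit$spec, nh)
  if (!fit$include_genetic)
    p <- p - chol_npar(fit$spec$genetic_order)
  if (!fit$include_perm)
    p <- p - chol_npar(fit$spec$perm_order)
  as.integer(p)
}

#' Parameter count of the equivalent multi-trait model
#'
#' Treating each of `n_harvests` harvests as a separate trait with an
#' unstructured genetic covariance and an unstructured residual covariance
#' requires \eqn{2 \cdot n(n+1)/2} parameters (and cannot separate the
#' permanent-environment effect from the residual). The comparison
#' quantifies the parsimony of the random regression formulation.
#'
#' @param n_harvests Number of measured harvests (traits).
#' @return Integer parameter count.
#' @export
count_parameters_multitrait <- function(n_harvests) {
  n_harvests <- as.integer(n_harvests)
  if (n_harvests < 1L) stop("need at least one harvest")
  2L * chol_npar(n_harvests)
}

#' Upper 1% chi-squared critical value
#' @param df Degrees of freedom.
#' @return The critical value; `chisq_crit_1pct(1)` is 6.63 to two decimals.
#' @export
chisq_crit_1pct <- function(df = 1L) stats::qchisq(0.99, df)

#' Default model grid
#'
#' Genetic orders \{3, 4\} crossed with permanent-environment orders
#' \{1, 2\} and residual structures \{homogeneous, diagonal,
#' unstructured\}: 12 candidate models, labelled `Leg3.1.H` ... `Leg4.2.US`.
#'
#' @param genetic_orders,perm_orders,residuals Grid axes.
#' @return A list of [model_spec()] objects.
#' @export
default_model_grid <- function(genetic_orders = c(3L, 4L),
                               perm_orders = c(1L, 2L),
                               residuals = c("homogeneous", "diagonal",
                                             "unstructured")) {
  specs <- list()
  for (res in residuals)
    for (ma in genetic_orders)
      for (mp in perm_orders)
        specs[[length(specs) + 1L]] <- model_spec(ma, mp, res)
  specs
}

#' Fit and compare a grid of random regression models
#'
#' Fits each candidate model, computes its parameter count and BIC, and
#' (optionally) likelihood-ratio tests of the genetic and
#' permanent-environment terms against reduced fits. Reduced fits are
#' cached across candidates that share them. Per-model failures are
#' recorded, not fatal. The selected model is the minimum-BIC converged
#' fit; a parsimony report (the most parsimonious model within one LRT
#' critical value of the best) is included because information criteria and
#' parsimony judgments can disagree on real data.
#'
#' @param table Phenotype table.
#' @param schedule A [harvest_schedule()].
#' @param specs List of [model_spec()]s (default [default_model_grid()]).
#' @param control A [reml_control()].
#' @param compute_lrt Compute the term-wise LRTs (two extra reduced fits
#'   per distinct reduced model)?
#' @return An object of class `model_comparison`: a data frame `table`
#'   (label, p, converged, logL, BIC, LRTs, significance flags), the list
#'   of `fits`, `best` (minimum-BIC label) and `best_fit`.
#' @export
scan_models <- function(table, schedule, specs = default_model_grid(),
                        control = reml_control(), compute_lrt = TRUE) {
  if (!length(specs)) stop("empty model grid")
  nh <- sum(schedule$measured)
  fits <- list()
  reduced_cache <- list()
  rows <- vector("list", length(specs))

  reduced_fit <- function(spec, drop) {
    key <- paste(drop,
                 if (drop == "genetic") spec$perm_order else spec$genetic_order,
                 spec$residual, sep = "|")
    if (is.null(reduced_cache[[key]])) {
      reduced_cache[[key]] <<- tryCatch(
        fit_reml(table, schedule, spec, control,
                 include_genetic = drop != "genetic",
                 include_perm = drop != "perm"),
        error = function(e) NULL)
    }
    reduced_cache[[key]]
  }

  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    label <- spec_label(spec)
    p <- count_parameters(spec, nh)
    fit <- tryCatch(fit_reml(table, schedule, spec, control),
                    error = function(e) {
                      warning("fit failed for ", label, ": ",
                              conditionMessage(e))
                      NULL
                    })
    fits[[label]] <- fit
    row <- data.frame(model = label, genetic_order = spec$genetic_order,
                      perm_order = spec$perm_order, residual = spec$residual,
                      p = p, converged = !is.null(fit) && fit$converged,
                      logL = NA_real_, BIC = NA_real_,
                      LRT_genetic = NA_real_, sig_genetic = NA,
                      LRT_perm = NA_real_, sig_perm = NA,
                      stringsAsFactors = FALSE)
    if (!is.null(fit)) {
      row$logL <- fit$logL
      if (fit$converged)
        row$BIC <- bic(fit$logL, p, fit$n_records, fit$rank_X)
      if (compute_lrt && fit$converged) {
        rg <- reduced_fit(spec, "genetic")
        if (!is.null(rg)) {
          t <- lrt(fit, rg)
          row$LRT_genetic <- t$statistic; row$sig_genetic <- t$significant_1pct
        }
        rp <- reduced_fit(spec, "perm")
        if (!is.null(rp)) {
          t <- lrt(fit, rp)
          row$LRT_perm <- t$statistic; row$sig_perm <- t$significant_1pct
        }
      }
    }
    rows[[i]] <- row
  }

  tab <- do.call(rbind, rows)
  conv <- tab[tab$converged & !is.na(tab$BIC), , drop = FALSE]
  best <- if (nrow(conv)) conv$model[which.min(conv$BIC)] else NA_character_
  # parsimony view: fewest parameters among converged models whose BIC is
  # within the chi-squared 1% critical value of the minimum
  parsimony <- NA_character_
  if (nrow(conv)) {
    near <- conv[conv$BIC <= min(conv$BIC) + chisq_crit_1pct(1L), , drop = FALSE]
    parsimony <- near$model[order(near$p, near$BIC)][1L]
  }
  structure(list(table = tab, fits = fits, best = best,
                 best_fit = if (!is.na(best)) fits[[best]] else NULL,
                 parsimony = parsimony),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  tab <- x$table
  tab$logL <- round(tab$logL, digits)
  tab$BIC <- round(tab$BIC, digits)
  tab$LRT_genetic <- round(tab$LRT_genetic, digits)
  tab$LRT_perm <- round(tab$LRT_perm, digits)
  print(tab[, c("model", "p", "converged", "logL", "BIC",
                "LRT_genetic", "LRT_perm")], row.names = FALSE)
  cat("minimum-BIC model:", x$best,
      " | most parsimonious near-equivalent:", x$parsimony, "\n")
  invisible(x)
}
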