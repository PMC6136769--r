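#' Ideotype trajectory
#'
#' The per-day maximum estimated genetic value across the evaluated cohort:
#' the idealized target genotype against which every clone is measured.
#' Cohort-relative: subsetting the clones changes the ideotype.
#'
#' @param gvalues A [genetic_values()] surface with at least 2 genotypes.
#' @return Numeric vector over the surface's days.
#' @export
ideotype <- function(gvalues) {
  if (!inherits(gvalues, "genetic_value_surface"))
    stop("`gvalues` must be a genetic_value_surface")
  if (nrow(gvalues$values) == 0L) stop("empty genetic value surface")
  apply(gvalues$values, 2L, max)
}

#' Genotype-ideotype persistence index
#'
#' For each clone the squared deviation from the ideotype (the per-day
#' maximum genetic value) is summed over every integer day of the
#' evaluation range, \eqn{D_i = \sum_j (\hat g_{ij} - \max_i \hat
#' g_{ij})^2}, and the persistence index is the normalized reciprocal
#' \deqn{Persistence_i = \frac{1/D_i}{\sum_i 1/D_i} \times 100,}
#' so the indices are positive and sum to 100: a clone that tracks the
#' best performer closely across all harvests scores high even when it is
#' never itself the top yielder. A clone that *is* the ideotype everywhere
#' (D = 0, impossible once any two distinct curves cross) has its raw score
#' replaced by \eqn{1/\epsilon}, \eqn{\epsilon = 10^{-12} \bar D}, and is
#' flagged.
#'
#' @param gvalues A [genetic_values()] surface whose day grid covers
#'   `day_range` at integer resolution.
#' @param day_range Evaluation range in days (default `c(250, 1615)`).
#' @param days_only Optional integer vector restricting the sum to specific
#'   days (e.g. the measured harvests); default uses every integer day in
#'   `day_range`.
#' @return A data frame of class `persistence_table`, sorted by descending
#'   persistence: genotype, `D` (summed squared deviation), `persistence`
#'   (percent), `rank`, `degenerate` flag.
#' @export
persistence_index <- function(gvalues, day_range = c(250, 1615),
                              days_only = NULL) {
  if (!inherits(gvalues, "genetic_value_surface"))
    stop("`gvalues` must be a genetic_value_surface")
  if (nrow(gvalues$values) < 2L) stop("need at least 2 genotypes")
  want <- if (is.null(days_only)) seq(day_range[1L], day_range[2L])
          else as.numeric(days_only)
  idx <- match(want, gvalues$days)
  if (anyNA(idx))
    stop("the genetic value surface does not cover the requested days; ",
         "evaluate genetic_values() on an integer-day grid spanning ",
         day_range[1L], "-", day_range[2L])
  G <- gvalues$values[, idx, drop = FALSE]
  ideo <- apply(G, 2L, max)
  D <- rowSums((G - matrix(ideo, nrow(G), length(ideo), byrow = TRUE))^2)
  degenerate <- D == 0
  if (any(degenerate)) {
    eps <- 1e-12 * mean(D[!degenerate])
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
    warning(sum(degenerate), " clone(s) coincide with the ideotype at ",
            "every day; raw score capped at 1/eps")
    D[degenerate] <- eps
  }
  inv <- 1 / D
  pct <- 100 * inv / sum(inv)
  out <- data.frame(genotype = rownames(gvalues$values), D = D,
                    persistence = pct, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$persistence, out$genotype), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("persistence_table", "data.frame")
  out
}
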