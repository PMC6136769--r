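#' Plot variance and heritability trajectories
#'
#' Variance components over days (left axis scale) with heritability shown
#' in its own panel.
#'
#' @param traj A [trajectories()] data frame.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj) {
  long <- rbind(
    data.frame(day = traj$day, value = traj$var_genetic,
               series = "genetic variance", panel = "variance"),
    data.frame(day = traj$day, value = traj$var_perm,
               series = "permanent environment", panel = "variance"),
    data.frame(day = traj$day, value = traj$var_phenotypic,
               series = "phenotypic variance", panel = "variance"),
    data.frame(day = traj$day, value = traj$h2,
               series = "heritability", panel = "heritability"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "days since uniformity harvest", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the genetic value curves of all genotypes
#'
#' @param gv A [genetic_values()] surface.
#' @param highlight Optional genotype ids drawn in colour.
#' @return A ggplot object.
#' @export
plot_genetic_values <- function(gv, highlight = NULL) {
  df <- data.frame(
    genotype = rep(rownames(gv$values), times = length(gv$days)),
    day = rep(gv$days, each = nrow(gv$values)),
    value = as.vector(gv$values))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                        group = .data$genotype)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = "days since uniformity harvest",
                  y = "estimated genetic value (Mg/ha)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight))
    p <- p + ggplot2::geom_line(
      data = df[df$genotype %in% highlight, ],
      ggplot2::aes(colour = .data$genotype), linewidth = 0.8)
  p
}

#' Plot the eigenfunctions of the genetic covariance function
#'
#' @param ef An [eigenfunctions()] result.
#' @return A ggplot object with proportional eigenvalues in the legend.
#' @export
plot_eigenfunctions <- function(ef) {
  labs <- sprintf("Psi%d (%.2f%%)", seq_along(ef$values), ef$proportions)
  df <- data.frame(
    day = rep(ef$days, times = ncol(ef$functions)),
    value = as.vector(ef$functions),
    fn = factor(rep(labs, each = length(ef$days)), levels = labs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                   colour = .data$fn)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "days since uniformity harvest", y = "eigenfunction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the most and least persistent clones
#'
#' Genetic value trajectories of the `top_k` most and `bottom_k` least
#' persistent clones, persistence percentages in the legend.
#'
#' @param gv A [genetic_values()] surface.
#' @param pers A [persistence_index()] table over the same cohort.
#' @param top_k,bottom_k How many clones from each end of the ranking.
#' @return A ggplot object.
#' @export
plot_persistence <- function(gv, pers, top_k = 10L, bottom_k = 5L) {
  sel <- rbind(utils::head(pers, top_k), utils::tail(pers, bottom_k))
  sel <- sel[!duplicated(sel$genotype), ]
  labs <- sprintf("%s (%.2f%%)", sel$genotype, sel$persistence)
  keep <- match(sel$genotype, rownames(gv$values))
  df <- data.frame(
    clone = factor(rep(labs, times = length(gv$days)), levels = labs),
    day = rep(gv$days, each = nrow(sel)),
    value = as.vector(gv$values[keep, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                   colour = .data$clone)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "days since uniformity harvest",
                  y = "estimated genetic value (Mg/ha)", colour = NULL) +
    ggplot2::theme_minimal()
}
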