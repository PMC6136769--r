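#' Harvest schedule for a multi-harvest trial
#'
#' Defines the harvest days of a longitudinal trial (days since the
#' uniformity harvest), which of them carry phenotypic records, and the
#' anchors used to standardize time onto \eqn{[-1, 1]} for the Legendre
#' basis. Prediction-only time points (e.g. a harvest at which no yield was
#' recorded) are declared with `measured = FALSE` so that genetic values can
#' be predicted there without any data entering the fit.
#'
#' @param days Integer vector of harvest days, strictly increasing.
#' @param measured Logical vector, one entry per day; `FALSE` marks
#'   prediction-only time points. Default: all measured.
#' @param day_min,day_max Standardization anchors. Default to the first and
#'   last *measured* day, so that the measured range maps exactly onto
#'   \eqn{[-1, 1]}.
#' @return An object of class `harvest_schedule`.
#' @examples
#' harvest_schedule(c(250, 500, 815, 1090, 1405, 1615),
#'                  measured = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
#' @export
harvest_schedule <- function(days, measured = rep(TRUE, length(days)),
                             day_min = NULL, day_max = NULL) {
  days <- as.integer(days)
  if (length(days) < 2L || any(diff(days) <= 0L))
    stop("`days` must be strictly increasing with at least 2 entries")
  if (length(measured) != length(days))
    stop("`measured` must have one entry per day")
  if (sum(measured) < 2L)
    stop("at least 2 measured days are required")
  mdays <- days[measured]
  if (is.null(day_min)) day_min <- min(mdays)
  if (is.null(day_max)) day_max <- max(mdays)
  if (day_min > min(days) || day_max < max(days))
    stop("anchors must cover all schedule days")
  structure(
    list(days = days, measured = as.logical(measured),
         day_min = as.integer(day_min), day_max = as.integer(day_max)),
    class = "harvest_schedule")
}

#' Days of a schedule carrying phenotypic records
#' @param schedule A [harvest_schedule()].
#' @return Integer vector of measured days.
#' @export
measured_days <- function(schedule) schedule$days[schedule$measured]

#' @export
print.harvest_schedule <- function(x, ...) {
  cat("Harvest schedule:", paste0(x$days, ifelse(x$measured, "", "*")),
      "\n  (* = prediction-only)  anchors:", x$day_min, "-", x$day_max, "\n")
  invisible(x)
}

#' Standardize a harvest day onto the interval -1 to 1
#'
#' Affine map \eqn{t^* = 2 (d - d_{min}) / (d_{max} - d_{min}) - 1} so that
#' the anchor days map to -1 and +1. Days outside the anchor range raise an
#' error: evaluating the polynomial basis outside the data support is
#' extrapolation and must be requested explicitly by widening the anchors.
#'
#' @param day Numeric vector of days.
#' @param schedule A [harvest_schedule()] supplying the anchors.
#' @return Numeric vector of standardized times in \eqn{[-1, 1]}.
#' @export
standardize_time <- function(day, schedule) {
  lo <- schedule$day_min; hi <- schedule$day_max
  if (lo >= hi) stop("day_min must be < day_max")
  if (any(day < lo | day > hi))
    stop("day outside the standardization range [", lo, ", ", hi,
         "]; widen the schedule anchors to extrapolate")
  2 * (day - lo) / (hi - lo) - 1
}

#' Normalized Legendre polynomial basis row
#'
#' Evaluates the first `order` normalized Legendre polynomials
#' \eqn{\phi_m(x) = \sqrt{(2m+1)/2}\, P_m(x)}, \eqn{m = 0, \dots,
#' order - 1}, at a standardized time. The normalization makes the basis
#' orthonormal on \eqn{[-1, 1]}, the convention used throughout the
#' covariance-function literature. "Order" counts coefficients, so order
#' \eqn{k} spans polynomial degrees up to \eqn{k - 1}.
#'
#' @param t_star Standardized time in \eqn{[-1, 1]}.
#' @param order Number of basis functions (\eqn{\ge 1}).
#' @return Numeric vector of length `order`.
#' @seealso [legendre_basis()] for whole design blocks.
#' @export
legendre_row <- function(t_star, order) {
  drop(legendre_basis(t_star, order))
}

#' Normalized Legendre basis matrix
#'
#' @param t_star Numeric vector of standardized times in \eqn{[-1, 1]}.
#' @param order Number of basis functions.
#' @return Matrix with `length(t_star)` rows and `order` columns; column
#'   \eqn{m + 1} holds \eqn{\phi_m(t^*)}.
#' @export
legendre_basis <- function(t_star, order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    stop("`order` must be a single integer >= 1")
  order <- as.integer(order)
  if (any(abs(t_star) > 1 + 1e-12))
    stop("standardized time outside [-1, 1]")
  n <- length(t_star)
  P <- matrix(0, n, order)
  P[, 1L] <- 1
  if (order >= 2L) P[, 2L] <- t_star
  if (order >= 3L) {
    # three-term recurrence (m+1) P_{m+1} = (2m+1) x P_m - m P_{m-1}
    for (m in 1L:(order - 2L))
      P[, m + 2L] <- ((2 * m + 1) * t_star * P[, m + 1L] - m * P[, m]) / (m + 1)
  }
  sweep(P, 2L, sqrt((2 * seq_len(order) - 1) / 2), `*`)
}

#' Random regression model specification
#'
#' One candidate model: the fixed mean curve order, the orders of the
#' genotype and permanent-environment random regressions, and the residual
#' covariance structure. Residual structures: `"homogeneous"` (one variance),
#' `"diagonal"` (one variance per measured harvest) or `"unstructured"`
#' (full symmetric covariance across harvests within a plot). Printed labels
#' follow the `Leg<ma>.<mp>.<H|D|US>` convention.
#'
#' @param genetic_order Order (number of coefficients) of the genotype
#'   random regression, \eqn{\ge 1}.
#' @param perm_order Order of the plot permanent-environment random
#'   regression, \eqn{\ge 1}.
#' @param residual One of `"homogeneous"`, `"diagonal"`, `"unstructured"`.
#' @param fixed_order Order of the fixed mean trajectory (default 5, a
#'   quartic).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(4, 1, "diagonal")
#' parse_model_spec("Leg4.1.D")
#' @export
model_spec <- function(genetic_order, perm_order,
                       residual = c("diagonal", "homogeneous", "unstructured"),
                       fixed_order = 5L) {
  residual <- match.arg(residual)
  genetic_order <- as.integer(genetic_order)
  perm_order <- as.integer(perm_order)
  fixed_order <- as.integer(fixed_order)
  if (genetic_order < 1L || perm_order < 1L)
    stop("random regression orders must be >= 1")
  if (genetic_order > fixed_order || perm_order > fixed_order)
    stop("random orders cannot exceed the fixed order")
  structure(
    list(fixed_order = fixed_order, genetic_order = genetic_order,
         perm_order = perm_order, residual = residual),
    class = "model_spec")
}

#' @rdname model_spec
#' @param label A label such as `"Leg4.1.D"`.
#' @export
parse_model_spec <- function(label, fixed_order = 5L) {
  m <- regmatches(label, regexec("^Leg([0-9]+)\\.([0-9]+)\\.(H|D|US)$", label))[[1]]
  if (length(m) != 4L) stop("cannot parse model label: ", label)
  res <- c(H = "homogeneous", D = "diagonal", US = "unstructured")[[m[4L]]]
  model_spec(as.integer(m[2L]), as.integer(m[3L]), res, fixed_order)
}

#' @rdname model_spec
#' @param spec A `model_spec`.
#' @export
spec_label <- function(spec) {
  code <- c(homogeneous = "H", diagonal = "D", unstructured = "US")[[spec$residual]]
  paste0("Leg", spec$genetic_order, ".", spec$perm_order, ".", code)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Random regression model", spec_label(x),
      sprintf("(fixed order %d, genetic %d, perm.env. %d, %s residuals)\n",
              x$fixed_order, x$genetic_order, x$perm_order, x$residual))
  invisible(x)
}

#' Number of (co)variance parameters of a model
#'
#' Counts the parameters estimated by REML: the genetic coefficient
#' covariance (\eqn{M_a (M_a + 1)/2}), the permanent-environment coefficient
#' covariance (\eqn{M_p (M_p + 1)/2}) and the residual parameters (1 for a
#' homogeneous structure, one per measured harvest for a diagonal one,
#' \eqn{n(n+1)/2} for an unstructured one).
#'
#' @param spec A [model_spec()].
#' @param n_measured_harvests Number of harvests carrying records.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, n_measured_harvests) {
  n_measured_harvests <- as.integer(n_measured_harvests)
  if (n_measured_harvests < 1L) stop("need at least one measured harvest")
  ma <- spec$genetic_order; mp <- spec$perm_order
  r <- switch(spec$residual,
              homogeneous = 1L,
              diagonal = n_measured_harvests,
              unstructured = (n_measured_harvests * (n_measured_harvests + 1L)) %/% 2L)
  as.integer((ma * (ma + 1L)) %/% 2L + (mp * (mp + 1L)) %/% 2L + r)
}

#' Assemble a phenotype table
#'
#' Validates and normalizes a long-format phenotype data frame. Required
#' columns: `genotype`, `replication`, `day`, `yield`; an optional `plot`
#' column identifies the experimental plot (defaulting to the
#' genotype-by-replication combination, the plot structure of a single-row
#' clone trial). Missing yields are kept as `NA` records (dead or lost
#' plots); they are dropped, with a log message, when design matrices are
#' built.
#'
#' @param df Data frame with the columns above.
#' @param schedule A [harvest_schedule()]; every `day` must be one of its
#'   measured days.
#' @return A validated `phenotype_table` (a data.frame).
#' @export
phenotype_table <- function(df, schedule) {
  req <- c("genotype", "replication", "day", "yield")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  out <- data.frame(genotype = as.character(df$genotype),
                    replication = as.integer(df$replication),
                    day = as.integer(df$day),
                    yield = as.numeric(df$yield),
                    stringsAsFactors = FALSE)
  out$plot <- if ("plot" %in% names(df)) as.character(df$plot)
              else paste(out$genotype, out$replication, sep = ":")
  bad <- setdiff(unique(out$day), measured_days(schedule))
  if (length(bad))
    stop("days not in the measured schedule: ", paste(bad, collapse = ", "))
  if (any(out$yield < 0, na.rm = TRUE)) stop("negative yields found")
  dup <- duplicated(out[, c("plot", "day")])
  if (any(dup))
    stop("duplicate (plot, day) records: e.g. plot ", out$plot[dup][1L],
         " day ", out$day[dup][1L])
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Build design matrices for a random regression model
#'
#' Constructs the fixed-effects matrix `X` (replication indicators followed
#' by the fixed-order Legendre regression), the genotype random-regression
#' incidence `Z` (one block of `genetic_order` columns per genotype) and the
#' plot permanent-environment incidence `W` (one block of `perm_order`
#' columns per plot), all with one row per non-missing record. Records with
#' missing yield are dropped (logged via `message`). The replication
#' indicator columns and the constant Legendre column are deliberately kept
#' jointly rank-deficient; the fitting routine works with the numerical
#' rank of `X`.
#'
#' @param table A [phenotype_table()] (or a raw data frame, coerced).
#' @param schedule A [harvest_schedule()].
#' @param spec A [model_spec()].
#' @return A list of class `design_matrices` with sparse `X`, `Z`, `W`
#'   (from the Matrix package), the response `y`, `harvest_index` (residual
#'   block label per record), index maps `genotypes` and `plots`, and the
#'   retained record table.
#' @export
build_design <- function(table, schedule, spec) {
  if (!inherits(table, "phenotype_table")) table <- phenotype_table(table, schedule)
  if (nrow(table) == 0L) stop("empty phenotype table")
  all_genotypes <- sort(unique(table$genotype))
  drop_n <- sum(is.na(table$yield))
  if (drop_n > 0L)
    message("dropping ", drop_n, " record(s) with missing yield")
  tab <- table[!is.na(table$yield), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no non-missing records")
  lost <- setdiff(all_genotypes, unique(tab$genotype))
  if (length(lost))
    warning("genotype(s) with zero non-missing records dropped from Z: ",
            paste(lost, collapse = ", "))

  # canonical (sorted) index maps and record order: estimates are then
  # exactly invariant to the order in which records arrive
  genotypes <- sort(unique(tab$genotype))
  plots <- sort(unique(tab$plot))
  tab <- tab[order(match(tab$genotype, genotypes), tab$plot, tab$day), ,
             drop = FALSE]
  rownames(tab) <- NULL

  mdays <- measured_days(schedule)
  tstar <- standardize_time(tab$day, schedule)
  reps <- sort(unique(tab$replication))
  Xrep <- outer(tab$replication, reps, `==`) * 1
  colnames(Xrep) <- paste0("rep", reps)
  Xleg <- legendre_basis(tstar, spec$fixed_order)
  colnames(Xleg) <- paste0("phi", seq_len(spec$fixed_order) - 1L)
  X <- cbind(Xrep, Xleg)

  gi <- match(tab$genotype, genotypes)
  pi <- match(tab$plot, plots)
  n <- nrow(tab)

  Phi_a <- legendre_basis(tstar, spec$genetic_order)
  Phi_p <- legendre_basis(tstar, spec$perm_order)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), spec$genetic_order),
    j = rep((gi - 1L) * spec$genetic_order, spec$genetic_order) +
      rep(seq_len(spec$genetic_order), each = n),
    x = as.vector(Phi_a),
    dims = c(n, length(genotypes) * spec$genetic_order))
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), spec$perm_order),
    j = rep((pi - 1L) * spec$perm_order, spec$perm_order) +
      rep(seq_len(spec$perm_order), each = n),
    x = as.vector(Phi_p),
    dims = c(n, length(plots) * spec$perm_order))

  structure(
    list(X = Matrix::Matrix(X, sparse = TRUE), Z = Z, W = W,
         y = tab$yield,
         harvest_index = match(tab$day, mdays),
         genotypes = genotypes, plots = plots,
         all_genotypes = all_genotypes,
         n_dropped = drop_n,
         table = tab, schedule = schedule, spec = spec),
    class = "design_matrices")
}
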