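#' Interval set for one statistic
#'
#' An ordered partition of the real line into `k` half-open intervals
#' `L_1 = (-Inf, d_1], L_j = (d_{j-1}, d_j], ..., L_k = (d_{k-1}, +Inf)`,
#' defined by `k - 1` finite, strictly increasing cut points.
#'
#' @param statistic Name of the statistic the partition belongs to.
#' @param cuts Finite, strictly increasing cut points (may be empty, giving
#'   the single interval covering the whole line).
#' @param ameva_value Ameva coefficient of the partition (>= 0).
#' @return An object of class `interval_set` with fields `statistic`, `cuts`,
#'   `lower`, `upper`, `k`, `ameva_value`.
#' @export
interval_set <- function(statistic, cuts = numeric(0), ameva_value = 0) {
  cuts <- as.numeric(cuts)
  if (length(cuts) && (!all(is.finite(cuts)) || any(diff(cuts) <= 0)))
    stop("interval_set: cuts must be finite and strictly increasing",
         call. = FALSE)
  if (!is.finite(ameva_value) || ameva_value < 0)
    stop("interval_set: ameva_value must be >= 0", call. = FALSE)
  structure(list(statistic = as.character(statistic),
                 cuts = cuts,
                 lower = c(-Inf, cuts),
                 upper = c(cuts, Inf),
                 k = length(cuts) + 1L,
                 ameva_value = ameva_value),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %s: %d intervals, Ameva = %.4g\n",
              x$statistic, x$k, x$ameva_value))
  invisible(x)
}

#' Locate the interval containing a value
#'
#' Uses the half-open convention `(d_{j-1}, d_j]`: a value equal to a cut
#' point belongs to the interval below it, and the first/last intervals are
#' unbounded, so every finite value matches exactly one interval.
#'
#' @param interval_set An [interval_set()].
#' @param x Numeric vector of values; all must be finite.
#' @return Integer interval indices in `1..k`.
#' @export
assign_interval <- function(interval_set, x) {
  stopifnot(inherits(interval_set, "interval_set"))
  if (!all(is.finite(x)))
    stop("assign_interval: values must be finite", call. = FALSE)
  findInterval(x, interval_set$cuts, left.open = TRUE) + 1L
}

#' Contingency table of class counts per interval
#'
#' Wraps a counts matrix `n_ij` (classes `i = 1..l` as rows, intervals
#' `j = 1..k` as columns) together with its marginals and grand total.
#'
#' @param counts Non-negative matrix of counts, classes x intervals.
#' @return An object of class `contingency_table` with fields `counts`,
#'   `class_totals` (`n_i.`), `interval_totals` (`n_.j`), `N`, `k`, `l`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("contingency_table: counts must be finite and >= 0", call. = FALSE)
  structure(list(counts = counts,
                 class_totals = rowSums(counts),
                 interval_totals = colSums(counts),
                 N = sum(counts),
                 k = ncol(counts),
                 l = nrow(counts)),
            class = "contingency_table")
}

#' Build a contingency table from values, labels and cut points
#'
#' Each value is assigned to exactly one half-open interval `(d_{j-1}, d_j]`
#' (the first interval extends to -Inf) and counted against its class label.
#'
#' @param values Numeric vector of statistic values.
#' @param labels Class label per value.
#' @param cutpoints Finite, strictly increasing cut points (possibly empty).
#' @param class_set Optional class ordering; defaults to sorted unique labels.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(values, labels, cutpoints = numeric(0),
                              class_set = NULL) {
  if (length(values) == 0) stop("build_contingency: empty input", call. = FALSE)
  if (length(values) != length(labels))
    stop("build_contingency: values and labels must have equal length",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("build_contingency: values must be finite", call. = FALSE)
  labels <- as.character(labels)
  class_set <- class_set %||% sort(unique(labels))
  iset <- interval_set("x", cuts = cutpoints)
  j <- assign_interval(iset, values)
  counts <- table(factor(labels, levels = class_set),
                  factor(j, levels = seq_len(iset$k)))
  m <- matrix(as.numeric(counts), nrow = length(class_set),
              dimnames = list(class_set, paste0("L", seq_len(iset$k))))
  contingency_table(m)
}

#' Chi-squared statistic of a contingency table
#'
#' Computes `chi2(k) = N * (-1 + sum_ij n_ij^2 / (n_i. * n_.j))`. Cells whose
#' class or interval marginal is zero contribute nothing to the sum.
#'
#' @param table A [contingency_table()].
#' @return The chi-squared value (dimensionless, >= 0).
#' @export
chi2_stat <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$N == 0) stop("chi2_stat: empty table (N = 0)", call. = FALSE)
  denom <- outer(table$class_totals, table$interval_totals)
  term <- table$counts^2 / denom
  term[denom == 0] <- 0
  table$N * (-1 + sum(term))
}

#' Ameva coefficient of a contingency table
#'
#' The chi-squared statistic normalized by the number of intervals and
#' classes: `Ameva(k) = chi2(k) / (k * (l - 1))`. It rewards partitions whose
#' intervals are strongly class-pure while penalizing extra intervals, and it
#' doubles as a per-statistic measure of class-discrimination power.
#'
#' @param table A [contingency_table()].
#' @return The Ameva value (dimensionless, >= 0).
#' @export
ameva_stat <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$l < 2)
    stop("ameva_stat: at least 2 classes are required", call. = FALSE)
  chi2_stat(table) / (table$k * (table$l - 1))
}

ameva_for_cuts <- function(values, labels, cuts, class_set) {
  ameva_stat(build_contingency(values, labels, cuts, class_set))
}

#' Supervised Ameva discretization of one statistic
#'
#' Greedy top-down search for the cut points that maximize the Ameva
#' coefficient. Candidate cut points are the midpoints between consecutive
#' distinct sorted values; starting from the single interval covering the
#' whole line, the candidate that most increases the global Ameva value is
#' added, and the search stops as soon as no candidate yields a strict
#' increase. Ties are broken toward the smallest cut value so the result is
#' deterministic.
#'
#' @param values Numeric statistic values for the training windows.
#' @param labels Activity label per value; at least 2 distinct classes for a
#'   nontrivial result.
#' @param max_intervals Optional cap on the interval count (default
#'   unlimited).
#' @return An [interval_set()] carrying the selected cuts and the Ameva value
#'   of the final partition. A constant statistic yields the single interval
#'   `(-Inf, +Inf)` with Ameva value 0 and a warning.
#' @export
discretize_statistic <- function(values, labels, max_intervals = Inf) {
  if (length(values) != length(labels))
    stop("discretize_statistic: values and labels must align", call. = FALSE)
  if (!all(is.finite(values)))
    stop("discretize_statistic: values must be finite", call. = FALSE)
  labels <- as.character(labels)
  class_set <- sort(unique(labels))
  if (length(class_set) < 2)
    stop("discretize_statistic: at least 2 classes are required",
         call. = FALSE)
  sv <- sort(unique(values))
  if (length(sv) < 2) {
    warning("discretize_statistic: constant statistic, returning one interval")
    return(interval_set("x", numeric(0), 0))
  }
  candidates <- (sv[-1] + sv[-length(sv)]) / 2
  cuts <- numeric(0)
  best <- 0  # one interval: chi2 = 0 exactly
  repeat {
    if (length(cuts) + 1L >= max_intervals || length(candidates) == 0) break
    scores <- vapply(candidates, function(cand)
      ameva_for_cuts(values, labels, sort(c(cuts, cand)), class_set),
      numeric(1))
    top <- max(scores)
    if (top <= best + 1e-12) break
    # ties toward the smallest candidate cut
    pick <- which(scores >= top - 1e-12)[1]
    cuts <- sort(c(cuts, candidates[pick]))
    candidates <- candidates[-pick]
    best <- top
  }
  interval_set("x", cuts, best)
}

#' Discretize every statistic of a feature table
#'
#' Runs [discretize_statistic()] on each column and assembles the
#' discretization matrix: the per-statistic interval bounds that map any real
#' value to exactly one interval.
#'
#' @param table A [feature_table()].
#' @param max_intervals Optional cap passed to [discretize_statistic()].
#' @return An object of class `discretization_matrix`: a named list of
#'   [interval_set()]s, one per statistic, with an `ameva_values` attribute.
#' @export
discretize_table <- function(table, max_intervals = Inf) {
  stopifnot(inherits(table, "feature_table"))
  sets <- lapply(colnames(table$features), function(p) {
    iset <- discretize_statistic(table$features[, p], table$labels,
                                 max_intervals)
    iset$statistic <- p
    iset
  })
  names(sets) <- colnames(table$features)
  structure(sets, class = "discretization_matrix",
            ameva_values = vapply(sets, `[[`, numeric(1), "ameva_value"))
}

#' @export
print.discretization_matrix <- function(x, ...) {
  cat(sprintf("<discretization_matrix> %d statistics\n", length(x)))
  for (s in x)
    cat(sprintf("  %s: k = %d, Ameva = %.4g\n", s$statistic, s$k,
                s$ameva_value))
  invisible(x)
}
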