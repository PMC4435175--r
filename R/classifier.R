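#' Class matrix: training counts per (statistic, interval, activity)
#'
#' For each statistic `p`, `counts[[p]][i, j]` is the number of training
#' windows of activity `j` whose value of statistic `p` falls in interval `i`
#' of the discretization. Column sums give the per-activity totals
#' (`v_p.j`); for a complete training table these are identical across
#' statistics.
#'
#' @param counts Named list of non-negative matrices (intervals x activities)
#'   sharing the same activity columns.
#' @return An object of class `class_matrix` with fields `counts`,
#'   `class_names`, `activity_totals` (list of per-statistic column sums).
#' @export
class_matrix <- function(counts) {
  if (!length(counts) || is.null(names(counts)))
    stop("class_matrix: a named list of count matrices is required",
         call. = FALSE)
  cls <- colnames(counts[[1]])
  for (p in names(counts)) {
    m <- counts[[p]]
    if (any(m < 0) || any(!is.finite(m)))
      stop("class_matrix: counts must be finite and >= 0", call. = FALSE)
    if (!identical(colnames(m), cls))
      stop("class_matrix: all statistics must share the same activity columns",
           call. = FALSE)
  }
  structure(list(counts = lapply(counts, function(m) {
                   storage.mode(m) <- "double"; m
                 }),
                 class_names = cls,
                 activity_totals = lapply(counts, colSums)),
            class = "class_matrix")
}

#' Build the class matrix from a labeled feature table
#'
#' Assigns every training window's statistic values to their discretization
#' intervals and counts occurrences per (statistic, interval, activity).
#' Counting is order-free: shuffling the training rows leaves the result
#' unchanged.
#'
#' @param table A [feature_table()].
#' @param W A `discretization_matrix` from [discretize_table()] covering every
#'   statistic of the table.
#' @return A [class_matrix()].
#' @export
build_class_matrix <- function(table, W) {
  stopifnot(inherits(table, "feature_table"),
            inherits(W, "discretization_matrix"))
  missing <- setdiff(colnames(table$features), names(W))
  if (length(missing))
    stop("build_class_matrix: statistics missing from discretization: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cls <- table$class_set
  counts <- lapply(colnames(table$features), function(p) {
    iset <- W[[p]]
    i <- assign_interval(iset, table$features[, p])
    tab <- table(factor(i, levels = seq_len(iset$k)),
                 factor(table$labels, levels = cls))
    m <- matrix(as.numeric(tab), nrow = iset$k,
                dimnames = list(paste0("L", seq_len(iset$k)), cls))
    m
  })
  names(counts) <- colnames(table$features)
  class_matrix(counts)
}

# u_pij for one statistic's count matrix (intervals x activities), with the
# zero convention: an activity with no training windows contributes ratio 0.
u_raw_from_counts <- function(m) {
  l <- ncol(m)
  totals <- colSums(m)
  r <- sweep(m, 2, ifelse(totals > 0, totals, 1), "/")
  r[, totals == 0] <- 0
  S <- rowSums(r)
  # sum_{q != j} (1 - r_iq) = (l - 1) - (S_i - r_ij)
  u <- r * ((l - 1) - (S - r)) / (l - 1)
  dimnames(u) <- dimnames(m)
  u
}

#' Build the activity-interval matrix from a class matrix
#'
#' For each statistic `p`, interval `i` and activity `j`, the unnormalized
#' likelihood is
#' `u_pij = (v_pij / v_p.j) * (1/(l-1)) * sum_{q != j} (1 - v_piq / v_p.q)`,
#' with the convention that a ratio with a zero activity total `v_p.q` is 0.
#' The value is high when interval `i` captures much of activity `j` and
#' little of the others. `u_norm` divides each interval row by its sum over
#' activities (all-zero rows stay zero) so that each row reads as a
#' probability distribution over activities; classification uses `u_norm`.
#'
#' @param V A [class_matrix()].
#' @return An object of class `activity_interval_matrix` with fields `u_raw`,
#'   `u_norm` (named lists of intervals x activities matrices) and
#'   `class_names`.
#' @export
build_activity_interval_matrix <- function(V) {
  stopifnot(inherits(V, "class_matrix"))
  if (length(V$class_names) < 2)
    stop("build_activity_interval_matrix: at least 2 activities are required",
         call. = FALSE)
  u_raw <- lapply(V$counts, u_raw_from_counts)
  u_norm <- lapply(u_raw, function(u) {
    s <- rowSums(u)
    un <- sweep(u, 1, ifelse(s > 0, s, 1), "/")
    un[s == 0, ] <- 0
    un
  })
  structure(list(u_raw = u_raw, u_norm = u_norm,
                 class_names = V$class_names),
            class = "activity_interval_matrix")
}

new_ameva_model <- function(discretization, activity_interval, class_names,
                            ameva_values, selected_statistics,
                            selection_threshold, novelty_threshold,
                            metadata) {
  structure(list(discretization = discretization,
                 activity_interval = activity_interval,
                 class_names = class_names,
                 ameva_values = ameva_values,
                 selected_statistics = selected_statistics,
                 selection_threshold = selection_threshold,
                 novelty_threshold = novelty_threshold,
                 metadata = metadata),
            class = "ameva_model")
}

#' @export
print.ameva_model <- function(x, ...) {
  cat(sprintf(paste0("<ameva_model> %d statistics (%d selected), ",
                     "%d activities: %s\n"),
              length(x$discretization), length(x$selected_statistics),
              length(x$class_names), paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Train an Ameva activity-recognition model
#'
#' Discretizes every statistic of the training table with the supervised
#' Ameva criterion, counts the class matrix, derives the activity-interval
#' likelihood matrix, and optionally prunes statistics whose Ameva
#' coefficient falls below `selection_threshold` (low-information statistics
#' cost sensing and CPU but add little to the vote).
#'
#' @param table A labeled [feature_table()] with at least 2 classes.
#' @param selection_threshold Minimum Ameva coefficient for a statistic to be
#'   kept (default 0: keep all).
#' @param novelty_threshold Mean winning likelihood below which a window is
#'   flagged as a novel activity (default 0.2).
#' @param max_intervals Optional cap per statistic.
#' @param metadata Named list stored verbatim in the model (e.g. `window_s`,
#'   `overlap_s`, `rate_hz`).
#' @return An object of class `ameva_model`.
#' @export
train_ameva <- function(table, selection_threshold = 0,
                        novelty_threshold = 0.2, max_intervals = Inf,
                        metadata = list()) {
  stopifnot(inherits(table, "feature_table"))
  if (length(table$class_set) < 2)
    stop("train_ameva: at least 2 classes are required", call. = FALSE)
  W <- discretize_table(table, max_intervals)
  V <- build_class_matrix(table, W)
  U <- build_activity_interval_matrix(V)
  av <- attr(W, "ameva_values")
  selected <- select_statistics(av, selection_threshold)
  new_ameva_model(discretization = W, activity_interval = U,
                  class_names = table$class_set, ameva_values = av,
                  selected_statistics = selected,
                  selection_threshold = selection_threshold,
                  novelty_threshold = novelty_threshold,
                  metadata = metadata)
}

#' Prune statistics by Ameva coefficient
#'
#' Keeps the statistics whose Ameva coefficient is at least `threshold`,
#' preserving their order. Raising the threshold drops the least
#' class-informative statistics first, which is how a 561-statistic window
#' vector can shrink to a few dozen without hurting the vote.
#'
#' @param ameva_values Named numeric vector of per-statistic Ameva
#'   coefficients.
#' @param threshold Minimum coefficient to keep (>= 0).
#' @return Character vector of kept statistic names.
#' @export
select_statistics <- function(ameva_values, threshold = 0) {
  if (threshold < 0)
    stop("select_statistics: threshold must be >= 0", call. = FALSE)
  keep <- names(ameva_values)[ameva_values >= threshold]
  if (!length(keep))
    stop("select_statistics: no statistic reaches the threshold; lower it",
         call. = FALSE)
  keep
}

#' Classify one window by interval majority vote
#'
#' For every selected statistic, the window's value is located in its
#' discretization interval and each activity accumulates that interval's
#' normalized likelihood. The most probable activity (mpa) is the argmax of
#' the summed scores; ties go to the lowest class index and are flagged.
#'
#' @param model An [ameva_model].
#' @param x Named numeric vector with a value for every selected statistic.
#' @return An object of class `ameva_classification`: list with `activity`,
#'   `score` (winning summed likelihood), `scores` (per class),
#'   `n_statistics`, `tie`, and `novel` (see [detect_novel()]).
#' @export
classify_window <- function(model, x) {
  stopifnot(inherits(model, "ameva_model"))
  sel <- model$selected_statistics
  if (!all(sel %in% names(x)))
    stop("classify_window: missing statistics: ",
         paste(setdiff(sel, names(x)), collapse = ", "), call. = FALSE)
  if (!all(is.finite(x[sel])))
    stop("classify_window: statistic values must be finite", call. = FALSE)
  scores <- stats::setNames(numeric(length(model$class_names)),
                            model$class_names)
  for (p in sel) {
    i <- assign_interval(model$discretization[[p]], x[[p]])
    scores <- scores + model$activity_interval$u_norm[[p]][i, ]
  }
  win <- which.max(scores)  # lowest index on ties
  tie <- sum(abs(scores - scores[win]) < 1e-12) > 1
  cl <- structure(list(activity = model$class_names[win],
                       score = unname(scores[win]),
                       scores = scores,
                       n_statistics = length(sel),
                       tie = tie,
                       novel = NA),
                  class = "ameva_classification")
  cl$novel <- detect_novel(cl, model$novelty_threshold)
  cl
}

#' Flag a window as a novel (untrained) activity
#'
#' A window whose winning likelihood, averaged over the statistics that
#' voted, is low does not fit any trained activity well — an indication that
#' the user is doing something the system was never trained on.
#'
#' @param classification An `ameva_classification` from [classify_window()].
#' @param threshold Mean winning likelihood below which the window is flagged
#'   (default 0.2).
#' @return Logical flag.
#' @export
detect_novel <- function(classification, threshold = 0.2) {
  stopifnot(inherits(classification, "ameva_classification"))
  classification$score / classification$n_statistics < threshold
}

#' Predict activities for a feature table
#'
#' @param object An [ameva_model].
#' @param newdata A [feature_table()] or a numeric matrix/data frame with
#'   named statistic columns.
#' @param ... Unused.
#' @return A data frame with one row per window: `activity`, `score`,
#'   `novel`, `tie`.
#' @export
predict.ameva_model <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "feature_table")) newdata$features
           else as.matrix(newdata)
  out <- lapply(seq_len(nrow(feats)), function(r)
    classify_window(object, feats[r, ]))
  data.frame(activity = vapply(out, `[[`, "", "activity"),
             score = vapply(out, `[[`, numeric(1), "score"),
             novel = vapply(out, `[[`, logical(1), "novel"),
             tie = vapply(out, `[[`, logical(1), "tie"))
}

#' Evaluate a model on a labeled feature table
#'
#' Computes the confusion matrix and the standard derived metrics, in
#' percent. Per-class recall (sensitivity), specificity, precision and F1 are
#' macro-averaged over classes; accuracy is overall.
#'
#' @param model An [ameva_model].
#' @param table A labeled [feature_table()] whose labels come from the
#'   model's class set.
#' @return List with `confusion` (true x predicted counts), `accuracy`,
#'   `recall`, `specificity`, `precision`, `f1` (macro, in percent) and
#'   `per_class` (data frame of per-class metrics in percent).
#' @export
evaluate_model <- function(model, table) {
  stopifnot(inherits(model, "ameva_model"), inherits(table, "feature_table"))
  if (nrow(table$features) == 0)
    stop("evaluate_model: empty table", call. = FALSE)
  bad <- setdiff(table$class_set, model$class_names)
  if (length(bad))
    stop("evaluate_model: labels outside the model's class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  pred <- predict(model, table)$activity
  cls <- model$class_names
  conf <- table(factor(table$labels, levels = cls),
                factor(pred, levels = cls))
  conf <- matrix(as.numeric(conf), nrow = length(cls),
                 dimnames = list(true = cls, predicted = cls))
  N <- sum(conf)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- N - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  per_class <- data.frame(
    class = cls,
    recall = 100 * safe_div(tp, tp + fn),
    specificity = 100 * safe_div(tn, tn + fp),
    precision = 100 * safe_div(tp, tp + fp),
    row.names = NULL)
  per_class$f1 <- ifelse(per_class$precision + per_class$recall > 0,
                         2 * per_class$precision * per_class$recall /
                           (per_class$precision + per_class$recall), 0)
  list(confusion = conf,
       accuracy = 100 * sum(tp) / N,
       recall = mean(per_class$recall),
       specificity = mean(per_class$specificity),
       precision = mean(per_class$precision),
       f1 = mean(per_class$f1),
       per_class = per_class)
}
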