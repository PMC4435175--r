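#' Small reference fixtures for the discretization and voting machinery
#'
#' Typed in-memory constants used throughout the tests and examples:
#'
#' * `table1` — per-user time-window counts of a 10-user smartphone
#'   recording campaign (columns `user`, `phone`, `windows`; the counts sum
#'   to 6874).
#' * `table2` — a toy labeled dataset of 10 windows, 6 statistics and 3
#'   classes, as a [feature_table()].
#' * `table3` — class-count matrix over 6 intervals and 3 classes
#'   (12,480 values in total), in the printed intervals-as-rows layout.
#' * `table4_bounds` — an example 6-interval discretization of a normalized
#'   statistic, as an [interval_set()].
#' * `table5` — a class matrix of the standard-deviation statistic over 6
#'   intervals and 6 activities (intervals as rows).
#'
#' @return Named list with elements `table1`, `table2`, `table3`,
#'   `table4_bounds`, `table5`.
#' @export
har_fixtures <- function() {
  table1 <- data.frame(
    user = 1:10,
    phone = c("Samsung Galaxy S3", "Samsung Galaxy S4", "Samsung Galaxy S3",
              "LG Nexus 5", "Samsung Galaxy S3", "LG Nexus 5",
              "Samsung Galaxy S4", "Samsung Galaxy S4", "Samsung Galaxy S3",
              "LG Nexus 5"),
    windows = c(740, 683, 830, 716, 519, 683, 478, 854, 729, 642))

  t2 <- matrix(c(
    10.1, 3.9, 5.1, 13.3,  9.7,  1.9,
    12.7, 8.6, 3.1, 16.4, 16.2,  0.1,
     8.3, 1.5, 8.3,  9.5,  1.8, -2.4,
    11.3, 4.1, 6.3, 14.9, 11.2,  1.1,
     8.6, 1.2, 8.7,  9.1,  1.2,  1.3,
     9.8, 2.7, 6.5, 13.2,  9.7,  1.7,
    14.7, 9.2, 3.6, 15.3, 17.1, -0.2,
    11.7, 8.5, 2.9, 16.8, 14.3, -1.7,
    10.6, 3.6, 5.1, 13.8, 11.2,  0.8,
     9.2, 0.7, 8.9,  9.7,  0.9, -1.8), nrow = 10, byrow = TRUE,
    dimnames = list(NULL, c("mean", "sd", "max", "min", "energy",
                            "skewness")))
  table2 <- feature_table(t2, c("C1", "C2", "C3", "C1", "C3", "C1", "C2",
                                "C2", "C1", "C3"))

  table3 <- matrix(c(
    3213,   65,    1,
     412,  156,    4,
     318,  891,   86,
     136, 2178,  312,
      49,  710,  813,
       0,   13, 3123), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("L", 1:6), c("C1", "C2", "C3")))

  table4_bounds <- interval_set("normalized_stat",
                                cuts = c(-0.99, -0.98, -0.66, -0.28, 0.02))

  table5 <- matrix(c(
      0,   0,   0, 440, 524,  124,
      0,   0,   0, 367, 351,  388,
      3,   0,   0, 349, 362,  734,
    690, 375,  24,   1,   0,   17,
    394, 534, 226,   0,   0,    3,
     17,  57, 637,   0,   0,    0), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("L", 1:6),
                    c("walking", "upstairs", "downstairs", "sitting",
                      "standing", "lying")))

  list(table1 = table1, table2 = table2, table3 = table3,
       table4_bounds = table4_bounds, table5 = table5)
}

#' Expand an intervals-as-rows count matrix into values and labels
#'
#' Produces a dataset and cut points that reconstruct the given counts when
#' passed through [build_contingency()]: interval `j` is represented by the
#' value `j` and the cut points sit at half-integers. Useful for feeding
#' printed count tables through the counting code paths.
#'
#' @param counts Matrix with intervals as rows and classes as columns.
#' @return List with `values`, `labels`, `cutpoints`, `class_set`.
#' @export
expand_counts <- function(counts) {
  k <- nrow(counts)
  cls <- colnames(counts)
  values <- numeric(0)
  labels <- character(0)
  for (j in seq_len(k)) for (cl in cls) {
    n <- counts[j, cl]
    values <- c(values, rep(j, n))
    labels <- c(labels, rep(cl, n))
  }
  list(values = values, labels = labels,
       cutpoints = seq_len(k - 1) + 0.5, class_set = cls)
}

#' Wrap a printed class-count matrix as a single-statistic class matrix
#'
#' @param counts Matrix with intervals as rows and activities as columns.
#' @param statistic Name to give the statistic.
#' @return A [class_matrix()].
#' @export
class_matrix_from_counts <- function(counts, statistic = "sd") {
  class_matrix(stats::setNames(list(as.matrix(counts)), statistic))
}
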