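# Independent oracles used across the suite. These are deliberately naive
# (literal loops, exhaustive enumeration) and never share code with the
# package's vectorized implementations.

# Literal double-loop chi-squared summation over a counts matrix
# (classes x intervals), zero-marginal terms contributing 0.
brute_chi2 <- function(counts) {
  l <- nrow(counts); k <- ncol(counts)
  ni <- numeric(l); nj <- numeric(k); N <- 0
  for (i in seq_len(l)) for (j in seq_len(k)) {
    ni[i] <- ni[i] + counts[i, j]
    nj[j] <- nj[j] + counts[i, j]
    N <- N + counts[i, j]
  }
  s <- 0
  for (i in seq_len(l)) for (j in seq_len(k)) {
    if (ni[i] > 0 && nj[j] > 0)
      s <- s + counts[i, j]^2 / (ni[i] * nj[j])
  }
  N * (-1 + s)
}

brute_ameva <- function(counts) {
  brute_chi2(counts) / (ncol(counts) * (nrow(counts) - 1))
}

# Exhaustive search over all subsets of candidate cuts (midpoints between
# consecutive distinct values) yielding up to max_k intervals; returns the
# best Ameva value found.
exhaustive_best_ameva <- function(values, labels, max_k = 4) {
  sv <- sort(unique(values))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  best <- 0
  for (nc in 0:(max_k - 1)) {
    if (nc > length(cand)) break
    subsets <- if (nc == 0) list(integer(0))
               else utils::combn(seq_along(cand), nc, simplify = FALSE)
    for (s in subsets) {
      a <- ameva_stat(build_contingency(values, labels, cand[s]))
      if (a > best) best <- a
    }
  }
  best
}

# Random small non-degenerate contingency counts matrix.
random_counts <- function() {
  l <- sample(2:4, 1)
  k <- sample(1:5, 1)
  m <- matrix(rpois(l * k, 3), nrow = l)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

# Three well-separated activity specs over m statistics: class c has mean
# c * sep_sd standard deviations on every statistic (sd = 1).
separated_specs <- function(m = 6, sep_sd = 6, classes = c("A", "B", "C")) {
  stat_names <- paste0("S", seq_len(m))
  lapply(seq_along(classes), function(ci)
    activity_spec(classes[ci],
                  feature_means = setNames(rep(ci * sep_sd, m), stat_names),
                  feature_sds = setNames(rep(1, m), stat_names)))
}

# Same statistic names, identical distribution for every class.
identical_specs <- function(m = 6, classes = c("A", "B", "C")) {
  stat_names <- paste0("S", seq_len(m))
  lapply(classes, function(cl)
    activity_spec(cl, feature_means = setNames(rep(0, m), stat_names),
                  feature_sds = setNames(rep(1, m), stat_names)))
}

# Split a feature table into train/test by stratified row index parity.
split_table <- function(tab, test_frac = 0.25, seed = 99) {
  n <- nrow(tab$features)
  idx <- withr::with_seed(seed, sample(n, round(n * test_frac)))
  list(train = feature_table(tab$features[-idx, , drop = FALSE],
                             tab$labels[-idx]),
       test = feature_table(tab$features[idx, , drop = FALSE],
                            tab$labels[idx]))
}

# Build a window object directly from channel vectors (50 Hz default).
make_window <- function(ax, ay = ax * 0, az = ax * 0, rate_hz = 50,
                        start_s = 0) {
  n <- length(ax)
  structure(list(start_s = start_s, t = start_s + (seq_len(n) - 1) / rate_hz,
                 ax = ax, ay = ay, az = az, rate_hz = rate_hz),
            class = "ameva_window")
}
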