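# Minimal hand-built model around a single statistic whose discretization and
# likelihoods come from printed-count fixtures.
single_stat_model <- function(counts, cuts_set, statistic = "sd",
                              novelty_threshold = 0.2) {
  V <- class_matrix_from_counts(counts, statistic)
  U <- build_activity_interval_matrix(V)
  names(U$u_raw) <- statistic; names(U$u_norm) <- statistic
  W <- structure(setNames(list(cuts_set), statistic),
                 class = "discretization_matrix")
  amevaHAR:::new_ameva_model(
    discretization = W, activity_interval = U,
    class_names = colnames(counts),
    ameva_values = setNames(1, statistic),
    selected_statistics = statistic, selection_threshold = 0,
    novelty_threshold = novelty_threshold, metadata = list())
}

test_that("class matrix counting matches printed totals and is order-free", {
  fx <- har_fixtures()
  ex <- expand_counts(fx$table5)
  tab <- feature_table(matrix(ex$values, ncol = 1,
                              dimnames = list(NULL, "sd")), ex$labels)
  W <- structure(list(sd = interval_set("sd", ex$cutpoints)),
                 class = "discretization_matrix")
  V <- build_class_matrix(tab, W)
  # the class set is stored sorted; compare against the printed layout by name
  expect_equal(unname(V$counts$sd[, colnames(fx$table5)]),
               unname(fx$table5))
  expect_equal(V$activity_totals$sd[colnames(fx$table5)],
               c(walking = 1104, upstairs = 966, downstairs = 887,
                 sitting = 1157, standing = 1237, lying = 1266))

  perm <- withr::with_seed(3, sample(length(ex$values)))
  tab2 <- feature_table(matrix(ex$values[perm], ncol = 1,
                               dimnames = list(NULL, "sd")),
                        ex$labels[perm])
  expect_equal(build_class_matrix(tab2, W)$counts, V$counts)

  tab3 <- feature_table(matrix(1:4, ncol = 1, dimnames = list(NULL, "x")),
                        c("A", "A", "B", "B"))
  expect_error(build_class_matrix(tab3, W), "missing")
})

test_that("activity-interval likelihoods satisfy the printed properties", {
  # interval holding all of one activity's windows and nothing else -> u = 1
  m <- matrix(c(10, 0,
                 0, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("L1", "L2"), c("A", "B")))
  u <- build_activity_interval_matrix(class_matrix_from_counts(m))$u_raw$sd
  expect_equal(unname(u), diag(2))

  # an activity with zero training windows has a zero column and contributes
  # (1 - 0) = 1 inside the other activities' sums
  m0 <- matrix(c(5, 0, 0,
                 5, 4, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("L1", "L2"), c("A", "B", "C")))
  u0 <- build_activity_interval_matrix(class_matrix_from_counts(m0))$u_raw$sd
  expect_equal(unname(u0[, "C"]), c(0, 0))
  # row 1: u_A = (5/10) * (1/2) * ((1 - 0) + (1 - 0)) = 0.5
  expect_equal(u0["L1", "A"], 0.5)

  withr::with_seed(11, {
    for (rep in 1:40) {
      cm <- random_counts()
      if (ncol(cm) < 2) next
      rownames(cm) <- paste0("L", seq_len(nrow(cm)))
      colnames(cm) <- paste0("A", seq_len(ncol(cm)))
      # property tests operate on intervals x activities matrices
      cm <- t(cm)
      U <- build_activity_interval_matrix(class_matrix_from_counts(cm))
      u <- U$u_raw$sd
      tot <- colSums(cm)
      expect_true(all(u >= -1e-12 & u <= 1 + 1e-12))
      for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
        others <- setdiff(seq_len(ncol(cm)), j)
        # the sum over q != j of (1 - ratio) vanishes only when every other
        # activity lies entirely inside this interval
        zero_expected <- cm[i, j] == 0 ||
          all(tot[others] > 0 & cm[i, others] == tot[others])
        expect_equal(u[i, j] == 0, zero_expected)
        one_expected <- cm[i, j] == tot[j] && tot[j] == sum(cm[i, ]) &&
          tot[j] > 0
        expect_equal(abs(u[i, j] - 1) < 1e-12, one_expected)
      }
      rs <- rowSums(U$u_norm$sd)
      expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    }
  })
})

test_that("the majority vote returns the most probable activity", {
  fx <- har_fixtures()
  model <- single_stat_model(fx$table5, fx$table4_bounds)
  # a value in interval 6 (above 0.02) votes overwhelmingly downstairs
  cl <- classify_window(model, c(sd = 5))
  expect_equal(cl$activity, "downstairs")
  expect_gt(cl$scores[["downstairs"]], cl$scores[["walking"]])
  expect_false(cl$tie)

  # all-equal likelihood rows tie; lowest class index wins, flagged
  flat <- matrix(1, 2, 3, dimnames = list(c("L1", "L2"), c("A", "B", "C")))
  mflat <- single_stat_model(flat, interval_set("sd", 0))
  clf <- classify_window(mflat, c(sd = -1))
  expect_equal(clf$activity, "A")
  expect_true(clf$tie)

  expect_error(classify_window(model, c(sd = NaN)), "finite")
  expect_error(classify_window(model, c(other = 1)), "missing")
})

test_that("multi-statistic vote equals a brute-force score enumeration", {
  specs <- separated_specs(m = 3)
  tab <- generate_feature_table(specs, windows_per_class = 40, seed = 21)
  model <- train_ameva(tab)
  feats <- generate_feature_table(specs, windows_per_class = 10,
                                  seed = 22)$features
  for (r in seq_len(nrow(feats))) {
    x <- feats[r, ]
    scores <- setNames(numeric(length(model$class_names)),
                       model$class_names)
    for (cl in model$class_names) for (p in model$selected_statistics) {
      iset <- model$discretization[[p]]
      i <- max(which(c(-Inf, iset$cuts) < x[[p]]))
      scores[cl] <- scores[cl] + model$activity_interval$u_norm[[p]][i, cl]
    }
    got <- classify_window(model, x)
    expect_equal(got$activity, names(scores)[which.max(scores)])
    expect_equal(got$scores, scores)
  }
})

test_that("classification is invariant to statistic order and training duplication", {
  specs <- separated_specs(m = 4)
  tab <- generate_feature_table(specs, windows_per_class = 30, seed = 31)
  model <- train_ameva(tab)
  dup <- feature_table(rbind(tab$features, tab$features),
                       c(tab$labels, tab$labels))
  model_dup <- train_ameva(dup)
  x <- generate_feature_table(specs, windows_per_class = 5,
                              seed = 32)$features
  for (r in seq_len(nrow(x))) {
    a <- classify_window(model, x[r, ])
    expect_equal(classify_window(model, rev(x[r, ]))$activity, a$activity)
    expect_equal(classify_window(model_dup, x[r, ])$activity, a$activity)
  }
})

test_that("novelty flag fires on low summed likelihood", {
  fx <- har_fixtures()
  model <- single_stat_model(fx$table5, fx$table4_bounds)
  confident <- classify_window(model, c(sd = 5))  # u_norm 0.92
  expect_false(confident$novel)

  # an interval row that is all zero yields score 0 -> novel
  z <- fx$table5; z[2, ] <- 0
  mz <- single_stat_model(z, fx$table4_bounds)
  cl0 <- classify_window(mz, c(sd = -0.985))
  expect_equal(cl0$score, 0)
  expect_true(cl0$novel)
})

test_that("untrained activities are flagged novel more often than trained ones", {
  m <- 6
  stat_names <- paste0("S", 1:m)
  specs <- lapply(1:3, function(ci)
    activity_spec(LETTERS[ci],
                  feature_means = setNames(rep(ci * 10, m), stat_names),
                  feature_sds = setNames(rep(1, m), stat_names)))
  tab <- generate_feature_table(specs, windows_per_class = 150, seed = 41)
  model <- train_ameva(tab, novelty_threshold = 0.7)

  indist <- generate_feature_table(specs, windows_per_class = 50, seed = 42)
  # the untrained activity sits between trained classes: odd statistics near
  # the A/B boundary, even statistics near the B/C boundary, splitting votes
  novel_spec <- activity_spec("X",
    feature_means = setNames(ifelse(seq_len(m) %% 2 == 1, 15, 25),
                             stat_names),
    feature_sds = setNames(rep(1, m), stat_names))
  nov <- generate_feature_table(list(novel_spec, novel_spec),
                                windows_per_class = 50, seed = 43)
  rate <- function(ft) mean(predict(model, ft)$novel)
  expect_gt(rate(nov), rate(indist))
})

test_that("statistic selection keeps informative statistics first", {
  expect_equal(select_statistics(c(a = 1, b = 2), 0), c("a", "b"))
  expect_error(select_statistics(c(a = 1, b = 2), 5), "threshold")

  # one statistic is pure label-independent noise: its Ameva coefficient is
  # the minimum and it drops first as the threshold rises
  m <- 4
  stat_names <- c(paste0("S", 1:m), "noise")
  specs <- lapply(1:3, function(ci)
    activity_spec(LETTERS[ci],
                  feature_means = setNames(c(rep(ci * 8, m), 0), stat_names),
                  feature_sds = setNames(rep(1, m + 1), stat_names)))
  tab <- generate_feature_table(specs, windows_per_class = 80, seed = 51)
  model <- train_ameva(tab)
  expect_equal(names(which.min(model$ameva_values)), "noise")
  thr <- sort(model$ameva_values, decreasing = TRUE)[m]
  expect_false("noise" %in% select_statistics(model$ameva_values, thr))
})

test_that("evaluation metrics derive correctly from the confusion matrix", {
  specs <- separated_specs(m = 3, classes = c("A", "B"))[1:2]
  tab <- generate_feature_table(specs, windows_per_class = 40, seed = 61)
  model <- train_ameva(tab)
  perfect <- evaluate_model(model, tab)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)

  # force all-one-class predictions on balanced 2-class data: accuracy 50%
  lazy <- model
  for (p in names(lazy$activity_interval$u_norm)) {
    lazy$activity_interval$u_norm[[p]][, "A"] <- 1
    lazy$activity_interval$u_norm[[p]][, "B"] <- 0
  }
  half <- evaluate_model(lazy, tab)
  expect_equal(half$accuracy, 50)

  expect_error(evaluate_model(model,
                              feature_table(tab$features,
                                            rep(c("A", "Z"), 40))),
               "class set")
})
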