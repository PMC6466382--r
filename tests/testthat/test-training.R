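tabs <- default_modifier_tables()

# small labeled world built from precomputed distributions
make_scores <- function(mat, ids = sprintf("u%02d", seq_len(nrow(mat)))) {
  df <- as.data.frame(mat)
  names(df) <- msai_categories()
  cbind(data.frame(user_id = ids, stringsAsFactors = FALSE), df,
        data.frame(empty = rowSums(mat) == 0))
}

test_that("batch-average distribution is the renormalized element-wise mean", {
  d1 <- normalize_distribution(affect(anger = 1))
  d2 <- normalize_distribution(affect(loathing = 1))
  expect_equal(as.numeric(average_distribution(list(d1, d1))),
               as.numeric(d1))
  avg <- average_distribution(list(d1, d2))
  expect_equal(as.numeric(avg)[1:2], c(0.5, 0.5))

  # hand mean of three users
  d3 <- normalize_distribution(affect(anger = 1, loathing = 1))
  avg <- average_distribution(list(d1, d2, d3))
  expect_equal(as.numeric(avg)[1:2], c(0.5, 0.5))
  # empty distributions are dropped
  e <- normalize_distribution(affect())
  expect_equal(as.numeric(average_distribution(list(d1, e))),
               as.numeric(d1))
  expect_error(average_distribution(list(e)), "empty")
})

test_that("update proposals increment a top positive and top negative ratio by its share", {
  vs <- mdad:::new_condition_profile(affect(sadness = 0.6, joy = 0.4), "x")
  asd <- normalize_distribution(affect(joy = 0.4, trust = 0.1,
                                       sadness = 0.3, fear = 0.2))
  set.seed(1)
  out <- propose_update(vs, asd)
  chosen <- attr(out, "chosen")
  expect_length(chosen, 2)
  # positive pick from top-2 positives, negative from top-3 negatives
  expect_true(chosen[1] %in% c("joy", "trust"))
  expect_true(chosen[2] %in% c("sadness", "fear"))
  expect_equal(sum(out), 1)
  expect_true(all(out >= 0))

  # arithmetic: chosen dims gain their share fraction before renormalization
  pre <- affect(sadness = 0.6, joy = 0.4)
  ratios <- as.numeric(asd)
  names(ratios) <- msai_categories()
  for (cat in chosen) pre[cat] <- pre[cat] + ratios[cat]
  expect_equal(as.numeric(out), as.numeric(pre / sum(pre)))

  # uniform average: every increment is 1/11 pre-normalization
  asd_u <- normalize_distribution(affect() + 1)
  set.seed(2)
  out_u <- propose_update(vs, asd_u)
  pre_u <- affect(sadness = 0.6, joy = 0.4)
  for (cat in attr(out_u, "chosen")) pre_u[cat] <- pre_u[cat] + 1 / 11
  expect_equal(as.numeric(out_u), as.numeric(pre_u / sum(pre_u)))

  # the finer-grained scale applies the same rule at 1/100 the step
  set.seed(1)
  out_s <- propose_update(vs, asd, learning_scale = 0.01)
  pre_s <- affect(sadness = 0.6, joy = 0.4)
  for (cat in attr(out_s, "chosen"))
    pre_s[cat] <- pre_s[cat] + ratios[cat] / 100
  expect_equal(as.numeric(out_s), as.numeric(pre_s / sum(pre_s)))
})

test_that("error rate counts threshold disagreements with labels", {
  vs <- mdad:::new_condition_profile(affect(sadness = 1), "depressive")
  mat <- rbind(affect(sadness = 1),        # positive, labeled positive
               affect(joy = 1),            # negative, labeled negative
               affect(sadness = 1, joy = 1) / 2,  # cos ~ 0.71 -> positive
               affect(joy = 1))            # negative, labeled positive
  scores <- make_scores(mat)
  labels <- data.frame(user_id = scores$user_id,
                       conditions = c("depressive", "", "", "depressive"),
                       stringsAsFactors = FALSE)
  # u3 predicted positive but unlabeled, u4 labeled but predicted negative
  expect_equal(error_rate(vs, scores, labels), 0.5)
  labels$conditions <- c("depressive", "", "depressive", "")
  expect_equal(error_rate(vs, scores, labels), 0)
  labels$conditions <- c("", "depressive", "", "depressive")
  expect_equal(error_rate(vs, scores, labels), 1)
  expect_error(error_rate(vs, scores[0, ], labels), "empty")
})

test_that("training accepts only error-reducing updates, reproducibly", {
  set.seed(99)
  conds <- c("depressive", "anxiety")
  targets <- synthetic_condition_targets()
  # labeled cohort: 15 users per condition near the target + 30 controls
  rows <- list(); labs <- list()
  for (cond in conds) {
    for (i in 1:15) {
      rows[[length(rows) + 1L]] <-
        mdad:::rdirichlet_around(targets[[cond]], 80)
      labs[[length(labs) + 1L]] <- cond
    }
  }
  for (i in 1:30) {
    rows[[length(rows) + 1L]] <-
      mdad:::rdirichlet_around(targets$background, 80)
    labs[[length(labs) + 1L]] <- ""
  }
  cohort_scores <- make_scores(do.call(rbind, rows))
  labels <- data.frame(user_id = cohort_scores$user_id,
                       conditions = unlist(labs), stringsAsFactors = FALSE)
  # unlabeled corpus biased toward the condition targets
  corpus_scores <- make_scores(do.call(rbind, lapply(1:60, function(i) {
    tgt <- if (i %% 2) targets[[conds[1 + i %% 2]]] else targets$background
    mdad:::rdirichlet_around(tgt, 50)
  })))
  # start from perturbed profiles
  start <- lapply(conds, function(cond) {
    v <- 0.5 * targets[[cond]] + 0.5 / 11
    mdad:::new_condition_profile(v / sum(v), cond)
  })

  fit <- train_profiles(start, corpus_scores, cohort_scores, labels,
                        iterations = 25, batch_size = 40, seed = 7)
  tr <- fit$trace
  expect_equal(nrow(tr), 50L)
  # accepted-update error sequence is non-increasing per condition
  for (cond in conds) {
    sub <- tr[tr$condition == cond, ]
    expect_true(all(diff(sub$err) <= 0))
    expect_true(all(sub$err_star[sub$accepted] < sub$err[sub$accepted]))
  }
  # trained profiles stay on the simplex
  for (p in fit$profiles) {
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # determinism
  fit2 <- train_profiles(start, corpus_scores, cohort_scores, labels,
                         iterations = 25, batch_size = 40, seed = 7)
  expect_identical(fit$trace, fit2$trace)

  # perfectly separated cohort: no update is ever accepted
  perfect <- make_scores(rbind(affect(sadness = 1), affect(joy = 1)))
  plab <- data.frame(user_id = perfect$user_id,
                     conditions = c("depressive", ""),
                     stringsAsFactors = FALSE)
  vs <- mdad:::new_condition_profile(affect(sadness = 1), "depressive")
  fit3 <- train_profiles(list(vs), corpus_scores, perfect, plab,
                         iterations = 10, seed = 1, batch_size = 10)
  expect_false(any(fit3$trace$accepted))
  expect_equal(as.numeric(fit3$profiles[[1]]), as.numeric(vs))
})

test_that("average diagnostic precision matches the mean per-condition accuracy", {
  expect_equal(average_diagnostic_precision(
    data.frame(correct_with = 5, correct_without = 3), n_users = 10), 0.8)
  counts <- data.frame(correct_with = c(3, 2, 4, 1, 5),
                       correct_without = c(5, 6, 4, 7, 3))
  # adp equals the mean of per-condition accuracies
  expect_equal(average_diagnostic_precision(counts, n_users = 10),
               mean((counts$correct_with + counts$correct_without) / 10))
  # all correct for all conditions -> 1
  expect_equal(average_diagnostic_precision(
    data.frame(correct_with = c(4, 4), correct_without = c(6, 6)), 10), 1)
  expect_error(average_diagnostic_precision(counts, 0), "positive")
})

test_that("precision/recall/F1 match printed worked examples", {
  expect_equal(round(f1_score(0.77, 0.92), 2), 0.84)
  expect_equal(round(f1_score(0.69, 0.79), 2), 0.74)
  expect_equal(round(f1_score(0.75, 0.82), 2), 0.78)
  m <- precision_recall_f1(tp = 8, fp = 2, fn = 4)
  expect_equal(unname(m["precision"]), 0.8)
  expect_equal(unname(m["recall"]), 8 / 12)
  expect_equal(unname(m["f1"]),
               2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  p <- precision_recall_f1(tp = 5, fp = 0, fn = 0)
  expect_equal(unname(p), c(1, 1, 1))
  expect_error(precision_recall_f1(0, 0, 3), "precision undefined")
  expect_error(precision_recall_f1(0, 3, 0), "recall undefined")
})

test_that("stratified split reproduces the 70/30 arithmetic", {
  labels <- data.frame(
    user_id = sprintf("u%03d", 1:796),
    conditions = c(rep("depressive", 396), rep("", 400)),
    stringsAsFactors = FALSE)
  sp <- split_cohort(labels, train_frac = 0.7, seed = 5)
  with_cond <- function(df) sum(nzchar(df$conditions))
  expect_equal(with_cond(sp$train), 277)
  expect_equal(with_cond(sp$test), 119)
  expect_equal(nrow(sp$train) - with_cond(sp$train), 280)
  expect_equal(nrow(sp$test) - with_cond(sp$test), 120)
  # disjoint and exhaustive
  expect_length(intersect(sp$train$user_id, sp$test$user_id), 0)
  expect_setequal(c(sp$train$user_id, sp$test$user_id), labels$user_id)
  # deterministic
  sp2 <- split_cohort(labels, train_frac = 0.7, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_cohort(labels, 1.2), "between 0 and 1")
})
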