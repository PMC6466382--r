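#' Average sentiment distribution of a user batch
#'
#' Element-wise mean of the non-empty distributions, renormalized. This is
#' the public-sentiment signal that drives prototype correction: categories
#' that the crowd expresses strongly are the candidate update directions.
#'
#' @param distributions List of `sentiment_distribution` vectors, or a
#'   numeric matrix with 11 named columns (rows = users).
#' @return A `sentiment_distribution` (never empty).
#' @export
average_distribution <- function(distributions) {
  if (is.matrix(distributions)) {
    m <- distributions[, msai_categories(), drop = FALSE]
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0L) stop("all distributions empty", call. = FALSE)
    return(normalize_distribution(colMeans(m)))
  }
  keep <- Filter(Negate(is_empty_distribution), distributions)
  if (length(keep) == 0L) stop("all distributions empty", call. = FALSE)
  normalize_distribution(colMeans(do.call(rbind, lapply(keep, as_affect))))
}

#' Propose a stochastic prototype update
#'
#' The 11 sentiment ratios of the batch-average distribution are split into
#' positive and negative sub-distributions and sorted by ratio. One of the
#' top two positive and one of the top three negative sentiments are picked
#' uniformly at random, and the prototype is incremented on each picked
#' dimension by that dimension's sentiment increment, then renormalized.
#' The increment is the sentiment ratio, in percent, divided by 100 — i.e.
#' the category's share of the crowd average as a fraction, scaled by
#' `learning_scale` (default 1). If fewer categories than the pool size
#' carry nonzero ratio, the pick is from the available ones. Uses the
#' current RNG state; seed the session (or [train_profiles()]) for
#' reproducibility.
#'
#' @param vs A `condition_profile`.
#' @param asd Batch-average `sentiment_distribution` (not empty).
#' @param polarity Positive/negative category partition
#'   (default [default_polarity()]).
#' @param top_pos,top_neg Candidate pool sizes (defaults 2 and 3).
#' @param learning_scale Multiplier on the sentiment-share increment
#'   (default 1; smaller values give finer polishing steps).
#' @return The updated `condition_profile`, with attribute `chosen`
#'   (character vector: the incremented categories).
#' @export
propose_update <- function(vs, asd, polarity = default_polarity(),
                           top_pos = 2L, top_neg = 3L,
                           learning_scale = 1) {
  if (is_empty_distribution(asd))
    stop("average distribution is empty", call. = FALSE)
  ratios <- as_affect(unclass(asd))
  pick_from <- function(cats, top_k) {
    r <- sort(ratios[cats], decreasing = TRUE)
    r <- r[r > 0]
    if (length(r) == 0L) return(NULL)
    pool <- names(r)[seq_len(min(top_k, length(r)))]
    pool[sample.int(length(pool), 1L)]
  }
  chosen <- c(pick_from(polarity$positive, top_pos),
              pick_from(polarity$negative, top_neg))
  v <- as_affect(unclass(vs))
  for (cat in chosen) v[cat] <- v[cat] + learning_scale * ratios[cat]
  out <- new_condition_profile(v / sum(v), attr(vs, "condition"))
  attr(out, "chosen") <- chosen
  out
}

#' Diagnostic error rate of a prototype on a labeled cohort
#'
#' Fraction of labeled users whose positive/negative diagnosis for the
#' condition (probability at or above the positive threshold, 0.6) disagrees
#' with their label. Users without sentiment evidence are counted as
#' negative diagnoses.
#'
#' @param vs A `condition_profile`.
#' @param scores [score_users()] frame for the labeled cohort.
#' @param labels Data.frame with `user_id` and `conditions`
#'   (semicolon-separated labels, `""` for none).
#' @param positive_threshold Probability at which the diagnosis turns
#'   positive (default 0.6).
#' @return Misclassification fraction in `[0, 1]`.
#' @export
error_rate <- function(vs, scores, labels, positive_threshold = 0.6) {
  if (nrow(scores) == 0L) stop("empty cohort", call. = FALSE)
  cond <- attr(vs, "condition")
  truth <- has_condition(labels, scores$user_id, cond)
  m <- distribution_matrix(scores)
  p <- as_affect(unclass(vs))
  num <- as.numeric(m %*% p)
  den <- sqrt(rowSums(m^2)) * sqrt(sum(p^2))
  prob <- ifelse(den > 0, num / den, 0)
  predicted <- !scores$empty & prob >= positive_threshold
  mean(predicted != truth)
}

has_condition <- function(labels, user_ids, condition) {
  sets <- strsplit(labels$conditions, ";", fixed = TRUE)
  hit <- vapply(sets, function(s) condition %in% trimws(s), logical(1))
  hit[match(user_ids, labels$user_id)]
}

#' Train condition prototypes by stochastic error feedback
#'
#' For each condition in turn: draw a batch of unlabeled users, compute the
#' batch-average sentiment distribution, propose an update of the prototype
#' toward the crowd's strongest positive and negative sentiments
#' ([propose_update()]), and accept the update only if the diagnostic error
#' rate on the labeled cohort strictly decreases. The accepted-update error
#' sequence is therefore non-increasing by construction. Reproducible given
#' `seed`.
#'
#' @param profiles List of `condition_profile` objects.
#' @param corpus_scores [score_users()] frame for the unlabeled public
#'   corpus (batches are sampled from it, with replacement if it holds
#'   fewer than `batch_size` users).
#' @param cohort_scores [score_users()] frame for the labeled cohort.
#' @param labels Label frame (`user_id`, `conditions`) for the cohort.
#' @param iterations Update proposals per condition (default 100).
#' @param batch_size Unlabeled users per batch (default 1000).
#' @param polarity,top_pos,top_neg,learning_scale Passed to
#'   [propose_update()].
#' @param positive_threshold Passed to [error_rate()].
#' @param seed Integer seed for batch sampling and category picks.
#' @return List with `profiles` (trained) and `trace` (data.frame:
#'   `condition`, `iteration`, `err`, `err_star`, `accepted`, `chosen`).
#' @export
train_profiles <- function(profiles, corpus_scores, cohort_scores, labels,
                           iterations = 100L, batch_size = 1000L,
                           polarity = default_polarity(),
                           top_pos = 2L, top_neg = 3L, learning_scale = 1,
                           positive_threshold = 0.6, seed = 1L) {
  stopifnot(batch_size >= 1L, iterations >= 0L)
  corpus_m <- distribution_matrix(corpus_scores)
  corpus_m <- corpus_m[!corpus_scores$empty, , drop = FALSE]
  if (nrow(corpus_m) == 0L) stop("unlabeled corpus is empty", call. = FALSE)

  trace <- list()
  trained <- withr_seed(seed, {
    lapply(profiles, function(vs) {
      cond <- attr(vs, "condition")
      err <- error_rate(vs, cohort_scores, labels, positive_threshold)
      for (it in seq_len(iterations)) {
        idx <- sample.int(nrow(corpus_m), batch_size,
                          replace = batch_size > nrow(corpus_m))
        asd <- average_distribution(corpus_m[idx, , drop = FALSE])
        vs_star <- propose_update(vs, asd, polarity, top_pos, top_neg,
                                  learning_scale)
        err_star <- error_rate(vs_star, cohort_scores, labels,
                               positive_threshold)
        accepted <- err_star < err
        trace[[length(trace) + 1L]] <<- data.frame(
          condition = cond, iteration = it, err = err, err_star = err_star,
          accepted = accepted,
          chosen = paste(attr(vs_star, "chosen"), collapse = ";"),
          stringsAsFactors = FALSE)
        if (accepted) {
          vs <- vs_star
          attr(vs, "chosen") <- NULL
          err <- err_star
        }
      }
      vs
    })
  })
  list(profiles = trained,
       trace = do.call(rbind, c(trace, list(make.row.names = FALSE))))
}

#' Average diagnostic precision over conditions
#'
#' For each condition, count the users correctly classified as having it
#' plus the users correctly classified as not having it; the average
#' diagnostic precision is the total over conditions divided by
#' (number of conditions x number of evaluated users) — i.e. the mean
#' per-condition accuracy.
#'
#' @param counts Data.frame with one row per condition and columns
#'   `correct_with` and `correct_without`.
#' @param n_users Number of evaluated users (> 0).
#' @return Average diagnostic precision in `[0, 1]`.
#' @export
average_diagnostic_precision <- function(counts, n_users) {
  if (n_users <= 0) stop("n_users must be positive", call. = FALSE)
  n <- nrow(counts)
  if (n < 1L) stop("at least one condition required", call. = FALSE)
  sum(counts$correct_with + counts$correct_without) / (n * n_users)
}

#' Evaluate diagnoses against labels
#'
#' Builds per-condition confusion counts (positive diagnosis = probability
#' at or above the MMU threshold) and the average diagnostic precision.
#'
#' @param diagnoses Frame from [diagnose_users()] / [diagnose_scores()].
#' @param labels Label frame (`user_id`, `conditions`).
#' @return List with `counts` (per-condition TP/FP/FN/TN,
#'   `correct_with`/`correct_without`), `adp`, and `n_users`.
#' @export
evaluate_diagnoses <- function(diagnoses, labels) {
  conds <- sub("^prob_", "", grep("^prob_", names(diagnoses), value = TRUE))
  n_users <- nrow(diagnoses)
  rows <- lapply(conds, function(cond) {
    truth <- has_condition(labels, diagnoses$user_id, cond)
    lvl <- diagnoses[[paste0("level_", cond)]]
    pred <- lvl %in% c("MMU", "SMU")
    data.frame(condition = cond,
               tp = sum(pred & truth), fp = sum(pred & !truth),
               fn = sum(!pred & truth), tn = sum(!pred & !truth),
               correct_with = sum(pred & truth),
               correct_without = sum(!pred & !truth),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  list(counts = counts,
       adp = average_diagnostic_precision(counts, n_users),
       n_users = n_users)
}

#' Precision, recall and F1 from confusion counts
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative counts;
#'   `tp + fp` and `tp + fn` must be positive (undefined ratios are an
#'   error, not silently 0).
#' @return Named numeric: `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (tp + fp <= 0) stop("precision undefined: tp + fp = 0", call. = FALSE)
  if (tp + fn <= 0) stop("recall undefined: tp + fn = 0", call. = FALSE)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' @rdname precision_recall_f1
#' @param precision,recall Precision and recall in `(0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) stop("F1 undefined: precision + recall = 0",
                                    call. = FALSE)
  2 * precision * recall / (precision + recall)
}

#' Stratified 70/30 cohort split
#'
#' Splits a labeled cohort into training and testing sets, stratified by
#' condition-versus-none; the training size per stratum is
#' `floor(train_frac * n + 0.5)` (round half up), so a 396-user condition
#' stratum at 0.7 splits 277/119 and a 400-user control stratum 280/120.
#'
#' @param labels Label frame (`user_id`, `conditions`).
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with label frames `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(labels, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  strata <- ifelse(nzchar(trimws(labels$conditions)), "condition", "none")
  train_idx <- withr_seed(seed, {
    unlist(lapply(unique(strata), function(s) {
      idx <- which(strata == s)
      if (length(idx) < 2L)
        stop("stratum '", s, "' has fewer than 2 users", call. = FALSE)
      n_train <- floor(train_frac * length(idx) + 0.5)
      sample(idx, n_train)
    }), use.names = FALSE)
  })
  list(train = labels[sort(train_idx), , drop = FALSE],
       test = labels[-sort(train_idx), , drop = FALSE])
}
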