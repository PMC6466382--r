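#' Build a condition prototype vector from a screening-scale text
#'
#' Scores the items of a mental-health screening scale with the standard
#' pipeline, but with every matched sentiment word's degree factor forced to
#' the maximum configured degree-adverb weight: scale items describe the
#' most severe presentation of the condition, so the prototype is anchored
#' at the highest degree level. Item vectors are accumulated and normalized
#' into the condition's prototype sentiment distribution.
#'
#' @param items Character vector of scale items (one statement each).
#' @param lex An `msai_lexicon`.
#' @param tables A `modifier_tables` list.
#' @param condition Condition label to attach.
#' @param max_degree Degree weight forced on every matched word (default
#'   `max(tables$degree_adverbs)`, 2 when unset; the top of the 0-2 scale).
#' @return A `condition_profile`: named numeric simplex vector over
#'   [msai_categories()] with attribute `condition`.
#' @export
build_condition_profile <- function(items, lex,
                                    tables = default_modifier_tables(),
                                    condition = "condition",
                                    max_degree = NULL) {
  if (is.null(max_degree)) {
    max_degree <- if (length(tables$degree_adverbs) > 0)
      max(tables$degree_adverbs) else 2
  }
  item_vectors <- lapply(items, function(item) {
    sentences <- split_sentences(item)
    vs <- lapply(sentences, function(s) {
      ctxs <- attach_modifiers(tokenize(s, tables, lex), lex, tables)
      ctxs <- lapply(ctxs, function(ctx) {
        ctx$degree_weights <- max_degree
        ctx
      })
      score_sentence(ctxs, adversative_weight = tables$adversative_weight)
    })
    accumulate(vs)
  })
  ds <- normalize_distribution(accumulate(item_vectors))
  if (is_empty_distribution(ds))
    stop("scale text for '", condition,
         "' matched no sentiment words; profile undefined", call. = FALSE)
  new_condition_profile(as.numeric(ds), condition)
}

new_condition_profile <- function(values, condition) {
  v <- as_affect(values)
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
    stop("a condition profile must be a non-negative vector summing to 1",
         call. = FALSE)
  structure(v, condition = condition, class = "condition_profile")
}

#' Probability of a condition: cosine similarity to the prototype
#'
#' The probability that a user suffers from condition `c` is the cosine
#' similarity between the condition's prototype vector and the user's
#' sentiment distribution. Both vectors are non-negative, so the value lies
#' in `[0, 1]`; it is symmetric and invariant to positive rescaling of
#' either argument.
#'
#' @param vs Condition profile (or any non-negative 11-vector).
#' @param ds User sentiment distribution; must not be empty
#'   ([is_empty_distribution()]).
#' @return Cosine similarity in `[0, 1]`.
#' @export
probability <- function(vs, ds) {
  if (is_empty_distribution(ds))
    stop("insufficient sentiment evidence: empty distribution", call. = FALSE)
  a <- as_affect(unclass(vs))
  b <- as_affect(unclass(ds))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' Classify a condition probability into a risk level
#'
#' Severe (SMU) above the upper threshold, moderate (MMU) between the
#' thresholds inclusive, no-or-mild (NMU) below the lower threshold. The
#' boundary values 0.6 and 0.8 fall in MMU (the definitions of SMU and NMU
#' are strict inequalities). A user is considered higher-risk — a positive
#' diagnosis — at MMU or above.
#'
#' @param prob Probability in `[0, 1]`.
#' @param thresholds Named numeric `c(mmu = 0.6, smu = 0.8)`.
#' @return One of `"NMU"`, `"MMU"`, `"SMU"`.
#' @examples
#' classify_risk(0.85)  # "SMU"
#' classify_risk(0.70)  # "MMU"
#' classify_risk(0.80)  # "MMU" (boundary)
#' @export
classify_risk <- function(prob, thresholds = c(mmu = 0.6, smu = 0.8)) {
  if (length(prob) != 1L || is.na(prob) || prob < 0 || prob > 1)
    stop("prob must be a single value in [0, 1]", call. = FALSE)
  if (prob > thresholds[["smu"]]) "SMU"
  else if (prob >= thresholds[["mmu"]]) "MMU"
  else "NMU"
}

#' Diagnose one user against a set of condition profiles
#'
#' Accumulates the user's texts into a sentiment distribution and computes
#' an independent probability and risk level per condition: users may have
#' more than one disorder, so no condition suppresses another. A user with
#' no sentiment evidence is returned as all-NMU with `no_evidence = TRUE`
#' and a warning.
#'
#' @param texts Character vector of the user's short texts.
#' @param profiles List of `condition_profile` objects (>= 1).
#' @param lex An `msai_lexicon`.
#' @param tables A `modifier_tables` list.
#' @param thresholds Risk thresholds, see [classify_risk()].
#' @param user_id Identifier carried into the result.
#' @return A `diagnosis_result` list: `user_id`, `distribution`, `probs`
#'   (named per condition), `levels` (named per condition), `no_evidence`.
#' @export
diagnose_user <- function(texts, profiles, lex,
                          tables = default_modifier_tables(),
                          thresholds = c(mmu = 0.6, smu = 0.8),
                          user_id = "user") {
  if (length(profiles) == 0L) stop("at least one profile required",
                                   call. = FALSE)
  conds <- vapply(profiles, function(p) attr(p, "condition"), character(1))
  v <- accumulate(lapply(texts, score_text, lex = lex, tables = tables))
  ds <- normalize_distribution(v)
  if (is_empty_distribution(ds)) {
    warning("user '", user_id, "' has no sentiment evidence; all levels NMU",
            call. = FALSE)
    probs <- stats::setNames(rep(NA_real_, length(conds)), conds)
    levels <- stats::setNames(rep("NMU", length(conds)), conds)
    return(structure(list(user_id = user_id, distribution = ds,
                          probs = probs, levels = levels,
                          no_evidence = TRUE),
                     class = "diagnosis_result"))
  }
  probs <- vapply(profiles, probability, numeric(1), ds = ds)
  names(probs) <- conds
  levels <- vapply(probs, classify_risk, character(1),
                   thresholds = thresholds)
  structure(list(user_id = user_id, distribution = ds, probs = probs,
                 levels = levels, no_evidence = FALSE),
            class = "diagnosis_result")
}

#' Diagnose every user in a tweet table
#'
#' Scores all users with [score_users()] and evaluates each against every
#' condition profile.
#'
#' @param tweets Data.frame with `user_id`, `timestamp`, `text`.
#' @param profiles List of `condition_profile` objects.
#' @inheritParams diagnose_user
#' @inheritParams score_users
#' @return Data.frame with `user_id`, `prob_<condition>` and
#'   `level_<condition>` columns, and `no_evidence`.
#' @export
diagnose_users <- function(tweets, profiles, lex,
                           tables = default_modifier_tables(),
                           thresholds = c(mmu = 0.6, smu = 0.8),
                           window_days = 14) {
  scores <- score_users(tweets, lex, tables, window_days = window_days)
  diagnose_scores(scores, profiles, thresholds)
}

#' Diagnose users from precomputed sentiment distributions
#'
#' Same as [diagnose_users()] but starting from a [score_users()] frame,
#' avoiding re-scoring when the distributions are reused (e.g. inside the
#' training loop).
#'
#' @param scores Data.frame from [score_users()].
#' @param profiles List of `condition_profile` objects.
#' @param thresholds Risk thresholds.
#' @return Data.frame as in [diagnose_users()].
#' @export
diagnose_scores <- function(scores, profiles,
                            thresholds = c(mmu = 0.6, smu = 0.8)) {
  conds <- vapply(profiles, function(p) attr(p, "condition"), character(1))
  m <- distribution_matrix(scores)
  out <- data.frame(user_id = scores$user_id, stringsAsFactors = FALSE)
  for (k in seq_along(profiles)) {
    p <- as_affect(unclass(profiles[[k]]))
    num <- as.numeric(m %*% p)
    den <- sqrt(rowSums(m^2)) * sqrt(sum(p^2))
    prob <- ifelse(scores$empty, NA_real_, pmin(1, pmax(0, num / den)))
    lvl <- ifelse(is.na(prob), "NMU",
                  ifelse(prob > thresholds[["smu"]], "SMU",
                         ifelse(prob >= thresholds[["mmu"]], "MMU", "NMU")))
    out[[paste0("prob_", conds[k])]] <- prob
    out[[paste0("level_", conds[k])]] <- lvl
  }
  out$no_evidence <- scores$empty
  out
}
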