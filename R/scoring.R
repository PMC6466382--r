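#' Quantify the affect intensity of one sentence
#'
#' Each matched sentiment word contributes
#' `intensity x prod(degree weights) x adversative x negation + emoticon +
#' punctuation` to its sentiment category: the degree-adverb product is 1
#' when no adverb attaches, the adversative factor is 1.5 for words after an
#' adversative and 1 otherwise, the negation factor is -1 when negated and
#' +1 otherwise, and the emoticon / sentiment-punctuation weights (0 when
#' absent) are additive. The result is an 11-dimensional affect vector; a
#' sentence with no sentiment words scores the zero vector. Negation can
#' push a component negative; negatives are only clamped later, at
#' distribution normalization, so opposite contributions within a text can
#' cancel.
#'
#' @param contexts List of `word_context` objects from [attach_modifiers()]
#'   (one sentence).
#' @param adversative_weight Clause weight after an adversative
#'   (default 1.5).
#' @return Named numeric affect vector over [msai_categories()].
#' @examples
#' # "very sad" with sad = 0.6, very = 1.5 scores 0.9 on sadness
#' @export
score_sentence <- function(contexts, adversative_weight = 1.5) {
  v <- zero_affect()
  for (ctx in contexts) {
    alpha <- prod(ctx$degree_weights)  # empty product = 1
    beta <- if (isTRUE(ctx$after_adversative)) adversative_weight else 1
    eta <- if (isTRUE(ctx$negated)) -1 else 1
    contrib <- ctx$intensity * alpha * beta * eta +
      ctx$emoticon_weight + ctx$punct_weight
    v[ctx$category] <- v[ctx$category] + contrib
  }
  v
}

#' Sum affect vectors over sentences or texts
#'
#' Element-wise sum; the user-level affect vector is the sum over all the
#' user's texts of the per-text sums over sentences. An empty list sums to
#' the zero vector.
#'
#' @param vectors List of affect vectors (shared category order).
#' @return Named numeric affect vector.
#' @export
accumulate <- function(vectors) {
  v <- zero_affect()
  for (x in vectors) v <- v + as_affect(x)
  v
}

#' Score a short text into an affect vector
#'
#' Splits into sentences, tokenizes, attaches qualifiers and sums the
#' per-sentence affect vectors.
#'
#' @param text Character scalar.
#' @param lex An `msai_lexicon`.
#' @param tables A `modifier_tables` list.
#' @param window Qualifier attachment window (see [attach_modifiers()]).
#' @return Named numeric affect vector.
#' @export
score_text <- function(text, lex, tables = default_modifier_tables(),
                       window = 3L) {
  sentences <- split_sentences(text)
  vs <- lapply(sentences, function(s) {
    score_sentence(attach_modifiers(tokenize(s, tables, lex), lex, tables,
                                    window = window),
                   adversative_weight = tables$adversative_weight)
  })
  accumulate(vs)
}

#' Normalize an affect vector to a sentiment distribution
#'
#' Negative components (from negation) are clamped to 0, then the vector is
#' divided by its component sum, yielding an 11-dimensional probability
#' vector. If nothing positive remains, the distribution is flagged empty
#' (no sentiment evidence) and all components are zero.
#'
#' @param v Affect vector (named numeric over [msai_categories()]).
#' @return A `sentiment_distribution`: named numeric vector with attribute
#'   `empty` (logical). Components sum to 1 unless empty.
#' @export
normalize_distribution <- function(v) {
  v <- pmax(as_affect(v), 0)
  s <- sum(v)
  if (s <= 0) {
    return(structure(zero_affect(), empty = TRUE,
                     class = "sentiment_distribution"))
  }
  structure(v / s, empty = FALSE, class = "sentiment_distribution")
}

#' Is a sentiment distribution empty?
#'
#' @param ds A `sentiment_distribution`.
#' @return `TRUE` if the source text carried no (net-positive) sentiment.
#' @export
is_empty_distribution <- function(ds) isTRUE(attr(ds, "empty"))

#' Score users' tweets into per-user sentiment distributions
#'
#' Accumulates each user's texts within an observation window — by default
#' the 14 days up to the user's most recent tweet, matching a two-week
#' collection period — and normalizes to an 11-dimensional sentiment
#' distribution per user.
#'
#' @param tweets Data.frame with columns `user_id`, `timestamp` (ISO-8601
#'   character or POSIXct; `NA` timestamps are always in-window) and `text`.
#' @param lex An `msai_lexicon`.
#' @param tables A `modifier_tables` list.
#' @param window_days Observation window length in days (default 14).
#' @param window Qualifier attachment window (tokens).
#' @return Data.frame with `user_id`, one column per sentiment category,
#'   and `empty` (logical; no sentiment evidence for that user).
#' @export
score_users <- function(tweets, lex, tables = default_modifier_tables(),
                        window_days = 14, window = 3L) {
  stopifnot(all(c("user_id", "text") %in% names(tweets)))
  ts <- if ("timestamp" %in% names(tweets)) parse_timestamp(tweets$timestamp)
        else rep(as.POSIXct(NA), nrow(tweets))
  users <- unique(tweets$user_id)
  rows <- lapply(users, function(u) {
    i <- tweets$user_id == u
    tu <- tweets$text[i]
    tsu <- ts[i]
    if (any(!is.na(tsu))) {
      latest <- max(tsu, na.rm = TRUE)
      keep <- is.na(tsu) |
        (as.numeric(latest - tsu, units = "days") <= window_days)
      tu <- tu[keep]
    }
    v <- accumulate(lapply(tu, score_text, lex = lex, tables = tables,
                           window = window))
    ds <- normalize_distribution(v)
    c(as.list(ds), list(empty = is_empty_distribution(ds)))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  cbind(data.frame(user_id = users, stringsAsFactors = FALSE), out)
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  miss <- is.na(out) & !is.na(x)
  if (any(miss))
    out[miss] <- as.POSIXct(x[miss], tz = "UTC",
                            tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  out
}

# extract the 11-column distribution matrix from a score_users() frame
distribution_matrix <- function(scores) {
  m <- as.matrix(scores[, msai_categories(), drop = FALSE])
  rownames(m) <- scores$user_id
  m
}
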