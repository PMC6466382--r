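#' Default qualifier weight tables
#'
#' The weights that qualify a sentiment word's affect intensity at scoring
#' time:
#' * degree adverbs, multiplicative weight in `[0, 2]` ("very" = 1.5 and
#'   "little" = 0.5 anchor the scale; other entries are package defaults);
#' * negations, sign flip (weight -1);
#' * adversatives ("but", ...), weight 1.5 applied to every sentiment word
#'   of the clause after the adversative;
#' * emoticons and sentiment punctuation, additive weights in `[0, 1]` —
#'   weaker signals than degree adverbs.
#'
#' All tables are plain named vectors and can be edited or replaced; see
#' [read_modifier_tables()] for the TSV representation.
#'
#' @return A `modifier_tables` list with elements `degree_adverbs`
#'   (named numeric), `negations` (character), `adversatives` (character),
#'   `emoticons` (named numeric), `sentiment_punct` (named numeric),
#'   `adversative_weight` (scalar, 1.5).
#' @export
default_modifier_tables <- function() {
  new_modifier_tables(list(
    degree_adverbs = c(
      very = 1.5, extremely = 1.8, really = 1.4, so = 1.3, too = 1.6,
      quite = 1.2, pretty = 1.2, totally = 1.7, absolutely = 1.8,
      little = 0.5, slightly = 0.3, somewhat = 0.7, barely = 0.4,
      hardly = 0.4, almost = 0.8
    ),
    negations = c("not", "never", "no", "n't", "cannot", "nothing",
                  "nobody", "neither", "without"),
    adversatives = c("but", "however", "yet", "although", "though",
                     "nevertheless"),
    emoticons = c(
      ":)" = 0.5, ":-)" = 0.5, ":D" = 0.7, ":(" = 0.5, ":-(" = 0.5,
      ":'(" = 0.8, ";)" = 0.4, ":/" = 0.3, "<3" = 0.5, "D:" = 0.6
    ),
    sentiment_punct = c(
      "!" = 0.3, "!!" = 0.5, "!!!" = 0.8, "?!" = 0.6, "!?" = 0.6,
      "??" = 0.4, "..." = 0.2
    ),
    adversative_weight = 1.5
  ))
}

new_modifier_tables <- function(x) {
  stopifnot(is.list(x),
            all(c("degree_adverbs", "negations", "adversatives",
                  "emoticons", "sentiment_punct") %in% names(x)))
  if (is.null(x$adversative_weight)) x$adversative_weight <- 1.5
  if (any(x$degree_adverbs < 0 | x$degree_adverbs > 2))
    stop("degree adverb weights must lie in [0, 2]", call. = FALSE)
  if (any(x$emoticons < 0 | x$emoticons > 1))
    stop("emoticon weights must lie in [0, 1]", call. = FALSE)
  if (any(x$sentiment_punct < 0 | x$sentiment_punct > 1))
    stop("sentiment punctuation weights must lie in [0, 1]", call. = FALSE)
  structure(x, class = "modifier_tables")
}

#' Read / write qualifier tables as TSV
#'
#' Three tab-separated columns, no header: kind (one of `degree_adverb`,
#' `negation`, `adversative`, `emoticon`, `sentiment_punct`), surface form,
#' weight (empty for negations/adversatives, whose weights are fixed at -1
#' and 1.5).
#'
#' @param tables A `modifier_tables` list.
#' @param path File path.
#' @return `read_modifier_tables()` returns a `modifier_tables` list;
#'   `write_modifier_tables()` returns `path` invisibly.
#' @export
write_modifier_tables <- function(tables, path) {
  rows <- c(
    paste("degree_adverb", names(tables$degree_adverbs),
          tables$degree_adverbs, sep = "\t"),
    paste("negation", tables$negations, "", sep = "\t"),
    paste("adversative", tables$adversatives, "", sep = "\t"),
    paste("emoticon", names(tables$emoticons), tables$emoticons, sep = "\t"),
    paste("sentiment_punct", names(tables$sentiment_punct),
          tables$sentiment_punct, sep = "\t")
  )
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_modifier_tables
#' @export
read_modifier_tables <- function(path) {
  if (!file.exists(path)) stop("modifier table file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("kind", "surface", "weight"))
  pick <- function(kind) tab[tab$kind == kind, , drop = FALSE]
  named_num <- function(d) stats::setNames(as.numeric(d$weight), d$surface)
  new_modifier_tables(list(
    degree_adverbs = named_num(pick("degree_adverb")),
    negations = pick("negation")$surface,
    adversatives = pick("adversative")$surface,
    emoticons = named_num(pick("emoticon")),
    sentiment_punct = named_num(pick("sentiment_punct"))
  ))
}

#' Split a short text into sentences
#'
#' Splits on runs of terminal punctuation (`.`, `!`, `?`), keeping each run
#' attached to its sentence. Text without terminal punctuation is a single
#' sentence; empty text yields an empty vector.
#'
#' @param text A character scalar.
#' @return Character vector of sentences.
#' @examples
#' split_sentences("Help!!! So scared...")
#' @export
split_sentences <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  m <- regmatches(text, gregexpr("[^.!?]+[.!?]*", text))[[1]]
  m <- trimws(m)
  m[nzchar(m)]
}

#' Tokenize one sentence against qualifier tables and a lexicon
#'
#' Lowercases; strips URLs and @-mentions; keeps hashtag bodies as plain
#' words; emits emoticons and runs of sentiment punctuation as single
#' tokens. Each token is labeled with a kind by table and lexicon lookup:
#' `degree_adverb`, `negation`, `adversative`, `emoticon`,
#' `sentiment_punctuation`, `sentiment_word` (lexicon match; takes
#' precedence over `other`), or `other`.
#'
#' @param sentence A character scalar.
#' @param tables A `modifier_tables` list.
#' @param lex An `msai_lexicon`.
#' @return Data.frame with columns `surface`, `kind`, `position` (0-based).
#' @export
tokenize <- function(sentence, tables, lex) {
  s <- enc2utf8(tolower(trimws(sentence)))
  if (!nzchar(s)) {
    return(data.frame(surface = character(0), kind = character(0),
                      position = integer(0), stringsAsFactors = FALSE))
  }
  s <- gsub("(https?://|www\\.)\\S+", " ", s)
  s <- gsub("@\\w+", " ", s)
  s <- gsub("#(\\w)", "\\1", s)

  emo <- names(tables$emoticons)
  emo <- emo[order(-nchar(emo))]
  emo_pat <- paste(vapply(emo, escape_regex, character(1)), collapse = "|")
  pat <- paste0(
    if (nzchar(emo_pat)) paste0("(?:", emo_pat, ")|") else "",
    "[!?]+|\\.{3,}|[a-z']+"
  )
  surfaces <- regmatches(s, gregexpr(pat, s, perl = TRUE))[[1]]
  surfaces <- surfaces[nzchar(surfaces)]
  if (length(surfaces) == 0L) {
    return(data.frame(surface = character(0), kind = character(0),
                      position = integer(0), stringsAsFactors = FALSE))
  }

  lex_words <- unique(lex$word)
  kind <- vapply(surfaces, function(tok) {
    if (tok %in% names(tables$degree_adverbs)) return("degree_adverb")
    if (tok %in% tables$negations) return("negation")
    if (tok %in% tables$adversatives) return("adversative")
    if (tok %in% names(tables$emoticons)) return("emoticon")
    if (grepl("^([!?]+|\\.+)$", tok)) return("sentiment_punctuation")
    # n't clitics count as negation ("don't", "can't", ...)
    if (grepl("n't$", tok) && "n't" %in% tables$negations) return("negation")
    if (tok %in% lex_words) return("sentiment_word")
    "other"
  }, character(1), USE.NAMES = FALSE)

  data.frame(surface = surfaces, kind = kind,
             position = seq_along(surfaces) - 1L,
             stringsAsFactors = FALSE)
}

escape_regex <- function(x) gsub("([\\^$.|?*+()\\[\\]{}\\\\<>])", "\\\\\\1",
                                 x, perl = TRUE)

# map a punctuation run to its table weight; unseen runs fall back to the
# longest matching prefix key, else 0
punct_weight <- function(surface, tables) {
  w <- tables$sentiment_punct
  if (surface %in% names(w)) return(unname(w[surface]))
  keys <- names(w)[order(-nchar(names(w)))]
  for (k in keys) {
    if (startsWith(surface, k)) return(unname(w[k]))
  }
  0
}

#' Attach the closest qualifiers to each sentiment word
#'
#' Implements the proximity rule: each degree adverb and negation attaches
#' to its nearest sentiment word within `window` tokens (ties go to the
#' following sentiment word); each emoticon and sentiment-punctuation token
#' attaches to its nearest sentiment word anywhere in the sentence. A
#' qualifier token attaches to at most one sentiment word. A sentiment word
#' is `after_adversative` iff an adversative token precedes it in the
#' sentence.
#'
#' @param tokens Token data.frame from [tokenize()] (one sentence).
#' @param lex An `msai_lexicon` (supplies the matched word's category and
#'   intensity; a surface listed under several categories resolves to its
#'   highest-intensity entry so that every sentiment-word token yields
#'   exactly one context).
#' @param tables A `modifier_tables` list.
#' @param window Maximum token distance for degree-adverb/negation
#'   attachment (default 3).
#' @return List of `word_context` lists with elements `word`, `category`,
#'   `intensity`, `degree_weights` (numeric, possibly empty), `negated`,
#'   `after_adversative`, `emoticon_weight`, `punct_weight`.
#' @export
attach_modifiers <- function(tokens, lex, tables, window = 3L) {
  sw_idx <- which(tokens$kind == "sentiment_word")
  if (length(sw_idx) == 0L) return(list())
  sw_pos <- tokens$position[sw_idx]

  # nearest sentiment word for one modifier position; ties -> following word
  nearest_word <- function(pos, max_dist = Inf) {
    d <- abs(sw_pos - pos)
    if (min(d) > max_dist) return(NA_integer_)
    cand <- which(d == min(d))
    if (length(cand) > 1L) cand <- cand[which.max(sw_pos[cand])]
    cand
  }

  deg_w <- replicate(length(sw_idx), numeric(0), simplify = FALSE)
  negated <- logical(length(sw_idx))
  emo_w <- rep(0, length(sw_idx))
  emo_d <- rep(Inf, length(sw_idx))
  pun_w <- rep(0, length(sw_idx))
  pun_d <- rep(Inf, length(sw_idx))

  for (i in seq_len(nrow(tokens))) {
    kind <- tokens$kind[i]
    pos <- tokens$position[i]
    if (kind == "degree_adverb") {
      j <- nearest_word(pos, window)
      if (!is.na(j)) {
        w <- unname(tables$degree_adverbs[tokens$surface[i]])
        deg_w[[j]] <- c(deg_w[[j]], w)
      }
    } else if (kind == "negation") {
      j <- nearest_word(pos, window)
      if (!is.na(j)) negated[j] <- TRUE
    } else if (kind == "emoticon") {
      j <- nearest_word(pos)
      d <- abs(sw_pos[j] - pos)
      if (d < emo_d[j]) {
        emo_d[j] <- d
        emo_w[j] <- unname(tables$emoticons[tokens$surface[i]])
      }
    } else if (kind == "sentiment_punctuation") {
      j <- nearest_word(pos)
      d <- abs(sw_pos[j] - pos)
      if (d < pun_d[j]) {
        pun_d[j] <- d
        pun_w[j] <- punct_weight(tokens$surface[i], tables)
      }
    }
  }

  adv_pos <- tokens$position[tokens$kind == "adversative"]
  after_adv <- if (length(adv_pos) == 0L) rep(FALSE, length(sw_idx))
               else sw_pos > min(adv_pos)

  out <- vector("list", length(sw_idx))
  for (j in seq_along(sw_idx)) {
    surface <- tokens$surface[sw_idx[j]]
    hits <- lex[lex$word == surface, , drop = FALSE]
    h <- which.max(hits$intensity)
    out[[j]] <- structure(list(
      word = surface,
      category = hits$category[h],
      intensity = hits$intensity[h],
      degree_weights = deg_w[[j]],
      negated = negated[j],
      after_adversative = after_adv[j],
      emoticon_weight = emo_w[j],
      punct_weight = pun_w[j]
    ), class = "word_context")
  }
  out
}
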