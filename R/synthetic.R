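#' Specification for the synthetic-data generator
#'
#' Collects the knobs of the synthetic corpus: vocabulary size, cohort
#' sizes, tweet counts, Dirichlet concentration of user distributions
#' around their target, and the rate at which qualifier decorations are
#' injected. Defaults emulate a two-week hashtag-sampled cohort: around 14
#' tweets per user (the observed medians run 10-18), 20 users per condition
#' with 100 controls at test scale, and concentration 50 (low noise on the
#' simplex).
#'
#' @param n_words_per_category Pseudo-words generated per MSAI category
#'   (default 12; the three split source emotions get twice this, half per
#'   intensity mode).
#' @param n_users_per_condition Users per condition group (default 20).
#' @param n_controls Users with no condition (default 100).
#' @param n_unlabeled Users in the unlabeled public corpus (default 200).
#' @param tweets_per_user Mean tweets per user (default 14; actual counts
#'   are Poisson, floored at 3).
#' @param words_per_tweet Mean sentiment-bearing words per tweet
#'   (default 9, Poisson floored at 2).
#' @param concentration Dirichlet concentration around the target
#'   distribution (default 50; larger = less user-level noise).
#' @param modifier_rate Probability that a sentiment word is decorated with
#'   a degree adverb or trailing sentiment punctuation (default 0.2).
#' @param background_mix Weight of condition-profile mass mixed into the
#'   unlabeled corpus's generating distribution (default 0.5), biasing the
#'   crowd average toward the condition profiles as the training signal
#'   expects.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_words_per_category = 12L,
                           n_users_per_condition = 20L,
                           n_controls = 100L,
                           n_unlabeled = 200L,
                           tweets_per_user = 14,
                           words_per_tweet = 9,
                           concentration = 50,
                           modifier_rate = 0.2,
                           background_mix = 0.5) {
  stopifnot(n_words_per_category >= 2L, concentration > 0,
            modifier_rate >= 0, modifier_rate <= 1,
            background_mix >= 0, background_mix <= 1)
  structure(list(n_words_per_category = n_words_per_category,
                 n_users_per_condition = n_users_per_condition,
                 n_controls = n_controls,
                 n_unlabeled = n_unlabeled,
                 tweets_per_user = tweets_per_user,
                 words_per_tweet = words_per_tweet,
                 concentration = concentration,
                 modifier_rate = modifier_rate,
                 background_mix = background_mix),
            class = "generator_spec")
}

# pronounceable CV-syllable pseudo-words, unique
make_pseudo_words <- function(n, n_syllables = 3L) {
  consonants <- strsplit("bcdfglmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    w <- vapply(seq_len(n - length(out)), function(i) {
      paste0(paste0(sample(consonants, n_syllables, replace = TRUE),
                    sample(vowels, n_syllables, replace = TRUE)),
             collapse = "")
    }, character(1))
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate a fixture source lexicon and its 11-category refinement
#'
#' Produces an 8-emotion source lexicon of pronounceable pseudo-words,
#' unique across categories. The three emotions destined for splitting
#' (disgust, sadness, fear) receive bimodal intensities — a low-arousal
#' mode near 0.2 and a high-arousal mode near 0.8, modes separated by at
#' least 0.3 — so the 2-means split has a real boundary to find; the other
#' five emotions get uniform intensities. The refined lexicon is built with
#' the package's own pipeline ([build_msai_lexicon()]).
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return List with `source` (an `emotion_lexicon`-shaped data.frame) and
#'   `msai` (the normalized `msai_lexicon`).
#' @export
make_fixture_lexicon <- function(spec = generator_spec(), seed = 1L) {
  n <- spec$n_words_per_category
  split_cats <- c("disgust", "sadness", "fear")
  withr_seed(seed, {
    counts <- ifelse(nrc_categories() %in% split_cats, 2L * n, n)
    words <- make_pseudo_words(sum(counts))
    entries <- data.frame(
      word = words,
      category = rep(nrc_categories(), counts),
      intensity = NA_real_, stringsAsFactors = FALSE)
    for (cat in nrc_categories()) {
      i <- which(entries$category == cat)
      entries$intensity[i] <- if (cat %in% split_cats) {
        half <- length(i) %/% 2L
        c(stats::runif(half, 0.05, 0.35),
          stats::runif(length(i) - half, 0.65, 0.95))
      } else {
        stats::runif(length(i), 0.1, 0.9)
      }
    }
    source_lex <- structure(entries,
                            class = c("emotion_lexicon", "data.frame"),
                            categories = nrc_categories(),
                            n_rows = nrow(entries), n_skipped = 0L)
    list(source = source_lex,
         msai = build_msai_lexicon(source_lex, seed = seed))
  })
}

#' Default synthetic condition target distributions
#'
#' Ground-truth sentiment distributions for the five conditions, plus the
#' background (control) distribution. Each condition loads on a distinct
#' negative-sentiment signature (depressive on grief/sadness, anxiety on
#' fear, OCD on loathing/disgust, bipolar on alternating joy and sadness,
#' panic on terror), mutually dissimilar enough that cosine similarity
#' separates them; controls sit mostly on the four positive categories with
#' light negative mass.
#'
#' @return Named list of simplex vectors over [msai_categories()]
#'   (`depressive`, `anxiety`, `ocd`, `bipolar`, `panic`, `background`).
#' @export
synthetic_condition_targets <- function() {
  mk <- function(...) {
    v <- zero_affect()
    args <- c(...)
    v[names(args)] <- args
    v / sum(v)
  }
  list(
    depressive = mk(grief = 0.45, sadness = 0.35, fear = 0.10,
                    anger = 0.10),
    anxiety    = mk(fear = 0.55, anticipation = 0.15, sadness = 0.15,
                    surprise = 0.15),
    ocd        = mk(loathing = 0.45, disgust = 0.35, anger = 0.15,
                    trust = 0.05),
    bipolar    = mk(joy = 0.35, sadness = 0.25, grief = 0.15,
                    anger = 0.15, anticipation = 0.10),
    panic      = mk(terror = 0.55, fear = 0.20, surprise = 0.20,
                    sadness = 0.05),
    background = mk(joy = 0.30, trust = 0.25, anticipation = 0.20,
                    surprise = 0.15, sadness = 0.05, fear = 0.05)
  )
}

# one Dirichlet draw with concentration conc around target p (zeros stay 0)
rdirichlet_around <- function(target, conc) {
  g <- stats::rgamma(length(target), shape = conc * target, rate = 1)
  if (sum(g) <= 0) return(target)
  stats::setNames(g / sum(g), names(target))
}

#' Generate one user's tweets around a target distribution
#'
#' Draws the user's personal distribution from a Dirichlet centered on the
#' target, then composes tweets as word salads: each sentiment word is
#' sampled category-first from the personal distribution, then uniformly
#' within the category's lexicon words; at `modifier_rate`, a word is
#' decorated with a degree adverb or followed by sentiment punctuation.
#' Filler words and timestamps within a 14-day window complete the record.
#' Uses the current RNG state.
#'
#' @param user_id Identifier.
#' @param target Simplex vector over [msai_categories()].
#' @param lex An `msai_lexicon` to draw words from.
#' @param spec A [generator_spec()].
#' @param tables Modifier tables supplying decoration surfaces.
#' @param n_tweets Tweet count; default Poisson around
#'   `spec$tweets_per_user`, floored at 3. `0` yields an empty user.
#' @return Data.frame of tweets (`user_id`, `timestamp`, `text`).
#' @export
generate_user <- function(user_id, target, lex, spec = generator_spec(),
                          tables = default_modifier_tables(),
                          n_tweets = NULL) {
  if (is.null(n_tweets))
    n_tweets <- max(3L, stats::rpois(1L, spec$tweets_per_user))
  if (n_tweets == 0L)
    return(data.frame(user_id = character(0), timestamp = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  personal <- rdirichlet_around(as_affect(target), spec$concentration)
  by_cat <- split(lex$word, lex$category)
  fillers <- c("i", "am", "the", "and", "today", "it", "was", "been",
               "my", "this")
  deg <- names(tables$degree_adverbs)
  punct <- names(tables$sentiment_punct)

  base_time <- as.POSIXct("2018-07-15 12:00:00", tz = "UTC")
  texts <- vapply(seq_len(n_tweets), function(t) {
    n_words <- max(2L, stats::rpois(1L, spec$words_per_tweet))
    cats <- sample(names(personal), n_words, replace = TRUE, prob = personal)
    words <- vapply(cats, function(cat) {
      pool <- by_cat[[cat]]
      if (is.null(pool)) return(sample(fillers, 1L))
      pool[sample.int(length(pool), 1L)]
    }, character(1), USE.NAMES = FALSE)
    decorated <- vapply(words, function(w) {
      if (stats::runif(1) < spec$modifier_rate) {
        if (stats::runif(1) < 0.5) paste(deg[sample.int(length(deg), 1L)], w)
        else paste0(w, punct[sample.int(length(punct), 1L)])
      } else w
    }, character(1), USE.NAMES = FALSE)
    n_fill <- stats::rpois(1L, 2L)
    if (n_fill > 0L)
      decorated <- sample(c(decorated,
                            sample(fillers, n_fill, replace = TRUE)))
    paste0(paste(decorated, collapse = " "), ".")
  }, character(1))

  offsets <- sort(stats::runif(n_tweets, 0, 14 * 86400))
  data.frame(
    user_id = user_id,
    timestamp = format(base_time + offsets, "%Y-%m-%dT%H:%M:%S"),
    text = texts, stringsAsFactors = FALSE)
}

#' Generate a labeled cohort and an unlabeled public corpus
#'
#' Condition users are drawn around their condition's target distribution
#' (multi-label supported via `targets` mixtures), controls around the
#' background distribution, and unlabeled corpus users around a
#' background/condition mixture so that the crowd's average distribution
#' carries condition signal for training. User ids are disjoint across
#' groups.
#'
#' @param lex An `msai_lexicon`.
#' @param spec A [generator_spec()].
#' @param targets Named list of target distributions; must contain
#'   `background` plus one entry per condition
#'   (default [synthetic_condition_targets()]).
#' @param conditions Condition labels to generate
#'   (default [mdad_conditions()]).
#' @param tables Modifier tables for decorations.
#' @param seed Integer seed.
#' @return List with `tweets` (labeled cohort tweets), `labels` (`user_id`,
#'   `conditions`), and `corpus` (unlabeled tweets).
#' @export
generate_cohort <- function(lex, spec = generator_spec(),
                            targets = synthetic_condition_targets(),
                            conditions = mdad_conditions(),
                            tables = default_modifier_tables(),
                            seed = 1L) {
  stopifnot("background" %in% names(targets),
            all(conditions %in% names(targets)))
  withr_seed(seed, {
    tweets <- list()
    labels <- list()
    uid <- 0L
    for (cond in conditions) {
      for (k in seq_len(spec$n_users_per_condition)) {
        uid <- uid + 1L
        id <- sprintf("u%04d", uid)
        tweets[[id]] <- generate_user(id, targets[[cond]], lex, spec, tables)
        labels[[id]] <- data.frame(user_id = id, conditions = cond,
                                   stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(spec$n_controls)) {
      uid <- uid + 1L
      id <- sprintf("u%04d", uid)
      tweets[[id]] <- generate_user(id, targets$background, lex, spec, tables)
      labels[[id]] <- data.frame(user_id = id, conditions = "",
                                 stringsAsFactors = FALSE)
    }
    corpus <- list()
    for (k in seq_len(spec$n_unlabeled)) {
      id <- sprintf("p%04d", k)
      tgt <- if (stats::runif(1) < spec$background_mix) {
        cond <- conditions[sample.int(length(conditions), 1L)]
        targets[[cond]]
      } else targets$background
      corpus[[id]] <- generate_user(id, tgt, lex, spec, tables)
    }
    list(tweets = do.call(rbind, c(tweets, list(make.row.names = FALSE))),
         labels = do.call(rbind, c(labels, list(make.row.names = FALSE))),
         corpus = do.call(rbind, c(corpus, list(make.row.names = FALSE))))
  })
}

#' Generate a synthetic screening-scale text for a condition
#'
#' Composes scale items ("I feel <word> ...") whose sentiment words are the
#' highest-intensity lexicon words of the categories carrying the
#' condition's target mass, approximately in proportion to that mass, so
#' the derived profile lands near the target distribution.
#'
#' @param condition Condition label (a name of `targets`).
#' @param lex An `msai_lexicon`.
#' @param targets Named list of target distributions.
#' @param n_items Number of scale items (default 10).
#' @param words_per_item Sentiment words per item (default 3).
#' @param seed Integer seed.
#' @return Character vector of scale items.
#' @export
generate_scale_text <- function(condition, lex,
                                targets = synthetic_condition_targets(),
                                n_items = 10L, words_per_item = 3L,
                                seed = 1L) {
  target <- as_affect(targets[[condition]])
  by_cat <- split(lex[, c("word", "intensity")], lex$category)
  withr_seed(seed, {
    vapply(seq_len(n_items), function(i) {
      cats <- sample(names(target), words_per_item, replace = TRUE,
                     prob = target)
      words <- vapply(cats, function(cat) {
        pool <- by_cat[[cat]]
        pool$word[which.max(pool$intensity)]
      }, character(1), USE.NAMES = FALSE)
      paste0("I feel ", paste(words, collapse = " and "), " every day.")
    }, character(1))
  })
}

#' Generate a synthetic sense-similarity table
#'
#' Pairs each of a sample of lexicon words with one new pseudo-word
#' synonym at a similarity drawn uniformly from `[0.5, 1]`, standing in for
#' a WordNet-style synonym resource in tests and simulations.
#'
#' @param lex An `msai_lexicon`.
#' @param n_pairs Number of synonym pairs (default 20).
#' @param seed Integer seed.
#' @return Data.frame with `word`, `synonym`, `similarity`.
#' @export
generate_synonym_table <- function(lex, n_pairs = 20L, seed = 1L) {
  withr_seed(seed, {
    seeds <- sample(unique(lex$word), min(n_pairs, length(unique(lex$word))))
    data.frame(word = seeds,
               synonym = paste0(seeds, "ish"),
               similarity = stats::runif(length(seeds), 0.5, 1),
               stringsAsFactors = FALSE)
  })
}

#' Dirichlet-perturb a condition profile
#'
#' Mixes a profile with the uniform distribution and draws a Dirichlet
#' sample around the mixture — the standard simplex-valued perturbation
#' used to initialize training-recovery experiments. Uses the current RNG
#' state.
#'
#' @param profile A `condition_profile`.
#' @param mix Weight of the original profile in the mixture (default 0.2;
#'   smaller = stronger perturbation).
#' @param concentration Dirichlet concentration around the mixture
#'   (default 10).
#' @return A perturbed `condition_profile` for the same condition.
#' @export
perturb_profile <- function(profile, mix = 0.2, concentration = 10) {
  stopifnot(mix >= 0, mix <= 1, concentration > 0)
  center <- mix * as_affect(unclass(profile)) + (1 - mix) / 11
  v <- rdirichlet_around(center, concentration)
  new_condition_profile(v / sum(v), attr(profile, "condition"))
}
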