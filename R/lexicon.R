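#' Read an 8-emotion affect-intensity lexicon from TSV
#'
#' Reads a 3-column tab-separated lexicon in the NRC-Hashtag-Emotion dialect
#' (no header; default column order category, word, intensity). Rows with the
#' wrong field count, an empty or whitespace-containing word, a non-numeric
#' intensity, or an unknown emotion are skipped with a warning; more than 10%
#' malformed rows is an error. Duplicate (word, category) rows keep the
#' maximum intensity.
#'
#' @param path Path to the TSV file.
#' @param dialect Character vector giving the column order; a permutation of
#'   `c("category", "word", "intensity")`.
#' @param categories Allowed category names (default the 8 source emotions).
#' @return An `emotion_lexicon`: a data.frame with columns `word`, `category`
#'   and `intensity`, attributes `n_rows` (rows read) and `n_skipped`.
#' @seealso [build_msai_lexicon()] to refine into 11 categories.
#' @export
read_emotion_lexicon <- function(path,
                                 dialect = c("category", "word", "intensity"),
                                 categories = nrc_categories()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  if (!setequal(dialect, c("category", "word", "intensity")))
    stop("dialect must be a permutation of category, word, intensity",
         call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty lexicon file: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f) {
    if (length(f) != 3L) return(NULL)
    names(f) <- dialect
    word <- tolower(trimws(f[["word"]]))
    category <- tolower(trimws(f[["category"]]))
    intensity <- suppressWarnings(as.numeric(f[["intensity"]]))
    if (!nzchar(word) || grepl("\\s", word)) return(NULL)
    if (is.na(intensity)) return(NULL)
    if (!category %in% categories) return(NULL)
    data.frame(word = word, category = category, intensity = intensity,
               stringsAsFactors = FALSE)
  }
  parsed <- lapply(fields, parse_row)
  bad <- vapply(parsed, is.null, logical(1))
  n_skipped <- sum(bad)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d malformed row(s) in %s", n_skipped, path),
            call. = FALSE)
  if (n_skipped > 0.1 * length(lines))
    stop(sprintf("%d of %d rows malformed (>10%%) in %s",
                 n_skipped, length(lines), path), call. = FALSE)
  entries <- do.call(rbind, parsed[!bad])
  entries <- dedupe_max(entries)
  structure(entries,
            class = c("emotion_lexicon", "data.frame"),
            categories = categories,
            n_rows = length(lines),
            n_skipped = n_skipped)
}

# keep the maximum intensity per (word, category)
dedupe_max <- function(entries) {
  key <- paste(entries$word, entries$category, sep = "\r")
  mx <- tapply(entries$intensity, key, max)
  first <- !duplicated(key)
  out <- entries[first, , drop = FALSE]
  out$intensity <- as.numeric(mx[paste(out$word, out$category, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' One-dimensional k-means clustering of word intensities
#'
#' Lloyd's algorithm on scalar intensities, with random center
#' initialization and seeded restarts; the partition minimizing the
#' within-cluster sum of squared distances to the center is returned. Used
#' with `k = 2` to find the boundary between the high- and low-arousal
#' halves of an emotion word set.
#'
#' @param points Numeric vector of intensities (non-empty).
#' @param k Number of clusters; must not exceed the number of distinct
#'   points.
#' @param seed Integer seed controlling initialization (restarts draw from
#'   the seeded stream).
#' @param max_iter Iteration cap per restart.
#' @param nstart Number of random restarts; the lowest-cost state wins.
#' @return A `cluster_state` list: `points`, `k`, `centers` (ascending),
#'   `assignments` (cluster index per point), `cost` (the within-cluster
#'   sum of squares), `iterations`.
#' @examples
#' st <- kmeans_1d(c(0.1, 0.2, 0.8, 0.9), k = 2, seed = 1)
#' st$centers  # 0.15, 0.85
#' @export
kmeans_1d <- function(points, k, seed = 1L, max_iter = 100L, nstart = 10L) {
  if (length(points) == 0L) stop("points must be non-empty", call. = FALSE)
  if (!is.numeric(points) || anyNA(points))
    stop("points must be numeric without NA", call. = FALSE)
  n_distinct <- length(unique(points))
  if (k > n_distinct)
    stop(sprintf("k = %d exceeds the %d distinct point(s)", k, n_distinct),
         call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)

  run_once <- function() {
    centers <- sample(unique(points), k)
    assign_old <- rep(0L, length(points))
    it <- 0L
    repeat {
      it <- it + 1L
      d <- abs(outer(points, centers, "-"))
      assignment <- max.col(-d, ties.method = "first")
      for (j in seq_len(k)) {
        if (any(assignment == j))
          centers[j] <- mean(points[assignment == j])
      }
      if (identical(assignment, assign_old) || it >= max_iter) break
      assign_old <- assignment
    }
    cost <- sum((points - centers[assignment])^2)
    list(centers = centers, assignment = assignment, cost = cost,
         iterations = it)
  }

  best <- withr_seed(seed, {
    res <- run_once()
    for (r in seq_len(max(0L, nstart - 1L))) {
      cand <- run_once()
      if (cand$cost < res$cost - 1e-12) res <- cand
    }
    res
  })

  ord <- order(best$centers)
  relabel <- match(seq_along(ord), ord)
  structure(
    list(points = points, k = k,
         centers = best$centers[ord],
         assignments = relabel[best$assignment],
         cost = best$cost, iterations = best$iterations),
    class = "cluster_state")
}

# evaluate expr under a local RNG seed, restoring global RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Split one emotion category into a strong and a mild sub-category
#'
#' Clusters the category's intensities into two groups with [kmeans_1d()];
#' the cluster with the larger center takes `strong_label` (the
#' higher-arousal variant on the Plutchik wheel), the other `mild_label`.
#' Every word of the category lands in exactly one sub-category.
#'
#' @param lex An `emotion_lexicon`.
#' @param category Category to split (must have >= 2 distinct intensities).
#' @param strong_label,mild_label Names of the resulting sub-categories.
#' @param seed Integer seed passed to [kmeans_1d()].
#' @return Data.frame of entries with `category` relabeled to the
#'   sub-category names.
#' @export
split_emotion <- function(lex, category, strong_label, mild_label, seed = 1L) {
  sub <- lex[lex$category == category, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("category not present: ", category, call. = FALSE)
  if (length(unique(sub$intensity)) < 2L)
    stop("category '", category,
         "' has fewer than 2 distinct intensities; cannot split",
         call. = FALSE)
  st <- kmeans_1d(sub$intensity, k = 2L, seed = seed)
  # centers are sorted ascending: cluster 2 is the larger-center cluster
  sub$category <- ifelse(st$assignments == 2L, strong_label, mild_label)
  rownames(sub) <- NULL
  sub
}

#' Build the 11-category multipolarity affect-intensity lexicon
#'
#' Refines an 8-emotion lexicon into 11 sentiment categories: disgust,
#' sadness and fear — the negative emotions most expressed by users with
#' mental disorders — are each split by 1-d 2-means clustering into a
#' high-arousal (loathing, grief, terror) and a low-arousal (disgust,
#' sadness, fear) sub-category; anger, surprise, trust, joy and anticipation
#' pass through unchanged. The mapping preserves the total entry count.
#'
#' @param lex An `emotion_lexicon` from [read_emotion_lexicon()].
#' @param seed Integer seed for the clustering.
#' @param normalize If `TRUE` (default), apply [normalize_lexicon()] after
#'   the split.
#' @return An `msai_lexicon`: data.frame with columns `word`, `category`,
#'   `intensity` over the 11 categories of [msai_categories()].
#' @export
build_msai_lexicon <- function(lex, seed = 1L, normalize = TRUE) {
  splits <- list(
    disgust = c(strong = "loathing", mild = "disgust"),
    sadness = c(strong = "grief",    mild = "sadness"),
    fear    = c(strong = "terror",   mild = "fear")
  )
  parts <- list()
  for (cat in unique(lex$category)) {
    if (cat %in% names(splits)) {
      lab <- splits[[cat]]
      parts[[cat]] <- split_emotion(lex, cat, lab[["strong"]], lab[["mild"]],
                                    seed = seed)
    } else {
      parts[[cat]] <- as.data.frame(lex[lex$category == cat, , drop = FALSE])
    }
  }
  entries <- do.call(rbind, parts)
  rownames(entries) <- NULL
  out <- new_msai(entries)
  if (normalize) out <- normalize_lexicon(out)
  out
}

#' Construct an 11-category lexicon from a data.frame
#'
#' Validates categories against [msai_categories()], resolves duplicate
#' (word, category) pairs by maximum intensity, and orders entries
#' canonically. Useful for hand-built or externally derived lexicons.
#'
#' @param entries Data.frame with columns `word`, `category`, `intensity`.
#' @return An `msai_lexicon`.
#' @export
as_msai_lexicon <- function(entries) {
  entries <- as.data.frame(entries)[, c("word", "category", "intensity")]
  entries$word <- tolower(entries$word)
  new_msai(dedupe_max(entries))
}

new_msai <- function(entries) {
  cats <- msai_categories()
  bad <- setdiff(unique(entries$category), cats)
  if (length(bad) > 0L)
    stop("unknown sentiment categor(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ord <- order(match(entries$category, cats), entries$word)
  entries <- data.frame(word = entries$word[ord],
                        category = entries$category[ord],
                        intensity = entries$intensity[ord],
                        stringsAsFactors = FALSE)
  structure(entries, class = c("msai_lexicon", "data.frame"),
            category_order = cats)
}

#' Expand a lexicon with synonyms above a sense-similarity threshold
#'
#' Each synonym whose sense similarity to a seed word is strictly greater
#' than `threshold` is added with the seed word's category and intensity.
#' A synonym colliding with an existing entry of the same category keeps the
#' larger intensity; entries are never removed and intensities never lowered.
#'
#' @param lex An `msai_lexicon`.
#' @param synonyms Data.frame with columns `word` (seed), `synonym`
#'   (candidate token) and `similarity` in `[0, 1]`, e.g. derived from a
#'   WordNet-style sense-similarity resource, or `NULL` (returns `lex`
#'   unchanged with a warning).
#' @param threshold Strict lower bound on similarity (default 0.7).
#' @return The expanded `msai_lexicon` (at least as many entries as `lex`).
#' @export
expand_synonyms <- function(lex, synonyms, threshold = 0.7) {
  if (is.null(synonyms) || nrow(as.data.frame(synonyms)) == 0L) {
    if (is.null(synonyms))
      warning("no synonym source available; lexicon returned unchanged",
              call. = FALSE)
    return(lex)
  }
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  syn <- as.data.frame(synonyms)
  stopifnot(all(c("word", "synonym", "similarity") %in% names(syn)))
  syn <- syn[syn$similarity > threshold, , drop = FALSE]
  if (nrow(syn) == 0L) return(lex)

  seed_entries <- merge(as.data.frame(lex), syn[, c("word", "synonym")],
                        by = "word")
  if (nrow(seed_entries) == 0L) return(lex)
  added <- data.frame(word = tolower(seed_entries$synonym),
                      category = seed_entries$category,
                      intensity = seed_entries$intensity,
                      stringsAsFactors = FALSE)
  out <- dedupe_max(rbind(as.data.frame(lex), added))
  new_msai(out)
}

#' Min-max normalize lexicon intensities per category
#'
#' Rescales each sentiment category's intensities to `[0, 1]` by min-max
#' scaling, preserving within-category ranking. A category whose intensities
#' are all equal maps to 1.0 (the words carry the category's full, if
#' undifferentiated, intensity). Idempotent on categories already spanning
#' `[0, 1]`.
#'
#' @param lex An `msai_lexicon`.
#' @return The normalized `msai_lexicon`.
#' @export
normalize_lexicon <- function(lex) {
  entries <- as.data.frame(lex)
  for (cat in unique(entries$category)) {
    i <- entries$category == cat
    x <- entries$intensity[i]
    rng <- range(x)
    entries$intensity[i] <-
      if (diff(rng) == 0) 1.0 else (x - rng[1]) / diff(rng)
  }
  new_msai(entries)
}

#' Save / load an 11-category lexicon as TSV
#'
#' Writes (and reads back, losslessly) a 3-column tab-separated file in
#' column order category, word, intensity, full precision, no header.
#'
#' @param lex An `msai_lexicon` (non-empty).
#' @param path File path.
#' @return `write_msai_lexicon()` returns `path` invisibly;
#'   `read_msai_lexicon()` returns the `msai_lexicon`.
#' @export
write_msai_lexicon <- function(lex, path) {
  entries <- as.data.frame(lex)
  if (nrow(entries) == 0L) stop("refusing to save an empty lexicon",
                                call. = FALSE)
  lines <- paste(entries$category, entries$word,
                 formatC(entries$intensity, digits = 17, format = "g"),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_msai_lexicon
#' @export
read_msai_lexicon <- function(path) {
  raw <- read_emotion_lexicon(path, categories = msai_categories())
  new_msai(as.data.frame(raw))
}
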