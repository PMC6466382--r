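test_that("TSV reader parses, deduplicates by max, and skips malformed rows", {
  rows <- rbind(
    c("sadness", "sad", "0.3"),
    c("sadness", "sad", "0.5"),
    c("joy", "happy", "0.8"))
  lex <- read_emotion_lexicon(write_lexicon_tsv(rows))
  expect_equal(nrow(lex), 2L)
  expect_equal(lex$intensity[lex$word == "sad"], 0.5)

  # 24 rows, 2 malformed (bad numeric, wrong field count) -> 22 entries
  ok <- cbind(rep(nrc_categories(), length.out = 22),
              sprintf("word%02d", 1:22),
              sprintf("%.2f", seq(0.1, 0.9, length.out = 22)))
  path <- write_lexicon_tsv(ok, extra_lines = c("sadness\tbroken\tnot_a_number",
                                                "joy\tonly_two_fields"))
  expect_warning(lex24 <- read_emotion_lexicon(path), "skipped 2")
  expect_equal(nrow(lex24), 22L)
  expect_equal(attr(lex24, "n_skipped"), 2L)

  # >10% malformed is an error
  bad <- write_lexicon_tsv(rows[1:2, , drop = FALSE],
                           extra_lines = "nope\tnope\tnope")
  expect_error(suppressWarnings(read_emotion_lexicon(bad)), ">10%")
  expect_error(read_emotion_lexicon(tempfile()), "not found")
})

test_that("1-d k-means matches trivial cases and is deterministic", {
  st <- kmeans_1d(c(0.1, 0.9), k = 2, seed = 1)
  expect_equal(sort(st$centers), c(0.1, 0.9))
  expect_equal(st$cost, 0)

  st <- kmeans_1d(c(0.1, 0.2, 0.8, 0.9), k = 2, seed = 7)
  expect_equal(st$centers, c(0.15, 0.85))
  expect_equal(st$assignments, c(1L, 1L, 2L, 2L))

  st2 <- kmeans_1d(c(0.1, 0.2, 0.8, 0.9), k = 2, seed = 7)
  expect_identical(st, st2)

  expect_error(kmeans_1d(numeric(0), 2), "non-empty")
  expect_error(kmeans_1d(c(0.5, 0.5), 2), "distinct")
})

test_that("k-means cost matches the exhaustive 2-partition oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    pts <- round(runif(n), 3)
    if (length(unique(pts)) < 2) next
    st <- kmeans_1d(pts, k = 2, seed = i, nstart = 20)
    expect_equal(st$cost, brute_force_2means_cost(pts), tolerance = 1e-10)
    # cost definition: sum of squared distances to assigned centers
    expect_equal(st$cost, sum((pts - st$centers[st$assignments])^2))
  }
})

test_that("splitting an emotion assigns the larger-center cluster the strong label", {
  lex <- structure(
    data.frame(word = c("a", "b", "c"), category = "fear",
               intensity = c(0.2, 0.25, 0.8), stringsAsFactors = FALSE),
    class = c("emotion_lexicon", "data.frame"))
  out <- split_emotion(lex, "fear", "terror", "fear", seed = 1)
  expect_setequal(out$word[out$category == "terror"], "c")
  expect_setequal(out$word[out$category == "fear"], c("a", "b"))
  # partition property and determinism
  expect_setequal(out$word, lex$word)
  expect_identical(out, split_emotion(lex, "fear", "terror", "fear", seed = 1))
  lex$intensity <- rep(0.5, 3)
  expect_error(split_emotion(lex, "fear", "terror", "fear"), "distinct")
})

test_that("8-to-11 refinement preserves entry count and splits only the three negatives", {
  fx <- make_fixture_lexicon(generator_spec(n_words_per_category = 4L),
                             seed = 3)
  expect_equal(nrow(fx$msai), nrow(fx$source))
  expect_setequal(unique(fx$msai$category), msai_categories())
  # pass-through categories keep their words
  for (cat in c("anger", "surprise", "trust", "joy", "anticipation")) {
    expect_setequal(fx$msai$word[fx$msai$category == cat],
                    fx$source$word[fx$source$category == cat])
  }
  # split categories partition their source word sets
  expect_setequal(fx$msai$word[fx$msai$category %in% c("terror", "fear")],
                  fx$source$word[fx$source$category == "fear"])
})

test_that("synonym expansion is strict, inheriting, and never lowers intensities", {
  lex <- as_msai_lexicon(data.frame(
    word = c("sad", "blue"), category = c("sadness", "sadness"),
    intensity = c(0.6, 0.9)))
  syn <- data.frame(word = c("sad", "sad", "sad"),
                    synonym = c("unhappy", "down", "blue"),
                    similarity = c(0.8, 0.7, 0.9))
  out <- expand_synonyms(lex, syn, threshold = 0.7)
  # strictly greater than the threshold: 0.7 is excluded
  expect_false("down" %in% out$word)
  expect_equal(out$intensity[out$word == "unhappy"], 0.6)
  # collision keeps the larger existing intensity
  expect_equal(out$intensity[out$word == "blue"], 0.9)
  expect_gte(nrow(out), nrow(lex))

  expect_identical(expand_synonyms(lex, syn[0, ]), lex)
  expect_warning(unchanged <- expand_synonyms(lex, NULL), "unchanged")
  expect_identical(unchanged, lex)
})

test_that("per-category min-max normalization hits [0,1] and is idempotent", {
  lex <- as_msai_lexicon(data.frame(
    word = c("a", "b", "c", "d", "e", "f", "g"),
    category = c(rep("sadness", 3), rep("joy", 2), rep("fear", 2)),
    intensity = c(1, 3, 5, 0, 1, 2, 2)))
  out <- normalize_lexicon(lex)
  expect_equal(sort(out$intensity[out$category == "sadness"]),
               c(0, 0.5, 1))
  expect_equal(sort(out$intensity[out$category == "joy"]), c(0, 1))
  # constant category maps to 1
  expect_equal(out$intensity[out$category == "fear"], c(1, 1))
  expect_true(all(out$intensity >= 0 & out$intensity <= 1))
  # idempotence
  expect_equal(as.data.frame(normalize_lexicon(out)), as.data.frame(out))
})

test_that("lexicon TSV round-trip is lossless", {
  fx <- make_fixture_lexicon(generator_spec(n_words_per_category = 3L),
                             seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_msai_lexicon(fx$msai, path)
  back <- read_msai_lexicon(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$msai))

  empty <- fx$msai[0, , drop = FALSE]
  expect_error(write_msai_lexicon(empty, tempfile()), "empty")
  # unknown category on load
  bad <- write_lexicon_tsv(rbind(c("elation", "x", "0.5")))
  expect_error(suppressWarnings(read_msai_lexicon(bad)))
})
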