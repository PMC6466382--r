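# Shared fixtures, built in code.

# tiny hand lexicon with known intensities
tiny_lexicon <- function() {
  as_msai_lexicon(data.frame(
    word = c("sad", "gloomy", "happy", "cheerful", "scared", "furious",
             "shocked", "loyal"),
    category = c("sadness", "sadness", "joy", "joy", "fear", "anger",
                 "surprise", "trust"),
    intensity = c(0.6, 0.4, 0.8, 0.5, 0.7, 0.9, 0.3, 0.5)
  ))
}

# exhaustive 2-means oracle: minimal within-cluster sum of squares over all
# binary assignments with both clusters non-empty
brute_force_2means_cost <- function(points) {
  n <- length(points)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    a <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    c1 <- points[a]
    c2 <- points[!a]
    cost <- sum((c1 - mean(c1))^2) + sum((c2 - mean(c2))^2)
    if (cost < best) best <- cost
  }
  best
}

# write a TSV lexicon file (category, word, intensity rows + raw lines)
write_lexicon_tsv <- function(rows, extra_lines = character(0)) {
  path <- tempfile(fileext = ".tsv")
  lines <- c(apply(rows, 1, paste, collapse = "\t"), extra_lines)
  writeLines(lines, path)
  path
}

# small scored-word context for scoring tests
ctx <- function(category, intensity, degree = numeric(0), negated = FALSE,
                after_adversative = FALSE, emoticon = 0, punct = 0) {
  structure(list(word = "w", category = category, intensity = intensity,
                 degree_weights = degree, negated = negated,
                 after_adversative = after_adversative,
                 emoticon_weight = emoticon, punct_weight = punct),
            class = "word_context")
}

affect <- function(...) {
  v <- stats::setNames(numeric(11), msai_categories())
  args <- c(...)
  v[names(args)] <- args
  v
}
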