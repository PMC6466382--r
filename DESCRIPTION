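Package: mdad
Title: Mental-Disorder-Aided Diagnosis from Short-Text Sentiment Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lexicon-based multipolarity sentiment analysis for digital
    mental-health screening. Builds an 11-category affect-intensity lexicon
    from an 8-emotion source lexicon by one-dimensional k-means splitting of
    the negative emotions, scores short social-media texts into
    11-dimensional sentiment distributions using degree-adverb, negation,
    adversative, emoticon and sentiment-punctuation weights, estimates the
    probability of five mental-disorder conditions by cosine similarity to
    condition prototype vectors, classifies users into severe/moderate/no-risk
    levels, and refines the prototypes by a stochastic accept-reject
    error-feedback training loop. A synthetic-data module generates lexicons,
    modifier tables, scale texts and labeled cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
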