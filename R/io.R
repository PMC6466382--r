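#' Read and write tweet records as JSON Lines
#'
#' One JSON object per line with fields `user_id`, `timestamp` (ISO-8601)
#' and `text`. Lines that fail to parse or lack `user_id`/`text` are
#' skipped with a warning.
#'
#' @param path File path.
#' @param tweets Data.frame with columns `user_id`, `timestamp`, `text`.
#' @return `read_tweets()` returns the tweet data.frame; `write_tweets()`
#'   returns `path` invisibly.
#' @export
read_tweets <- function(path) {
  if (!file.exists(path)) stop("tweet file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(obj) || is.null(obj$user_id) || is.null(obj$text))
      return(NULL)
    data.frame(user_id = as.character(obj$user_id),
               timestamp = if (is.null(obj$timestamp)) NA_character_
                           else as.character(obj$timestamp),
               text = as.character(obj$text), stringsAsFactors = FALSE)
  })
  bad <- vapply(recs, is.null, logical(1))
  if (any(bad))
    warning(sprintf("skipped %d malformed JSONL line(s) in %s",
                    sum(bad), path), call. = FALSE)
  out <- do.call(rbind, recs[!bad])
  if (is.null(out)) stop("no valid tweet records in ", path, call. = FALSE)
  out
}

#' @rdname read_tweets
#' @export
write_tweets <- function(tweets, path) {
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    jsonlite::toJSON(list(user_id = tweets$user_id[i],
                          timestamp = tweets$timestamp[i],
                          text = tweets$text[i]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write condition profiles as CSV
#'
#' One row per condition: a `condition` column followed by the 11 named
#' sentiment columns in canonical order.
#'
#' @param profiles List of `condition_profile` objects.
#' @param path File path.
#' @return `read_profiles()` returns a list of `condition_profile` objects;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(data.frame(condition = attr(p, "condition"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(as_affect(unclass(p)))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("condition", msai_categories()), names(tab))
  if (length(missing) > 0L)
    stop("profile file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, msai_categories()])
    names(v) <- msai_categories()
    new_condition_profile(v / sum(v), tab$condition[i])
  })
}

#' Read and write cohort labels as CSV
#'
#' Columns `user_id` and `conditions` (semicolon-separated condition
#' labels; empty string for users with no disorder).
#'
#' @param labels Label data.frame.
#' @param path File path.
#' @return `read_labels()` returns the label data.frame; `write_labels()`
#'   returns `path` invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[, c("user_id", "conditions")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character"))
  stopifnot(all(c("user_id", "conditions") %in% names(tab)))
  tab$conditions[is.na(tab$conditions)] <- ""
  tab
}

#' Write a run manifest alongside an output artifact
#'
#' Records the inputs, seed and package version that produced an output
#' file, for reproducibility audits.
#'
#' @param path Output artifact path; the manifest lands at
#'   `<path>.manifest.json`.
#' @param inputs Named list of input paths/parameters.
#' @param seed Integer seed used by the run.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(path, inputs, seed) {
  manifest <- list(
    output = path,
    inputs = inputs,
    seed = seed,
    package = "mdad",
    version = as.character(utils::packageVersion("mdad")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- paste0(path, ".manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             mpath, useBytes = TRUE)
  invisible(mpath)
}
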