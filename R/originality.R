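#' Normalize text for similarity comparison
#'
#' Lowercases, removes URLs, strips punctuation to spaces, and collapses
#' whitespace. Tokens are the remaining whitespace-separated unigrams.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("(https?://|www\\.)\\S+", " ", x)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

.tokens <- function(x) {
  x <- normalize_text(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

#' Cosine similarity of two texts
#'
#' Cosine of the unigram term-frequency vectors of the two normalized
#' texts (no IDF weighting): 1 for identical token multisets, 0 for
#' disjoint vocabularies. A text that is empty after normalization has
#' no direction in term space; the similarity is then reported as 0 with
#' a warning.
#'
#' @param a,b character strings.
#' @return similarity in `[0, 1]`.
#' @examples
#' text_similarity("a b a", "a b")  # 3 / sqrt(10)
#' @export
text_similarity <- function(a, b) {
  ta <- .tokens(a); tb <- .tokens(b)
  if (length(ta) == 0 || length(tb) == 0) {
    warning("text empty after normalization; similarity undefined, using 0")
    return(0)
  }
  vocab <- union(ta, tb)
  fa <- tabulate(match(ta, vocab), nbins = length(vocab))
  fb <- tabulate(match(tb, vocab), nbins = length(vocab))
  sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
}

#' Retrieve candidate source documents from a local corpus
#'
#' Stand-in for web retrieval: ranks corpus documents by shared-token
#' count with the post text and returns those with any overlap (at most
#' `max_candidates`). Deterministic, so classification results are
#' reproducible, unlike a live search engine.
#'
#' @param text the post text.
#' @param corpus data.frame with `doc_id`, `site_name`, `url`, `text`.
#' @param max_candidates cap on returned documents.
#' @return subset of `corpus` rows, best-overlapping first.
#' @export
retrieve_candidates <- function(text, corpus, max_candidates = 20) {
  tp <- unique(.tokens(text))
  if (length(tp) == 0 || nrow(corpus) == 0) return(corpus[0, , drop = FALSE])
  overlap <- vapply(corpus$text,
                    function(d) length(intersect(tp, .tokens(d))),
                    numeric(1), USE.NAMES = FALSE)
  keep <- which(overlap > 0)
  keep <- keep[order(-overlap[keep])]
  corpus[utils::head(keep, max_candidates), , drop = FALSE]
}

#' Classify one post's originality against candidate sources
#'
#' Takes the best cosine similarity over the candidates. Above the high
#' threshold the post is non-original; inside the band between the two
#' thresholds (both boundaries included) it is "potentially
#' non-original" when the source's url or site name contains "lyrics" or
#' "quote" (case-insensitive), otherwise original; below the band it is
#' original. The binary label maps potential to non-original by default.
#' With no candidates the post is original with similarity 0 and a
#' `no_candidates` flag.
#'
#' @param text post text.
#' @param candidates data.frame of source documents (possibly 0 rows).
#' @param hi,lo similarity thresholds (defaults 0.96 and 0.92).
#' @param potential_as_nonoriginal count band matches as non-original in
#'   the binary label.
#' @return one-row data.frame: `best_similarity`, `best_source`,
#'   `raw_label` in original/potential/non_original, `binary_label` in
#'   O/N, `no_candidates`.
#' @export
classify_post <- function(text, candidates, hi = 0.96, lo = 0.92,
                          potential_as_nonoriginal = TRUE) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(data.frame(best_similarity = 0, best_source = NA_character_,
                      raw_label = "original", binary_label = "O",
                      no_candidates = TRUE, stringsAsFactors = FALSE))
  }
  sims <- vapply(candidates$text,
                 function(d) suppressWarnings(text_similarity(text, d)),
                 numeric(1), USE.NAMES = FALSE)
  best <- which.max(sims)
  s <- sims[best]
  src <- candidates[best, , drop = FALSE]
  keyword <- grepl("lyrics|quote", paste(src$url, src$site_name),
                   ignore.case = TRUE)
  raw <- if (s > hi) {
    "non_original"
  } else if (s >= lo && s <= hi && keyword) {
    "potential"
  } else {
    "original"
  }
  bin <- switch(raw,
                non_original = "N",
                potential = if (potential_as_nonoriginal) "N" else "O",
                original = "O")
  data.frame(best_similarity = s, best_source = src$doc_id,
             raw_label = raw, binary_label = bin, no_candidates = FALSE,
             stringsAsFactors = FALSE)
}

#' Classify every post in a table
#'
#' Runs [retrieve_candidates()] + [classify_post()] over a posts table.
#'
#' @param posts data.frame with a `text` column (and optionally
#'   `post_id`; row numbers are used otherwise).
#' @param corpus candidate source corpus.
#' @inheritParams classify_post
#' @param retriever function `(text, corpus) -> candidates`; defaults to
#'   [retrieve_candidates()].
#' @return data.frame: `post_id` plus the [classify_post()] columns.
#' @export
classify_posts <- function(posts, corpus, hi = 0.96, lo = 0.92,
                           potential_as_nonoriginal = TRUE,
                           retriever = retrieve_candidates) {
  ids <- if ("post_id" %in% names(posts)) as.character(posts$post_id)
         else as.character(seq_len(nrow(posts)))
  res <- lapply(seq_len(nrow(posts)), function(i) {
    cand <- retriever(posts$text[i], corpus)
    classify_post(posts$text[i], cand, hi = hi, lo = lo,
                  potential_as_nonoriginal = potential_as_nonoriginal)
  })
  out <- do.call(rbind, res)
  cbind(post_id = ids, out, stringsAsFactors = FALSE)
}

#' Precision, recall and F1 of binary originality predictions
#'
#' @param predicted,gold equal-length label vectors.
#' @param positive the positive class (default `"N"`, non-original).
#' @return list with `precision`, `recall`, `f1` (0 when undefined).
#' @examples
#' evaluate_classifier(c("N", "N", "O"), c("N", "O", "O"))
#' @export
evaluate_classifier <- function(predicted, gold, positive = "N") {
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must have the same length")
  }
  tp <- sum(predicted == positive & gold == positive)
  fp <- sum(predicted == positive & gold != positive)
  fn <- sum(predicted != positive & gold == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Originality sequence and transitions for one user's window
#'
#' Post-level with-silence stream over the `O`/`N`/`S` alphabet: every
#' post's binary originality label in chronological order, one `"S"`
#' token per silent calendar day. Only the post-level representation is
#' meaningful for originality (a day does not have a single dominant
#' originality).
#'
#' @param posts data.frame with `day` and `originality` (O/N) columns,
#'   chronologically sorted; an optional `post_id` column names posts in
#'   error messages.
#' @param window_start,window_end the window.
#' @param user_id carried through.
#' @return list with `sequence` (class `affect_sequence` over O/N/S) and
#'   `profile` (class `transition_profile`, 6 pair types).
#' @export
originality_sequence <- function(posts, window_start, window_end,
                                 user_id = NULL) {
  lab <- posts$originality
  bad <- is.na(lab) | !(lab %in% c("O", "N"))
  if (any(bad)) {
    ids <- if ("post_id" %in% names(posts)) posts$post_id[bad]
           else which(bad)
    stop("unlabeled or invalid originality for post(s): ",
         paste(ids, collapse = ", "))
  }
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  days <- as.Date(posts$day)
  if (is.unsorted(days)) stop("posts must be sorted chronologically")
  if (is.null(user_id)) {
    user_id <- if (nrow(posts)) posts$user_id[1] else NA_character_
  }
  all_days <- seq(window_start, window_end, by = "day")
  day_syms <- split(lab, factor(as.character(days),
                                levels = as.character(all_days)))
  symbols <- character(0); day_index <- integer(0)
  for (i in seq_along(all_days)) {
    s <- day_syms[[i]]
    if (length(s) == 0) s <- "S"
    symbols <- c(symbols, s)
    day_index <- c(day_index, rep.int(i, length(s)))
  }
  sq <- structure(list(user_id = user_id,
                       representation = "post_with_silence",
                       symbols = unname(symbols),
                       day_index = unname(day_index)),
                  class = "affect_sequence")
  list(sequence = sq, profile = count_transitions(sq$symbols, .orig_symbols))
}

#' Per-user originality features for a cohort
#'
#' Requires an `originality` (O/N) column on the cohort's posts (from
#' gold labels or [classify_posts()]). Returns the 6 pair-type
#' proportions of the with-silence originality stream plus the user's
#' share of non-original posts.
#'
#' @param cohort an `affect_cohort` whose posts carry `originality`.
#' @return data.frame: `user_id`, 6 pair proportions, `total`,
#'   `n_share`; pooled counts in attribute `n_occ`.
#' @export
originality_features <- function(cohort) {
  if (!"originality" %in% names(cohort$posts)) {
    stop("cohort posts carry no 'originality' column; ",
         "label them first (gold labels or classify_posts)")
  }
  keys <- transition_pairs(.orig_symbols)
  pooled <- stats::setNames(numeric(length(keys)), keys)
  rows <- list()
  for (i in seq_len(nrow(cohort$users))) {
    uid <- cohort$users$user_id[i]
    p <- .user_posts(cohort, uid)
    w <- cohort$windows[cohort$windows$user_id == uid, ]
    os <- originality_sequence(p, w$window_start, w$window_end, user_id = uid)
    if (os$profile$total < 1) next
    pooled <- pooled + os$profile$counts
    n_share <- if (nrow(p)) mean(p$originality == "N") else 0
    rows[[uid]] <- c(os$profile$proportions, total = os$profile$total,
                     n_share = n_share)
  }
  feat <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  feat <- cbind(user_id = names(rows), feat, stringsAsFactors = FALSE)
  rownames(feat) <- NULL
  attr(feat, "n_occ") <- pooled
  attr(feat, "representation") <- "post_with_silence"
  feat
}
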