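#' Dominant affect of one calendar day
#'
#' Aggregates the affect symbols of a day's posts to a single day-level
#' symbol. A day with no posts is silence (`"S"`). Otherwise the special
#' mixed rules are checked first: an equal positive and negative count
#' (both nonzero), or a mixed-post count equal to the total count of all
#' non-mixed posts, gives `"m"`. Failing those, the strict plurality
#' symbol wins; residual plurality ties resolve by the fixed precedence
#' mixed > negative > positive > neutral.
#'
#' @param symbols character vector of post affect symbols for one day
#'   (may be empty).
#' @param plurality_first if `TRUE`, strict plurality is evaluated before
#'   the two mixed rules (the rules then only break plurality ties).
#' @return one symbol in `+ - m 0 S`.
#' @examples
#' day_affect(c("+", "-", "+"))  # "+"
#' day_affect(c("+", "-"))       # "m": equal positive and negative
#' day_affect(character(0))      # "S": silent day
#' @export
day_affect <- function(symbols, plurality_first = FALSE) {
  if (length(symbols) == 0) return("S")
  .check_symbols(symbols, .affect_symbols, "affect symbol")
  counts <- table(factor(symbols, levels = .affect_symbols))
  np <- counts[["+"]]; nn <- counts[["-"]]
  nm <- counts[["m"]]; nz <- counts[["0"]]

  mixed_rule <- (np == nn && np > 0) || (nm == np + nn + nz)

  plurality <- function() {
    mx <- max(counts)
    top <- names(counts)[counts == mx]
    if (length(top) == 1) return(top)
    # precedence for unresolved ties: m > - > + > 0
    for (s in c("m", "-", "+", "0")) if (s %in% top) return(s)
  }

  if (plurality_first) {
    mx <- max(counts)
    top <- names(counts)[counts == mx]
    if (length(top) == 1) return(top[[1]])
    if (mixed_rule) return("m")
    return(plurality())
  }
  if (mixed_rule) return("m")
  plurality()
}

#' Build an affect sequence for one user's window
#'
#' Three representations of the same posting history:
#' `post_with_silence` keeps every post symbol in chronological order and
#' inserts exactly one `"S"` token at the position of each calendar day
#' without posts; `post_without_silence` keeps only the post symbols;
#' `day_level` aggregates each of the window's days to one symbol via
#' [day_affect()] (so its length always equals the window length).
#'
#' @param posts data.frame with at least `affect` and `day` columns,
#'   chronologically sorted, all days inside the window.
#' @param window_start,window_end first and last day of the window.
#' @param representation one of `"post_with_silence"`,
#'   `"post_without_silence"`, `"day_level"`.
#' @param user_id carried through to the result.
#' @param plurality_first passed to [day_affect()].
#' @return An object of class `affect_sequence`: list with `user_id`,
#'   `representation`, `symbols`, and `day_index` (1-based window day of
#'   each symbol, non-decreasing).
#' @export
build_sequence <- function(posts, window_start, window_end,
                           representation = c("post_with_silence",
                                              "post_without_silence",
                                              "day_level"),
                           user_id = NULL, plurality_first = FALSE) {
  representation <- match.arg(representation)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  days <- as.Date(posts$day)
  if (is.unsorted(days)) stop("posts must be sorted chronologically")
  if (length(days) && (min(days) < window_start || max(days) > window_end)) {
    stop("posts outside the window")
  }
  .check_symbols(posts$affect, .affect_symbols, "affect symbol")
  if (is.null(user_id)) {
    user_id <- if (nrow(posts)) posts$user_id[1] else NA_character_
  }

  all_days <- seq(window_start, window_end, by = "day")
  day_syms <- split(posts$affect, factor(as.character(days),
                                         levels = as.character(all_days)))

  if (representation == "day_level") {
    symbols <- vapply(day_syms, day_affect, character(1),
                      plurality_first = plurality_first)
    day_index <- seq_along(all_days)
  } else if (representation == "post_without_silence") {
    symbols <- posts$affect
    day_index <- match(as.character(days), as.character(all_days))
  } else {
    symbols <- character(0); day_index <- integer(0)
    for (i in seq_along(all_days)) {
      s <- day_syms[[i]]
      if (length(s) == 0) s <- "S"
      symbols <- c(symbols, s)
      day_index <- c(day_index, rep.int(i, length(s)))
    }
  }
  structure(list(user_id = user_id, representation = representation,
                 symbols = unname(symbols), day_index = unname(day_index)),
            class = "affect_sequence")
}

#' @export
print.affect_sequence <- function(x, ...) {
  cat("Affect sequence (", x$representation, ") for user ", x$user_id,
      ": ", length(x$symbols), " symbols\n", sep = "")
  cat(paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

#' Count bidirectional transitions in a sequence
#'
#' Every adjacent ordered pair of symbols increments its unordered
#' (bidirectional) pair type, so a sequence of length L contributes
#' exactly L - 1 transitions. For the 5-symbol affect alphabet there are
#' 15 types; for the 3-symbol originality alphabet 6.
#'
#' @param seq an `affect_sequence`, or a bare character vector of
#'   symbols.
#' @param alphabet symbol alphabet (defaults to the affect alphabet; use
#'   `c("O","N","S")` for originality streams).
#' @return Object of class `transition_profile`: list with `user_id`,
#'   `representation`, `counts` (named integer vector over all pair
#'   types), `total`, and `proportions` (counts/total; all zero when
#'   total is 0).
#' @examples
#' count_transitions(c("+", "-", "+", "+"))
#' @export
count_transitions <- function(seq, alphabet = .seq_symbols) {
  if (inherits(seq, "affect_sequence")) {
    symbols <- seq$symbols
    user_id <- seq$user_id
    representation <- seq$representation
  } else {
    symbols <- seq
    user_id <- NA_character_
    representation <- NA_character_
  }
  .check_symbols(symbols, alphabet, "symbol")
  keys <- transition_pairs(alphabet)
  counts <- stats::setNames(integer(length(keys)), keys)
  n <- length(symbols)
  if (n >= 2) {
    k <- pair_key(symbols[-n], symbols[-1], alphabet)
    tab <- table(k)
    counts[names(tab)] <- as.integer(tab)
  }
  total <- max(n - 1, 0)
  props <- if (total > 0) counts / total else counts * 0
  structure(list(user_id = user_id, representation = representation,
                 counts = counts, total = total, proportions = props),
            class = "transition_profile")
}

#' @export
print.transition_profile <- function(x, ...) {
  cat("Transition profile (", x$representation, "), total ", x$total,
      "\n", sep = "")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) print(nz) else cat("(no transitions)\n")
  invisible(x)
}

#' Per-user transition features for a cohort
#'
#' One row per user, one column per bidirectional pair type, holding the
#' user's proportion of transitions of that type under the chosen
#' representation (proportions rather than raw counts, so that posting
#' volume does not confound the correlation screen). Users with fewer
#' than two symbols carry no transition and are excluded with a warning.
#' The pooled per-pair counts across users are attached as attribute
#' `n_occ`, and per-user totals as column `total`.
#'
#' @param cohort an `affect_cohort`.
#' @param representation sequence representation, see [build_sequence()].
#' @param plurality_first passed to [day_affect()].
#' @return data.frame: `user_id`, 15 pair-proportion columns, `total`;
#'   attribute `n_occ` (pooled counts), attribute `representation`.
#' @export
transition_features <- function(cohort,
                                representation = c("post_with_silence",
                                                   "post_without_silence",
                                                   "day_level"),
                                plurality_first = FALSE) {
  representation <- match.arg(representation)
  keys <- transition_pairs(.seq_symbols)
  rows <- list(); pooled <- stats::setNames(numeric(length(keys)), keys)
  dropped <- character(0)
  for (i in seq_len(nrow(cohort$users))) {
    uid <- cohort$users$user_id[i]
    w <- cohort$windows[cohort$windows$user_id == uid, ]
    sq <- build_sequence(.user_posts(cohort, uid), w$window_start,
                         w$window_end, representation, user_id = uid,
                         plurality_first = plurality_first)
    prof <- count_transitions(sq)
    if (prof$total < 1) {
      dropped <- c(dropped, uid)
      next
    }
    pooled <- pooled + prof$counts
    rows[[uid]] <- c(prof$proportions, total = prof$total)
  }
  if (length(dropped)) {
    warning("excluded user(s) with fewer than 2 symbols: ",
            paste(dropped, collapse = ", "))
  }
  feat <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  feat <- cbind(user_id = names(rows), feat, stringsAsFactors = FALSE)
  rownames(feat) <- NULL
  attr(feat, "n_occ") <- pooled
  attr(feat, "representation") <- representation
  feat
}

#' Per-user affect frequency features
#'
#' Two families of shares per user: the share of the user's posts carrying
#' each of the four polarities, and the share of window days whose
#' day-level symbol is each of the five symbols (including silence).
#' Each family sums to 1 per user.
#'
#' @param cohort an `affect_cohort`.
#' @return data.frame: `user_id`, `post_+`, `post_-`, `post_m`, `post_0`,
#'   `day_+`, `day_-`, `day_m`, `day_0`, `day_S`.
#' @export
affect_frequencies <- function(cohort) {
  if (nrow(cohort$users) == 0) stop("empty cohort")
  rows <- lapply(cohort$users$user_id, function(uid) {
    p <- .user_posts(cohort, uid)
    w <- cohort$windows[cohort$windows$user_id == uid, ]
    post_tab <- table(factor(p$affect, levels = .affect_symbols))
    post_share <- if (nrow(p)) as.numeric(post_tab) / nrow(p)
                  else rep(0, 4)
    dl <- build_sequence(p, w$window_start, w$window_end, "day_level",
                         user_id = uid)
    day_tab <- table(factor(dl$symbols, levels = .seq_symbols))
    day_share <- as.numeric(day_tab) / length(dl$symbols)
    c(post_share, day_share)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("post_", .affect_symbols),
                  paste0("day_", .seq_symbols))
  cbind(user_id = cohort$users$user_id, out, stringsAsFactors = FALSE)
}
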