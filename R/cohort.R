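#' Average posts per day over a date interval
#'
#' Posting frequency is the post count inside the frame divided by the
#' frame length in days (both endpoints included). A rate of 0.3 posts
#' per day corresponds to roughly 110 posts in 365 days, i.e. about two
#' posts a week — the conventional bar for a "regular" user.
#'
#' @param days vector of class `Date`, one entry per post.
#' @param frame_start,frame_end first and last day of the frame (`Date`).
#' @return posts per day, a non-negative real.
#' @examples
#' posting_rate(as.Date("2012-01-01") + 0:59,
#'              as.Date("2012-01-01"), as.Date("2012-02-29"))
#' @export
posting_rate <- function(days, frame_start, frame_end) {
  frame_start <- as.Date(frame_start)
  frame_end <- as.Date(frame_end)
  len <- as.numeric(frame_end - frame_start) + 1
  if (!is.finite(len) || len < 1) {
    stop("frame must span at least one day")
  }
  n <- sum(days >= frame_start & days <= frame_end)
  n / len
}

#' Configuration of the participant-selection funnel
#'
#' Defaults mirror a two-month observation design: regular users post at
#' a rate of at least 0.3/day over their whole posting span, were active
#' in the week before completing the CES-D questionnaire, contributed at
#' least 20 posts in the 60 days before completion, are adults, and post
#' mostly in English.
#'
#' @param rate_threshold minimum posts/day over the user's posting span
#'   (inclusive boundary: a rate exactly at the threshold qualifies).
#' @param window_days length of the observation window ending at
#'   `cesd_date`.
#' @param min_posts minimum posts inside the window.
#' @param min_age minimum age in years.
#' @param max_non_english_share maximum tolerated share of posts in the
#'   window whose language tag is not `english_tag`.
#' @param activity_days length of the pre-completion activity check (the
#'   `activity_days` calendar days ending at and including `cesd_date`).
#' @param english_tag ISO-639-1 tag treated as English.
#' @param drop_non_english_posts drop non-English posts from the selected
#'   cohort's window (they are excluded from downstream analysis).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(rate_threshold = 0.3, window_days = 60,
                          min_posts = 20, min_age = 18,
                          max_non_english_share = 0.2, activity_days = 7,
                          english_tag = "en", drop_non_english_posts = TRUE) {
  structure(list(rate_threshold = rate_threshold, window_days = window_days,
                 min_posts = min_posts, min_age = min_age,
                 max_non_english_share = max_non_english_share,
                 activity_days = activity_days, english_tag = english_tag,
                 drop_non_english_posts = drop_non_english_posts),
            class = "cohort_config")
}

#' Apply the participant-selection funnel
#'
#' Filters users in a fixed order, recording an audit trail: (1) regular
#' posting rate over the user's full span from first to last post; (2) at
#' least one post in the week ending at `cesd_date`; (3) restriction of
#' each user's posts to the `window_days`-day window ending at
#' `cesd_date`; (4) minimum post count in the window; (5) adult age;
#' (6) non-English share in the window at most the configured maximum.
#' A user whose CES-D completion precedes all their posts simply fails
#' the activity stage; it is not an error.
#'
#' @param users data.frame from [read_users()] or [simulate_users()].
#' @param posts data.frame from [read_posts()] or [simulate_posts()].
#' @param config a [cohort_config()].
#' @return list with elements `cohort` (class `affect_cohort`: `users`,
#'   `posts` restricted to each user's window, `window_days`, and a
#'   per-user `windows` table) and `report` (class `filter_report`).
#' @export
select_cohort <- function(users, posts, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  posts <- posts[order(posts$user_id, posts$day), , drop = FALSE]
  split_posts <- split(posts, posts$user_id)
  alive <- users$user_id
  stages <- character(0); n_in <- integer(0); removed <- list()

  drop_stage <- function(name, keep) {
    stages <<- c(stages, name)
    n_in <<- c(n_in, length(alive))
    removed[[name]] <<- alive[!keep]
    alive <<- alive[keep]
  }

  # 1. regular users: rate over full posting span >= threshold
  keep <- vapply(alive, function(uid) {
    p <- split_posts[[uid]]
    if (is.null(p) || nrow(p) == 0) return(FALSE)
    posting_rate(p$day, min(p$day), max(p$day)) >= config$rate_threshold
  }, logical(1))
  drop_stage("regular_user_rate", keep)

  # 2. activity in the week before CES-D completion
  cd <- users$cesd_date[match(alive, users$user_id)]
  keep <- vapply(seq_along(alive), function(i) {
    p <- split_posts[[alive[i]]]
    any(p$day >= cd[i] - (config$activity_days - 1) & p$day <= cd[i])
  }, logical(1))
  drop_stage("active_week_before_cesd", keep)

  # 3. restrict to the observation window (no user is removed here unless
  # all their posts fall outside it)
  cd <- users$cesd_date[match(alive, users$user_id)]
  win_start <- cd - (config$window_days - 1)
  windowed <- lapply(seq_along(alive), function(i) {
    p <- split_posts[[alive[i]]]
    p[p$day >= win_start[i] & p$day <= cd[i], , drop = FALSE]
  })
  names(windowed) <- alive
  keep <- vapply(windowed, function(p) nrow(p) > 0, logical(1))
  drop_stage("window_restriction", keep)
  windowed <- windowed[keep]

  # 4. minimum posts in window
  keep <- vapply(windowed, function(p) nrow(p) >= config$min_posts, logical(1))
  drop_stage("min_posts_in_window", keep)
  windowed <- windowed[keep]

  # 5. adults only
  age <- users$age[match(alive, users$user_id)]
  keep <- !is.na(age) & age >= config$min_age
  drop_stage("min_age", keep)
  windowed <- windowed[keep]

  # 6. mostly-English posting
  keep <- vapply(windowed, function(p) {
    lang <- p$language
    share <- mean(!is.na(lang) & lang != config$english_tag)
    share <= config$max_non_english_share
  }, logical(1))
  drop_stage("max_non_english_share", keep)
  windowed <- windowed[keep]

  if (config$drop_non_english_posts) {
    windowed <- lapply(windowed, function(p) {
      p[is.na(p$language) | p$language == config$english_tag, , drop = FALSE]
    })
  }

  surv <- users[users$user_id %in% alive, , drop = FALSE]
  win_posts <- if (length(windowed)) do.call(rbind, windowed)
               else .empty_posts()
  rownames(win_posts) <- NULL
  windows <- data.frame(
    user_id = surv$user_id,
    window_start = surv$cesd_date - (config$window_days - 1),
    window_end = surv$cesd_date, stringsAsFactors = FALSE)

  report <- structure(
    data.frame(stage = stages, n_in = n_in,
               n_removed = lengths(removed[stages]),
               n_out = n_in - lengths(removed[stages]),
               stringsAsFactors = FALSE),
    removed_ids = removed, class = c("filter_report", "data.frame"))

  cohort <- structure(list(users = surv, posts = win_posts,
                           windows = windows,
                           window_days = config$window_days),
                      class = "affect_cohort")
  list(cohort = cohort, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Participant-selection funnel\n")
  print.data.frame(x, row.names = FALSE)
  cat("final sample:", x$n_out[nrow(x)], "of", x$n_in[1], "users\n")
  invisible(x)
}

#' @export
print.affect_cohort <- function(x, ...) {
  cat("Affect cohort:", nrow(x$users), "users,", nrow(x$posts),
      "posts in", x$window_days, "day windows\n")
  invisible(x)
}

#' Posts of one cohort user, chronologically ordered
#' @param cohort an `affect_cohort`.
#' @param user_id the user.
#' @return data.frame of posts.
#' @keywords internal
.user_posts <- function(cohort, user_id) {
  p <- cohort$posts[cohort$posts$user_id == user_id, , drop = FALSE]
  p[order(p$day), , drop = FALSE]
}
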