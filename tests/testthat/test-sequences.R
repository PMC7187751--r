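test_that("day_affect follows the mixed rules, plurality, and precedence", {
  expect_equal(day_affect(c("+", "-", "+")), "+")
  expect_equal(day_affect(c("+", "-")), "m")     # equal +/- counts
  expect_equal(day_affect(character(0)), "S")    # silent day
  expect_equal(day_affect("m"), "m")
  expect_equal(day_affect(c("0", "0")), "0")
  # mixed posts equal in number to all other posts
  expect_equal(day_affect(c("m", "m", "0", "+")), "m")
  # the +/- equality rule precedes plurality by default...
  expect_equal(day_affect(c("0", "0", "0", "+", "-")), "m")
  # ...unless plurality_first is set
  expect_equal(day_affect(c("0", "0", "0", "+", "-"), plurality_first = TRUE),
               "0")
  # residual plurality ties resolve m > - > + > 0
  expect_equal(day_affect(c("+", "0", "+", "0")), "+")
  expect_equal(day_affect(c("-", "0", "-", "0")), "-")
  expect_error(day_affect(c("+", "z")), "outside alphabet")
})

test_that("the sample week reproduces its printed representations", {
  posts <- posts_from_days(table1_week)
  start <- min(posts$day); end <- start + 6
  with_s <- build_sequence(posts, start, end, "post_with_silence")
  expect_equal(with_s$symbols,
               c("+", "-", "+", "-", "+", "+", "+", "S", "m", "0", "+", "-"))
  without_s <- build_sequence(posts, start, end, "post_without_silence")
  expect_equal(without_s$symbols, setdiff_symbols <-
                 with_s$symbols[with_s$symbols != "S"])
  expect_length(without_s$symbols, 11)
  day <- build_sequence(posts, start, end, "day_level")
  # Tuesday..Sunday; Monday's printed cell contradicts the stated tie rule
  expect_equal(day$symbols[2:7], c("+", "+", "S", "m", "0", "m"))
  expect_length(day$symbols, 7)
})

test_that("build_sequence validates ordering and window membership", {
  posts <- posts_from_days(table1_week)
  start <- min(posts$day)
  expect_error(build_sequence(posts[c(3, 1, 2), ], start, start + 6),
               "sorted")
  expect_error(build_sequence(posts, start, start + 2), "outside the window")
})

test_that("transition counting matches hand enumeration", {
  p <- count_transitions(c("+", "-", "+", "+"))
  expect_equal(p$total, 3)
  expect_equal(unname(p$counts["+<->-"]), 2L)
  expect_equal(unname(p$counts["+<->+"]), 1L)
  expect_equal(sum(p$counts), 3L)

  p2 <- count_transitions(c("S", "S", "S"))
  expect_equal(unname(p2$counts["S<->S"]), 2L)
  expect_equal(sum(p2$counts), 2L)

  posts <- posts_from_days(table1_week)
  seq1 <- build_sequence(posts, min(posts$day), min(posts$day) + 6,
                         "post_with_silence")
  p3 <- count_transitions(seq1)
  expected <- c("+<->-" = 5L, "+<->+" = 2L, "+<->S" = 1L, "m<->S" = 1L,
                "m<->0" = 1L, "+<->0" = 1L)
  expect_equal(p3$counts[names(expected)], expected, ignore_attr = TRUE)
  expect_equal(p3$total, 11)
  expect_equal(sum(p3$proportions), 1)
})

test_that("transition counts equal the brute-force oracle on random sequences", {
  set.seed(31)
  ab <- c("+", "-", "m", "0", "S")
  for (i in 1:200) {
    s <- sample(ab, sample(0:50, 1), replace = TRUE)
    got <- count_transitions(s)$counts
    expect_equal(got, brute_transition_counts(s, ab), ignore_attr = TRUE)
  }
})

test_that("transition counting is conserved, symmetric under reversal", {
  set.seed(32)
  ab <- c("+", "-", "m", "0", "S")
  for (i in 1:50) {
    s <- sample(ab, sample(2:40, 1), replace = TRUE)
    p <- count_transitions(s)
    expect_equal(sum(p$counts), length(s) - 1)
    expect_equal(p$counts, count_transitions(rev(s))$counts)
    # dropping silence shortens, never lengthens, the transition budget
    expect_lte(max(sum(s != "S") - 1, 0), length(s) - 1)
  }
})

test_that("day-level sequences always span the whole window", {
  sim <- simulate_cohort(sim_config(n_users = 6, seed = 17))
  sel <- select_cohort(sim$users, sim$posts)
  for (uid in sel$cohort$users$user_id) {
    w <- sel$cohort$windows[sel$cohort$windows$user_id == uid, ]
    p <- sel$cohort$posts[sel$cohort$posts$user_id == uid, ]
    d <- build_sequence(p, w$window_start, w$window_end, "day_level")
    expect_length(d$symbols, 60)
    expect_true(!is.unsorted(d$day_index))
  }
})

test_that("transition features are 15 proportions summing to one per user", {
  sim <- simulate_cohort(sim_config(n_users = 10, seed = 23))
  sel <- select_cohort(sim$users, sim$posts)
  for (rep_name in c("post_with_silence", "post_without_silence",
                     "day_level")) {
    feat <- transition_features(sel$cohort, rep_name)
    pair_cols <- setdiff(names(feat), c("user_id", "total"))
    expect_length(pair_cols, 15)
    expect_equal(unname(rowSums(feat[, pair_cols])),
                 rep(1, nrow(feat)))
    n_occ <- attr(feat, "n_occ")
    expect_equal(sum(n_occ), sum(feat$total))
  }
})

test_that("a degenerate single-affect user has one unit feature", {
  D <- as.Date("2012-06-30")
  users <- make_user_row("u1")
  sel <- select_cohort(users, daily_posts("u1", 60, D, affect = "+"))
  feat <- transition_features(sel$cohort, "post_without_silence")
  expect_equal(feat[["+<->+"]], 1)
  others <- setdiff(names(feat), c("user_id", "total", "+<->+"))
  expect_equal(unname(unlist(feat[, others])), rep(0, 14))
})

test_that("users with fewer than two symbols are excluded with a warning", {
  D <- as.Date("2012-06-30")
  users <- rbind(make_user_row("u1"), make_user_row("u2"))
  one_post <- daily_posts("u1", 1, D)
  cohort <- structure(list(
    users = users,
    posts = rbind(one_post, daily_posts("u2", 30, D)),
    windows = data.frame(user_id = c("u1", "u2"),
                         window_start = D - 29, window_end = D),
    window_days = 30), class = "affect_cohort")
  expect_warning(feat <- transition_features(cohort, "post_without_silence"),
                 "fewer than 2 symbols.*u1")
  expect_equal(feat$user_id, "u2")
})

test_that("affect frequencies form unit-sum share families", {
  sim <- simulate_cohort(sim_config(n_users = 8, seed = 41))
  sel <- select_cohort(sim$users, sim$posts)
  fr <- affect_frequencies(sel$cohort)
  post_cols <- paste0("post_", c("+", "-", "m", "0"))
  day_cols <- paste0("day_", c("+", "-", "m", "0", "S"))
  expect_equal(unname(rowSums(fr[, post_cols])), rep(1, nrow(fr)))
  expect_equal(unname(rowSums(fr[, day_cols])), rep(1, nrow(fr)))

  users <- make_user_row("u1")
  sel1 <- select_cohort(users, daily_posts("u1", 60, as.Date("2012-06-30"),
                                           affect = "+"))
  fr1 <- affect_frequencies(sel1$cohort)
  expect_equal(fr1[["post_+"]], 1)
  expect_equal(fr1[["day_+"]], 1)
})
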