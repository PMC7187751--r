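# Independent brute-force oracles, deliberately naive implementations.

# adjacent-pair counts by explicit loop over positions
brute_transition_counts <- function(symbols, alphabet) {
  keys <- character(0)
  for (i in seq_along(alphabet)) {
    for (j in i:length(alphabet)) {
      keys <- c(keys, paste0(alphabet[i], "<->", alphabet[j]))
    }
  }
  counts <- setNames(integer(length(keys)), keys)
  n <- length(symbols)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      a <- symbols[i]; b <- symbols[i + 1]
      ia <- match(a, alphabet); ib <- match(b, alphabet)
      key <- if (ia <= ib) paste0(a, "<->", b) else paste0(b, "<->", a)
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

# all permutations of 1..n (n small) by recursion
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# exhaustive two-sided permutation p for a Pearson correlation
exact_perm_p <- function(x, y) {
  r0 <- abs(cor(x, y))
  rs <- vapply(all_perms(length(y)),
               function(p) abs(cor(x, y[p])), numeric(1))
  mean(rs >= r0 - 1e-12)
}

# Mann-Whitney U by pair counting (half credit for ties)
brute_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# one-user posts frame from per-day symbol lists
posts_from_days <- function(day_symbols, start = as.Date("2012-06-04"),
                            user_id = "u1") {
  rows <- list()
  for (d in seq_along(day_symbols)) {
    syms <- day_symbols[[d]]
    for (s in syms) {
      rows[[length(rows) + 1]] <- data.frame(
        user_id = user_id, created_at = format(start + d - 1, "%Y-%m-%d"),
        text = "", affect = s, language = "en",
        originality_gold = NA_character_, day = start + d - 1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# the published sample week: post-level affect per day, Monday first
table1_week <- list(
  c("+", "-"),           # Monday
  c("+", "-", "+"),      # Tuesday
  c("+", "+"),           # Wednesday
  character(0),          # Thursday (silent)
  "m",                   # Friday
  "0",                   # Saturday
  c("+", "-")            # Sunday
)

make_user_row <- function(user_id, age = 25, cesd = 20,
                          cesd_date = as.Date("2012-06-30")) {
  data.frame(user_id = user_id, age = age, gender = "female",
             ethnicity = "caucasian", living_status = "single",
             ope = 3.5, con = 3.2, ext = 3.1, agr = 3.5, neu = 3.0,
             swl = 4.2, cesd = cesd, cesd_date = cesd_date,
             above_cutoff = cesd >= 22, stringsAsFactors = FALSE)
}

# n posts on consecutive days ending at `end`
daily_posts <- function(user_id, n, end, affect = "+") {
  days <- seq(end - n + 1, end, by = "day")
  data.frame(user_id = user_id, created_at = format(days, "%Y-%m-%d"),
             text = "t", affect = affect, language = "en",
             originality_gold = NA_character_, day = days,
             stringsAsFactors = FALSE)
}
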