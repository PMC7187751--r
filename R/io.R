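#' Read a table of posts
#'
#' Accepts a comma-delimited table (`.csv`) or record-per-line JSON
#' (`.jsonl`/`.ndjson`), auto-detected from the file extension. Required
#' columns are `user_id`, `created_at` (ISO-8601 date, optionally with a
#' time-of-day) and `affect`; `text`, `language` and `originality_gold`
#' are optional. Affect is stored on disk as one of the ASCII tokens
#' `pos`/`neg`/`mix`/`neu` and mapped to the in-memory symbols
#' `+`/`-`/`m`/`0`; silence is never stored, it is derived from calendar
#' gaps when sequences are built.
#'
#' @param path path to the posts file.
#' @param dialect `"auto"` (default, by extension), `"csv"` or `"jsonl"`.
#' @return A data.frame with columns `user_id`, `created_at`, `text`,
#'   `affect` (symbols), `language`, `originality_gold`, plus a derived
#'   `day` column of class `Date`. Zero rows for an empty file.
#' @seealso [write_posts()], [read_users()]
#' @export
read_posts <- function(path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  raw <- .read_table(path, dialect)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    return(.empty_posts())
  }
  .require_fields(raw, c("user_id", "created_at", "affect"), path)
  for (opt in c("text", "language", "originality_gold")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  }
  posts <- data.frame(
    user_id = as.character(raw$user_id),
    created_at = as.character(raw$created_at),
    text = as.character(raw$text),
    affect = .decode_affect(raw$affect),
    language = as.character(raw$language),
    originality_gold = as.character(raw$originality_gold),
    stringsAsFactors = FALSE
  )
  posts$day <- .parse_day(posts$created_at)
  if (any(posts$user_id == "" | is.na(posts$user_id))) {
    stop("schema error: empty user_id in row(s) ",
         paste(which(posts$user_id == "" | is.na(posts$user_id)), collapse = ", "))
  }
  posts
}

#' Write a table of posts
#'
#' Inverse of [read_posts()]; affect symbols are encoded back to the
#' on-disk tokens and the derived `day` column is dropped. A read of the
#' written file reproduces all modeled fields.
#'
#' @param posts data.frame as returned by [read_posts()].
#' @inheritParams read_posts
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  out <- posts[, c("user_id", "created_at", "text", "affect",
                   "language", "originality_gold")]
  out$affect <- names(.affect_tokens)[match(out$affect, .affect_tokens)]
  .write_table(out, path, dialect)
}

#' Read a table of user profiles
#'
#' Columns: `user_id`, `age`, `gender`, `ethnicity`, `living_status`, the
#' five OCEAN trait scores `ope`/`con`/`ext`/`agr`/`neu` (1-5 scale),
#' `swl` (1-7), `cesd` (integer 0-60) and `cesd_date` (ISO date of CES-D
#' completion). Scale ranges are validated; a CES-D score outside 0-60 or
#' a duplicated `user_id` is an error. The returned frame carries a
#' logical `above_cutoff` column marking scores at or above the
#' conventional CES-D cut-off of 22 for probable depressive disorder.
#'
#' @inheritParams read_posts
#' @param cesd_cutoff threshold for the `above_cutoff` flag (default 22).
#' @return data.frame of user profiles, `cesd_date` as `Date`.
#' @export
read_users <- function(path, dialect = c("auto", "csv", "jsonl"),
                       cesd_cutoff = 22) {
  dialect <- match.arg(dialect)
  raw <- .read_table(path, dialect)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    return(.empty_users())
  }
  .require_fields(raw, c("user_id", "ope", "con", "ext", "agr", "neu",
                         "swl", "cesd", "cesd_date"), path)
  for (opt in c("age", "gender", "ethnicity", "living_status")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  }
  users <- data.frame(
    user_id = as.character(raw$user_id),
    age = as.numeric(raw$age),
    gender = as.character(raw$gender),
    ethnicity = as.character(raw$ethnicity),
    living_status = as.character(raw$living_status),
    ope = as.numeric(raw$ope), con = as.numeric(raw$con),
    ext = as.numeric(raw$ext), agr = as.numeric(raw$agr),
    neu = as.numeric(raw$neu),
    swl = as.numeric(raw$swl),
    cesd = as.numeric(raw$cesd),
    cesd_date = as.character(raw$cesd_date),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(users$user_id)
  if (any(dup)) {
    stop("uniqueness error: duplicate user_id in row(s) ",
         paste(which(dup), collapse = ", "), ": ",
         paste(unique(users$user_id[dup]), collapse = ", "))
  }
  .check_range(users$cesd, 0, 60, "cesd")
  if (any(users$cesd != round(users$cesd))) {
    stop("range error: cesd must be integer-valued, row(s) ",
         paste(which(users$cesd != round(users$cesd)), collapse = ", "))
  }
  for (tr in c("ope", "con", "ext", "agr", "neu")) {
    .check_range(users[[tr]], 1, 5, tr)
  }
  .check_range(users$swl, 1, 7, "swl")
  users$cesd_date <- .parse_day(users$cesd_date, field = "cesd_date")
  users$above_cutoff <- users$cesd >= cesd_cutoff
  users
}

#' Write a table of user profiles
#' @param users data.frame as returned by [read_users()].
#' @inheritParams read_posts
#' @return `path`, invisibly.
#' @export
write_users <- function(users, path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  cols <- c("user_id", "age", "gender", "ethnicity", "living_status",
            "ope", "con", "ext", "agr", "neu", "swl", "cesd", "cesd_date")
  out <- users[, cols]
  out$cesd_date <- format(out$cesd_date, "%Y-%m-%d")
  .write_table(out, path, dialect)
}

#' Read a candidate source corpus
#'
#' Columns: `doc_id`, `site_name`, `url`, `text` (non-empty).
#' @inheritParams read_posts
#' @return data.frame of source documents.
#' @export
read_corpus <- function(path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  raw <- .read_table(path, dialect)
  .require_fields(raw, c("doc_id", "text"), path)
  for (opt in c("site_name", "url")) {
    if (!opt %in% names(raw)) raw[[opt]] <- ""
  }
  corpus <- data.frame(
    doc_id = as.character(raw$doc_id),
    site_name = as.character(raw$site_name),
    url = as.character(raw$url),
    text = as.character(raw$text),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(corpus$text))) {
    stop("schema error: empty text in corpus row(s) ",
         paste(which(!nzchar(corpus$text)), collapse = ", "))
  }
  corpus
}

#' @rdname read_corpus
#' @param corpus data.frame of source documents.
#' @export
write_corpus <- function(corpus, path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  .write_table(corpus[, c("doc_id", "site_name", "url", "text")], path, dialect)
}

# ---- internals --------------------------------------------------------

.detect_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

.read_table <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") dialect <- .detect_dialect(path)
  if (dialect == "csv") {
    if (length(readLines(path, n = 1L, warn = FALSE)) == 0) {
      return(data.frame())
    }
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(data.frame())
    recs <- lapply(lines, jsonlite::fromJSON)
    nms <- unique(unlist(lapply(recs, names)))
    cols <- lapply(nms, function(nm) {
      vapply(recs, function(r) {
        v <- r[[nm]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    })
    names(cols) <- nms
    as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

.write_table <- function(x, path, dialect) {
  if (dialect == "auto") dialect <- .detect_dialect(path)
  if (dialect == "csv") {
    utils::write.csv(x, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(x))) {
      rec <- as.list(x[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  digits = NA), con)
    }
  }
  invisible(path)
}

.require_fields <- function(raw, fields, path) {
  missing <- setdiff(fields, names(raw))
  if (length(missing)) {
    stop("schema error in ", path, ": missing required field(s) ",
         paste(missing, collapse = ", "))
  }
  invisible(raw)
}

.decode_affect <- function(x) {
  x <- as.character(x)
  sym <- .affect_tokens[x]
  # accept in-memory symbols too, so round-tripping hand-built frames works
  direct <- x %in% .affect_symbols
  sym[direct] <- x[direct]
  bad <- is.na(sym)
  if (any(bad)) {
    stop("schema error: invalid affect symbol(s) ",
         paste(unique(x[bad]), collapse = ", "),
         " in row(s) ", paste(which(bad), collapse = ", "),
         " (expected pos/neg/mix/neu)")
  }
  unname(sym)
}

.parse_day <- function(x, field = "created_at") {
  # ISO-8601 date, optionally followed by a time-of-day; the calendar day
  # is the unit, so only the date part is parsed (no timezone arithmetic)
  d <- as.Date(substr(as.character(x), 1, 10), format = "%Y-%m-%d")
  bad <- is.na(d) | is.na(x)
  if (any(bad)) {
    stop("schema error: unparseable ", field, " in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  d
}

.check_range <- function(x, lo, hi, field) {
  bad <- is.na(x) | x < lo | x > hi
  if (any(bad)) {
    stop("range error: ", field, " outside [", lo, ", ", hi, "] in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  invisible(x)
}

.empty_posts <- function() {
  data.frame(user_id = character(0), created_at = character(0),
             text = character(0), affect = character(0),
             language = character(0), originality_gold = character(0),
             day = as.Date(character(0)), stringsAsFactors = FALSE)
}

.empty_users <- function() {
  data.frame(user_id = character(0), age = numeric(0), gender = character(0),
             ethnicity = character(0), living_status = character(0),
             ope = numeric(0), con = numeric(0), ext = numeric(0),
             agr = numeric(0), neu = numeric(0), swl = numeric(0),
             cesd = numeric(0), cesd_date = as.Date(character(0)),
             above_cutoff = logical(0), stringsAsFactors = FALSE)
}
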