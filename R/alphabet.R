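#' Affect and sequence alphabets
#'
#' Posts carry one of four affect polarities: `"+"` (positive), `"-"`
#' (negative), `"m"` (mixed, i.e. both valences present), `"0"` (neutral).
#' Sequences over calendar days add a fifth symbol `"S"` for a silence day,
#' a day inside the observation window with no posts. Originality sequences
#' use `"O"` (original), `"N"` (non-original) and `"S"`.
#'
#' @name alphabets
#' @keywords internal
NULL

# canonical symbol orders; pair keys are always written with the earlier
# symbol first, so {a,b} and {b,a} collapse to one bidirectional type
.affect_symbols <- c("+", "-", "m", "0")
.seq_symbols <- c("+", "-", "m", "0", "S")
.orig_symbols <- c("O", "N", "S")

# on-disk tokens (the +/- symbols are not CSV-safe across tools)
.affect_tokens <- c("pos" = "+", "neg" = "-", "mix" = "m", "neu" = "0")

#' Enumerate bidirectional transition types for an alphabet
#'
#' For a k-symbol alphabet there are k self-pairs plus choose(k, 2) mixed
#' pairs; for the 5-symbol affect alphabet that is 15 types, for the
#' 3-symbol originality alphabet 6.
#'
#' @param alphabet character vector of symbols in canonical order.
#' @return Character vector of pair keys of the form `"a<->b"`.
#' @examples
#' transition_pairs()          # the 15 affect pair types
#' transition_pairs(c("O", "N", "S"))
#' @export
transition_pairs <- function(alphabet = .seq_symbols) {
  k <- length(alphabet)
  keys <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      keys <- c(keys, paste0(alphabet[i], "<->", alphabet[j]))
    }
  }
  keys
}

#' Canonical key of one unordered symbol pair
#' @param a,b single symbols from `alphabet`.
#' @inheritParams transition_pairs
#' @return A pair key `"x<->y"` with x preceding y in the alphabet.
#' @export
pair_key <- function(a, b, alphabet = .seq_symbols) {
  ia <- match(a, alphabet)
  ib <- match(b, alphabet)
  if (anyNA(c(ia, ib))) {
    stop("symbol(s) outside alphabet: ",
         paste(setdiff(c(a, b), alphabet), collapse = ", "))
  }
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  paste0(alphabet[lo], "<->", alphabet[hi])
}

.check_symbols <- function(x, alphabet, what = "symbol") {
  bad <- !(x %in% alphabet)
  if (any(bad)) {
    stop(what, " outside alphabet {", paste(alphabet, collapse = ", "),
         "}: ", paste(unique(x[bad]), collapse = ", "))
  }
  invisible(x)
}

# run code under a temporary RNG state so package functions do not clobber
# the caller's random stream; seed = NULL leaves the stream alone
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
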