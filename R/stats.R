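#' Permutation test for a Pearson correlation
#'
#' The observed coefficient is the ordinary sample Pearson r. Its
#' two-sided significance is assessed against the permutation
#' distribution obtained by shuffling `y` with a seeded generator; the
#' add-one estimator p = (1 + #\{|r_b| >= |r|\}) / (n_perm + 1) never
#' returns exactly zero, so the attainable minimum is 1/(n_perm + 1).
#'
#' @param x,y equal-length numeric vectors, n >= 3, neither constant.
#' @param n_perm number of random permutations (default 10000).
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return list with `r`, `p`, `n`, `n_perm`, `seed`.
#' @export
perm_corr_test <- function(x, y, n_perm = 10000, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector")
  }
  cx <- x - mean(x); cy <- y - mean(y)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  r <- sum(cx * cy) / denom
  exceed <- .with_seed(seed, {
    e <- 0L
    for (b in seq_len(n_perm)) {
      rb <- sum(cx * cy[sample.int(n)]) / denom
      # tolerance so exact ties (e.g. sign flips of the same pairing)
      # count as at-least-as-extreme
      if (abs(rb) >= abs(r) - 1e-12) e <- e + 1L
    }
    e
  })
  list(r = r, p = (1 + exceed) / (n_perm + 1), n = n, n_perm = n_perm,
       seed = seed)
}

#' Percentile bootstrap confidence interval for a Pearson correlation
#'
#' Resamples (x, y) pairs with replacement; a resample in which either
#' coordinate is constant carries no correlation and is redrawn (with a
#' retry cap). The interval is the percentile interval of the resampled
#' coefficients.
#'
#' @inheritParams perm_corr_test
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param max_retry redraw cap per degenerate resample.
#' @return list with `lo`, `hi`, `level`, `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(x, y, n_boot = 2000, level = 0.95, seed = NULL,
                         max_retry = 100) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 5) stop("need at least 5 paired observations")
  rs <- .with_seed(seed, {
    out <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      for (try in seq_len(max_retry)) {
        idx <- sample.int(n, replace = TRUE)
        if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
        if (try == max_retry) stop("could not draw a non-degenerate resample")
      }
      out[b] <- stats::cor(x[idx], y[idx])
    }
    out
  })
  qs <- stats::quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lo = qs[1], hi = qs[2], level = level, n_boot = n_boot, seed = seed)
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of z:
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#' Significance by default via the t approximation
#' t = r sqrt((n - 3) / (1 - r^2)) on n - 3 degrees of freedom; a
#' permutation variant shuffles the z-residuals of y against those of x.
#'
#' @param x,y,z equal-length numeric vectors, n >= 4.
#' @param method `"t"` (default) or `"permutation"`.
#' @inheritParams perm_corr_test
#' @return list with `r`, `p`, `n`, `method`.
#' @export
partial_corr <- function(x, y, z, method = c("t", "permutation"),
                         n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must share a length")
  if (n < 4) stop("need at least 4 observations")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("degenerate input: a control correlation is +/-1")
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  if (method == "t") {
    tt <- r * sqrt((n - 3) / max(1 - r^2, 1e-15))
    p <- 2 * stats::pt(-abs(tt), df = n - 3)
  } else {
    rx <- stats::residuals(stats::lm(x ~ z))
    ry <- stats::residuals(stats::lm(y ~ z))
    p <- perm_corr_test(rx, ry, n_perm = n_perm, seed = seed)$p
  }
  list(r = r, p = p, n = n, method = method)
}

#' Wilcoxon-Mann-Whitney test
#'
#' U statistic for the first sample (U = n_x n_y when every x exceeds
#' every y), with a tie-corrected normal approximation for the two-sided
#' p value.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `U`, `Z`, `p`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both groups must be non-empty")
  all_v <- c(x, y)
  rk <- rank(all_v)
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  N <- nx + ny
  mu <- nx * ny / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    # all values tied: no evidence either way
    return(list(U = U, Z = 0, p = 1, n_x = nx, n_y = ny))
  }
  Z <- (U - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(Z)))
  list(U = U, Z = Z, p = p, n_x = nx, n_y = ny)
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with
#' marginal-product chance agreement. When both annotators are constant
#' and identical, agreement is perfect by definition (kappa 1); constant
#' but different marginals with p_e = 1 cannot occur.
#'
#' @param a,b equal-length categorical label vectors.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(c("+", "+", "-", "-"), c("+", "-", "+", "-"))  # 0
#' @export
cohens_kappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a)
  if (length(b) != n) stop("label vectors must have the same length")
  if (n == 0) stop("empty label vectors")
  po <- mean(a == b)
  lev <- union(a, b)
  pa <- table(factor(a, levels = lev)) / n
  pb <- table(factor(b, levels = lev)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (pe >= 1 - 1e-12) {
    if (identical(a, b)) return(1)
    stop("degenerate input: chance agreement is 1")
  }
  (po - pe) / (1 - pe)
}

#' Mean pairwise Cohen's kappa over several annotators
#' @param raters list of equal-length label vectors (>= 2).
#' @return mean kappa over all annotator pairs.
#' @export
average_pairwise_kappa <- function(raters) {
  k <- length(raters)
  if (k < 2) stop("need at least two annotators")
  pairs <- utils::combn(k, 2)
  mean(apply(pairs, 2, function(ij) {
    cohens_kappa(raters[[ij[1]]], raters[[ij[2]]])
  }))
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around the standard Shapiro-Wilk routine.
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 5000) stop("n must be in [3, 5000]")
  if (stats::sd(x) == 0) stop("degenerate input: constant vector")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Correlation screen of features against psychometric scales
#'
#' One permutation Pearson correlation with a bootstrap confidence
#' interval per scale x feature pair, tiered as in small-sample
#' exploratory screens: p < alpha_sig is "significant", p < alpha_trend
#' a "trend", otherwise "ns". Constant columns (e.g. a transition type
#' nobody exhibits) yield an `NA` coefficient and tier "ns" rather than
#' an error. Per-pair seeds are derived deterministically from `seed`,
#' so identical inputs give bit-identical tables.
#'
#' @param features data.frame with `user_id` plus numeric feature
#'   columns (a `total` column is ignored); typically from
#'   [transition_features()], [affect_frequencies()] or
#'   [originality_features()].
#' @param scales data.frame with `user_id` plus numeric scale columns
#'   (e.g. ope, con, ext, agr, neu, swl, cesd).
#' @param n_perm,n_boot resampling sizes (defaults 10000 and 2000).
#' @param seed base integer seed.
#' @param alpha_sig,alpha_trend tier thresholds (defaults 0.01, 0.05).
#' @param bh also report Benjamini-Hochberg adjusted p values.
#' @return data.frame of class `affect_screen`, one row per scale x
#'   feature: `scale`, `feature`, `representation`, `n`, `r`, `ci_lo`,
#'   `ci_hi`, `r2`, `p`, `tier`, `n_perm`, `n_boot`, `seed` (+ `p_bh`).
#'   Pooled transition counts, when present on `features`, are carried
#'   in attribute `n_occ`.
#' @export
correlation_screen <- function(features, scales, n_perm = 10000,
                               n_boot = 2000, seed = 1,
                               alpha_sig = 0.01, alpha_trend = 0.05,
                               bh = FALSE) {
  if (!(0 < alpha_sig && alpha_sig < alpha_trend && alpha_trend < 1)) {
    stop("tier thresholds must satisfy 0 < alpha_sig < alpha_trend < 1")
  }
  if (!"user_id" %in% names(features) || !"user_id" %in% names(scales)) {
    stop("both tables need a user_id column")
  }
  only_f <- setdiff(features$user_id, scales$user_id)
  only_s <- setdiff(scales$user_id, features$user_id)
  if (length(only_f) || length(only_s)) {
    stop("user mismatch between tables; only in features: ",
         paste(only_f, collapse = ", "), "; only in scales: ",
         paste(only_s, collapse = ", "))
  }
  scales <- scales[match(features$user_id, scales$user_id), , drop = FALSE]
  fcols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                   c("total"))
  scols <- names(scales)[vapply(scales, is.numeric, logical(1))]
  representation <- attr(features, "representation")
  if (is.null(representation)) representation <- NA_character_

  rows <- vector("list", length(scols) * length(fcols))
  idx <- 0
  for (sc in scols) {
    for (fc in fcols) {
      idx <- idx + 1
      x <- scales[[sc]]; y <- features[[fc]]
      seed_i <- (as.numeric(seed) + idx) %% 2147483647
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[idx]] <- data.frame(
          scale = sc, feature = fc, representation = representation,
          n = length(x), r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          r2 = NA_real_, p = NA_real_, tier = "ns", n_perm = n_perm,
          n_boot = n_boot, seed = seed_i, stringsAsFactors = FALSE)
        next
      }
      pt <- perm_corr_test(x, y, n_perm = n_perm, seed = seed_i)
      ci <- bootstrap_ci(x, y, n_boot = n_boot, seed = seed_i)
      tier <- if (pt$p < alpha_sig) "significant"
              else if (pt$p < alpha_trend) "trend" else "ns"
      rows[[idx]] <- data.frame(
        scale = sc, feature = fc, representation = representation,
        n = pt$n, r = pt$r, ci_lo = ci$lo, ci_hi = ci$hi, r2 = pt$r^2,
        p = pt$p, tier = tier, n_perm = n_perm, n_boot = n_boot,
        seed = seed_i, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_occ") <- attr(features, "n_occ")
  attr(out, "alphas") <- c(alpha_sig, alpha_trend)
  class(out) <- c("affect_screen", "data.frame")
  out
}

#' @export
print.affect_screen <- function(x, ...) {
  needed <- c("scale", "feature", "representation", "n", "r", "ci_lo",
              "ci_hi", "r2", "p", "tier")
  if (!all(needed %in% names(x))) {
    # column subsets are plain tables
    return(print.data.frame(x, row.names = FALSE))
  }
  cat("Correlation screen:", nrow(x), "scale x feature pairs, n =",
      x$n[1], "\n")
  hits <- x[x$tier != "ns" & !is.na(x$p), , drop = FALSE]
  if (nrow(hits) == 0) {
    cat("no pairs below the trend threshold\n")
  } else {
    hits <- hits[order(hits$p), c("scale", "feature", "representation",
                                  "r", "ci_lo", "ci_hi", "r2", "p", "tier")]
    print.data.frame(format(hits, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.affect_screen <- function(object, ...) {
  tab <- table(factor(object$tier, levels = c("significant", "trend", "ns")))
  cat("tiers:", paste(names(tab), as.integer(tab), sep = "=",
                      collapse = ", "), "\n")
  print.affect_screen(object)
  invisible(object)
}

#' Reshape a screen into a scales-by-features matrix
#'
#' @param screen an `affect_screen`.
#' @param value which column to spread (default `"r"`).
#' @return matrix, scales as rows and features as columns, preceded by
#'   an `n_occ` row when pooled counts are available.
#' @export
screen_matrix <- function(screen, value = "r") {
  scales <- unique(screen$scale); feats <- unique(screen$feature)
  m <- matrix(NA_real_, nrow = length(scales), ncol = length(feats),
              dimnames = list(scales, feats))
  for (i in seq_len(nrow(screen))) {
    m[screen$scale[i], screen$feature[i]] <- screen[[value]][i]
  }
  n_occ <- attr(screen, "n_occ")
  if (!is.null(n_occ)) {
    top <- n_occ[intersect(feats, names(n_occ))]
    pad <- stats::setNames(rep(NA_real_, length(feats)), feats)
    pad[names(top)] <- top
    m <- rbind(n_occ = pad, m)
  }
  m
}
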