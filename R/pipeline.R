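#' End-to-end run configuration
#'
#' @param representations affect sequence representations to analyze.
#' @param n_perm,n_boot resampling sizes for the correlation screens.
#' @param seed base seed for all resampling.
#' @param alpha_sig,alpha_trend significance tiers (0.01 / 0.05).
#' @param hi,lo originality similarity thresholds.
#' @param potential_as_nonoriginal see [classify_post()].
#' @param cohort a [cohort_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(representations = c("post_with_silence",
                                           "post_without_silence",
                                           "day_level"),
                       n_perm = 10000, n_boot = 2000, seed = 1,
                       alpha_sig = 0.01, alpha_trend = 0.05,
                       hi = 0.96, lo = 0.92,
                       potential_as_nonoriginal = TRUE,
                       cohort = cohort_config()) {
  if (!(0 < alpha_sig && alpha_sig < alpha_trend && alpha_trend < 1)) {
    stop("tier thresholds must satisfy 0 < alpha_sig < alpha_trend < 1")
  }
  structure(list(representations = representations, n_perm = n_perm,
                 n_boot = n_boot, seed = seed, alpha_sig = alpha_sig,
                 alpha_trend = alpha_trend, hi = hi, lo = lo,
                 potential_as_nonoriginal = potential_as_nonoriginal,
                 cohort = cohort),
            class = "run_config")
}

.scale_cols <- c("ope", "con", "ext", "agr", "neu", "swl", "cesd")

#' Run the full analysis pipeline
#'
#' Applies the participant-selection funnel, builds the requested affect
#' sequence representations and their transition features, computes the
#' affect frequency features, labels post originality (gold labels if
#' present, otherwise the cosine-similarity classifier against `corpus`)
#' and builds originality transition features, then screens every
#' feature family against the seven psychometric scales with permutation
#' correlation tests, and finally computes the raw and
#' neuroticism-controlled (partial) correlation between each user's
#' non-original post share and CES-D.
#'
#' @param users user profiles ([read_users()] / [simulate_users()]).
#' @param posts posts table ([read_posts()] / [simulate_posts()]).
#' @param corpus optional source corpus for originality classification.
#' @param config a [run_config()].
#' @return object of class `affectseq_run`: list with `report`,
#'   `cohort`, `screens` (named list of `affect_screen` tables),
#'   `originality` (per-post classification or gold labels used),
#'   `mediation` (raw and partial correlation of non-original share vs
#'   CES-D), and `config`.
#' @export
run_pipeline <- function(users, posts, corpus = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sel <- select_cohort(users, posts, config$cohort)
  cohort <- sel$cohort
  if (nrow(cohort$users) == 0) {
    first_empty <- sel$report$stage[which(sel$report$n_out == 0)[1]]
    stop("empty cohort after stage '", first_empty, "'")
  }
  scales <- cohort$users[, c("user_id", .scale_cols)]

  screens <- list()
  for (rep_name in config$representations) {
    feat <- transition_features(cohort, rep_name)
    sc <- scales[scales$user_id %in% feat$user_id, , drop = FALSE]
    screens[[paste0("affect_", rep_name)]] <- correlation_screen(
      feat, sc, n_perm = config$n_perm, n_boot = config$n_boot,
      seed = config$seed, alpha_sig = config$alpha_sig,
      alpha_trend = config$alpha_trend)
  }
  freq <- affect_frequencies(cohort)
  screens$frequency <- correlation_screen(
    freq, scales[scales$user_id %in% freq$user_id, , drop = FALSE],
    n_perm = config$n_perm, n_boot = config$n_boot, seed = config$seed,
    alpha_sig = config$alpha_sig, alpha_trend = config$alpha_trend)

  originality <- NULL
  mediation <- NULL
  gold <- cohort$posts$originality_gold
  have_gold <- length(gold) > 0 && !all(is.na(gold))
  if (have_gold || !is.null(corpus)) {
    if (have_gold) {
      cohort$posts$originality <- ifelse(gold == "non_original", "N", "O")
      originality <- data.frame(post_id = seq_len(nrow(cohort$posts)),
                                binary_label = cohort$posts$originality,
                                source = "gold", stringsAsFactors = FALSE)
    } else {
      cls <- classify_posts(cohort$posts, corpus, hi = config$hi,
                            lo = config$lo,
                            potential_as_nonoriginal =
                              config$potential_as_nonoriginal)
      cohort$posts$originality <- cls$binary_label
      cls$source <- "classifier"
      originality <- cls
    }
    ofeat <- originality_features(cohort)
    osc <- scales[scales$user_id %in% ofeat$user_id, , drop = FALSE]
    screens$originality <- correlation_screen(
      ofeat, osc, n_perm = config$n_perm, n_boot = config$n_boot,
      seed = config$seed, alpha_sig = config$alpha_sig,
      alpha_trend = config$alpha_trend)
    osc_al <- osc[match(ofeat$user_id, osc$user_id), ]
    if (stats::sd(ofeat$n_share) > 0) {
      raw <- perm_corr_test(ofeat$n_share, osc_al$cesd,
                            n_perm = config$n_perm, seed = config$seed)
      partial <- partial_corr(ofeat$n_share, osc_al$cesd, osc_al$neu)
      mediation <- list(raw = raw, partial = partial)
    }
  }

  structure(list(report = sel$report, cohort = cohort, screens = screens,
                 originality = originality, mediation = mediation,
                 config = config),
            class = "affectseq_run")
}

#' @export
print.affectseq_run <- function(x, ...) {
  cat("== Affect transition analysis run ==\n")
  print(x$report)
  for (nm in names(x$screens)) {
    cat("\n--", nm, "--\n")
    print(x$screens[[nm]])
  }
  if (!is.null(x$mediation)) {
    cat("\n-- originality vs CES-D --\n")
    cat(sprintf("raw r = %.3f (perm p = %.4g)\n",
                x$mediation$raw$r, x$mediation$raw$p))
    cat(sprintf("partial r (given neu) = %.3f (p = %.4g)\n",
                x$mediation$partial$r, x$mediation$partial$p))
  }
  invisible(x)
}

#' @export
summary.affectseq_run <- function(object, ...) {
  hits <- do.call(rbind, lapply(names(object$screens), function(nm) {
    s <- object$screens[[nm]]
    h <- s[s$tier != "ns" & !is.na(s$p), , drop = FALSE]
    if (nrow(h)) cbind(screen = nm, as.data.frame(h)) else NULL
  }))
  cat("Tiered findings across", length(object$screens), "screens:\n")
  if (is.null(hits) || nrow(hits) == 0) {
    cat("(none below the trend threshold)\n")
  } else {
    hits <- hits[order(hits$p),
                 c("screen", "scale", "feature", "r", "p", "tier")]
    print.data.frame(format(hits, digits = 3), row.names = FALSE)
  }
  invisible(hits)
}

#' Write a run's tables to a directory
#'
#' Emits the funnel report, every correlation screen (long table plus a
#' scales-by-features r matrix), the per-post originality labels, and a
#' markdown summary whose every number is copied from the emitted
#' tables.
#'
#' @param run an `affectseq_run`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(run$report),
                   file.path(dir, "funnel_report.csv"), row.names = FALSE)
  for (nm in names(run$screens)) {
    s <- run$screens[[nm]]
    utils::write.csv(as.data.frame(s),
                     file.path(dir, paste0("screen_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(screen_matrix(s),
                     file.path(dir, paste0("matrix_", nm, ".csv")))
  }
  if (!is.null(run$originality)) {
    utils::write.csv(run$originality, file.path(dir, "originality.csv"),
                     row.names = FALSE)
  }
  lines <- c("# Analysis summary", "",
             sprintf("Cohort: %d users, %d posts.",
                     nrow(run$cohort$users), nrow(run$cohort$posts)), "")
  for (nm in names(run$screens)) {
    s <- run$screens[[nm]]
    h <- s[s$tier != "ns" & !is.na(s$p), , drop = FALSE]
    lines <- c(lines, sprintf("## %s", nm), "")
    if (nrow(h) == 0) {
      lines <- c(lines, "No tiered findings.", "")
    } else {
      lines <- c(lines, sprintf(
        "- %s x %s: r = %.3f, 95%% CI (%.3f, %.3f), p = %.4g [%s]",
        h$scale, h$feature, h$r, h$ci_lo, h$ci_hi, h$p, h$tier), "")
    }
  }
  if (!is.null(run$mediation)) {
    lines <- c(lines, "## Originality vs CES-D", "",
               sprintf("- raw r = %.3f, perm p = %.4g",
                       run$mediation$raw$r, run$mediation$raw$p),
               sprintf("- partial r given neuroticism = %.3f, p = %.4g",
                       run$mediation$partial$r, run$mediation$partial$p), "")
  }
  writeLines(lines, file.path(dir, "summary.md"))
  invisible(dir)
}
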