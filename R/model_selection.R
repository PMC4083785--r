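#' Best-account Bayes factors for one fitted data structure
#'
#' The strength of evidence for a bias is the maximum likelihood over the
#' whole grid (where the bias is free to act) divided by the maximum
#' likelihood over the family in which the bias is switched off.  Because
#' the restricted family is a subset of the grid, each ratio is at least
#' 1.  Three ratios are computed:
#' \describe{
#'   \item{bf_content}{full grid vs the no-content family (\code{b = 0}).}
#'   \item{bf_coordination}{full grid vs the no-coordination family
#'     (\code{c = 0}).}
#'   \item{bf_any}{full grid vs the drift family
#'     (\code{b = 0} and \code{c = 0}): evidence that some bias, content
#'     or coordination, is at work.}
#' }
#' For completeness a non-nested ratio \code{bf_both_vs_drift} — the best
#' model using both biases simultaneously (\code{b > 0} and
#' \code{c != 0}) against drift — is also reported; unlike the others it
#' can fall below 1.
#'
#' The default evidence threshold is 19 (in keeping with a 0.05
#' significance criterion; 20 corresponds to Kass and Raftery's "strong
#' support").
#'
#' @param fit a [grid_search()] result.
#' @param threshold evidence criterion carried along for
#'   [classify_bias()] (default 19).
#' @return an object of class \code{"bayes_factors"}: a list with the
#'   four ratios, the threshold, and the structure's identifiers.
#' @export
bayes_factors <- function(fit, threshold = 19) {
  stopifnot(inherits(fit, "fit_result"))
  if (threshold <= 0) stop("evidence threshold must be positive")
  fm <- fit$family_maxima
  need <- c("unconstrained", "no_content", "no_coordination", "drift")
  absent <- need[is.na(fm[need])]
  if (length(absent) > 0) {
    stop("grid lacks the family required for Bayes factors: ",
         paste(absent, collapse = ", "),
         " (include b = 0 and c = 0 levels)")
  }
  structure(
    list(
      society_id = fit$society_id, concept_id = fit$concept_id,
      bf_content = exp(fm[["unconstrained"]] - fm[["no_content"]]),
      bf_coordination = exp(fm[["unconstrained"]] - fm[["no_coordination"]]),
      bf_any = exp(fm[["unconstrained"]] - fm[["drift"]]),
      bf_both_vs_drift = if (is.na(fm[["both_biased"]])) NA_real_ else
        exp(fm[["both_biased"]] - fm[["drift"]]),
      threshold = threshold
    ),
    class = "bayes_factors"
  )
}

#' @export
print.bayes_factors <- function(x, ...) {
  cat(sprintf(
    "<bayes_factors %s/%s: content=%.3g coordination=%.3g any=%.3g (threshold %g) -> %s>\n",
    x$society_id, x$concept_id, x$bf_content, x$bf_coordination, x$bf_any,
    x$threshold, classify_bias(x)
  ))
  invisible(x)
}

BIAS_CATEGORIES <- c("content_only", "coordination_only", "both",
                     "indeterminate_bias", "drift_consistent")

#' Classify a data structure by the biases its data demand
#'
#' Applies the evidence threshold to the best-account Bayes factors:
#' \describe{
#'   \item{content_only}{significant evidence for content bias but not
#'     coordination bias.}
#'   \item{coordination_only}{the reverse.}
#'   \item{both}{significant evidence for each bias individually.}
#'   \item{indeterminate_bias}{significant evidence that some bias is
#'     present (\code{bf_any}), but insufficient evidence to pinpoint
#'     which.}
#'   \item{drift_consistent}{no significant evidence against the neutral
#'     drift account.}
#' }
#'
#' @param bf a [bayes_factors()] object.
#' @param threshold evidence criterion; defaults to the one stored in
#'   \code{bf}.
#' @return a length-1 factor with levels \code{content_only},
#'   \code{coordination_only}, \code{both}, \code{indeterminate_bias},
#'   \code{drift_consistent}.
#' @export
classify_bias <- function(bf, threshold = bf$threshold) {
  if (threshold <= 0) stop("evidence threshold must be positive")
  con <- bf$bf_content >= threshold
  coo <- bf$bf_coordination >= threshold
  cat_name <- if (con && coo) {
    "both"
  } else if (con) {
    "content_only"
  } else if (coo) {
    "coordination_only"
  } else if (bf$bf_any >= threshold) {
    "indeterminate_bias"
  } else {
    "drift_consistent"
  }
  factor(cat_name, levels = BIAS_CATEGORIES)
}

#' Summarize fits and classifications over a corpus
#'
#' Aggregates per-structure fits the way the single-structure analyses
#' are usually reported: histograms of the best-fit memory size,
#' coordination bias and content bias; counts and proportions of the
#' bias categories; median Bayes factors; and per-generation
#' variant-diversity statistics (mean, sd, max, min of the number of
#' distinct variant types at each generation, across structures).
#'
#' @param corp the [corpus()] the fits belong to, or \code{NULL} to skip
#'   the diversity statistics (e.g. when only fit records are at hand).
#' @param fits list of [grid_search()] results, aligned with
#'   \code{corp$data_structures}.
#' @param bfs optional list of [bayes_factors()] aligned with
#'   \code{fits}; computed from \code{fits} if omitted.
#' @param threshold evidence criterion for classification (default 19).
#' @return an object of class \code{"corpus_summary"}: a list with
#'   components \code{n}, \code{m_hist}, \code{c_hist}, \code{b_hist}
#'   (named count vectors over grid levels), \code{category_counts},
#'   \code{category_proportions}, \code{median_bf} (named vector),
#'   \code{diversity} (a 4 x G matrix of mean/sd/max/min distinct-type
#'   counts per generation) and \code{threshold}.
#' @export
summarize_corpus <- function(corp, fits, bfs = NULL, threshold = 19) {
  n <- length(fits)
  if (n == 0) stop("cannot summarize an empty corpus")
  if (!is.null(corp)) {
    stopifnot(inherits(corp, "corpus"))
    if (length(corp$data_structures) != n) {
      stop("corpus and fit list have different lengths")
    }
  }
  if (is.null(bfs)) bfs <- lapply(fits, bayes_factors, threshold = threshold)
  if (length(bfs) != n) stop("fit and Bayes-factor lists have different lengths")

  ml_m <- vapply(fits, function(f) f$ml$m, numeric(1))
  ml_c <- vapply(fits, function(f) f$ml$c, numeric(1))
  ml_b <- vapply(fits, function(f) f$ml$b, numeric(1))
  grid <- fits[[1]]$grid
  hist_over <- function(x, levels) {
    table(factor(as.character(x), levels = as.character(levels)))
  }
  cats <- factor(vapply(bfs, function(b) {
    as.character(classify_bias(b, threshold))
  }, character(1)), levels = BIAS_CATEGORIES)

  diversity <- NULL
  if (!is.null(corp)) {
    gmax <- max(vapply(corp$data_structures, function(d) d$n_generations,
                       numeric(1)))
    div <- t(vapply(corp$data_structures, function(d) {
      tr <- diversity_trajectory(d)
      c(tr, rep(NA_real_, gmax - length(tr)))
    }, numeric(gmax)))
    diversity <- rbind(
      mean = apply(div, 2, mean, na.rm = TRUE),
      sd = apply(div, 2, stats::sd, na.rm = TRUE),
      max = apply(div, 2, max, na.rm = TRUE),
      min = apply(div, 2, min, na.rm = TRUE)
    )
    colnames(diversity) <- paste0("G", seq_len(gmax))
  }

  structure(
    list(
      n = n,
      m_hist = hist_over(ml_m, grid$m_levels),
      c_hist = hist_over(ml_c, grid$c_levels),
      b_hist = hist_over(ml_b, grid$b_levels),
      category_counts = table(cats),
      category_proportions = table(cats) / n,
      median_bf = c(
        content = stats::median(vapply(bfs, `[[`, numeric(1), "bf_content")),
        coordination = stats::median(vapply(bfs, `[[`, numeric(1),
                                            "bf_coordination")),
        any = stats::median(vapply(bfs, `[[`, numeric(1), "bf_any"))
      ),
      diversity = diversity,
      threshold = threshold
    ),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus summary (%d data structures, evidence threshold %g)\n",
              x$n, x$threshold))
  cat("\nBest-fit memory size:\n"); print(x$m_hist)
  cat("\nBest-fit coordination bias:\n"); print(x$c_hist)
  cat("\nBest-fit content bias:\n"); print(x$b_hist)
  cat("\nBias categories:\n")
  tab <- cbind(count = as.integer(x$category_counts),
               proportion = round(as.numeric(x$category_proportions), 3))
  rownames(tab) <- names(x$category_counts)
  print(tab)
  cat("\nMedian Bayes factors:\n"); print(round(x$median_bf, 2))
  if (!is.null(x$diversity)) {
    cat("\nVariant types per generation:\n"); print(round(x$diversity, 2))
  }
  invisible(x)
}

#' Plot a corpus summary
#'
#' Four base-graphics panels: histograms of the best-fit memory size,
#' coordination bias and content bias, and the bias-category counts.
#'
#' @param x a [summarize_corpus()] result.
#' @param ... passed to [graphics::barplot()].
#' @return \code{x}, invisibly.
#' @export
plot.corpus_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$m_hist, main = "memory size m", ylab = "structures", ...)
  graphics::barplot(x$c_hist, main = "coordination bias c", las = 2, ...)
  graphics::barplot(x$b_hist, main = "content bias b", las = 2, ...)
  graphics::barplot(x$category_counts, main = "bias category", las = 2, ...)
  invisible(x)
}
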