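#' A participant's interaction history at a decision point
#'
#' @param ego character vector of the participant's own past productions
#'   (E-entries), oldest first.
#' @param allo character vector of witnessed partner productions
#'   (A-entries), oldest first.
#' @return an object of class \code{"history"}.
#' @export
history <- function(ego = character(0), allo = character(0)) {
  structure(list(ego = as.character(ego), allo = as.character(allo)),
            class = "history")
}

#' A point in the choice-model parameter space
#'
#' @param m memory size: the model remembers at most the last \code{m/2}
#'   ego entries and the last \code{m/2} allo entries.  Must be a positive
#'   even integer.
#' @param c coordination bias in \[-1, 1\]: -1 fully egocentric (only own
#'   past productions are copied), +1 fully allocentric (only partners'
#'   productions), 0 unbiased.  Internally reparameterized as
#'   \code{gamma = (c + 1) / 2}, the weight on the allo component.
#' @param b content-bias level in \[0, 1\]: how strongly the target variant
#'   \code{tau} is preferred once it has entered memory.
#' @param tau the target variant label of the content bias; required when
#'   \code{b > 0}.
#' @param mu mutation rate in \[0, 1\]: the probability mass given to a
#'   flat distribution over the variant universe.
#' @return an object of class \code{"parameter_setting"}.
#' @examples
#' parameter_setting(m = 2, c = -0.8, b = 0.6, tau = "V1")
#' @export
parameter_setting <- function(m, c = 0, b = 0, tau = NULL, mu = 0.02) {
  if (length(m) != 1 || is.na(m) || m <= 0 || m %% 2 != 0) {
    stop("memory size m must be a positive even integer, got ", m)
  }
  if (c < -1 || c > 1) stop("coordination bias c must lie in [-1, 1]")
  if (b < 0 || b > 1) stop("content-bias level b must lie in [0, 1]")
  if (mu < 0 || mu > 1) stop("mutation rate mu must lie in [0, 1]")
  if (b > 0 && (is.null(tau) || !nzchar(tau))) {
    stop("a content bias (b > 0) requires a target variant tau")
  }
  structure(
    list(m = as.integer(m), c = c, b = b,
         tau = if (is.null(tau)) NULL else as.character(tau), mu = mu),
    class = "parameter_setting"
  )
}

#' @export
print.parameter_setting <- function(x, ...) {
  cat(sprintf("<parameter_setting m=%d c=%g b=%g tau=%s mu=%g>\n",
              x$m, x$c, x$b, if (is.null(x$tau)) "-" else x$tau, x$mu))
  invisible(x)
}

#' Truncate a history to its memory windows
#'
#' Keeps the last \code{m/2} ego entries and the last \code{m/2} allo
#' entries of a history; everything older is forgotten.
#'
#' @param h a [history()].
#' @param m memory size (positive even integer).
#' @return list with components \code{ego} and \code{allo}, each a
#'   chronologically ordered character vector of at most \code{m/2}
#'   labels.
#' @export
memory_windows <- function(h, m) {
  if (length(m) != 1 || is.na(m) || m <= 0 || m %% 2 != 0) {
    stop("memory size m must be a positive even integer, got ", m)
  }
  half <- m %/% 2
  le <- length(h$ego)
  la <- length(h$allo)
  list(
    ego = if (le > half) h$ego[(le - half + 1L):le] else h$ego,
    allo = if (la > half) h$allo[(la - half + 1L):la] else h$allo
  )
}

#' Relative frequencies of labels in a memory window
#'
#' @param window character vector of labels.
#' @return named numeric vector of probabilities over the distinct labels
#'   in \code{window} (in order of first appearance).  An empty window
#'   yields an empty named vector — the sentinel that
#'   [combine_memory()] resolves.
#' @export
relative_freq <- function(window) {
  if (length(window) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  u <- unique(window)
  counts <- tabulate(match(window, u), nbins = length(u))
  stats::setNames(counts / length(window), u)
}

#' Mix the egocentric and allocentric memory distributions
#'
#' Returns \code{(1 - gamma) * ego_dist + gamma * allo_dist} with
#' \code{gamma = (c + 1) / 2}.  If exactly one of the two distributions is
#' empty (its window held no entries), all weight goes to the non-empty
#' one, keeping the result normalized.
#'
#' @param ego_dist,allo_dist named probability vectors as returned by
#'   [relative_freq()]; one (not both) may be empty.
#' @param c coordination bias in \[-1, 1\].
#' @return named numeric probability vector over the union of the two
#'   supports.
#' @export
combine_memory <- function(ego_dist, allo_dist, c) {
  if (length(ego_dist) == 0 && length(allo_dist) == 0) {
    stop("cannot combine two empty memory distributions")
  }
  if (length(ego_dist) == 0) return(allo_dist)
  if (length(allo_dist) == 0) return(ego_dist)
  gamma <- (c + 1) / 2
  labels <- unique(c(names(ego_dist), names(allo_dist)))
  e <- numeric(length(labels))
  e[match(names(ego_dist), labels)] <- ego_dist
  a <- numeric(length(labels))
  a[match(names(allo_dist), labels)] <- allo_dist
  stats::setNames((1 - gamma) * e + gamma * a, labels)
}

#' Effective content-bias coefficient
#'
#' The content bias is only effective when its target is available in
#' memory: a participant must have produced or witnessed a variant before
#' they can prefer it.  The effective coefficient is therefore \code{b}
#' when \code{tau} occurs in either memory window and 0 otherwise.
#'
#' @param tau target variant label.
#' @param b content-bias level in \[0, 1\].
#' @param ego_window,allo_window memory windows as returned by
#'   [memory_windows()].
#' @return \code{b} or \code{0}.
#' @export
effective_beta <- function(tau, b, ego_window, allo_window) {
  if (b < 0 || b > 1) stop("content-bias level b must lie in [0, 1]")
  if (b > 0 && tau %in% c(ego_window, allo_window)) b else 0
}

#' Probability distribution over a participant's next variant
#'
#' The full choice model.  Writing \code{f_E} and \code{f_A} for the
#' relative-frequency distributions of the ego and allo memory windows
#' (last \code{m/2} entries each), \code{gamma = (c + 1) / 2}, and
#' \code{beta} for the effective content bias ([effective_beta()]), the
#' probability of producing variant \code{x} is
#'
#' \deqn{P(x) = (1 - \mu)\,[(1 - \beta)\,((1-\gamma) f_E(x) + \gamma f_A(x))
#'   + \beta\,\delta_\tau(x)] + \mu \, \phi(x),}
#'
#' where \eqn{\delta_\tau} is the point mass on the target variant and
#' \eqn{\phi} the flat distribution over the variant universe.  If one
#' memory window is empty, the frequency mixture collapses to the
#' non-empty window.  Setting \code{b = 0, c = 0} recovers the neutral
#' drift model (random copying from memory plus mutation).
#'
#' @param h a [history()]; at least one of \code{ego}/\code{allo} must be
#'   non-empty (a first-generation choice has no history and is not
#'   modelled).
#' @param p a [parameter_setting()].
#' @param universe character vector of all possible variant labels; must
#'   contain every label in the memory windows.
#' @return an object of class \code{"choice_distribution"}: a named
#'   numeric probability vector over \code{universe}, summing to 1.
#' @examples
#' h <- history(ego = c("red", "red"), allo = c("blue", "red"))
#' p <- parameter_setting(m = 4, c = 0, b = 0.4, tau = "blue")
#' choice_distribution(h, p, universe = c("red", "blue", "green", "yellow"))
#' @export
choice_distribution <- function(h, p, universe) {
  universe <- as.character(universe)
  if (length(universe) == 0) stop("variant universe must be non-empty")
  if (anyDuplicated(universe) > 0) stop("variant universe has duplicate labels")
  win <- memory_windows(h, p$m)
  if (length(win$ego) == 0 && length(win$allo) == 0 && p$mu < 1) {
    stop("empty history: the choice model does not cover first-generation choices")
  }
  mem <- c(win$ego, win$allo)
  mem_idx <- match(mem, universe)
  if (anyNA(mem_idx)) {
    stop("memory contains label(s) outside the universe: ",
         paste(setdiff(mem, universe), collapse = ", "))
  }
  K <- length(universe)
  prob <- rep(p$mu / K, K)
  names(prob) <- universe
  if (p$mu < 1) {
    base <- combine_memory(relative_freq(win$ego), relative_freq(win$allo),
                           p$c)
    beta <- if (p$b > 0) effective_beta(p$tau, p$b, win$ego, win$allo) else 0
    q <- (1 - beta) * base
    if (beta > 0) {
      q[p$tau] <- (if (p$tau %in% names(q)) q[[p$tau]] else 0) + beta
    }
    qi <- match(names(q), universe)
    prob[qi] <- prob[qi] + (1 - p$mu) * q
  }
  structure(prob, class = "choice_distribution")
}

#' @export
print.choice_distribution <- function(x, digits = 4, ...) {
  cat("<choice_distribution>\n")
  print(round(unclass(x), digits))
  invisible(x)
}
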