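#' Reconstruct the choice events of a data structure
#'
#' Turns the production grid back into the sequence of modelled decisions.
#' One event is produced for every production in generations 2..G
#' (generation 1 is excluded: a first production has no history, so its
#' variant choice cannot be predicted).  At generation \code{g},
#' participant \code{p}'s history holds
#' \itemize{
#'   \item ego entries: \code{p}'s own productions at generations
#'     \code{1..g-1};
#'   \item allo entries: the production of \code{p}'s partner in each of
#'     generations \code{1..g-1} — partners rotate, so this is a different
#'     participant each generation — plus, if and only if \code{p} drew
#'     second in their current pair, the partner's generation-\code{g}
#'     production.
#' }
#' Participants witness only their own partner's productions, never those
#' of other pairs (interaction is pairwise and anonymous).
#'
#' @param d a [data_structure()].
#' @return list of events; each event is a list with elements
#'   \code{generation}, \code{participant}, \code{produced} (label) and
#'   \code{history} (a [history()]).  For the default 8 x 7 design there
#'   are 48 events.
#' @export
build_choice_events <- function(d) {
  pt <- partner_tables(d)
  events <- vector("list", d$n_participants * (d$n_generations - 1))
  k <- 0L
  for (g in seq_len(d$n_generations)[-1]) {
    for (p in seq_len(d$n_participants)) {
      prior <- seq_len(g - 1)
      ego <- d$productions[prior, p]
      allo <- d$productions[cbind(prior, pt$partner[prior, p])]
      if (pt$second[g, p]) {
        allo <- c(allo, d$productions[g, pt$partner[g, p]])
      }
      k <- k + 1L
      events[[k]] <- list(
        generation = g, participant = p,
        produced = d$productions[g, p],
        history = history(ego = ego, allo = allo)
      )
    }
  }
  events
}

# per-generation partner index and drew-second flag, from the schedule
partner_tables <- function(d) {
  sched <- d$schedule
  partner <- matrix(NA_integer_, d$n_generations, d$n_participants)
  second <- matrix(FALSE, d$n_generations, d$n_participants)
  for (i in seq_len(nrow(sched))) {
    g <- sched$generation[i]
    a <- sched$first[i]
    b <- sched$second[i]
    partner[g, a] <- b
    partner[g, b] <- a
    second[g, b] <- TRUE
  }
  list(partner = partner, second = second)
}

#' Log-likelihood of a data structure under one parameter setting
#'
#' The likelihood of a data structure is the product over its choice
#' events ([build_choice_events()]; generation 1 is excluded) of the
#' probability the choice model assigns to the variant actually produced,
#' given the producer's history at that moment.  The flat mutation
#' component ranges over the structure's variant universe.
#'
#' With \code{mu = 0} an unexplainable choice has probability 0 and the
#' function returns \code{-Inf} (a sentinel, not an error): such settings
#' lose every model comparison.
#'
#' @param d a [data_structure()].
#' @param p a [parameter_setting()].
#' @return the log-likelihood (a scalar; \code{0} when every choice was
#'   certain, \code{-Inf} when some choice was impossible).
#' @export
data_structure_loglik <- function(d, p) {
  events <- build_choice_events(d)
  sum(vapply(events, function(e) {
    log(choice_distribution(e$history, p, d$universe)[[e$produced]])
  }, numeric(1)))
}

#' The exhaustive parameter grid
#'
#' Defaults reproduce the standard design: content-bias level \code{b}
#' from 0 to 1 in steps of 0.1 (11 levels), coordination bias \code{c}
#' from -1 to 1 in steps of 0.2 (11 levels), memory size \code{m} in
#' \{2, 4, 6, 8\}, mutation fixed at \code{mu = 0.02} — 484 points in
#' (m, c, b) space, with the content-bias target \code{tau} profiled over
#' up to 8 candidate variants at each point.
#'
#' @param m_levels memory sizes (positive even integers).
#' @param c_levels coordination-bias levels in \[-1, 1\].
#' @param b_levels content-bias levels in \[0, 1\].
#' @param mu mutation rate, fixed across the grid.
#' @param max_tau_candidates cap on the number of content-bias target
#'   candidates considered per structure (the most frequent variants).
#' @return an object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(m_levels = c(2L, 4L, 6L, 8L),
                      c_levels = round(seq(-1, 1, by = 0.2), 10),
                      b_levels = round(seq(0, 1, by = 0.1), 10),
                      mu = 0.02,
                      max_tau_candidates = 8L) {
  if (any(m_levels <= 0 | m_levels %% 2 != 0)) {
    stop("all memory sizes must be positive even integers")
  }
  if (any(c_levels < -1 | c_levels > 1)) stop("c levels must lie in [-1, 1]")
  if (any(b_levels < 0 | b_levels > 1)) stop("b levels must lie in [0, 1]")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  structure(
    list(m_levels = as.integer(m_levels), c_levels = c_levels,
         b_levels = b_levels, mu = mu,
         max_tau_candidates = as.integer(max_tau_candidates)),
    class = "grid_spec"
  )
}

#' Candidate content-bias targets for a data structure
#'
#' All variant types attested in the grid, capped at the most frequent
#' (frequency over all productions; ties broken by order of first
#' appearance, scanning generation by generation).
#'
#' @param d a [data_structure()].
#' @param max_candidates cap on the number of candidates (default 8).
#' @return character vector of candidate target labels.
#' @export
tau_candidates <- function(d, max_candidates = 8L) {
  labs <- attested_labels(d$productions)  # order of first appearance
  counts <- vapply(labs, function(l) sum(d$productions == l), numeric(1))
  labs <- labs[order(-counts, seq_along(labs))]
  labs[seq_len(min(length(labs), max_candidates))]
}

#' Exhaustive maximum-likelihood grid search for one data structure
#'
#' Evaluates the data-structure log-likelihood at every (m, c, b) grid
#' point.  At points with \code{b > 0} the content-bias target \code{tau}
#' is profiled out: the likelihood is maximized over the structure's
#' candidate targets ([tau_candidates()]) and the winning target is
#' reported alongside.  At \code{b = 0} the target is inert and reported
#' as \code{NA}.
#'
#' Ties in the argmax are broken toward the drift model: points are
#' ranked by \code{b} ascending, then \code{|c|} ascending (negative
#' before positive at equal magnitude), then \code{m} ascending, and the
#' first point attaining the maximum (within 1e-10) wins.  This gives a
#' deterministic, conservative attribution of bias.
#'
#' @param d a [data_structure()].
#' @param grid a [grid_spec()].
#' @param keep_tau_table if \code{TRUE}, also return the full per-target
#'   log-likelihood table (one row per (m, c, b, tau) combination).
#' @return an object of class \code{"fit_result"}: a list with
#'   \describe{
#'     \item{table}{data frame with one row per (m, c, b) grid point:
#'       \code{m}, \code{c}, \code{b}, \code{tau} (winning target or NA),
#'       \code{loglik}.}
#'     \item{ml}{the maximum-likelihood [parameter_setting()], with its
#'       \code{loglik} attached.}
#'     \item{family_maxima}{named vector of maximum log-likelihoods within
#'       the constrained families \code{unconstrained}, \code{no_content}
#'       (b = 0), \code{no_coordination} (c = 0), \code{drift}
#'       (b = 0 and c = 0), \code{content} (b > 0), \code{coordination}
#'       (c != 0) and \code{both_biased} (b > 0 and c != 0); \code{NA} for
#'       families absent from the grid.}
#'     \item{tau_candidates}{the candidate targets used.}
#'     \item{n_points}{number of (m, c, b) points evaluated (484 for the
#'       default grid).}
#'   }
#' @export
grid_search <- function(d, grid = grid_spec(), keep_tau_table = FALSE) {
  stopifnot(inherits(d, "data_structure"))
  lab <- d$universe
  K <- length(lab)
  mu <- grid$mu
  events <- build_choice_events(d)
  n_ev <- length(events)
  if (n_ev == 0) stop("data structure has no choice events (single generation)")
  prod_int <- vapply(events, function(e) match(e$produced, lab), integer(1))
  ego_int <- lapply(events, function(e) match(e$history$ego, lab))
  allo_int <- lapply(events, function(e) match(e$history$allo, lab))

  taus <- tau_candidates(d, grid$max_tau_candidates)
  tau_int <- match(taus, lab)
  n_tau <- length(taus)
  eq <- outer(prod_int, tau_int, "==")  # event produced the candidate target?

  n_pts <- length(grid$m_levels) * length(grid$c_levels) * length(grid$b_levels)
  res <- data.frame(m = integer(n_pts), c = numeric(n_pts), b = numeric(n_pts),
                    tau = character(n_pts), loglik = numeric(n_pts),
                    stringsAsFactors = FALSE)
  tau_rows <- if (keep_tau_table) vector("list", n_pts) else NULL
  k <- 0L
  for (m in grid$m_levels) {
    half <- m %/% 2L
    fE <- numeric(n_ev); fA <- numeric(n_ev)
    emptyE <- logical(n_ev); emptyA <- logical(n_ev)
    present <- matrix(FALSE, n_ev, max(n_tau, 1L))
    for (i in seq_len(n_ev)) {
      ew <- utils::tail(ego_int[[i]], half)
      aw <- utils::tail(allo_int[[i]], half)
      emptyE[i] <- length(ew) == 0L
      emptyA[i] <- length(aw) == 0L
      fE[i] <- if (emptyE[i]) 0 else mean(ew == prod_int[i])
      fA[i] <- if (emptyA[i]) 0 else mean(aw == prod_int[i])
      if (n_tau > 0) present[i, seq_len(n_tau)] <- tau_int %in% c(ew, aw)
    }
    for (cc in grid$c_levels) {
      gam <- (cc + 1) / 2
      wE <- ifelse(emptyE, 0, ifelse(emptyA, 1, 1 - gam))
      wA <- ifelse(emptyA, 0, ifelse(emptyE, 1, gam))
      base <- wE * fE + wA * fA
      for (b in grid$b_levels) {
        k <- k + 1L
        if (b <= 0 || n_tau == 0) {
          ll <- sum(log((1 - mu) * base + mu / K))
          win_tau <- NA_character_
          if (keep_tau_table) {
            tau_rows[[k]] <- data.frame(m = m, c = cc, b = b,
                                        tau = NA_character_, loglik = ll,
                                        stringsAsFactors = FALSE)
          }
        } else {
          lls <- numeric(n_tau)
          for (t in seq_len(n_tau)) {
            beta <- b * present[, t]
            pr <- (1 - mu) * ((1 - beta) * base + beta * eq[, t]) + mu / K
            lls[t] <- sum(log(pr))
          }
          t_best <- which.max(lls)  # first max: candidate order breaks ties
          ll <- lls[t_best]
          win_tau <- taus[t_best]
          if (keep_tau_table) {
            tau_rows[[k]] <- data.frame(m = m, c = cc, b = b, tau = taus,
                                        loglik = lls, stringsAsFactors = FALSE)
          }
        }
        res$m[k] <- m; res$c[k] <- cc; res$b[k] <- b
        res$tau[k] <- win_tau; res$loglik[k] <- ll
      }
    }
  }

  # drift-closest argmax: b asc, |c| asc (negative first), m asc
  pref <- order(res$b, abs(res$c), res$c, res$m)
  top <- pref[res$loglik[pref] >= max(res$loglik) - 1e-10][1]
  ml <- parameter_setting(m = res$m[top], c = res$c[top], b = res$b[top],
                          tau = if (is.na(res$tau[top])) NULL else res$tau[top],
                          mu = mu)
  ml$loglik <- res$loglik[top]

  fam <- function(sel) if (any(sel)) max(res$loglik[sel]) else NA_real_
  is_b0 <- res$b <= 1e-12
  is_c0 <- abs(res$c) <= 1e-9
  family_maxima <- c(
    unconstrained = max(res$loglik),
    no_content = fam(is_b0),
    no_coordination = fam(is_c0),
    drift = fam(is_b0 & is_c0),
    content = fam(!is_b0),
    coordination = fam(!is_c0),
    both_biased = fam(!is_b0 & !is_c0)
  )

  structure(
    list(society_id = d$society_id, concept_id = d$concept_id,
         table = res, ml = ml, family_maxima = family_maxima,
         tau_candidates = taus, n_points = n_pts, grid = grid,
         tau_table = if (keep_tau_table) do.call(rbind, tau_rows) else NULL),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result %s/%s: %d grid points; ML m=%d c=%g b=%g tau=%s (loglik %.3f)>\n",
    x$society_id, x$concept_id, x$n_points,
    x$ml$m, x$ml$c, x$ml$b,
    if (is.null(x$ml$tau)) "-" else x$ml$tau, x$ml$loglik
  ))
  invisible(x)
}
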