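# Independent brute-force implementations of the choice model and the
# data-structure likelihood, written as direct per-label arithmetic.
# These deliberately share no code with the package internals.

oracle_choice_prob <- function(ego, allo, m, cc, b, tau, mu, universe) {
  half <- m / 2
  ew <- if (length(ego) > half) ego[seq(length(ego) - half + 1, length(ego))] else ego
  aw <- if (length(allo) > half) allo[seq(length(allo) - half + 1, length(allo))] else allo
  if (length(ew) == 0 && length(aw) == 0) stop("oracle: empty history")
  gam <- (cc + 1) / 2
  K <- length(universe)
  in_mem <- !is.null(tau) && (tau %in% ew || tau %in% aw)
  beta <- if (b > 0 && in_mem) b else 0
  vapply(universe, function(x) {
    base <- if (length(ew) == 0) {
      sum(aw == x) / length(aw)
    } else if (length(aw) == 0) {
      sum(ew == x) / length(ew)
    } else {
      (1 - gam) * sum(ew == x) / length(ew) + gam * sum(aw == x) / length(aw)
    }
    q <- (1 - beta) * base + beta * as.numeric(!is.null(tau) && x == tau)
    (1 - mu) * q + mu / K
  }, numeric(1))
}

# event-by-event likelihood: walks the schedule itself rather than using
# build_choice_events()
oracle_structure_loglik <- function(d, m, cc, b, tau, mu) {
  sched <- as.data.frame(d$schedule)
  n <- d$n_participants
  G <- d$n_generations
  ll <- 0
  for (g in 2:G) {
    for (p in 1:n) {
      ego <- d$productions[1:(g - 1), p]
      allo <- character(0)
      drew_second_now <- FALSE
      partner_now <- NA
      for (t in 1:g) {
        row <- sched[sched$generation == t &
                       (sched$first == p | sched$second == p), ]
        partner <- if (row$first == p) row$second else row$first
        if (t < g) {
          allo <- c(allo, d$productions[t, partner])
        } else {
          drew_second_now <- row$second == p
          partner_now <- partner
        }
      }
      if (drew_second_now) allo <- c(allo, d$productions[g, partner_now])
      pr <- oracle_choice_prob(ego, allo, m, cc, b, tau, mu, d$universe)
      ll <- ll + log(pr[[d$productions[g, p]]])
    }
  }
  ll
}

# nested-loop grid search over explicit (m, c, b, tau) combinations,
# profiling tau by an explicit max
oracle_grid_table <- function(d, m_levels, c_levels, b_levels, taus, mu) {
  rows <- list()
  k <- 0
  for (m in m_levels) {
    for (cc in c_levels) {
      for (b in b_levels) {
        ll <- if (b == 0) {
          oracle_structure_loglik(d, m, cc, 0, NULL, mu)
        } else {
          max(vapply(taus, function(tt) {
            oracle_structure_loglik(d, m, cc, b, tt, mu)
          }, numeric(1)))
        }
        k <- k + 1
        rows[[k]] <- data.frame(m = m, c = cc, b = b, loglik = ll)
      }
    }
  }
  do.call(rbind, rows)
}
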