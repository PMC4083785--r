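#' Round-robin pairing schedule
#'
#' Builds a schedule by the standard circle method: one participant stays
#' fixed while the others rotate, so that over \code{n - 1} generations
#' every unordered pair of the \code{n} participants meets exactly once.
#' With \code{g < n - 1} the rotation is truncated (no pair repeats; not
#' all pairs meet); with \code{g > n - 1} the rotation restarts, so pairs
#' repeat only after every pair has met.  Which member of each pair draws
#' first is assigned uniformly at random per generation.
#'
#' @param n number of participants (even).
#' @param g number of generations.
#' @param seed optional integer seed for the draw-order randomization.
#' @return a [pairing_schedule()] that passes [validate_schedule()].
#' @examples
#' sched <- round_robin_schedule(8, 7, seed = 1)
#' validate_schedule(sched, 8, 7)  # character(0)
#' @export
round_robin_schedule <- function(n, g, seed = NULL) {
  if (n %% 2 != 0 || n < 2) stop("participant count must be even and >= 2")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", g * n / 2)
  k <- 0L
  for (r in seq_len(g)) {
    # circle method: participant n fixed, 1..n-1 rotate
    a <- (r - 1) %% (n - 1) + 1
    pairs <- rbind(c(n, a))
    for (i in seq_len(n / 2 - 1)) {
      pairs <- rbind(pairs, c(
        (r - 1 + i) %% (n - 1) + 1,
        (r - 1 - i) %% (n - 1) + 1
      ))
    }
    for (j in seq_len(nrow(pairs))) {
      k <- k + 1L
      flip <- stats::runif(1) < 0.5
      rows[[k]] <- data.frame(
        generation = r, pair = j,
        first = if (flip) pairs[j, 2] else pairs[j, 1],
        second = if (flip) pairs[j, 1] else pairs[j, 2]
      )
    }
  }
  pairing_schedule(do.call(rbind, rows))
}

#' Configuration for the micro-society forward simulator
#'
#' The defaults mirror the standard communication-game design: four
#' isolated 8-person micro-societies, each communicating 16 concepts over
#' 7 generations of round-robin pairings — 64 data structures of 56
#' productions each.
#'
#' @param n_participants participants per micro-society (even; default 8).
#' @param n_generations generations (default 7; with
#'   \code{n_participants - 1} generations every pair meets exactly once).
#' @param n_societies number of independent micro-societies (default 4).
#' @param n_concepts concepts per micro-society (default 16); each
#'   (society, concept) pair yields one data structure.
#' @param true_params the generating [parameter_setting()], or a plain
#'   list with elements \code{m}, \code{c}, \code{b}, \code{tau},
#'   \code{mu}.  \code{tau} may be omitted even when \code{b > 0} if
#'   \code{tau_rule = "random_g1"}.
#' @param universe_size number \code{K} of potential variant labels
#'   (\code{"V1"}..\code{"VK"}).  The default 7 makes the expected number
#'   of distinct types among 8 independent uniform first-generation draws
#'   about 4.2, matching the starting diversity typical of coded
#'   communication-game corpora.
#' @param init_rule how generation 1 is filled (the choice model does not
#'   govern first productions): \code{"uniform_over_K"} — independent
#'   uniform draws from the universe; \code{"all_distinct"} — a random
#'   draw of \code{n_participants} distinct labels (requires
#'   \code{universe_size >= n_participants}); \code{"fixed_assignment"} —
#'   the labels in \code{init_assignment}.
#' @param init_assignment character vector of length
#'   \code{n_participants} used when \code{init_rule = "fixed_assignment"}.
#' @param tau_rule how the content-bias target is chosen when
#'   \code{b > 0}: \code{"random_g1"} — independently for each data
#'   structure, uniformly among the variant types present at its first
#'   generation (so different structures, and societies, can favour
#'   different variants); \code{"from_params"} — the fixed \code{tau} in
#'   \code{true_params}.
#' @param seed master seed; per-structure seeds are derived from it
#'   deterministically.
#' @return an object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_participants = 8, n_generations = 7,
                              n_societies = 4, n_concepts = 16,
                              true_params = list(m = 2, c = 0, b = 0,
                                                 tau = NULL, mu = 0.02),
                              universe_size = 7,
                              init_rule = c("uniform_over_K", "all_distinct",
                                            "fixed_assignment"),
                              init_assignment = NULL,
                              tau_rule = c("random_g1", "from_params"),
                              seed = NULL) {
  init_rule <- match.arg(init_rule)
  tau_rule <- match.arg(tau_rule)
  tp <- unclass(true_params)
  # validate the parameter point; a placeholder target is substituted when
  # tau is resolved per structure at simulation time
  check <- parameter_setting(
    m = tp$m, c = tp$c %||% 0, b = tp$b %||% 0,
    tau = if (!is.null(tp$tau)) tp$tau else
      if ((tp$b %||% 0) > 0) "<per-structure>" else NULL,
    mu = tp$mu %||% 0.02
  )
  if (check$b > 0 && is.null(tp$tau) && tau_rule != "random_g1") {
    stop("b > 0 with tau_rule = \"from_params\" requires a tau in true_params")
  }
  if (n_participants %% 2 != 0) stop("n_participants must be even")
  if (n_generations < 1) stop("n_generations must be at least 1")
  if (universe_size < 1) stop("universe_size must be at least 1")
  if (init_rule == "all_distinct" && universe_size < n_participants) {
    stop("init_rule \"all_distinct\" needs universe_size >= n_participants")
  }
  if (init_rule == "fixed_assignment" &&
      (is.null(init_assignment) ||
       length(init_assignment) != n_participants)) {
    stop("init_rule \"fixed_assignment\" needs init_assignment of length ",
         n_participants)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_generations = as.integer(n_generations),
         n_societies = as.integer(n_societies),
         n_concepts = as.integer(n_concepts),
         m = check$m, c = check$c, b = check$b,
         tau = tp$tau, mu = check$mu,
         universe_size = as.integer(universe_size),
         init_rule = init_rule, init_assignment = init_assignment,
         tau_rule = tau_rule, seed = seed),
    class = "simulation_config"
  )
}

#' Forward-simulate one data structure
#'
#' Generation 1 is filled by the configured initialization rule (first
#' productions have no history, so the choice model does not apply).
#' Generations 2..G are then filled pair by pair in schedule order: the
#' first drawer samples from [choice_distribution()] given their history
#' (own past productions plus witnessed partner productions), the second
#' drawer likewise but with the first drawer's just-made production
#' already in their allo history.  Mutation draws uniformly from the full
#' \code{K}-label universe, so extinct or never-seen variants can (re-)
#' enter.
#'
#' @param cfg a [simulation_config()].
#' @param society_id,concept_id identifiers for the resulting structure.
#' @param seed optional integer seed.
#' @return a [data_structure()] whose \code{universe} is the full set of
#'   \code{K} potential labels.
#' @export
simulate_data_structure <- function(cfg, society_id = "S1", concept_id = "C1",
                                    seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_participants
  G <- cfg$n_generations
  K <- cfg$universe_size
  universe <- sprintf("V%d", seq_len(K))

  sched <- round_robin_schedule(n, G)
  prods <- matrix(NA_character_, G, n)
  prods[1, ] <- switch(
    cfg$init_rule,
    uniform_over_K = sample(universe, n, replace = TRUE),
    all_distinct = sample(universe, n, replace = FALSE),
    fixed_assignment = {
      ia <- as.character(cfg$init_assignment)
      if (!all(ia %in% universe)) {
        stop("init_assignment contains labels outside the universe")
      }
      ia
    }
  )

  params <- if (cfg$b > 0) {
    tau <- if (cfg$tau_rule == "random_g1" && is.null(cfg$tau)) {
      g1_types <- unique(prods[1, ])
      g1_types[sample.int(length(g1_types), 1)]
    } else {
      cfg$tau
    }
    parameter_setting(m = cfg$m, c = cfg$c, b = cfg$b, tau = tau, mu = cfg$mu)
  } else {
    parameter_setting(m = cfg$m, c = cfg$c, b = 0, mu = cfg$mu)
  }

  pt <- partner_tables_from_schedule(sched, n, G)
  ego <- lapply(seq_len(n), function(p) prods[1, p])
  allo <- lapply(seq_len(n), function(p) prods[1, pt$partner[1, p]])

  for (g in seq_len(G)[-1]) {
    rows <- which(sched$generation == g)
    new_prod <- character(n)
    for (i in rows) {
      f <- sched$first[i]
      s <- sched$second[i]
      new_prod[f] <- sample_choice(history(ego[[f]], allo[[f]]),
                                   params, universe)
      new_prod[s] <- sample_choice(
        history(ego[[s]], c(allo[[s]], new_prod[f])), params, universe
      )
    }
    prods[g, ] <- new_prod
    for (p in seq_len(n)) {
      ego[[p]] <- c(ego[[p]], new_prod[p])
      allo[[p]] <- c(allo[[p]], new_prod[pt$partner[g, p]])
    }
  }
  d <- data_structure(prods, sched, society_id, concept_id,
                      universe = universe)
  attr(d, "true_params") <- params
  d
}

sample_choice <- function(h, params, universe) {
  pr <- choice_distribution(h, params, universe)
  universe[sample.int(length(universe), 1, prob = as.numeric(pr))]
}

partner_tables_from_schedule <- function(sched, n, G) {
  partner_tables(list(schedule = sched, n_generations = G,
                      n_participants = n))
}

#' Forward-simulate a corpus of micro-society data structures
#'
#' Simulates \code{n_societies x n_concepts} independent data structures
#' ([simulate_data_structure()]).  Per-structure seeds are drawn
#' deterministically from the master seed, so a corpus is fully
#' reproducible from its configuration and seed (both echoed in the
#' corpus metadata), and the structures are independent given the seed.
#'
#' @param cfg a [simulation_config()].
#' @param seed master seed; overrides \code{cfg$seed} if given.
#' @return a [corpus()]; each structure's generating parameters are kept
#'   in its \code{"true_params"} attribute.
#' @examples
#' corp <- simulate_corpus(simulation_config(n_societies = 1,
#'                                           n_concepts = 2, seed = 42))
#' length(corp)  # 2
#' @export
simulate_corpus <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n_struct <- cfg$n_societies * cfg$n_concepts
  struct_seeds <- sample.int(.Machine$integer.max - 1L, n_struct)
  dss <- vector("list", n_struct)
  k <- 0L
  for (s in seq_len(cfg$n_societies)) {
    for (co in seq_len(cfg$n_concepts)) {
      k <- k + 1L
      dss[[k]] <- simulate_data_structure(
        cfg, society_id = sprintf("S%d", s),
        concept_id = sprintf("C%d", co), seed = struct_seeds[k]
      )
    }
  }
  corpus(dss, metadata = list(
    generator = "culsel forward simulator",
    seed = seed,
    config = list(
      n_participants = cfg$n_participants, n_generations = cfg$n_generations,
      n_societies = cfg$n_societies, n_concepts = cfg$n_concepts,
      m = cfg$m, c = cfg$c, b = cfg$b, tau = cfg$tau, mu = cfg$mu,
      universe_size = cfg$universe_size, init_rule = cfg$init_rule,
      tau_rule = cfg$tau_rule
    )
  ))
}

#' Variant diversity per generation
#'
#' @param d a [data_structure()].
#' @return integer vector of length \code{n_generations}: the number of
#'   distinct variant types produced at each generation.
#' @export
diversity_trajectory <- function(d) {
  apply(d$productions, 1, function(r) length(unique(r)))
}
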