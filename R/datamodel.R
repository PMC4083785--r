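#' Pairing schedule for a round-robin micro-society game
#'
#' A pairing schedule records, for every generation, how the participants
#' were partitioned into pairs and which member of each pair produced
#' first.  In the standard design \code{n} participants play \code{n - 1}
#' generations so that every participant interacts with every other
#' exactly once (a full round robin).
#'
#' @param rounds a data frame with columns \code{generation}, \code{pair},
#'   \code{first}, \code{second}: one row per pair per generation, with
#'   \code{first}/\code{second} the 1-based participant indices in draw
#'   order (\code{first} drew first).
#' @return an object of class \code{"pairing_schedule"} (a validated data
#'   frame).
#' @seealso [validate_schedule()], [round_robin_schedule()]
#' @export
pairing_schedule <- function(rounds) {
  rounds <- as.data.frame(rounds)
  needed <- c("generation", "pair", "first", "second")
  missing <- setdiff(needed, names(rounds))
  if (length(missing) > 0) {
    stop("pairing schedule lacks column(s): ", paste(missing, collapse = ", "))
  }
  rounds <- rounds[order(rounds$generation, rounds$pair), needed, drop = FALSE]
  rounds$generation <- as.integer(rounds$generation)
  rounds$pair <- as.integer(rounds$pair)
  rounds$first <- as.integer(rounds$first)
  rounds$second <- as.integer(rounds$second)
  rownames(rounds) <- NULL
  structure(rounds, class = c("pairing_schedule", "data.frame"))
}

#' Validate a pairing schedule
#'
#' Checks that every generation is a perfect matching of the participants
#' (n/2 disjoint pairs covering everyone), that no unordered pair of
#' participants meets twice across generations, and — when \code{g >= n - 1}
#' — that all \code{choose(n, 2)} pairs are covered (round-robin
#' completeness).  Violations are returned, not thrown, so that callers can
#' report all problems at once.
#'
#' @param schedule a [pairing_schedule()] (or coercible data frame).
#' @param n number of participants.
#' @param g number of generations.
#' @return a character vector of violation messages; \code{character(0)}
#'   if the schedule is valid.
#' @export
validate_schedule <- function(schedule, n, g) {
  v <- character(0)
  sched <- try(pairing_schedule(schedule), silent = TRUE)
  if (inherits(sched, "try-error")) {
    return(paste("unparseable schedule:", attr(sched, "condition")$message))
  }
  if (n %% 2 != 0) v <- c(v, sprintf("participant count %d is odd", n))
  gens <- sort(unique(sched$generation))
  if (!identical(gens, seq_len(g))) {
    v <- c(v, sprintf(
      "generations present (%s) do not equal 1..%d",
      paste(gens, collapse = ","), g
    ))
  }
  ids <- c(sched$first, sched$second)
  if (any(ids < 1 | ids > n)) {
    v <- c(v, sprintf("participant indices outside 1..%d", n))
  }
  for (gen in intersect(gens, seq_len(g))) {
    rows <- sched[sched$generation == gen, , drop = FALSE]
    members <- c(rows$first, rows$second)
    if (nrow(rows) != n / 2 || !setequal(members, seq_len(n)) ||
        anyDuplicated(members) > 0) {
      v <- c(v, sprintf(
        "generation %d is not a perfect matching of %d participants", gen, n
      ))
    }
  }
  # round-robin: a pair may meet again only once the rotation is exhausted
  # (i.e. at most ceiling(g / (n - 1)) times over g generations)
  key <- paste(pmin(sched$first, sched$second),
               pmax(sched$first, sched$second), sep = "-")
  cap <- ceiling(g / (n - 1))
  counts <- table(key)
  over <- names(counts)[counts > cap]
  if (length(over) > 0) {
    v <- c(v, sprintf(
      "round-robin violated: pair(s) %s meet more often than the rotation allows",
      paste(over, collapse = ", ")
    ))
  }
  if (g >= n - 1 && length(unique(key)) < choose(n, 2)) {
    v <- c(v, sprintf(
      "round-robin incomplete: %d of %d distinct pairs covered",
      length(unique(key)), choose(n, 2)
    ))
  }
  v
}

#' Construct a coded data structure
#'
#' A data structure is the unit of analysis: all coded variant productions
#' for one concept in one micro-society, as a generation-by-participant
#' grid together with the pairing schedule under which they were produced.
#' The default design has 8 participants and 7 generations, i.e. 56
#' productions.
#'
#' @param productions character matrix of variant labels with
#'   \code{n_generations} rows and \code{n_participants} columns;
#'   \code{productions[g, p]} is what participant \code{p} produced at
#'   generation \code{g}.
#' @param schedule a [pairing_schedule()] covering all generations.
#' @param society_id,concept_id identifiers; the pair must be unique
#'   within a corpus.
#' @param universe character vector of all variant labels considered
#'   possible for this structure (the support of the mutation
#'   distribution).  Defaults to the labels attested in the grid; may be a
#'   superset of them, never a subset.
#' @return an object of class \code{"data_structure"}.
#' @examples
#' sched <- round_robin_schedule(4, 3, seed = 1)
#' prods <- matrix("A", nrow = 3, ncol = 4)
#' d <- data_structure(prods, sched, "S1", "C1")
#' @export
data_structure <- function(productions, schedule, society_id, concept_id,
                           universe = NULL) {
  d <- structure(
    list(
      society_id = as.character(society_id),
      concept_id = as.character(concept_id),
      n_participants = ncol(productions),
      n_generations = nrow(productions),
      productions = productions,
      schedule = pairing_schedule(schedule),
      universe = if (is.null(universe)) {
        attested_labels(productions)
      } else {
        as.character(universe)
      }
    ),
    class = "data_structure"
  )
  problems <- validate_data_structure(d)
  if (length(problems) > 0) {
    stop(
      sprintf("invalid data structure (%s/%s): %s",
              d$society_id, d$concept_id, paste(problems, collapse = "; "))
    )
  }
  d
}

# labels in order of first appearance, scanning generation by generation
attested_labels <- function(productions) {
  unique(as.character(t(productions)))
}

#' Validate a data structure
#'
#' @param d a \code{data_structure} (or a list with the same fields).
#' @return character vector of violation messages (empty if valid).
#' @export
validate_data_structure <- function(d) {
  v <- character(0)
  n <- d$n_participants
  g <- d$n_generations
  prods <- d$productions
  if (!is.matrix(prods) || !is.character(prods)) {
    return("productions must be a character matrix (generations x participants)")
  }
  expected <- n * g
  filled <- sum(!is.na(prods) & nzchar(prods))
  if (nrow(prods) != g || ncol(prods) != n || filled != expected) {
    v <- c(v, sprintf("expected %d productions (%d generations x %d participants), found %d",
                      expected, g, n, filled))
  }
  if (length(d$universe) == 0 || any(!nzchar(d$universe)) ||
      anyDuplicated(d$universe) > 0) {
    v <- c(v, "universe must be a non-empty set of unique, non-empty labels")
  }
  stray <- setdiff(stats::na.omit(as.character(prods)), d$universe)
  if (length(stray) > 0) {
    v <- c(v, sprintf("production label(s) not in universe: %s",
                      paste(stray, collapse = ", ")))
  }
  c(v, validate_schedule(d$schedule, n, g))
}

#' @export
print.data_structure <- function(x, ...) {
  cat(sprintf(
    "<data_structure %s/%s: %d participants x %d generations, %d variant types>\n",
    x$society_id, x$concept_id, x$n_participants, x$n_generations,
    length(unique(as.character(x$productions)))
  ))
  invisible(x)
}

#' Construct a corpus of data structures
#'
#' @param data_structures list of [data_structure()] objects with unique
#'   (society_id, concept_id) pairs.
#' @param metadata named list of provenance notes (seeds, generator
#'   configuration, ...), stored verbatim.
#' @return an object of class \code{"corpus"}.
#' @export
corpus <- function(data_structures = list(), metadata = list()) {
  stopifnot(is.list(data_structures))
  if (length(data_structures) > 0) {
    ok <- vapply(data_structures, inherits, logical(1), "data_structure")
    if (!all(ok)) stop("all corpus elements must be data_structure objects")
    keys <- vapply(data_structures, function(d) {
      paste(d$society_id, d$concept_id, sep = "\r")
    }, character(1))
    if (anyDuplicated(keys) > 0) {
      dup <- keys[duplicated(keys)][1]
      stop("duplicate (society_id, concept_id): ", gsub("\r", "/", dup))
    }
  }
  structure(list(data_structures = data_structures, metadata = metadata),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  n <- length(x$data_structures)
  total <- sum(vapply(x$data_structures,
                      function(d) d$n_participants * d$n_generations,
                      numeric(1)))
  cat(sprintf("<corpus: %d data structure(s), %d productions>\n", n, total))
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$data_structures)
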