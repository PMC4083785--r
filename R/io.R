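CORPUS_SCHEMA <- "culsel-corpus-v1"

#' Write a corpus to disk
#'
#' Two formats are supported.  \code{"json"} is the full-fidelity format:
#' one document per corpus, each data structure an object with its
#' productions as generation-major nested lists, its schedule spelled out
#' explicitly, and its (possibly extended) variant universe
#' (\code{"schema": "culsel-corpus-v1"}).  \code{"csv"} is a flat
#' interchange export with one row per production (columns
#' \code{society}, \code{concept}, \code{generation}, \code{participant},
#' \code{pair_id}, \code{drew_second}, \code{label}); it carries the full
#' grid and schedule but drops corpus metadata and any universe labels not
#' attested in the grid.
#'
#' @param corp a [corpus()].
#' @param path output file path.
#' @param format \code{"json"} or \code{"csv"}; by default inferred from
#'   the file extension.
#' @return \code{path}, invisibly.
#' @seealso [read_corpus()]
#' @export
write_corpus <- function(corp, path, format = c("auto", "json", "csv")) {
  format <- resolve_format(match.arg(format), path)
  stopifnot(inherits(corp, "corpus"))
  if (format == "json") {
    doc <- list(
      schema = CORPUS_SCHEMA,
      metadata = corp$metadata,
      data_structures = lapply(corp$data_structures, ds_to_list)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    df <- corpus_to_flat(corp)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a corpus from disk
#'
#' Reads a corpus written by [write_corpus()].  Every data structure is
#' re-validated on the way in (grid completeness, labels within universe,
#' perfect matching per generation, round-robin completeness); a violation
#' raises an error naming the offending structure and rule rather than
#' silently accepting malformed data.
#'
#' @inheritParams write_corpus
#' @param path input file path.
#' @return a validated [corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "json", "csv")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    doc <- tryCatch(
      jsonlite::read_json(path, simplifyVector = FALSE),
      error = function(e) stop("JSON parse failure in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!identical(doc$schema, CORPUS_SCHEMA)) {
      stop("unrecognized corpus schema: ",
           if (is.null(doc$schema)) "<missing>" else doc$schema)
    }
    dss <- lapply(doc$data_structures, ds_from_list)
    corpus(dss, metadata = as_metadata(doc$metadata))
  } else {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stop("CSV parse failure in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    corpus_from_flat(df, path)
  }
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) return(ext)
  stop("cannot infer corpus format from extension of ", path,
       "; pass format = \"json\" or \"csv\"")
}

as_metadata <- function(x) if (is.null(x)) list() else x

ds_to_list <- function(d) {
  list(
    society_id = d$society_id,
    concept_id = d$concept_id,
    n_participants = d$n_participants,
    n_generations = d$n_generations,
    universe = as.list(d$universe),
    # generation-major: productions[[g]][[p]]
    productions = lapply(seq_len(d$n_generations), function(g) {
      as.list(unname(d$productions[g, ]))
    }),
    schedule = lapply(seq_len(nrow(d$schedule)), function(i) {
      as.list(d$schedule[i, c("generation", "pair", "first", "second")])
    })
  )
}

ds_from_list <- function(x) {
  id <- paste0(x$society_id %||% "?", "/", x$concept_id %||% "?")
  n <- x$n_participants %||% stop("record ", id, ": n_participants missing")
  g <- x$n_generations %||% stop("record ", id, ": n_generations missing")
  rows <- lapply(x$productions, function(r) vapply(r, as.character, character(1)))
  lens <- lengths(rows)
  if (length(rows) != g || any(lens != n)) {
    stop(sprintf("record %s: expected %d productions (%d x %d grid)",
                 id, n * g, g, n))
  }
  prods <- do.call(rbind, rows)
  sched <- do.call(rbind, lapply(x$schedule, function(r) {
    data.frame(generation = r$generation, pair = r$pair,
               first = r$first, second = r$second)
  }))
  tryCatch(
    data_structure(prods, sched, x$society_id, x$concept_id,
                   universe = unlist(x$universe, use.names = FALSE)),
    error = function(e) stop("record ", id, ": ", conditionMessage(e),
                             call. = FALSE)
  )
}

corpus_to_flat <- function(corp) {
  if (length(corp$data_structures) == 0) {
    return(data.frame(
      society = character(0), concept = character(0),
      generation = integer(0), participant = integer(0),
      pair_id = integer(0), drew_second = logical(0), label = character(0)
    ))
  }
  rows <- lapply(corp$data_structures, function(d) {
    sched <- d$schedule
    pair_of <- matrix(NA_integer_, d$n_generations, d$n_participants)
    second <- matrix(FALSE, d$n_generations, d$n_participants)
    for (i in seq_len(nrow(sched))) {
      pair_of[sched$generation[i], c(sched$first[i], sched$second[i])] <- sched$pair[i]
      second[sched$generation[i], sched$second[i]] <- TRUE
    }
    gg <- rep(seq_len(d$n_generations), each = d$n_participants)
    pp <- rep(seq_len(d$n_participants), times = d$n_generations)
    data.frame(
      society = d$society_id,
      concept = d$concept_id,
      generation = gg,
      participant = pp,
      pair_id = pair_of[cbind(gg, pp)],
      drew_second = second[cbind(gg, pp)],
      label = d$productions[cbind(gg, pp)],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

corpus_from_flat <- function(df, path) {
  needed <- c("society", "concept", "generation", "participant",
              "pair_id", "drew_second", "label")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("CSV ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(corpus())
  key <- paste(df$society, df$concept, sep = "\r")
  dss <- lapply(split(df, factor(key, levels = unique(key))), flat_to_ds)
  corpus(unname(dss))
}

flat_to_ds <- function(sub) {
  id <- paste0(sub$society[1], "/", sub$concept[1])
  n <- max(sub$participant)
  g <- max(sub$generation)
  if (nrow(sub) != n * g ||
      anyDuplicated(sub[, c("generation", "participant")]) > 0) {
    stop(sprintf("record %s: expected %d productions, found %d rows",
                 id, n * g, nrow(sub)), call. = FALSE)
  }
  prods <- matrix(NA_character_, g, n)
  prods[cbind(sub$generation, sub$participant)] <- sub$label
  # rebuild the schedule from pair membership and draw-order flags
  sched_rows <- unique(sub[, c("generation", "pair_id")])
  sched <- do.call(rbind, lapply(seq_len(nrow(sched_rows)), function(i) {
    gen <- sched_rows$generation[i]
    pid <- sched_rows$pair_id[i]
    mem <- sub[sub$generation == gen & sub$pair_id == pid, ]
    if (nrow(mem) != 2 || sum(mem$drew_second) != 1) {
      stop(sprintf(
        "record %s: generation %d pair %d must have exactly two members, one marked drew_second",
        id, gen, pid), call. = FALSE)
    }
    data.frame(generation = gen, pair = pid,
               first = mem$participant[!mem$drew_second],
               second = mem$participant[mem$drew_second])
  }))
  tryCatch(
    data_structure(prods, sched, sub$society[1], sub$concept[1]),
    error = function(e) stop("record ", id, ": ", conditionMessage(e),
                             call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
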