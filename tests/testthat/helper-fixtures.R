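# Fixtures are built in code; nothing is read from disk.

# deterministic 3-generation round robin for 4 participants:
# {1-2, 3-4}, {1-3, 2-4}, {1-4, 2-3}
rr4_schedule <- function() {
  pairing_schedule(data.frame(
    generation = rep(1:3, each = 2),
    pair = rep(1:2, 3),
    first = c(1, 3, 1, 2, 1, 2),
    second = c(2, 4, 3, 4, 4, 3)
  ))
}

# 2 participants over 3 generations (the single pair repeats, which the
# cyclic round-robin rule allows); draw order alternates
toy2x3_structure <- function() {
  sched <- data.frame(
    generation = 1:3, pair = 1,
    first = c(1, 2, 1), second = c(2, 1, 2)
  )
  prods <- rbind(
    c("r", "u"),
    c("r", "r"),
    c("u", "r")
  )
  data_structure(prods, sched, "toy", "c1")
}

# 4 participants x 3 generations with mixed labels, for grid-search checks
toy4x3_structure <- function() {
  prods <- rbind(
    c("r", "u", "g", "r"),
    c("r", "r", "g", "g"),
    c("r", "r", "r", "g")
  )
  data_structure(prods, rr4_schedule(), "toy", "c2")
}

# structure where everyone always produces the same variant
uniform_structure <- function(label = "A", n = 8, g = 7, seed = 5) {
  sched <- round_robin_schedule(n, g, seed = seed)
  data_structure(matrix(label, g, n), sched, "uni", "c1")
}

# synthetic analogue of a strongly content-biased coded structure:
# 4 variant types at G1, one of which takes over completely by G4
synthetic_takeover_structure <- function() {
  sched <- round_robin_schedule(8, 7, seed = 99)
  prods <- rbind(
    c("red", "red", "green", "green", "blue", "blue", "yellow", "red"),
    c("red", "red", "green", "blue", "blue", "red", "red", "red"),
    c("red", "red", "red", "blue", "red", "red", "red", "red"),
    c("red", "red", "red", "red", "red", "red", "red", "red"),
    c("red", "red", "red", "red", "red", "red", "red", "red"),
    c("red", "red", "red", "red", "red", "red", "red", "red"),
    c("red", "red", "red", "red", "red", "red", "red", "red")
  )
  data_structure(prods, sched, "syn", "takeover")
}

drift_config <- function(...) {
  simulation_config(true_params = list(m = 2, c = 0, b = 0, mu = 0.02), ...)
}

biased_config <- function(...) {
  simulation_config(true_params = list(m = 2, c = -0.8, b = 0.6, mu = 0.02),
                    tau_rule = "random_g1", ...)
}

# random small corpus for round-trip property tests
random_corpus <- function(seed, n_structures = 3) {
  set.seed(seed)
  dss <- lapply(seq_len(n_structures), function(i) {
    n <- sample(c(4, 8), 1)
    g <- sample(2:(n - 1), 1)
    sched <- round_robin_schedule(n, g)
    labs <- sample(letters, sample(2:5, 1))
    prods <- matrix(sample(labs, n * g, replace = TRUE), g, n)
    data_structure(prods, sched, sprintf("S%d", i), sprintf("C%d", i),
                   universe = unique(c(labs, "unseen")))
  })
  corpus(dss, metadata = list(note = "round-trip fixture", seed = seed))
}

expect_corpus_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a$data_structures)) {
    da <- a$data_structures[[i]]
    db <- b$data_structures[[i]]
    expect_equal(da$society_id, db$society_id)
    expect_equal(da$concept_id, db$concept_id)
    expect_equal(unname(da$productions), unname(db$productions))
    expect_equal(as.data.frame(da$schedule), as.data.frame(db$schedule))
    expect_setequal(da$universe, db$universe)
  }
}
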