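test_that("memory windows keep the last m/2 entries of each kind", {
  h <- history(ego = c("r", "g", "r"), allo = c("u", "r"))
  expect_equal(memory_windows(h, 4), list(ego = c("g", "r"), allo = c("u", "r")))
  expect_equal(memory_windows(history(allo = "r"), 8),
               list(ego = character(0), allo = "r"))
  expect_equal(memory_windows(history(ego = letters[1:5], allo = "a"), 2),
               list(ego = "e", allo = "a"))
  expect_error(memory_windows(h, 3), "even")
  expect_error(memory_windows(h, 0), "even")
})

test_that("relative frequencies are counts over window length", {
  expect_equal(relative_freq(c("r", "r")), c(r = 1.0))
  expect_equal(relative_freq(c("u", "r")), c(u = 0.5, r = 0.5))
  expect_equal(relative_freq(c("a", "a", "b", "c")),
               c(a = 0.5, b = 0.25, c = 0.25))
  expect_length(relative_freq(character(0)), 0)
})

test_that("coordination bias mixes ego and allo distributions via gamma", {
  expect_equal(combine_memory(c(r = 1), c(u = 1), c = 0),
               c(r = 0.5, u = 0.5))
  # fully egocentric: only self-produced variants count
  expect_equal(combine_memory(c(r = 1), c(u = 1), c = -1), c(r = 1, u = 0))
  # gamma = 0.8: r = 0.2 * 1 + 0.8 * 0.5
  expect_equal(combine_memory(c(r = 1), c(u = 0.5, r = 0.5), c = 0.6),
               c(r = 0.6, u = 0.4))
  # an empty side hands all weight to the other
  expect_equal(combine_memory(c(r = 1), relative_freq(character(0)), c = 1),
               c(r = 1))
  expect_error(combine_memory(relative_freq(character(0)),
                              relative_freq(character(0)), c = 0),
               "empty")
})

test_that("content bias is effective only when its target is in memory", {
  expect_equal(effective_beta("r", 0.4, c("g", "r"), c("u", "u")), 0.4)
  expect_equal(effective_beta("y", 0.4, c("g", "r"), c("u", "u")), 0)
  expect_equal(effective_beta("r", 0, c("g", "r"), c("u", "u")), 0)
})

test_that("the full choice distribution matches hand-computed cases", {
  u4 <- c("r", "u", "g", "y")
  h <- history(ego = c("r", "r"), allo = c("u", "r"))
  p <- parameter_setting(m = 4, c = 0, b = 0.4, tau = "u", mu = 0.02)
  # base: r = 0.75, u = 0.25; content bias: scale by 0.6, add 0.4 at u;
  # mutation: 0.98 * q + 0.02 / 4
  expect_equal(as.numeric(choice_distribution(h, p, u4)),
               c(0.446, 0.544, 0.005, 0.005), tolerance = 1e-12)

  # degenerate identity: one variant, no mutation
  p0 <- parameter_setting(m = 2, c = 0, b = 0, mu = 0)
  expect_equal(as.numeric(choice_distribution(history("a", "a"), p0, "a")), 1)

  # mutation floor: every variant keeps at least mu / K
  p1 <- parameter_setting(m = 4, c = -1, b = 0, mu = 0.02)
  d <- choice_distribution(history(ego = "r", allo = "u"), p1, u4)
  expect_true(all(d >= 0.005 - 1e-15))
  expect_equal(d[["g"]], 0.005)
})

test_that("degenerate inputs are rejected", {
  p <- parameter_setting(m = 2, c = 0, b = 0, mu = 0.02)
  expect_error(choice_distribution(history(), p, c("a", "b")), "empty history")
  expect_error(choice_distribution(history("a"), p, character(0)),
               "non-empty")
  expect_error(choice_distribution(history("z"), p, c("a", "b")),
               "outside the universe")
  expect_error(parameter_setting(m = 3), "even")
  expect_error(parameter_setting(m = 2, c = 2), "\\[-1, 1\\]")
  expect_error(parameter_setting(m = 2, b = 0.5), "tau")
})

random_case <- function(universe) {
  n_e <- sample(0:4, 1)
  n_a <- if (n_e == 0) sample(1:4, 1) else sample(0:4, 1)
  list(
    h = history(ego = sample(universe, n_e, replace = TRUE),
                allo = sample(universe, n_a, replace = TRUE)),
    m = sample(c(2, 4, 6, 8), 1),
    c = sample(seq(-1, 1, by = 0.2), 1),
    b = sample(seq(0, 1, by = 0.1), 1),
    tau = sample(universe, 1)
  )
}

test_that("normalization, mutation floor and drift reduction hold on random cases", {
  set.seed(2024)
  for (rep in 1:400) {
    K <- sample(2:10, 1)
    u <- paste0("L", seq_len(K))
    cs <- random_case(u)
    p <- parameter_setting(m = cs$m, c = cs$c, b = cs$b,
                           tau = if (cs$b > 0) cs$tau else NULL, mu = 0.02)
    d <- choice_distribution(cs$h, p, u)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0.02 / K - 1e-15))
  }

  # drift reduction: b = 0, c = 0, mu = 0 gives the plain window-frequency mean
  set.seed(2025)
  for (rep in 1:100) {
    u <- c("a", "b", "c")
    ego <- sample(u, 3, replace = TRUE)
    allo <- sample(u, 2, replace = TRUE)
    p <- parameter_setting(m = 8, c = 0, b = 0, mu = 0)
    d <- choice_distribution(history(ego, allo), p, u)
    manual <- vapply(u, function(x) {
      (mean(ego == x) + mean(allo == x)) / 2
    }, numeric(1))
    expect_equal(as.numeric(d), as.numeric(manual), tolerance = 1e-14)
  }
})

test_that("egocentric limit reproduces ego-window frequencies exactly", {
  set.seed(2026)
  u <- c("a", "b", "c", "d")
  for (rep in 1:50) {
    ego <- sample(u, 4, replace = TRUE)
    allo <- sample(u, 3, replace = TRUE)
    p <- parameter_setting(m = 8, c = -1, b = 0, mu = 0)
    d <- choice_distribution(history(ego, allo), p, u)
    expect_equal(as.numeric(d),
                 vapply(u, function(x) mean(ego == x), numeric(1),
                        USE.NAMES = FALSE),
                 tolerance = 1e-14)
  }
})

test_that("the target's probability increases strictly with b while in memory", {
  u <- c("a", "b", "c")
  h <- history(ego = c("a", "b"), allo = c("c", "b"))
  probs <- vapply(seq(0.1, 1, by = 0.1), function(b) {
    p <- parameter_setting(m = 4, c = 0, b = b, tau = "c", mu = 0.02)
    choice_distribution(h, p, u)[["c"]]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  # out-of-memory target: b has no effect
  p_hi <- parameter_setting(m = 2, c = 0, b = 0.9, tau = "a", mu = 0.02)
  p_lo <- parameter_setting(m = 2, c = 0, b = 0, mu = 0.02)
  h2 <- history(ego = c("a", "b"), allo = c("c", "c"))  # window drops "a"
  expect_equal(as.numeric(choice_distribution(h2, p_hi, u)),
               as.numeric(choice_distribution(h2, p_lo, u)))
})

test_that("the distribution agrees with the brute-force oracle on random cases", {
  set.seed(77)
  u <- c("p", "q", "r", "s")
  for (rep in 1:300) {
    cs <- random_case(u)
    p <- parameter_setting(m = cs$m, c = cs$c, b = cs$b,
                           tau = if (cs$b > 0) cs$tau else NULL, mu = 0.02)
    got <- as.numeric(choice_distribution(cs$h, p, u))
    want <- as.numeric(oracle_choice_prob(
      cs$h$ego, cs$h$allo, cs$m, cs$c, cs$b,
      if (cs$b > 0) cs$tau else NULL, 0.02, u
    ))
    expect_equal(got, want, tolerance = 1e-13)
  }
})
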