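test_that("an 8x7 structure yields 48 events with partner-only visibility", {
  d <- simulate_data_structure(drift_config(), seed = 8)
  ev <- build_choice_events(d)
  expect_length(ev, 48)  # 8 participants x generations 2..7
  expect_true(all(vapply(ev, function(e) e$generation >= 2, logical(1))))

  sched <- as.data.frame(d$schedule)
  for (e in ev[1:16]) {
    g <- e$generation; p <- e$participant
    # ego: own productions, oldest first
    expect_equal(e$history$ego, unname(d$productions[1:(g - 1), p]))
    # allo length: one witnessed production per prior generation, plus the
    # current partner's if p drew second
    row <- sched[sched$generation == g &
                   (sched$first == p | sched$second == p), ]
    drew_second <- row$second == p
    expect_length(e$history$allo, (g - 1) + as.integer(drew_second))
  }
})

test_that("second drawers see their partner's current production, first drawers do not", {
  d <- toy2x3_structure()
  ev <- build_choice_events(d)
  expect_length(ev, 4)
  # generation 2: participant 2 drew first, participant 1 drew second
  e_first <- ev[[which(vapply(ev, function(e) {
    e$generation == 2 && e$participant == 2
  }, logical(1)))]]
  e_second <- ev[[which(vapply(ev, function(e) {
    e$generation == 2 && e$participant == 1
  }, logical(1)))]]
  expect_equal(e_first$history$allo, "r")         # partner's G1 only
  expect_equal(e_second$history$allo, c("u", "r"))  # + partner's current G2
})

test_that("saturated structures have log-likelihood zero", {
  d <- uniform_structure()
  # every factor is 1 under pure memory copying
  expect_equal(data_structure_loglik(
    d, parameter_setting(m = 2, c = 0, b = 0, mu = 0)), 0)
  # with a singleton universe the flat mutation component is also a sure thing
  expect_equal(data_structure_loglik(
    d, parameter_setting(m = 2, c = 0, b = 0, mu = 0.02)), 0)
})

test_that("structure likelihoods match the event-by-event oracle", {
  d <- toy2x3_structure()
  p <- parameter_setting(m = 4, c = 0, b = 0.5, tau = "r", mu = 0.02)
  expect_equal(data_structure_loglik(d, p),
               oracle_structure_loglik(d, 4, 0, 0.5, "r", 0.02),
               tolerance = 1e-12)

  d2 <- toy4x3_structure()
  for (pars in list(list(m = 2, c = -0.6, b = 0, tau = NULL),
                    list(m = 4, c = 0.4, b = 0.3, tau = "g"),
                    list(m = 8, c = 1, b = 0.9, tau = "r"))) {
    p2 <- parameter_setting(m = pars$m, c = pars$c, b = pars$b,
                            tau = pars$tau, mu = 0.02)
    expect_equal(data_structure_loglik(d2, p2),
                 oracle_structure_loglik(d2, pars$m, pars$c, pars$b,
                                         pars$tau, 0.02),
                 tolerance = 1e-12)
  }
})

test_that("impossible choices give -Inf only when mutation is off", {
  d <- toy2x3_structure()  # contains an innovation at G3
  expect_equal(data_structure_loglik(
    d, parameter_setting(m = 2, c = 1, b = 0, mu = 0)), -Inf)
  expect_true(is.finite(data_structure_loglik(
    d, parameter_setting(m = 2, c = 1, b = 0, mu = 0.02))))
})

test_that("the default grid covers 484 points and profiles tau within them", {
  d <- simulate_data_structure(biased_config(), seed = 9)
  fit <- grid_search(d)
  expect_equal(fit$n_points, 484)
  expect_equal(nrow(fit$table), 4 * 11 * 11)
  expect_true(all(is.na(fit$table$tau[fit$table$b == 0])))
  expect_true(all(!is.na(fit$table$tau[fit$table$b > 0])))
})

test_that("grid search equals the nested-loop oracle point by point", {
  d <- toy4x3_structure()
  grid <- grid_spec()
  fit <- grid_search(d, grid)
  want <- oracle_grid_table(d, grid$m_levels, grid$c_levels, grid$b_levels,
                            tau_candidates(d), grid$mu)
  got <- fit$table[order(fit$table$m, fit$table$c, fit$table$b), ]
  want <- want[order(want$m, want$c, want$b), ]
  expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
})

test_that("families nest: unconstrained >= b=0 >= drift, and c=0 likewise", {
  for (seed in c(14, 15, 16)) {
    d <- simulate_data_structure(biased_config(), seed = seed)
    fm <- grid_search(d)$family_maxima
    expect_gte(fm[["unconstrained"]], fm[["no_content"]])
    expect_gte(fm[["unconstrained"]], fm[["no_coordination"]])
    expect_gte(fm[["no_content"]], fm[["drift"]])
    expect_gte(fm[["no_coordination"]], fm[["drift"]])
  }
})

test_that("flat likelihoods resolve to the drift-closest setting", {
  d <- uniform_structure()
  fit <- grid_search(d)
  # every parameter is ineffective: all 484 points tie at loglik 0
  expect_true(all(abs(fit$table$loglik) < 1e-12))
  expect_equal(fit$ml$b, 0)
  expect_equal(fit$ml$c, 0)
  expect_equal(fit$ml$m, 2)
})

test_that("tau candidates are attested types, most frequent first, capped at 8", {
  d <- toy4x3_structure()
  expect_equal(tau_candidates(d), c("r", "g", "u"))  # 7, 4, 1 occurrences

  expect_equal(tau_candidates(uniform_structure()), "A")

  # 9 types: drop the rarest; ties broken by first appearance
  sched <- round_robin_schedule(8, 7, seed = 17)
  prods <- matrix("x1", 7, 8)
  prods[1, ] <- paste0("x", 1:8)
  prods[2, 1] <- "x9"
  d9 <- data_structure(prods, sched, "S", "C")
  cand <- tau_candidates(d9)
  expect_length(cand, 8)
  expect_equal(cand[1], "x1")
  # x9 appears later than the tied x2..x8, so it is the one dropped
  expect_setequal(cand, paste0("x", 1:8))
})

test_that("strong simulated content bias recovers its target", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(
      true_params = list(m = 2, c = 0, b = 0.9, mu = 0.02),
      tau_rule = "random_g1"
    )
    d <- simulate_data_structure(cfg, seed = 100 + seed)
    truth <- attr(d, "true_params")$tau
    fit <- grid_search(d)
    if (!is.null(fit$ml$tau) && fit$ml$tau == truth) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
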