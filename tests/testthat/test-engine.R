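test_that("a zero-length horizon produces no events", {
  m <- spread_model(n = 5)
  tr <- simulate_spread(m, t_end = 0, seed = 1)
  expect_equal(nrow(tr$events), 0)
  expect_equal(tr$final$mod, tr$initial$mod)
})

test_that("identical seed, config and method give identical trajectories", {
  m <- spread_model(n = 12, mechanism = "combined")
  for (meth in c("next_reaction", "direct")) {
    a <- simulate_spread(m, t_end = 20, seed = 33, method = meth)
    b <- simulate_spread(m, t_end = 20, seed = 33, method = meth)
    expect_identical(a$events, b$events)
  }
})

test_that("a chain with no enabled channels is absorbing and holds to t_end", {
  r <- spread_rates(k_on = 0, k_demodification = 0,
                    k_background_acetylation = 0)
  m <- spread_model(n = 4, mechanism = "diffusion", rates = r)
  tr <- simulate_spread(m, t_end = 10, seed = 1, init = "all_U_empty")
  expect_equal(nrow(tr$events), 0)
  expect_equal(state_at(tr, 10)$mod, rep("U", 4))
})

test_that("every recorded event was enabled and invariants hold along the run", {
  m <- spread_model(n = 15, mechanism = "combined", enzymes = "dual",
                    initiation_sites = c(Mt = 2, At = 14))
  tr <- simulate_spread(m, t_end = 40, seed = 5)
  expect_gt(nrow(tr$events), 100)
  rp <- replay_trajectory(tr)  # apply_reaction(check = TRUE) at every event
  expect_equal(rp$final$mod, tr$final$mod)
  expect_equal(rp$final$occ, tr$final$occ)
  # without connectivity, enzymes never pass each other: the left-to-right
  # sequence of enzyme types only changes at binding/unbinding events
  expect_equal(rp$order_breaks, 0L)
  expect_true(all(diff(tr$events$time) > 0))
})

test_that("incremental propensity bookkeeping agrees with full re-derivation", {
  m <- spread_model(n = 20, mechanism = "combined", enzymes = "dual",
                    initiation_sites = c(Mt = 3, At = 18),
                    connectivity_sites = c(4, 10, 16),
                    rates = spread_rates(k_interaction = 0.5))
  expect_no_error(simulate_spread(m, t_end = 25, seed = 9, validate = TRUE))
})

test_that("state_at replays the piecewise-constant trajectory", {
  m <- spread_model(n = 8, mechanism = "diffusion")
  tr <- simulate_spread(m, t_end = 10, seed = 2)
  expect_equal(state_at(tr, 0)$mod, tr$initial$mod)
  expect_equal(state_at(tr, 10)$mod, tr$final$mod)
  # between two recorded events the earlier state holds (right-continuity)
  ev <- tr$events
  mid <- (ev$time[5] + ev$time[6]) / 2
  expect_equal(state_at(tr, mid), state_at(tr, ev$time[5]))
  expect_error(state_at(tr, 11), class = "nucspread_domain_error")
  expect_error(state_at(tr, -1), class = "nucspread_domain_error")
})

test_that("kymograph sampling matches state_at on the grid", {
  m <- spread_model(n = 6, mechanism = "combined")
  tr <- simulate_spread(m, t_end = 8, seed = 3)
  ky <- kymograph(tr, dt = 1)
  expect_equal(nrow(ky), 9 * 6)
  for (t in c(0, 3, 8)) {
    slice <- ky[ky$time == t, ]
    expect_equal(slice$mod, state_at(tr, t)$mod)
    expect_equal(slice$occ, state_at(tr, t)$occ)
  }
  # dt = t_end gives exactly the initial and final states
  ky2 <- kymograph(tr, dt = 8)
  expect_equal(unique(ky2$time), c(0, 8))
  expect_error(kymograph(tr, dt = 0), class = "nucspread_domain_error")
  # a trajectory with no events is constant everywhere
  m0 <- spread_model(n = 4, rates = spread_rates(
    k_on = 0, k_demodification = 0, k_background_acetylation = 0))
  tr0 <- simulate_spread(m0, t_end = 5, seed = 1, init = "all_U_empty")
  ky0 <- kymograph(tr0, dt = 1)
  expect_true(all(ky0$mod == "U"))
})

test_that("time-weighted state distribution converges to the exact stationary law", {
  m <- spread_model(n = 2, mechanism = "diffusion",
                    initiation_sites = c(Mt = 1))
  ex <- exact_stationary(m)
  expect_equal(sum(ex$prob), 1, tolerance = 1e-10)
  expect_equal(nrow(ex), 36)  # (3 marks x 2 occupancies)^2 all reachable
  tv_short <- tv_distance(ex, empirical_state_distribution(m, 500, seed = 4))
  tv_long <- tv_distance(ex, empirical_state_distribution(m, 2e4, seed = 4))
  expect_lt(tv_long, 0.02)
  expect_lt(tv_long, tv_short)  # error shrinks with simulated time
})

test_that("next-reaction and direct methods sample the same stationary law", {
  m <- spread_model(n = 2, mechanism = "combined",
                    initiation_sites = c(Mt = 2))
  ex <- exact_stationary(m)
  emp_nr <- empirical_state_distribution(m, 1.5e4, seed = 6,
                                         method = "next_reaction")
  emp_d <- empirical_state_distribution(m, 1.5e4, seed = 7,
                                        method = "direct")
  expect_lt(tv_distance(ex, emp_nr), 0.02)
  expect_lt(tv_distance(ex, emp_d), 0.02)
})

test_that("on-site catalysis outraces every other channel", {
  # competing-risk probability that a methyltransferase on a U nucleosome
  # fires its 1000 s^-1 catalysis before anything else
  m <- spread_model(n = 50, mechanism = "combined")
  s <- initial_state(m, "all_U_empty")
  s$occ[25] <- "Mt"
  ch <- enumerate_reactions(s, m)
  # channels competing for the enzyme's own nucleosome
  local <- ch[ch$pos1 == 25 | (!is.na(ch$pos2) & ch$pos2 == 25), ]
  p_cat <- local$propensity[local$kind == "catalyze_site"] /
    sum(local$propensity)
  expect_gt(p_cat, 0.99)
})
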