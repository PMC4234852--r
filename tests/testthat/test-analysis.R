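# hand-built trajectory factory for estimator tests
toy_trajectory <- function(model, init, events, t_end) {
  traj <- structure(list(model = model, seed = NA_integer_,
                         method = "next_reaction", t_end = t_end,
                         initial = init, events = events, final = NULL),
                    class = "spread_trajectory")
  traj$final <- state_at(traj, t_end)
  traj
}

empty_events <- function() {
  tibble::tibble(time = double(), kind = character(), enzyme = character(),
                 pos1 = integer(), pos2 = integer())
}

test_that("a frozen fully methylated trajectory gives unit probabilities", {
  m <- spread_model(n = 4, rates = spread_rates(k_demodification = 0,
                                                k_on = 0))
  tr <- toy_trajectory(m, initial_state(m, "all_M_occupied"),
                       empty_events(), 50)
  prof <- positional_profile(tr)
  expect_equal(prof$p_M, rep(1, 4))
  expect_equal(prof$p_Mt, rep(1, 4))
  cd <- count_distribution(tr, "M")
  expect_equal(cd$prob[cd$count == 4], 1)
  expect_equal(sum(cd$prob), 1)
})

test_that("two-interval toy trajectory is weighted by time spent in each state", {
  m <- spread_model(n = 2, initiation_sites = c(Mt = 1))
  init <- array_state(c("M", "U"), c("empty", "empty"))
  ev <- tibble::tibble(time = 30, kind = "demodify", enzyme = "none",
                       pos1 = 1L, pos2 = NA_integer_)
  tr <- toy_trajectory(m, init, ev, 100)
  prof <- positional_profile(tr, steady_fraction = 1)
  expect_equal(prof$p_M, c(0.3, 0))
  expect_equal(prof$p_U, c(0.7, 1))
  expect_equal(prof$p_M + prof$p_A + prof$p_U, c(1, 1))
  cd <- count_distribution(tr, "M", steady_fraction = 1)
  expect_equal(cd$prob[cd$count == 1], 0.3)
  expect_equal(cd$prob[cd$count == 0], 0.7)
  # restricting to the final 60% (t >= 40) sees only the second state
  prof2 <- positional_profile(tr, steady_fraction = 0.6)
  expect_equal(prof2$p_M, c(0, 0))
})

test_that("binned dynamics computes interpolated quartiles per bin", {
  m <- spread_model(n = 4, rates = spread_rates(k_demodification = 0,
                                                k_on = 0))
  mk <- function(n_m) {
    mods <- c(rep("M", n_m), rep("U", 4 - n_m))
    toy_trajectory(m, array_state(mods, rep("empty", 4)), empty_events(), 5)
  }
  bd <- binned_dynamics(list(mk(1), mk(2), mk(4)), "n_M")
  expect_equal(nrow(bd), 5)
  expect_true(all(bd$min == 1 & bd$max == 4))
  expect_true(all(bd$q25 == 1.5 & bd$median == 2 & bd$q75 == 3))
  expect_true(all(bd$min <= bd$q25 & bd$q25 <= bd$median &
                    bd$median <= bd$q75 & bd$q75 <= bd$max))
})

test_that("event-log estimators agree with the engine's streaming accumulators", {
  m <- spread_model(n = 10, mechanism = "combined")
  ens <- simulate_ensemble(m, reps = 1, t_end = 30, seed = 17)
  tr <- simulate_spread(m, t_end = 30, seed = ens$rep_seeds[1])
  prof_r <- positional_profile(list(tr), steady_fraction = 0.6)
  expect_equal(as.data.frame(prof_r), as.data.frame(ens$profile),
               tolerance = 1e-8)
  cd_r <- count_distribution(list(tr), "M", steady_fraction = 0.6)
  cd_c <- count_distribution(ens, "M")
  expect_equal(cd_r$prob, cd_c$prob, tolerance = 1e-8)
  bd_r <- binned_dynamics(list(tr), "n_M")
  bd_c <- binned_dynamics(ens, "n_M")
  expect_equal(bd_r$median, bd_c$median, tolerance = 1e-8)
  expect_equal(sum(cd_r$prob), 1, tolerance = 1e-9)
  expect_equal(prof_r$p_U + prof_r$p_A + prof_r$p_M, rep(1, 10),
               tolerance = 1e-9)
})

test_that("time-weighted occupancy estimates converge to the analytic background", {
  # with no enzyme influx each nucleosome is a two-state telegraph process
  # with equal 2.4 s^-1 switching rates: stationary P(U) = 1/2, and the
  # estimation error shrinks with simulated time
  m <- spread_model(n = 10, rates = spread_rates(k_on = 0))
  err <- sapply(c(200, 5000), function(T) {
    tr <- simulate_spread(m, t_end = T, seed = 11, init = "all_U_empty")
    mean(abs(positional_profile(list(tr), 1)$p_U - 0.5))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("establishment time finds the first bin at the plateau criterion", {
  dyn <- tibble::tibble(time = 0:99, median = pmin(0:99, 40))
  dyn$min <- dyn$q25 <- dyn$q75 <- dyn$max <- dyn$median
  class(dyn) <- c("spread_dynamics", class(dyn))
  et <- establishment_time(dyn)
  expect_equal(et$plateau, 40)
  expect_equal(et$time, 36)   # first time median >= 0.9 * 40
  et2 <- establishment_time(dyn, level = 0.5)
  expect_equal(et2$time, 20)
})

test_that("a fully seeded array always classifies as the high state", {
  res <- seeding_experiment(k = 50, reps = 4, t_end = 40, seed = 3)
  expect_equal(res$fraction, 1)
  expect_equal(res$n_high, 4)
  expect_true(all(res$tail_M[[1]] > 25))
  expect_error(seeding_experiment(k = 1, reps = 0),
               class = "nucspread_domain_error")
})

test_that("the boundary statistic time-averages M minus A per window and replicate", {
  m <- spread_model(n = 50, enzymes = "dual")
  fake <- structure(list(model = m, reps = 2, t_end = 30, bin = 1,
                         steady_fraction = 0.6,
                         counts = dplyr::bind_rows(
                           tibble::tibble(rep = 1, time = 0:29, n_U = 0,
                                          n_A = 0, n_M = 50, n_Mt = 0,
                                          n_At = 0),
                           tibble::tibble(rep = 2, time = 0:29, n_U = 10,
                                          n_A = 30, n_M = 10, n_Mt = 0,
                                          n_At = 0))),
                    class = "spread_ensemble")
  bs <- boundary_statistic(fake, window = 10, window_starts = c(0, 10))
  expect_equal(sort(bs$m_minus_a[bs$window_start == 0]), c(-20, 50))
  bd <- boundary_distribution(bs)
  expect_equal(as.numeric(tapply(bd$prob, bd$window_start, sum)), c(1, 1))
  expect_equal(sort(bd$value[bd$window_start == 0]), c(-20, 50))
  expect_error(boundary_statistic(fake, window = 10, window_starts = 25),
               class = "nucspread_domain_error")
  # single-enzyme ensembles are rejected
  fake_single <- fake
  fake_single$model <- spread_model(n = 50)
  expect_error(boundary_statistic(fake_single),
               class = "nucspread_domain_error")
})

test_that("tidy and glance summarize trajectories and ensembles", {
  m <- spread_model(n = 6, mechanism = "diffusion")
  tr <- simulate_spread(m, t_end = 5, seed = 1)
  expect_identical(tidy(tr), tr$events)
  g <- glance(tr)
  expect_equal(g$n_events, nrow(tr$events))
  ens <- simulate_ensemble(m, reps = 2, t_end = 5, seed = 1)
  expect_identical(tidy(ens), ens$counts)
  expect_equal(glance(ens)$reps, 2)
  sd <- seeding_experiment(k = 50, reps = 2, t_end = 20, seed = 2)
  expect_false("tail_M" %in% names(tidy(sd)))
})

test_that("autoplot methods return ggplot objects", {
  m <- spread_model(n = 6, mechanism = "combined")
  tr <- simulate_spread(m, t_end = 5, seed = 4)
  expect_s3_class(autoplot(kymograph(tr, 1)), "ggplot")
  ens <- simulate_ensemble(m, reps = 2, t_end = 5, seed = 4)
  expect_s3_class(autoplot(positional_profile(ens)), "ggplot")
  expect_s3_class(autoplot(binned_dynamics(ens)), "ggplot")
  expect_s3_class(autoplot(count_distribution(ens, "M")), "ggplot")
})
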