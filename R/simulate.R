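# shared plumbing between the R surface and the compiled engine

engine_args <- function(model, init) {
  st <- check_state(init, model)
  sites <- model$initiation_sites
  r <- model$rates
  list(n = model$n,
       mech = match(model$mechanism,
                    c("diffusion", "recruitment", "combined")) - 1L,
       dual = model$enzymes == "dual",
       mt_site = if ("Mt" %in% names(sites)) sites[["Mt"]] else 0L,
       at_site = if ("At" %in% names(sites)) sites[["At"]] else 0L,
       conn_sites = model$connectivity_sites,
       k_on = r$k_on, k_off = r$k_off, k_cat = r$k_transferase,
       k_nbr = r$k_neighbor,
       k_slide = r$k_slide / 2,  # engine takes the per-direction rate
       k_recr = r$k_recruitment,
       k_demod = r$k_demodification, k_bg = r$k_background_acetylation,
       k_int = r$k_interaction,
       init_mods = mod_code(st$mod), init_occ = occ_code(st$occ))
}

resolve_init <- function(model, init) {
  if (is.null(init)) initial_state(model, "all_A_empty")
  else if (is.character(init)) initial_state(model, init)
  else check_state(init, model)
}

#' Simulate one trajectory of the spreading model
#'
#' Runs an exact stochastic simulation of the continuous-time Markov chain
#' defined by [enumerate_reactions()] and returns the full event log. The
#' default method is the next-reaction method (an indexed-priority-queue
#' Gillespie variant updating only the channels whose propensities changed);
#' `"direct"` is the classical direct method, retained as an independent
#' cross-validation route. Identical `(model, init, seed, method)` give
#' identical trajectories. If the total propensity reaches zero before
#' `t_end` the final state is held to `t_end` (absorbing).
#'
#' @param model A [spread_model()].
#' @param t_end Simulation horizon in seconds (>= 0).
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#' @param init Initial state: an [array_state()], a preset name accepted by
#'   [initial_state()], or `NULL` for `"all_A_empty"`.
#' @param method `"next_reaction"` (default) or `"direct"`.
#' @param validate If `TRUE` (next-reaction only), re-derive every propensity
#'   from scratch after each event and stop on any disagreement with the
#'   incremental bookkeeping. Slow; for debugging.
#' @return A `spread_trajectory`: a list with the `model`, `seed`, `method`,
#'   `t_end`, `initial` state, `events` tibble (`time`, `kind`, `enzyme`,
#'   `pos1`, `pos2`) and `final` state.
#' @export
#' @examples
#' m <- spread_model(n = 10, mechanism = "diffusion")
#' tr <- simulate_spread(m, t_end = 5, seed = 1)
#' tr
simulate_spread <- function(model, t_end, seed = NULL, init = NULL,
                            method = c("next_reaction", "direct"),
                            validate = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end < 0)
    abort("`t_end` must be a single non-negative number",
          class = "nucspread_domain_error")
  if (!is.null(seed)) set.seed(seed)
  st <- resolve_init(model, init)
  ea <- engine_args(model, st)
  res <- do.call(cpp_simulate, c(ea, list(
    t_end = t_end, method = if (method == "next_reaction") 0L else 1L,
    validate = validate, record_events = TRUE, bin_dt = -1,
    window_start = 0, state_dist = FALSE, max_events = 0)))
  ev <- res$events
  events <- tibble(time = ev$time,
                   kind = KIND_LEVELS[ev$kind + 1L],
                   enzyme = c("none", "Mt", "At")[ev$enzyme + 1L],
                   pos1 = ev$pos1,
                   pos2 = ifelse(ev$pos2 == 0L, NA_integer_, ev$pos2))
  structure(list(model = model, seed = seed, method = method, t_end = t_end,
                 initial = st, events = events,
                 final = array_state(MOD_LEVELS[res$final_mods + 1L],
                                     OCC_LEVELS[res$final_occ + 1L])),
            class = "spread_trajectory")
}

#' @export
print.spread_trajectory <- function(x, ...) {
  cat("<spread_trajectory> ", nrow(x$events), " events over ", x$t_end,
      " s (", x$model$mechanism, ", ", x$model$enzymes, ", n = ",
      x$model$n, ")\n", sep = "")
  invisible(x)
}

# replay the event log in integer codes; returns codes at time t
replay_codes <- function(traj, t) {
  mods <- mod_code(traj$initial$mod)
  occ <- occ_code(traj$initial$occ)
  ev <- traj$events
  idx <- which(ev$time <= t)
  for (r in idx) {
    k <- ev$kind[r]; i <- ev$pos1[r]; j <- ev$pos2[r]
    e <- match(ev$enzyme[r], c("none", "Mt", "At")) - 1L
    if (k == "initiate" || k == "recruit") occ[i] <- e
    else if (k == "unbind") occ[i] <- 0L
    else if (k == "catalyze_site") mods[i] <- if (e == 1L) 2L else 1L
    else if (k == "catalyze_neighbor") mods[j] <- if (e == 1L) 2L else 1L
    else if (k == "slide") { occ[j] <- occ[i]; occ[i] <- 0L }
    else if (k == "background_acetylate") mods[i] <- 1L
    else if (k == "demodify") mods[i] <- 0L
    else if (k == "connect") { tmp <- occ[i]; occ[i] <- occ[j]; occ[j] <- tmp }
  }
  list(mods = mods, occ = occ)
}

#' State of a trajectory at an arbitrary time
#'
#' The trajectory is piecewise constant and right-continuous: `state_at()`
#' returns the state holding at time `t` (the initial state for `t = 0`, the
#' final state for any `t` past the last event).
#'
#' @param traj A [simulate_spread()] trajectory.
#' @param t Time in `[0, t_end]`.
#' @return An [array_state()].
#' @export
state_at <- function(traj, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > traj$t_end)
    abort("`t` must lie in [0, t_end]", class = "nucspread_domain_error")
  cd <- replay_codes(traj, t)
  array_state(MOD_LEVELS[cd$mods + 1L], OCC_LEVELS[cd$occ + 1L])
}

#' Kymograph of a trajectory
#'
#' Samples the trajectory on a regular time grid (`floor(t_end / dt) + 1`
#' rows at times `0, dt, 2 dt, ...`), recording each nucleosome's
#' modification state and occupancy — the position-by-time raster used to
#' visualize spreading.
#'
#' @param traj A [simulate_spread()] trajectory.
#' @param dt Sampling interval in seconds (> 0).
#' @return A tibble of class `spread_kymograph` with columns `time`,
#'   `position`, `mod`, `occ`.
#' @export
#' @examples
#' m <- spread_model(n = 10)
#' tr <- simulate_spread(m, t_end = 10, seed = 1)
#' ky <- kymograph(tr, dt = 1)
#' head(ky)
kymograph <- function(traj, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    abort("`dt` must be a single positive number",
          class = "nucspread_domain_error")
  times <- seq(0, by = dt, length.out = floor(traj$t_end / dt + 1e-9) + 1L)
  n <- traj$model$n
  # single forward replay over the sorted grid
  mods <- mod_code(traj$initial$mod)
  occ <- occ_code(traj$initial$occ)
  ev <- traj$events
  r <- 1L
  nev <- nrow(ev)
  rows <- vector("list", length(times))
  enz <- match(ev$enzyme, c("none", "Mt", "At")) - 1L
  for (s in seq_along(times)) {
    t <- times[s]
    while (r <= nev && ev$time[r] <= t) {
      k <- ev$kind[r]; i <- ev$pos1[r]; j <- ev$pos2[r]; e <- enz[r]
      if (k == "initiate" || k == "recruit") occ[i] <- e
      else if (k == "unbind") occ[i] <- 0L
      else if (k == "catalyze_site") mods[i] <- if (e == 1L) 2L else 1L
      else if (k == "catalyze_neighbor") mods[j] <- if (e == 1L) 2L else 1L
      else if (k == "slide") { occ[j] <- occ[i]; occ[i] <- 0L }
      else if (k == "background_acetylate") mods[i] <- 1L
      else if (k == "demodify") mods[i] <- 0L
      else if (k == "connect") { tmp <- occ[i]; occ[i] <- occ[j]; occ[j] <- tmp }
      r <- r + 1L
    }
    rows[[s]] <- tibble(time = t, position = seq_len(n),
                        mod = MOD_LEVELS[mods + 1L],
                        occ = OCC_LEVELS[occ + 1L])
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spread_kymograph", class(out))
  out
}

#' Simulate a replicate ensemble with streaming summaries
#'
#' Runs `reps` independent trajectories and accumulates, inside the compiled
#' engine, the summaries the analysis layer needs — per-second time-weighted
#' species counts, the time-weighted positional profile, and the
#' steady-state total-count distribution — without retaining event logs.
#' Replicate seeds are drawn from the master `seed` so any single replicate
#' can be re-run bit-identically with [simulate_spread()].
#'
#' @param model A [spread_model()].
#' @param reps Number of replicates (>= 1).
#' @param t_end Horizon per replicate, seconds.
#' @param seed Master integer seed.
#' @param init Initial state (as in [simulate_spread()]).
#' @param bin Width of the recording bins in seconds (default 1).
#' @param steady_fraction Fraction of the horizon, counted from the end,
#'   treated as steady state for the profile and count distribution
#'   (default 0.6, i.e. the final 60%).
#' @param method SSA variant, as in [simulate_spread()].
#' @return A `spread_ensemble` list: `counts` (tibble: `rep`, `time` = bin
#'   start, time-weighted `n_U`, `n_A`, `n_M`, `n_Mt`, `n_At`), `profile` and
#'   `count_dist` (ensemble-averaged matrices as tibbles), `final` states,
#'   `rep_seeds`, plus the call parameters.
#' @export
#' @examples
#' m <- spread_model(n = 10, mechanism = "diffusion")
#' ens <- simulate_ensemble(m, reps = 4, t_end = 20, seed = 1)
#' head(ens$counts)
simulate_ensemble <- function(model, reps, t_end, seed = NULL, init = NULL,
                              bin = 1, steady_fraction = 0.6,
                              method = c("next_reaction", "direct")) {
  method <- match.arg(method)
  if (reps < 1) abort("`reps` must be >= 1", class = "nucspread_domain_error")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  st <- resolve_init(model, init)
  ea <- engine_args(model, st)
  w0 <- (1 - steady_fraction) * t_end
  nbins <- max(1L, as.integer(ceiling(t_end / bin - 1e-9)))

  counts <- vector("list", reps)
  finals <- vector("list", reps)
  prof_acc <- NULL
  cdist_acc <- NULL
  for (i in seq_len(reps)) {
    set.seed(rep_seeds[i])
    res <- do.call(cpp_simulate, c(ea, list(
      t_end = t_end, method = if (method == "next_reaction") 0L else 1L,
      validate = FALSE, record_events = FALSE, bin_dt = bin,
      window_start = w0, state_dist = FALSE, max_events = 0)))
    b <- res$bins
    counts[[i]] <- tibble(rep = i,
                          time = (seq_len(nbins) - 1) * bin,
                          n_U = b[, 1], n_A = b[, 2], n_M = b[, 3],
                          n_Mt = b[, 4], n_At = b[, 5])
    finals[[i]] <- array_state(MOD_LEVELS[res$final_mods + 1L],
                               OCC_LEVELS[res$final_occ + 1L])
    prof_acc <- if (is.null(prof_acc)) res$profile else prof_acc + res$profile
    cdist_acc <- if (is.null(cdist_acc)) res$count_dist
                 else cdist_acc + res$count_dist
  }
  prof <- prof_acc / reps
  cdist <- cdist_acc / reps
  profile <- tibble(position = seq_len(model$n),
                    p_U = prof[, 1], p_A = prof[, 2], p_M = prof[, 3],
                    p_Mt = prof[, 4], p_At = prof[, 5])
  class(profile) <- c("spread_profile", class(profile))
  count_dist <- tibble(count = 0:model$n,
                       p_U = cdist[, 1], p_A = cdist[, 2], p_M = cdist[, 3],
                       p_Mt = cdist[, 4], p_At = cdist[, 5])
  class(count_dist) <- c("spread_count_dist", class(count_dist))
  structure(list(model = model, reps = reps, t_end = t_end, bin = bin,
                 steady_fraction = steady_fraction, method = method,
                 seed = seed, rep_seeds = rep_seeds,
                 counts = dplyr::bind_rows(counts),
                 profile = profile, count_dist = count_dist,
                 final = finals),
            class = "spread_ensemble")
}

#' @export
print.spread_ensemble <- function(x, ...) {
  cat("<spread_ensemble> ", x$reps, " replicates x ", x$t_end,
      " s (", x$model$mechanism, ", ", x$model$enzymes, ", n = ",
      x$model$n, ")\n", sep = "")
  invisible(x)
}
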