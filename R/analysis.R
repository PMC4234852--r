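# Exact time-weighted estimators on event logs (single forward replay).
# Every interval between events contributes its duration; the steady-state
# window is the final `steady_fraction` of the horizon.
traj_stats <- function(traj, steady_fraction = 0.6, bin = 1) {
  n <- traj$model$n
  t_end <- traj$t_end
  w0 <- (1 - steady_fraction) * t_end
  wlen <- t_end - w0
  mods <- mod_code(traj$initial$mod)
  occ <- occ_code(traj$initial$occ)
  cnt <- c(tabulate(mods + 1L, 3L), tabulate(occ + 1L, 3L)[2:3]) # U A M Mt At
  prof <- matrix(0, n, 5)
  cdist <- matrix(0, n + 1, 5)
  nbins <- max(1L, as.integer(ceiling(t_end / bin - 1e-9)))
  bins <- matrix(0, nbins, 5)
  bin_dur <- numeric(nbins)
  last_mod_t <- numeric(n)
  last_occ_t <- numeric(n)

  flush_mod <- function(i, t) {
    d <- min(t, t_end) - max(last_mod_t[i], w0)
    if (d > 0) prof[i, mods[i] + 1L] <<- prof[i, mods[i] + 1L] + d
    last_mod_t[i] <<- t
  }
  flush_occ <- function(i, t) {
    d <- min(t, t_end) - max(last_occ_t[i], w0)
    if (d > 0 && occ[i] > 0L)
      prof[i, 3L + occ[i]] <<- prof[i, 3L + occ[i]] + d
    last_occ_t[i] <<- t
  }
  set_mod <- function(i, v, t) {
    if (mods[i] == v) return(invisible())
    flush_mod(i, t)
    cnt[mods[i] + 1L] <<- cnt[mods[i] + 1L] - 1
    cnt[v + 1L] <<- cnt[v + 1L] + 1
    mods[i] <<- v
  }
  set_occ <- function(i, v, t) {
    if (occ[i] == v) return(invisible())
    flush_occ(i, t)
    if (occ[i] > 0L) cnt[3L + occ[i]] <<- cnt[3L + occ[i]] - 1
    if (v > 0L) cnt[3L + v] <<- cnt[3L + v] + 1
    occ[i] <<- v
  }
  accumulate <- function(t0, t1) {
    if (t1 <= t0) return(invisible())
    b0 <- min(floor(t0 / bin), nbins - 1)
    s <- t0
    while (s < t1) {
      bend <- if (b0 == nbins - 1) t_end else (b0 + 1) * bin
      e <- min(t1, bend)
      bins[b0 + 1, ] <<- bins[b0 + 1, ] + cnt * (e - s)
      bin_dur[b0 + 1] <<- bin_dur[b0 + 1] + (e - s)
      s <- e
      if (s >= t1) break
      b0 <- b0 + 1
    }
    wd <- min(t1, t_end) - max(t0, w0)
    if (wd > 0)
      for (sp in 1:5)
        cdist[cnt[sp] + 1L, sp] <<- cdist[cnt[sp] + 1L, sp] + wd
  }

  ev <- traj$events
  enz <- match(ev$enzyme, c("none", "Mt", "At")) - 1L
  t_prev <- 0
  for (r in seq_len(nrow(ev))) {
    t <- ev$time[r]
    accumulate(t_prev, t)
    k <- ev$kind[r]; i <- ev$pos1[r]; j <- ev$pos2[r]; e <- enz[r]
    if (k == "initiate" || k == "recruit") set_occ(i, e, t)
    else if (k == "unbind") set_occ(i, 0L, t)
    else if (k == "catalyze_site") set_mod(i, if (e == 1L) 2L else 1L, t)
    else if (k == "catalyze_neighbor") set_mod(j, if (e == 1L) 2L else 1L, t)
    else if (k == "slide") { set_occ(j, occ[i], t); set_occ(i, 0L, t) }
    else if (k == "background_acetylate") set_mod(i, 1L, t)
    else if (k == "demodify") set_mod(i, 0L, t)
    else if (k == "connect") {
      o1 <- occ[i]; o2 <- occ[j]
      set_occ(i, o2, t); set_occ(j, o1, t)
    }
    t_prev <- t
  }
  accumulate(t_prev, t_end)
  for (i in seq_len(n)) { flush_mod(i, t_end); flush_occ(i, t_end) }

  ok <- bin_dur > 0
  bins[ok, ] <- bins[ok, ] / bin_dur[ok]
  colnames(bins) <- colnames(prof) <- colnames(cdist) <-
    c("n_U", "n_A", "n_M", "n_Mt", "n_At")
  list(profile = if (wlen > 0) prof / wlen else prof,
       count_dist = if (wlen > 0) cdist / wlen else cdist,
       bins = bins, bin_times = (seq_len(nbins) - 1) * bin)
}

as_traj_list <- function(x) {
  if (inherits(x, "spread_trajectory")) return(list(x))
  if (is.list(x) && length(x) && all(vapply(x, inherits, logical(1),
                                            "spread_trajectory")))
    return(x)
  abort("expected a spread_trajectory, a list of them, or a spread_ensemble",
        class = "nucspread_domain_error")
}

#' Time-weighted positional modification profile
#'
#' The probability, per nucleosome position, of carrying each modification
#' state and of being occupied by each transferase, estimated as time
#' averages over the final `steady_fraction` of each trajectory and averaged
#' across the ensemble — the stationary pattern a ChIP-style readout would
#' see.
#'
#' @param x A `spread_ensemble`, a `spread_trajectory`, or a list of
#'   trajectories (all sharing one configuration).
#' @param steady_fraction Fraction of the horizon, from the end, used as the
#'   steady-state window (default 0.6). For ensembles the window is fixed at
#'   simulation time and must match.
#' @return A tibble of class `spread_profile`: `position`, `p_U`, `p_A`,
#'   `p_M`, `p_Mt`, `p_At`; the three modification probabilities sum to 1 at
#'   every position.
#' @export
positional_profile <- function(x, steady_fraction = 0.6) {
  if (inherits(x, "spread_ensemble")) {
    if (abs(steady_fraction - x$steady_fraction) > 1e-12)
      abort("ensemble was recorded with a different `steady_fraction`",
            class = "nucspread_domain_error")
    return(x$profile)
  }
  trajs <- as_traj_list(x)
  profs <- lapply(trajs, function(tr) traj_stats(tr, steady_fraction)$profile)
  prof <- Reduce(`+`, profs) / length(profs)
  out <- tibble(position = seq_len(nrow(prof)),
                p_U = prof[, 1], p_A = prof[, 2], p_M = prof[, 3],
                p_Mt = prof[, 4], p_At = prof[, 5])
  class(out) <- c("spread_profile", class(out))
  out
}

#' Steady-state distribution of a total species count
#'
#' Time-weighted probability mass over the total number of nucleosomes in a
#' modification state (or the total number of bound enzymes), over the final
#' `steady_fraction` of each trajectory, averaged across the ensemble.
#'
#' @inheritParams positional_profile
#' @param species One of `"M"`, `"A"`, `"U"`, `"Mt"`, `"At"`.
#' @return A tibble `count` (0..n), `prob` (sums to 1), `species`.
#' @export
count_distribution <- function(x, species = c("M", "A", "U", "Mt", "At"),
                               steady_fraction = 0.6) {
  species <- match.arg(species)
  col <- paste0("p_", species)
  if (inherits(x, "spread_ensemble")) {
    if (abs(steady_fraction - x$steady_fraction) > 1e-12)
      abort("ensemble was recorded with a different `steady_fraction`",
            class = "nucspread_domain_error")
    cd <- x$count_dist
    out <- tibble(count = cd$count, prob = cd[[col]], species = species)
  } else {
    trajs <- as_traj_list(x)
    cds <- lapply(trajs,
                  function(tr) traj_stats(tr, steady_fraction)$count_dist)
    cd <- Reduce(`+`, cds) / length(cds)
    sp_col <- paste0("n_", species)
    out <- tibble(count = seq_len(nrow(cd)) - 1L, prob = cd[, sp_col],
                  species = species)
  }
  class(out) <- c("spread_count_distribution", class(out))
  out
}

#' Binned ensemble dynamics of a species count
#'
#' Per time bin, order statistics (minimum, quartiles, median, maximum) of a
#' per-trajectory time-weighted count across the replicate ensemble — the
#' error-bar representation of activation and relaxation time courses.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param x A `spread_ensemble` (uses its recorded bins) or a list of
#'   trajectories.
#' @param observable One of `"n_M"`, `"n_A"`, `"n_U"`, `"n_Mt"`, `"n_At"`.
#' @param bin Bin width in seconds (trajectory input only; ensembles use the
#'   width they were recorded with).
#' @return A tibble of class `spread_dynamics`: `time` (bin start), `min`,
#'   `q25`, `median`, `q75`, `max`.
#' @export
binned_dynamics <- function(x, observable = "n_M", bin = 1) {
  obs_ok <- c("n_U", "n_A", "n_M", "n_Mt", "n_At")
  if (!observable %in% obs_ok)
    abort(paste("`observable` must be one of", paste(obs_ok, collapse = ", ")),
          class = "nucspread_domain_error")
  if (inherits(x, "spread_ensemble")) {
    per_rep <- x$counts[, c("rep", "time", observable)]
    names(per_rep)[3] <- "value"
  } else {
    trajs <- as_traj_list(x)
    per_rep <- dplyr::bind_rows(lapply(seq_along(trajs), function(i) {
      st <- traj_stats(trajs[[i]], bin = bin)
      tibble(rep = i, time = st$bin_times, value = st$bins[, observable])
    }))
  }
  out <- per_rep %>%
    group_by(.data$time) %>%
    summarise(min = min(.data$value),
              q25 = unname(quantile(.data$value, 0.25, type = 7)),
              median = unname(quantile(.data$value, 0.5, type = 7)),
              q75 = unname(quantile(.data$value, 0.75, type = 7)),
              max = max(.data$value),
              .groups = "drop")
  attr(out, "observable") <- observable
  class(out) <- c("spread_dynamics", class(out))
  out
}

#' Time for the median trace to reach its stationary plateau
#'
#' Estimates the establishment time of a modification pattern from binned
#' ensemble dynamics: the plateau is the mean of the median trace over the
#' final `plateau_fraction` of the horizon, and the establishment time is
#' the first bin at which the median reaches `level` times that plateau.
#'
#' @param dynamics A [binned_dynamics()] tibble.
#' @param level Fraction of the plateau to reach (default 0.9).
#' @param plateau_fraction Final fraction of the horizon that defines the
#'   plateau (default 0.25).
#' @return A one-row tibble: `time` (s; `NA` if never reached), `plateau`,
#'   `level`.
#' @export
establishment_time <- function(dynamics, level = 0.9,
                               plateau_fraction = 0.25) {
  t_max <- max(dynamics$time)
  tail_rows <- dynamics$time >= (1 - plateau_fraction) * t_max
  plateau <- mean(dynamics$median[tail_rows])
  hit <- which(dynamics$median >= level * plateau)
  tibble(time = if (length(hit)) dynamics$time[min(hit)] else NA_real_,
         plateau = plateau, level = level)
}

#' Relaxation experiment: pattern stability without initiation influx
#'
#' Starts every replicate fully methylated with a methyltransferase on every
#' nucleosome, disables influx at the initiation site, and follows the decay
#' (or persistence) of the total methylation level. Diffusion-only and
#' weak-recruitment mechanisms decay to the background; the combined
#' mechanism can maintain the pattern through recruitment alone.
#'
#' @param model A [spread_model()]; its initiation channels are disabled for
#'   the run.
#' @param reps Number of replicates (>= 1).
#' @param t_end Horizon in seconds.
#' @param seed Master seed.
#' @param ... Passed to [simulate_ensemble()].
#' @return A [binned_dynamics()] tibble of the total methylation count, with
#'   the underlying `spread_ensemble` in attribute `"ensemble"`.
#' @export
relaxation_experiment <- function(model, reps, t_end, seed = NULL, ...) {
  if (reps < 1) abort("`reps` must be >= 1", class = "nucspread_domain_error")
  m0 <- model
  m0$rates$k_on <- 0
  ens <- simulate_ensemble(m0, reps = reps, t_end = t_end, seed = seed,
                           init = "all_M_occupied", ...)
  out <- binned_dynamics(ens, "n_M")
  attr(out, "ensemble") <- ens
  out
}

# per-replicate time-average of a counts column over the final tail_fraction
tail_means <- function(ens, observable = "n_M", tail_fraction = 0.1) {
  t0 <- (1 - tail_fraction) * ens$t_end
  ens$counts %>%
    filter(.data$time >= t0 - 1e-9) %>%
    group_by(.data$rep) %>%
    summarise(value = mean(.data[[observable]]), .groups = "drop") %>%
    arrange(.data$rep)
}

#' Seeding bistability experiment
#'
#' Starts the combined diffusion + recruitment model from `k` equidistant
#' methylated nucleosomes, each occupied by a methyltransferase, on an
#' otherwise unmodified, enzyme-free array, and measures the fraction of
#' replicates that end in the high-methylation stationary state. A replicate
#' is classified "high" if its time-averaged total methylation over the
#' final `tail_fraction` of the run exceeds `threshold` (default n/2 — the
#' two modes sit near 0 and ~0.8 n, so any mid-gap threshold is equivalent).
#' By default initiation influx is disabled, matching the relaxation-style
#' setting this experiment probes (with influx active at the single-enzyme
#' default of 2.4 s^-1 every replicate establishes the pattern within about
#' a minute, erasing the dependence on the seed count); set `influx = TRUE`
#' to keep the initiation channel open.
#'
#' @param k Vector of seed counts.
#' @param reps Replicates per seed count.
#' @param t_end Horizon in seconds (default 400, ample for the end states to
#'   settle).
#' @param seed Master seed.
#' @param n Array length (default 50).
#' @param k_recruitment Recruitment rate (default 2.4 s^-1).
#' @param influx Keep initiation influx active? Default `FALSE`.
#' @param threshold High-state classification threshold (default `n / 2`).
#' @param tail_fraction Final fraction of the run used by the classifier
#'   (default 0.1).
#' @param model Optional pre-built combined-mechanism model overriding `n`
#'   and `k_recruitment`.
#' @return A tibble of class `spread_seeding`, one row per seed count:
#'   `seeds`, `reps`, `n_high`, `fraction`, `conf_low`, `conf_high`
#'   (Clopper-Pearson 95%), `mean_M_high` (ensemble mean of the final-window
#'   methylation among high replicates), and `tail_M` (list-column of the
#'   per-replicate final-window means).
#' @export
#' @examples
#' \donttest{
#' seeding_experiment(k = 1, reps = 20, t_end = 200, seed = 1)
#' }
seeding_experiment <- function(k, reps, t_end = 400, seed = NULL, n = 50,
                               k_recruitment = 2.4, influx = FALSE,
                               threshold = n / 2, tail_fraction = 0.1,
                               model = NULL) {
  if (reps < 1) abort("`reps` must be >= 1", class = "nucspread_domain_error")
  if (is.null(model))
    model <- spread_model(n = n, mechanism = "combined", enzymes = "single_mt",
                          rates = spread_rates(k_on = 2.4,
                                               k_recruitment = k_recruitment))
  if (!influx) model$rates$k_on <- 0
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(k))
  rows <- lapply(seq_along(k), function(idx) {
    ki <- k[idx]
    ens <- simulate_ensemble(model, reps = reps, t_end = t_end,
                             seed = sub_seeds[idx],
                             init = initial_state(model, "k_seeds", k = ki))
    tm <- tail_means(ens, "n_M", tail_fraction)$value
    high <- tm > threshold
    ci <- binom.test(sum(high), reps)$conf.int
    tibble(seeds = ki, reps = reps, n_high = sum(high),
           fraction = mean(high), conf_low = ci[1], conf_high = ci[2],
           mean_M_high = if (any(high)) mean(tm[high]) else NA_real_,
           tail_M = list(tm))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spread_seeding", class(out))
  out
}

#' Boundary statistic for dual-enzyme runs
#'
#' For each sampling window, the per-replicate time average of (total
#' methylated minus total acetylated nucleosomes) — the summary that tracks
#' where the modification boundary sits and whether one mark has taken over
#' the array.
#'
#' @param ens A dual-enzyme `spread_ensemble` recorded with bins no wider
#'   than the window.
#' @param window Window length in seconds (default 10).
#' @param window_starts Window start times (default `seq(0, 700, 100)`,
#'   clipped to windows that fit in the horizon is an error instead).
#' @return A tibble of class `spread_boundary`: `window_start`, `rep`,
#'   `m_minus_a`.
#' @export
boundary_statistic <- function(ens, window = 10,
                               window_starts = seq(0, 700, by = 100)) {
  if (!inherits(ens, "spread_ensemble"))
    abort("`ens` must be a spread_ensemble", class = "nucspread_domain_error")
  if (ens$model$enzymes != "dual")
    abort("the boundary statistic is defined for dual-enzyme models",
          class = "nucspread_domain_error")
  if (any(window_starts + window > ens$t_end + 1e-9))
    abort("a sampling window extends beyond t_end",
          class = "nucspread_domain_error")
  rows <- lapply(window_starts, function(w) {
    ens$counts %>%
      filter(.data$time >= w - 1e-9, .data$time < w + window - 1e-9) %>%
      group_by(.data$rep) %>%
      summarise(m_minus_a = mean(.data$n_M - .data$n_A), .groups = "drop") %>%
      mutate(window_start = w)
  })
  out <- dplyr::bind_rows(rows) %>%
    select("window_start", "rep", "m_minus_a")
  class(out) <- c("spread_boundary", class(out))
  out
}

#' Replicate distribution of the boundary statistic
#'
#' Aggregates [boundary_statistic()] values into a probability distribution
#' per window (values rounded to the nearest integer count difference).
#'
#' @param bs A [boundary_statistic()] tibble.
#' @return A tibble: `window_start`, `value`, `prob` (sums to 1 per window).
#' @export
boundary_distribution <- function(bs) {
  bs %>%
    mutate(value = round(.data$m_minus_a)) %>%
    group_by(.data$window_start, .data$value) %>%
    summarise(nrep = n(), .groups = "drop_last") %>%
    mutate(prob = .data$nrep / sum(.data$nrep)) %>%
    ungroup() %>%
    select("window_start", "value", "prob")
}
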