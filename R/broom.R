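#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trajectory into its event log
#'
#' @param x A `spread_trajectory`.
#' @param ... Unused.
#' @return The events tibble (`time`, `kind`, `enzyme`, `pos1`, `pos2`).
#' @method tidy spread_trajectory
#' @export
tidy.spread_trajectory <- function(x, ...) x$events

#' One-row trajectory summary
#'
#' @param x A `spread_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: horizon, event count, per-kind counts and the
#'   final species totals.
#' @method glance spread_trajectory
#' @export
glance.spread_trajectory <- function(x, ...) {
  ev <- x$events
  fin <- x$final
  tibble(t_end = x$t_end, n_events = nrow(ev),
         n_slide = sum(ev$kind == "slide"),
         n_recruit = sum(ev$kind == "recruit"),
         n_connect = sum(ev$kind == "connect"),
         final_M = sum(fin$mod == "M"), final_A = sum(fin$mod == "A"),
         final_Mt = sum(fin$occ == "Mt"), final_At = sum(fin$occ == "At"))
}

#' Tidy an ensemble into per-replicate binned counts
#'
#' @param x A `spread_ensemble`.
#' @param ... Unused.
#' @return The long counts tibble (`rep`, `time`, `n_U` ... `n_At`).
#' @method tidy spread_ensemble
#' @export
tidy.spread_ensemble <- function(x, ...) x$counts

#' One-row ensemble summary
#'
#' @param x A `spread_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble with replicate count, horizon and the ensemble
#'   mean final-bin species totals.
#' @method glance spread_ensemble
#' @export
glance.spread_ensemble <- function(x, ...) {
  last <- x$counts %>% filter(.data$time == max(.data$time))
  tibble(reps = x$reps, t_end = x$t_end,
         mechanism = x$model$mechanism, enzymes = x$model$enzymes,
         mean_final_M = mean(last$n_M), mean_final_A = mean(last$n_A),
         mean_final_Mt = mean(last$n_Mt), mean_final_At = mean(last$n_At))
}

#' Tidy a seeding experiment
#'
#' @param x A `spread_seeding` result.
#' @param ... Unused.
#' @return The per-seed-count summary without the list-column.
#' @method tidy spread_seeding
#' @export
tidy.spread_seeding <- function(x, ...) {
  out <- x
  out$tail_M <- NULL
  class(out) <- setdiff(class(out), "spread_seeding")
  out
}
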