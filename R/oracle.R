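# Exact small-system machinery: enumerate the reachable state space with the
# reference rule set (enumerate_reactions / apply_reaction), build the CTMC
# generator, and solve for its stationary distribution. Feasible for short
# arrays only; used to validate the stochastic engine.

state_key <- function(state) {
  # base-9 code per position, matching the engine's encoding
  sum((mod_code(state$mod) + 3 * occ_code(state$occ)) *
        9^(seq_len(nrow(state)) - 1))
}

#' Enumerate the reachable state space of a small model
#'
#' Breadth-first search over states reachable from `init` by the model's
#' reaction channels. Exponential in `n`; intended for `n <= 4` or so.
#'
#' @param model A [spread_model()].
#' @param init Starting [array_state()] (default all-U, empty).
#' @return A list with `states` (list of array states) and `key` (numeric
#'   codes, in discovery order).
#' @export
reachable_states <- function(model, init = NULL) {
  init <- if (is.null(init)) initial_state(model, "all_U_empty")
          else check_state(init, model)
  seen <- new.env(parent = emptyenv())
  states <- list(init)
  assign(sprintf("%.0f", state_key(init)), 1L, envir = seen)
  q <- 1L
  while (q <= length(states)) {
    s <- states[[q]]
    ch <- enumerate_reactions(s, model)
    for (r in seq_len(nrow(ch))) {
      s2 <- apply_reaction(s, ch[r, ], check = FALSE)
      k2 <- sprintf("%.0f", state_key(s2))
      if (is.null(get0(k2, envir = seen))) {
        states[[length(states) + 1L]] <- s2
        assign(k2, length(states), envir = seen)
      }
    }
    q <- q + 1L
  }
  list(states = states,
       key = vapply(states, state_key, numeric(1)))
}

#' Exact CTMC generator matrix of a small model
#'
#' Builds the infinitesimal generator Q over the reachable state space:
#' `Q[i, j]` is the total propensity of moving from state i to state j, and
#' rows sum to zero.
#'
#' @inheritParams reachable_states
#' @return A list: `Q` (dense matrix), `states`, `key`.
#' @export
generator_matrix <- function(model, init = NULL) {
  rs <- reachable_states(model, init)
  m <- length(rs$states)
  idx <- setNames(seq_len(m), sprintf("%.0f", rs$key))
  Q <- matrix(0, m, m)
  for (i in seq_len(m)) {
    ch <- enumerate_reactions(rs$states[[i]], model)
    for (r in seq_len(nrow(ch))) {
      s2 <- apply_reaction(rs$states[[i]], ch[r, ], check = FALSE)
      j <- idx[[sprintf("%.0f", state_key(s2))]]
      if (j != i) Q[i, j] <- Q[i, j] + ch$propensity[r]
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  list(Q = Q, states = rs$states, key = rs$key)
}

#' Exact stationary distribution of a small model
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a dense linear solve over the
#' reachable state space. The chain restricted to that space is irreducible
#' for all standard configurations, so the solution is unique.
#'
#' @inheritParams reachable_states
#' @return A tibble: `key` (state code), `prob`.
#' @export
exact_stationary <- function(model, init = NULL) {
  g <- generator_matrix(model, init)
  m <- nrow(g$Q)
  A <- rbind(t(g$Q), rep(1, m))
  b <- c(rep(0, m), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  tibble(key = g$key, prob = pi_hat / sum(pi_hat))
}

#' Empirical time-weighted state distribution of a small-system run
#'
#' Simulates one long trajectory with the compiled engine, accumulating the
#' fraction of time spent in every discrete joint state (array length at
#' most 12), after discarding a burn-in. Comparable directly with
#' [exact_stationary()] via the shared state coding.
#'
#' @param model A [spread_model()] with small `n`.
#' @param t_end Simulated seconds.
#' @param seed Integer seed.
#' @param init Initial state (default all-U, empty).
#' @param burn_in Fraction of the run discarded from the front (default 0.1).
#' @param method SSA variant.
#' @return A tibble: `key`, `prob`.
#' @export
empirical_state_distribution <- function(model, t_end, seed = NULL,
                                         init = NULL, burn_in = 0.1,
                                         method = c("next_reaction",
                                                    "direct")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  st <- resolve_init(model, init)
  ea <- engine_args(model, st)
  res <- do.call(cpp_simulate, c(ea, list(
    t_end = t_end, method = if (method == "next_reaction") 0L else 1L,
    validate = FALSE, record_events = FALSE, bin_dt = -1,
    window_start = burn_in * t_end, state_dist = TRUE, max_events = 0)))
  tibble(key = res$state_codes,
         prob = res$state_times / sum(res$state_times))
}

#' Total-variation distance between two state distributions
#'
#' @param p,q Tibbles with columns `key`, `prob` (as returned by
#'   [exact_stationary()] and [empirical_state_distribution()]).
#' @return Half the L1 distance, in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  merged <- dplyr::full_join(p, q, by = "key", suffix = c("_p", "_q")) %>%
    mutate(across(c("prob_p", "prob_q"), ~ tidyr::replace_na(.x, 0)))
  sum(abs(merged$prob_p - merged$prob_q)) / 2
}
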