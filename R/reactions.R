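#' Enumerate the reaction channels enabled in a state
#'
#' Lists every reaction channel of the continuous-time Markov chain that is
#' enabled in `state` under `model`, with its propensity. The channel kinds:
#'
#' * `initiate` — an enzyme binds its (unoccupied) initiation site, rate
#'   `k_on`; independent of the modification state of the site.
#' * `unbind` — a bound enzyme releases, rate `k_off`.
#' * `catalyze_site` — a bound enzyme converts its own unmodified nucleosome
#'   to its mark, rate `k_transferase`.
#' * `catalyze_neighbor` — (recruitment/combined only) a bound enzyme marks
#'   an unmodified flanking nucleosome, rate `k_neighbor`; the neighbour's
#'   occupancy is irrelevant.
#' * `slide` — (diffusion/combined only) a bound enzyme hops to an empty
#'   adjacent nucleosome at rate `k_slide / 2` per direction (equal chance
#'   left or right, total hop rate `k_slide`); boundaries are reflective and
#'   enzymes cannot pass one another.
#' * `recruit` — (recruitment/combined only) an enzyme binds an unoccupied
#'   nucleosome carrying its own mark, rate `k_recruitment` per eligible
#'   nucleosome.
#' * `background_acetylate` — (single-enzyme models only) ubiquitous U -> A,
#'   rate `k_background_acetylation`, regardless of occupancy.
#' * `demodify` — ubiquitous M -> U and A -> U, rate `k_demodification`,
#'   regardless of occupancy (a bound enzyme does not shield its mark).
#' * `connect` — per unordered pair of connectivity sites with at least one
#'   bound enzyme, rate `k_interaction`; the enzyme hops across (or the two
#'   enzymes exchange positions), independent of modification states.
#'
#' @param state An [array_state()].
#' @param model A [spread_model()].
#' @return A tibble with columns `kind`, `enzyme` (`"Mt"`, `"At"` or
#'   `"none"`), `pos1`, `pos2` (`NA` for single-position channels) and
#'   `propensity` (s^-1). For `catalyze_neighbor` and `slide`, `pos1` is the
#'   enzyme's position and `pos2` the target nucleosome.
#' @export
#' @examples
#' m <- spread_model(n = 6, mechanism = "combined")
#' s <- initial_state(m, "k_seeds", k = 1)
#' enumerate_reactions(s, m)
enumerate_reactions <- function(state, model) {
  state <- check_state(state, model)
  n <- model$n
  r <- model$rates
  mech <- model$mechanism
  dual <- model$enzymes == "dual"
  mods <- state$mod
  occ <- state$occ

  out <- list()
  add <- function(kind, enzyme, pos1, pos2, a) {
    if (a > 0)
      out[[length(out) + 1L]] <<- list(kind = kind, enzyme = enzyme,
                                       pos1 = as.integer(pos1),
                                       pos2 = as.integer(pos2), propensity = a)
  }

  # initiation: modification-independent, blocked if the site is occupied
  for (e in names(model$initiation_sites)) {
    site <- model$initiation_sites[[e]]
    if (occ[site] == "empty") add("initiate", e, site, NA, r$k_on)
  }

  for (i in seq_len(n)) {
    if (occ[i] != "empty") {
      e <- occ[i]
      add("unbind", e, i, NA, r$k_off)
      if (mods[i] == "U") add("catalyze_site", e, i, NA, r$k_transferase)
      if (mech %in% c("recruitment", "combined")) {
        for (j in c(i - 1L, i + 1L))
          if (j >= 1L && j <= n && mods[j] == "U")
            add("catalyze_neighbor", e, i, j, r$k_neighbor)
      }
      if (mech %in% c("diffusion", "combined")) {
        for (j in c(i - 1L, i + 1L))
          if (j >= 1L && j <= n && occ[j] == "empty")
            add("slide", e, i, j, r$k_slide / 2)
      }
    } else {
      if (mech %in% c("recruitment", "combined")) {
        if (mods[i] == "M") add("recruit", "Mt", i, NA, r$k_recruitment)
        if (dual && mods[i] == "A") add("recruit", "At", i, NA, r$k_recruitment)
      }
    }
    if (!dual && mods[i] == "U")
      add("background_acetylate", "none", i, NA, r$k_background_acetylation)
    if (mods[i] != "U")
      add("demodify", "none", i, NA, r$k_demodification)
  }

  cs <- model$connectivity_sites
  if (length(cs) >= 2) {
    for (a_i in seq_len(length(cs) - 1L)) {
      for (b_i in seq(a_i + 1L, length(cs))) {
        p <- cs[a_i]; q <- cs[b_i]
        if (occ[p] != "empty" || occ[q] != "empty")
          add("connect", "none", p, q, r$k_interaction)
      }
    }
  }

  if (!length(out))
    return(tibble(kind = character(), enzyme = character(),
                  pos1 = integer(), pos2 = integer(), propensity = double()))
  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}

#' Apply one reaction to a state
#'
#' Deterministically updates an array state by firing a single reaction
#' channel. Only the positions named in the channel change.
#'
#' @param state An [array_state()].
#' @param reaction A one-row tibble (e.g. one row of [enumerate_reactions()])
#'   or a list with elements `kind`, `enzyme`, `pos1`, `pos2`.
#' @param check If `TRUE`, verify the channel's preconditions hold in `state`
#'   and raise a logic error otherwise.
#' @return The updated [array_state()].
#' @export
#' @examples
#' m <- spread_model(n = 4)
#' s <- initial_state(m, "all_U_empty")
#' apply_reaction(s, list(kind = "initiate", enzyme = "Mt", pos1 = 2, pos2 = NA))
apply_reaction <- function(state, reaction, check = TRUE) {
  mods <- state$mod
  occ <- state$occ
  kind <- reaction$kind
  e <- reaction$enzyme
  i <- reaction$pos1
  j <- reaction$pos2
  fail <- function(msg) abort(paste0("reaction not enabled: ", msg),
                              class = "nucspread_logic_error")
  switch(kind,
    initiate = {
      if (check && occ[i] != "empty") fail("initiation site occupied")
      occ[i] <- e
    },
    unbind = {
      if (check && occ[i] == "empty") fail("no enzyme to unbind")
      occ[i] <- "empty"
    },
    catalyze_site = {
      if (check && (occ[i] == "empty" || mods[i] != "U"))
        fail("catalyze_site needs a bound enzyme on a U nucleosome")
      mods[i] <- enzyme_mark(occ[i])
    },
    catalyze_neighbor = {
      if (check && (occ[i] == "empty" || mods[j] != "U"))
        fail("catalyze_neighbor needs a bound enzyme and a U neighbour")
      mods[j] <- enzyme_mark(occ[i])
    },
    slide = {
      if (check && (occ[i] == "empty" || occ[j] != "empty" || abs(j - i) != 1))
        fail("slide needs a bound enzyme and an empty adjacent target")
      occ[j] <- occ[i]
      occ[i] <- "empty"
    },
    recruit = {
      if (check && (occ[i] != "empty" || mods[i] != enzyme_mark(e)))
        fail("recruit needs an empty nucleosome carrying the enzyme's mark")
      occ[i] <- e
    },
    background_acetylate = {
      if (check && mods[i] != "U") fail("background acetylation needs U")
      mods[i] <- "A"
    },
    demodify = {
      if (check && mods[i] == "U") fail("demodification needs a mark")
      mods[i] <- "U"
    },
    connect = {
      if (check && occ[i] == "empty" && occ[j] == "empty")
        fail("connect needs at least one bound enzyme")
      tmp <- occ[i]; occ[i] <- occ[j]; occ[j] <- tmp
    },
    abort(sprintf("unknown reaction kind '%s'", kind),
          class = "nucspread_config_error")
  )
  array_state(mods, occ)
}
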