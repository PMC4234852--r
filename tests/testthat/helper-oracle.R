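# An independent, deliberately naive channel enumerator: every rule clause is
# tested literally, position by position, with no shared code with
# enumerate_reactions(). Used as the brute-force oracle for the rule set.
naive_channels <- function(state, model) {
  n <- model$n
  mods <- state$mod
  occ <- state$occ
  r <- model$rates
  dual <- identical(model$enzymes, "dual")
  has_recr <- model$mechanism %in% c("recruitment", "combined")
  has_diff <- model$mechanism %in% c("diffusion", "combined")
  rows <- data.frame(kind = character(), enzyme = character(),
                     pos1 = integer(), pos2 = integer(),
                     propensity = numeric())
  put <- function(kind, enzyme, p1, p2, a) {
    if (a > 0)
      rows <<- rbind(rows, data.frame(kind = kind, enzyme = enzyme,
                                      pos1 = p1, pos2 = p2, propensity = a))
  }
  # R1: initiation at an unoccupied initiation site, any modification state
  for (e in names(model$initiation_sites))
    if (occ[model$initiation_sites[[e]]] == "empty")
      put("initiate", e, model$initiation_sites[[e]], NA, r$k_on)
  for (i in 1:n) {
    # R2: unbind whatever is bound
    if (occ[i] %in% c("Mt", "At")) put("unbind", occ[i], i, NA, r$k_off)
    # R3: on-site catalysis only from U
    if (occ[i] == "Mt" && mods[i] == "U")
      put("catalyze_site", "Mt", i, NA, r$k_transferase)
    if (occ[i] == "At" && mods[i] == "U")
      put("catalyze_site", "At", i, NA, r$k_transferase)
    # R4: neighbour catalysis (recruitment mechanisms only), target occupancy
    # irrelevant
    if (has_recr && occ[i] != "empty") {
      if (i - 1 >= 1 && mods[i - 1] == "U")
        put("catalyze_neighbor", occ[i], i, i - 1L, r$k_neighbor)
      if (i + 1 <= n && mods[i + 1] == "U")
        put("catalyze_neighbor", occ[i], i, i + 1L, r$k_neighbor)
    }
    # R5: sliding into an empty neighbour (diffusion mechanisms only),
    # half the total hop rate per direction, reflective boundaries
    if (has_diff && occ[i] != "empty") {
      if (i - 1 >= 1 && occ[i - 1] == "empty")
        put("slide", occ[i], i, i - 1L, r$k_slide / 2)
      if (i + 1 <= n && occ[i + 1] == "empty")
        put("slide", occ[i], i, i + 1L, r$k_slide / 2)
    }
    # R6: recruitment to an empty nucleosome carrying the enzyme's own mark
    if (has_recr && occ[i] == "empty" && mods[i] == "M")
      put("recruit", "Mt", i, NA, r$k_recruitment)
    if (has_recr && dual && occ[i] == "empty" && mods[i] == "A")
      put("recruit", "At", i, NA, r$k_recruitment)
    # R7: ubiquitous background acetylation (single-enzyme model only)
    if (!dual && mods[i] == "U")
      put("background_acetylate", "none", i, NA, r$k_background_acetylation)
    # R8: ubiquitous demodification, occupancy irrelevant
    if (mods[i] %in% c("A", "M"))
      put("demodify", "none", i, NA, r$k_demodification)
  }
  # R9: connectivity pairs with at least one bound enzyme
  cs <- model$connectivity_sites
  if (length(cs) >= 2)
    for (a in seq_along(cs)) for (b in seq_along(cs))
      if (a < b && (occ[cs[a]] != "empty" || occ[cs[b]] != "empty"))
        put("connect", "none", cs[a], cs[b], r$k_interaction)
  rows
}

canonical_channels <- function(df) {
  df <- as.data.frame(df)
  df$pos2[is.na(df$pos2)] <- -1L
  df[order(df$kind, df$enzyme, df$pos1, df$pos2), , drop = FALSE]
}

random_state <- function(model) {
  n <- model$n
  occ_pool <- if (model$enzymes == "dual") c("empty", "Mt", "At")
              else c("empty", "Mt")
  array_state(sample(c("U", "A", "M"), n, replace = TRUE),
              sample(occ_pool, n, replace = TRUE, prob = c(0.6, rep(
                0.4 / (length(occ_pool) - 1), length(occ_pool) - 1))))
}

random_small_model <- function(n) {
  mech <- sample(c("diffusion", "recruitment", "combined"), 1)
  enz <- sample(c("single_mt", "dual"), 1)
  sites <- if (enz == "dual") {
    p <- sample(n, 2)
    c(Mt = p[1], At = p[2])
  } else c(Mt = sample(n, 1))
  conn <- if (n >= 4 && stats::runif(1) < 0.5) sort(sample(n, 3)) else integer(0)
  spread_model(n = n, mechanism = mech, enzymes = enz,
               initiation_sites = sites, connectivity_sites = conn,
               rates = spread_rates(k_on = stats::runif(1, 0.01, 3),
                                    k_interaction = stats::runif(1, 0.01, 1)))
}

# replay a trajectory's event log through apply_reaction(check = TRUE),
# verifying every recorded event was structurally enabled; returns the final
# state and the number of enzyme-order changes observed outside connect events
replay_trajectory <- function(traj) {
  st <- traj$initial
  order_breaks <- 0L
  occupied_seq <- function(s) paste(s$occ[s$occ != "empty"], collapse = "")
  prev_seq <- occupied_seq(st)
  for (r in seq_len(nrow(traj$events))) {
    ev <- traj$events[r, ]
    st <- apply_reaction(st, as.list(ev), check = TRUE)
    new_seq <- occupied_seq(st)
    if (!ev$kind %in% c("connect", "initiate", "recruit", "unbind") &&
        new_seq != prev_seq)
      order_breaks <- order_breaks + 1L
    prev_seq <- new_seq
  }
  list(final = st, order_breaks = order_breaks)
}
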