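#' Kinetic rate constants for the spreading model
#'
#' Builds the set of first-order rate constants that parameterize every
#' reaction channel of the nucleosome-array model. Defaults are the standard
#' working values derived from physical constants (see
#' [diffusion_limited_association()], [slide_rate()],
#' [off_rate_from_residence()]): enzymes bind their initiation site at the
#' diffusion-limited apparent rate, reside ~10 s on chromatin, hop between
#' neighbouring nucleosomes at the 1D-sliding rate, and marks turn over at
#' the ubiquitous background demodification rate.
#'
#' @param k_on Initiation-site binding rate (s^-1). Default 2.4 for
#'   single-enzyme models; dual-enzyme models conventionally use 0.01 (set by
#'   [spread_model()] when left `NULL`).
#' @param k_off Enzyme release rate from a nucleosome (s^-1); 0.1 = 1/(10 s
#'   residence time).
#' @param k_transferase On-site catalysis rate, U to the enzyme's own mark
#'   (s^-1). Effectively instantaneous at 1000.
#' @param k_neighbor Catalysis rate on a flanking nucleosome (s^-1).
#' @param k_slide Total 1D-diffusion hop rate (s^-1), split equally between
#'   the two directions (`k_slide / 2` per sliding channel) so that the
#'   walk's mean squared displacement matches `2 * D_1d * t` with
#'   `k_slide = 2 * D_1d / d^2`; see [slide_rate()].
#' @param k_recruitment Binding rate at a nucleosome carrying the enzyme's own
#'   mark, per eligible nucleosome (s^-1).
#' @param k_demodification Ubiquitous demodification rate, M->U and A->U
#'   (s^-1).
#' @param k_background_acetylation Ubiquitous background acetylation U->A
#'   (s^-1); active only in single-enzyme models, where the acetyltransferase
#'   is implicit.
#' @param k_interaction Chromatin-contact rate per unordered pair of
#'   connectivity sites (s^-1).
#'
#' @return A named list of class `spread_rates`.
#' @export
#' @examples
#' spread_rates(k_recruitment = 4.8)
spread_rates <- function(k_on = NULL,
                         k_off = 0.1,
                         k_transferase = 1000,
                         k_neighbor = 0.2,
                         k_slide = 0.6,
                         k_recruitment = 2.4,
                         k_demodification = 2.4,
                         k_background_acetylation = 2.4,
                         k_interaction = 0.1) {
  r <- list(k_on = k_on, k_off = k_off, k_transferase = k_transferase,
            k_neighbor = k_neighbor, k_slide = k_slide,
            k_recruitment = k_recruitment,
            k_demodification = k_demodification,
            k_background_acetylation = k_background_acetylation,
            k_interaction = k_interaction)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      abort(sprintf("rate `%s` must be a single non-negative number", nm),
            class = "nucspread_config_error")
    r[[nm]] <- as.numeric(v)
  }
  structure(r, class = "spread_rates")
}

#' Bundled chromatin-connectivity site layouts
#'
#' Equidistant interaction-site layouts on the 50-nucleosome array used by the
#' connectivity experiments. Every listed site is connected to every other
#' listed site.
#'
#' @param n_sites One of 0, 2, 3, 5 or 10.
#' @return Integer vector of 1-based array positions (empty for 0).
#' @export
#' @examples
#' connectivity_layout(5)
connectivity_layout <- function(n_sites) {
  layouts <- list(`0` = integer(0),
                  `2` = c(15L, 35L),
                  `3` = c(12L, 25L, 38L),
                  `5` = c(8L, 16L, 25L, 34L, 42L),
                  `10` = c(3L, 8L, 13L, 18L, 23L, 28L, 33L, 38L, 43L, 48L))
  key <- as.character(n_sites)
  if (!key %in% names(layouts))
    abort("connectivity layouts are defined for 0, 2, 3, 5 or 10 sites",
          class = "nucspread_config_error")
  layouts[[key]]
}

#' Configure a nucleosome-array spreading model
#'
#' A model is an array of `n` nucleosomes, each in one modification state
#' (A/U/M) and carrying at most one transferase (Mt/At). Enzymes enter at
#' designated initiation sites and move by the selected mechanism: `diffusion`
#' (nearest-neighbour sliding with reflective boundaries), `recruitment`
#' (binding at nucleosomes carrying the enzyme's own mark plus catalysis of
#' flanking nucleosomes), or `combined` (both). With `enzymes = "single_mt"`
#' only the methyltransferase is explicit and acetylation is a ubiquitous
#' background reaction; with `enzymes = "dual"` both transferases compete for
#' nucleosomes and acetylation requires a bound acetyltransferase. Optional
#' connectivity sites model long-range chromatin contacts: each pair of sites
#' can, at rate `k_interaction`, let a bound enzyme hop across or let two
#' bound enzymes exchange positions.
#'
#' @param n Number of nucleosomes (>= 2). Default 50, a ~10 kb gene.
#' @param mechanism `"diffusion"`, `"recruitment"` or `"combined"`.
#' @param enzymes `"single_mt"` or `"dual"`.
#' @param initiation_sites Named integer vector of 1-based positions, names in
#'   `c("Mt","At")`. Defaults: Mt at the array centre for single-enzyme
#'   models; Mt at 5 and At at 45 for dual models. Use an empty vector (or
#'   `k_on = 0`) to disable initiation influx.
#' @param connectivity_sites Integer vector of 1-based connectivity positions
#'   (distinct), or a single count in `c(0,2,3,5,10)` to use the bundled
#'   equidistant layouts of [connectivity_layout()].
#' @param rates A [spread_rates()] object. A `NULL` `k_on` is filled with the
#'   conventional default (2.4 single-enzyme, 0.01 dual).
#'
#' @return An object of class `spread_model`.
#' @export
#' @examples
#' m <- spread_model(mechanism = "combined")
#' m
#' spread_model(mechanism = "recruitment", enzymes = "dual",
#'              rates = spread_rates(k_recruitment = 4.8),
#'              connectivity_sites = 10)
spread_model <- function(n = 50,
                         mechanism = c("diffusion", "recruitment", "combined"),
                         enzymes = c("single_mt", "dual"),
                         initiation_sites = NULL,
                         connectivity_sites = integer(0),
                         rates = spread_rates()) {
  mechanism <- match.arg(mechanism)
  enzymes <- match.arg(enzymes)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    abort("`n` must be a single integer >= 2", class = "nucspread_config_error")
  n <- as.integer(n)
  if (!inherits(rates, "spread_rates"))
    rates <- do.call(spread_rates, as.list(rates))
  if (is.null(rates$k_on))
    rates$k_on <- if (enzymes == "dual") 0.01 else 2.4

  if (is.null(initiation_sites)) {
    initiation_sites <- if (enzymes == "dual") {
      c(Mt = 5L, At = 45L)
    } else {
      c(Mt = as.integer(floor((n + 1) / 2)))
    }
  }
  if (length(initiation_sites)) {
    if (is.null(names(initiation_sites)) ||
        !all(names(initiation_sites) %in% c("Mt", "At")) ||
        anyDuplicated(names(initiation_sites)))
      abort("`initiation_sites` must be named with distinct names in c('Mt','At')",
            class = "nucspread_config_error")
    if ("At" %in% names(initiation_sites) && enzymes != "dual")
      abort("an At initiation site requires enzymes = 'dual'",
            class = "nucspread_config_error")
    if (!all(initiation_sites >= 1 & initiation_sites <= n))
      abort("initiation sites must lie in [1, n]",
            class = "nucspread_config_error")
    if (length(initiation_sites) == 2 &&
        initiation_sites[["Mt"]] == initiation_sites[["At"]])
      abort("dual-enzyme initiation sites must be distinct",
            class = "nucspread_config_error")
    initiation_sites <- vapply(initiation_sites, as.integer, integer(1))
  } else {
    initiation_sites <- integer(0)
  }

  # a single value in {0,2,3,5,10} is read as a layout count (a lone
  # connectivity site would have no partner anyway)
  if (length(connectivity_sites) == 1L &&
      connectivity_sites %in% c(0, 2, 3, 5, 10))
    connectivity_sites <- connectivity_layout(connectivity_sites)
  connectivity_sites <- as.integer(connectivity_sites)
  if (length(connectivity_sites)) {
    if (anyDuplicated(connectivity_sites))
      abort("connectivity sites must be distinct",
            class = "nucspread_config_error")
    if (!all(connectivity_sites >= 1 & connectivity_sites <= n))
      abort("connectivity sites must lie in [1, n]",
            class = "nucspread_config_error")
    connectivity_sites <- sort(connectivity_sites)
  }

  structure(list(n = n, mechanism = mechanism, enzymes = enzymes,
                 initiation_sites = initiation_sites,
                 connectivity_sites = connectivity_sites,
                 rates = rates),
            class = "spread_model")
}

#' @export
print.spread_model <- function(x, ...) {
  cat("<spread_model> ", x$n, " nucleosomes, mechanism = ", x$mechanism,
      ", enzymes = ", x$enzymes, "\n", sep = "")
  if (length(x$initiation_sites))
    cat("  initiation:", paste(names(x$initiation_sites), "at",
                               x$initiation_sites, collapse = ", "), "\n")
  else cat("  initiation: none\n")
  if (length(x$connectivity_sites))
    cat("  connectivity sites:", paste(x$connectivity_sites, collapse = ", "),
        "\n")
  rr <- x$rates
  cat("  rates: k_on=", rr$k_on, " k_off=", rr$k_off,
      " k_transferase=", rr$k_transferase, " k_neighbor=", rr$k_neighbor,
      "\n         k_slide=", rr$k_slide, " k_recruitment=", rr$k_recruitment,
      " k_demodification=", rr$k_demodification, sep = "")
  if (x$enzymes == "single_mt")
    cat(" k_background_acetylation=", rr$k_background_acetylation, sep = "")
  if (length(x$connectivity_sites))
    cat(" k_interaction=", rr$k_interaction, sep = "")
  cat("\n")
  invisible(x)
}

#' Construct an array state
#'
#' The instantaneous state of the nucleosome array: one modification state and
#' one occupancy per position, as a tibble with columns `position`, `mod`
#' (`"U"`, `"A"`, `"M"`) and `occ` (`"empty"`, `"Mt"`, `"At"`).
#'
#' @param mods Character vector of modification states.
#' @param occ Character vector of occupancies, same length.
#' @return A tibble of class `array_state`.
#' @export
#' @examples
#' array_state(c("A", "U", "M"), c("empty", "Mt", "empty"))
array_state <- function(mods, occ) {
  if (length(mods) != length(occ) || length(mods) < 2)
    abort("`mods` and `occ` must have equal length >= 2",
          class = "nucspread_config_error")
  if (!all(mods %in% MOD_LEVELS) || !all(occ %in% OCC_LEVELS))
    abort("invalid modification or occupancy labels",
          class = "nucspread_config_error")
  st <- tibble(position = seq_along(mods), mod = as.character(mods),
               occ = as.character(occ))
  class(st) <- c("array_state", class(st))
  st
}

#' Equidistant seed positions
#'
#' Positions of `k` seeds placed symmetrically on an `n`-site array:
#' `floor(n * (2 * i - 1) / (2 * k) + 0.5)` for `i = 1..k` (half-up rounding).
#' For `n = 50` this gives 25; 13 and 38; 5, 15, 25, 35, 45 for k = 1, 2, 5.
#'
#' @param n Array length.
#' @param k Number of seeds, `1 <= k <= n`.
#' @return Integer vector of 1-based positions.
#' @export
seed_positions <- function(n, k) {
  if (k < 1 || k > n)
    abort("`k` must lie in [1, n]", class = "nucspread_config_error")
  pos <- as.integer(floor(n * (2 * seq_len(k) - 1) / (2 * k) + 0.5))
  pos <- pmin(pmax(pos, 1L), as.integer(n))
  if (anyDuplicated(pos)) pos <- unique(pos) # only possible when k ~ n
  pos
}

#' Initial-state presets
#'
#' Standard initial conditions for the simulation experiments:
#' `"all_A_empty"` (a fully acetylated, enzyme-free array — the activation
#' experiments), `"all_M_occupied"` (fully methylated, every nucleosome bound
#' by a methyltransferase — the relaxation experiments), `"all_U_empty"`, or
#' `k` methylated, methyltransferase-bound seed nucleosomes placed
#' equidistantly on an otherwise unmodified, enzyme-free array (the seeding
#' experiments; see [seed_positions()]).
#'
#' @param model A [spread_model()].
#' @param preset `"all_A_empty"`, `"all_M_occupied"`, `"all_U_empty"`, or
#'   `"k_seeds"`.
#' @param k Number of seeds when `preset = "k_seeds"`.
#' @return An [array_state()] tibble.
#' @export
#' @examples
#' m <- spread_model(mechanism = "combined")
#' initial_state(m, "k_seeds", k = 2)
initial_state <- function(model,
                          preset = c("all_A_empty", "all_M_occupied",
                                     "all_U_empty", "k_seeds"),
                          k = 1) {
  preset <- match.arg(preset)
  n <- model$n
  switch(preset,
    all_A_empty = array_state(rep("A", n), rep("empty", n)),
    all_U_empty = array_state(rep("U", n), rep("empty", n)),
    all_M_occupied = array_state(rep("M", n), rep("Mt", n)),
    k_seeds = {
      pos <- seed_positions(n, k)
      mods <- rep("U", n); occ <- rep("empty", n)
      mods[pos] <- "M"; occ[pos] <- "Mt"
      array_state(mods, occ)
    })
}

# internal: validate a state against a model
check_state <- function(state, model) {
  if (!inherits(state, "array_state"))
    state <- array_state(state$mod, state$occ)
  if (nrow(state) != model$n)
    abort("state length does not match model `n`",
          class = "nucspread_config_error")
  if (model$enzymes != "dual" && any(state$occ == "At"))
    abort("At occupancy requires a dual-enzyme model",
          class = "nucspread_config_error")
  state
}
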