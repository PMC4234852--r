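# Config files, bundled presets, TSV serialization, run manifests.

#' Read a model configuration file
#'
#' Loads a YAML model configuration and validates it into a
#' [spread_model()]. Recognized keys: `n`, `mechanism`, `enzymes`,
#' `initiation_sites` (map enzyme -> position), `connectivity_sites`
#' (list of positions or a layout count), and `rates` (any subset of the
#' [spread_rates()] names; omitted rates take their defaults). Unknown keys,
#' out-of-range positions and negative rates are rejected with descriptive
#' errors.
#'
#' @param path Path to a YAML file.
#' @return A [spread_model()].
#' @export
read_spread_config <- function(path) {
  if (!file.exists(path))
    abort(paste("config file not found:", path),
          class = "nucspread_config_error")
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
  names(cfg)[names(cfg) %in% c("FALSE", "false")] <- "n"
  known <- c("n", "mechanism", "enzymes", "initiation_sites",
             "connectivity_sites", "rates")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    abort(paste("unknown config keys:", paste(extra, collapse = ", ")),
          class = "nucspread_config_error")
  rate_names <- names(formals(spread_rates))
  if (!is.null(cfg$rates)) {
    bad <- setdiff(names(cfg$rates), rate_names)
    if (length(bad))
      abort(paste("unknown rate keys:", paste(bad, collapse = ", ")),
            class = "nucspread_config_error")
  }
  args <- list()
  if (!is.null(cfg$n)) args$n <- cfg$n
  if (!is.null(cfg$mechanism)) args$mechanism <- cfg$mechanism
  if (!is.null(cfg$enzymes)) args$enzymes <- cfg$enzymes
  if (!is.null(cfg$initiation_sites)) # an empty map means: no initiation
    args$initiation_sites <- if (length(cfg$initiation_sites))
      unlist(cfg$initiation_sites) else integer(0)
  if (!is.null(cfg$connectivity_sites))
    args$connectivity_sites <- if (length(cfg$connectivity_sites))
      unlist(cfg$connectivity_sites) else integer(0)
  args$rates <- do.call(spread_rates, as.list(cfg$rates))
  do.call(spread_model, args)
}

#' Write a model configuration file
#'
#' @param model A [spread_model()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_spread_config <- function(model, path) {
  cfg <- list(n = model$n, mechanism = model$mechanism,
              enzymes = model$enzymes,
              initiation_sites = as.list(model$initiation_sites),
              connectivity_sites = as.list(model$connectivity_sites),
              rates = unclass(model$rates))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Bundled experiment presets
#'
#' Named model configurations covering the standard experiments, shipped as
#' YAML files under `system.file("extdata/presets", package = "nucspread")`:
#'
#' * `diffusion_single` — single methyltransferase, 1D diffusion only,
#'   initiation at the array centre (the basic spreading demonstration).
#' * `recruitment_single` / `recruitment_single_strong` — recruitment only,
#'   `k_recruitment` 2.4 / 4.8 s^-1.
#' * `combined_single` / `combined_single_weak` — diffusion + recruitment,
#'   `k_recruitment` 2.4 / 0.24 s^-1 (the bistable seeding regime uses
#'   `combined_single`).
#' * `dual_diffusion`, `dual_recruitment_weak` (`k_recruitment` 1.2),
#'   `dual_recruitment_strong` (4.8), `dual_combined_weak` (0.48) — two
#'   competing transferases with initiation sites at positions 5 and 45 and
#'   `k_on` 0.01 s^-1 (the boundary and connectivity experiments).
#'
#' @param name Preset name.
#' @param connectivity_sites Optional override: positions, or a layout count
#'   in `c(0,2,3,5,10)` (see [connectivity_layout()]).
#' @param k_interaction Optional chromatin-contact rate override.
#' @param ... Rate overrides passed to [spread_rates()] on top of the
#'   preset's values.
#' @return A [spread_model()].
#' @export
#' @examples
#' spread_preset("combined_single")
#' spread_preset("dual_recruitment_weak", connectivity_sites = 10,
#'               k_interaction = 0.1)
spread_preset <- function(name, connectivity_sites = NULL,
                          k_interaction = NULL, ...) {
  dir <- system.file("extdata", "presets", package = "nucspread")
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path)) {
    avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(avail, collapse = ", ")),
          class = "nucspread_config_error")
  }
  model <- read_spread_config(path)
  over <- list(...)
  if (!is.null(k_interaction)) over$k_interaction <- k_interaction
  if (length(over)) {
    rates <- utils::modifyList(unclass(model$rates), over)
    model$rates <- do.call(spread_rates, rates)
  }
  if (!is.null(connectivity_sites))
    model <- spread_model(n = model$n, mechanism = model$mechanism,
                          enzymes = model$enzymes,
                          initiation_sites = model$initiation_sites,
                          connectivity_sites = connectivity_sites,
                          rates = model$rates)
  model
}

#' Write an event log as TSV
#'
#' Serializes a trajectory's event log (columns `time`, `kind`, `enzyme`,
#' `pos1`, `pos2`) with a commented header carrying the horizon and the
#' initial state, sufficient to reconstruct the trajectory next to its model
#' configuration.
#'
#' @param traj A [simulate_spread()] trajectory.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nucspread event log",
               paste0("# t_end: ", format(traj$t_end, digits = 17)),
               paste0("# seed: ", if (is.null(traj$seed)) "NA" else traj$seed),
               paste0("# method: ", traj$method),
               paste0("# initial_mods: ", paste(traj$initial$mod,
                                                collapse = "")),
               paste0("# initial_occ: ",
                      paste(occ_code(traj$initial$occ), collapse = ""))),
             con)
  ev <- traj$events
  writeLines("time\tkind\tenzyme\tpos1\tpos2", con)
  if (nrow(ev))
    writeLines(paste(format(ev$time, digits = 17), ev$kind, ev$enzyme,
                     ev$pos1, ifelse(is.na(ev$pos2), "NA", ev$pos2),
                     sep = "\t"), con)
  invisible(path)
}

#' Read an event log TSV
#'
#' @param path Path written by [write_event_log()].
#' @param model Optional [spread_model()]; if supplied, a full
#'   `spread_trajectory` is reconstructed (replayable with [state_at()]),
#'   otherwise the events tibble is returned with the header metadata as
#'   attributes.
#' @return A tibble or a `spread_trajectory`.
#' @export
read_event_log <- function(path, model = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    x <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(x)) sub(paste0("^# ", key, ": "), "", x[1]) else NA_character_
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                           stringsAsFactors = FALSE)
  ev <- tibble(time = as.numeric(tab$time), kind = as.character(tab$kind),
               enzyme = as.character(tab$enzyme),
               pos1 = as.integer(tab$pos1),
               pos2 = suppressWarnings(as.integer(tab$pos2)))
  t_end <- as.numeric(meta("t_end"))
  mods <- strsplit(meta("initial_mods"), "")[[1]]
  occ <- OCC_LEVELS[as.integer(strsplit(meta("initial_occ"), "")[[1]]) + 1L]
  init <- array_state(mods, occ)
  if (is.null(model)) {
    attr(ev, "t_end") <- t_end
    attr(ev, "initial") <- init
    return(ev)
  }
  traj <- structure(list(model = model,
                         seed = suppressWarnings(as.integer(meta("seed"))),
                         method = meta("method"), t_end = t_end,
                         initial = check_state(init, model), events = ev,
                         final = NULL),
                    class = "spread_trajectory")
  traj$final <- state_at(traj, t_end)
  traj
}

#' Write a kymograph as integer-coded TSV
#'
#' One row per sampling time; columns `time`, `m<pos>` (modification state,
#' coded U/A/M -> 0/1/2) and `o<pos>` (occupancy, coded empty/Mt/At ->
#' 0/1/2). The coding is repeated in a header comment so the file is
#' self-describing for heat-map rendering.
#'
#' @param ky A [kymograph()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(ky, path) {
  wide_m <- tidyr::pivot_wider(ky, id_cols = "time", names_from = "position",
                               values_from = "mod", names_prefix = "m")
  wide_o <- tidyr::pivot_wider(ky, id_cols = "time", names_from = "position",
                               values_from = "occ", names_prefix = "o")
  m_codes <- as.data.frame(lapply(wide_m[-1], mod_code))
  o_codes <- as.data.frame(lapply(wide_o[-1], occ_code))
  out <- cbind(time = wide_m$time, m_codes, o_codes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nucspread kymograph",
               "# modification coding: U=0 A=1 M=2; occupancy coding: empty=0 Mt=1 At=2"),
             con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for an ensemble run
#'
#' Records everything needed to re-run an ensemble bit-identically: the full
#' model configuration and its hash, the master and per-replicate seeds, the
#' horizon, method, package version and output files.
#'
#' @param ens A [simulate_ensemble()] result.
#' @param path Output YAML path.
#' @param outputs Character vector of files produced by the run.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(ens, path, outputs = character()) {
  cfg <- list(n = ens$model$n, mechanism = ens$model$mechanism,
              enzymes = ens$model$enzymes,
              initiation_sites = as.list(ens$model$initiation_sites),
              connectivity_sites = as.list(ens$model$connectivity_sites),
              rates = unclass(ens$model$rates))
  manifest <- list(
    package = "nucspread",
    version = as.character(utils::packageVersion("nucspread")),
    config = cfg,
    config_hash = rlang::hash(ens$model),
    master_seed = ens$seed,
    replicate_seeds = ens$rep_seeds,
    reps = ens$reps, t_end = ens$t_end, bin = ens$bin,
    steady_fraction = ens$steady_fraction, method = ens$method,
    outputs = as.list(outputs))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Re-run an ensemble from its manifest
#'
#' Rebuilds the model from the manifest's embedded configuration (verifying
#' the hash) and repeats the simulation with the recorded seeds, horizon and
#' method; the result is bit-identical to the original run.
#'
#' @param path Manifest YAML path.
#' @return A `spread_ensemble`.
#' @export
replay_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  cfg <- man$config
  model <- spread_model(
    n = cfg$n, mechanism = cfg$mechanism, enzymes = cfg$enzymes,
    initiation_sites = if (length(cfg$initiation_sites))
      unlist(cfg$initiation_sites) else integer(0),
    connectivity_sites = if (length(cfg$connectivity_sites))
      unlist(cfg$connectivity_sites) else integer(0),
    rates = do.call(spread_rates, cfg$rates))
  if (!identical(rlang::hash(model), man$config_hash))
    abort("manifest config hash mismatch", class = "nucspread_config_error")
  simulate_ensemble(model, reps = man$reps, t_end = man$t_end,
                    seed = man$master_seed, bin = man$bin,
                    steady_fraction = man$steady_fraction,
                    method = man$method)
}
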