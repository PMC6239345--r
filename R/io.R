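# Config and table I/O: YAML channel configs (lossless round trip of the
# maximal conductances and modulation flags), CSV sweep/spectrum tables and
# JSON summaries.

#' Write / read a channel configuration
#'
#' Serialises the maximal conductances, the structural constants of each
#' channel (activation exponent, component fractions) and the modulation
#' flags to YAML. Reading returns the pieces needed to rebuild the identical
#' channel set with [build_channel_set()].
#'
#' @param path file path.
#' @param g_max named numeric vector `c(shaker, shab, novel)`, nS.
#' @param modulation a [modulation_state()].
#' @return `write_channel_config()` the path, invisibly;
#'   `read_channel_config()` a list with `g_max`, `modulation` and
#'   `channels` (the rebuilt set).
#' @export
write_channel_config <- function(path, g_max = gbar_default(),
                                 modulation = modulation_state()) {
  channels <- build_channel_set(modulation, g_max = g_max)
  cfg <- list(
    channels = lapply(names(channels), function(nm) {
      ch <- channels[[nm]]
      list(name = nm, g_max_nS = unname(g_max[nm]), gamma = ch$gamma,
           components = lapply(ch$components, function(cc) {
             list(fraction = cc$fraction, inactivating = !is.null(cc$h))
           }))
    }),
    modulation = list(serotonin = modulation$serotonin,
                      pip2_depleted = modulation$pip2_depleted,
                      shab_scale = modulation$shab_scale)
  )
  names(cfg$channels) <- names(channels)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_channel_config
#' @export
read_channel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g_max <- vapply(cfg$channels, function(ch) as.numeric(ch$g_max_nS), numeric(1))
  names(g_max) <- names(cfg$channels)
  m <- cfg$modulation
  modulation <- modulation_state(isTRUE(m$serotonin), isTRUE(m$pip2_depleted),
                                 as.numeric(m$shab_scale))
  list(g_max = g_max, modulation = modulation,
       channels = build_channel_set(modulation, g_max = g_max))
}

#' Write a sweep of operating points as CSV
#'
#' Columns: voltage, light conductance, pump and exchanger currents and the
#' per-channel conductances.
#'
#' @param sweep an `operating_sweep` from [sweep_light_levels()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Write an impedance spectrum as CSV with a JSON provenance sidecar
#'
#' @param spectrum an `impedance_spectrum`.
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  prov <- list(V_mV = spectrum$V,
               freeze = lapply(unclass(spectrum$freeze), as.character))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
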