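## Run configuration: every numeric constant of the method in one flat list,
## serializable to/from YAML.

#' Default run configuration
#'
#' Flat list of all tunable constants: contact criteria (9 Angstrom
#' C-beta-C-beta cutoff, at least 5 close residue pairs, 20% per-SSE residue
#' fraction), the 19 Angstrom cross-linkable window and 9 Angstrom simulated
#' disulfide criterion, the agreement weight q, the mRMR stop threshold in
#' bits, plan size and sigmoid midpoint k0, the misalignment/flexibility noise
#' settings, link probability tiers, SSE commonality fractions, the r sweep
#' for fold labelling, and the RNG seed.
#'
#' @return named list.
#' @export
defaultConfig <- function() {
  list(contactDistance = 9.0, minContacts = 5L, minResidueFraction = 0.20,
       xlinkMaxDistance = 19.0, simDistance = 9.0,
       q = 0.8, stopThreshold = 0.01, maxPairs = NULL,
       planSize = 10L, k0 = 3L,
       pNear = 0.95, pMid = 0.5, pFar = 0.05,
       deltaMax = 2L, decay = 1.0,
       nBackbones = 5L, amplitudeMax = 3.0, enmCutoff = 10.0,
       presenceFraction = 0.5, overlapFraction = 0.5,
       rValues = c(0.05, 0.1, 0.15, 0.2),
       seed = 1L)
}

#' Read / write a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults, so a config
#' file round-trips losslessly through [writeConfig()] and [readConfig()].
#'
#' @param path YAML file path.
#' @return named list as in [defaultConfig()].
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  ints <- c("minContacts", "planSize", "k0", "deltaMax", "nBackbones", "seed")
  for (nm in ints) cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg
}

#' @rdname readConfig
#' @param config configuration list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

## Short stable hash of a config for run logs.
configHash <- function(config) {
  s <- yaml::as.yaml(config[order(names(config))])
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}
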