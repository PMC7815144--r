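#' Default run configuration
#'
#' The full configuration bundle: kinetic constants, cost model, physiology,
#' environment, simulation protocol and the reference genotype, all at
#' their standard values (no-competition scenario with a constant 2 mM
#' glucose supply).
#'
#' @return Nested list of class `glycoConfig`.
#' @export
defaultConfig <- function() {
  structure(list(kinetics = kineticParameters(),
                 cost = costModel(),
                 physiology = physiologyParameters(),
                 environment = environmentConfig("ncg",
                   schedule = glucoseSchedule("constant", Glc0_on = 2),
                   D = 5, d = 1e-6),
                 simulation = simulationConfig(),
                 reference = referenceGenotype()),
            class = "glycoConfig")
}

#' Named configuration presets
#'
#' * `"table1"` / `"ncg_constant"`: constant 2 mM supply, no competition.
#' * `"ncg_square_T40"`, `"ncg_square_T120"`, `"ncg_square_T200"`:
#'   no-competition square-wave supply alternating 2 mM ON and 0.01 mM OFF
#'   phases of equal duration, total period 40/120/200 min.
#' * `"chemostat_pulse_T100_cv5"`: chemostat fed by a pulse train of 1 min
#'   pulses of 300 mM glucose separated by OFF phases of mean 99 min
#'   (CV 5 %) at 0.01 mM supply, dilution rate 4e-3 /min.
#' * `"cost_power_sum"`, `"cost_power_of_sum"`: the two expression-cost
#'   variants (weights 1, exponent 4).
#'
#' @param name Preset name.
#' @return A `glycoConfig`.
#' @export
presetConfig <- function(name = c("table1", "ncg_constant",
                                  "ncg_square_T40", "ncg_square_T120",
                                  "ncg_square_T200",
                                  "chemostat_pulse_T100_cv5",
                                  "cost_power_sum", "cost_power_of_sum")) {
  name <- match.arg(name)
  cfg <- defaultConfig()
  sq <- function(T) glucoseSchedule("square_wave", Glc0_on = 2,
                                    Glc0_off = 0.01, T_on = T / 2,
                                    T_off_mean = T / 2)
  if (name %in% c("ncg_square_T40", "ncg_square_T120", "ncg_square_T200")) {
    T <- as.numeric(sub("ncg_square_T", "", name))
    cfg$environment <- environmentConfig("ncg", schedule = sq(T), D = 5,
                                         d = 1e-6)
  } else if (name == "chemostat_pulse_T100_cv5") {
    cfg$environment <- environmentConfig("chemostat",
      schedule = glucoseSchedule("pulse_train", Glc0_on = 300,
                                 Glc0_off = 0.01, T_on = 1,
                                 T_off_mean = 99, T_off_cv = 0.05),
      D = 4e-3, V_ch = 1e-8)
    cfg$simulation$N0 <- 50000
  } else if (name == "cost_power_of_sum") {
    cfg$cost <- costModel("power_of_sum")
  }
  cfg
}

#' Built-in genotypes
#'
#' The reference genotype and the balanced-competitor (BC) /
#' imbalanced-competitor (IC) genotype pair used in the no-mutation
#' coexistence experiments.
#'
#' @return Named list of genotype vectors.
#' @export
builtinGenotypes <- function() {
  list(reference = referenceGenotype(),
       BC = genotype(9.90956, 6.97388, 6.14105, 1.27357),
       IC = genotype(10.92211, 5.65143, 4.82003, 2.07099))
}

# Recursively overlay user values onto defaults, rejecting unknown keys.
.mergeConfig <- function(base, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]))
      .mergeConfig(base[[nm]], user[[nm]], paste0(path, nm, "."))
    else user[[nm]]
  }
  base
}

#' Load a run configuration from YAML or JSON
#'
#' Any subset of the configuration tree may be given; missing values take
#' their defaults (optionally from a named preset via a top-level `preset`
#' key). Unknown keys are rejected with an error naming them. Units are
#' fixed package-wide: minutes, mM, litres.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `glycoConfig`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- if (!is.null(user$preset)) presetConfig(user$preset)
          else defaultConfig()
  user$preset <- NULL
  if (!is.null(user$reference))
    user$reference <- genotype(unlist(user$reference))
  merged <- .mergeConfig(lapply(base, function(x)
    if (is.list(x)) unclassKeep(x) else x), user)
  # revalidate through the constructors
  out <- defaultConfig()
  out$kinetics <- do.call(kineticParameters, merged$kinetics)
  cm <- merged$cost
  cm$k_e <- NULL
  out$cost <- do.call(costModel, cm)
  ph <- merged$physiology
  ph <- ph[!names(ph) %in% c("u_g", "u_d", "H_min")]
  out$physiology <- do.call(physiologyParameters, ph)
  sch <- merged$environment$schedule
  env <- merged$environment
  env$schedule <- do.call(glucoseSchedule, sch)
  out$environment <- do.call(environmentConfig, env)
  sim <- merged$simulation
  out$simulation <- do.call(simulationConfig, sim)
  out$reference <- genotype(unlist(merged$reference))
  out
}

unclassKeep <- function(x) {
  x <- unclass(x)
  lapply(x, function(el) if (is.list(el)) unclassKeep(el) else el)
}

#' Serialize a configuration
#'
#' @param config A `glycoConfig`.
#' @param path Output path; `.yaml` or `.json` by extension.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  plain <- unclassKeep(config)
  plain$reference <- as.list(config$reference)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

# Doubles formatted to survive a write/read round trip exactly.
.fmtNum <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 17, format = "g")
  df
}

.writeCsv <- function(df, path, unitComment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", unitComment), con)
  utils::write.csv(.fmtNum(df), con, row.names = FALSE, quote = FALSE)
}

#' Write run outputs to a directory
#'
#' Writes `tracks.csv` (long-format tracked-cell dynamics),
#' `tracked_cells.csv` (per-cell constants), `population.csv` (per-interval
#' summary), `events.csv` (per-interval birth/death/washout increments) and
#' `run_meta.json` (resolved configuration, seed, final counters, package
#' version). All concentrations are mM, volumes L, times min.
#'
#' @param run A `glycoRun`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeOutputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- run$tracks
  if (is.null(tracks))
    tracks <- data.frame(time = numeric(0), cell = integer(0),
                         FBP = numeric(0), ATP = numeric(0),
                         Pi = numeric(0), V = numeric(0), H = numeric(0),
                         Glc = numeric(0))
  .writeCsv(tracks, file.path(dir, "tracks.csv"),
            "time min; FBP/ATP/Pi/Glc mM; V L; H dimensionless")
  if (!is.null(run$trackedCells))
    .writeCsv(run$trackedCells, file.path(dir, "tracked_cells.csv"),
              "vmax mM/min; k 1/min; vatp_e mM/min")
  .writeCsv(run$summary, file.path(dir, "population.csv"),
            "time min; glc mM; counters cumulative")
  if (!is.null(run$resolved$cycles))
    .writeCsv(run$resolved$cycles, file.path(dir, "cycles.csv"),
              "supply cycle boundaries, min")
  ev <- run$summary[, c("time", "births", "deaths", "washouts")]
  ev[-1] <- lapply(ev[-1], function(x) c(x[1], diff(x)))
  .writeCsv(ev, file.path(dir, "events.csv"),
            "per-interval event counts")
  meta <- list(config = unclassKeep(run$config), seed = run$seed,
               status = run$status,
               counters = as.list(run$population$counters),
               finalN = nrow(run$population$state),
               package = as.character(utils::packageVersion("glycosim")))
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a tracks table written by [writeOutputs()]
#'
#' @param path Path to `tracks.csv`.
#' @return Data frame with the original column types.
#' @export
readTracks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  for (nm in intersect(names(df), c("time", "FBP", "ATP", "Pi", "V", "H",
                                    "Glc", "vatp_e", "H_max")))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}
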