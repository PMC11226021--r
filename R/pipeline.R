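# One entry point chaining the stages, with a run manifest for
# reproducibility. The Rscript wrapper in inst/scripts/mzexacto-cli.R is a
# thin shell over this function.

#' Run one pipeline stage
#'
#' Executes a stage of the consolidation workflow and writes its outputs
#' plus a `manifest.json` (inputs, parameter values, package version, seed)
#' into `out_dir`. Offline by default: no stage touches the network.
#'
#' Subcommands and their required `config` keys:
#' \describe{
#'   \item{simulate}{`seed`; optional `n_compounds`, `n_samples`,
#'     `rt_jitter_sd`, `name_corruption_rate`, `n_decoys`, `noise_scale`.
#'     Writes `features.csv`, `refdb.json`, `ground_truth.csv`.}
#'   \item{spread}{`input` (feature CSV), `refdb` (store JSON). Writes
#'     `spread_set.json`.}
#'   \item{exacto}{`input`, `refdb`, `chemicals` (text file, one name per
#'     line); optional `mf_min`, `rt_halfwidth`, `decontaminate`,
#'     `strong_mf`, `min_samples`. Writes `exacto.csv`, `decisions.csv`.}
#'   \item{standardify}{`input` (exacto CSV) and either `standard`
#'     (+ optional `known_amount`) or `calibration` (calibration CSV).
#'     Writes `standardized.csv`.}
#'   \item{categorate}{`input`, `refdb`, `library` (category CSV),
#'     `orientation`. Writes `similarity.csv`, `flags.csv`.}
#' }
#'
#' @param subcommand one of `"simulate"`, `"spread"`, `"exacto"`,
#'   `"standardify"`, `"categorate"`.
#' @param config named list of stage parameters (see above).
#' @param out_dir run directory (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(subcommand = c("simulate", "spread", "exacto",
                                        "standardify", "categorate"),
                         config = list(), out_dir = ".") {
  subcommand <- match.arg(subcommand)
  known_keys <- list(
    simulate = c("seed", "n_compounds", "n_samples", "rt_jitter_sd",
                 "name_corruption_rate", "n_decoys", "noise_scale"),
    spread = c("input", "refdb"),
    exacto = c("input", "refdb", "chemicals", "mf_min", "rt_halfwidth",
               "decontaminate", "strong_mf", "min_samples", "aggregation"),
    standardify = c("input", "standard", "known_amount", "calibration"),
    categorate = c("input", "refdb", "library", "orientation")
  )
  bad <- setdiff(names(config), known_keys[[subcommand]])
  if (length(bad))
    mz_stop("mz_usage_error", "unknown config key(s) for '%s': %s (valid: %s)",
            subcommand, paste(bad, collapse = ", "),
            paste(known_keys[[subcommand]], collapse = ", "))
  for (f in intersect(c("input", "refdb", "chemicals", "library", "calibration"),
                      names(config)))
    if (!file.exists(config[[f]]))
      mz_stop("mz_io_error", "input file does not exist: %s", config[[f]])

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- function(f) { written <<- c(written, file.path(out_dir, f));
    file.path(out_dir, f) }

  if (subcommand == "simulate") {
    seed <- as.integer(config$seed %||% 1L)
    cfg <- experiment_config(
      n_compounds = as.integer(config$n_compounds %||% 25L),
      n_samples = as.integer(config$n_samples %||% 12L),
      rt_jitter_sd = as.numeric(config$rt_jitter_sd %||% 0),
      name_corruption_rate = as.numeric(config$name_corruption_rate %||% 0),
      n_decoys = as.integer(config$n_decoys %||% 0L),
      noise_scale = as.numeric(config$noise_scale %||% 0),
      seed = seed)
    sim <- generate_feature_table(cfg)
    df <- sim$table$records
    csv <- data.frame(Compound.Name = df$compound_name, File.Name = df$sample_id,
                      Base.Peak.MZ = format_num(df$base_peak_mz),
                      Match.Factor = format_num(df$match_factor),
                      Component.RT = format_num(df$rt),
                      Component.Area = format_num(df$area),
                      check.names = FALSE)
    utils::write.csv(csv, out("features.csv"), row.names = FALSE)
    write_compound_store(generate_reference_db(cfg), out("refdb.json"))
    gt <- as.data.frame(as.table(sim$truth$planted), stringsAsFactors = FALSE)
    names(gt) <- c("chemical", "sample", "true_area")
    gt$true_area <- format_num(gt$true_area)
    utils::write.csv(gt, out("ground_truth.csv"), row.names = FALSE)
  } else if (subcommand == "spread") {
    tab <- read_feature_csv(config$input)
    store <- read_compound_store(config$refdb)
    ss <- spread_out(tab, list(local_backend(store)))
    write_spread_set(ss, out("spread_set.json"))
  } else if (subcommand == "exacto") {
    tab <- read_feature_csv(config$input)
    store <- read_compound_store(config$refdb)
    chems <- readLines(config$chemicals, warn = FALSE)
    chems <- trimws(chems[nzchar(trimws(chems))])
    ss <- spread_out(tab, list(local_backend(store)))
    et <- mz_exacto(ss, chems,
                    decontaminate = !identical(tolower(as.character(
                      config$decontaminate %||% "on")), "off"),
                    mf_min = as.numeric(config$mf_min %||% 75),
                    rt_halfwidth = as.numeric(config$rt_halfwidth %||% 0.35),
                    aggregation = config$aggregation %||% "sum",
                    strong_mf = as.numeric(config$strong_mf %||% 75),
                    min_samples = as.integer(config$min_samples %||% 1L),
                    backends = list(local_backend(store)))
    write_exacto_csv(et, out("exacto.csv"))
    dec <- et$decisions
    for (nm in names(dec)) if (is.numeric(dec[[nm]])) dec[[nm]] <- format_num(dec[[nm]])
    utils::write.csv(dec, out("decisions.csv"), row.names = FALSE)
  } else if (subcommand == "standardify") {
    et <- read_exacto_csv(config$input)
    st <- if (!is.null(config$standard)) {
      standardify_internal(et, config$standard,
                           known_amount = if (!is.null(config$known_amount))
                             as.numeric(config$known_amount))
    } else if (!is.null(config$calibration)) {
      standardify_external(et, read_calibration_csv(config$calibration))
    } else mz_stop("mz_usage_error",
                   "standardify needs either 'standard' or 'calibration'")
    write_standardized_csv(st, out("standardized.csv"))
  } else if (subcommand == "categorate") {
    store <- read_compound_store(config$refdb)
    lib <- read_chem_library(config$library,
                             orientation = config$orientation %||% "wide")
    chems <- readLines(config$input, warn = FALSE)
    chems <- trimws(chems[nzchar(trimws(chems))])
    backends <- list(local_backend(store))
    queries <- resolve_batch(chems, backends)
    res <- categorate(queries, lib, backends)
    utils::write.csv(res$similarity, out("similarity.csv"), row.names = FALSE)
    utils::write.csv(res$flags, out("flags.csv"), row.names = FALSE)
  }

  manifest <- list(
    subcommand = subcommand,
    parameters = config,
    outputs = basename(written),
    package = "mzexacto",
    version = as.character(utils::packageVersion("mzexacto"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, file.path(out_dir, "manifest.json")))
}
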