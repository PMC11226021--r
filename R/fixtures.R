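# Deterministic synthetic-experiment generator.
#
# Emulates the post-deconvolution, post-library-search stage of a GC-MS
# study: a table of tentative identifications across samples with planted
# ground truth (true per-sample areas, retention-time jitter, corrupted
# names that are recoverable through the m/z rescue, decoys with disjoint
# top-2 m/z, and ubiquitous contaminants such as column-bleed siloxanes).
# Everything downstream of a seed is deterministic.
#
# The bundled compound panel (inst/extdata/volatile_panel.csv) carries real
# volatile names and structures; the fragment spectra attached to them are
# SYNTHETIC (plausible fragment ladders with a unique top-2 pair per
# compound), sufficient for exercising the matching logic, not library
# reference spectra.

#' The bundled volatile compound panel
#'
#' @return data.frame with columns `name`, `smiles`, `synonyms`
#'   (semicolon-separated).
#' @export
volatile_panel <- function() {
  path <- system.file("extdata", "volatile_panel.csv", package = "mzexacto")
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

# synthetic fragment ladder for panel compound i: unique top-2 set per
# compound (pairs (40+3i, 54+3i) never collide as sets), plus minor peaks
synthetic_spectrum <- function(i, decoy = FALSE) {
  base <- if (decoy) 200 + 3 * i else 40 + 3 * i
  data.frame(
    mz = c(base, base + 14, base + 27, base + 41),
    intensity = c(100, 78, 34, 12)
  )
}

#' Configure a synthetic GC-MS experiment
#'
#' The defaults describe the clean baseline condition: every planted
#' compound present in every sample under its correct name, no retention
#' jitter, no area noise, no decoys. Stress conditions (jitter, corrupted
#' names, decoys, contaminants) are opted into per argument.
#'
#' @param n_compounds planted compounds, drawn from [volatile_panel()]
#'   (max 30).
#' @param n_samples number of samples.
#' @param rt_jitter_sd Gaussian retention-time jitter, minutes.
#' @param name_corruption_rate probability that a planted record's name is
#'   replaced by a wrong (but rescuable: same synthetic top-2 m/z) name.
#' @param n_decoys decoy compounds with top-2 m/z disjoint from every
#'   planted compound, one record per sample.
#' @param contaminants character vector of contaminant names injected into
#'   every sample and left unresolvable by the reference store (default the
#'   classic column-bleed siloxane).
#' @param mf_range match-factor range (percent) for planted records.
#' @param decoy_mf_range match-factor range for decoys/contaminants.
#' @param noise_scale relative s.d. of multiplicative Gaussian area noise.
#' @param area_range log10 range the true areas are drawn from.
#' @param rt_start,rt_spacing chromatographic layout: compound `i` elutes at
#'   `rt_start + i * rt_spacing` minutes.
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration (which includes this seed).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(n_compounds = 25L, n_samples = 12L,
                              rt_jitter_sd = 0, name_corruption_rate = 0,
                              n_decoys = 0L,
                              contaminants = "Cyclotetrasiloxane, octamethyl-",
                              mf_range = c(80, 99),
                              decoy_mf_range = c(60, 90),
                              noise_scale = 0,
                              area_range = c(4, 6),
                              rt_start = 4, rt_spacing = 0.75,
                              seed = 1L) {
  panel <- volatile_panel()
  if (n_compounds < 1L || n_compounds > nrow(panel))
    mz_stop("mz_fixture_error", "n_compounds must be in [1, %d]", nrow(panel))
  if (n_samples < 1L) mz_stop("mz_fixture_error", "n_samples must be >= 1")
  if (rt_jitter_sd < 0 || name_corruption_rate < 0 || name_corruption_rate > 1 ||
      noise_scale < 0)
    mz_stop("mz_fixture_error", "invalid noise/corruption parameters")

  compounds <- panel[seq_len(n_compounds), , drop = FALSE]
  compounds$rt_center <- rt_start + seq_len(n_compounds) * rt_spacing
  compounds$partner <- paste0(compounds$name, ", branched isomer")

  decoy_pool <- c("Cyclopentasiloxane, decamethyl-", "Diethyl phthalate",
                  "Dibutyl phthalate", "Benzophenone",
                  "2,6-di-tert-butylphenol", "Butylated hydroxytoluene",
                  "Hexamethylcyclotrisiloxane", "Diisooctyl adipate")
  if (n_decoys > length(decoy_pool))
    mz_stop("mz_fixture_error", "at most %d decoys available", length(decoy_pool))
  decoys <- utils::head(decoy_pool, n_decoys)

  # true areas are part of the experimental condition: drawn once here,
  # reproducibly from the seed
  set.seed(seed)
  true_areas <- matrix(
    round(10 ^ stats::runif(n_compounds * n_samples, area_range[1], area_range[2])),
    nrow = n_compounds,
    dimnames = list(compounds$name, sprintf("sample_%02d", seq_len(n_samples))))

  structure(list(
    compounds = compounds, true_areas = true_areas,
    n_samples = n_samples, samples = colnames(true_areas),
    rt_jitter_sd = rt_jitter_sd, name_corruption_rate = name_corruption_rate,
    decoys = decoys, contaminants = contaminants,
    mf_range = mf_range, decoy_mf_range = decoy_mf_range,
    noise_scale = noise_scale, rt_range = c(rt_start, rt_start +
                                              (n_compounds + 1) * rt_spacing),
    seed = as.integer(seed)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "experiment_config: %d compounds x %d samples (seed %d)\n",
    nrow(x$compounds), x$n_samples, x$seed))
  cat(sprintf("  rt jitter %.3g min, corruption %.0f%%, noise %.0f%%, %d decoy(s), %d contaminant(s)\n",
              x$rt_jitter_sd, 100 * x$name_corruption_rate,
              100 * x$noise_scale, length(x$decoys), length(x$contaminants)))
  invisible(x)
}

#' Build the reference store matching an experiment configuration
#'
#' One resolvable record per planted compound (CID, SMILES, synthetic
#' spectrum, synonyms), per rescue-partner name (same synthetic top-2 m/z
#' as its planted compound, so corrupted records are rescuable), and per
#' decoy (disjoint top-2 m/z). Contaminants get no record, so they resolve
#' `unresolved` and exercise decontamination.
#'
#' @param config an `experiment_config`.
#' @return a `compound_store`.
#' @export
generate_reference_db <- function(config) {
  cmp <- config$compounds
  recs <- list()
  for (i in seq_len(nrow(cmp))) {
    syn <- if (nzchar(cmp$synonyms[i])) trimws(strsplit(cmp$synonyms[i], ";")[[1]])
      else character()
    recs[[length(recs) + 1L]] <- compound_record(
      cmp$name[i], status = "resolved_by_name", cid = 100000L + i,
      smiles = cmp$smiles[i], spectrum = synthetic_spectrum(i),
      synonyms = syn)
    # rescue partner: wrong name, same top-2 m/z, structure-only record
    recs[[length(recs) + 1L]] <- compound_record(
      cmp$partner[i], status = "resolved_by_structure",
      smiles = cmp$smiles[i], spectrum = synthetic_spectrum(i))
  }
  for (j in seq_along(config$decoys)) {
    recs[[length(recs) + 1L]] <- compound_record(
      config$decoys[j], status = "resolved_by_name", cid = 900000L + j,
      smiles = "CCCCCCCC", spectrum = synthetic_spectrum(j, decoy = TRUE))
  }
  compound_store(recs)
}

#' Generate a synthetic feature table with ground truth
#'
#' One record per (planted compound, sample) with positive true area:
#' retention time = compound center + Gaussian jitter, area = true area
#' times multiplicative Gaussian noise (truncated at 0), match factor
#' uniform in `mf_range`; with probability `name_corruption_rate` the name
#' is replaced by the compound's rescue-partner name. Decoys contribute one
#' record per sample at a random retention time; contaminants one record
#' per sample at a fixed late retention time. Fully reproducible from
#' `seed`.
#'
#' @param config an `experiment_config`.
#' @param seed overrides `config$seed` for the stochastic draws (the
#'   planted areas stay those of the config).
#' @return list with `table` (a `feature_table`) and `truth` (list:
#'   `planted` matrix of true areas, `provenance` data.frame uid ->
#'   {planted, corrupted, decoy, contaminant} with the source compound).
#' @export
generate_feature_table <- function(config, seed = config$seed) {
  set.seed(seed)
  cmp <- config$compounds
  samples <- config$samples
  rows <- list()
  prov <- list()
  for (s in seq_along(samples)) {
    for (i in seq_len(nrow(cmp))) {
      true_area <- config$true_areas[i, s]
      if (true_area <= 0) next
      rt <- cmp$rt_center[i] + stats::rnorm(1, 0, max(config$rt_jitter_sd, 1e-12))
      area <- true_area * (1 + stats::rnorm(1, 0, max(config$noise_scale, 1e-12)))
      area <- max(area, 0)
      if (config$noise_scale == 0) area <- true_area
      if (config$rt_jitter_sd == 0) rt <- cmp$rt_center[i]
      mf <- stats::runif(1, config$mf_range[1], config$mf_range[2])
      corrupted <- stats::runif(1) < config$name_corruption_rate
      nm <- if (corrupted) cmp$partner[i] else cmp$name[i]
      spec <- synthetic_spectrum(i)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[s], compound_name = nm, rt = rt,
        base_peak_mz = spec$mz[1], match_factor = mf, area = area,
        stringsAsFactors = FALSE)
      prov[[length(prov) + 1L]] <- data.frame(
        kind = if (corrupted) "corrupted" else "planted",
        source = cmp$name[i], stringsAsFactors = FALSE)
    }
    for (j in seq_along(config$decoys)) {
      spec <- synthetic_spectrum(j, decoy = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[s], compound_name = config$decoys[j],
        rt = stats::runif(1, config$rt_range[1], config$rt_range[2]),
        base_peak_mz = spec$mz[1],
        match_factor = stats::runif(1, config$decoy_mf_range[1],
                                    config$decoy_mf_range[2]),
        area = round(10 ^ stats::runif(1, 3, 5)), stringsAsFactors = FALSE)
      prov[[length(prov) + 1L]] <- data.frame(
        kind = "decoy", source = config$decoys[j], stringsAsFactors = FALSE)
    }
    for (k in seq_along(config$contaminants)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[s], compound_name = config$contaminants[k],
        rt = config$rt_range[2] + 1 + k,
        base_peak_mz = 281, match_factor = stats::runif(1, 85, 99),
        area = round(10 ^ stats::runif(1, 4, 6)), stringsAsFactors = FALSE)
      prov[[length(prov) + 1L]] <- data.frame(
        kind = "contaminant", source = config$contaminants[k],
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  ord <- stats::ave(seq_len(nrow(rec)), rec$sample_id, FUN = seq_along)
  rec$uid <- paste0(rec$sample_id, "#", ord)
  provenance <- cbind(uid = rec$uid, do.call(rbind, prov))
  tab <- feature_table(rec[, c("uid", "sample_id", "compound_name", "rt",
                               "base_peak_mz", "match_factor", "area")])
  list(table = tab,
       truth = list(planted = config$true_areas, provenance = provenance))
}

#' The standards serial-dilution design
#'
#' Four standards — ethyl hexanoate, methyl salicylate, octanal, undecane —
#' at three dilution levels (low / medium / high), with the published
#' per-level amounts in ng: low (0.000087, 0.0001179, 0.000082, 0.000072),
#' medium (434.5, 589.5, 410, 370), high (2172.5, 2947.5, 2050, 1850).
#' Detector responses are proportional to amount under a configurable
#' response factor, with optional multiplicative noise.
#'
#' @param response_factor counts per ng.
#' @param noise_scale relative s.d. of response noise.
#' @param seed seed for the noise draws.
#' @return list with `amounts` (4 x 3 matrix, ng), `config` (an
#'   `experiment_config` whose true areas are the responses), and `store`
#'   (matching reference store).
#' @export
standards_dilution_fixture <- function(response_factor = 1000,
                                       noise_scale = 0, seed = 1L) {
  std_names <- c("ethyl hexanoate", "methyl salicylate", "octanal", "undecane")
  amounts <- matrix(
    c(0.000087, 434.5, 2172.5,
      0.0001179, 589.5, 2947.5,
      0.000082, 410, 2050,
      0.000072, 370, 1850),
    nrow = 4, byrow = TRUE,
    dimnames = list(std_names, c("low", "medium", "high")))

  config <- experiment_config(n_compounds = 4L, n_samples = 3L,
                              contaminants = character(), seed = seed)
  # panel rows 1-4 are exactly the four standards
  stopifnot(identical(config$compounds$name, std_names))
  responses <- amounts * response_factor
  if (noise_scale > 0) {
    set.seed(seed)
    z <- matrix(stats::rnorm(length(responses)), nrow = nrow(responses))
    responses <- pmax(responses * (1 + noise_scale * z), 0)
  }
  dimnames(responses) <- list(std_names, config$samples)
  config$true_areas <- responses
  list(amounts = amounts, config = config,
       store = generate_reference_db(config))
}
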