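# Compound-metadata resolution: chemical name -> identifier, monoisotopic
# mass, fragment spectrum, synonyms, structure. Offline-first: the primary
# backend is a local JSON store; optional live adapters (PubChem PUG REST,
# CACTUS structure resolver) share the same interface and are never required.

# Monoisotopic masses of the most abundant isotope (IUPAC/CODATA).
.isotope_mass <- c(
  H  = 1.0078250319, D = 2.0141017781,
  B  = 11.0093054,
  C  = 12.0, N = 14.0030740052, O = 15.9949146221,
  F  = 18.9984031627,
  Na = 22.9897692820, Mg = 23.9850417,
  Si = 27.9769265347, P = 30.97376199842, S = 31.9720707,
  Cl = 34.96885271, K = 38.9637064864, Ca = 39.962590866,
  As = 74.92159457, Se = 79.9165218, Br = 78.9183376, I = 126.9044719
)

#' Monoisotopic mass of an elemental composition
#'
#' Sum of count x most-abundant-isotope mass over the elements of a
#' composition, the mass-spectrometric "exact mass" convention.
#'
#' @param composition named numeric vector or list, element symbol -> count
#'   (counts >= 1).
#' @return mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1))   # water, 18.010565
#' monoisotopic_mass(c(C = 11, H = 24)) # undecane, 156.187801
monoisotopic_mass <- function(composition) {
  composition <- unlist(composition)
  if (length(composition) == 0L)
    mz_stop("mz_chem_error", "empty elemental composition")
  unknown <- setdiff(names(composition), names(.isotope_mass))
  if (length(unknown))
    mz_stop("mz_chem_error", "unknown element symbol(s): %s",
            paste(unknown, collapse = ", "))
  if (any(composition < 1))
    mz_stop("mz_chem_error", "element counts must be >= 1")
  sum(.isotope_mass[names(composition)] * composition)
}

# "C11H24" -> c(C = 11, H = 24)
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula))
    mz_stop("mz_chem_error", "empty molecular formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula)
    mz_stop("mz_chem_error", "cannot parse molecular formula: %s", formula)
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  tapply(counts, elems, sum)
}

#' Build a compound record
#'
#' @param query_name name the record answers for.
#' @param status `"resolved_by_name"` (has a database identifier),
#'   `"resolved_by_structure"` (structure only), or `"unresolved"`.
#' @param cid optional integer compound identifier.
#' @param smiles optional SMILES string.
#' @param exact_mass optional monoisotopic mass, Da. Computed from `smiles`
#'   when absent and a structure is available.
#' @param spectrum optional data.frame/matrix with columns `mz`,
#'   `intensity`; intensities are rescaled to base peak = 100 and the
#'   spectrum is sorted by descending intensity (ties: ascending m/z).
#' @param synonyms character vector of alternative names.
#' @param source provenance: `"local_cache"`, `"pubchem"` or `"cactus"`.
#' @return a `compound_record`.
#' @export
compound_record <- function(query_name, status = "unresolved", cid = NULL,
                            smiles = NULL, exact_mass = NULL, spectrum = NULL,
                            synonyms = character(), source = "local_cache") {
  status <- match.arg(status,
                      c("resolved_by_name", "resolved_by_structure", "unresolved"))
  if (status == "resolved_by_name" && is.null(cid))
    mz_stop("mz_integrity_error", "resolved_by_name requires a cid (%s)", query_name)
  if (status == "resolved_by_structure" && (is.null(smiles) || !is.null(cid)))
    mz_stop("mz_integrity_error",
            "resolved_by_structure requires smiles and no cid (%s)", query_name)
  if (is.null(exact_mass) && !is.null(smiles) && status != "unresolved") {
    mol <- parse_smiles(smiles)
    exact_mass <- molecule_mass(mol)
  }
  if (status != "unresolved" && (is.null(exact_mass) || exact_mass <= 0))
    mz_stop("mz_integrity_error", "resolved record must carry exact_mass > 0 (%s)",
            query_name)
  if (!is.null(spectrum)) {
    spectrum <- as.data.frame(spectrum)
    names(spectrum)[1:2] <- c("mz", "intensity")
    if (any(spectrum$intensity <= 0))
      mz_stop("mz_integrity_error", "spectrum intensities must be positive (%s)",
              query_name)
    spectrum$intensity <- spectrum$intensity / max(spectrum$intensity) * 100
    spectrum <- spectrum[order(-spectrum$intensity, spectrum$mz), , drop = FALSE]
    rownames(spectrum) <- NULL
  }
  structure(list(query_name = query_name, status = status,
                 cid = if (!is.null(cid)) as.integer(cid),
                 smiles = smiles, exact_mass = exact_mass,
                 spectrum = spectrum, synonyms = as.character(synonyms),
                 source = source),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("compound_record '%s' [%s]\n", x$query_name, x$status))
  if (!is.null(x$cid)) cat(sprintf("  cid: %d\n", x$cid))
  if (!is.null(x$smiles)) cat(sprintf("  smiles: %s\n", x$smiles))
  if (!is.null(x$exact_mass)) cat(sprintf("  exact mass: %.6f Da\n", x$exact_mass))
  if (!is.null(x$spectrum))
    cat(sprintf("  spectrum: %d peaks, base peak m/z %.4g\n",
                nrow(x$spectrum), x$spectrum$mz[1]))
  if (length(x$synonyms)) cat("  synonyms:", paste(x$synonyms, collapse = "; "), "\n")
  invisible(x)
}

#' Top-k published m/z values of a compound's fragment spectrum
#'
#' Returns the m/z of the `k` most intense peaks in descending intensity
#' order; intensity ties are broken toward the lower m/z. Fewer than `k`
#' peaks returns them all.
#'
#' @param record a `compound_record` with a spectrum.
#' @param k number of peaks.
#' @return numeric vector of m/z values.
#' @export
top_mz <- function(record, k = 2L) {
  if (is.null(record$spectrum) || nrow(record$spectrum) == 0L)
    mz_stop("mz_spectrum_error",
            "no fragment spectrum for '%s': m/z matching unavailable",
            record$query_name)
  utils::head(record$spectrum$mz, k)
}

## ---- local store ----------------------------------------------------------

#' Create or load a local compound reference store
#'
#' The store is a single versioned JSON document holding one record per
#' compound (name, optional CID, SMILES, formula, monoisotopic mass,
#' fragment spectrum as m/z-intensity pairs, synonyms). It is the offline
#' stand-in for live chemistry services: the whole test suite runs from it.
#'
#' @param records list of `compound_record`s (for a fresh store), or `NULL`.
#' @param path optional path to a store JSON file to load.
#' @return a `compound_store`.
#' @export
compound_store <- function(records = list(), path = NULL) {
  if (!is.null(path)) return(read_compound_store(path))
  names(records) <- vapply(records, function(r) r$query_name, "")
  if (anyDuplicated(normalize_name(names(records))))
    mz_stop("mz_integrity_error", "duplicate compound names in store")
  idx <- new.env(parent = emptyenv())
  store <- structure(list(records = records, index = idx),
                     class = "compound_store")
  rebuild_store_index(store)
  store
}

rebuild_store_index <- function(store) {
  rm(list = ls(store$index), envir = store$index)
  for (nm in names(store$records)) {
    rec <- store$records[[nm]]
    for (key in unique(normalize_name(c(rec$query_name, rec$synonyms))))
      if (!exists(key, envir = store$index, inherits = FALSE))
        assign(key, nm, envir = store$index)
  }
  invisible(store)
}

#' @export
print.compound_store <- function(x, ...) {
  cat(sprintf("compound_store: %d records, %d lookup keys\n",
              length(x$records), length(ls(x$index))))
  invisible(x)
}

#' Serialize a compound store to JSON
#' @param store a `compound_store`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_compound_store <- function(store, path) {
  doc <- list(
    schema = "mzexacto-compound-store/1",
    compounds = lapply(unname(store$records), function(r) {
      list(query_name = r$query_name, status = r$status,
           cid = r$cid, smiles = r$smiles, exact_mass = r$exact_mass,
           spectrum = if (!is.null(r$spectrum))
             lapply(seq_len(nrow(r$spectrum)), function(i)
               c(r$spectrum$mz[i], r$spectrum$intensity[i])),
           synonyms = r$synonyms, source = r$source)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a compound store from JSON
#' @param path store JSON path.
#' @return a `compound_store`.
#' @export
read_compound_store <- function(path) {
  if (!file.exists(path))
    mz_stop("mz_io_error", "store file does not exist: %s", path)
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "mzexacto-compound-store/1"))
    mz_stop("mz_integrity_error", "unrecognized store schema in %s", path)
  recs <- lapply(doc$compounds, function(r) {
    spec <- NULL
    if (!is.null(r$spectrum) && length(r$spectrum)) {
      m <- do.call(rbind, lapply(r$spectrum, function(p) as.numeric(unlist(p))))
      spec <- data.frame(mz = m[, 1], intensity = m[, 2])
    }
    compound_record(r$query_name, status = r$status, cid = r$cid,
                    smiles = r$smiles, exact_mass = r$exact_mass,
                    spectrum = spec, synonyms = unlist(r$synonyms) %||% character(),
                    source = r$source %||% "local_cache")
  })
  compound_store(recs)
}

## ---- backends & resolution ------------------------------------------------

#' Local-store resolution backend
#' @param store a `compound_store`.
#' @return a backend function usable in [resolve_compound()].
#' @export
local_backend <- function(store) {
  force(store)
  structure(function(name) {
    key <- normalize_name(name)
    if (!exists(key, envir = store$index, inherits = FALSE)) return(NULL)
    rec <- store$records[[get(key, envir = store$index)]]
    # answer under the queried name but keep the canonical name findable
    rec$synonyms <- setdiff(unique(c(rec$synonyms, rec$query_name)), name)
    rec$query_name <- name
    rec
  }, backend_name = "local_cache")
}

#' PubChem PUG REST backend (optional, online)
#'
#' Resolves a name to a CID and monoisotopic mass via the PUG REST API.
#' Provided for completeness of the resolver interface; nothing in the
#' package, its tests, or its defaults requires network access.
#'
#' @return a backend function.
#' @export
pubchem_backend <- function() {
  structure(function(name) {
    base <- "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/name"
    url <- sprintf(
      "%s/%s/property/MonoisotopicMass,CanonicalSMILES/JSON",
      base, utils::URLencode(name, reserved = TRUE))
    ans <- tryCatch(jsonlite::fromJSON(url), error = function(e) NULL)
    props <- ans$PropertyTable$Properties
    if (is.null(props) || !nrow(props)) return(NULL)
    compound_record(name, status = "resolved_by_name", cid = props$CID[1],
                    smiles = props$CanonicalSMILES[1],
                    exact_mass = as.numeric(props$MonoisotopicMass[1]),
                    source = "pubchem")
  }, backend_name = "pubchem")
}

#' CACTUS structure-resolver backend (optional, online)
#'
#' Falls back from name lookup to structure generation: asks the NCI CACTUS
#' service for a SMILES, from which the monoisotopic mass is computed
#' locally. Never required by the offline workflow.
#'
#' @return a backend function.
#' @export
cactus_backend <- function() {
  structure(function(name) {
    url <- sprintf("https://cactus.nci.nih.gov/chemical/structure/%s/smiles",
                   utils::URLencode(name, reserved = TRUE))
    smi <- tryCatch(suppressWarnings(readLines(url, warn = FALSE))[1],
                    error = function(e) NULL)
    if (is.null(smi) || !nzchar(smi)) return(NULL)
    compound_record(name, status = "resolved_by_structure", smiles = smi,
                    source = "cactus")
  }, backend_name = "cactus")
}

#' Resolve a chemical name through an ordered backend cascade
#'
#' The first backend that answers wins. A name-lookup failure cascades to
#' the next backend (typically a structure generator); total failure yields
#' an `unresolved` record, never an error, so one obscure tentative identity
#' cannot abort a batch.
#'
#' @param name chemical name.
#' @param backends ordered list of backend functions (local cache first by
#'   default usage).
#' @return a `compound_record` (possibly with status `"unresolved"`).
#' @export
resolve_compound <- function(name, backends) {
  if (!nzchar(trimws(name)))
    mz_stop("mz_chem_error", "cannot resolve an empty name")
  if (!is.list(backends)) backends <- list(backends)
  for (b in backends) {
    rec <- b(name)
    if (!is.null(rec)) return(rec)
  }
  compound_record(name, status = "unresolved", source = "local_cache")
}

#' Batch-resolve distinct names into a registry
#'
#' Resolves every distinct name once (misses are reported together) and
#' returns the registry used by [spread_out()] and [mz_exacto()].
#'
#' @param names character vector of chemical names.
#' @param backends backend list as in [resolve_compound()].
#' @return named list, name -> `compound_record`.
#' @export
resolve_batch <- function(names, backends) {
  names <- unique(names)
  reg <- lapply(names, resolve_compound, backends = backends)
  names(reg) <- names
  misses <- names[vapply(reg, function(r) r$status == "unresolved", TRUE)]
  if (length(misses))
    message(sprintf("%d of %d names unresolved: %s", length(misses),
                    length(names), paste(utils::head(misses, 8), collapse = "; ")))
  reg
}

#' Import compound records into a store from a CSV
#'
#' Columns: `name`, then any of `cid`, `smiles`, `formula`, `exact_mass`,
#' `spectrum` (semicolon-separated `mz:intensity` pairs), `synonyms`
#' (semicolon-separated). Mass is taken from `exact_mass`, else computed
#' from `formula`, else from `smiles`.
#'
#' @param path CSV path.
#' @return a `compound_store`.
#' @export
import_store_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"name" %in% names(df))
    mz_stop("mz_schema_error", "store CSV needs a 'name' column")
  recs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    get_field <- function(f) {
      v <- row[[f]] %||% NA_character_
      if (is.null(v) || is.na(v) || !nzchar(trimws(v))) NULL else trimws(v)
    }
    cid <- get_field("cid"); smi <- get_field("smiles")
    mass <- get_field("exact_mass"); formula <- get_field("formula")
    if (is.null(mass) && !is.null(formula))
      mass <- monoisotopic_mass(parse_formula(formula))
    spec <- NULL
    spec_txt <- get_field("spectrum")
    if (!is.null(spec_txt)) {
      pairs <- strsplit(strsplit(spec_txt, ";")[[1]], ":")
      m <- do.call(rbind, lapply(pairs, as.numeric))
      spec <- data.frame(mz = m[, 1], intensity = m[, 2])
    }
    syn <- get_field("synonyms")
    syn <- if (is.null(syn)) character() else trimws(strsplit(syn, ";")[[1]])
    status <- if (!is.null(cid)) "resolved_by_name"
      else if (!is.null(smi)) "resolved_by_structure"
      else "unresolved"
    compound_record(row$name, status = status, cid = cid, smiles = smi,
                    exact_mass = if (!is.null(mass)) as.numeric(mass),
                    spectrum = spec, synonyms = syn)
  })
  compound_store(recs)
}
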