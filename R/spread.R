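# Expansion of the flat feature table into field-wise wide matrices keyed
# by unique record ids, with a registry of resolved compound metadata.
# Within each sample, slots are ordered by retention time ascending (stable
# on ties by uid), so the grids reflect elution order.

#' Expand a feature table into field-wise wide matrices
#'
#' Builds one (slot x sample) grid per field — `area`, `name`,
#' `match_factor`, `base_peak_mz`, `rt`, plus a `uid` grid tying every cell
#' back to its input record — and resolves every distinct tentative
#' compound name through the given backend(s) into a registry. Resolution
#' failures mark the registry entry `unresolved`; they never abort the
#' expansion.
#'
#' @param table a `feature_table`.
#' @param resolver backend list (see [resolve_compound()]); typically
#'   `list(local_backend(store))`.
#' @return a `spread_set`: list with `samples`, `matrices` (named list of
#'   grids, `NA` marks an empty cell), and `registry` (name ->
#'   `compound_record`).
#' @export
spread_out <- function(table, resolver) {
  rec <- table$records
  samples <- table$samples
  per_sample <- split(seq_len(nrow(rec)), factor(rec$sample_id, levels = samples))
  # stable RT order within sample, ties by uid
  per_sample <- lapply(per_sample, function(idx)
    idx[order(rec$rt[idx], rec$uid[idx])])
  n_slots <- max(vapply(per_sample, length, 1L))

  grid <- function(field, mode) {
    m <- matrix(if (mode == "character") NA_character_ else NA_real_,
                nrow = n_slots, ncol = length(samples),
                dimnames = list(NULL, samples))
    for (s in seq_along(samples)) {
      idx <- per_sample[[s]]
      if (length(idx)) m[seq_along(idx), s] <- rec[[field]][idx]
    }
    m
  }
  matrices <- list(
    uid          = grid("uid", "character"),
    name         = grid("compound_name", "character"),
    area         = grid("area", "numeric"),
    match_factor = grid("match_factor", "numeric"),
    base_peak_mz = grid("base_peak_mz", "numeric"),
    rt           = grid("rt", "numeric")
  )
  registry <- resolve_batch(unique(rec$compound_name), resolver)
  structure(list(samples = samples, matrices = matrices, registry = registry),
            class = "spread_set")
}

#' @export
print.spread_set <- function(x, ...) {
  filled <- sum(!is.na(x$matrices$uid))
  resolved <- sum(vapply(x$registry, function(r) r$status != "unresolved", TRUE))
  cat(sprintf("spread_set: %d slots x %d samples (%d records)\n",
              nrow(x$matrices$uid), length(x$samples), filled))
  cat(sprintf("  registry: %d names, %d resolved\n",
              length(x$registry), resolved))
  invisible(x)
}

#' Collapse a spread set back to a feature table
#'
#' The inverse of [spread_out()]: one record per non-empty cell, uids
#' preserved. Verifies grid integrity (a cell must be empty in every grid
#' or in none).
#'
#' @param spreadset a `spread_set`.
#' @return a `feature_table` (record order: sample by sample, slots top to
#'   bottom, i.e. retention-time order within sample).
#' @export
flatten <- function(spreadset) {
  m <- spreadset$matrices
  empt <- is.na(m$uid)
  for (f in c("name", "area", "match_factor", "base_peak_mz", "rt"))
    if (!identical(unname(is.na(m[[f]])), unname(empt)))
      mz_stop("mz_integrity_error",
              "grid '%s' disagrees with the uid grid about empty cells", f)
  recs <- do.call(rbind, lapply(seq_along(spreadset$samples), function(s) {
    rows <- which(!empt[, s])
    if (!length(rows)) return(NULL)
    data.frame(uid = m$uid[rows, s], sample_id = spreadset$samples[s],
               compound_name = m$name[rows, s], rt = m$rt[rows, s],
               base_peak_mz = m$base_peak_mz[rows, s],
               match_factor = m$match_factor[rows, s],
               area = m$area[rows, s], stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  feature_table(recs)
}

#' Serialize a spread set to JSON (pipeline checkpointing)
#' @param spreadset a `spread_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_spread_set <- function(spreadset, path) {
  ft <- flatten(spreadset)
  doc <- list(schema = "mzexacto-spread-set/1",
              samples = spreadset$samples,
              records = ft$records,
              registry_names = names(spreadset$registry))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
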