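# CSV ingest/export for the formats the workflow touches.
#
# The default input dialect is the Agilent Unknowns Analysis export: one CSV
# with columns Compound.Name, File.Name, Base.Peak.MZ, Match.Factor,
# Component.RT and Component.Area. Any other vendor's export is ingestible by
# supplying a column_map from the logical field names to that export's
# headers.

.default_column_map <- c(
  compound_name = "Compound.Name",
  sample_id     = "File.Name",
  base_peak_mz  = "Base.Peak.MZ",
  match_factor  = "Match.Factor",
  rt            = "Component.RT",
  area          = "Component.Area"
)

#' Read a deconvolution + library-search export
#'
#' Parses the per-component tentative-identification table exported by peak
#' deconvolution software into a `feature_table`: one record per
#' deconvoluted component per sample, carrying the library hit name,
#' retention time, base-peak m/z, match factor and integrated area.
#'
#' Rows with an empty compound name or a non-numeric retention time or area
#' are dropped and counted in the attached load report. Each usable row gets
#' a deterministic unique id `"<sample_id>#<ordinal>"` where the ordinal is
#' the 1-based position of the row among that sample's usable rows, so ids
#' are reproducible across runs.
#'
#' Match factors are expected on the 0--100 scale; if every value in the
#' file is <= 1 they are taken to be fractions and rescaled by 100 with a
#' warning.
#'
#' @param path path to a CSV file (RFC 4180, header row required,
#'   period-decimal).
#' @param column_map optional named character vector mapping logical field
#'   names (`compound_name`, `sample_id`, `base_peak_mz`, `match_factor`,
#'   `rt`, `area`) to the file's header names. Unmapped fields fall back to
#'   the default dialect.
#' @return a `feature_table`: list with `records` (data.frame with columns
#'   `uid`, `sample_id`, `compound_name`, `rt`, `base_peak_mz`,
#'   `match_factor`, `area`), `samples` (distinct sample ids in order of
#'   first appearance) and `load_report` (`total`, `usable`, `dropped`).
#' @export
read_feature_csv <- function(path, column_map = NULL) {
  if (!file.exists(path))
    mz_stop("mz_io_error", "input file does not exist: %s", path)
  raw <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  cmap <- .default_column_map
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cmap))
    if (length(bad))
      mz_stop("mz_schema_error", "unknown logical field(s) in column_map: %s",
              paste(bad, collapse = ", "))
    cmap[names(column_map)] <- make.names(column_map)
  }
  missing <- cmap[!(cmap %in% names(raw))]
  if (length(missing))
    mz_stop("mz_schema_error", "missing required column(s): %s",
            paste(missing, collapse = ", "))

  df <- data.frame(
    sample_id     = as.character(raw[[cmap[["sample_id"]]]]),
    compound_name = as.character(raw[[cmap[["compound_name"]]]]),
    rt            = suppressWarnings(as.numeric(raw[[cmap[["rt"]]]])),
    base_peak_mz  = suppressWarnings(as.numeric(raw[[cmap[["base_peak_mz"]]]])),
    match_factor  = suppressWarnings(as.numeric(raw[[cmap[["match_factor"]]]])),
    area          = suppressWarnings(as.numeric(raw[[cmap[["area"]]]])),
    stringsAsFactors = FALSE
  )
  total <- nrow(df)
  usable <- !is.na(df$rt) & df$rt > 0 &
    !is.na(df$area) & df$area >= 0 &
    nzchar(trimws(df$compound_name))
  df <- df[usable, , drop = FALSE]
  if (nrow(df) == 0L)
    mz_stop("mz_empty_error", "no usable rows in %s", path)

  if (all(df$match_factor <= 1, na.rm = TRUE)) {
    warning("match factors all <= 1; assuming 0-1 scale and rescaling by 100")
    df$match_factor <- df$match_factor * 100
  }
  ord <- stats::ave(seq_len(nrow(df)), df$sample_id, FUN = seq_along)
  df$uid <- paste0(df$sample_id, "#", ord)
  rownames(df) <- NULL
  feature_table(
    df[, c("uid", "sample_id", "compound_name", "rt", "base_peak_mz",
           "match_factor", "area")],
    load_report = list(total = total, usable = nrow(df),
                       dropped = total - nrow(df))
  )
}

#' Construct a feature table from a records data frame
#'
#' Low-level constructor used by [read_feature_csv()] and the synthetic
#' fixture generator. Validates the record invariants (positive finite RT,
#' match factor in `[0, 100]`, non-negative area, unique uids).
#'
#' @param records data.frame with columns `uid`, `sample_id`,
#'   `compound_name`, `rt`, `base_peak_mz`, `match_factor`, `area`.
#' @param load_report optional list recording parse counts.
#' @return a `feature_table`.
#' @export
feature_table <- function(records, load_report = NULL) {
  needed <- c("uid", "sample_id", "compound_name", "rt", "base_peak_mz",
              "match_factor", "area")
  if (!all(needed %in% names(records)))
    mz_stop("mz_schema_error", "records must have columns: %s",
            paste(needed, collapse = ", "))
  if (nrow(records) == 0L)
    mz_stop("mz_empty_error", "a feature table must contain records")
  if (anyDuplicated(records$uid))
    mz_stop("mz_integrity_error", "duplicate uid(s) in feature table")
  if (any(!is.finite(records$rt)) || any(records$rt <= 0))
    mz_stop("mz_integrity_error", "retention times must be finite and positive")
  if (any(is.na(records$match_factor)) ||
      any(records$match_factor < 0 | records$match_factor > 100))
    mz_stop("mz_integrity_error", "match factors must lie in [0, 100]")
  if (any(is.na(records$area)) || any(records$area < 0))
    mz_stop("mz_integrity_error", "areas must be non-negative")
  structure(
    list(records = records,
         samples = unique(records$sample_id),
         load_report = load_report %||%
           list(total = nrow(records), usable = nrow(records), dropped = 0L)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d records, %d samples, %d compound names\n",
              nrow(x$records), length(x$samples),
              length(unique(x$records$compound_name))))
  lr <- x$load_report
  cat(sprintf("  load report: %d total, %d usable, %d dropped\n",
              lr$total, lr$usable, lr$dropped))
  invisible(x)
}

#' Read a user chemical-category library
#'
#' A category library labels sets of chemicals by a shared property
#' (e.g. "fruity", "insect repellent"). Two CSV orientations are accepted:
#' wide (one column per category; rows are member chemicals; blank cells
#' ignored) and long (exactly two columns: category, chemical).
#'
#' @param path CSV file path.
#' @param orientation `"wide"` or `"long"`.
#' @return a `chem_library`: named list, category label -> character vector
#'   of member chemicals (trimmed, deduplicated).
#' @export
read_chem_library <- function(path, orientation = c("wide", "long")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    mz_stop("mz_io_error", "input file does not exist: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    mz_stop("mz_empty_error", "category library is empty: %s", path)

  if (orientation == "long") {
    if (ncol(raw) != 2L)
      mz_stop("mz_schema_error",
              "long-orientation library must have exactly 2 columns, found %d",
              ncol(raw))
    cats <- trimws(raw[[1]]); members <- trimws(raw[[2]])
    keep <- nzchar(cats) & nzchar(members)
    cats <- cats[keep]; members <- members[keep]
    lib <- lapply(split(members, factor(cats, levels = unique(cats))), unique)
  } else {
    labels <- trimws(names(raw))
    if (any(!nzchar(labels)))
      mz_stop("mz_schema_error", "wide-orientation library has an empty category label")
    lib <- lapply(raw, function(col) {
      v <- trimws(col)
      unique(v[nzchar(v)])
    })
    names(lib) <- labels
  }
  lib <- lib[vapply(lib, length, 1L) > 0L]
  if (!length(lib))
    mz_stop("mz_empty_error", "category library has no members: %s", path)
  structure(lib, class = "chem_library")
}

#' Write a consolidated compounds-by-samples table to CSV
#'
#' One row per chemical with its optimal retention time, exact mass, best
#' match factor and one area column per sample (input sample order). Values
#' are written at full precision so a re-read reproduces the table.
#'
#' @param table an `exacto_table` (see [mz_exacto()]).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_exacto_csv <- function(table, path) {
  if (!inherits(table, "exacto_table"))
    mz_stop("mz_schema_error", "table must be an exacto_table")
  df <- table$rows
  if (nrow(df) == 0L)
    mz_stop("mz_empty_error", "refusing to write an empty exacto table")
  out <- df
  for (nm in names(out)) if (is.numeric(out[[nm]])) out[[nm]] <- format_num(out[[nm]])
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) mz_stop("mz_io_error",
                                              "cannot open %s for writing", path))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a consolidated table written by [write_exacto_csv()]
#'
#' @param path CSV path.
#' @return an `exacto_table`.
#' @export
read_exacto_csv <- function(path) {
  if (!file.exists(path))
    mz_stop("mz_io_error", "input file does not exist: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("chemical", "optimal_rt", "exact_mass", "best_match_factor")
  if (!all(fixed %in% names(df)))
    mz_stop("mz_schema_error", "not an exacto table CSV: %s", path)
  for (nm in setdiff(names(df), "chemical")) df[[nm]] <- as.numeric(df[[nm]])
  exacto_table(df, samples = setdiff(names(df), fixed))
}

# internal constructor shared by mz_exacto and read_exacto_csv
exacto_table <- function(rows, samples, decisions = NULL) {
  structure(list(rows = rows, samples = samples, decisions = decisions),
            class = "exacto_table")
}

#' @export
print.exacto_table <- function(x, ...) {
  cat(sprintf("exacto_table: %d chemicals x %d samples\n",
              nrow(x$rows), length(x$samples)))
  print(utils::head(x$rows, 10), row.names = FALSE)
  if (nrow(x$rows) > 10) cat(sprintf("  ... %d more rows\n", nrow(x$rows) - 10))
  invisible(x)
}
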