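# Criteria subsetting of categorization output and raw feature tables.

#' Subset categorized compounds by a criterion
#'
#' Selects query names from a [categorate()] result by a single
#' `(key, relation, value)` criterion against one of the three report
#' sections: `tier` (similarity tiers; key is a category label or `"any"`),
#' `flag` (tri-state annotation flags; key is a source name), or `profile`
#' (substructure profiles; key is `ring_count`, `charge_count`, an element
#' symbol, or a functional-group label). Multiple calls compose
#' conjunctively. Output preserves query order and is deduplicated.
#'
#' @param reports a `categorate_result`.
#' @param field `"tier"`, `"flag"` or `"profile"`.
#' @param key criterion key (see above).
#' @param relation one of `"=="`, `"!="`, `">"`, `">="`, `"<"`, `"<="`
#'   (`"="` accepted as `"=="`).
#' @param value comparison value.
#' @return character vector of query names meeting the criterion.
#' @export
#' @examples
#' \dontrun{exacto_these(rep, "profile", "ring_count", ">=", 2)}
exacto_these <- function(reports, field = c("tier", "flag", "profile"),
                         key, relation, value) {
  field <- match.arg(field)
  if (relation == "=") relation <- "=="
  if (!relation %in% c("==", "!=", ">", ">=", "<", "<="))
    mz_stop("mz_query_error", "unknown relation '%s'", relation)
  rel <- match.fun(relation)

  if (field == "tier") {
    sim <- reports$similarity
    cats <- unique(sim$category)
    if (!identical(key, "any") && !key %in% cats)
      mz_stop("mz_query_error", "unknown category '%s'; valid: any, %s",
              key, paste(cats, collapse = ", "))
    rows <- if (identical(key, "any")) sim else sim[sim$category == key, ]
    hits <- rows$query[rel(rows$tier, value)]
    return(unique(hits[order(match(hits, unique(sim$query)))]))
  }

  if (field == "flag") {
    fl <- reports$flags
    if (!key %in% .annotation_sources)
      mz_stop("mz_query_error", "unknown flag '%s'; valid: %s",
              key, paste(.annotation_sources, collapse = ", "))
    return(unique(fl$query[rel(fl[[key]], value)]))
  }

  profs <- reports$profiles
  valid <- c("ring_count", "charge_count", .group_labels)
  get_key <- function(p) {
    if (key == "ring_count") return(p$ring_count)
    if (key == "charge_count") return(p$charge_count)
    if (key %in% names(p$group_counts)) return(p$group_counts[[key]])
    if (key %in% names(p$atom_counts)) return(p$atom_counts[[key]])
    if (grepl("^[A-Z][a-z]?$", key)) return(0L)   # element absent => 0
    mz_stop("mz_query_error",
            "unknown profile key '%s'; valid: %s, or an element symbol",
            key, paste(valid, collapse = ", "))
  }
  hits <- names(profs)[vapply(profs, function(p) isTRUE(rel(get_key(p), value)), TRUE)]
  unique(hits)
}

#' Filter compound names by match factor
#'
#' Returns the distinct compound names whose best (maximum) match factor
#' across all records strictly exceeds `min_mf`. Optionally a compound must
#' also qualify (match factor above the threshold) in at least `min_samples`
#' distinct samples, the cross-sample presence criterion.
#'
#' @param table a `feature_table`.
#' @param min_mf match-factor threshold in `[0, 100]`; strict `>`.
#' @param min_samples minimum number of distinct samples with a qualifying
#'   record (default 1).
#' @return character vector of compound names, in order of first appearance.
#' @export
filter_by_match_factor <- function(table, min_mf, min_samples = 1L) {
  if (min_mf < 0 || min_mf > 100)
    mz_stop("mz_query_error", "min_mf must lie in [0, 100]")
  rec <- table$records
  ok <- rec$match_factor > min_mf
  if (!any(ok)) return(character())
  qual <- rec[ok, c("compound_name", "sample_id")]
  n_samp <- tapply(qual$sample_id, qual$compound_name,
                   function(s) length(unique(s)))
  keep <- names(n_samp)[n_samp >= min_samples]
  unique(rec$compound_name)[unique(rec$compound_name) %in% keep]
}
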