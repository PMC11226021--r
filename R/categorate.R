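# Categorization of query compounds: MCS-Tanimoto similarity tiers against
# user-defined chemical categories, tri-state annotation flags from bundled
# lookup snapshots, and per-query substructure profiles.

.annotation_sources <- c("natural_product", "flavor", "pathway", "mesh",
                         "label", "reactive_group")

#' Categorize query compounds against a chemical-category library
#'
#' For every (query, category) pair the best MCS-Tanimoto score over the
#' category's members is computed and tiered: `strong` when the score is
#' strictly greater than `strong_threshold` (default 0.95), `moderate` when
#' strictly greater than `moderate_threshold` (default 0.85), else `none`.
#' The name of the most similar member is recorded. Each query additionally
#' gets a substructure profile and tri-state annotation flags.
#'
#' @param queries list of `compound_record`s (need SMILES to be scored;
#'   structureless queries are reported in the skip list).
#' @param library a `chem_library` (see [read_chem_library()]).
#' @param resolver backend list used to resolve library member names to
#'   structures (see [resolve_compound()]); members without a structure are
#'   skipped with a warning.
#' @param strong_threshold,moderate_threshold Tanimoto cutoffs in `(0, 1]`,
#'   `strong_threshold >= moderate_threshold`; both strict inequalities.
#' @param annotations optional annotation tables (see [annotation_tables()]).
#' @return a `categorate_result`: list with `similarity` (data.frame:
#'   `query`, `category`, `tier`, `best_match_name`, `best_score`), `flags`
#'   (one row per query, tri-state columns per annotation source plus
#'   provenance), `profiles` (named list of `substructure_profile`), and
#'   `skipped` (structureless query names).
#' @export
categorate <- function(queries, library, resolver,
                       strong_threshold = 0.95, moderate_threshold = 0.85,
                       annotations = NULL) {
  if (!length(library))
    mz_stop("mz_empty_error", "category library is empty")
  if (strong_threshold <= 0 || strong_threshold > 1 ||
      moderate_threshold <= 0 || strong_threshold < moderate_threshold)
    mz_stop("mz_chem_error",
            "thresholds must lie in (0,1] with strong >= moderate")

  qnames <- vapply(queries, function(q) q$query_name, "")
  qmols <- lapply(queries, function(q)
    if (!is.null(q$smiles)) parse_smiles(q$smiles, name = q$query_name))
  skipped <- qnames[vapply(qmols, is.null, TRUE)]
  if (length(skipped) == length(queries))
    mz_stop("mz_chem_error", "no query has a structure; nothing to categorize")

  # resolve library members once
  member_names <- unique(unlist(library))
  member_recs <- resolve_batch(member_names, resolver)
  member_mols <- lapply(member_recs, function(r)
    if (!is.null(r$smiles)) parse_smiles(r$smiles, name = r$query_name))
  dead <- member_names[vapply(member_mols, is.null, TRUE)]
  if (length(dead))
    warning(sprintf("skipping %d library member(s) without structures: %s",
                    length(dead), paste(utils::head(dead, 5), collapse = "; ")))

  sim <- do.call(rbind, lapply(seq_along(queries), function(qi) {
    do.call(rbind, lapply(names(library), function(cat) {
      row <- data.frame(query = qnames[qi], category = cat, tier = "none",
                        best_match_name = NA_character_, best_score = NA_real_,
                        stringsAsFactors = FALSE)
      if (is.null(qmols[[qi]])) return(row)
      members <- setdiff(library[[cat]], dead)
      if (!length(members)) { row$best_score <- 0; return(row) }
      scores <- vapply(members, function(m)
        tanimoto_mcs(qmols[[qi]], member_mols[[m]]), 0)
      k <- which.max(scores)
      row$best_score <- scores[k]
      row$best_match_name <- members[k]
      row$tier <- if (scores[k] > strong_threshold) "strong"
        else if (scores[k] > moderate_threshold) "moderate" else "none"
      row
    }))
  }))
  rownames(sim) <- NULL

  flags <- do.call(rbind, lapply(queries, flag_membership,
                                 annotations = annotations))
  profiles <- stats::setNames(
    lapply(seq_along(queries), function(qi)
      if (!is.null(qmols[[qi]])) substructure_profile(qmols[[qi]])),
    qnames)
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]

  structure(list(similarity = sim, flags = flags, profiles = profiles,
                 skipped = skipped),
            class = "categorate_result")
}

#' @export
print.categorate_result <- function(x, ...) {
  cat(sprintf("categorate_result: %d queries x %d categories\n",
              length(unique(x$similarity$query)),
              length(unique(x$similarity$category))))
  cat(sprintf("  tiers: %s\n",
              paste(names(table(x$similarity$tier)), table(x$similarity$tier),
                    sep = "=", collapse = " ")))
  if (length(x$skipped))
    cat("  skipped (no structure):", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Assemble annotation lookup tables
#'
#' Each table is a snapshot of one annotation source (natural products,
#' flavor/smell, pathway, medical subject headings, product labels,
#' reactive groups) as a data.frame with columns `name` and/or `cid`.
#' Flags are tri-state: `"true"` when the compound is in the snapshot,
#' `"false"` when the snapshot explicitly lists it with `flag = FALSE`,
#' `"unknown"` when the snapshot does not mention it.
#'
#' @param natural_product,flavor,pathway,mesh,label,reactive_group
#'   data.frames with columns `name` and/or `cid`, optional logical `flag`
#'   (default `TRUE` for listed rows).
#' @return named list of annotation tables.
#' @export
annotation_tables <- function(natural_product = NULL, flavor = NULL,
                              pathway = NULL, mesh = NULL, label = NULL,
                              reactive_group = NULL) {
  tabs <- list(natural_product = natural_product, flavor = flavor,
               pathway = pathway, mesh = mesh, label = label,
               reactive_group = reactive_group)
  tabs[!vapply(tabs, is.null, TRUE)]
}

#' Tri-state annotation flags for one compound
#'
#' Lookup order: CID first, then normalized name, then synonyms; the
#' provenance of each hit is recorded.
#'
#' @param record a `compound_record`.
#' @param annotations tables from [annotation_tables()].
#' @return one-row data.frame: `query`, one tri-state column per source,
#'   and a `provenance` column noting how matches were made.
#' @export
flag_membership <- function(record, annotations = NULL) {
  out <- data.frame(query = record$query_name, stringsAsFactors = FALSE)
  prov <- character()
  for (src in .annotation_sources) {
    tab <- annotations[[src]]
    val <- "unknown"
    if (!is.null(tab)) {
      hit <- NULL; how <- NULL
      if (!is.null(record$cid) && "cid" %in% names(tab)) {
        k <- which(tab$cid == record$cid)
        if (length(k)) { hit <- k[1]; how <- "cid" }
      }
      if (is.null(hit) && "name" %in% names(tab)) {
        keys <- normalize_name(tab$name)
        k <- which(keys == normalize_name(record$query_name))
        if (length(k)) { hit <- k[1]; how <- "name" }
        else if (length(record$synonyms)) {
          k <- which(keys %in% normalize_name(record$synonyms))
          if (length(k)) { hit <- k[1]; how <- "synonym" }
        }
      }
      if (!is.null(hit)) {
        flag <- if ("flag" %in% names(tab)) isTRUE(as.logical(tab$flag[hit])) else TRUE
        val <- if (flag) "true" else "false"
        prov <- c(prov, paste0(src, ":", how))
      }
    }
    out[[src]] <- val
  }
  out$provenance <- paste(prov, collapse = ";")
  out
}
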