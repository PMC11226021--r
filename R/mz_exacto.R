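# Core consolidation: gather each query chemical's component areas across
# all samples by (1) name/synonym matches at high match factor, then (2) a
# top-2 m/z rescue pass inside mass-ordered retention-time windows; then
# aggregate into a compounds x samples table and optionally decontaminate.
#
# Claims are exclusive: a record feeds at most one output chemical, with
# conflicts resolved deterministically in ascending exact-mass order.

#' Plan retention-time windows for a set of query chemicals
#'
#' Queries are ordered by ascending exact mass so likely retention-time
#' windows can be read off the structure of the input data: each query's
#' anchors are the RTs of records whose tentative name matches it
#' (synonym-aware) with match factor strictly above `mf_min`, and its
#' window is `median(anchors) +/- rt_halfwidth`. A query with no anchors
#' but a known exact mass gets a window interpolated from the exact-mass to
#' median-RT relation of the anchored queries (linear between the two
#' nearest anchored masses; extrapolation clamped to the data's RT range).
#' A query with neither anchors nor mass gets an empty window (name-match
#' only).
#'
#' @param queries list of `compound_record`s.
#' @param spreadset a `spread_set`.
#' @param rt_halfwidth window half-width in minutes (> 0).
#' @param mf_min match-factor floor (percent, strict `>`).
#' @return a `query_plan`: data.frame ordered by exact mass (`name`,
#'   `exact_mass`, `rt_lo`, `rt_hi`, `n_anchors`, `window_source`), with the
#'   per-query anchor RTs attached as an attribute.
#' @export
plan_queries <- function(queries, spreadset, rt_halfwidth = 0.35, mf_min = 75) {
  if (!length(queries)) mz_stop("mz_empty_error", "no query chemicals")
  if (rt_halfwidth <= 0) mz_stop("mz_query_error", "rt_halfwidth must be > 0")
  m <- spreadset$matrices
  rec_names <- normalize_name(m$name)
  all_rt <- m$rt

  qname <- vapply(queries, function(q) q$query_name, "")
  qmass <- vapply(queries, function(q) q$exact_mass %||% NA_real_, 0)
  keysets <- lapply(queries, function(q)
    unique(normalize_name(c(q$query_name, q$synonyms))))

  anchors <- lapply(keysets, function(keys) {
    hit <- !is.na(rec_names) & (rec_names %in% keys) & m$match_factor > mf_min
    sort(all_rt[hit])
  })
  med <- vapply(anchors, function(a) if (length(a)) stats::median(a) else NA_real_, 0)

  # spectral anchors for queries without name anchors: records whose
  # tentative identity shares the query's unit-rounded top-2 m/z (the same
  # fragment-agreement evidence the rescue pass uses) localize the window
  reg0 <- spreadset$registry
  reg_top <- lapply(reg0, function(r)
    if (!is.null(r$spectrum)) paste(sort(unit_mass(top_mz(r, 2L))), collapse = "/"))
  rec_top <- vapply(match(as.vector(m$name), names(reg0)), function(i)
    if (!is.na(i) && !is.null(reg_top[[i]])) reg_top[[i]] else NA_character_, "")
  spectral <- rep(FALSE, length(queries))
  for (k in which(is.na(med))) {
    q <- queries[[k]]
    if (is.null(q$spectrum)) next
    qt <- paste(sort(unit_mass(top_mz(q, 2L))), collapse = "/")
    hit <- !is.na(rec_top) & rec_top == qt &
      !is.na(as.vector(m$match_factor)) & as.vector(m$match_factor) > mf_min
    if (any(hit)) {
      med[k] <- stats::median(as.vector(all_rt)[hit])
      spectral[k] <- TRUE
    }
  }

  if (all(vapply(anchors, length, 1L) == 0L) && all(is.na(qmass)))
    mz_stop("mz_plan_error",
            "no query has name anchors and none has an exact mass; cannot bound windows")

  # Mass->RT trend for unanchored-but-massed queries: anchored queries give
  # (exact mass, median anchor RT) points; the general structure of the
  # input data contributes (identity mass, observed RT) points for every
  # record whose tentative identity resolves in the registry above the
  # match-factor floor. Median RT per distinct mass, linear interpolation
  # between the two nearest masses, extrapolation clamped to the data's RT
  # range.
  rt_range <- range(all_rt, na.rm = TRUE)
  reg <- spreadset$registry
  reg_mass <- vapply(reg, function(r) r$exact_mass %||% NA_real_, 0)
  rec_flat_names <- as.vector(m$name)
  rec_mass <- reg_mass[match(rec_flat_names, names(reg))]
  ok <- !is.na(rec_mass) & !is.na(as.vector(m$match_factor)) &
    as.vector(m$match_factor) > mf_min
  trend_x <- c(qmass[!is.na(med) & !is.na(qmass)], rec_mass[ok])
  trend_y <- c(med[!is.na(med) & !is.na(qmass)], as.vector(all_rt)[ok])
  center <- med
  if (length(trend_x)) {
    agg_y <- tapply(trend_y, trend_x, stats::median)
    xs <- as.numeric(names(agg_y)); ys <- as.numeric(agg_y)
    for (k in which(is.na(med))) {
      if (is.na(qmass[k])) next
      c_k <- if (length(xs) == 1L) ys
        else stats::approx(xs, ys, xout = qmass[k], rule = 2, ties = mean)$y
      center[k] <- min(max(c_k, rt_range[1]), rt_range[2])
    }
  }

  plan <- data.frame(
    name = qname, exact_mass = qmass,
    rt_lo = center - rt_halfwidth, rt_hi = center + rt_halfwidth,
    n_anchors = vapply(anchors, length, 1L),
    window_source = ifelse(vapply(anchors, length, 1L) > 0, "anchors",
                    ifelse(spectral, "spectral_anchors",
                    ifelse(!is.na(center), "mass_interpolation", "none"))),
    stringsAsFactors = FALSE
  )
  ord <- order(plan$exact_mass, plan$name, na.last = TRUE)
  plan <- plan[ord, , drop = FALSE]
  rownames(plan) <- NULL
  attr(plan, "anchors") <- anchors[ord]
  attr(plan, "keysets") <- keysets[ord]
  class(plan) <- c("query_plan", "data.frame")
  plan
}

# decisions bookkeeping: one row per (query, sample) with a claim or absence
new_decision <- function(query, sample, uid = NA_character_, mode = "absent",
                         area = 0, rt = NA_real_, mf = NA_real_) {
  data.frame(query = query, sample = sample, uid = uid, mode = mode,
             area = area, rt = rt, match_factor = mf, stringsAsFactors = FALSE)
}

#' Name-pass matches for one planned query
#'
#' All records whose normalized tentative name or synonym equals the query
#' with match factor strictly above `mf_min`. Claims are exclusive: records
#' already claimed (by a lower-mass query) are skipped and the conflict is
#' logged.
#'
#' @param plan_entry one row of a [plan_queries()] result (with its keyset
#'   attached as `attr(, "keys")`).
#' @param spreadset a `spread_set`.
#' @param claimed environment mapping uid -> claiming query (shared across
#'   queries; updated in place).
#' @param mf_min match-factor floor.
#' @return data.frame of match decisions (`mode = "name"`).
#' @export
find_name_matches <- function(plan_entry, spreadset, claimed = new.env(),
                              mf_min = 75) {
  m <- spreadset$matrices
  keys <- attr(plan_entry, "keys")
  out <- NULL
  conflicts <- character()
  for (s in spreadset$samples) {
    rows <- which(!is.na(m$uid[, s]) &
                  normalize_name(m$name[, s]) %in% keys &
                  m$match_factor[, s] > mf_min)
    for (r in rows) {
      uid <- m$uid[r, s]
      if (exists(uid, envir = claimed, inherits = FALSE)) {
        conflicts <- c(conflicts,
          sprintf("%s already claimed by %s; skipped for %s",
                  uid, get(uid, envir = claimed), plan_entry$name))
        next
      }
      assign(uid, plan_entry$name, envir = claimed)
      out <- rbind(out, new_decision(plan_entry$name, s, uid, "name",
                                     m$area[r, s], m$rt[r, s],
                                     m$match_factor[r, s]))
    }
  }
  if (length(conflicts)) {
    if (is.null(out)) out <- new_decision("", "")[0, , drop = FALSE]
    attr(out, "conflicts") <- conflicts
  }
  out
}

#' m/z rescue pass for one planned query
#'
#' In samples where the query found no name match, unclaimed records are
#' rescued when (a) their RT lies inside the query's window, (b) the
#' unit-mass-rounded set of the top-`k` published m/z of the record's
#' tentative identity (looked up in the registry) equals the query's, and
#' (c) no other query claimed them. Among several candidates in one sample
#' the highest match factor wins, then the RT closest to the window center,
#' then the largest area.
#'
#' @inheritParams find_name_matches
#' @param k number of top peaks compared (default 2).
#' @param mz_tolerance m/z agreement tolerance in Da before unit rounding
#'   (0 = unit-mass set equality, the quadrupole convention).
#' @param samples_without_name_match the search space: samples the name
#'   pass left empty for this query.
#' @param query_record the query's `compound_record` (defaults to the
#'   registry entry under the query's name).
#' @return data.frame of match decisions (`mode = "mz"`), or `NULL`.
#' @export
rescue_by_mz <- function(plan_entry, spreadset, claimed = new.env(),
                         k = 2L, mz_tolerance = 0,
                         samples_without_name_match = spreadset$samples,
                         query_record = NULL) {
  reg <- spreadset$registry
  qrec <- query_record %||% reg[[plan_entry$name]]
  if (is.null(qrec) || is.null(qrec$spectrum)) return(NULL)
  if (is.na(plan_entry$rt_lo)) return(NULL)
  q_top <- sort(unit_mass(top_mz(qrec, k)))
  m <- spreadset$matrices
  center <- (plan_entry$rt_lo + plan_entry$rt_hi) / 2

  # precompute top-k sets for registry identities once per call
  reg_tops <- lapply(reg, function(r)
    if (!is.null(r$spectrum)) sort(unit_mass(top_mz(r, k))))

  mz_equal <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    if (mz_tolerance > 0) all(abs(a - b) <= mz_tolerance) else all(a == b)
  }

  out <- NULL
  for (s in samples_without_name_match) {
    rows <- which(!is.na(m$uid[, s]) &
                  m$rt[, s] >= plan_entry$rt_lo & m$rt[, s] <= plan_entry$rt_hi)
    cands <- integer()
    for (r in rows) {
      uid <- m$uid[r, s]
      if (exists(uid, envir = claimed, inherits = FALSE)) next
      ident <- reg_tops[[m$name[r, s]]]
      if (is.null(ident) || !mz_equal(ident, q_top)) next
      # sanity check: observed base peak vs the claimed identity's base peak
      irec <- reg[[m$name[r, s]]]
      if (!is.null(irec$spectrum) && !is.na(m$base_peak_mz[r, s])) {
        if (abs(unit_mass(m$base_peak_mz[r, s]) - unit_mass(irec$spectrum$mz[1])) > 0.5)
          warning(sprintf(
            "record %s: observed base peak %.4g disagrees with identity '%s'",
            uid, m$base_peak_mz[r, s], m$name[r, s]))
      }
      cands <- c(cands, r)
    }
    if (!length(cands)) next
    o <- order(-m$match_factor[cands, s],
               abs(m$rt[cands, s] - center),
               -m$area[cands, s])
    r <- cands[o[1]]
    uid <- m$uid[r, s]
    assign(uid, plan_entry$name, envir = claimed)
    out <- rbind(out, new_decision(plan_entry$name, s, uid, "mz",
                                   m$area[r, s], m$rt[r, s],
                                   m$match_factor[r, s]))
  }
  out
}

#' Consolidate query chemicals into a compounds-by-samples area table
#'
#' Runs the full two-pass matching over a [spread_out()] result: name
#' matches first (in ascending exact-mass order, exclusive claims), then
#' the top-2 m/z rescue inside each query's retention-time window. Per
#' chemical and sample the claimed areas are aggregated (sum by default —
#' deconvolution can split one elution into several components — or max),
#' the optimal retention time is the area-weighted mean of claimed RTs, and
#' the best match factor is the maximum. Absent means area exactly 0. Rows
#' are ordered by ascending exact mass, unresolved chemicals last
#' (alphabetical).
#'
#' @param spreadset a `spread_set` from [spread_out()].
#' @param chemicals character vector of query chemical names.
#' @param decontaminate drop chemicals that are unresolved, structureless,
#'   weakly matched or too rarely seen (default on; see [decontaminate()]).
#' @param mf_min match-factor floor for name matches and anchors (percent,
#'   strict `>`; default 75).
#' @param rt_halfwidth RT window half-width in minutes (default 0.35).
#' @param mz_tolerance m/z tolerance passed to [rescue_by_mz()].
#' @param aggregation `"sum"` or `"max"` within a (chemical, sample).
#' @param strong_mf,min_samples decontamination parameters.
#' @param backends optional resolver backends consulted for query chemicals
#'   that never occur among the tentative identities (and so are absent
#'   from the spread set's registry).
#' @return an `exacto_table`; its `decisions` element logs every claim
#'   (query, sample, uid, mode, area, rt, match_factor) for audit.
#' @export
mz_exacto <- function(spreadset, chemicals, decontaminate = TRUE,
                      mf_min = 75, rt_halfwidth = 0.35, mz_tolerance = 0,
                      aggregation = c("sum", "max"),
                      strong_mf = 75, min_samples = 1L, backends = NULL) {
  aggregation <- match.arg(aggregation)
  if (!length(chemicals)) mz_stop("mz_empty_error", "empty chemical list")
  chemicals <- unique(chemicals)
  reg <- spreadset$registry
  queries <- lapply(chemicals, function(nm) {
    r <- reg[[nm]]
    if (is.null(r)) {
      # chemical not among the tentative identities: try the registry's
      # records by synonym, then any extra backends, else carry unresolved
      hit <- Filter(function(x) normalize_name(nm) %in%
                      normalize_name(c(x$query_name, x$synonyms)), reg)
      r <- if (length(hit)) {
        h <- hit[[1]]
        h$synonyms <- setdiff(unique(c(h$synonyms, h$query_name)), nm)
        h$query_name <- nm
        h
      } else if (!is.null(backends)) resolve_compound(nm, backends)
        else compound_record(nm, status = "unresolved")
    }
    r
  })
  names(queries) <- chemicals

  plan <- plan_queries(queries, spreadset, rt_halfwidth = rt_halfwidth,
                       mf_min = mf_min)
  keysets <- attr(plan, "keysets")

  claimed <- new.env(parent = emptyenv())
  decisions <- NULL
  conflicts <- character()

  # pass 1: name matches, in plan (exact-mass) order
  name_hits <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    entry <- plan[i, , drop = FALSE]
    attr(entry, "keys") <- keysets[[i]]
    d <- find_name_matches(entry, spreadset, claimed, mf_min = mf_min)
    conflicts <- c(conflicts, attr(d, "conflicts"))
    name_hits[i] <- list(d)
    decisions <- rbind(decisions, d)
  }

  # pass 2: m/z rescue in samples that pass 1 left empty
  for (i in seq_len(nrow(plan))) {
    entry <- plan[i, , drop = FALSE]
    have <- unique(name_hits[[i]]$sample)
    missing <- setdiff(spreadset$samples, have)
    if (!length(missing)) next
    d <- rescue_by_mz(entry, spreadset, claimed, k = 2L,
                      mz_tolerance = mz_tolerance,
                      samples_without_name_match = missing,
                      query_record = queries[[plan$name[i]]])
    decisions <- rbind(decisions, d)
  }

  if (is.null(decisions)) decisions <- new_decision("", "")[0, , drop = FALSE]

  # aggregate
  samples <- spreadset$samples
  rows <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    nm <- plan$name[i]
    d <- decisions[decisions$query == nm, , drop = FALSE]
    areas <- stats::setNames(numeric(length(samples)), samples)
    opt_rt <- NA_real_; best_mf <- NA_real_
    if (!is.null(d) && nrow(d)) {
      for (s in unique(d$sample)) {
        a <- d$area[d$sample == s]
        areas[s] <- if (aggregation == "sum") sum(a) else max(a)
      }
      w <- d$area
      opt_rt <- if (sum(w) > 0) sum(d$rt * w) / sum(w) else mean(d$rt)
      best_mf <- max(d$match_factor)
    }
    cbind(data.frame(chemical = nm, optimal_rt = opt_rt,
                     exact_mass = plan$exact_mass[i],
                     best_match_factor = best_mf, stringsAsFactors = FALSE),
          as.data.frame(as.list(areas), check.names = FALSE))
  }))
  rownames(rows) <- NULL

  n_matched_samples <- vapply(rows$chemical, function(nm) {
    d <- decisions[decisions$query == nm, , drop = FALSE]
    if (is.null(d) || !nrow(d)) 0L else length(unique(d$sample))
  }, 1L)

  tab <- exacto_table(rows, samples = samples, decisions = decisions)
  attr(tab, "conflicts") <- conflicts
  attr(tab, "n_matched_samples") <- n_matched_samples
  attr(tab, "registry") <- queries

  if (decontaminate)
    tab <- decontaminate(tab, registry = queries, strong_mf = strong_mf,
                         min_samples = min_samples)
  tab
}

#' Remove weakly supported or unidentifiable chemicals
#'
#' Drops rows whose compound is `unresolved` in the registry, carries
#' neither an identifier nor a structure, whose best match factor is not
#' strictly above `strong_mf`, or which matched in fewer than `min_samples`
#' samples. Removal reasons are recorded per chemical in
#' `attr(, "removed")`.
#'
#' @param table an `exacto_table` carrying decision metadata.
#' @param registry name -> `compound_record` for the table's chemicals
#'   (taken from the table when omitted).
#' @param strong_mf match-factor strictness (percent, strict `>`).
#' @param min_samples minimum number of samples with a claimed record.
#' @return the filtered `exacto_table`.
#' @export
decontaminate <- function(table, registry = attr(table, "registry"),
                          strong_mf = 75, min_samples = 1L) {
  rows <- table$rows
  nms <- attr(table, "n_matched_samples") %||%
    stats::setNames(rowSums(rows[, table$samples, drop = FALSE] > 0), rows$chemical)
  removed <- character()
  keep <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    nm <- rows$chemical[i]
    r <- registry[[nm]]
    reason <- NULL
    if (is.null(r) || r$status == "unresolved")
      reason <- "not found in public databases"
    else if (is.null(r$cid) && is.null(r$smiles))
      reason <- "no identifier or structure"
    else if (is.na(rows$best_match_factor[i]) ||
             rows$best_match_factor[i] <= strong_mf)
      reason <- sprintf("best match factor %.1f not above %.1f",
                        rows$best_match_factor[i], strong_mf)
    else if (nms[[nm]] < min_samples)
      reason <- sprintf("matched in %d sample(s), fewer than %d",
                        nms[[nm]], min_samples)
    if (is.null(reason)) keep[i] <- TRUE
    else removed[nm] <- reason
  }
  out <- exacto_table(rows[keep, , drop = FALSE], samples = table$samples,
                      decisions = table$decisions)
  out$rows <- `rownames<-`(out$rows, NULL)
  attr(out, "removed") <- removed
  attr(out, "n_matched_samples") <- nms[keep]
  attr(out, "registry") <- registry
  attr(out, "conflicts") <- attr(table, "conflicts")
  out
}
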