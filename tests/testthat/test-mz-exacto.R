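# The consolidation core: window planning, name pass, m/z rescue,
# aggregation, decontamination.

# small bespoke world: two compounds + a rescue partner + a decoy
tiny_world <- function() {
  recs <- list(
    compound_record("linalool", status = "resolved_by_name", cid = 6549,
                    smiles = "CC(C)=CCCC(C)(O)C=C",
                    spectrum = data.frame(mz = c(71, 93, 55, 41),
                                          intensity = c(100, 80, 40, 30))),
    compound_record("undecane", status = "resolved_by_name", cid = 14257,
                    smiles = "CCCCCCCCCCC",
                    spectrum = data.frame(mz = c(57, 43, 71, 85),
                                          intensity = c(100, 90, 55, 30))),
    # wrong identity sharing linalool's top-2 (the rescue path)
    compound_record("plinol", status = "resolved_by_structure",
                    smiles = "CC1CCC(C)(O)C1C=C",
                    spectrum = data.frame(mz = c(71, 93, 43),
                                          intensity = c(100, 75, 20))),
    # decoy with disjoint top-2
    compound_record("diethyl phthalate", status = "resolved_by_name",
                    cid = 6781, smiles = "CCOC(=O)c1ccccc1C(=O)OCC",
                    spectrum = data.frame(mz = c(149, 177, 105),
                                          intensity = c(100, 28, 20)))
  )
  compound_store(recs)
}

tiny_table <- function(rows) {
  ord <- stats::ave(seq_len(nrow(rows)), rows$sample_id, FUN = seq_along)
  rows$uid <- paste0(rows$sample_id, "#", ord)
  feature_table(rows[, c("uid", "sample_id", "compound_name", "rt",
                         "base_peak_mz", "match_factor", "area")])
}

rowdf <- function(sample, name, rt, mf, area, bp = 71) {
  data.frame(sample_id = sample, compound_name = name, rt = rt,
             base_peak_mz = bp, match_factor = mf, area = area,
             stringsAsFactors = FALSE)
}

test_that("windows are median(anchors) +/- halfwidth, in exact-mass order", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.31, 92, 100),
    rowdf("s2", "linalool", 8.32, 94, 110),
    rowdf("s3", "linalool", 8.33, 91, 120),
    rowdf("s1", "undecane", 8.50, 93, 200, bp = 57)))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  plan <- plan_queries(ss$registry[c("linalool", "undecane")], ss,
                       rt_halfwidth = 0.35, mf_min = 75)
  lin <- plan[plan$name == "linalool", ]
  expect_equal(lin$rt_lo, 8.32 - 0.35)
  expect_equal(lin$rt_hi, 8.32 + 0.35)
  expect_equal(lin$n_anchors, 3L)
  # queries ordered by ascending exact mass: linalool (154.14) < undecane (156.19)
  expect_equal(plan$name, c("linalool", "undecane"))
  expect_true(all(diff(plan$exact_mass) >= 0))
  # an automated hit 0.001 min away from the manual anchor must be admitted
  expect_true(8.315 >= lin$rt_lo && 8.315 <= lin$rt_hi)
})

test_that("an unanchored query's window interpolates the mass-RT trend", {
  store <- compound_store(list(
    compound_record("light", status = "resolved_by_name", cid = 1,
                    exact_mass = 100,
                    spectrum = data.frame(mz = c(41, 55), intensity = c(100, 50))),
    compound_record("mid", status = "resolved_by_name", cid = 2,
                    exact_mass = 150,
                    spectrum = data.frame(mz = c(43, 57), intensity = c(100, 50))),
    compound_record("heavy", status = "resolved_by_name", cid = 3,
                    exact_mass = 200,
                    spectrum = data.frame(mz = c(45, 59), intensity = c(100, 50)))
  ))
  ft <- tiny_table(rbind(
    rowdf("s1", "light", 5.0, 90, 10),
    rowdf("s1", "heavy", 9.0, 90, 10)))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  plan <- plan_queries(ss$registry[c("light", "heavy")], ss, 0.35, 75)
  # "mid" never occurs by name: mass 150 sits midway between 100 and 200,
  # so its window centers midway between the anchored medians 5 and 9
  qmid <- store$records[["mid"]]
  plan2 <- plan_queries(list(store$records[["light"]], qmid,
                             store$records[["heavy"]]), ss, 0.35, 75)
  mid <- plan2[plan2$name == "mid", ]
  expect_equal(mid$window_source, "mass_interpolation")
  expect_equal((mid$rt_lo + mid$rt_hi) / 2, 7.0)
})

test_that("planning fails only when no anchors and no masses exist at all", {
  ft <- tiny_table(rowdf("s1", "whatever", 5, 90, 10))
  ss <- suppressMessages(spread_out(ft, list(function(name) NULL)))
  q <- list(compound_record("ghost", status = "unresolved"))
  expect_error(plan_queries(q, ss, 0.35, 75), class = "mz_plan_error")
})

test_that("the name pass respects the strict match-factor floor", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.3, 70, 100),   # below floor 75
    rowdf("s2", "linalool", 8.3, 75, 110),   # at floor: strict >, excluded
    rowdf("s3", "linalool", 8.3, 76, 120)))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, "linalool", decontaminate = FALSE)
  dec <- et$decisions
  # only the MF-76 record qualifies for the name pass (strict >); the two
  # weaker records are still recoverable, but only through the m/z rescue
  expect_equal(dec$mode[dec$sample == "s3"], "name")
  expect_true(all(dec$mode[dec$sample %in% c("s1", "s2")] == "mz"))
})

test_that("claims are exclusive and resolved toward the lower mass", {
  # two queries sharing a synonym; the record can satisfy both
  store <- compound_store(list(
    compound_record("alpha", status = "resolved_by_name", cid = 1,
                    exact_mass = 120, synonyms = "shared name",
                    spectrum = data.frame(mz = c(41, 55), intensity = c(100, 50))),
    compound_record("beta", status = "resolved_by_name", cid = 2,
                    exact_mass = 180, synonyms = "shared name",
                    spectrum = data.frame(mz = c(43, 57), intensity = c(100, 50)))
  ))
  ft <- tiny_table(rowdf("s1", "shared name", 6.0, 90, 500))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, c("beta", "alpha"), decontaminate = FALSE,
                  backends = list(local_backend(store)))
  expect_equal(et$rows$chemical, c("alpha", "beta"))  # mass order
  expect_equal(as.numeric(et$rows[et$rows$chemical == "alpha", "s1"]), 500)
  expect_equal(as.numeric(et$rows[et$rows$chemical == "beta", "s1"]), 0)
  expect_match(paste(attr(et, "conflicts"), collapse = " "), "already claimed")
  # uid accounting: no uid appears under two queries
  expect_false(anyDuplicated(et$decisions$uid) > 0)
})

test_that("m/z rescue recovers misnamed records inside the window only", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.31, 92, 100),
    rowdf("s2", "linalool", 8.32, 91, 110),
    rowdf("s3", "plinol",   8.34, 88, 130),    # misnamed, same top-2 -> rescue
    rowdf("s4", "plinol",  12.00, 88, 140)))   # outside window -> absent
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, "linalool", decontaminate = FALSE)
  areas <- as.numeric(et$rows[1, ss$samples])
  expect_equal(areas, c(100, 110, 130, 0))
  dec <- et$decisions
  expect_equal(dec$mode[dec$sample == "s3"], "mz")
  expect_equal(dec$mode[dec$sample == "s1"], "name")
})

test_that("decoys with disjoint top-2 m/z are never rescued", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.31, 92, 100),
    rowdf("s2", "diethyl phthalate", 8.33, 95, 999, bp = 149)))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, "linalool", decontaminate = FALSE)
  expect_equal(as.numeric(et$rows[1, "s2"]), 0)
})

test_that("among rescue candidates the higher match factor wins", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.31, 92, 100),
    rowdf("s2", "plinol", 8.30, 80, 300),
    rowdf("s2", "plinol", 8.35, 90, 200)))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, "linalool", decontaminate = FALSE)
  dec <- et$decisions
  s2 <- dec[dec$sample == "s2", ]
  expect_equal(nrow(s2), 1)
  expect_equal(s2$match_factor, 90)
  expect_equal(as.numeric(et$rows[1, "s2"]), 200)
})

test_that("split peaks aggregate by summation and optimal RT is area-weighted", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.30, 92, 300),
    rowdf("s1", "linalool", 8.40, 90, 100)))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, "linalool", decontaminate = FALSE)
  expect_equal(as.numeric(et$rows[1, "s1"]), 400)
  expect_equal(et$rows$optimal_rt, (8.30 * 300 + 8.40 * 100) / 400)
  expect_equal(et$rows$best_match_factor, 92)
  et2 <- mz_exacto(ss, "linalool", decontaminate = FALSE, aggregation = "max")
  expect_equal(as.numeric(et2$rows[1, "s1"]), 300)
})

test_that("a chemical absent everywhere yields a zero row when kept", {
  store <- tiny_world()
  ft <- tiny_table(rowdf("s1", "linalool", 8.3, 92, 100))
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et <- mz_exacto(ss, c("linalool", "undecane"), decontaminate = FALSE)
  und <- et$rows[et$rows$chemical == "undecane", ]
  expect_equal(as.numeric(und[ , "s1"]), 0)
  expect_error(mz_exacto(ss, character()), class = "mz_empty_error")
})

test_that("decontaminate drops unresolved, weak and rare chemicals with reasons", {
  store <- tiny_world()
  ft <- tiny_table(rbind(
    rowdf("s1", "linalool", 8.31, 92, 100),
    rowdf("s2", "linalool", 8.32, 93, 110),
    rowdf("s1", "undecane", 9.10, 60, 500, bp = 57),   # weak MF
    rowdf("s1", "Column bleed", 14.0, 95, 900, bp = 281)))  # unresolved
  ss <- suppressMessages(spread_out(ft, list(local_backend(store))))
  et_off <- mz_exacto(ss, c("linalool", "undecane", "Column bleed"),
                      decontaminate = FALSE, mf_min = 50)
  expect_equal(nrow(et_off$rows), 3)
  et_on <- mz_exacto(ss, c("linalool", "undecane", "Column bleed"),
                     decontaminate = TRUE, mf_min = 50)
  expect_equal(et_on$rows$chemical, "linalool")
  removed <- attr(et_on, "removed")
  expect_match(removed[["Column bleed"]], "not found in public databases")
  expect_match(removed[["undecane"]], "match factor")
  # min_samples: linalool in 2 samples survives 2, dies at 3
  et3 <- mz_exacto(ss, "linalool", decontaminate = TRUE, min_samples = 3)
  expect_equal(nrow(et3$rows), 0)
})

test_that("consolidation conserves area and is deterministic", {
  cfg <- experiment_config(n_compounds = 10, n_samples = 6,
                           rt_jitter_sd = 0.05, name_corruption_rate = 0.3,
                           n_decoys = 3, seed = 17)
  sim <- generate_feature_table(cfg)
  store <- generate_reference_db(cfg)
  ss <- suppressMessages(spread_out(sim$table, list(local_backend(store))))
  et1 <- mz_exacto(ss, cfg$compounds$name)
  et2 <- mz_exacto(ss, cfg$compounds$name)
  expect_identical(et1$rows, et2$rows)
  total_out <- sum(et1$rows[, cfg$samples])
  total_in <- sum(sim$table$records$area)
  expect_lte(total_out, total_in)
  expect_false(anyDuplicated(et1$decisions$uid) > 0)
})
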