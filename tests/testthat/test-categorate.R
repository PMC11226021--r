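# Tanimoto tiering against category libraries and annotation flags.

alkane_rec <- function(n, name = paste0("alkane", n)) {
  compound_record(name, status = "resolved_by_name", cid = n,
                  smiles = strrep("C", n))
}

test_that("an identical library member scores 1.0 and tiers strong", {
  q <- compound_record("undecane", status = "resolved_by_name", cid = 14257,
                       smiles = "CCCCCCCCCCC")
  backend <- list(list_backend(list(q)))
  lib <- structure(list(alkanes = "undecane"), class = "chem_library")
  res <- suppressMessages(categorate(list(q), lib, backend))
  expect_equal(res$similarity$best_score, 1.0)
  expect_equal(res$similarity$tier, "strong")
  expect_equal(res$similarity$best_match_name, "undecane")
})

test_that("tier boundaries are strict: exactly 0.95 is moderate, 0.85 none", {
  # linear alkanes give exact scores: C(n) vs C(n+k) -> n / (n + k)
  members <- list(alkane_rec(20, "eicosane"))
  backend <- list(list_backend(members))
  lib <- structure(list(ref = "eicosane"), class = "chem_library")
  tiers <- vapply(c(25, 24, 19, 18, 17, 10), function(n) {
    q <- alkane_rec(n)
    r <- suppressMessages(categorate(list(q), lib, backend))
    # scores: 20/25=0.8 handled below; here n<=20 -> n/20, n>20 -> 20/n
    r$similarity$tier
  }, "")
  # scores: 20/25 = 0.80, 20/24 = 0.833, 19/20 = 0.95, 18/20 = 0.90,
  #         17/20 = 0.85, 10/20 = 0.50
  expect_equal(tiers, c("none", "none", "moderate", "moderate", "none", "none"))

  # strong needs strictly more than 0.95: 24/25 = 0.96 qualifies
  lib25 <- structure(list(ref = "pentacosane"), class = "chem_library")
  backend25 <- list(list_backend(list(alkane_rec(25, "pentacosane"))))
  r <- suppressMessages(categorate(list(alkane_rec(24)), lib25, backend25))
  expect_equal(r$similarity$best_score, 0.96)
  expect_equal(r$similarity$tier, "strong")
  expect_equal(r$similarity$best_match_name, "pentacosane")
})

test_that("the similarity report has one row per query-category pair", {
  qs <- lapply(c(5, 6, 7), alkane_rec)
  backend <- list(list_backend(c(qs, list(alkane_rec(10, "decane"),
                                          alkane_rec(20, "eicosane")))))
  lib <- structure(list(short = "decane", long = "eicosane"),
                   class = "chem_library")
  res <- suppressMessages(categorate(qs, lib, backend))
  expect_equal(nrow(res$similarity), 6)
  expect_true(all(res$similarity$tier %in% c("strong", "moderate", "none")))
  strong_rows <- res$similarity[res$similarity$tier == "strong", ]
  expect_true(all(nzchar(strong_rows$best_match_name)))
})

test_that("raising the strong threshold never creates more strong rows", {
  qs <- lapply(c(18, 19, 20, 21), alkane_rec)
  backend <- list(list_backend(c(qs, list(alkane_rec(20, "eicosane")))))
  lib <- structure(list(ref = "eicosane"), class = "chem_library")
  n_strong <- vapply(c(0.90, 0.94, 0.98), function(th) {
    r <- suppressMessages(categorate(qs, lib, backend, strong_threshold = th,
                                     moderate_threshold = 0.5))
    sum(r$similarity$tier == "strong")
  }, 1L)
  expect_true(all(diff(n_strong) <= 0))
})

test_that("structureless queries are skipped, structureless members warned", {
  q1 <- alkane_rec(5)
  q2 <- compound_record("ghost", status = "unresolved")
  member <- alkane_rec(5, "pentane")
  dud <- compound_record("no structure", status = "resolved_by_name",
                         cid = 7, exact_mass = 50)
  backend <- list(list_backend(list(member, dud)))
  lib <- structure(list(grp = c("pentane", "no structure")),
                   class = "chem_library")
  expect_warning(
    res <- suppressMessages(categorate(list(q1, q2), lib, backend)),
    "without structures")
  expect_equal(res$skipped, "ghost")
  expect_equal(res$similarity$tier[res$similarity$query == "ghost"], "none")
  expect_false("ghost" %in% names(res$profiles))
})

test_that("annotation flags follow cid-name-synonym lookup order", {
  ann <- annotation_tables(
    flavor = data.frame(cid = 14257, name = "undecane"),
    natural_product = data.frame(name = "linalool"),
    pathway = data.frame(name = "x", flag = FALSE)
  )
  by_cid <- compound_record("UNDECANE  ", status = "resolved_by_name",
                            cid = 14257, exact_mass = 1)
  row <- flag_membership(by_cid, ann)
  expect_equal(row$flavor, "true")
  expect_match(row$provenance, "flavor:cid")

  by_syn <- compound_record("3,7-dimethyl-1,6-octadien-3-ol",
                            status = "resolved_by_structure", smiles = "CCO",
                            synonyms = "Linalool")
  row2 <- flag_membership(by_syn, ann)
  expect_equal(row2$natural_product, "true")
  expect_match(row2$provenance, "synonym")

  row3 <- flag_membership(compound_record("nothing", exact_mass = 1,
                                          status = "unresolved"), ann)
  expect_true(all(unlist(row3[mzexacto:::.annotation_sources]) == "unknown"))

  row4 <- flag_membership(compound_record("x", status = "unresolved"), ann)
  expect_equal(row4$pathway, "false")
})
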