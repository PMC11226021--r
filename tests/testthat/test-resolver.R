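# Name -> metadata resolution, monoisotopic masses, spectrum handling.

test_that("monoisotopic masses match hand-summed isotope arithmetic", {
  # 2 x 1.0078250319 + 15.9949146221
  expect_equal(monoisotopic_mass(c(H = 2, O = 1)), 18.010565, tolerance = 1e-6)
  # 11 x 12 + 24 x 1.0078250319
  expect_equal(monoisotopic_mass(c(C = 11, H = 24)), 156.187801, tolerance = 1e-6)
  expect_error(monoisotopic_mass(c()), class = "mz_chem_error")
  expect_error(monoisotopic_mass(c(Xx = 1)), "Xx", class = "mz_chem_error")
})

test_that("monoisotopic mass is additive over disjoint compositions", {
  set.seed(41)
  els <- names(mzexacto:::.isotope_mass)
  for (rep in 1:25) {
    pick <- sample(els, 6)
    a <- stats::setNames(sample(1:9, 3, replace = TRUE), pick[1:3])
    b <- stats::setNames(sample(1:9, 3, replace = TRUE), pick[4:6])
    expect_equal(monoisotopic_mass(c(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("top_mz ranks by intensity with low-m/z tie-break", {
  r <- compound_record("x", status = "resolved_by_name", cid = 1,
                       exact_mass = 100,
                       spectrum = data.frame(mz = c(43, 71, 57),
                                             intensity = c(100, 80, 60)))
  expect_equal(top_mz(r, 2), c(43, 71))
  r2 <- compound_record("y", status = "resolved_by_name", cid = 2,
                        exact_mass = 100,
                        spectrum = data.frame(mz = c(69, 55),
                                              intensity = c(90, 90)))
  expect_equal(top_mz(r2, 1), 55)
  r3 <- compound_record("z", status = "resolved_by_name", cid = 3,
                        exact_mass = 100,
                        spectrum = data.frame(mz = 43, intensity = 100))
  expect_length(top_mz(r3, 2), 1)
  r4 <- compound_record("w", status = "resolved_by_name", cid = 4,
                        exact_mass = 100)
  expect_error(top_mz(r4), class = "mz_spectrum_error")
})

test_that("spectra are normalized to base peak 100 on construction", {
  r <- compound_record("x", status = "resolved_by_name", cid = 1,
                       exact_mass = 10,
                       spectrum = data.frame(mz = c(50, 60), intensity = c(2, 8)))
  expect_equal(r$spectrum$intensity, c(100, 25))
  expect_equal(r$spectrum$mz, c(60, 50))
})

test_that("resolution cascades through backends and never throws on a miss", {
  hit <- compound_record("undecane", status = "resolved_by_name", cid = 14257,
                         exact_mass = 156.1878, synonyms = "n-undecane")
  backend <- list_backend(list(hit))
  r <- resolve_compound("Undecane", list(backend))
  expect_equal(r$status, "resolved_by_name")
  expect_equal(r$exact_mass, 156.1878)
  # synonym-aware
  expect_equal(resolve_compound("N-UNDECANE", list(backend))$cid, 14257L)
  # total miss -> unresolved, no error
  miss <- resolve_compound("xqzzt-not-a-chemical", list(backend))
  expect_equal(miss$status, "unresolved")
})

test_that("a structure-only cache entry resolves by structure with computed mass", {
  rec <- compound_record("mystery alcohol", status = "resolved_by_structure",
                         smiles = "CCCO")
  expect_null(rec$cid)
  # C3H8O = 3*12 + 8*1.0078250319 + 15.9949146221
  expect_equal(rec$exact_mass, 60.057515, tolerance = 1e-6)
})

test_that("the JSON store round-trips records field-for-field", {
  cfg <- experiment_config(n_compounds = 4, n_samples = 2, n_decoys = 2, seed = 2)
  store <- generate_reference_db(cfg)
  # 4 planted + 4 rescue partners + 2 decoys
  expect_length(store$records, 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_compound_store(store, f)
  back <- read_compound_store(f)
  expect_equal(names(back$records), names(store$records))
  for (nm in names(store$records)) {
    a <- store$records[[nm]]; b <- back$records[[nm]]
    expect_equal(a$status, b$status)
    expect_equal(a$cid, b$cid)
    expect_equal(a$exact_mass, b$exact_mass, tolerance = 1e-12)
    expect_equal(a$spectrum, b$spectrum, tolerance = 1e-12)
    expect_equal(a$synonyms, b$synonyms)
  }
})

test_that("resolution is deterministic for a fixed store", {
  cfg <- experiment_config(n_compounds = 3, n_samples = 2, seed = 9)
  store <- generate_reference_db(cfg)
  b <- list(local_backend(store))
  r1 <- resolve_compound("linalool", b)
  r2 <- resolve_compound("linalool", b)
  expect_identical(r1, r2)
})

test_that("store CSV import computes masses from formula or structure", {
  df <- data.frame(
    name = c("undecane", "benzyl alcohol"),
    cid = c("14257", ""),
    smiles = c("", "OCc1ccccc1"),
    formula = c("C11H24", ""),
    spectrum = c("57:100;43:90", "79:100;108:60"),
    synonyms = c("n-undecane", ""),
    stringsAsFactors = FALSE
  )
  f <- write_tmp_csv(df)
  st <- import_store_csv(f)
  expect_equal(st$records[["undecane"]]$exact_mass, 156.187801, tolerance = 1e-6)
  expect_equal(st$records[["undecane"]]$status, "resolved_by_name")
  expect_equal(st$records[["benzyl alcohol"]]$status, "resolved_by_structure")
  expect_equal(st$records[["benzyl alcohol"]]$exact_mass, 108.057515,
               tolerance = 1e-5)
})
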