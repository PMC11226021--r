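# Calibration fits and internal/external quantification.

test_that("exact data give exact coefficients and R^2 = 1", {
  lin <- fit_calibration(c(1, 2, 3), c(3, 5, 7))
  expect_equal(unname(coef(lin)), c(1, 2), tolerance = 1e-12)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)

  lg <- fit_calibration(c(1, exp(1), exp(2)), 4 * c(0, 1, 2) + 2, kind = "log")
  expect_equal(unname(coef(lg)), c(2, 4), tolerance = 1e-12)
  expect_equal(lg$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate calibration inputs are rejected by name", {
  expect_error(fit_calibration(1, 2), class = "mz_fit_error")
  expect_error(fit_calibration(c(1, 2), c(1, 2, 3)), class = "mz_fit_error")
  expect_error(fit_calibration(c(0, 1), c(1, 2), kind = "log"),
               class = "mz_fit_error")
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), class = "mz_fit_error")
})

test_that("inverse prediction undoes the fitted curve to 1e-9", {
  set.seed(12)
  for (kind in c("linear", "log")) {
    amounts <- sort(stats::runif(6, 0.5, 100))
    slope <- stats::runif(1, 0.5, 5); intercept <- stats::runif(1, -3, 3)
    x <- if (kind == "log") log(amounts) else amounts
    model <- fit_calibration(amounts, slope * x + intercept, kind = kind)
    expect_equal(model$r_squared, 1, tolerance = 1e-9)
    got <- predict(model, response = predict(model, amount = amounts))
    expect_equal(got, amounts, tolerance = 1e-9)
  }
  m <- fit_calibration(c(1, 2, 3), c(3, 5, 7))
  expect_equal(predict(m, response = 7), 3, tolerance = 1e-12)
  lg <- fit_calibration(c(1, exp(1), exp(2)), 4 * c(0, 1, 2) + 2, kind = "log")
  expect_equal(predict(lg, response = 2), 1, tolerance = 1e-12)
})

test_that("refitting at predicted points reproduces the coefficients", {
  model <- fit_calibration(c(1, 5, 25, 125), c(11, 52, 260, 1301))
  refit <- fit_calibration(model$amounts,
                           predict(model, amount = model$amounts))
  expect_equal(coef(refit), coef(model), tolerance = 1e-9)
})

make_exacto <- function(areas) {
  # areas: named list chemical -> numeric vector over samples s1..sk
  k <- length(areas[[1]])
  samples <- paste0("s", seq_len(k))
  rows <- do.call(rbind, lapply(names(areas), function(nm) {
    cbind(data.frame(chemical = nm, optimal_rt = 5, exact_mass = 100,
                     best_match_factor = 90, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(areas[[nm]], samples)),
                        check.names = FALSE))
  }))
  mzexacto:::exacto_table(rows, samples = samples)
}

test_that("internal standardization is ratio times known amount", {
  et <- make_exacto(list(analyte = c(500, 600), tetradecane = c(250, 300)))
  st <- standardify_internal(et, "tetradecane", known_amount = 10)
  expect_equal(as.numeric(st$rows[st$rows$chemical == "analyte", st$samples]),
               c(20, 20))
  # the standard's own row is identically the known amount
  expect_equal(as.numeric(st$rows[st$rows$chemical == "tetradecane", st$samples]),
               c(10, 10))
  # bare ratios without an amount
  st2 <- standardify_internal(et, "tetradecane")
  expect_equal(as.numeric(st2$rows[st2$rows$chemical == "tetradecane", st2$samples]),
               c(1, 1))
})

test_that("a missing or zero-area standard is an error naming the samples", {
  et <- make_exacto(list(analyte = c(500, 600), std = c(250, 0)))
  expect_error(standardify_internal(et, "std"), "s2",
               class = "mz_standard_error")
  expect_error(standardify_internal(et, "absent"), class = "mz_standard_error")
})

test_that("internal quantities are invariant to per-sample rescaling", {
  set.seed(77)
  et <- make_exacto(list(a = stats::runif(3, 10, 100),
                         b = stats::runif(3, 10, 100),
                         std = stats::runif(3, 10, 100)))
  base <- standardify_internal(et, "std", known_amount = 5)
  scaled <- et
  fac <- stats::runif(3, 0.1, 10)
  for (i in seq_along(et$samples))
    scaled$rows[[et$samples[i]]] <- et$rows[[et$samples[i]]] * fac[i]
  again <- standardify_internal(scaled, "std", known_amount = 5)
  expect_equal(again$rows, base$rows, tolerance = 1e-12)
})

test_that("external standardization inverse-predicts and flags extrapolation", {
  et <- make_exacto(list(analyte = c(7, 100)))
  model <- fit_calibration(c(1, 2, 3), c(3, 5, 7))
  st <- standardify_external(et, list(default = model))
  expect_equal(as.numeric(st$rows[1, st$samples]), c(3, 49.5))
  expect_equal(unname(st$extrapolated[1, ]), c(FALSE, TRUE))

  # per-chemical model beats the default; missing model is an error
  lg <- fit_calibration(c(1, exp(1), exp(2)), 4 * c(0, 1, 2) + 2, kind = "log")
  st2 <- standardify_external(et, list(analyte = lg))
  expect_equal(as.numeric(st2$rows[1, "s1"]), exp((7 - 2) / 4))
  expect_error(standardify_external(et, list(other = model)),
               class = "mz_standard_error")
})

test_that("negative linear inversions are reported unclamped with the flag", {
  et <- make_exacto(list(trace = c(0.5, 5)))
  model <- fit_calibration(c(1, 2, 3), c(3, 5, 7))
  st <- standardify_external(et, list(default = model))
  expect_lt(as.numeric(st$rows[1, "s1"]), 0)
  expect_true(st$extrapolated[1, "s1"])
})
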