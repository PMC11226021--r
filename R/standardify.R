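# Quantification of consolidated areas against internal or external
# standards. External calibration fits detector response on amount (linear)
# or on ln(amount) ("natural log fit") by ordinary least squares and
# inverse-predicts analyte amounts; internal standardization expresses each
# chemical's area relative to a spiked standard's area in the same sample.

#' Fit a calibration curve
#'
#' Ordinary least squares of detector response on amount (`kind = "linear"`,
#' `response = slope * amount + intercept`) or on the natural log of amount
#' (`kind = "log"`, `response = slope * ln(amount) + intercept`).
#'
#' @param amounts standard amounts (ng); > 0 for the log fit; not all equal.
#' @param responses detector responses (counts), same length.
#' @param kind `"linear"` or `"log"`.
#' @param standard_name optional name carried on the model.
#' @return a `calibration` object: `standard_name`, `kind`, `slope`,
#'   `intercept`, `r_squared`, `n_points`, and the fitted response range
#'   used for extrapolation flagging.
#' @export
#' @examples
#' fit_calibration(c(1, 2, 3), c(3, 5, 7))           # slope 2, intercept 1
#' fit_calibration(c(1, exp(1), exp(2)), 4 * log(c(1, exp(1), exp(2))) + 2,
#'                 kind = "log")
fit_calibration <- function(amounts, responses, kind = c("linear", "log"),
                            standard_name = NA_character_) {
  kind <- match.arg(kind)
  if (length(amounts) != length(responses))
    mz_stop("mz_fit_error", "amounts and responses differ in length")
  if (length(amounts) < 2L)
    mz_stop("mz_fit_error", "calibration needs at least 2 points")
  if (kind == "log" && any(amounts <= 0))
    mz_stop("mz_fit_error", "log calibration requires positive amounts")
  x <- if (kind == "log") log(amounts) else amounts
  if (isTRUE(all.equal(stats::var(x), 0)))
    mz_stop("mz_fit_error", "amounts are all equal; slope is undefined")
  fit <- stats::lm(responses ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(standard_name = standard_name, kind = kind,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = length(amounts),
                 response_range = range(responses),
                 amounts = amounts, responses = responses),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration%s: %s fit, %d points\n",
              if (!is.na(x$standard_name)) paste0(" '", x$standard_name, "'") else "",
              x$kind, x$n_points))
  cat(sprintf("  response = %.6g * %s + %.6g,  R^2 = %.4f\n",
              x$slope, if (x$kind == "log") "ln(amount)" else "amount",
              x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.calibration <- function(object, ...) {
  cat(sprintf("Calibration curve (%s fit)\n", object$kind))
  print(object)
  cat(sprintf("  fitted response range: [%.6g, %.6g]\n",
              object$response_range[1], object$response_range[2]))
  invisible(object)
}

#' Predict response from amount, or invert a response to an amount
#'
#' `predict(model, amount = a)` evaluates the fitted curve;
#' `predict(model, response = r)` inverse-predicts the amount (the
#' quantification direction): linear `(r - intercept)/slope`, log
#' `exp((r - intercept)/slope)`.
#'
#' @param object a `calibration`.
#' @param amount amounts at which to evaluate the curve.
#' @param response responses to invert.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.calibration <- function(object, amount = NULL, response = NULL, ...) {
  if (!is.null(amount)) {
    x <- if (object$kind == "log") log(amount) else amount
    return(object$slope * x + object$intercept)
  }
  if (is.null(response))
    mz_stop("mz_fit_error", "supply either amount or response")
  if (object$slope == 0)
    mz_stop("mz_fit_error", "zero slope: calibration cannot be inverted")
  z <- (response - object$intercept) / object$slope
  if (object$kind == "log") exp(z) else z
}

#' Quantify against an internal standard
#'
#' Each chemical's area is divided by the standard's area in the same
#' sample and multiplied by the spiked amount (a bare ratio when
#' `known_amount` is omitted). The standard must be present with positive
#' area in every sample.
#'
#' @param table an `exacto_table`.
#' @param standard_name chemical name of the internal standard (must be a
#'   row of the table).
#' @param known_amount spiked amount in ng; `NULL` reports ratios.
#' @return a `standardized_table`: `rows` mirror the exacto table with
#'   areas replaced by quantities, `method = "internal"`.
#' @export
standardify_internal <- function(table, standard_name, known_amount = NULL) {
  rows <- table$rows
  smp <- table$samples
  k <- which(normalize_name(rows$chemical) == normalize_name(standard_name))
  if (!length(k))
    mz_stop("mz_standard_error", "internal standard '%s' is not in the table",
            standard_name)
  std <- as.numeric(rows[k[1], smp])
  bad <- smp[is.na(std) | std <= 0]
  if (length(bad))
    mz_stop("mz_standard_error",
            "internal standard '%s' has zero area in sample(s): %s",
            standard_name, paste(bad, collapse = ", "))
  scale <- known_amount %||% 1
  out <- rows
  for (i in seq_along(smp)) out[[smp[i]]] <- rows[[smp[i]]] / std[i] * scale
  structure(list(rows = out, samples = smp, method = "internal",
                 standard_name = standard_name,
                 known_amount = known_amount,
                 extrapolated = matrix(FALSE, nrow(out), length(smp),
                                       dimnames = list(out$chemical, smp))),
            class = "standardized_table")
}

#' Quantify against external calibration curves
#'
#' Each chemical's per-sample response is inverse-predicted through its
#' calibration model (per-chemical entry in `models`, else the `default`
#' model). Responses outside the model's fitted response range are flagged
#' extrapolated; negative linear predictions are reported as-is with the
#' flag.
#'
#' @param table an `exacto_table`.
#' @param models named list of `calibration` objects (names are chemical
#'   names; an entry named `"default"` catches the rest).
#' @return a `standardized_table` with `method = "external"` and a logical
#'   `extrapolated` matrix.
#' @export
standardify_external <- function(table, models) {
  rows <- table$rows
  smp <- table$samples
  keys <- normalize_name(names(models))
  out <- rows
  extra <- matrix(FALSE, nrow(rows), length(smp),
                  dimnames = list(rows$chemical, smp))
  for (i in seq_len(nrow(rows))) {
    kk <- which(keys == normalize_name(rows$chemical[i]))
    model <- if (length(kk)) models[[kk[1]]] else models[["default"]]
    if (is.null(model))
      mz_stop("mz_standard_error", "no calibration model for '%s' and no default",
              rows$chemical[i])
    resp <- as.numeric(rows[i, smp])
    out[i, smp] <- predict(model, response = resp)
    extra[i, ] <- resp < model$response_range[1] | resp > model$response_range[2]
  }
  structure(list(rows = out, samples = smp, method = "external",
                 extrapolated = extra),
            class = "standardized_table")
}

#' @export
print.standardized_table <- function(x, ...) {
  cat(sprintf("standardized_table (%s): %d chemicals x %d samples\n",
              x$method, nrow(x$rows), length(x$samples)))
  if (any(x$extrapolated))
    cat(sprintf("  %d cell(s) flagged extrapolated\n", sum(x$extrapolated)))
  print(utils::head(x$rows, 10), row.names = FALSE)
  invisible(x)
}

#' Write a standardized table (with extrapolation flags) to CSV
#' @param table a `standardized_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_standardized_csv <- function(table, path) {
  df <- table$rows
  flags <- apply(table$extrapolated, 1, function(r)
    paste(colnames(table$extrapolated)[r], collapse = ";"))
  df$extrapolated_in <- flags
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- format_num(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a calibration input CSV
#'
#' Columns: `standard_name`, `amount`, `response`, optional `kind`
#' (`linear`/`log`, default linear). One model is fitted per standard.
#'
#' @param path CSV path.
#' @return named list of `calibration` models.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("standard_name", "amount", "response")
  if (!all(need %in% names(df)))
    mz_stop("mz_schema_error", "calibration CSV needs columns: %s",
            paste(need, collapse = ", "))
  out <- lapply(split(df, df$standard_name), function(d) {
    kind <- if ("kind" %in% names(d) && nzchar(d$kind[1])) d$kind[1] else "linear"
    fit_calibration(as.numeric(d$amount), as.numeric(d$response),
                    kind = kind, standard_name = d$standard_name[1])
  })
  out
}
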