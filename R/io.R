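#' Read a measurement panel from delimited text
#'
#' Expects a header with columns `brand`, `element`, `replicate`, `value`
#' and optionally `unit` (default ug/L) and `provenance`. Comma and
#' semicolon dialects are auto-detected. Row-level problems (unknown
#' element symbol, negative or missing value, duplicate key) are collected
#' and reported together with their line numbers.
#'
#' @param path path to a delimited text file.
#' @param sep field separator; `NULL` (default) auto-detects `,` vs `;`.
#' @return A [measurement_table()].
#' @export
read_panel <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(";", header, fixed = TRUE)) ";" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("brand", "element", "replicate", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$unit)) raw$unit <- "ug/L"
  if (is.null(raw$provenance)) raw$provenance <- "measured"
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  problems <- character(0)
  bad_el <- !(raw$element %in% element_panel()$symbol)
  if (any(bad_el)) {
    problems <- c(problems, sprintf("line %d: unknown element '%s'",
                                    line[bad_el], raw$element[bad_el]))
  }
  v <- suppressWarnings(as.numeric(raw$value))
  bad_v <- is.na(v) | v < 0
  if (any(bad_v)) {
    problems <- c(problems, sprintf("line %d: invalid value '%s'",
                                    line[bad_v], raw$value[bad_v]))
  }
  key <- paste(raw$brand, raw$element, raw$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- c(problems,
                  sprintf("line %d: duplicate (brand, element, replicate) key",
                          line[dup]))
  }
  if (length(problems) > 0L) {
    stop("invalid panel file '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  measurement_table(raw$brand, raw$element, raw$replicate, v,
                    unit = raw$unit, provenance = raw$provenance)
}

#' Write a measurement panel as delimited text
#'
#' Long tidy format (brand, element, replicate, value, unit, provenance),
#' values in the canonical unit ug/L; round-trips through [read_panel()].
#'
#' @param panel a [measurement_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "measurement_table"))
  out <- as.data.frame(panel)
  out$unit <- "ug/L"
  out <- out[, c("brand", "element", "replicate", "value", "unit",
                 "provenance")]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Two-significant-figure scientific notation
#'
#' Renders numbers in the `a.b x 10^n` style used by the published risk
#' tables, to make visual diffing against them trivial.
#'
#' @param x numeric vector.
#' @param digits significant digits; default 2.
#' @return character vector (`""` for `NA`, `"0"` for zero).
#' @examples
#' format_sci(9.367e-07)  # "9.4 \u00d7 10^-7"
#' @export
format_sci <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (v == 0) return("0")
    e <- floor(log10(abs(v)))
    mant <- signif(v, digits) / 10^e
    # rounding can push the mantissa to 10
    if (abs(mant) >= 10) {
      mant <- mant / 10
      e <- e + 1
    }
    sprintf("%.*f \u00d7 10^%d", digits - 1L, mant, e)
  }, "")
}

.write_wide <- function(risk, value_col, path, formatted = TRUE) {
  brands <- unique(risk$brand)
  els <- unique(risk$element)
  wide <- data.frame(brand = brands, stringsAsFactors = FALSE)
  for (el in els) {
    v <- risk[[value_col]][match(paste(brands, el),
                                 paste(risk$brand, risk$element))]
    wide[[el]] <- if (formatted) format_sci(v) else v
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = TRUE)
  path
}

#' Render report files for an assessment
#'
#' Writes machine-readable tidy tables at full precision and wide
#' human-readable tables per scenario (EDI and THQ per element plus HI;
#' ILCR per carcinogen with its risk band) in 2-significant-figure
#' scientific notation. Wide tables are pivoted from the same numbers as
#' the tidy ones; rendering never recomputes. Empty inputs produce
#' headers-only files.
#'
#' @param assessment a [assess_risk()] result.
#' @param tests optional [compare_brands()] result.
#' @param screen optional [screen_exceedance()] result.
#' @param dir output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(assessment, tests = NULL, screen = NULL,
                           dir = ".") {
  stopifnot(inherits(assessment, "risk_assessment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tidy <- as.data.frame(assessment)
  p <- file.path(dir, "risk_tidy.csv")
  utils::write.csv(tidy, p, row.names = FALSE, quote = TRUE)
  files <- c(files, p)
  for (sc in unique(tidy$scenario)) {
    sub <- assessment$risk[assessment$risk$scenario == sc, , drop = FALSE]
    tag <- gsub("[^A-Za-z0-9]+", "_", sc)
    p_edi <- file.path(dir, sprintf("edi_%s.csv", tag))
    p_hq <- file.path(dir, sprintf("thq_%s.csv", tag))
    .write_wide(sub, "edi", p_edi)
    # append HI column to the THQ table
    .write_wide(sub, "hq", p_hq)
    hq <- utils::read.csv(p_hq, stringsAsFactors = FALSE,
                          check.names = FALSE)
    hi <- assessment$hi[assessment$hi$scenario == sc, , drop = FALSE]
    hq$HI <- sprintf("%.2f", hi$hi[match(hq$brand, hi$brand)])
    utils::write.csv(hq, p_hq, row.names = FALSE, quote = TRUE)
    carc <- sub[!is.na(sub$ilcr), , drop = FALSE]
    p_il <- file.path(dir, sprintf("ilcr_%s.csv", tag))
    if (nrow(carc) > 0L) {
      carc$ilcr_band <- paste0(format_sci(carc$ilcr), " (", carc$band, ")")
      .write_wide(carc, "ilcr_band", p_il, formatted = FALSE)
    } else {
      utils::write.csv(data.frame(brand = character(0)), p_il,
                       row.names = FALSE)
    }
    files <- c(files, p_edi, p_hq, p_il)
  }
  if (!is.null(tests)) {
    p <- file.path(dir, "brand_comparison.csv")
    utils::write.csv(as.data.frame(tests), p, row.names = FALSE,
                     quote = TRUE)
    files <- c(files, p)
  }
  if (!is.null(screen)) {
    p <- file.path(dir, "exceedance_screen.csv")
    utils::write.csv(as.data.frame(screen), p, row.names = FALSE,
                     quote = TRUE)
    files <- c(files, p)
  }
  invisible(files)
}
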