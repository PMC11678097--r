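#' Replicate-level concentration panels
#'
#' A measurement table is the raw input of every stage of the pipeline:
#' one row per (brand, element, replicate) with the concentration stored
#' in the canonical unit ug/L and a free-text provenance tag
#' (`"measured"`, `"printed"`, `"edi-inverted"`, `"synthetic"`, ...).
#' Keys must be unique and concentrations non-negative; element symbols
#' are restricted to the 19-member panel.
#'
#' @param brand character vector of brand labels.
#' @param element character vector of panel element symbols.
#' @param replicate integer replicate index (>= 1).
#' @param value numeric concentrations.
#' @param unit unit of `value`, `"ug/L"` (default) or `"mg/L"`; recycled.
#' @param provenance provenance tag per record; recycled.
#' @return An object of classes `measurement_table` and `data.frame` with
#'   columns `brand`, `element`, `replicate`, `value` (ug/L), `provenance`.
#' @examples
#' measurement_table("ED 3", "Pb", 1, 32.79)
#' @export
measurement_table <- function(brand, element, replicate, value,
                              unit = "ug/L", provenance = "measured") {
  n <- length(value)
  brand <- rep_len(as.character(brand), n)
  element <- as_element(rep_len(as.character(element), n))
  replicate <- rep_len(as.integer(replicate), n)
  provenance <- rep_len(as.character(provenance), n)
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate indices must be integers >= 1", call. = FALSE)
  }
  value <- convert_conc(as.numeric(value), rep_len(unit, n), "ug/L")
  tab <- data.frame(brand = brand, element = element, replicate = replicate,
                    value = value, provenance = provenance,
                    stringsAsFactors = FALSE)
  key <- paste(tab$brand, tab$element, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), c("brand", "element", "replicate")]
    stop("duplicate (brand, element, replicate) key(s): ",
         paste(apply(d, 1L, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("Measurement panel: %d records, %d brand(s), %d element(s) [ug/L]\n",
              nrow(x), length(unique(x$brand)), length(unique(x$element))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Mean concentration per brand and element
#'
#' Arithmetic mean over replicates, the aggregation used upstream of the
#' intake formula.
#'
#' @param panel a [measurement_table()].
#' @return data.frame with columns `brand`, `element`, `n`, `mean` (ug/L).
#' @export
panel_means <- function(panel) {
  stopifnot(inherits(panel, "measurement_table"))
  agg <- stats::aggregate(value ~ brand + element, data = panel,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ brand + element, data = panel,
                          FUN = length)
  out <- merge(agg, cnt, by = c("brand", "element"),
               suffixes = c("", ".n"))
  names(out) <- c("brand", "element", "mean", "n")
  out[, c("brand", "element", "n", "mean")]
}
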