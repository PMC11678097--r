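#' Estimated daily intake (EDI)
#'
#' The chronic daily intake of an element through beverage consumption,
#'
#'   EDI = C x IR x EF x EXD / (BW x AT)   (mg/kg/day)
#'
#' with C the concentration in mg/L. Concentrations are passed in the
#' package's canonical unit ug/L and converted to mg/L inside the formula.
#' With the default averaging convention AT = EXD x 365 the exposure
#' duration cancels, so EDI = C x IR x EF / (BW x 365).
#'
#' @param conc_ugl concentration(s) in ug/L, non-negative.
#' @param scenario an [exposure_scenario()].
#' @return EDI in mg/kg/day, same length as `conc_ugl`.
#' @examples
#' compute_edi(32.79, builtin_scenarios()$adolescent)  # ~1.1e-4
#' @export
compute_edi <- function(conc_ugl, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(!is.finite(conc_ugl)) || any(conc_ugl < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  c_mgl <- convert_conc(conc_ugl, "ug/L", "mg/L")
  c_mgl * scenario$IR * scenario$EF * scenario$EXD /
    (scenario$BW * scenario$AT)
}

#' Concentration that yields a given intake
#'
#' Algebraic inverse of [compute_edi()]; used to reconstruct concentrations
#' from published intake tables.
#'
#' @param edi intake(s) in mg/kg/day, non-negative.
#' @param scenario an [exposure_scenario()].
#' @return concentration in ug/L.
#' @export
invert_edi <- function(edi, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(!is.finite(edi)) || any(edi < 0)) {
    stop("EDI must be finite and non-negative", call. = FALSE)
  }
  c_mgl <- edi * scenario$BW * scenario$AT /
    (scenario$IR * scenario$EF * scenario$EXD)
  convert_conc(c_mgl, "mg/L", "ug/L")
}

#' Hazard quotient (HQ)
#'
#' Ratio of estimated daily intake to the oral reference dose,
#' HQ = EDI / RfD. HQ > 1 flags potential non-carcinogenic risk.
#'
#' @param edi intake in mg/kg/day.
#' @param element element symbol with an RfD entry.
#' @param tox a [toxicity_reference()].
#' @return dimensionless hazard quotient.
#' @export
compute_hq <- function(edi, element, tox = toxicity_reference()) {
  stopifnot(inherits(tox, "toxicity_reference"))
  element <- as_element(element)
  rfd <- tox$rfd[element]
  if (anyNA(rfd)) {
    stop("no oral reference dose (RfD) for element(s): ",
         paste(element[is.na(rfd)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(edi)) || any(edi < 0)) {
    stop("EDI must be finite and non-negative", call. = FALSE)
  }
  unname(edi / rfd)
}

#' Hazard index (HI)
#'
#' Arithmetic sum of hazard quotients across co-occurring elements, under
#' the additive-risk assumption: HI = sum(HQ).
#'
#' @param hqs numeric vector of non-negative hazard quotients.
#' @return dimensionless hazard index.
#' @export
compute_hi <- function(hqs) {
  if (length(hqs) == 0L) stop("no hazard quotients to sum", call. = FALSE)
  if (any(!is.finite(hqs)) || any(hqs < 0)) {
    stop("hazard quotients must be finite and non-negative", call. = FALSE)
  }
  sum(hqs)
}

#' Incremental lifetime cancer risk (ILCR)
#'
#' ILCR = EDI x CSF for the five elements carrying an oral cancer slope
#' factor (Cr, Ni, As, Cd, Pb). Elements without a slope factor raise an
#' explicit error rather than returning zero.
#'
#' @param edi intake in mg/kg/day.
#' @param element carcinogen symbol.
#' @param tox a [toxicity_reference()].
#' @return dimensionless lifetime risk.
#' @export
compute_ilcr <- function(edi, element, tox = toxicity_reference()) {
  stopifnot(inherits(tox, "toxicity_reference"))
  element <- as_element(element)
  csf <- tox$csf[element]
  if (anyNA(csf)) {
    stop("no cancer slope factor for element(s): ",
         paste(element[is.na(csf)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(edi)) || any(edi < 0)) {
    stop("EDI must be finite and non-negative", call. = FALSE)
  }
  unname(edi * csf)
}

#' Categorical cancer-risk band
#'
#' ILCR below 1e-6 is acceptable; above 1e-4 is high; the closed range
#' 1e-6 to 1e-4 (both boundaries included) is moderate.
#'
#' @param ilcr non-negative lifetime risk value(s).
#' @return character vector in `{"acceptable", "moderate", "high"}`.
#' @examples
#' classify_ilcr(c(9.4e-7, 1e-6, 1.2e-4))
#' @export
classify_ilcr <- function(ilcr) {
  if (any(!is.finite(ilcr)) || any(ilcr < 0)) {
    stop("ILCR must be finite and non-negative", call. = FALSE)
  }
  ifelse(ilcr < 1e-6, "acceptable",
         ifelse(ilcr > 1e-4, "high", "moderate"))
}

.assess_one <- function(panel, brand, scenario, tox, elements) {
  sub <- panel[panel$brand == brand & panel$element %in% elements, ,
               drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("brand '", brand, "' has no records for the requested elements",
         call. = FALSE)
  }
  means <- stats::aggregate(value ~ element, data = sub, FUN = mean)
  missing <- setdiff(elements, means$element)
  if (length(missing) > 0L) {
    warning("brand '", brand, "': no measurements for ",
            paste(missing, collapse = ", "),
            "; excluded from the hazard index", call. = FALSE)
  }
  edi <- compute_edi(means$value, scenario)
  hq <- compute_hq(edi, means$element, tox)
  carc <- means$element[means$element %in% names(tox$csf)]
  ilcr <- rep(NA_real_, nrow(means))
  ilcr[means$element %in% carc] <-
    compute_ilcr(edi[means$element %in% carc],
                 means$element[means$element %in% carc], tox)
  band <- rep(NA_character_, length(ilcr))
  band[!is.na(ilcr)] <- classify_ilcr(ilcr[!is.na(ilcr)])
  data.frame(
    brand = brand, scenario = scenario$name, element = means$element,
    conc_ugl = means$value, edi = edi, hq = hq, hq_flag = hq > 1,
    ilcr = ilcr, band = band,
    stringsAsFactors = FALSE
  )
}

#' Risk characterisation for one brand
#'
#' Averages replicates per element, then runs the EDI -> HQ -> HI and
#' EDI -> ILCR chains for a single brand under one exposure scenario.
#' Elements absent from the panel are dropped from the hazard index with
#' a warning rather than aborting the assessment.
#'
#' @param panel a [measurement_table()].
#' @param brand brand label present in the panel.
#' @param scenario an [exposure_scenario()].
#' @param tox a [toxicity_reference()].
#' @param elements elements to assess; default the fifteen micro elements.
#' @return A list with `brand`, `scenario`, per-element data.frame `risk`
#'   (conc, edi, hq, ilcr, band), and scalar `hi`.
#' @export
assess_brand <- function(panel, brand, scenario,
                         tox = toxicity_reference(),
                         elements = micro_elements()) {
  stopifnot(inherits(panel, "measurement_table"))
  elements <- as_element(elements)
  risk <- .assess_one(panel, brand, scenario, tox, elements)
  list(brand = brand, scenario = scenario$name, risk = risk,
       hi = compute_hi(risk$hq))
}

#' Full risk assessment of a measurement panel
#'
#' The top-level entry point: for every brand in the panel and every
#' requested exposure scenario, replicates are averaged per element and
#' the intake, hazard-quotient, hazard-index and cancer-risk chains are
#' evaluated. Returns a classed object with `print`, `summary` and
#' `as.data.frame` methods.
#'
#' @param panel a [measurement_table()].
#' @param scenarios list of [exposure_scenario()] objects; default the
#'   adolescent and adult presets.
#' @param tox a [toxicity_reference()].
#' @param elements elements to assess; default the micro panel.
#' @return An object of class `risk_assessment`: list with `risk` (long
#'   data.frame, one row per brand x scenario x element), `hi` (data.frame
#'   brand x scenario), `scenarios`, `tox`.
#' @examples
#' fit <- assess_risk(reference_panel())
#' fit
#' @export
assess_risk <- function(panel,
                        scenarios = builtin_scenarios()[c("adolescent", "adult")],
                        tox = toxicity_reference(),
                        elements = micro_elements()) {
  stopifnot(inherits(panel, "measurement_table"))
  if (inherits(scenarios, "exposure_scenario")) scenarios <- list(scenarios)
  elements <- as_element(elements)
  brands <- unique(panel$brand)
  rows <- list()
  hi <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "exposure_scenario"))
    for (b in brands) {
      r <- .assess_one(panel, b, sc, tox, elements)
      rows[[length(rows) + 1L]] <- r
      hi[[length(hi) + 1L]] <- data.frame(
        brand = b, scenario = sc$name, hi = compute_hi(r$hq),
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(risk = do.call(rbind, rows), hi = do.call(rbind, hi),
         scenarios = scenarios, tox = tox),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  ns <- vapply(x$scenarios, `[[`, "", "name")
  cat("Elemental health-risk assessment\n")
  cat(sprintf("  %d brand(s) x %d element(s), scenarios: %s\n",
              length(unique(x$risk$brand)),
              length(unique(x$risk$element)),
              paste(ns, collapse = ", ")))
  cat(sprintf("  hazard index range: %s - %s\n",
              format(min(x$hi$hi), digits = 2),
              format(max(x$hi$hi), digits = 2)))
  carc <- x$risk[!is.na(x$risk$ilcr), , drop = FALSE]
  if (nrow(carc) > 0L) {
    worst <- carc[which.max(carc$ilcr), ]
    cat(sprintf("  max ILCR: %s (%s, %s, %s; band %s)\n",
                format(worst$ilcr, digits = 2), worst$element,
                worst$brand, worst$scenario, worst$band))
    tb <- table(factor(carc$band,
                       levels = c("acceptable", "moderate", "high")))
    cat(sprintf("  ILCR bands: %d acceptable, %d moderate, %d high\n",
                tb[["acceptable"]], tb[["moderate"]], tb[["high"]]))
  }
  invisible(x)
}

#' @export
summary.risk_assessment <- function(object, ...) {
  carc <- object$risk[!is.na(object$risk$ilcr), , drop = FALSE]
  out <- list(
    hi = object$hi,
    hq_exceedances = object$risk[object$risk$hq_flag, , drop = FALSE],
    ilcr_by_band = split(
      carc[, c("brand", "scenario", "element", "ilcr")],
      factor(carc$band, levels = c("acceptable", "moderate", "high")))
  )
  class(out) <- "summary.risk_assessment"
  out
}

#' @export
print.summary.risk_assessment <- function(x, ...) {
  cat("Hazard indices (HI = sum of HQ):\n")
  print.data.frame(x$hi, row.names = FALSE, digits = 2)
  if (nrow(x$hq_exceedances) == 0L) {
    cat("No hazard quotient exceeds 1.\n")
  } else {
    cat("Hazard quotients above 1:\n")
    print.data.frame(x$hq_exceedances, row.names = FALSE, digits = 2)
  }
  for (band in names(x$ilcr_by_band)) {
    rows <- x$ilcr_by_band[[band]]
    cat(sprintf("ILCR band '%s': %d brand-element pair(s)\n",
                band, nrow(rows)))
    if (band == "high" && nrow(rows) > 0L) {
      print.data.frame(rows, row.names = FALSE, digits = 2)
    }
  }
  invisible(x)
}

#' @export
as.data.frame.risk_assessment <- function(x, ...) {
  merge(x$risk, x$hi, by = c("brand", "scenario"), sort = FALSE)
}
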