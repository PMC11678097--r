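#' The 19-element analyte panel
#'
#' The closed set of elements quantified in the beverage panel: four
#' macro-minerals determined by ICP-OES and reported in mg/L, and fifteen
#' trace (micro) elements determined by ICP-MS and reported in ug/L.
#'
#' @return A data.frame with columns `symbol` and `class`
#'   (`"macro"` or `"micro"`), one row per element, in panel order.
#' @examples
#' element_panel()
#' @export
element_panel <- function() {
  data.frame(
    symbol = c(
      "Na", "K", "Mg", "Ca",
      "B", "Al", "V", "Cr", "Mn", "Fe", "Co", "Ni",
      "Cu", "Zn", "As", "Sr", "Cd", "Ba", "Pb"
    ),
    class = rep(c("macro", "micro"), c(4L, 15L)),
    stringsAsFactors = FALSE
  )
}

#' @rdname element_panel
#' @export
macro_elements <- function() {
  p <- element_panel()
  p$symbol[p$class == "macro"]
}

#' @rdname element_panel
#' @export
micro_elements <- function() {
  p <- element_panel()
  p$symbol[p$class == "micro"]
}

#' Validate element symbols against the closed panel
#'
#' @param x character vector of chemical symbols.
#' @return `x`, unchanged, if every symbol is one of the 19 panel members.
#' @export
as_element <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), element_panel()$symbol)
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

.canonical_unit <- function(unit) {
  # accept the micro sign, "u" spelling and the micro sign
  u <- gsub("\u00b5|\u03bc", "u", tolower(trimws(unit)))
  u[u %in% c("ug/l", "ug l-1", "ugl")] <- "ug/L"
  u[u %in% c("mg/l", "mg l-1", "mgl")] <- "mg/L"
  bad <- setdiff(unique(u), c("ug/L", "mg/L"))
  if (length(bad) > 0L) {
    stop("unknown concentration unit(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  u
}

#' Convert concentrations between ug/L and mg/L
#'
#' The conversion is the exact factor 1000 (1 mg/L = 1000 ug/L); a
#' round trip is the identity. Concentrations must be non-negative.
#'
#' @param value numeric vector of concentrations.
#' @param from,to units, `"ug/L"` or `"mg/L"` (the micro sign is accepted).
#' @return numeric vector in the target unit.
#' @examples
#' convert_conc(32.79, "ug/L", "mg/L")  # 0.03279
#' @export
convert_conc <- function(value, from, to) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  from <- .canonical_unit(from)
  to <- .canonical_unit(to)
  factor_of <- function(u) ifelse(u == "ug/L", 1, 1000)  # value in ug/L
  value * factor_of(from) / factor_of(to)
}

#' Exposure scenarios
#'
#' An exposure scenario collects the population parameters of the chronic
#' daily-intake model: `IR` the beverage intake rate (L/day), `EF` the
#' exposure frequency (days/year), `EXD` the exposure duration (years),
#' `BW` body weight (kg) and `AT` the averaging time (days). Unless given
#' explicitly, `AT` is derived as `EXD * 365`, the convention for
#' non-carcinogenic averaging; with that convention `EXD` cancels from the
#' intake formula.
#'
#' @param name scenario label.
#' @param IR intake rate, L/day.
#' @param EF exposure frequency, days/year.
#' @param EXD exposure duration, years.
#' @param BW body weight, kg.
#' @param AT averaging time in days; default `EXD * 365`.
#' @return An object of class `exposure_scenario`.
#' @examples
#' exposure_scenario("adolescent", IR = 0.23, EF = 240, EXD = 8, BW = 45)
#' @export
exposure_scenario <- function(name, IR, EF, EXD, BW, AT = NULL) {
  if (is.null(AT)) AT <- EXD * 365
  pars <- c(IR = IR, EF = EF, EXD = EXD, BW = BW, AT = AT)
  if (any(!is.finite(pars)) || any(pars <= 0)) {
    stop("all scenario parameters must be strictly positive", call. = FALSE)
  }
  structure(
    list(name = as.character(name), IR = IR, EF = EF, EXD = EXD,
         BW = BW, AT = AT),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(
    "Exposure scenario '%s': IR %g L/day, EF %g d/yr, EXD %g yr, BW %g kg, AT %g d\n",
    x$name, x$IR, x$EF, x$EXD, x$BW, x$AT))
  invisible(x)
}

#' Built-in exposure scenarios
#'
#' Three presets: `adolescent` (10-18 years: IR 0.23 L/day, BW 45 kg,
#' EXD 8 years), `adult` (18-65 years: IR 0.16 L/day, BW 70 kg, EXD 47
#' years), both with EF 240 days/year and AT = EXD x 365; and
#' `adult_effective`, identical to `adult` except IR = 0.15 L/day. The
#' stated adult intake rate of 0.16 L/day does not reproduce the published
#' adult intake tables, which are internally consistent with 0.15 L/day;
#' both presets are shipped rather than resolving the discrepancy, and
#' `adult_effective` is the one that reproduces the published adult cells.
#'
#' @return Named list of [exposure_scenario()] objects.
#' @examples
#' builtin_scenarios()$adolescent
#' @export
builtin_scenarios <- function() {
  list(
    adolescent = exposure_scenario("adolescent", IR = 0.23, EF = 240,
                                   EXD = 8, BW = 45),
    adult = exposure_scenario("adult", IR = 0.16, EF = 240,
                              EXD = 47, BW = 70),
    adult_effective = exposure_scenario("adult_effective", IR = 0.15,
                                        EF = 240, EXD = 47, BW = 70)
  )
}

#' Toxicity reference values
#'
#' Oral reference doses (RfD, mg/kg/day) for the fifteen trace elements and
#' oral cancer slope factors (CSF, (mg/kg/day)^-1) for the five carcinogens
#' Cr, Ni, As, Cd and Pb. Defaults are the values used throughout the
#' package; overrides replace individual entries and must be positive.
#'
#' @param rfd named numeric vector of RfD overrides (mg/kg/day).
#' @param csf named numeric vector of CSF overrides ((mg/kg/day)^-1).
#' @return An object of class `toxicity_reference` with elements `rfd`
#'   and `csf` (named numeric vectors).
#' @examples
#' tox <- toxicity_reference()
#' tox$rfd[["As"]]  # 0.0003
#' @export
toxicity_reference <- function(rfd = NULL, csf = NULL) {
  default_rfd <- c(
    B = 0.2, Al = 1, V = 0.009, Cr = 0.003, Mn = 0.14, Fe = 0.7,
    Co = 0.0003, Ni = 0.02, Cu = 0.04, Zn = 0.3, As = 0.0003,
    Sr = 0.6, Cd = 0.0005, Ba = 0.07, Pb = 0.0035
  )
  default_csf <- c(Cr = 0.5, Ni = 1.7, As = 1.5, Cd = 0.38, Pb = 0.0085)
  apply_override <- function(tab, ov, what) {
    if (is.null(ov)) return(tab)
    if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop(what, " overrides must be named by element", call. = FALSE)
    }
    as_element(names(ov))
    if (any(!is.finite(ov)) || any(ov <= 0)) {
      stop(what, " values must be strictly positive", call. = FALSE)
    }
    tab[names(ov)] <- ov
    tab
  }
  structure(
    list(rfd = apply_override(default_rfd, rfd, "RfD"),
         csf = apply_override(default_csf, csf, "CSF")),
    class = "toxicity_reference"
  )
}

#' Regulatory drinking-water limits
#'
#' Maximum permissible trace-element levels in drinking water (ug/L) per
#' limit body: WHO, EU, US EPA, and OEHHA (which carries a single proposed
#' notification level, vanadium at 15 ug/L). `NA` marks a limit the body
#' does not set; an unavailable limit can never produce an exceedance flag.
#'
#' @return A data.frame with columns `element`, `WHO`, `EU`, `USEPA`,
#'   `OEHHA`, one row per micro element.
#' @export
regulatory_limits <- function() {
  data.frame(
    element = c("B", "Al", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
                "As", "Sr", "Cd", "Ba", "Pb"),
    WHO   = c(2400, NA, NA, 50, NA, 300, NA, 70, 2000, NA, 10, NA, 3, 1300, 10),
    EU    = c(1500, 200, NA, 50, 50, 200, NA, 20, 2000, NA, 10, NA, 5, NA, 10),
    USEPA = c(1400, 200, NA, 100, 50, 300, 100, 100, 1300, 5000, 10, 1500,
              5, 2000, 15),
    OEHHA = c(NA, NA, 15, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Look up a regulatory ceiling
#'
#' @param body one of `"WHO"`, `"EU"`, `"USEPA"`, `"OEHHA"`.
#' @param element a micro-element symbol.
#' @param limits limit table, by default [regulatory_limits()].
#' @return The ceiling in ug/L, or `NA_real_` where the body sets no limit.
#' @examples
#' lookup_limit("EU", "Ni")    # 20
#' lookup_limit("WHO", "Al")   # NA: not available
#' @export
lookup_limit <- function(body, element, limits = regulatory_limits()) {
  body <- as.character(body)
  if (!body %in% setdiff(names(limits), "element")) {
    stop("unknown limit body: ", body, call. = FALSE)
  }
  element <- as_element(element)
  i <- match(element, limits$element)
  if (anyNA(i)) {
    stop("no regulatory limit row for element: ",
         paste(element[is.na(i)], collapse = ", "), call. = FALSE)
  }
  limits[[body]][i]
}
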