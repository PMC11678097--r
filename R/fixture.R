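# The bundled reference panel: a nine-brand (ED 1 ... ED 9) energy-drink
# survey measured by ICP-OES (macro, mg/L) and ICP-MS (micro, ug/L).
# Concentrations reported directly in the survey are carried verbatim
# ("printed" provenance); the remaining micro cells are back-calculated
# from the survey's adolescent daily-intake table, which is exactly
# consistent with the intake formula ("edi-inverted" provenance, 2-s.f.
# precision).

.fixture_brands <- function() sprintf("ED %d", 1:9)

# Adolescent estimated daily intakes (mg/kg/day), brand x micro element.
.fixture_edi_adolescent <- function() {
  el <- micro_elements()
  m <- matrix(c(
    # B      Al      V       Cr      Mn      Fe      Co      Ni      Cu      Zn      As      Sr      Cd      Ba      Pb
    1.6e-3, 1.5e-3, 3.4e-5, 1.2e-4, 4.0e-5, 5.8e-4, 4.4e-6, 1.8e-5, 5.6e-5, 2.2e-4, 5.3e-6, 1.3e-4, 2.6e-6, 4.8e-5, 2.7e-5,  # ED 1
    6.7e-4, 7.7e-4, 6.7e-6, 9.4e-5, 2.4e-5, 4.1e-4, 6.4e-7, 9.4e-6, 2.4e-5, 6.7e-5, 1.4e-5, 1.1e-5, 1.4e-6, 2.2e-5, 2.8e-5,  # ED 2
    6.4e-4, 1.0e-3, 1.7e-5, 2.1e-4, 2.4e-5, 5.1e-4, 1.4e-5, 2.2e-5, 3.6e-5, 3.5e-5, 1.4e-5, 1.3e-2, 9.1e-7, 6.7e-5, 1.1e-4,  # ED 3
    1.9e-3, 9.4e-4, 1.0e-5, 1.9e-4, 2.4e-5, 6.7e-4, 1.6e-6, 7.3e-6, 2.2e-5, 5.1e-5, 8.5e-6, 8.0e-5, 1.0e-6, 2.6e-5, 2.2e-5,  # ED 4
    1.6e-3, 7.7e-4, 1.7e-5, 1.2e-4, 2.2e-4, 7.2e-4, 3.5e-6, 1.0e-5, 1.8e-5, 9.7e-5, 1.1e-5, 7.7e-5, 1.1e-6, 5.1e-5, 3.2e-5,  # ED 5
    1.4e-3, 1.0e-3, 1.0e-5, 1.0e-4, 8.1e-5, 8.7e-4, 1.3e-6, 7.6e-6, 2.4e-5, 6.6e-5, 1.3e-5, 6.1e-5, 6.4e-7, 4.2e-5, 3.1e-5,  # ED 6
    2.7e-3, 1.0e-3, 1.0e-5, 4.7e-5, 4.0e-5, 1.0e-3, 4.7e-6, 8.5e-6, 1.3e-5, 3.8e-5, 7.7e-5, 1.0e-5, 6.4e-7, 1.6e-5, 2.5e-5,  # ED 7
    1.3e-3, 9.1e-4, 1.7e-6, 9.4e-5, 3.7e-4, 9.5e-4, 3.9e-6, 1.2e-5, 3.9e-5, 1.2e-4, 3.6e-5, 2.4e-4, 1.2e-6, 5.3e-5, 2.2e-5,  # ED 8
    1.2e-3, 9.7e-4, 1.0e-6, 2.3e-4, 2.4e-5, 4.6e-4, 2.5e-6, 6.9e-6, 9.9e-6, 3.9e-5, 4.2e-5, 5.1e-5, 8.7e-7, 2.4e-5, 1.7e-5   # ED 9
  ), nrow = 9L, byrow = TRUE,
  dimnames = list(.fixture_brands(), el))
  m
}

# Micro-element concentrations reported verbatim in the survey text (ug/L),
# with brand attribution.
.fixture_printed_micro <- function() {
  data.frame(
    brand = c("ED 3", "ED 7",        # B range
              "ED 2", "ED 1",        # Al range
              "ED 9", "ED 1",        # V range
              "ED 9",                # Cr maximum
              "ED 2", "ED 7",        # Fe range
              "ED 3",                # Ni maximum
              "ED 1", "ED 7",        # As range
              "ED 3",                # Sr maximum
              "ED 1", "ED 6", "ED 7",# Cd extremes
              "ED 7", "ED 3",        # Ba range
              "ED 3"),               # Pb maximum
    element = c("B", "B", "Al", "Al", "V", "V", "Cr", "Fe", "Fe", "Ni",
                "As", "As", "Sr", "Cd", "Cd", "Cd", "Ba", "Ba", "Pb"),
    value = c(194.01, 796.82, 227.54, 456.97, 0.29, 10.44, 67.53,
              121.86, 308.31, 6.57, 1.57, 23.05, 3878.21,
              0.78, 0.19, 0.19, 4.81, 19.98, 32.79),
    stringsAsFactors = FALSE
  )
}

# Macro-mineral concentrations reported verbatim (mg/L); no intake table
# exists for the macro elements, so only reported cells are bundled.
.fixture_printed_macro <- function() {
  data.frame(
    brand = c("ED 9", "ED 4", "ED 3", "ED 5", "ED 2", "ED 3",
              "ED 2", "ED 3", "ED 9"),
    element = c("Na", "Na", "K", "K", "Ca", "Ca", "Mg", "Mg", "Mg"),
    value_mgl = c(8.62, 619.85, 5.51, 189.57, 2.54, 116.1,
                  0.013, 196, 543.97),
    stringsAsFactors = FALSE
  )
}

#' Published adolescent daily intakes for the reference brands
#'
#' The adolescent estimated daily intakes (mg/kg/day, 2 significant
#' figures) for the nine reference brands and fifteen micro elements, as
#' published; these are the values the bundled panel is back-calculated
#' from.
#'
#' @return A long data.frame with columns `brand`, `element`, `edi`.
#' @export
reference_intakes <- function() {
  m <- .fixture_edi_adolescent()
  data.frame(
    brand = rep(rownames(m), times = ncol(m)),
    element = rep(colnames(m), each = nrow(m)),
    edi = as.vector(m),
    stringsAsFactors = FALSE
  )
}

#' The bundled nine-brand reference panel
#'
#' A [measurement_table()] of the nine reference energy-drink brands
#' (ED 1 ... ED 9): the full 9 x 15 micro-element panel as single mean
#' records (replicate = 1) plus the reported macro-mineral cells.
#' Concentrations reported directly carry provenance `"printed"` and are
#' verbatim; the remaining micro cells carry provenance `"edi-inverted"`
#' and are back-calculated from the published adolescent intakes via
#' [invert_edi()], hence precise to 2 significant figures.
#'
#' @return A [measurement_table()] with 135 micro records and 9 macro
#'   records.
#' @examples
#' ref <- reference_panel()
#' ref[ref$brand == "ED 3" & ref$element == "Pb", ]
#' @export
reference_panel <- function() {
  adolescent <- builtin_scenarios()$adolescent
  edi <- reference_intakes()
  micro <- data.frame(
    brand = edi$brand, element = edi$element,
    value = invert_edi(edi$edi, adolescent),
    provenance = "edi-inverted", stringsAsFactors = FALSE)
  printed <- .fixture_printed_micro()
  key <- function(d) paste(d$brand, d$element)
  i <- match(key(printed), key(micro))
  micro$value[i] <- printed$value
  micro$provenance[i] <- "printed"
  macro <- .fixture_printed_macro()
  measurement_table(
    brand = c(micro$brand, macro$brand),
    element = c(micro$element, macro$element),
    replicate = 1L,
    value = c(micro$value, convert_conc(macro$value_mgl, "mg/L", "ug/L")),
    provenance = c(micro$provenance, rep("printed", nrow(macro))))
}
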