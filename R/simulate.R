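# Run expr under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Default per-element lognormal parameters, taken from the bundled
# nine-brand reference panel so that simulated panels share its
# between-brand spread (1-3 orders of magnitude for some elements).
.reference_log_params <- function(elements) {
  ref <- reference_panel()
  vapply(elements, function(el) {
    v <- ref$value[ref$element == el]
    if (length(v) < 2L) return(c(log_mean = log(max(v, 1e-6)), log_sd = 0.5))
    c(log_mean = mean(log(v)), log_sd = stats::sd(log(v)))
  }, c(log_mean = 0, log_sd = 0))
}

#' Configuration for the synthetic panel generator
#'
#' Describes a brand x element x replicate measurement panel with
#' lognormal between-brand variation (heavy-tailed, as observed across
#' commercial brands), multiplicative replicate measurement noise with a
#' per-element coefficient of variation, and optional per-(brand, element)
#' contamination spikes that multiply the brand's true concentration.
#'
#' Defaults emulate the study design: 9 brands, the fifteen micro
#' elements, triplicate measurements, per-element lognormal parameters
#' matched to the bundled reference panel, and a 2% replicate CV typical
#' of ICP-MS precision.
#'
#' @param brands brand count (labelled `brand_01`, ...) or character
#'   labels.
#' @param elements element symbols to simulate.
#' @param replicates replicates per (brand, element); default 3.
#' @param log_mean,log_sd lognormal parameters of the brand-level true
#'   concentration (log ug/L); scalar or named per-element vectors;
#'   default fitted from the reference panel.
#' @param replicate_cv coefficient of variation of the multiplicative
#'   replicate noise; scalar or named per-element; default 0.02.
#' @param spikes optional data.frame with columns `brand`, `element`,
#'   `multiplier` (> 0).
#' @param seed integer seed; identical configs generate identical panels.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(brands = 9, elements = micro_elements(),
                         replicates = 3, log_mean = NULL, log_sd = NULL,
                         replicate_cv = 0.02, spikes = NULL, seed = 1L) {
  elements <- as_element(elements)
  if (length(brands) == 1L && is.numeric(brands)) {
    brands <- sprintf("brand_%02d", seq_len(brands))
  }
  brands <- as.character(brands)
  if (length(replicates) != 1L || replicates < 1L) {
    stop("replicates must be a single integer >= 1", call. = FALSE)
  }
  expand_par <- function(x, default, what, lower_ok) {
    if (is.null(x)) x <- default
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(elements)), elements)
    }
    if (!all(elements %in% names(x))) {
      stop(what, " must cover every simulated element", call. = FALSE)
    }
    x <- x[elements]
    if (any(!is.finite(x)) || any(x < lower_ok)) {
      stop("invalid ", what, call. = FALSE)
    }
    x
  }
  defaults <- NULL
  if (is.null(log_mean) || is.null(log_sd)) {
    defaults <- .reference_log_params(elements)
  }
  log_mean <- expand_par(log_mean, defaults["log_mean", ], "log_mean", -Inf)
  log_sd <- expand_par(log_sd, defaults["log_sd", ], "log_sd", 0)
  replicate_cv <- expand_par(replicate_cv, 0.02, "replicate_cv", 0)
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
    stopifnot(all(c("brand", "element", "multiplier") %in% names(spikes)))
    as_element(spikes$element)
    if (any(!is.finite(spikes$multiplier)) || any(spikes$multiplier <= 0)) {
      stop("spike multipliers must be strictly positive", call. = FALSE)
    }
  }
  structure(
    list(brands = brands, elements = elements,
         replicates = as.integer(replicates), log_mean = log_mean,
         log_sd = log_sd, replicate_cv = replicate_cv, spikes = spikes,
         seed = as.integer(seed)),
    class = "panel_config"
  )
}

#' Generate a synthetic measurement panel
#'
#' Brand-level true concentrations are drawn lognormal per element,
#' multiplied by any configured spike, and observed through multiplicative
#' replicate noise: value = true x (1 + eps), eps ~ Normal(0, cv)
#' truncated at -1 so concentrations stay strictly positive. Generation
#' is deterministic under the config seed and does not disturb the
#' caller's RNG stream.
#'
#' @param config a [panel_config()].
#' @return A [measurement_table()] with provenance `"synthetic"`.
#' @examples
#' cfg <- panel_config(brands = 3, elements = "As", seed = 42)
#' generate_panel(cfg)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  .with_seed(config$seed, {
    nb <- length(config$brands)
    rows <- lapply(config$elements, function(el) {
      true <- exp(stats::rnorm(nb, config$log_mean[[el]],
                               config$log_sd[[el]]))
      names(true) <- config$brands
      if (!is.null(config$spikes)) {
        sp <- config$spikes[config$spikes$element == el, , drop = FALSE]
        for (i in seq_len(nrow(sp))) {
          true[[sp$brand[i]]] <- true[[sp$brand[i]]] * sp$multiplier[i]
        }
      }
      cv <- config$replicate_cv[[el]]
      vals <- unlist(lapply(config$brands, function(b) {
        if (cv == 0) return(rep(true[[b]], config$replicates))
        eps <- stats::rnorm(config$replicates, 0, cv)
        while (any(eps <= -1)) {
          eps[eps <= -1] <- stats::rnorm(sum(eps <= -1), 0, cv)
        }
        true[[b]] * (1 + eps)
      }))
      data.frame(
        brand = rep(config$brands, each = config$replicates),
        element = el,
        replicate = rep(seq_len(config$replicates), nb),
        value = vals, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    measurement_table(tab$brand, tab$element, tab$replicate, tab$value,
                      provenance = "synthetic")
  })
}

#' Re-inflate the reference panel to triplicates
#'
#' Expands each single-record mean of the bundled reference panel to
#' three replicates under multiplicative noise (mean-preserving in
#' expectation), so the rank tests and the exceedance screen can be
#' exercised on fixture-shaped data.
#'
#' @param noise_cv coefficient of variation of the replicate noise;
#'   `0` returns exact triplicates of the means.
#' @param seed integer seed.
#' @param replicates replicates per record; default 3.
#' @return A [measurement_table()] with provenance `"synthetic"`.
#' @export
fixture_with_replicates <- function(noise_cv = 0.02, seed = 1L,
                                    replicates = 3L) {
  if (length(noise_cv) != 1L || !is.finite(noise_cv) || noise_cv < 0) {
    stop("noise_cv must be a single non-negative number", call. = FALSE)
  }
  ref <- reference_panel()
  .with_seed(seed, {
    vals <- unlist(lapply(ref$value, function(v) {
      if (noise_cv == 0) return(rep(v, replicates))
      eps <- stats::rnorm(replicates, 0, noise_cv)
      while (any(eps <= -1)) {
        eps[eps <= -1] <- stats::rnorm(sum(eps <= -1), 0, noise_cv)
      }
      v * (1 + eps)
    }))
    measurement_table(
      brand = rep(ref$brand, each = replicates),
      element = rep(ref$element, each = replicates),
      replicate = rep(seq_len(replicates), nrow(ref)),
      value = vals, provenance = "synthetic")
  })
}
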