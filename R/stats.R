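#' Kruskal-Wallis H test with tie correction
#'
#' Rank-based k-sample location test. Pooled observations are ranked with
#' midranks for ties, then
#'
#'   H  = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)
#'   H' = H / (1 - sum(t^3 - t) / (N^3 - N))
#'
#' where R_j is the rank sum of group j and t runs over tie-group sizes.
#' The p-value is the upper chi-square tail of H' at k - 1 degrees of
#' freedom. When all N observations are identical the tie-correction
#' denominator vanishes; H' is then defined as 0 with p = 1 and a warning.
#'
#' @param groups list of k >= 2 non-empty numeric samples, N = sum(n_j) >= 3.
#' @return An object of class `kw_test`: list with `statistic` (H'),
#'   `H` (uncorrected), `tie_correction`, `df` (k - 1), `p_raw`, `p_adj`
#'   (`NA` until a family adjustment is applied), `n`, `family_size`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))  # H = 2.4, df = 1
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  nj <- lengths(groups)
  if (any(nj == 0L)) stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("non-finite observations", call. = FALSE)
  N <- length(x)
  if (N < 3L) stop("need at least 3 observations in total", call. = FALSE)
  k <- length(groups)
  r <- rank(x, ties.method = "average")
  g <- rep(seq_len(k), nj)
  Rj <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie_sizes <- table(x)
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  if (C <= 0) {
    warning("all observations identical; H' defined as 0", call. = FALSE)
    Hp <- 0
    p <- 1
  } else {
    Hp <- H / C
    p <- stats::pchisq(Hp, df = k - 1, lower.tail = FALSE)
  }
  structure(
    list(test = "kruskal_wallis", statistic = Hp, H = H,
         tie_correction = C, df = k - 1L, p_raw = p, p_adj = NA_real_,
         n = N, family_size = NA_integer_),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H test: H' = %.4f, df = %d, N = %d, p = %.4g",
              x$statistic, x$df, x$n, x$p_raw))
  if (!is.na(x$p_adj)) cat(sprintf(", p.adj = %.4g (m = %d)",
                                   x$p_adj, x$family_size))
  cat("\n")
  invisible(x)
}

#' One-sample Student's t test against a norm value
#'
#' Tests whether the mean of a small replicate sample exceeds (or differs
#' from) a fixed normative value mu0: t = (xbar - mu0) / (s / sqrt(n)),
#' df = n - 1. A zero-variance sample is an untestable state, not a
#' number: the returned object carries `untestable = TRUE` and `NA`
#' statistic and p-value.
#'
#' @param values numeric sample, n >= 2.
#' @param mu0 the norm value tested against.
#' @param alternative `"greater"` (default; exceedance direction) or
#'   `"two_sided"`.
#' @return An object of class `t_test`: list with `statistic`, `df`,
#'   `p_raw`, `p_adj` (`NA` until adjusted), `n`, `estimate` (sample
#'   mean), `mu0`, `alternative`, `untestable`, `family_size`.
#' @examples
#' one_sample_t(c(1, 2, 3), 0, "two_sided")  # t = 3.4641, p = 0.0742
#' @export
one_sample_t <- function(values, mu0,
                         alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 observations", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite observations", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  base <- list(test = "one_sample_t", statistic = NA_real_, df = n - 1L,
               p_raw = NA_real_, p_adj = NA_real_, n = n, estimate = m,
               mu0 = mu0, alternative = alternative, untestable = FALSE,
               family_size = NA_integer_)
  if (s == 0) {
    base$untestable <- TRUE
    return(structure(base, class = "t_test"))
  }
  t <- (m - mu0) / (s / sqrt(n))
  p <- switch(alternative,
              greater = stats::pt(t, df = n - 1, lower.tail = FALSE),
              two_sided = 2 * stats::pt(abs(t), df = n - 1,
                                        lower.tail = FALSE))
  base$statistic <- t
  base$p_raw <- p
  structure(base, class = "t_test")
}

#' @export
print.t_test <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("One-sample t test vs mu0 = %g: untestable (zero variance, n = %d)\n",
                x$mu0, x$n))
    return(invisible(x))
  }
  cat(sprintf("One-sample t test (%s) vs mu0 = %g: t = %.4f, df = %d, p = %.4g",
              x$alternative, x$mu0, x$statistic, x$df, x$p_raw))
  if (!is.na(x$p_adj)) cat(sprintf(", p.adj = %.4g (m = %d)",
                                   x$p_adj, x$family_size))
  cat("\n")
  invisible(x)
}

#' Bonferroni family-wise adjustment
#'
#' p_adj = min(1, m * p), order-preserving. With m = 1 it is the identity;
#' it never decreases a p-value.
#'
#' @param p_raw numeric vector of raw p-values in [0, 1] (`NA` passed
#'   through, e.g. untestable rows).
#' @param m family size, >= max(1, length(p_raw)).
#' @return adjusted p-values, same length and order as `p_raw`.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 4)  # 0.04, 1
#' @export
bonferroni <- function(p_raw, m = length(p_raw)) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m)) {
    stop("family size m must be a positive integer", call. = FALSE)
  }
  ok <- !is.na(p_raw)
  if (any(p_raw[ok] < 0 | p_raw[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p_raw))
  out[ok] <- pmin(1, m * p_raw[ok])
  out
}

#' Between-brand comparison of element concentrations
#'
#' One tie-corrected Kruskal-Wallis test per element, comparing replicate
#' concentrations across brands, with Bonferroni adjustment over the
#' batch (family size = number of elements tested together). Per-element
#' failures (e.g. a single brand) are recorded in the `note` column
#' without aborting the batch.
#'
#' @param panel a [measurement_table()].
#' @param elements elements to test; default every element in the panel.
#' @return A data.frame of class `brand_comparison`: one row per element
#'   with `statistic` (H'), `df`, `n`, `p_raw`, `p_adj`, `family_size`,
#'   `note`.
#' @export
compare_brands <- function(panel, elements = NULL) {
  stopifnot(inherits(panel, "measurement_table"))
  if (is.null(elements)) {
    elements <- intersect(element_panel()$symbol, unique(panel$element))
  } else {
    elements <- as_element(elements)
  }
  rows <- lapply(elements, function(el) {
    sub <- panel[panel$element == el, , drop = FALSE]
    groups <- split(sub$value, sub$brand)
    res <- tryCatch({
      if (length(groups) < 2L) stop("fewer than two brands", call. = FALSE)
      withCallingHandlers(
        kruskal_wallis(groups),
        warning = function(w) invokeRestart("muffleWarning"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(element = el, statistic = NA_real_, df = NA_integer_,
                 n = nrow(sub), p_raw = NA_real_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      note <- if (res$tie_correction <= 0) "all observations identical" else ""
      data.frame(element = el, statistic = res$statistic, df = res$df,
                 n = res$n, p_raw = res$p_raw, note = note,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p_raw))
  out$p_adj <- bonferroni(out$p_raw, m = max(1L, m))
  out$family_size <- max(1L, m)
  out <- out[, c("element", "statistic", "df", "n", "p_raw", "p_adj",
                 "family_size", "note")]
  class(out) <- c("brand_comparison", "data.frame")
  out
}

#' @export
print.brand_comparison <- function(x, ...) {
  cat(sprintf(
    "Between-brand Kruskal-Wallis tests (%d element(s), Bonferroni m = %d)\n",
    nrow(x), x$family_size[1L]))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regulatory exceedance screen
#'
#' For every (brand, element, limit body) with an available ceiling, the
#' replicate concentrations are tested against the ceiling with a
#' one-sample t test (one-sided "greater" by default, matching the
#' exceedance question). Bonferroni adjustment uses the number of tests
#' actually performed in the batch. A row is `untestable` when the body
#' sets no limit or the replicates have zero variance (or n < 2);
#' `exceeds` requires both mean > limit and p_adj < alpha; otherwise
#' `within`.
#'
#' @param panel a [measurement_table()].
#' @param bodies limit bodies to screen against; default WHO, EU, US EPA.
#' @param alpha significance level, in (0, 1); default 0.05.
#' @param alternative passed to [one_sample_t()].
#' @param limits limit table, default [regulatory_limits()].
#' @return A data.frame of class `exceedance_report`: one row per
#'   brand x element x body with `mean`, `limit`, `statistic`, `df`,
#'   `p_raw`, `p_adj`, `family_size`, `flag`.
#' @export
screen_exceedance <- function(panel, bodies = c("WHO", "EU", "USEPA"),
                              alpha = 0.05,
                              alternative = c("greater", "two_sided"),
                              limits = regulatory_limits()) {
  stopifnot(inherits(panel, "measurement_table"))
  alternative <- match.arg(alternative)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  bad <- setdiff(bodies, setdiff(names(limits), "element"))
  if (length(bad) > 0L) {
    stop("unknown limit body: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  els <- intersect(limits$element, unique(panel$element))
  combos <- expand.grid(brand = unique(panel$brand), element = els,
                        body = bodies, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    b <- combos$brand[i]; el <- combos$element[i]; body <- combos$body[i]
    lim <- lookup_limit(body, el, limits)
    vals <- panel$value[panel$brand == b & panel$element == el]
    row <- data.frame(brand = b, element = el, body = body,
                      n = length(vals), mean = mean(vals), limit = lim,
                      statistic = NA_real_, df = NA_integer_,
                      p_raw = NA_real_, flag = "untestable",
                      stringsAsFactors = FALSE)
    if (is.na(lim) || length(vals) < 2L) return(row)
    tt <- one_sample_t(vals, lim, alternative)
    if (tt$untestable) return(row)
    row$statistic <- tt$statistic
    row$df <- tt$df
    row$p_raw <- tt$p_raw
    row$flag <- "pending"
    row
  })
  out <- do.call(rbind, rows)
  m <- sum(out$flag == "pending")
  out$p_adj <- bonferroni(out$p_raw, m = max(1L, m))
  out$family_size <- max(1L, m)
  testable <- out$flag == "pending"
  out$flag[testable] <- ifelse(
    out$mean[testable] > out$limit[testable] & out$p_adj[testable] < alpha,
    "exceeds", "within")
  attr(out, "alpha") <- alpha
  attr(out, "alternative") <- alternative
  class(out) <- c("exceedance_report", "data.frame")
  out
}

#' @export
print.exceedance_report <- function(x, ...) {
  n_ex <- sum(x$flag == "exceeds")
  n_un <- sum(x$flag == "untestable")
  cat(sprintf(
    "Regulatory exceedance screen: %d comparison(s), %d testable (Bonferroni m = %d), alpha = %g\n",
    nrow(x), x$family_size[1L], x$family_size[1L], attr(x, "alpha")))
  cat(sprintf("  %d exceed, %d untestable\n", n_ex, n_un))
  if (n_ex > 0L) {
    print.data.frame(
      as.data.frame(x)[x$flag == "exceeds",
                       c("brand", "element", "body", "mean", "limit",
                         "statistic", "p_adj")],
      row.names = FALSE, digits = 4)
  }
  invisible(x)
}
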