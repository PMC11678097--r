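# Independent oracles used across the suite.

# Tie-corrected Kruskal-Wallis statistic via the ANOVA-on-ranks identity
# H' = (N - 1) * SS_between(ranks) / SS_total(ranks), an algebraically
# different route from the rank-sum formula in the package.
oracle_kw_stat <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x, ties.method = "average")
  sst <- sum((r - mean(r))^2)
  if (sst == 0) return(0)
  rbar <- tapply(r, g, mean)
  ssb <- sum(lengths(groups) * (rbar - mean(r))^2)
  (length(x) - 1) * ssb / sst
}

# Enumerate every assignment of the pooled values to groups of the given
# sizes and evaluate stat_fn on each (feasible for N <= 8).
enumerate_assignments <- function(values, sizes, stat_fn) {
  out <- numeric(0)
  recurse <- function(remaining, sizes_left, chosen) {
    if (length(sizes_left) == 1L) {
      out[[length(out) + 1L]] <<- stat_fn(c(chosen, list(values[remaining])))
      return(invisible(NULL))
    }
    for (idx in utils::combn(remaining, sizes_left[1L], simplify = FALSE)) {
      recurse(setdiff(remaining, idx), sizes_left[-1L],
              c(chosen, list(values[idx])))
    }
  }
  recurse(seq_along(values), sizes, list())
  out
}

# Student-t CDF for df = 2 in closed form: F(t) = 1/2 + t / (2 sqrt(t^2 + 2)).
t_cdf_df2 <- function(t) 0.5 + t / (2 * sqrt(t^2 + 2))

# Round to 2 significant figures, the precision of the published tables.
sig2 <- function(x) signif(x, 2)
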