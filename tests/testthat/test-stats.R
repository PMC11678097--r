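test_that("Kruskal-Wallis matches hand computation and base R", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$statistic, 2.4)   # R1 = 3, R2 = 7: 12/20 * (9/2 + 49/2) - 15
  expect_equal(kw$df, 1L)
  expect_equal(kw$n, 4L)
  # agreement with the independently maintained implementation
  set.seed(81)
  for (i in 1:20) {
    groups <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE),
                     function(n) round(rnorm(n), sample(0:1, 1)))
    if (length(unique(unlist(groups))) < 2) next
    ours <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_along(groups), lengths(groups)))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_raw, ref$p.value)
  }
})

test_that("tie correction is inert on tie-free data and handles degeneracy", {
  set.seed(19)
  g <- split(rnorm(12), rep(1:3, each = 4))
  kw <- kruskal_wallis(g)
  expect_identical(kw$statistic, kw$H)
  expect_equal(kw$tie_correction, 1)
  # all observations identical: H' defined as 0, p = 1, with a warning
  expect_warning(kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2))),
                 "identical")
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_raw, 1)
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "empty group")
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  # balanced groups with equal rank sums give H = 0
  expect_equal(kruskal_wallis(list(c(1, 4), c(2, 3)))$statistic, 0)
})

test_that("H' is rank-based: bounded, monotone-invariant", {
  set.seed(37)
  for (i in 1:50) {
    sizes <- sample(2:5, sample(2:4, 1), replace = TRUE)
    x <- sample(1:4, sum(sizes), replace = TRUE)  # heavy ties
    groups <- split(x, rep(seq_along(sizes), sizes))
    if (length(unique(x)) < 2) next
    kw <- kruskal_wallis(groups)
    expect_gte(kw$statistic, 0)
    expect_lte(kw$statistic, sum(sizes) - 1 + 1e-12)
    # invariant under strictly monotone transformation of the pooled data
    kw2 <- kruskal_wallis(lapply(groups, function(v) exp(v / 2)))
    expect_equal(kw2$statistic, kw$statistic)
  }
})

test_that("H' equals the permutation-enumeration oracle on small instances", {
  set.seed(7)
  configs <- list(c(2, 2), c(3, 2), c(4, 3), c(4, 4), c(2, 2, 2),
                  c(3, 3, 2))
  for (sizes in configs) {
    values <- sample(1:3, sum(sizes), replace = TRUE)  # force ties
    if (length(unique(values)) < 2) values[1] <- values[1] + 1
    ours <- enumerate_assignments(
      values, sizes, function(g) kruskal_wallis(g)$statistic)
    oracle <- enumerate_assignments(values, sizes, oracle_kw_stat)
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
})

test_that("chi-square p is reported alongside the exact permutation law", {
  # tiny instance: exact tail mass of H' from full enumeration
  groups <- list(c(1.2, 3.4), c(2.2, 5.1, 0.7))
  kw <- kruskal_wallis(groups)
  perm <- enumerate_assignments(unlist(groups), lengths(groups),
                                oracle_kw_stat)
  p_exact <- mean(perm >= kw$statistic - 1e-12)
  expect_gte(p_exact, 0)
  expect_lte(p_exact, 1)
  # the observed statistic is a member of its own permutation law
  expect_true(any(abs(perm - kw$statistic) < 1e-12))
  # the chi-square approximation is reported, not asserted, at this n
  expect_true(is.finite(kw$p_raw))
})

test_that("one-sample t matches the df = 2 closed form and base R", {
  tt <- one_sample_t(c(1, 2, 3), 2, "two_sided")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_raw, 1)
  tt2 <- one_sample_t(c(1, 2, 3), 0, "two_sided")
  expect_equal(round(tt2$statistic, 4), 3.4641)
  expect_equal(tt2$df, 2L)
  expect_equal(round(tt2$p_raw, 4), 0.0742)
  set.seed(23)
  for (i in 1:200) {
    x <- rnorm(3, sd = runif(1, 0.1, 10))
    mu0 <- rnorm(1)
    two <- one_sample_t(x, mu0, "two_sided")
    gre <- one_sample_t(x, mu0, "greater")
    expect_equal(two$p_raw, 2 * (1 - t_cdf_df2(abs(two$statistic))),
                 tolerance = 1e-6)
    expect_equal(gre$p_raw, 1 - t_cdf_df2(gre$statistic),
                 tolerance = 1e-6)
    ref <- stats::t.test(x, mu = mu0)
    expect_equal(two$statistic, unname(ref$statistic))
    expect_equal(two$p_raw, ref$p.value)
  }
  # zero variance is an untestable state, not a number
  z <- one_sample_t(c(5, 5, 5), 3)
  expect_true(z$untestable)
  expect_true(is.na(z$statistic) && is.na(z$p_raw))
  expect_error(one_sample_t(1, 0), "n >= 2")
})

test_that("Bonferroni adjustment caps, preserves order, never decreases", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(0.00692 / 9, m = 9), 0.00692)
  p <- c(0.04, 0.001, 0.9, NA, 0)
  adj <- bonferroni(p, m = 5)
  expect_equal(which(is.na(adj)), 4L)
  expect_true(all(adj >= p, na.rm = TRUE))
  expect_identical(bonferroni(p[1:3], m = 1), p[1:3])  # identity at m = 1
  expect_equal(adj[!is.na(adj)],
               p.adjust(p[!is.na(p)], "bonferroni", n = 5))
  expect_error(bonferroni(1.2, m = 2), "\\[0, 1\\]")
  expect_error(bonferroni(0.5, m = 0), "positive integer")
})

test_that("between-brand comparison detects a shifted brand and logs failures", {
  cfg <- panel_config(brands = 9, elements = c("Mg", "Ca"),
                      log_mean = log(50), log_sd = 0.2,
                      replicate_cv = 0.02,
                      spikes = data.frame(brand = "brand_03",
                                          element = "Mg",
                                          multiplier = 25),
                      seed = 104)
  panel <- generate_panel(cfg)
  cb <- compare_brands(panel)
  expect_equal(cb$family_size[1], 2L)
  expect_lt(cb$p_adj[cb$element == "Mg"], 0.05)
  expect_equal(cb$n, c(27L, 27L))
  # constant equal values across two brands: degenerate H = 0 path
  flat <- measurement_table(rep(c("A", "B"), each = 3), "Zn",
                            rep(1:3, 2), rep(7, 6))
  cbf <- compare_brands(flat)
  expect_equal(cbf$statistic, 0)
  expect_equal(cbf$p_adj, 1)
  expect_match(cbf$note, "identical")
  # single-brand element is reported, not fatal
  one <- measurement_table(rep("A", 3), "Cu", 1:3, c(1, 2, 3))
  both <- measurement_table(
    c(rep("A", 3), rep(c("A", "B"), each = 3)),
    c(rep("Cu", 3), rep("Zn", 6)),
    c(1:3, rep(1:3, 2)), c(1, 2, 3, 4, 5, 6, 1, 2, 3))
  cbb <- compare_brands(both)
  expect_true(is.na(cbb$p_adj[cbb$element == "Cu"]))
  expect_match(cbb$note[cbb$element == "Cu"], "fewer than two brands")
  expect_false(is.na(cbb$p_adj[cbb$element == "Zn"]))
})

test_that("exceedance screen flags true exceedances and honours N/A limits", {
  rep3 <- fixture_with_replicates(noise_cv = 0.02, seed = 5)
  # screening the arsenic ceiling alone keeps the Bonferroni family small
  scr_as <- screen_exceedance(
    rep3, bodies = "WHO",
    limits = regulatory_limits()[regulatory_limits()$element == "As", ])
  as_ed7 <- scr_as[scr_as$brand == "ED 7", ]
  expect_equal(as_ed7$flag, "exceeds")  # 23.05 ug/L against the WHO 10
  expect_lt(as_ed7$p_adj, 0.05)
  scr <- screen_exceedance(rep3)
  # a body with no ceiling is untestable, never flagged
  al_who <- scr[scr$element == "Al" & scr$body == "WHO", ]
  expect_true(all(al_who$flag == "untestable"))
  expect_true(all(is.na(al_who$p_adj)))
  # exceeds implies mean above limit and significance
  ex <- scr[scr$flag == "exceeds", ]
  expect_true(all(ex$mean > ex$limit))
  expect_true(all(ex$p_adj < 0.05))
  expect_error(screen_exceedance(rep3, alpha = 1.5), "alpha")
  expect_error(screen_exceedance(rep3, bodies = "FDA"), "unknown limit body")
  # concentrations far below every ceiling: no exceedance
  low <- generate_panel(panel_config(brands = 4, elements = c("As", "Pb"),
                                     log_mean = log(0.5), log_sd = 0.2,
                                     replicate_cv = 0.05, seed = 9))
  expect_equal(sum(screen_exceedance(low)$flag == "exceeds"), 0L)
})
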