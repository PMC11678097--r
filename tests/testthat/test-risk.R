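adolescent <- builtin_scenarios()$adolescent
adult <- builtin_scenarios()$adult
tox <- toxicity_reference()

test_that("intake formula reproduces the published worked cells", {
  # Pb, ED 3, adolescents: 32.79 ug/L
  edi_pb <- compute_edi(32.79, adolescent)
  expect_equal(sig2(edi_pb), 1.1e-4)
  expect_equal(sig2(compute_hq(edi_pb, "Pb", tox)), 3.1e-2)
  # As, ED 7, adolescents: 23.05 ug/L
  edi_as <- compute_edi(23.05, adolescent)
  expect_equal(sig2(edi_as), 7.7e-5)
  expect_equal(sig2(compute_hq(edi_as, "As", tox)), 2.6e-1)
  # zero concentration gives zero everywhere
  expect_equal(compute_edi(0, adolescent), 0)
  expect_equal(compute_hq(0, "Pb", tox), 0)
})

test_that("EDI is linear, scenario-proportional and EXD-invariant", {
  set.seed(11)
  conc <- runif(20, 0, 500)
  k <- runif(20, 0, 10)
  expect_equal(compute_edi(k * conc, adolescent),
               k * compute_edi(conc, adolescent))
  # adolescent / adult (stated IR) ratio is constant across concentrations
  ratio <- compute_edi(conc, adolescent) / compute_edi(conc, adult)
  expect_equal(ratio, rep((0.23 / 45) / (0.16 / 70), 20))
  # changing EXD with AT auto-derived never changes intake
  for (exd in c(1, 8, 47, 70)) {
    s <- exposure_scenario("v", IR = 0.23, EF = 240, EXD = exd, BW = 45)
    expect_equal(compute_edi(conc, s), compute_edi(conc, adolescent))
  }
})

test_that("hazard quotient and index obey their definitions", {
  # HQ = 1 exactly when EDI equals the reference dose
  for (el in micro_elements()) {
    expect_identical(compute_hq(tox$rfd[[el]], el, tox), 1)
  }
  expect_error(compute_hq(1e-5, "Na", tox), "no oral reference dose")
  expect_equal(compute_hi(numeric(3)), 0)
  set.seed(3)
  h <- runif(15)
  expect_identical(compute_hi(h), compute_hi(rev(h)))
  expect_error(compute_hi(c(0.1, -0.2)), "non-negative")
  expect_error(compute_hi(numeric(0)), "no hazard quotients")
})

test_that("cancer risk is EDI x CSF with explicit no-slope-factor errors", {
  edi_pb <- compute_edi(32.79, adolescent)
  expect_equal(sig2(compute_ilcr(edi_pb, "Pb", tox)), 9.4e-7)
  expect_equal(compute_ilcr(0, "As", tox), 0)
  edi_as <- compute_edi(23.05, adolescent)
  expect_equal(sig2(compute_ilcr(edi_as, "As", tox)), 1.2e-4)
  expect_error(compute_ilcr(1e-5, "Cu", tox), "no cancer slope factor")
  # linear in EDI
  set.seed(5)
  e <- runif(10, 0, 1e-3)
  expect_equal(compute_ilcr(3 * e, "Cr", tox),
               3 * compute_ilcr(e, "Cr", tox))
})

test_that("risk bands follow the published thresholds with moderate boundaries", {
  expect_equal(classify_ilcr(9.4e-7), "acceptable")
  expect_equal(classify_ilcr(1e-6), "moderate")
  expect_equal(classify_ilcr(1e-4), "moderate")
  expect_equal(classify_ilcr(1.2e-4), "high")
  expect_error(classify_ilcr(-1e-6), "non-negative")
  # monotone non-decreasing in its argument
  x <- sort(c(0, 10^runif(50, -8, -3), 1e-6, 1e-4))
  lev <- match(classify_ilcr(x), c("acceptable", "moderate", "high"))
  expect_true(all(diff(lev) >= 0))
})

test_that("invert_edi is the exact inverse of compute_edi", {
  expect_equal(invert_edi(0, adolescent), 0)
  expect_equal(round(invert_edi(1.1e-4, adolescent), 2), 32.73)
  set.seed(42)
  for (sc in list(adolescent, adult)) {
    e <- 10^runif(1000, -8, -2)
    expect_equal(compute_edi(invert_edi(e, sc), sc), e,
                 tolerance = 1e-12)
  }
  expect_error(invert_edi(-1, adolescent), "non-negative")
})

test_that("brand assessment averages replicates and degrades gracefully", {
  panel <- measurement_table(
    brand = rep("A", 6), element = rep(c("As", "Pb"), each = 3),
    replicate = rep(1:3, 2), value = c(20, 23, 26, 30, 33, 36))
  expect_warning(
    res <- assess_brand(panel, "A", adolescent, tox),
    "excluded from the hazard index")
  expect_equal(sort(res$risk$element), c("As", "Pb"))
  expect_equal(res$risk$conc_ugl[res$risk$element == "As"], 23)
  expect_equal(res$hi, sum(res$risk$hq))
  # all-zero panel: zero HI, every band acceptable
  zero <- measurement_table(rep("Z", 15), micro_elements(), 1,
                            rep(0, 15))
  rz <- assess_brand(zero, "Z", adolescent, tox)
  expect_equal(rz$hi, 0)
  expect_true(all(rz$risk$band[!is.na(rz$risk$band)] == "acceptable"))
})

test_that("assess_risk returns a coherent classed object", {
  fit <- assess_risk(reference_panel())
  expect_s3_class(fit, "risk_assessment")
  # HI additivity: the HI table equals per-group HQ sums exactly
  for (i in seq_len(nrow(fit$hi))) {
    sub <- fit$risk[fit$risk$brand == fit$hi$brand[i] &
                    fit$risk$scenario == fit$hi$scenario[i], ]
    expect_identical(fit$hi$hi[i], sum(sub$hq))
  }
  expect_equal(nrow(fit$risk), 9 * 15 * 2)
  expect_true(all(fit$risk$element[!is.na(fit$risk$ilcr)] %in%
                  c("Cr", "Ni", "As", "Cd", "Pb")))
  expect_output(print(fit), "health-risk assessment")
  expect_output(print(summary(fit)), "Hazard indices")
  df <- as.data.frame(fit)
  expect_true(all(c("edi", "hq", "ilcr", "band", "hi") %in% names(df)))
})
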