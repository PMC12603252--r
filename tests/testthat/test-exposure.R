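profiles <- default_profiles()
analytes <- default_analytes()

test_that("chronic daily intake follows the intake equation and is linear in concentration", {
  # direct-arithmetic oracle: (ED * C * EF * IR) / (BW * AT)
  expect_equal(compute_intake(1.3465, profiles$children, at = 6 * 365),
               (6 * 1.3465 * 365 * 0.13) / (18.6 * 2190))
  expect_equal(compute_intake(1.3465, profiles$adult_male, at = 30 * 365),
               (30 * 1.3465 * 365 * 0.26) / (66.2 * 10950))
  expect_identical(compute_intake(0, profiles$children, at = 2190), 0)
  # homogeneity of degree 1
  cs <- c(0.01, 0.5, 3, 120)
  base <- compute_intake(cs, profiles$adult_female, at = 10950)
  expect_equal(compute_intake(7 * cs, profiles$adult_female, at = 10950),
               7 * base)
  expect_error(compute_intake(-1, profiles$children, at = 10), "c_mg_kg")
  expect_error(compute_intake(1, profiles$children, at = 0), "'at'")
})

test_that("hazard quotients reproduce the published children and adult values", {
  expect_equal(compute_hq(1.3465, "children", "Cd"), 9.411, tolerance = 1e-4)
  expect_identical(compute_hq(0, "children", "Cd"), 0)
  # demographic rescaling at the same concentration
  expect_equal(round(compute_hq(1.3465, "adult_female", "Cd"), 2), 6.11)
  expect_equal(round(compute_hq(1.3465, "adult_male", "Cd"), 3), 5.288)
  expect_error(compute_hq(1, "children", analytes$Zn), NA)
  no_rfd <- analyte("X", slope_factor = 1)
  expect_error(compute_hq(1, "children", no_rfd), "no reference dose")
})

test_that("adult-to-children HQ ratios are concentration- and analyte-invariant", {
  # closed form: (IR_a / BW_a) / (IR_c / BW_c) under AT = ED x 365
  r_male <- (0.26 / 66.2) / (0.13 / 18.6)
  r_female <- (0.26 / 57.3) / (0.13 / 18.6)
  expect_equal(round(r_male, 4), 0.5619)
  for (an in c("Cd", "Pb", "Zn", "Ni", "NO3")) for (conc in c(0.2, 1.35, 44)) {
    hq_c <- compute_hq(conc, "children", an)
    expect_equal(compute_hq(conc, "adult_male", an) / hq_c, r_male)
    expect_equal(compute_hq(conc, "adult_female", an) / hq_c, r_female)
  }
})

test_that("hazard index is the order-invariant sum of hazard quotients", {
  hqs <- c(9.411, 2.95, 1.04, 4.72, 5.65)
  expect_equal(round(compute_hi(hqs), 2), 23.77)
  expect_equal(round(compute_hi(c(13.05, 13.63, 1.11, 4.55, 6.47)), 2), 38.81)
  expect_identical(compute_hi(3.2), 3.2)
  set.seed(1)
  expect_identical(compute_hi(hqs), compute_hi(sample(hqs)))
  expect_error(compute_hi(numeric(0)), "empty")
  expect_error(compute_hi(c(1, -0.1)), "non-negative")
})

test_that("carcinogenic risk applies slope factor, carcinogenic AT and the unit factor", {
  expect_equal(signif(compute_cr(7.786, "children", "Ni"), 3), 7.93e-6)
  # direct-arithmetic oracle
  expect_equal(compute_cr(7.786, "children", "Ni"),
               (6 * 7.786 * 365 * 0.13) / (18.6 * 25550) * 1.7 * 1e-3)
  expect_identical(compute_cr(0, "children", "Ni"), 0)
  expect_equal(compute_cr(2 * 7.786, "children", "Ni"),
               2 * compute_cr(7.786, "children", "Ni"))
  # the unit factor can be disabled
  expect_equal(compute_cr(7.786, "children", "Ni", unit_factor = 1),
               1e3 * compute_cr(7.786, "children", "Ni"))
  expect_error(compute_cr(1, "children", "Zn"), "not carcinogenic")
  expect_error(compute_cr(1, "children", "NO3"), "not carcinogenic")
})

test_that("total carcinogenic risk sums the published per-metal risks", {
  expect_equal(signif(compute_tcr(c(8.88e-7, 2.36e-8, 7.93e-6)), 3), 8.84e-6)
  expect_equal(signif(compute_tcr(c(3.12e-6, 2.01e-8, 7.6e-6)), 4), 1.074e-5)
  expect_error(compute_tcr(numeric(0)), "empty")
})

test_that("risk bands are ordered, left-closed and monotone", {
  expect_equal(as.character(classify_hq(c(0.05, 0.1, 0.99, 1, 4, 23.77))),
               c("insignificant", "low", "low", "moderate", "very high",
                 "very high"))
  expect_equal(as.character(classify_cr(c(0, 7.93e-6, 5e-5, 5e-4, 2e-3))),
               c("not significant", "low", "medium", "high",
                 "relatively high"))
  # monotone non-decreasing in the argument
  x <- sort(stats::runif(50, 0, 10))
  expect_true(!is.unsorted(classify_hq(x)))
  y <- sort(stats::runif(50, 0, 2e-3))
  expect_true(!is.unsorted(classify_cr(y)))
})

test_that("concentration back-derivation inverts the HQ and CR equations", {
  expect_equal(back_derive_concentration(9.411, "children", "Cd"),
               9.411 * 0.001 * 18.6 / 0.13)  # = hq * rfd * bw / ir
  expect_identical(back_derive_concentration(0, "children", "Cd"), 0)
  set.seed(7)
  for (k in 1:20) {
    hq <- stats::runif(1, 0, 50)
    prof <- sample(names(profiles), 1)
    an <- sample(c("Cd", "Pb", "Zn", "Ni", "NO3"), 1)
    conv <- sample(c("ed_years", "table"), 1)
    c_back <- back_derive_concentration(hq, prof, an, conv)
    expect_equal(compute_hq(c_back, prof, an, conv), hq,
                 tolerance = 1e-12)
  }
  for (an in c("Cd", "Pb", "Ni")) {
    cr <- stats::runif(1, 0, 1e-4)
    c_back <- back_derive_concentration_cr(cr, "adult_female", an)
    expect_equal(compute_cr(c_back, "adult_female", an), cr,
                 tolerance = 1e-12)
  }
})

test_that("the deterministic report aggregates HQ into HI and CR into TCR per group and vegetable", {
  fx <- suppressWarnings(pipeline_fixture(seed = 11))
  rep <- risk_report(fx$concentrations)
  expect_equal(nrow(rep$summary), 6)  # 3 groups x 2 vegetables
  for (i in seq_len(nrow(rep$summary))) {
    sub <- rep$records[rep$records$group == rep$summary$group[i] &
                       rep$records$vegetable == rep$summary$vegetable[i], ]
    expect_equal(rep$summary$hi[i], sum(sub$hq, na.rm = TRUE))
    expect_equal(rep$summary$tcr[i], sum(sub$cr, na.rm = TRUE))
    expect_equal(as.character(rep$summary$hi_band[i]),
                 as.character(classify_hq(rep$summary$hi[i])))
  }
  # CR defined exactly for the carcinogens
  expect_setequal(unique(rep$records$analyte[!is.na(rep$records$cr)]),
                  c("Cd", "Pb", "Ni"))
  expect_setequal(unique(rep$records$analyte[is.na(rep$records$cr)]),
                  c("Zn", "NO3"))
  # flat CSV round trip keeps records and summary rows
  path <- withr::local_tempfile(fileext = ".csv")
  write_risk_report(rep, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), nrow(rep$records) + nrow(rep$summary))
  expect_equal(sum(tab$analyte == "ALL"), 6)
})

test_that("profile and analyte validation is loud", {
  expect_error(exposure_profile("g", ir = 0.13, ef = 367, ed = 6, bw = 18.6),
               "ef")
  expect_error(exposure_profile("g", ir = -1, ef = 365, ed = 6, bw = 18.6),
               "ir")
  expect_error(exposure_profile("g", ir = 0.1, ef = 365, ed = 6, bw = 18.6,
                                at_noncarc = 10950, at_carc = 100),
               "at_carc")
  expect_error(analyte("X", rfd = -0.1), "rfd")
  expect_true(analyte("Ni", rfd = 0.02, slope_factor = 1.7)$is_carcinogen)
  expect_false(analyte("Zn", rfd = 0.3)$is_carcinogen)
})
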