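unit_space <- function(p) {
  factor_space(lapply(seq_len(p), function(i)
    sobol_factor(paste0("x", i), "normal", mean = 0, sd = 1)))
}

test_that("the Saltelli design has the prescribed size and is seed-reproducible", {
  sp <- unit_space(3)
  d1 <- generate_design(sp, 4, seed = 1)
  expect_equal(d1$n_evaluations, 4 * (3 + 2))  # n_base x (p + 2)
  d2 <- generate_design(sp, 4, seed = 1, second_order = TRUE)
  expect_equal(d2$n_evaluations, 4 * (2 * 3 + 2))  # n_base x (2p + 2)
  expect_identical(generate_design(sp, 4, seed = 1)$X, d1$X)
  expect_false(identical(generate_design(sp, 4, seed = 2)$X, d1$X))
  # column-swap structure: AB_i differs from A only in column i
  for (i in 1:3) {
    diffcols <- which(colSums(d1$AB[[i]] != d1$A) > 0)
    expect_identical(diffcols, setNames(i, paste0("x", i)))
  }
})

test_that("an additive model recovers its closed-form variance shares", {
  # Y = X1 + 2 X2 with unit-variance inputs: S1 = (1, 4)/5, ST = S1, S2 = 0
  sp <- unit_space(2)
  d <- generate_design(sp, 8192, seed = 4, second_order = TRUE)
  res <- estimate_indices(function(X) X[, "x1"] + 2 * X[, "x2"], d)
  expect_equal(res$indices$s1, c(0.2, 0.8), tolerance = 0.05)
  expect_equal(res$indices$st, c(0.2, 0.8), tolerance = 0.05)
  expect_lt(abs(res$s2[1, 2]), 0.05)
  expect_equal(sum(res$indices$s1), 1, tolerance = 0.05)
})

test_that("total-order indices dominate first-order ones up to estimator noise", {
  sp <- unit_space(3)
  model <- function(X) X[, "x1"] * X[, "x2"] + X[, "x3"]
  d <- generate_design(sp, 1024, seed = 6, sampling = "halton")
  res <- estimate_indices(model, d)
  expect_true(all(res$indices$st >= res$indices$s1 - 0.02))
})

test_that("Saltelli estimates agree with the brute-force double-loop estimator", {
  sp <- ishigami_space()
  d <- generate_design(sp, 2048, seed = 2, sampling = "halton")
  fast <- estimate_indices(function(X) ishigami(X), d)
  slow <- sobol_double_loop(function(X) ishigami(X), sp, seed = 3)
  expect_lt(max(abs(fast$indices$s1 - slow$s1)), 0.05)
  expect_lt(max(abs(fast$indices$st - slow$st)), 0.05)
})

test_that("index estimates are equivariant under factor relabelling", {
  # estimates for a factor must not depend on its position in the space
  # (up to re-sampling noise, since reordering reassigns the draws)
  sp <- factor_space(
    sobol_factor("a", "normal", mean = 0, sd = 1),
    sobol_factor("b", "normal", mean = 0, sd = 2))
  sp_swapped <- factor_space(
    sobol_factor("b", "normal", mean = 0, sd = 2),
    sobol_factor("a", "normal", mean = 0, sd = 1))
  model <- function(X) X[, "a"] + X[, "b"]^2
  r1 <- estimate_indices(model, generate_design(sp, 16384, seed = 9,
                                                sampling = "halton"))
  r2 <- estimate_indices(model, generate_design(sp_swapped, 16384, seed = 9,
                                                sampling = "halton"))
  for (nm in c("a", "b")) {
    i1 <- match(nm, r1$indices$factor)
    i2 <- match(nm, r2$indices$factor)
    expect_lt(abs(r1$indices$s1[i1] - r2$indices$s1[i2]), 0.05)
    expect_lt(abs(r1$indices$st[i1] - r2$indices$st[i2]), 0.05)
  }
})

test_that("constant model output is refused and negative noise is not clipped", {
  sp <- unit_space(2)
  d <- generate_design(sp, 64, seed = 1)
  expect_error(estimate_indices(function(X) rep(3, nrow(X)), d),
               "constant model output")
  # a null factor's small-sample index estimate may be negative; the label
  # clips at zero
  sp3 <- unit_space(3)
  d3 <- generate_design(sp3, 128, seed = 12)
  res <- estimate_indices(function(X) X[, "x1"], d3)
  expect_true(any(res$indices$s1 < 0) || all(res$indices$s1 >= 0))
  expect_equal(as.character(classify_sensitivity(-0.005)), "insensitive")
})

test_that("sensitivity labels follow the published cut-points", {
  labels <- classify_sensitivity(c(0.913, 0.11, 0.05, 0.01, 0.009, 0.001))
  expect_equal(as.character(labels),
               c("highly sensitive", "highly sensitive", "sensitive",
                 "sensitive", "insensitive", "insensitive"))
})

test_that("the risk adapter reproduces the deterministic equations at the factor means", {
  prof <- default_profiles()$children
  ans <- default_analytes()
  means <- c(Cd = 1.3465, Pb = 1.5068, Ni = 7.786)
  ev <- risk_model_adapter(prof, ans[c("Cd", "Pb", "Ni")], means,
                           endpoint = "tcr")
  at_means <- ev(matrix(means, nrow = 1,
                        dimnames = list(NULL, names(means))))
  expect_equal(at_means,
               unname(compute_tcr(vapply(names(means), function(a)
                 compute_cr(means[[a]], prof, ans[[a]]), numeric(1)))))
  # single random factor: it owns all the variance
  sp <- factor_space(
    sobol_factor("Cd", "lognormal", mean = 1.3465, sd = 0.8),
    sobol_factor("EF", "fixed", value = 365))
  res <- sobol_risk(sp, prof, ans["Cd"], c(Cd = 1.3465), endpoint = "hq",
                    n_base = 4096, seed = 5, second_order = FALSE,
                    sampling = "halton")
  expect_equal(res$indices$s1[res$indices$factor == "Cd"], 1,
               tolerance = 0.05)
  expect_error(risk_model_adapter(prof, ans["Zn"], c(Zn = 10),
                                  endpoint = "cr"),
               "not computable")
})

test_that("interactions through the BW quotient raise total above first order for IR", {
  # CR ~ C * IR / BW: with C, IR and BW all lognormal the model is
  # non-additive, so ST(IR) > S1(IR); verified against the double-loop oracle
  prof <- default_profiles()$children
  ans <- default_analytes()
  sp <- factor_space(
    sobol_factor("Ni", "lognormal", mean = 7.786, sd = 5.9),
    sobol_factor("IR", "lognormal", mean = 0.13, sd = 0.065),
    sobol_factor("BW", "lognormal", mean = 18.6, sd = 9.3))
  model <- risk_model_adapter(prof, ans["Ni"], c(Ni = 7.786),
                              endpoint = "cr")
  res <- estimate_indices(model,
                          generate_design(sp, 8192, seed = 10,
                                          sampling = "halton"))
  ir <- match("IR", res$indices$factor)
  expect_gt(res$indices$st[ir], res$indices$s1[ir])
  slow <- sobol_double_loop(model, sp, seed = 11)
  expect_lt(max(abs(res$indices$s1 - slow$s1)), 0.05)
  expect_lt(max(abs(res$indices$st - slow$st)), 0.05)
})

test_that("the default risk factor space attributes CR variance where the model puts it", {
  prof <- default_profiles()$children
  ans <- default_analytes()
  means <- c(Cd = 1.3465, Pb = 1.5068, Zn = 10.3, Ni = 7.786, NO3 = 529)
  cvs <- c(Cd = 0.62, Pb = 0.9, Zn = 0.33, Ni = 0.76, NO3 = 0.67)
  sp <- risk_factor_space(prof, means, cvs)
  res <- sobol_risk(sp, prof, ans, means, endpoint = "tcr",
                    n_base = 2048, seed = 13, second_order = FALSE,
                    sampling = "halton")
  idx <- res$indices
  get <- function(f, col) idx[[col]][idx$factor == f]
  # Ni carries most of the mean CR and the widest spread: it must dominate
  expect_equal(idx$factor[which.max(idx$st)], "Ni")
  # non-carcinogens cannot move the CR endpoint; fixed factors are inert
  for (f in c("Zn", "NO3", "EF", "ED")) expect_lt(get(f, "st"), 0.01)
  # IR and BW enter every term, so they stay measurably sensitive
  expect_gt(get("IR", "st"), 0.01)
  expect_gt(get("BW", "st"), 0.005)
  expect_true(all(idx$st >= idx$s1 - 0.02))
})
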