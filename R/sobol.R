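#' Declare a random (or fixed) input factor for sensitivity analysis
#'
#' A factor couples a name with a samplable marginal distribution, expressed
#' through its quantile function so that the same declaration serves plain
#' Monte Carlo and Latin hypercube sampling.
#'
#' @param name Factor name (must be unique within a [factor_space()]).
#' @param dist One of `"lognormal"` (moment-matched from `mean`/`sd`),
#'   `"uniform"` (`min`/`max`), `"normal"` (`mean`/`sd`) or `"fixed"`
#'   (`value`).
#' @param mean,sd Arithmetic mean and SD for `"lognormal"`/`"normal"`.
#' @param min,max Bounds for `"uniform"`.
#' @param value Constant for `"fixed"`.
#' @return An object of class `sobol_factor` with a `quantile` function
#'   mapping (0,1) to the factor's scale.
#' @examples
#' sobol_factor("IR", "lognormal", mean = 0.13, sd = 0.026)
#' @export
sobol_factor <- function(name,
                         dist = c("lognormal", "uniform", "normal", "fixed"),
                         mean = NULL, sd = NULL, min = NULL, max = NULL,
                         value = NULL) {
  dist <- match.arg(dist)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  q <- switch(dist,
    lognormal = {
      spec <- fit_lognormal(mean, sd)
      function(u) stats::qlnorm(u, spec$mu, spec$sigma)
    },
    uniform = {
      if (is.null(min) || is.null(max) || !(min < max))
        stop("uniform factor needs min < max", call. = FALSE)
      function(u) stats::qunif(u, min, max)
    },
    normal = {
      if (is.null(mean) || is.null(sd) || sd <= 0)
        stop("normal factor needs mean and sd > 0", call. = FALSE)
      function(u) stats::qnorm(u, mean, sd)
    },
    fixed = {
      if (is.null(value)) stop("fixed factor needs a value", call. = FALSE)
      function(u) rep(value, length(u))
    })
  structure(list(name = name, dist = dist, quantile = q),
            class = "sobol_factor")
}

#' Assemble an ordered space of independent input factors
#'
#' @param ... [sobol_factor()] objects (at least two non-fixed factors are
#'   required for a meaningful variance decomposition; the constructor only
#'   enforces p >= 2 and unique names).
#' @return An object of class `factor_space` (list of factors, `p` = count).
#' @export
factor_space <- function(...) {
  factors <- list(...)
  if (length(factors) == 1L && is.list(factors[[1]]) &&
      !inherits(factors[[1]], "sobol_factor"))
    factors <- factors[[1]]
  if (!all(vapply(factors, inherits, logical(1), "sobol_factor")))
    stop("all arguments must be sobol_factor objects", call. = FALSE)
  nms <- vapply(factors, `[[`, character(1), "name")
  if (length(factors) < 2L)
    stop("a factor space needs at least two factors", call. = FALSE)
  if (anyDuplicated(nms))
    stop("factor names must be unique", call. = FALSE)
  names(factors) <- nms
  structure(list(factors = factors, p = length(factors)),
            class = "factor_space")
}

#' Saltelli cross-sampling design for Sobol index estimation
#'
#' Draws two independent base samples A and B of size `n_base` over the
#' factor space and builds the column-swap matrices AB_i (column i of A
#' replaced by column i of B), plus BA_i when second-order indices are
#' requested. Model evaluations total `n_base * (p + 2)` (first order) or
#' `n_base * (2p + 2)` (with second order).
#'
#' @param space A [factor_space()].
#' @param n_base Base sample size (>= 2).
#' @param seed Integer seed.
#' @param second_order Also build the BA_i matrices for second-order
#'   index estimation.
#' @param sampling `"random"` (plain pseudo-random Monte Carlo, default),
#'   `"halton"` (randomly shifted Halton low-discrepancy sequence, the
#'   accurate choice for index estimation at moderate `n_base`) or `"lhs"`
#'   (Latin hypercube via the \pkg{lhs} package, if installed).
#' @return An object of class `sobol_design` with matrices `A`, `B`, lists
#'   `AB` (and `BA`), and the stacked evaluation matrix `X` with
#'   `n_evaluations` rows.
#' @examples
#' sp <- factor_space(sobol_factor("x1", "uniform", min = 0, max = 1),
#'                    sobol_factor("x2", "uniform", min = 0, max = 1))
#' generate_design(sp, n_base = 8, seed = 1)$n_evaluations  # 32
#' @export
generate_design <- function(space, n_base, seed, second_order = FALSE,
                            sampling = c("random", "halton", "lhs")) {
  stopifnot(inherits(space, "factor_space"))
  sampling <- match.arg(sampling)
  if (!is.numeric(n_base) || length(n_base) != 1L || n_base < 2)
    stop("'n_base' must be at least 2", call. = FALSE)
  n_base <- as.integer(n_base)
  p <- space$p
  set.seed(as.integer(seed))
  to_scale <- function(u) {
    x <- vapply(seq_len(p),
                function(j) space$factors[[j]]$quantile(u[, j]),
                numeric(n_base))
    x <- matrix(x, nrow = n_base, ncol = p)
    colnames(x) <- names(space$factors)
    x
  }
  if (sampling == "halton") {
    # Saltelli's prescription: one 2p-dimensional low-discrepancy stream,
    # first p columns -> A, last p -> B; randomized by a seed-dependent
    # Cranley-Patterson rotation so the seed stays meaningful.
    U <- halton_matrix(n_base, 2L * p)
    U <- (U + matrix(stats::runif(2L * p), n_base, 2L * p,
                     byrow = TRUE)) %% 1
    uA <- U[, seq_len(p), drop = FALSE]
    uB <- U[, p + seq_len(p), drop = FALSE]
  } else if (sampling == "lhs") {
    if (!requireNamespace("lhs", quietly = TRUE))
      stop("sampling = 'lhs' requires the 'lhs' package", call. = FALSE)
    uA <- lhs::randomLHS(n_base, p)
    uB <- lhs::randomLHS(n_base, p)
  } else {
    uA <- matrix(stats::runif(n_base * p), nrow = n_base, ncol = p)
    uB <- matrix(stats::runif(n_base * p), nrow = n_base, ncol = p)
  }
  A <- to_scale(uA)
  B <- to_scale(uB)
  AB <- lapply(seq_len(p), function(i) { M <- A; M[, i] <- B[, i]; M })
  BA <- if (second_order)
    lapply(seq_len(p), function(i) { M <- B; M[, i] <- A[, i]; M })
  else NULL
  X <- do.call(rbind, c(list(A, B), AB, BA))
  structure(
    list(A = A, B = B, AB = AB, BA = BA, X = X, n_base = n_base, p = p,
         second_order = second_order, factor_names = names(space$factors),
         n_evaluations = nrow(X), seed = as.integer(seed)),
    class = "sobol_design"
  )
}

# Van der Corput radical-inverse sequences in the first `d` prime bases
# (skipping index 0); adequate low-discrepancy coverage for d <= ~12.
halton_matrix <- function(n, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113)
  if (d > length(primes))
    stop("halton sampling supports at most ", length(primes), " dimensions",
         call. = FALSE)
  vapply(primes[seq_len(d)], function(base) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      f <- 1; r <- 0; k <- i
      while (k > 0) {
        f <- f / base
        r <- r + f * (k %% base)
        k <- k %/% base
      }
      out[i] <- r
    }
    out
  }, numeric(n))
}

#' Estimate Sobol sensitivity indices from a Saltelli design
#'
#' First-order indices use the Saltelli (2010) estimator
#' `S1_i = mean(f(B) * (f(AB_i) - f(A))) / V`; total-order indices use the
#' Jansen estimator `ST_i = mean((f(A) - f(AB_i))^2) / (2 V)`; second-order
#' indices (when the design carries BA matrices) use the Saltelli (2002)
#' closed identity
#' `S2_ij = (mean(f(BA_i) * f(AB_j)) - mean(f(A) * f(B))) / V - S1_i - S1_j`.
#' The total variance V is the sample variance of the pooled A and B
#' evaluations. Small-sample estimates may be slightly negative and are
#' reported as-is; [classify_sensitivity()] clips at zero for labelling.
#'
#' @param model A function taking a numeric matrix with named factor columns
#'   and returning one scalar output per row.
#' @param design A [generate_design()] object.
#' @return An object of class `sobol_result`: list with data.frame `indices`
#'   (`factor`, `s1`, `st`, `label`), matrix `s2` (or `NULL`), `n_base`,
#'   `variance`.
#' @examples
#' sp <- factor_space(sobol_factor("x1", "normal", mean = 0, sd = 1),
#'                    sobol_factor("x2", "normal", mean = 0, sd = 2))
#' d <- generate_design(sp, 1024, seed = 1)
#' estimate_indices(function(X) X[, "x1"] + X[, "x2"], d)
#' @export
estimate_indices <- function(model, design) {
  stopifnot(inherits(design, "sobol_design"))
  p <- design$p
  n <- design$n_base
  fA <- as.numeric(model(design$A))
  fB <- as.numeric(model(design$B))
  if (length(fA) != n || length(fB) != n)
    stop("'model' must return one value per design row", call. = FALSE)
  fAB <- lapply(design$AB, function(M) as.numeric(model(M)))
  fBA <- if (design$second_order)
    lapply(design$BA, function(M) as.numeric(model(M))) else NULL
  V <- stats::var(c(fA, fB))
  if (!is.finite(V) || V <= .Machine$double.eps * max(abs(c(fA, fB)), 1)^2)
    stop("constant model output: total variance is zero", call. = FALSE)
  s1 <- vapply(seq_len(p),
               function(i) mean(fB * (fAB[[i]] - fA)) / V, numeric(1))
  st <- vapply(seq_len(p),
               function(i) mean((fA - fAB[[i]])^2) / (2 * V), numeric(1))
  s2 <- NULL
  if (design$second_order) {
    s2 <- matrix(NA_real_, p, p,
                 dimnames = list(design$factor_names, design$factor_names))
    mAB <- mean(fA * fB)
    for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
      sij <- (mean(fBA[[i]] * fAB[[j]]) - mAB) / V - s1[i] - s1[j]
      s2[i, j] <- s2[j, i] <- sij
    }
  }
  indices <- data.frame(factor = design$factor_names, s1 = s1, st = st,
                        label = classify_sensitivity(s1))
  structure(list(indices = indices, s2 = s2, n_base = n, variance = V),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> n_base ", x$n_base,
      ", output variance ", format(x$variance, digits = 4), "\n", sep = "")
  d <- x$indices
  d$s1 <- round(d$s1, 4)
  d$st <- round(d$st, 4)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Classify a sensitivity index
#'
#' Labels: greater than 0.1 `highly sensitive`; 0.01 to 0.1 `sensitive`;
#' below 0.01 `insensitive`. Negative estimator noise is clipped to zero
#' before labelling.
#'
#' @param index Numeric vector of sensitivity indices.
#' @return Ordered factor `insensitive < sensitive < highly sensitive`.
#' @examples
#' classify_sensitivity(c(0.913, 0.05, 0.001))
#' @export
classify_sensitivity <- function(index) {
  if (!is.numeric(index) || any(!is.finite(index)))
    stop("'index' must be finite numeric", call. = FALSE)
  x <- pmax(index, 0)
  cut(x, breaks = c(-Inf, 0.01, 0.1, Inf), right = FALSE,
      labels = c("insensitive", "sensitive", "highly sensitive"),
      ordered_result = TRUE)
}

#' Bind the risk equations as a sensitivity-analysis model
#'
#' Returns an evaluator mapping a factor-space sample matrix to a scalar
#' risk. Recognised columns: `IR`, `BW`, `EF`, `ED` (exposure-factor
#' overrides) and analyte names (concentration overrides, mg·kg⁻¹); factors
#' absent from the matrix are held at the profile values / `conc_means`.
#'
#' @param profile An [exposure_profile] (or default-profile name).
#' @param analytes Named list of [analyte]s entering the endpoint.
#' @param conc_means Named numeric vector of baseline mean concentrations,
#'   mg·kg⁻¹, one per analyte in `analytes`.
#' @param endpoint `"hq"`, `"cr"` (single analyte), `"hi"` or `"tcr"`
#'   (sums over `analytes`; CR endpoints skip non-carcinogens, HQ endpoints
#'   skip analytes without an RfD).
#' @param at_convention See [compute_hq()].
#' @param unit_factor See [compute_cr()].
#' @return A function `f(X)` suitable for [estimate_indices()].
#' @examples
#' ev <- risk_model_adapter("children", default_analytes()["Ni"],
#'                          c(Ni = 7.786), endpoint = "cr")
#' ev(cbind(Ni = c(7.786, 15.572)))
#' @export
risk_model_adapter <- function(profile, analytes, conc_means,
                               endpoint = c("hq", "cr", "hi", "tcr"),
                               at_convention = c("ed_years", "table"),
                               unit_factor = 1e-3) {
  profile <- as_profile(profile)
  endpoint <- match.arg(endpoint)
  at_convention <- match.arg(at_convention)
  if (endpoint %in% c("hq", "cr") && length(analytes) != 1L)
    stop("endpoint '", endpoint, "' needs exactly one analyte", call. = FALSE)
  analytes <- lapply(analytes, as_analyte)
  nms <- vapply(analytes, `[[`, character(1), "name")
  names(analytes) <- nms
  if (!all(nms %in% names(conc_means)))
    stop("'conc_means' must name every analyte", call. = FALSE)
  carc <- endpoint %in% c("cr", "tcr")
  used <- Filter(function(a)
    if (carc) a$is_carcinogen else !is.null(a$rfd), analytes)
  if (!length(used))
    stop("endpoint '", endpoint,
         "' is not computable for this analyte set", call. = FALSE)

  function(X) {
    X <- as.matrix(X)
    col <- function(nm, default)
      if (nm %in% colnames(X)) X[, nm] else rep(default, nrow(X))
    ir <- col("IR", profile$ir)
    bw <- col("BW", profile$bw)
    ef <- col("EF", profile$ef)
    ed <- col("ED", profile$ed)
    at <- if (carc) profile$at_carc
          else if (at_convention == "ed_years") ed * 365
          else profile$at_noncarc
    out <- 0
    for (a in used) {
      conc <- col(a$name, conc_means[[a$name]])
      intake <- (ed * conc * ef * ir) / (bw * at)
      out <- out + if (carc) intake * a$slope_factor * unit_factor
                   else intake / a$rfd
    }
    as.numeric(out)
  }
}

#' Sobol sensitivity analysis of a dietary risk endpoint
#'
#' One-call wrapper: builds the Saltelli design over the given factor space,
#' binds the risk equations via [risk_model_adapter()] and estimates the
#' indices.
#'
#' @inheritParams risk_model_adapter
#' @param space A [factor_space()] whose factor names follow the adapter's
#'   conventions (`IR`, `BW`, `EF`, `ED`, analyte names).
#' @param n_base Base sample size.
#' @param seed Integer seed.
#' @param second_order Estimate second-order indices too.
#' @param sampling See [generate_design()].
#' @return A `sobol_result`.
#' @export
sobol_risk <- function(space, profile, analytes, conc_means,
                       endpoint = c("hq", "cr", "hi", "tcr"),
                       n_base = 4096, seed, second_order = TRUE,
                       at_convention = c("ed_years", "table"),
                       unit_factor = 1e-3,
                       sampling = c("random", "halton", "lhs")) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  design <- generate_design(space, n_base, seed, second_order, sampling)
  model <- risk_model_adapter(profile, analytes, conc_means, endpoint,
                              at_convention, unit_factor)
  estimate_indices(model, design)
}

#' Default factor space for the risk sensitivity analysis
#'
#' Concentrations are lognormal at the supplied means with the supplied
#' coefficients of variation; intake rate and body weight are lognormal with
#' CV 0.2 around the profile values; exposure frequency and duration are
#' fixed. These exposure-factor distributions are modelling assumptions
#' (coefficients of variation typical of dietary-survey data), overridable
#' by building the space by hand.
#'
#' @param profile An [exposure_profile] (or default-profile name).
#' @param conc_means Named numeric vector of mean concentrations, mg·kg⁻¹.
#' @param conc_cvs Named numeric vector of concentration coefficients of
#'   variation (same names); single values are recycled.
#' @param exposure_cv CV for the IR and BW lognormals (default 0.2).
#' @param vary_ef_ed Keep EF and ED as (fixed) factors in the space.
#' @return A [factor_space()].
#' @export
risk_factor_space <- function(profile, conc_means, conc_cvs = 0.5,
                              exposure_cv = 0.2, vary_ef_ed = TRUE) {
  profile <- as_profile(profile)
  if (length(conc_cvs) == 1L)
    conc_cvs <- stats::setNames(rep(conc_cvs, length(conc_means)),
                                names(conc_means))
  factors <- lapply(names(conc_means), function(nm)
    sobol_factor(nm, "lognormal", mean = conc_means[[nm]],
                 sd = conc_means[[nm]] * conc_cvs[[nm]]))
  factors <- c(factors, list(
    sobol_factor("IR", "lognormal", mean = profile$ir,
                 sd = profile$ir * exposure_cv),
    sobol_factor("BW", "lognormal", mean = profile$bw,
                 sd = profile$bw * exposure_cv)))
  if (vary_ef_ed)
    factors <- c(factors, list(
      sobol_factor("EF", "fixed", value = profile$ef),
      sobol_factor("ED", "fixed", value = profile$ed)))
  factor_space(factors)
}
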