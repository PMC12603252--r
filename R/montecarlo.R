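#' Monte Carlo simulation of the hazard quotient
#'
#' Propagates a lognormal concentration distribution through the
#' hazard-quotient equation: each iteration draws a concentration (and, in
#' the extended mode, an intake rate and body weight) and evaluates
#' [compute_hq()]. By default only the concentration is random.
#'
#' @param conc_spec [fit_lognormal()] specification of the concentration,
#'   mg·kg⁻¹.
#' @param profile An [exposure_profile] (or default-profile name).
#' @param analyte An [analyte] (or registry name) with an RfD.
#' @param n_iter Number of iterations (default 50,000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param at_convention Averaging-time convention, see [compute_hq()].
#' @param ir_spec,bw_spec Optional [fit_lognormal()] specifications for the
#'   intake rate (kg·day⁻¹) and body weight (kg); when supplied these
#'   exposure factors are drawn per iteration instead of held at the
#'   profile values.
#'
#' @return An object of class `simulation_result`: list with `samples`,
#'   `mean`, `p95`, `n_iter`, `seed`.
#' @examples
#' sim <- simulate_hq(fit_lognormal(1.3465, 0.83), "children", "Cd",
#'                    n_iter = 1000, seed = 1)
#' summarize_simulation(sim)
#' @export
simulate_hq <- function(conc_spec, profile, analyte, n_iter = 50000, seed,
                        at_convention = c("ed_years", "table"),
                        ir_spec = NULL, bw_spec = NULL) {
  profile <- as_profile(profile)
  analyte <- as_analyte(analyte)
  at_convention <- match.arg(at_convention)
  if (is.null(analyte$rfd))
    stop("no reference dose for analyte '", analyte$name, "'", call. = FALSE)
  simulate_risk(conc_spec, profile, n_iter, seed, ir_spec, bw_spec,
                at = noncarc_at(profile, at_convention),
                scale = 1 / analyte$rfd)
}

#' Monte Carlo simulation of the carcinogenic risk
#'
#' As [simulate_hq()] but propagating through [compute_cr()] (carcinogenic
#' averaging time, slope factor and the 10⁻³ unit factor).
#'
#' @inheritParams simulate_hq
#' @param analyte An [analyte] with a slope factor.
#' @param unit_factor See [compute_cr()].
#' @return A `simulation_result`.
#' @export
simulate_cr <- function(conc_spec, profile, analyte, n_iter = 50000, seed,
                        unit_factor = 1e-3, ir_spec = NULL, bw_spec = NULL) {
  profile <- as_profile(profile)
  analyte <- as_analyte(analyte)
  if (!analyte$is_carcinogen)
    stop("analyte '", analyte$name,
         "' is not carcinogenic (no slope factor)", call. = FALSE)
  simulate_risk(conc_spec, profile, n_iter, seed, ir_spec, bw_spec,
                at = profile$at_carc,
                scale = analyte$slope_factor * unit_factor)
}

# Shared sampler: risk = ED*C*EF*IR/(BW*AT) * scale, with C (and optionally
# IR, BW) random.
simulate_risk <- function(conc_spec, profile, n_iter, seed,
                          ir_spec, bw_spec, at, scale) {
  if (!inherits(conc_spec, "lognormal_spec"))
    stop("'conc_spec' must be a lognormal_spec (see fit_lognormal)",
         call. = FALSE)
  if (!is.numeric(n_iter) || length(n_iter) != 1L || n_iter < 1)
    stop("'n_iter' must be a positive integer", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible simulation", call. = FALSE)
  n_iter <- as.integer(n_iter)
  set.seed(as.integer(seed))
  conc <- rlnorm_spec(n_iter, conc_spec)
  ir <- if (is.null(ir_spec)) profile$ir else rlnorm_spec(n_iter, ir_spec)
  bw <- if (is.null(bw_spec)) profile$bw else rlnorm_spec(n_iter, bw_spec)
  samples <- (profile$ed * conc * profile$ef * ir) / (bw * at) * scale
  structure(
    list(samples = samples, mean = mean(samples),
         p95 = unname(stats::quantile(samples, 0.95, type = 7)),
         n_iter = n_iter, seed = as.integer(seed)),
    class = "simulation_result"
  )
}

#' Summarise a Monte Carlo simulation
#'
#' @param result A `simulation_result`.
#' @return Named vector `c(mean, p95)`; the 95th percentile is the empirical
#'   quantile with linear interpolation between order statistics
#'   ([stats::quantile()] type 7).
#' @export
summarize_simulation <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  c(mean = result$mean, p95 = result$p95)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d iterations (seed %d): mean %.4g, p95 %.4g\n",
    x$n_iter, x$seed, x$mean, x$p95))
  invisible(x)
}

#' Monte Carlo risk summary for every group, vegetable and analyte
#'
#' Convenience wrapper running [simulate_hq()] (all analytes with an RfD) and
#' [simulate_cr()] (carcinogens) for each exposure profile, from per
#' vegetable × analyte concentration means and SDs.
#'
#' @param conc A concentration table accepted by [read_concentration_table()].
#' @param profiles,analytes Registries as in [risk_report()].
#' @param n_iter Iterations per simulation.
#' @param seed Integer seed; sub-seeds are derived per simulation so results
#'   do not depend on execution order.
#' @param at_convention See [compute_hq()].
#' @return A data.frame with columns `group`, `vegetable`, `analyte`,
#'   `endpoint` (`"hq"`/`"cr"`), `mean`, `p95`, `n_iter`.
#' @export
mc_risk_summary <- function(conc, profiles = default_profiles(),
                            analytes = default_analytes(),
                            n_iter = 50000, seed,
                            at_convention = c("ed_years", "table")) {
  at_convention <- match.arg(at_convention)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  conc <- read_concentration_table(conc)
  conc <- conc[conc$analyte %in% names(analytes), , drop = FALSE]
  stats_tab <- stats::aggregate(
    concentration_mg_per_kg ~ vegetable + analyte, data = conc,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  stats_tab <- cbind(stats_tab[c("vegetable", "analyte")],
                     as.data.frame(stats_tab$concentration_mg_per_kg))
  rows <- list()
  k <- 0L
  for (g in names(profiles)) for (i in seq_len(nrow(stats_tab))) {
    an <- analytes[[stats_tab$analyte[i]]]
    if (!is.finite(stats_tab$sd[i]) || stats_tab$sd[i] <= 0) next
    spec <- fit_lognormal(stats_tab$mean[i], stats_tab$sd[i])
    k <- k + 1L
    sub_seed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
    if (!is.null(an$rfd)) {
      sim <- simulate_hq(spec, profiles[[g]], an, n_iter, sub_seed,
                         at_convention)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, vegetable = stats_tab$vegetable[i], analyte = an$name,
        endpoint = "hq", mean = sim$mean, p95 = sim$p95, n_iter = n_iter)
    }
    if (an$is_carcinogen) {
      sim <- simulate_cr(spec, profiles[[g]], an, n_iter, sub_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, vegetable = stats_tab$vegetable[i], analyte = an$name,
        endpoint = "cr", mean = sim$mean, p95 = sim$p95, n_iter = n_iter)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
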