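#' Chronic daily intake from vegetable consumption
#'
#' Computes the ingestion-route chronic daily intake
#' \deqn{Intake = \frac{ED \times C \times EF \times IR}{BW \times AT}}
#' in mg·kg⁻¹·day⁻¹. Intake is linear in the concentration, so vectors of
#' concentrations are accepted and mapped elementwise.
#'
#' @param c_mg_kg Concentration(s) in the vegetable, mg·kg⁻¹ (dry weight);
#'   non-negative.
#' @param profile An [exposure_profile] (or the name of a default profile).
#' @param at Averaging time in days; strictly positive.
#'
#' @return Intake(s), mg·kg⁻¹·day⁻¹.
#' @examples
#' compute_intake(1.3465, default_profiles()$children, at = 6 * 365)
#' @export
compute_intake <- function(c_mg_kg, profile, at) {
  profile <- as_profile(profile)
  if (!is.numeric(c_mg_kg) || any(!is.finite(c_mg_kg)) || any(c_mg_kg < 0))
    stop("'c_mg_kg' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(at) || length(at) != 1L || !is.finite(at) || at <= 0)
    stop("'at' must be a single positive number of days", call. = FALSE)
  (profile$ed * c_mg_kg * profile$ef * profile$ir) / (profile$bw * at)
}

#' Hazard quotient of a non-carcinogenic exposure
#'
#' HQ = Intake / RfD, the ratio of chronic daily intake to the analyte's oral
#' reference dose. The averaging time follows `at_convention`: `"ed_years"`
#' (default) sets AT = ED × 365 per group, the convention under which the
#' children-to-adult HQ ratios are internally consistent; `"table"` uses the
#' profile's tabulated non-carcinogenic AT.
#'
#' @inheritParams compute_intake
#' @param analyte An [analyte] (or registry name); must carry an RfD.
#' @param at_convention `"ed_years"` or `"table"`.
#'
#' @return Hazard quotient(s), dimensionless.
#' @examples
#' compute_hq(1.3465, "children", "Cd")  # ~9.41
#' @export
compute_hq <- function(c_mg_kg, profile, analyte,
                       at_convention = c("ed_years", "table")) {
  profile <- as_profile(profile)
  analyte <- as_analyte(analyte)
  if (is.null(analyte$rfd))
    stop("no reference dose for analyte '", analyte$name, "'", call. = FALSE)
  at <- noncarc_at(profile, at_convention)
  compute_intake(c_mg_kg, profile, at) / analyte$rfd
}

#' Hazard index: sum of hazard quotients
#'
#' @param hqs Numeric vector of non-negative hazard quotients for the
#'   analytes co-occurring in one exposure scenario; must be non-empty.
#' @return The hazard index (arithmetic sum), dimensionless.
#' @examples
#' compute_hi(c(9.411, 2.95, 1.04, 4.72, 5.65))  # 23.77
#' @export
compute_hi <- function(hqs) {
  if (length(hqs) == 0L)
    stop("hazard index is undefined over an empty set of hazard quotients",
         call. = FALSE)
  if (!is.numeric(hqs) || any(!is.finite(hqs)) || any(hqs < 0))
    stop("'hqs' must be finite and non-negative", call. = FALSE)
  sum(hqs)
}

#' Incremental lifetime carcinogenic risk
#'
#' CR = Intake × S_F × 10⁻³, with intake averaged over the carcinogenic
#' averaging time of the profile. The 10⁻³ scaling of the published risk
#' equation is retained by default; set `unit_factor = 1` to disable it.
#'
#' @inheritParams compute_hq
#' @param analyte An [analyte] with an oral slope factor.
#' @param unit_factor Multiplier applied after the slope factor; the default
#'   `1e-3` follows the published equation.
#'
#' @return Carcinogenic risk(s), dimensionless lifetime probability.
#' @examples
#' compute_cr(7.786, "children", "Ni")  # ~7.93e-6
#' @export
compute_cr <- function(c_mg_kg, profile, analyte, unit_factor = 1e-3) {
  profile <- as_profile(profile)
  analyte <- as_analyte(analyte)
  if (!analyte$is_carcinogen)
    stop("analyte '", analyte$name,
         "' is not carcinogenic (no slope factor)", call. = FALSE)
  compute_intake(c_mg_kg, profile, profile$at_carc) *
    analyte$slope_factor * unit_factor
}

#' Total carcinogenic risk: sum of carcinogenic risks
#'
#' @param crs Numeric vector of non-negative carcinogenic risks; non-empty.
#' @return The total carcinogenic risk (arithmetic sum).
#' @examples
#' compute_tcr(c(8.88e-7, 2.36e-8, 7.93e-6))  # 8.84e-6
#' @export
compute_tcr <- function(crs) {
  if (length(crs) == 0L)
    stop("total carcinogenic risk is undefined over an empty set of risks",
         call. = FALSE)
  if (!is.numeric(crs) || any(!is.finite(crs)) || any(crs < 0))
    stop("'crs' must be finite and non-negative", call. = FALSE)
  sum(crs)
}

#' Risk-band classification of hazard quotients / indices
#'
#' Bands: below 0.1 insignificant; 0.1 to 1 low; 1 to 4 moderate; 4 and
#' above very high. Intervals are closed on the left, so exactly 1 is
#' "moderate".
#'
#' @param h Numeric vector of HQ or HI values (non-negative).
#' @return An ordered factor with levels `insignificant < low < moderate <
#'   very high`.
#' @examples
#' classify_hq(c(0.05, 0.5, 1, 23.77))
#' @export
classify_hq <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0))
    stop("'h' must be finite and non-negative", call. = FALSE)
  cut(h, breaks = c(-Inf, 0.1, 1, 4, Inf), right = FALSE,
      labels = c("insignificant", "low", "moderate", "very high"),
      ordered_result = TRUE)
}

#' Risk-band classification of carcinogenic risks
#'
#' Bands at the conventional cut-points: below 1e-6 not significant;
#' 1e-6 to 1e-5 low; 1e-5 to 1e-4 medium; 1e-4 to 1e-3 high; 1e-3 and above
#' relatively high. Intervals are closed on the left.
#'
#' @param cr Numeric vector of CR or TCR values (non-negative).
#' @return An ordered factor with levels `not significant < low < medium <
#'   high < relatively high`.
#' @examples
#' classify_cr(c(0, 7.93e-6, 2e-3))
#' @export
classify_cr <- function(cr) {
  if (!is.numeric(cr) || any(!is.finite(cr)) || any(cr < 0))
    stop("'cr' must be finite and non-negative", call. = FALSE)
  cut(cr, breaks = c(-Inf, 1e-6, 1e-5, 1e-4, 1e-3, Inf), right = FALSE,
      labels = c("not significant", "low", "medium", "high",
                 "relatively high"),
      ordered_result = TRUE)
}

#' Invert the hazard-quotient equation for concentration
#'
#' Solves HQ = (ED × C × EF × IR) / (BW × AT × RfD) for C, so that
#' `compute_hq(back_derive_concentration(hq, ...), ...)` returns `hq` to
#' machine precision. Used to calibrate synthetic concentration data from
#' published hazard quotients.
#'
#' @param hq Hazard quotient(s), non-negative.
#' @inheritParams compute_hq
#' @return Concentration(s), mg·kg⁻¹.
#' @examples
#' back_derive_concentration(9.411, "children", "Cd")  # ~1.3465
#' @export
back_derive_concentration <- function(hq, profile, analyte,
                                      at_convention = c("ed_years", "table")) {
  profile <- as_profile(profile)
  analyte <- as_analyte(analyte)
  if (is.null(analyte$rfd))
    stop("no reference dose for analyte '", analyte$name, "'", call. = FALSE)
  if (!is.numeric(hq) || any(!is.finite(hq)) || any(hq < 0))
    stop("'hq' must be finite and non-negative", call. = FALSE)
  at <- noncarc_at(profile, at_convention)
  hq * analyte$rfd * profile$bw * at / (profile$ed * profile$ef * profile$ir)
}

#' Invert the carcinogenic-risk equation for concentration
#'
#' Solves CR = Intake × S_F × unit_factor for the concentration, the exact
#' inverse of [compute_cr()].
#'
#' @param cr Carcinogenic risk(s), non-negative.
#' @inheritParams compute_cr
#' @return Concentration(s), mg·kg⁻¹.
#' @examples
#' back_derive_concentration_cr(7.93e-6, "children", "Ni")  # ~7.786
#' @export
back_derive_concentration_cr <- function(cr, profile, analyte,
                                         unit_factor = 1e-3) {
  profile <- as_profile(profile)
  analyte <- as_analyte(analyte)
  if (!analyte$is_carcinogen)
    stop("analyte '", analyte$name,
         "' is not carcinogenic (no slope factor)", call. = FALSE)
  if (!is.numeric(cr) || any(!is.finite(cr)) || any(cr < 0))
    stop("'cr' must be finite and non-negative", call. = FALSE)
  cr * profile$bw * profile$at_carc /
    (profile$ed * profile$ef * profile$ir * analyte$slope_factor * unit_factor)
}
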