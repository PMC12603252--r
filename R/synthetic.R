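#' Reference summary statistics used to calibrate the synthetic generator
#'
#' Children's published mean ± SD hazard quotients per vegetable × analyte,
#' the children's mean carcinogenic risk for Ni, and the pooled spatial
#' concentration ranges, for a surveyed set of radish and carrot samples.
#' These are the calibration inputs of [calibrate_targets()]; the children's
#' row is used because it is internally consistent with the adult rows under
#' the AT = ED × 365 convention.
#'
#' @return A list with data.frames `hq` (`vegetable`, `analyte`, `hq_mean`,
#'   `hq_sd`), `cr` (`vegetable`, `analyte`, `cr_mean`) and `ranges`
#'   (`analyte`, `lo`, `hi` in mg·kg⁻¹).
#' @export
calibration_reference <- function() {
  hq <- data.frame(
    vegetable = rep(c("radish", "carrot"), each = 5),
    analyte = rep(c("Cd", "Pb", "Zn", "Ni", "NO3"), 2),
    hq_mean = c(9.411, 2.95, 1.04, 4.72, 5.65,
                13.05, 13.63, 1.11, 4.55, 6.47),
    hq_sd   = c(5.81, 2.66, 0.341, 3.58, 3.76,
                6.17, 10.76, 0.48, 3.43, 4.39)
  )
  cr <- data.frame(
    vegetable = c("radish", "carrot"),
    analyte = "Ni",
    cr_mean = c(7.93e-6, 7.6e-6)
  )
  ranges <- data.frame(
    analyte = c("Cd", "Pb", "Ni", "Zn", "NO3"),
    lo = c(0.151, 0.171, 0.251, 2.333, 7.588),
    hi = c(4.096, 6.794, 8.092, 18.275, 859.275)
  )
  list(hq = hq, cr = cr, ranges = ranges)
}

#' Back-derive concentration calibration targets from published risk values
#'
#' For each vegetable × analyte, derives the target mean concentration by
#' inverting the risk equations against the children's published values:
#' from the hazard quotient for most analytes, or from the carcinogenic risk
#' where an analyte appears in `cr_table` (Ni, whose HQ-implied mean falls
#' outside the published concentration range). Nitrate's HQ-implied mean
#' also exceeds its published range and is capped at the range maximum. Any
#' target mean still outside its range is clamped to the range midpoint with
#' a warning. The coefficient of variation is taken from the published
#' HQ mean ± SD (HQ is linear in concentration, so the CVs coincide).
#'
#' @param hq_table data.frame `vegetable`, `analyte`, `hq_mean`, `hq_sd`
#'   (children's values).
#' @param cr_table data.frame `vegetable`, `analyte`, `cr_mean` naming the
#'   analytes to calibrate from CR instead of HQ (children's values).
#' @param profiles Named list of profiles; the `children` profile anchors
#'   the inversion.
#' @param analytes Named list of [analyte]s.
#' @param ranges data.frame `analyte`, `lo`, `hi`: admissible concentration
#'   range per analyte, mg·kg⁻¹ (pooled across vegetables).
#' @param at_convention See [compute_hq()].
#' @return A data.frame of class `calibration_targets`: `vegetable`,
#'   `analyte`, `target_mean`, `cv`, `lo`, `hi`, `source`
#'   (`"hq"`, `"cr"`, `"hq_capped"` or `"midpoint"`).
#' @examples
#' calibrate_targets()
#' @export
calibrate_targets <- function(hq_table = calibration_reference()$hq,
                              cr_table = calibration_reference()$cr,
                              profiles = default_profiles(),
                              analytes = default_analytes(),
                              ranges = calibration_reference()$ranges,
                              at_convention = "ed_years") {
  children <- profiles$children
  if (is.null(children)) stop("'profiles' must contain 'children'",
                              call. = FALSE)
  out <- hq_table
  out$target_mean <- NA_real_
  out$cv <- out$hq_sd / out$hq_mean
  out$source <- "hq"
  for (i in seq_len(nrow(out))) {
    an <- analytes[[out$analyte[i]]]
    if (is.null(an)) stop("analyte '", out$analyte[i],
                          "' missing from registry", call. = FALSE)
    in_cr <- which(cr_table$analyte == an$name &
                   cr_table$vegetable == out$vegetable[i])
    if (length(in_cr)) {
      out$target_mean[i] <- back_derive_concentration_cr(
        cr_table$cr_mean[in_cr[1L]], children, an)
      out$source[i] <- "cr"
    } else {
      out$target_mean[i] <- back_derive_concentration(
        out$hq_mean[i], children, an, at_convention)
    }
    rng <- ranges[ranges$analyte == an$name, ]
    if (nrow(rng) != 1L) stop("no range for analyte '", an$name, "'",
                              call. = FALSE)
    out$lo[i] <- rng$lo
    out$hi[i] <- rng$hi
    if (an$name == "NO3" && out$target_mean[i] > rng$hi) {
      out$target_mean[i] <- rng$hi
      out$source[i] <- "hq_capped"
    }
    if (out$target_mean[i] < rng$lo || out$target_mean[i] > rng$hi) {
      warning("target mean for ", an$name, " (", out$vegetable[i], "), ",
              format(out$target_mean[i], digits = 4),
              " mg/kg, lies outside the admissible range [", rng$lo, ", ",
              rng$hi, "]; clamped to the range midpoint", call. = FALSE)
      out$target_mean[i] <- (rng$lo + rng$hi) / 2
      out$source[i] <- "midpoint"
    }
  }
  out <- out[, c("vegetable", "analyte", "target_mean", "cv", "lo", "hi",
                 "source")]
  class(out) <- c("calibration_targets", "data.frame")
  out
}

# Truncated lognormal by resampling (preserves the in-range shape, unlike
# clipping). Errors if the acceptance region is too improbable.
rlnorm_trunc <- function(n, spec, lo, hi, max_tries = 1000L) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- rlnorm_spec(n, spec)
    out <- c(out, draw[draw >= lo & draw <= hi])
    tries <- tries + 1L
    if (tries > max_tries)
      stop("truncated sampling failed: range [", lo, ", ", hi,
           "] captures too little lognormal mass", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Configuration of the synthetic site-concentration generator
#'
#' @param n_sites Number of sampling sites (default 21).
#' @param n_districts Number of districts the sites are grouped into
#'   (default 11; descriptive metadata only).
#' @param seed Integer seed (mandatory).
#' @param extent Spatial extent `c(xmin, xmax, ymin, ymax)` in km; defaults
#'   to a 20 × 20 km urban plain.
#' @param targets A [calibrate_targets()] data.frame.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 21, n_districts = 11, seed,
                             extent = c(0, 20, 0, 20),
                             targets = calibrate_targets()) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_sites >= 1, n_districts >= 1, length(extent) == 4,
            extent[1] < extent[2], extent[3] < extent[4])
  structure(list(n_sites = as.integer(n_sites),
                 n_districts = as.integer(n_districts),
                 seed = as.integer(seed), extent = extent,
                 targets = targets),
            class = "synthetic_config")
}

#' Generate a synthetic site-concentration table
#'
#' Draws site coordinates uniformly over the extent, assigns districts
#' round-robin, and draws one concentration per site × vegetable × analyte
#' from the moment-matched lognormal of each calibration target, truncated
#' by resampling to the target's admissible range. Fully reproducible from
#' the seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with `sites` (data.frame `site_id`, `lat`, `lon`,
#'   `district`; coordinates are planar km despite the column names, which
#'   follow the concentration-table layout) and `concentrations`
#'   (a `concentration_table`).
#' @examples
#' gs <- generate_sites(synthetic_config(seed = 1))
#' head(gs$concentrations)
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_sites
  ext <- config$extent
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    lon = stats::runif(n, ext[1], ext[2]),
    lat = stats::runif(n, ext[3], ext[4]),
    district = sprintf("D%02d", ((seq_len(n) - 1L) %% config$n_districts) + 1L)
  )
  tg <- config$targets
  rows <- lapply(seq_len(nrow(tg)), function(i) {
    spec <- fit_lognormal(tg$target_mean[i], tg$target_mean[i] * tg$cv[i])
    data.frame(site_id = sites$site_id, lat = sites$lat, lon = sites$lon,
               vegetable = tg$vegetable[i], analyte = tg$analyte[i],
               concentration_mg_per_kg =
                 rlnorm_trunc(n, spec, tg$lo[i], tg$hi[i]))
  })
  conc <- do.call(rbind, rows)
  rownames(conc) <- NULL
  class(conc) <- c("concentration_table", "data.frame")
  list(sites = sites[, c("site_id", "lat", "lon", "district")],
       concentrations = conc)
}

#' One-call synthetic fixture for the whole pipeline
#'
#' Generates a calibrated site-concentration bundle and (optionally) writes
#' the CSV inputs consumed by the deterministic, Monte Carlo, sensitivity
#' and spatial stages: the long concentration table, the per
#' vegetable × analyte summary statistics, and the calibration targets.
#'
#' @param seed Integer seed.
#' @param n_sites Number of sites (default 21; use a large value, e.g. 2000,
#'   for statistical validation of the calibration).
#' @param dir Output directory, or `NULL` to skip writing.
#' @return A list with `sites`, `concentrations`, `targets`, `summary`
#'   (realised mean/sd per vegetable × analyte) and `paths` (named character
#'   vector, empty when `dir` is `NULL`).
#' @export
pipeline_fixture <- function(seed, n_sites = 21, dir = NULL) {
  config <- synthetic_config(n_sites = n_sites, seed = seed)
  gen <- generate_sites(config)
  conc <- gen$concentrations
  sm <- stats::aggregate(
    concentration_mg_per_kg ~ vegetable + analyte, data = conc,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  sm <- cbind(sm[c("vegetable", "analyte")],
              as.data.frame(sm$concentration_mg_per_kg))
  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      concentrations = file.path(dir, "concentrations.csv"),
      summary = file.path(dir, "concentration_summary.csv"),
      targets = file.path(dir, "calibration_targets.csv")
    )
    utils::write.csv(conc, paths[["concentrations"]], row.names = FALSE)
    utils::write.csv(sm, paths[["summary"]], row.names = FALSE)
    utils::write.csv(as.data.frame(gen$sites), file.path(dir, "sites.csv"),
                     row.names = FALSE)
    paths <- c(paths, sites = file.path(dir, "sites.csv"))
    utils::write.csv(as.data.frame(config$targets), paths[["targets"]],
                     row.names = FALSE)
  }
  list(sites = gen$sites, concentrations = conc, targets = config$targets,
       summary = sm, paths = paths)
}
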