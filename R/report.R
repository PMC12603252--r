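#' Read a site-level concentration table
#'
#' Reads (or validates) a long-format concentration table with columns
#' `site_id`, `lat`, `lon`, `vegetable`, `analyte`, `concentration_mg_per_kg`.
#'
#' @param x Path to a CSV file, or a data.frame already in that layout.
#' @return A validated data.frame of class `concentration_table`.
#' @export
read_concentration_table <- function(x) {
  tab <- if (is.character(x) && length(x) == 1L) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else {
    stop("'x' must be a CSV path or a data.frame", call. = FALSE)
  }
  needed <- c("site_id", "lat", "lon", "vegetable", "analyte",
              "concentration_mg_per_kg")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("concentration table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  conc <- tab$concentration_mg_per_kg
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("'concentration_mg_per_kg' must be finite and non-negative",
         call. = FALSE)
  class(tab) <- c("concentration_table", "data.frame")
  tab
}

#' Deterministic risk report per demographic group and vegetable
#'
#' Averages the measured concentrations per vegetable × analyte and computes,
#' for every exposure profile, the hazard quotient of each analyte with an
#' RfD, the carcinogenic risk of each analyte with a slope factor, the hazard
#' index HI = ΣHQ and the total carcinogenic risk TCR = ΣCR, together with
#' their risk-band labels.
#'
#' @param conc A `concentration_table` (see [read_concentration_table()]),
#'   a data.frame in that layout, or a path to such a CSV.
#' @param profiles Named list of [exposure_profile]s
#'   (default [default_profiles()]).
#' @param analytes Named list of [analyte]s (default [default_analytes()]).
#'   Only analytes present in both the registry and the table are assessed.
#' @param at_convention Averaging-time convention for hazard quotients,
#'   see [compute_hq()].
#' @param unit_factor Carcinogenic-risk scaling, see [compute_cr()].
#'
#' @return An object of class `risk_report`: a list with
#'   \describe{
#'     \item{records}{data.frame, one row per group × vegetable × analyte,
#'       with mean concentration, intake, `hq`, `cr` (NA where undefined)
#'       and band labels.}
#'     \item{summary}{data.frame, one row per group × vegetable with `hi`,
#'       `tcr` and their band labels.}
#'   }
#' @examples
#' fx <- pipeline_fixture(seed = 1)
#' risk_report(fx$concentrations)
#' @export
risk_report <- function(conc, profiles = default_profiles(),
                        analytes = default_analytes(),
                        at_convention = c("ed_years", "table"),
                        unit_factor = 1e-3) {
  at_convention <- match.arg(at_convention)
  conc <- read_concentration_table(conc)
  keep <- conc$analyte %in% names(analytes)
  if (!any(keep))
    stop("no analyte in the table matches the analyte registry",
         call. = FALSE)
  conc <- conc[keep, , drop = FALSE]
  means <- stats::aggregate(
    concentration_mg_per_kg ~ vegetable + analyte, data = conc, FUN = mean)

  records <- do.call(rbind, lapply(names(profiles), function(g) {
    prof <- profiles[[g]]
    out <- means
    out$group <- g
    out$intake <- compute_intake(out$concentration_mg_per_kg, prof,
                                 noncarc_at(prof, at_convention))
    out$hq <- NA_real_
    out$cr <- NA_real_
    for (i in seq_len(nrow(out))) {
      an <- analytes[[out$analyte[i]]]
      if (!is.null(an$rfd))
        out$hq[i] <- compute_hq(out$concentration_mg_per_kg[i], prof, an,
                                at_convention)
      if (an$is_carcinogen)
        out$cr[i] <- compute_cr(out$concentration_mg_per_kg[i], prof, an,
                                unit_factor)
    }
    out
  }))
  records$hq_band <- factor(NA, levels = levels(classify_hq(0)),
                            ordered = TRUE)
  ok <- !is.na(records$hq)
  records$hq_band[ok] <- classify_hq(records$hq[ok])
  records$cr_band <- factor(NA, levels = levels(classify_cr(0)),
                            ordered = TRUE)
  ok <- !is.na(records$cr)
  records$cr_band[ok] <- classify_cr(records$cr[ok])
  records <- records[, c("group", "vegetable", "analyte",
                         "concentration_mg_per_kg", "intake",
                         "hq", "cr", "hq_band", "cr_band")]
  records <- records[order(records$group, records$vegetable,
                           records$analyte), ]
  rownames(records) <- NULL

  summary <- do.call(rbind, lapply(split(
    records, list(records$group, records$vegetable), drop = TRUE),
    function(d) {
      data.frame(group = d$group[1], vegetable = d$vegetable[1],
                 hi = compute_hi(d$hq[!is.na(d$hq)]),
                 tcr = if (any(!is.na(d$cr)))
                   compute_tcr(d$cr[!is.na(d$cr)]) else NA_real_)
    }))
  summary$hi_band <- classify_hq(summary$hi)
  summary$tcr_band <- factor(NA, levels = levels(classify_cr(0)),
                             ordered = TRUE)
  ok <- !is.na(summary$tcr)
  summary$tcr_band[ok] <- classify_cr(summary$tcr[ok])
  summary <- summary[order(summary$group, summary$vegetable), ]
  rownames(summary) <- NULL

  structure(list(records = records, summary = summary,
                 at_convention = at_convention, unit_factor = unit_factor),
            class = "risk_report")
}

# Display rounding only: >= 1 to 2 decimals, otherwise 3 significant figures.
fmt_hq <- function(x) ifelse(x >= 1, sprintf("%.2f", x),
                             formatC(signif(x, 3), format = "fg"))
fmt_cr <- function(x) formatC(x, format = "e", digits = 2)

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> ", length(unique(x$records$group)), " group(s) x ",
      length(unique(x$records$vegetable)), " vegetable(s), ",
      length(unique(x$records$analyte)), " analyte(s)\n", sep = "")
  s <- x$summary
  s$hi <- fmt_hq(s$hi)
  s$tcr <- ifelse(is.na(x$summary$tcr), "-", fmt_cr(x$summary$tcr))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write a risk report to CSV
#'
#' Writes one row per group × vegetable × analyte followed by the HI/TCR
#' summary rows (marked `analyte = "ALL"`), in a single flat CSV.
#'
#' @param report A [risk_report()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_risk_report <- function(report, path) {
  stopifnot(inherits(report, "risk_report"))
  rec <- report$records
  rec$hq_band <- as.character(rec$hq_band)
  rec$cr_band <- as.character(rec$cr_band)
  sm <- report$summary
  sumrows <- data.frame(group = sm$group, vegetable = sm$vegetable,
                        analyte = "ALL",
                        concentration_mg_per_kg = NA_real_,
                        intake = NA_real_,
                        hq = sm$hi, cr = sm$tcr,
                        hq_band = as.character(sm$hi_band),
                        cr_band = as.character(sm$tcr_band))
  utils::write.csv(rbind(rec, sumrows), path, row.names = FALSE, na = "")
  invisible(path)
}
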