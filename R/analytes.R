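#' Define an analyte and its toxicity reference values
#'
#' An analyte bundles the chronic oral reference dose (RfD) used for
#' non-carcinogenic hazard quotients and, for carcinogens, the oral slope
#' factor used for incremental lifetime cancer risk.
#'
#' @param name Analyte identifier (e.g. `"Cd"`, `"NO3"`).
#' @param rfd Oral reference dose in mg·kg⁻¹·day⁻¹, or `NULL` if none is
#'   established.
#' @param slope_factor Oral slope factor in (mg·kg⁻¹·day⁻¹)⁻¹, or `NULL` for
#'   non-carcinogens. An analyte is treated as carcinogenic exactly when a
#'   slope factor is present.
#'
#' @return An object of class `analyte`: a list with elements `name`, `rfd`,
#'   `slope_factor` and `is_carcinogen`.
#' @examples
#' analyte("Cd", rfd = 0.001, slope_factor = 0.38)
#' @export
analyte <- function(name, rfd = NULL, slope_factor = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(rfd)) {
    if (!is.numeric(rfd) || length(rfd) != 1L || !is.finite(rfd) || rfd <= 0)
      stop("'rfd' must be a single positive number or NULL", call. = FALSE)
  }
  if (!is.null(slope_factor)) {
    if (!is.numeric(slope_factor) || length(slope_factor) != 1L ||
        !is.finite(slope_factor) || slope_factor <= 0)
      stop("'slope_factor' must be a single positive number or NULL",
           call. = FALSE)
  }
  structure(
    list(name = name, rfd = rfd, slope_factor = slope_factor,
         is_carcinogen = !is.null(slope_factor)),
    class = "analyte"
  )
}

#' @export
print.analyte <- function(x, ...) {
  cat("<analyte> ", x$name, "\n", sep = "")
  cat("  RfD:          ", if (is.null(x$rfd)) "none" else
      paste(format(x$rfd), "mg/kg/day"), "\n", sep = "")
  cat("  slope factor: ", if (is.null(x$slope_factor)) "none" else
      paste(format(x$slope_factor), "(mg/kg/day)^-1"), "\n", sep = "")
  invisible(x)
}

#' Default analyte registry
#'
#' The five analytes of the tuberous-vegetable assessment with their IRIS
#' oral reference doses (Pb 0.00357, Cd 0.001, Zn 0.3, Ni 0.02, nitrate
#' 1.6 mg·kg⁻¹·day⁻¹) and oral slope factors for the three carcinogens
#' (Cd 0.38, Pb 0.0085, Ni 1.7 (mg·kg⁻¹·day⁻¹)⁻¹).
#'
#' @return A named list of [analyte] objects (`Cd`, `Pb`, `Zn`, `Ni`, `NO3`).
#' @examples
#' default_analytes()$Ni
#' @export
default_analytes <- function() {
  list(
    Cd  = analyte("Cd",  rfd = 0.001,   slope_factor = 0.38),
    Pb  = analyte("Pb",  rfd = 0.00357, slope_factor = 0.0085),
    Zn  = analyte("Zn",  rfd = 0.3),
    Ni  = analyte("Ni",  rfd = 0.02,    slope_factor = 1.7),
    NO3 = analyte("NO3", rfd = 1.6)
  )
}

as_analyte <- function(x) {
  if (inherits(x, "analyte")) return(x)
  if (is.character(x) && length(x) == 1L) {
    reg <- default_analytes()
    if (x %in% names(reg)) return(reg[[x]])
    stop("unknown analyte '", x, "'", call. = FALSE)
  }
  stop("'analyte' must be an analyte object or a registry name",
       call. = FALSE)
}
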