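#' Default pipeline configuration
#'
#' Single source of truth for the toxicity constants, exposure profiles and
#' stage parameters driving [run_pipeline()]. The same structure can be read
#' from YAML with [read_config()]; a bundled copy lives at
#' `system.file("extdata", "default_config.yaml", package = "vegrisk")`.
#'
#' @return A nested list of class `vegrisk_config`.
#' @export
default_config <- function() {
  structure(list(
    at_convention = "ed_years",
    unit_factor = 1e-3,
    analytes = lapply(default_analytes(), function(a)
      list(name = a$name, rfd = a$rfd, slope_factor = a$slope_factor)),
    profiles = lapply(default_profiles(), unclass),
    synth = list(n_sites = 21, n_districts = 11, extent = c(0, 20, 0, 20)),
    mc = list(n_iter = 50000),
    sobol = list(n_base = 2048, second_order = TRUE, endpoint = "tcr",
                 vegetable = "radish", group = "children",
                 exposure_cv = 0.2),
    idw = list(power = 2, nrow = 40, ncol = 40, analytes = NULL,
               vegetable = "radish"),
    stages = c("synth", "risk", "mc", "sobol", "idw")
  ), class = "vegrisk_config")
}

config_error <- function(...) {
  stop(structure(class = c("vegrisk_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

validate_config <- function(config) {
  for (f in c("at_convention", "analytes", "profiles", "stages"))
    if (is.null(config[[f]])) config_error("config field missing: ", f)
  if (!config$at_convention %in% c("ed_years", "table"))
    config_error("config field at_convention: must be 'ed_years' or 'table'")
  bad <- setdiff(config$stages, c("synth", "risk", "mc", "sobol", "idw"))
  if (length(bad))
    config_error("config field stages: unknown stage(s) ",
                 paste(bad, collapse = ", "))
  for (nm in names(config$analytes)) {
    a <- config$analytes[[nm]]
    if (is.null(a$name)) config_error("config field analytes.", nm, ".name")
  }
  for (nm in names(config$profiles)) {
    p <- config$profiles[[nm]]
    for (f in c("group", "ir", "ef", "ed", "bw"))
      if (is.null(p[[f]]))
        config_error("config field profiles.", nm, ".", f)
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [default_config()] values; the
#' merged configuration is validated (invalid files raise a
#' `vegrisk_config_error` naming the offending field).
#'
#' @param path Path to a YAML file.
#' @return A validated `vegrisk_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merged <- utils::modifyList(unclass(default_config()), user)
  validate_config(structure(merged, class = "vegrisk_config"))
}

config_registries <- function(config) {
  analytes <- lapply(config$analytes, function(a)
    analyte(a$name, rfd = a$rfd, slope_factor = a$slope_factor))
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")
  profiles <- lapply(config$profiles, function(p)
    exposure_profile(p$group, p$ir, p$ef, p$ed, p$bw,
                     p$at_noncarc %||% 10950, p$at_carc %||% 25550))
  names(profiles) <- vapply(profiles, `[[`, character(1), "group")
  list(analytes = analytes, profiles = profiles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full risk-assessment pipeline
#'
#' Executes the enabled stages in dependency order — `synth` (calibrated
#' synthetic site concentrations), `risk` (deterministic HQ/HI/CR/TCR
#' report), `mc` (Monte Carlo mean / 95th-percentile summaries), `sobol`
#' (variance-based sensitivity indices) and `idw` (inverse-distance-weighted
#' concentration grids) — writing each stage's outputs under `out_dir` and a
#' JSON manifest recording the configuration snapshot, seeds and output
#' paths. A stage failure aborts with an error naming the stage.
#'
#' @param config A `vegrisk_config` (see [default_config()],
#'   [read_config()]).
#' @param seed Integer seed; every stochastic stage derives its sub-seed
#'   from it.
#' @param out_dir Output directory (created if needed).
#' @param conc Optional concentration table (path or data.frame) to use
#'   instead of the synthetic stage's output; required if `"synth"` is not
#'   among the enabled stages.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), seed, out_dir,
                         conc = NULL) {
  validate_config(config)
  if (missing(seed)) config_error("config field seed: required")
  seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reg <- config_registries(config)
  stages <- config$stages
  outputs <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      if (inherits(e, "vegrisk_config_error")) stop(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  conc_tab <- NULL
  if ("synth" %in% stages) {
    run_stage("synth", function() {
      fx <- pipeline_fixture(seed = seed,
                             n_sites = config$synth$n_sites %||% 21,
                             dir = file.path(out_dir, "synth"))
      conc_tab <<- fx$concentrations
      outputs$synth <<- as.list(fx$paths)
    })
  } else {
    if (is.null(conc))
      config_error("config field stages: 'synth' disabled but no ",
                   "concentration table supplied")
    conc_tab <- read_concentration_table(conc)
  }

  report <- NULL
  if ("risk" %in% stages) run_stage("risk", function() {
    report <<- risk_report(conc_tab, reg$profiles, reg$analytes,
                           config$at_convention, config$unit_factor)
    path <- file.path(out_dir, "risk_report.csv")
    write_risk_report(report, path)
    outputs$risk <<- list(report = path)
  })

  if ("mc" %in% stages) run_stage("mc", function() {
    mc <- mc_risk_summary(conc_tab, reg$profiles, reg$analytes,
                          n_iter = config$mc$n_iter %||% 50000,
                          seed = seed + 1L,
                          at_convention = config$at_convention)
    path <- file.path(out_dir, "mc_summary.csv")
    utils::write.csv(mc, path, row.names = FALSE)
    outputs$mc <<- list(summary = path)
  })

  if ("sobol" %in% stages) run_stage("sobol", function() {
    sb <- config$sobol
    veg <- sb$vegetable %||% "radish"
    sub <- conc_tab[conc_tab$vegetable == veg, , drop = FALSE]
    means <- tapply(sub$concentration_mg_per_kg, sub$analyte, mean)
    cvs <- tapply(sub$concentration_mg_per_kg, sub$analyte,
                  function(v) stats::sd(v) / mean(v))
    cvs[!is.finite(cvs) | cvs <= 0] <- 0.5
    space <- risk_factor_space(reg$profiles[[sb$group %||% "children"]],
                               stats::setNames(as.numeric(means),
                                               names(means)),
                               stats::setNames(as.numeric(cvs), names(cvs)),
                               exposure_cv = sb$exposure_cv %||% 0.2)
    res <- sobol_risk(space, reg$profiles[[sb$group %||% "children"]],
                      reg$analytes[names(means)],
                      stats::setNames(as.numeric(means), names(means)),
                      endpoint = sb$endpoint %||% "tcr",
                      n_base = sb$n_base %||% 2048, seed = seed + 2L,
                      second_order = isTRUE(sb$second_order %||% TRUE),
                      at_convention = config$at_convention,
                      unit_factor = config$unit_factor)
    p1 <- file.path(out_dir, "sobol_indices.csv")
    utils::write.csv(res$indices, p1, row.names = FALSE)
    outputs$sobol <<- list(indices = p1)
    if (!is.null(res$s2)) {
      p2 <- file.path(out_dir, "sobol_second_order.csv")
      pairs <- which(upper.tri(res$s2), arr.ind = TRUE)
      utils::write.csv(data.frame(
        factor_i = rownames(res$s2)[pairs[, 1]],
        factor_j = colnames(res$s2)[pairs[, 2]],
        s2 = res$s2[pairs]), p2, row.names = FALSE)
      outputs$sobol$second_order <<- p2
    }
  })

  if ("idw" %in% stages) run_stage("idw", function() {
    iw <- config$idw
    veg <- iw$vegetable %||% "radish"
    which_an <- iw$analytes %||% unique(conc_tab$analyte)
    ext <- config$synth$extent %||% c(0, 20, 0, 20)
    nrow_ <- iw$nrow %||% 40
    ncol_ <- iw$ncol %||% 40
    spec <- grid_spec(ext[1], ext[3],
                      cellsize = (ext[2] - ext[1]) / ncol_,
                      nrow = nrow_, ncol = ncol_)
    outputs$idw <<- list()
    for (an in which_an) {
      sub <- conc_tab[conc_tab$vegetable == veg & conc_tab$analyte == an, ]
      if (!nrow(sub)) next
      s <- site_set(sub$site_id, sub$lon, sub$lat,
                    sub$concentration_mg_per_kg)
      g <- idw_grid(s, spec, power = iw$power %||% 2)
      pa <- file.path(out_dir, paste0("idw_", veg, "_", an, ".asc"))
      pc <- file.path(out_dir, paste0("idw_", veg, "_", an, ".csv"))
      write_esri_ascii(g, pa)
      utils::write.csv(grid_to_df(g), pc, row.names = FALSE)
      outputs$idw[[an]] <<- list(asc = pa, csv = pc)
    }
  })

  manifest <- list(
    package = "vegrisk",
    version = as.character(utils::packageVersion("vegrisk")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    stages = stages,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  manifest$path <- file.path(out_dir, "manifest.json")
  invisible(manifest)
}

#' Render a human-readable risk summary
#'
#' Formats the deterministic report in the conventional layout: one block
#' per group × vegetable listing the hazard quotient of every analyte, the
#' hazard index, the carcinogenic risks and the total carcinogenic risk,
#' each with its risk band. HQ/HI are shown with 2 decimals (3 significant
#' figures below 1), CR/TCR with 3 significant figures; underlying values
#' are full precision.
#'
#' @param x A [risk_report()], or a [run_pipeline()] manifest whose `risk`
#'   stage ran.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(x) {
  if (!inherits(x, "risk_report")) {
    path <- tryCatch(x$outputs$risk$report, error = function(e) NULL)
    if (is.null(path))
      stop("'x' must be a risk_report or a manifest with a risk stage",
           call. = FALSE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    lines <- character(0)
    for (g in unique(tab$group)) for (v in unique(tab$vegetable)) {
      sub <- tab[tab$group == g & tab$vegetable == v, ]
      if (!nrow(sub)) next
      lines <- c(lines, render_block(g, v, sub))
    }
    writeLines(lines)
    return(invisible(lines))
  }
  rec <- x$records
  rec$hq_band <- as.character(rec$hq_band)
  rec$cr_band <- as.character(rec$cr_band)
  sm <- x$summary
  lines <- character(0)
  for (i in seq_len(nrow(sm))) {
    sub <- rec[rec$group == sm$group[i] & rec$vegetable == sm$vegetable[i], ]
    all_row <- data.frame(analyte = "ALL", hq = sm$hi[i], cr = sm$tcr[i],
                          hq_band = as.character(sm$hi_band[i]),
                          cr_band = as.character(sm$tcr_band[i]))
    lines <- c(lines, render_block(sm$group[i], sm$vegetable[i],
                                   rbind(sub[, names(all_row)], all_row)))
  }
  writeLines(lines)
  invisible(lines)
}

render_block <- function(group, vegetable, sub) {
  hdr <- sprintf("== %s / %s ==", group, vegetable)
  band_or_dash <- function(value, band) {
    if (is.na(value) || is.na(band) || !nzchar(band)) "-" else band
  }
  body <- vapply(seq_len(nrow(sub)), function(i) {
    hq <- if (is.na(sub$hq[i])) "      -" else
      sprintf("%7s", fmt_hq(sub$hq[i]))
    cr <- if (is.na(sub$cr[i])) "        -" else fmt_cr(sub$cr[i])
    lab <- if (sub$analyte[i] == "ALL") "HI/TCR" else sub$analyte[i]
    sprintf("  %-6s HQ %s [%s]  CR %s [%s]", lab, hq,
            band_or_dash(sub$hq[i], sub$hq_band[i]),
            cr, band_or_dash(sub$cr[i], sub$cr_band[i]))
  }, character(1))
  c(hdr, body, "")
}
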