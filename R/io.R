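.spectrum_cols <- c("frequency_hz", "eps_real", "eps_imag")

# Full-precision CSV writer: doubles are rendered with 17 significant
# digits, which round-trips IEEE doubles exactly through strtod-based
# readers (including utils::read.csv).
.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.read_csv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
           error = function(e) stop("cannot parse ", path, ": ",
                                    conditionMessage(e)))
}
.study_cols <- c("liver_id", "group", "phase", "hour", "site", "replicate",
                 "frequency_hz", "eps_real", "eps_imag")

#' Read a permittivity spectrum from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns
#' `frequency_hz,eps_real,eps_imag` ('.' decimal separator), one row per
#' grid point. Additional metadata columns are ignored. Frequencies must
#' be strictly increasing; violations are reported with their row number.
#'
#' @param path File path.
#' @return A [permittivity_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- .read_csv_file(path)
  missing_cols <- setdiff(.spectrum_cols, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         "; expected header 'frequency_hz,eps_real,eps_imag'")
  if (!nrow(df)) stop(path, ": no data rows")
  for (col in .spectrum_cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(path, ": non-numeric value in column '", col, "' at data row ",
           bad)
    }
  }
  permittivity_spectrum(df$frequency_hz, df$eps_real, df$eps_imag)
}

#' Write a permittivity spectrum to CSV
#'
#' Full-precision CSV that round-trips losslessly through
#' [read_spectrum_csv()].
#'
#' @param spectrum A [permittivity_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  .write_csv_precise(
    data.frame(frequency_hz = spectrum$frequencies,
               eps_real = spectrum$eps_real,
               eps_imag = spectrum$eps_imag),
    path
  )
}

#' Read a study dataset from long-format CSV
#'
#' Columns: `liver_id,group,phase,hour,site,replicate,frequency_hz,
#' eps_real,eps_imag`. Optionally reads a per-liver weights CSV with
#' columns `liver_id,group,pre_g,post_g`.
#'
#' @param path Spectra CSV path.
#' @param weights_path Optional weights CSV path.
#' @return A [drs_study()].
#' @export
read_study_csv <- function(path, weights_path = NULL) {
  df <- .read_csv_file(path)
  missing_cols <- setdiff(.study_cols, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  weights <- NULL
  if (!is.null(weights_path)) weights <- .read_csv_file(weights_path)
  drs_study(df, weights = weights)
}

#' Write a study dataset to long-format CSV
#'
#' @param study A [drs_study()].
#' @param path Spectra CSV path.
#' @param weights_path Optional weights CSV path (written only when the
#'   study carries weights).
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path, weights_path = NULL) {
  stopifnot(inherits(study, "drs_study"))
  .write_csv_precise(study$spectra, path)
  if (!is.null(weights_path) && !is.null(study$weights))
    .write_csv_precise(study$weights, weights_path)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted Cole-Cole parameters (SI units, relaxation times in
#' seconds), 95% confidence intervals, goodness of fit and provenance
#' (input descriptor, seed, package version) as a JSON document.
#'
#' @param fit A [fit_cole_cole()] result.
#' @param path Output path.
#' @param input Optional input descriptor (e.g. source file) recorded as
#'   provenance.
#' @param seed Optional seed recorded as provenance.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, input = NULL, seed = NULL) {
  stopifnot(inherits(fit, "drs_fit"))
  est <- fit$params[.par_names]
  doc <- list(
    parameters = est,
    ci95 = apply(fit$ci95, 1, function(r) unname(r), simplify = FALSE),
    r_squared = fit$r_squared,
    residual_norm = fit$residual_norm,
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    provenance = list(
      input = if (is.null(input)) NA else input,
      seed = if (is.null(seed)) NA else seed,
      software = paste0("drsliver ",
                        as.character(utils::packageVersion("drsliver")))
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Liver-level averaged spectra for every liver of one (phase, hour).
.liver_spectra <- function(study, phase, hour, group = NULL) {
  sub <- .study_subset(study, phase, hour, group)
  ids <- unique(sub$liver_id)
  out <- lapply(ids, function(id) average_replicates(study, id, phase, hour))
  names(out) <- ids
  out
}

.stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study analysis end-to-end: replicate averaging,
#' two-pole Cole-Cole fits per liver and timepoint, water-content
#' estimation against the deionized-water reference, relative
#' conductivity change against the in vivo hour-1 control reference with
#' group means and standard errors, Sidak-corrected per-frequency
#' comparisons (hourly within-group pairs and between-group contrasts),
#' and the liver-weight summary. Deterministic given the study.
#'
#' @param study A [drs_study()] (e.g. from [generate_study()] or
#'   [read_study_csv()]).
#' @param water_debye Deionized-water reference parameters
#'   ([water_debye_default()]).
#' @param threshold Significance threshold for comparisons.
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV/JSON files.
#' @return A list with elements `fits` (per-liver-cell parameter table),
#'   `water_content` (per-cell estimates and group summaries),
#'   `relative_change` (long table of group mean/SE change per
#'   frequency), `comparisons` (named list of `drs_comparison` and a
#'   formatted `table`), `weights` (group weight summaries).
#' @export
run_pipeline <- function(study, water_debye = water_debye_default(),
                         threshold = 0.05, out_dir = NULL) {
  stopifnot(inherits(study, "drs_study"))
  if (!nrow(study$spectra)) stop("empty dataset")
  sp <- study$spectra
  phases <- intersect(.study_phases, unique(sp$phase))
  hours <- sort(unique(sp$hour))
  groups <- intersect(.study_groups, unique(sp$group))
  grid <- study$grid
  reference <- .stage("water_reference",
                      water_reference(grid, debye = water_debye))

  # --- fits + water content per liver cell ---------------------------------
  fit_rows <- list(); water_rows <- list(); k <- 0L
  fits <- list()
  for (phase in phases) for (hour in hours) {
    spectra <- .stage("averaging", .liver_spectra(study, phase, hour))
    for (id in names(spectra)) {
      fit <- .stage("cole_cole_fit", fit_cole_cole(spectra[[id]]))
      wc <- .stage("water_content", estimate_water_content(fit, reference))
      k <- k + 1L
      g <- sp$group[match(id, sp$liver_id)]
      fits[[paste(id, phase, hour)]] <- fit
      fit_rows[[k]] <- data.frame(
        liver_id = id, group = g, phase = phase, hour = hour,
        eps_inf = fit$params$eps_inf,
        delta_eps_1 = fit$params$delta_eps_1, tau_1 = fit$params$tau_1,
        alpha_1 = fit$params$alpha_1,
        delta_eps_2 = fit$params$delta_eps_2, tau_2 = fit$params$tau_2,
        alpha_2 = fit$params$alpha_2,
        r_squared = fit$r_squared, converged = fit$converged
      )
      water_rows[[k]] <- data.frame(liver_id = id, group = g, phase = phase,
                                    hour = hour, water_pct = wc$percent)
    }
  }
  fit_table <- do.call(rbind, fit_rows)
  water_table <- do.call(rbind, water_rows)
  water_groups <- aggregate(water_pct ~ group + phase + hour,
                            data = water_table,
                            FUN = function(v) c(mean = mean(v),
                                                se = sd(v) / sqrt(length(v))))
  water_groups <- cbind(water_groups[1:3],
                        as.data.frame(water_groups$water_pct))

  # --- relative conductivity change vs in vivo hour-1 controls -------------
  rel_table <- NULL
  if ("invivo" %in% phases && "CON" %in% groups && 1 %in% hours) {
    ref_mat <- .stage("relative_change",
                      .liver_matrix(study, "invivo", 1, "CON",
                                    value = "sigma"))
    sigma_control <- colMeans(ref_mat)
    rel_rows <- list(); k <- 0L
    for (phase in phases) for (hour in hours) for (g in groups) {
      if (phase == "invivo" && g == "CON" && hour == 1) next
      m <- tryCatch(.liver_matrix(study, phase, hour, g, value = "sigma"),
                    error = function(e) NULL)
      if (is.null(m) || nrow(m) < 2) next
      delta <- t(apply(m, 1, relative_change, sigma_control = sigma_control))
      gs <- group_summary(delta)
      k <- k + 1L
      rel_rows[[k]] <- data.frame(group = g, phase = phase, hour = hour,
                                  frequency_hz = grid,
                                  delta_sigma_pct = gs$mean,
                                  se_pct = gs$se)
    }
    rel_table <- do.call(rbind, rel_rows)
  }

  # --- comparison tables ---------------------------------------------------
  comparisons <- list()
  if ("invivo" %in% phases && length(hours) >= 2) {
    for (g in intersect(c("CON", "AHEP"), groups)) {
      comparisons[[paste0("invivo_hourly_", g)]] <-
        .stage("anova", hourly_comparisons(study, g, "invivo", hours,
                                           threshold = threshold))
    }
    if (all(c("CON", "AHEP") %in% groups)) {
      comparisons$invivo_CON_vs_AHEP <- lapply(hours, function(h)
        .stage("anova",
               per_frequency_anova(study, list("CON", h, "AHEP", h),
                                   "invivo", family_size = length(hours),
                                   threshold = threshold)))
      names(comparisons$invivo_CON_vs_AHEP) <- paste0("hour", hours)
    }
  }
  if ("NMP" %in% phases && max(hours) == 4) {
    for (g in intersect(c("AHEP", "SCS"), groups)) {
      comparisons[[paste0("NMP_4h_CON_vs_", g)]] <-
        .stage("anova",
               per_frequency_anova(study, list("CON", 4, g, 4), "NMP",
                                   family_size = 4, threshold = threshold))
    }
  }
  comp_table <- do.call(rbind, lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    if (inherits(x, "drs_comparison")) x <- list(x)
    data.frame(comparison = nm,
               contrast = vapply(x, `[[`, character(1), "contrast"),
               significant = vapply(x, function(ci)
                 format_ranges(ci$significant_ranges), character(1)))
  }))

  # --- weights -------------------------------------------------------------
  weights <- NULL
  if (!is.null(study$weights)) {
    weights <- do.call(rbind, lapply(groups, function(g) {
      ws <- weight_summary(study$weights, group = g)
      data.frame(group = g, mean_pre_g = ws$mean_pre,
                 mean_post_g = ws$mean_post,
                 mean_increase_g = ws$mean_increase, n = ws$n)
    }))
  }

  result <- list(fits = fit_table, fit_objects = fits,
                 water_content = list(per_liver = water_table,
                                      by_group = water_groups),
                 relative_change = rel_table,
                 comparisons = c(comparisons, list(table = comp_table)),
                 weights = weights)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_csv_precise(fit_table, file.path(out_dir, "fits.csv"))
    .write_csv_precise(water_table, file.path(out_dir, "water_content.csv"))
    .write_csv_precise(water_groups,
                       file.path(out_dir, "water_content_groups.csv"))
    if (!is.null(rel_table))
      .write_csv_precise(rel_table, file.path(out_dir, "relative_change.csv"))
    if (!is.null(comp_table))
      .write_csv_precise(comp_table, file.path(out_dir, "comparisons.csv"))
    if (!is.null(weights))
      .write_csv_precise(weights, file.path(out_dir, "weight_summary.csv"))
    jsonlite::write_json(
      list(software = paste0("drsliver ",
                             as.character(utils::packageVersion("drsliver"))),
           n_spectra = nrow(unique(sp[c("liver_id", "phase", "hour", "site",
                                        "replicate")])),
           grid_points = length(grid),
           grid_hz = range(grid)),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}
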