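.study_groups <- c("CON", "AHEP", "SCS")
.study_phases <- c("invivo", "NMP")

#' Dielectric study dataset
#'
#' Container for a full study: long-format spectra with liver, group,
#' phase, hour, site and replicate metadata, plus optional per-liver
#' weights. All spectra must share one frequency grid. Records are stored
#' in a canonical sort order (liver, phase, hour, site, replicate,
#' frequency), so all downstream aggregation is invariant to the row
#' order of the input.
#'
#' @param spectra Data frame with columns `liver_id`, `group` (one of
#'   CON/AHEP/SCS), `phase` (invivo/NMP), `hour` (1-4), `site`,
#'   `replicate`, `frequency_hz`, `eps_real`, `eps_imag`.
#' @param weights Optional data frame with columns `liver_id`, `group`,
#'   `pre_g`, `post_g` (liver weight in grams before and after machine
#'   perfusion).
#' @param config Optional generating configuration (kept as provenance).
#' @return An object of class `drs_study` with elements `spectra`,
#'   `weights`, `grid`, `config`.
#' @export
drs_study <- function(spectra, weights = NULL, config = NULL) {
  need <- c("liver_id", "group", "phase", "hour", "site", "replicate",
            "frequency_hz", "eps_real", "eps_imag")
  missing_cols <- setdiff(need, names(spectra))
  if (length(missing_cols))
    stop("spectra is missing columns: ", paste(missing_cols, collapse = ", "))
  spectra <- as.data.frame(spectra)[need]
  bad_group <- setdiff(unique(spectra$group), .study_groups)
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  bad_phase <- setdiff(unique(spectra$phase), .study_phases)
  if (length(bad_phase))
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "))
  if (!all(spectra$hour %in% 1:4)) stop("hour must be in 1..4")
  ord <- order(spectra$liver_id, spectra$phase, spectra$hour,
               spectra$site, spectra$replicate, spectra$frequency_hz)
  spectra <- spectra[ord, , drop = FALSE]
  rownames(spectra) <- NULL

  key <- paste(spectra$liver_id, spectra$phase, spectra$hour,
               spectra$site, spectra$replicate, sep = "\r")
  n_rec <- length(unique(key))
  grid <- spectra$frequency_hz[key == key[1]]
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("each record must hold one strictly increasing frequency grid")
  if (nrow(spectra) != n_rec * length(grid) ||
      !all(spectra$frequency_hz == rep(grid, n_rec)))
    stop("all spectra must share one frequency grid")
  rec <- spectra[!duplicated(key),
                 c("liver_id", "phase", "hour", "site", "replicate")]
  cnt <- aggregate(replicate ~ liver_id + phase + hour, data = rec,
                   FUN = length)
  if (any(cnt$replicate > 20))
    stop("at most 2 sites x 10 replicates per (liver, phase, hour)")
  if (!is.null(weights)) {
    wneed <- c("liver_id", "group", "pre_g", "post_g")
    if (!all(wneed %in% names(weights)))
      stop("weights needs columns: ", paste(wneed, collapse = ", "))
    weights <- as.data.frame(weights)[wneed]
  }
  structure(list(spectra = spectra, weights = weights, grid = grid,
                 config = config),
            class = "drs_study")
}

#' @export
print.drs_study <- function(x, ...) {
  k <- paste(x$spectra$liver_id, x$spectra$phase, x$spectra$hour,
             x$spectra$site, x$spectra$replicate, sep = "\r")
  cat(sprintf("<drs_study> %d spectra on a %d-point grid (%.3g-%.3g Hz)\n",
              length(unique(k)), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  livers: %d; groups: %s\n",
              length(unique(x$spectra$liver_id)),
              paste(sort(unique(x$spectra$group)), collapse = ", ")))
  invisible(x)
}

# Subset of the long table for one (phase, hour); optionally one group.
.study_subset <- function(study, phase, hour, group = NULL) {
  sp <- study$spectra
  keep <- sp$phase == phase & sp$hour == hour
  if (!is.null(group)) keep <- keep & sp$group %in% group
  sp[keep, , drop = FALSE]
}

# Liver-level means: one row per liver, one column per frequency.
# Relies on the canonical sort order of drs_study.
.liver_matrix <- function(study, phase, hour, group = NULL,
                          value = c("eps_imag", "eps_real", "sigma")) {
  value <- match.arg(value)
  sub <- .study_subset(study, phase, hour, group)
  if (!nrow(sub)) stop("no records for phase=", phase, ", hour=", hour)
  nf <- length(study$grid)
  v <- switch(value,
    eps_imag = sub$eps_imag,
    eps_real = sub$eps_real,
    sigma = 2 * pi * sub$frequency_hz * .eps0 * sub$eps_imag
  )
  livers <- split(v, sub$liver_id)
  out <- t(vapply(livers, function(x) rowMeans(matrix(x, nrow = nf)),
                  numeric(nf)))
  grp <- vapply(split(sub$group, sub$liver_id), `[`, character(1), 1)
  attr(out, "group") <- grp
  out
}

#' Average all replicate spectra of one liver
#'
#' Pointwise arithmetic mean of \eqn{\varepsilon'} and
#' \eqn{\varepsilon''} over all sites and replicates measured on a liver
#' at one (phase, hour), producing the liver-level spectrum that enters
#' fitting and group statistics.
#'
#' @param study A [drs_study()].
#' @param liver_id Liver identifier.
#' @param phase `"invivo"` or `"NMP"`.
#' @param hour Hour 1-4.
#' @return A [permittivity_spectrum()].
#' @export
average_replicates <- function(study, liver_id, phase, hour) {
  stopifnot(inherits(study, "drs_study"))
  sub <- study$spectra
  sub <- sub[sub$liver_id == liver_id & sub$phase == phase & sub$hour == hour, ]
  if (!nrow(sub))
    stop("no records for liver ", liver_id, ", phase ", phase, ", hour ", hour)
  nf <- length(study$grid)
  permittivity_spectrum(
    study$grid,
    rowMeans(matrix(sub$eps_real, nrow = nf)),
    rowMeans(matrix(sub$eps_imag, nrow = nf))
  )
}

#' Group mean and standard error
#'
#' Mean and standard error (sd / sqrt(N)) across liver-level values. For
#' a matrix (livers in rows, frequencies in columns) the summary is per
#' frequency; for a vector (one value per liver) it is scalar.
#'
#' @param x Numeric vector or matrix of liver-level values.
#' @return List with `mean`, `se`, `n`.
#' @export
#' @examples
#' group_summary(c(1, 2, 3)) # mean 2, se 0.577
group_summary <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n < 2) stop("group summary needs N >= 2 livers")
    list(mean = colMeans(x), se = apply(x, 2, sd) / sqrt(n), n = n)
  } else {
    n <- length(x)
    if (n < 2) stop("group summary needs N >= 2 livers")
    list(mean = mean(x), se = sd(x) / sqrt(n), n = n)
  }
}

#' Relative change in conductivity
#'
#' \eqn{\Delta\sigma(f) = (\sigma(f) - \sigma_{control}(f)) /
#' \sigma_{control}(f) \times 100}. The reference is the in vivo hour-1
#' control conductivity in the study design.
#'
#' @param sigma A [conductivity_spectrum()] (or numeric vector).
#' @param sigma_control Reference [conductivity_spectrum()] (or numeric
#'   vector) on the same grid, strictly positive.
#' @return Numeric vector of per-frequency changes in percent.
#' @export
relative_change <- function(sigma, sigma_control) {
  s <- if (inherits(sigma, "conductivity_spectrum")) sigma$sigma else sigma
  s0 <- if (inherits(sigma_control, "conductivity_spectrum"))
    sigma_control$sigma else sigma_control
  if (inherits(sigma, "conductivity_spectrum") &&
      inherits(sigma_control, "conductivity_spectrum") &&
      any(sigma$frequencies != sigma_control$frequencies))
    stop("sigma and sigma_control must share the frequency grid")
  if (length(s) != length(s0)) stop("lengths differ")
  if (any(s0 <= 0)) stop("reference conductivity must be positive everywhere")
  (s - s0) / s0 * 100
}

#' Sidak correction for multiple comparisons
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m}, clipped to \[0, 1\], where `m` is the
#' number of comparisons in the family.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size, integer >= 1.
#' @return Adjusted p-values.
#' @export
#' @examples
#' sidak_adjust(0.05, 2) # 0.0975
sidak_adjust <- function(p, m) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (length(m) != 1 || is.na(m) || m < 1)
    stop("family size m must be a single integer >= 1")
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Merge contiguous significant frequencies into ranges
#'
#' Maximal runs of consecutive grid points with adjusted p-value below
#' the threshold, reported in GHz as in the study's comparison tables.
#'
#' @param p_adjusted Adjusted p-values, one per grid point.
#' @param frequencies Frequency grid, Hz.
#' @param threshold Significance threshold (default 0.05).
#' @return Data frame with columns `f_low_ghz`, `f_high_ghz`; zero rows
#'   when nothing is significant.
#' @export
merge_significant_ranges <- function(p_adjusted, frequencies,
                                     threshold = 0.05) {
  if (length(p_adjusted) != length(frequencies))
    stop("p_adjusted and frequencies must have equal length")
  sig <- p_adjusted < threshold
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(f_low_ghz = frequencies[starts[keep]] / 1e9,
             f_high_ghz = frequencies[ends[keep]] / 1e9)
}

#' Render significance ranges in table style
#'
#' Formats the output of [merge_significant_ranges()] the way the
#' comparison tables print it, e.g. `"9.5-14 GHz"`, with `"NS"` for an
#' empty set.
#'
#' @param ranges Data frame from [merge_significant_ranges()].
#' @return A single string.
#' @export
format_ranges <- function(ranges) {
  if (!nrow(ranges)) return("NS")
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))
  paste(sprintf("%s-%s GHz", fmt(ranges$f_low_ghz), fmt(ranges$f_high_ghz)),
        collapse = "; ")
}

#' Per-frequency ANOVA with a Sidak-corrected pairwise contrast
#'
#' At each frequency point, fits a two-factor (group x hour) fixed-effects
#' ANOVA in its cell-means form on liver-level conductivity values for
#' one measurement phase, extracts the requested pairwise contrast via a
#' pooled-variance t statistic, applies the Sidak correction over the
#' contrast family, thresholds at `threshold` and merges contiguous
#' significant points into frequency ranges.
#'
#' The default family size is 6 for a within-group contrast (the six
#' hourly pairs of a four-hour phase) and 4 for a between-group contrast
#' (the four hourly time points); override with `family_size`.
#'
#' Cells with zero residual variance across all cells at a frequency are
#' degenerate: the contrast p-value is 0 when the two cell means differ
#' and 1 otherwise, with a warning.
#'
#' @param study A [drs_study()].
#' @param contrast List or vector `(group_a, hour_a, group_b, hour_b)`.
#' @param phase `"invivo"` or `"NMP"`.
#' @param family_size Number of comparisons in the Sidak family.
#' @param threshold Significance threshold on adjusted p-values.
#' @return An object of class `drs_comparison`: list with `frequencies`,
#'   `p_raw`, `p_adjusted`, `significant_ranges`, `contrast`,
#'   `family_size`, `threshold`.
#' @export
per_frequency_anova <- function(study, contrast, phase,
                                family_size = NULL, threshold = 0.05) {
  stopifnot(inherits(study, "drs_study"))
  contrast <- as.list(contrast)
  if (length(contrast) != 4)
    stop("contrast must be (group_a, hour_a, group_b, hour_b)")
  ga <- as.character(contrast[[1]]); ha <- as.integer(contrast[[2]])
  gb <- as.character(contrast[[3]]); hb <- as.integer(contrast[[4]])
  if (ga == gb && ha == hb) stop("contrast compares a cell with itself")
  if (is.null(family_size)) family_size <- if (ga == gb) 6L else 4L

  sp <- study$spectra
  phases_ok <- sp$phase == phase
  if (!any(phases_ok)) stop("no records for phase ", phase)
  cells <- unique(sp[phases_ok, c("group", "hour")])
  cell_stats <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    m <- .liver_matrix(study, phase, cells$hour[i], cells$group[i],
                       value = "sigma")
    if (nrow(m) < 2)
      stop("cell (", cells$group[i], ", hour ", cells$hour[i],
           ") has fewer than 2 livers")
    cell_stats[[i]] <- list(n = nrow(m), mean = colMeans(m),
                            ss = colSums(sweep(m, 2, colMeans(m))^2))
  }
  names(cell_stats) <- paste(cells$group, cells$hour)
  ka <- paste(ga, ha); kb <- paste(gb, hb)
  if (!ka %in% names(cell_stats) || !kb %in% names(cell_stats))
    stop("contrast cell missing from the study: ",
         paste(setdiff(c(ka, kb), names(cell_stats)), collapse = ", "))

  ss_within <- Reduce(`+`, lapply(cell_stats, `[[`, "ss"))
  df_within <- sum(vapply(cell_stats, `[[`, numeric(1), "n") - 1)
  mse <- ss_within / df_within
  a <- cell_stats[[ka]]; b <- cell_stats[[kb]]
  diff_mean <- a$mean - b$mean
  se <- sqrt(mse * (1 / a$n + 1 / b$n))
  p_raw <- numeric(length(se))
  ok <- se > 0
  p_raw[ok] <- 2 * pt(-abs(diff_mean[ok] / se[ok]), df_within)
  p_raw[!ok] <- ifelse(diff_mean[!ok] != 0, 0, 1)
  if (any(se == 0))
    warning("zero residual variance at ", sum(se == 0),
            " frequency point(s); degenerate p-values assigned")
  p_adj <- sidak_adjust(p_raw, family_size)
  ranges <- merge_significant_ranges(p_adj, study$grid, threshold)
  structure(
    list(frequencies = study$grid, p_raw = p_raw, p_adjusted = p_adj,
         significant_ranges = ranges,
         contrast = sprintf("%s %d h vs %s %d h, %s", ga, ha, gb, hb, phase),
         family_size = family_size, threshold = threshold),
    class = "drs_comparison"
  )
}

#' @export
print.drs_comparison <- function(x, ...) {
  cat(sprintf("<drs_comparison> %s (Sidak m = %d, p < %g)\n",
              x$contrast, x$family_size, x$threshold))
  cat("  significant:", format_ranges(x$significant_ranges), "\n")
  invisible(x)
}

#' All hourly pairwise comparisons within one group
#'
#' Runs [per_frequency_anova()] for every hour pair of one group and
#' phase, with the family size equal to the number of pairs (six for four
#' hours), mirroring the hourly-based comparison tables.
#'
#' @param study A [drs_study()].
#' @param group Group label.
#' @param phase Phase label.
#' @param hours Hours to compare (default 1:4).
#' @param threshold Significance threshold.
#' @return Named list of `drs_comparison` objects (`"1v2"`, `"1v3"`, ...).
#' @export
hourly_comparisons <- function(study, group, phase, hours = 1:4,
                               threshold = 0.05) {
  pairs <- utils::combn(hours, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    per_frequency_anova(study,
                        list(group, pairs[1, i], group, pairs[2, i]),
                        phase, family_size = m, threshold = threshold)
  })
  names(out) <- sprintf("%dv%d", pairs[1, ], pairs[2, ])
  out
}

#' Liver weight summary
#'
#' Arithmetic group means of pre- and post-machine-perfusion liver
#' weights and their difference. Livers with a missing weight are
#' excluded with a warning.
#'
#' @param weights Data frame with columns `liver_id`, `group`, `pre_g`,
#'   `post_g`.
#' @param group Optional group label to restrict to.
#' @return List with `mean_pre`, `mean_post`, `mean_increase` (grams) and
#'   `n`.
#' @export
#' @examples
#' weight_summary(data.frame(liver_id = "L1", group = "CON",
#'                           pre_g = 1666.9, post_g = 1755.3))
weight_summary <- function(weights, group = NULL) {
  if (!is.null(group)) weights <- weights[weights$group == group, ]
  ok <- !is.na(weights$pre_g) & !is.na(weights$post_g)
  if (any(!ok)) {
    warning(sum(!ok), " liver(s) excluded for missing weight")
    weights <- weights[ok, ]
  }
  if (!nrow(weights)) stop("no livers with both weights")
  list(mean_pre = mean(weights$pre_g),
       mean_post = mean(weights$post_g),
       mean_increase = mean(weights$post_g) - mean(weights$pre_g),
       n = nrow(weights))
}
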