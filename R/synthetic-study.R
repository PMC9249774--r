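#' Baseline liver Cole-Cole parameters
#'
#' Ground truth for a healthy control liver in vivo at hour 1 (the study
#' reference cell). The broadening values and the water relaxation time
#' are the characteristic liver values (alpha_1 = 0.06, alpha_2 = 0.16,
#' tau_2 = 7 ps); the water-pole strength delta_eps_2 = 37.614 is
#' calibrated so that the water-content estimate of this baseline against
#' the default deionized-water reference on the default grid equals the
#' control-liver level of 56.05%.
#'
#' @return A [cole_cole_params()] object.
#' @export
liver_baseline_default <- function() {
  cole_cole_params(eps_inf = 4, delta_eps_1 = 15, tau_1 = 0.8e-9,
                   alpha_1 = 0.06, delta_eps_2 = 37.614, tau_2 = 7e-12,
                   alpha_2 = 0.16)
}

#' Default group/phase/hour trend profiles
#'
#' Injury and perfusion trends expressed as target relative conductivity
#' changes (percent, vs the in vivo hour-1 control baseline) at the lower
#' and upper band edge. The generator converts each (low, high) pair into
#' multiplicative adjustments of the two relaxation strengths by solving
#' a 2 x 2 linear system using the baseline pole shares at the band
#' edges.
#'
#' The shipped values are calibrated to the experiment's qualitative
#' course: controls drift up ~2.5% (2 h) then ~7.5% (3-4 h) in the low
#' band in vivo; hepatic-artery-occluded (AHEP) livers climb from ~5% to
#' ~17% low-band and ~8% high-band; during normothermic machine perfusion
#' all groups start with a low-band drop and high-band rise that relaxes
#' towards baseline in controls, while AHEP conductivity rises again and
#' cold-stored (SCS) livers stay elevated in the high band (where the
#' water pole dominates, so their water content stays high).
#'
#' @return Data frame with columns `group`, `phase`, `hour`, `low_pct`,
#'   `high_pct`.
#' @export
default_trend_profiles <- function() {
  invivo_con <- data.frame(hour = 1:4,
                           low_pct = c(0, 2.5, 7.5, 7.5),
                           high_pct = c(0, 1, 2, 3))
  rbind(
    cbind(group = "CON", phase = "invivo", invivo_con),
    cbind(group = "AHEP", phase = "invivo",
          data.frame(hour = 1:4, low_pct = c(5, 9, 13, 17),
                     high_pct = c(2, 4, 6, 8))),
    cbind(group = "SCS", phase = "invivo", invivo_con),
    cbind(group = "CON", phase = "NMP",
          data.frame(hour = 1:4, low_pct = c(-12, -9, -6, -3),
                     high_pct = c(11, 8, 5, 2))),
    cbind(group = "AHEP", phase = "NMP",
          data.frame(hour = 1:4, low_pct = c(-13, -10, -7, -2),
                     high_pct = c(12, 9, 7, 9))),
    cbind(group = "SCS", phase = "NMP",
          data.frame(hour = 1:4, low_pct = c(-14, -11, -8, -4),
                     high_pct = c(13, 11, 10, 10)))
  )
}

#' Default liver weight parameters
#'
#' Group means of pre- and post-perfusion liver weight (grams), with a
#' common inter-liver standard deviation of 60 g used by the generator.
#'
#' @return Data frame with columns `group`, `pre_mean_g`, `post_mean_g`,
#'   `sd_g`.
#' @export
default_weight_params <- function() {
  data.frame(group = c("CON", "AHEP", "SCS"),
             pre_mean_g = c(1666.9, 1648.9, 1625.7),
             post_mean_g = c(1755.3, 1774.3, 1790.0),
             sd_g = 60)
}

#' Synthetic study configuration
#'
#' Defines the conditions of the emulated experiment: three groups
#' (CON/AHEP/SCS) of 7 livers, measured in vivo and during normothermic
#' machine perfusion at hours 1-4, at 2 sites x 10 replicates per
#' timepoint, on the 167-point 200 MHz-14 GHz grid, with 1% multiplicative
#' measurement noise and 5% inter-liver variability.
#'
#' @param n_livers_per_group Livers per group (default 7).
#' @param groups Group labels (subset of CON/AHEP/SCS).
#' @param phases Phase labels (subset of invivo/NMP).
#' @param hours Hourly timepoints (default 1:4).
#' @param grid Frequency grid, Hz (default [drs_grid()]).
#' @param n_sites,n_replicates Measurement scheme per (liver, phase,
#'   hour); defaults 2 sites x 10 replicates.
#' @param noise_sd Relative SD of the multiplicative Gaussian measurement
#'   noise, applied independently per frequency point to eps' and eps''.
#' @param inter_liver_cv Coefficient of variation of the lognormal
#'   per-liver multipliers on delta_eps_1, delta_eps_2, tau_1, tau_2.
#' @param alpha_jitter_sd SD of the additive per-liver jitter on alpha_1
#'   and alpha_2 (clipped to \[0, 0.3\]).
#' @param baseline Ground-truth [cole_cole_params()] of the reference
#'   cell.
#' @param trend_profiles Data frame as [default_trend_profiles()]; must
#'   cover every (group, phase, hour).
#' @param weight_params Data frame as [default_weight_params()].
#' @param seed Integer seed; the dataset is a pure function of the
#'   configuration including the seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_livers_per_group = 7,
                         groups = c("CON", "AHEP", "SCS"),
                         phases = c("invivo", "NMP"),
                         hours = 1:4,
                         grid = drs_grid(),
                         n_sites = 2, n_replicates = 10,
                         noise_sd = 0.01,
                         inter_liver_cv = 0.05,
                         alpha_jitter_sd = 0.005,
                         baseline = liver_baseline_default(),
                         trend_profiles = default_trend_profiles(),
                         weight_params = default_weight_params(),
                         seed = 1L) {
  if (!all(groups %in% .study_groups)) stop("unknown group label")
  if (!all(phases %in% .study_phases)) stop("unknown phase label")
  if (n_livers_per_group < 1 || n_sites < 1 || n_replicates < 1)
    stop("counts must be positive")
  if (n_sites > 2 || n_replicates > 10)
    stop("the measurement scheme allows at most 2 sites x 10 replicates")
  if (noise_sd < 0 || inter_liver_cv < 0 || alpha_jitter_sd < 0)
    stop("all variability parameters must be >= 0")
  stopifnot(inherits(baseline, "cole_cole_params"))
  needed <- expand.grid(group = groups, phase = phases, hour = hours,
                        stringsAsFactors = FALSE)
  have <- paste(trend_profiles$group, trend_profiles$phase,
                trend_profiles$hour)
  miss <- setdiff(paste(needed$group, needed$phase, needed$hour), have)
  if (length(miss))
    stop("trend_profiles missing cells: ", paste(miss, collapse = "; "))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed < 0 || seed > 2^31 - 10)
    stop("seed must be a non-negative integer below 2^31 - 10")
  seed <- as.integer(seed)
  structure(
    list(n_livers_per_group = n_livers_per_group, groups = groups,
         phases = phases, hours = hours, grid = grid, n_sites = n_sites,
         n_replicates = n_replicates, noise_sd = noise_sd,
         inter_liver_cv = inter_liver_cv, alpha_jitter_sd = alpha_jitter_sd,
         baseline = baseline, trend_profiles = trend_profiles,
         weight_params = weight_params, seed = seed),
    class = "study_config"
  )
}

# Per-liver lognormal multipliers (mean 1) on the four scale parameters
# plus additive alpha jitter. Drawn in one fixed order from the config
# seed so that generate_study() and ground_truth() agree exactly.
.liver_multipliers <- function(config) {
  ids <- as.vector(vapply(config$groups, function(g)
    paste0(g, "-", seq_len(config$n_livers_per_group)),
    character(config$n_livers_per_group)))
  n <- length(ids)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  cv <- config$inter_liver_cv
  sdlog <- sqrt(log(1 + cv^2))
  mult <- matrix(exp(rnorm(n * 4, -sdlog^2 / 2, sdlog)), nrow = n,
                 dimnames = list(ids, c("delta_eps_1", "delta_eps_2",
                                        "tau_1", "tau_2")))
  jit <- matrix(rnorm(n * 2, 0, config$alpha_jitter_sd), nrow = n,
                dimnames = list(ids, c("alpha_1", "alpha_2")))
  list(scale = mult, alpha = jit)
}

# Convert (low_pct, high_pct) conductivity targets into multiplicative
# adjustments (m1, m2) of the two relaxation strengths, using the
# baseline pole loss shares at the band edges.
.profile_multipliers <- function(config) {
  b <- config$baseline
  g <- config$grid
  comp <- separate_dispersions(b, g[c(1, length(g))])
  l1 <- comp$pole1$eps_imag; l2 <- comp$pole2$eps_imag
  tot <- l1 + l2
  s <- rbind(c(l1[1], l2[1]) / tot[1], c(l1[2], l2[2]) / tot[2])
  tp <- config$trend_profiles
  ab <- t(apply(tp[, c("low_pct", "high_pct")] / 100, 1,
                function(rhs) solve(s, rhs)))
  data.frame(group = tp$group, phase = tp$phase, hour = tp$hour,
             mult_1 = pmax(1 + ab[, 1], 0.05),
             mult_2 = pmax(1 + ab[, 2], 0.05))
}

.cell_params <- function(config, multipliers, profiles, group, liver_index,
                         phase, hour) {
  id <- paste0(group, "-", liver_index)
  if (!id %in% rownames(multipliers$scale)) stop("unknown liver: ", id)
  row <- profiles$group == group & profiles$phase == phase &
    profiles$hour == hour
  if (!any(row)) stop("no trend profile for (", group, ", ", phase, ", ",
                      hour, ")")
  b <- config$baseline
  m <- multipliers$scale[id, ]
  j <- multipliers$alpha[id, ]
  cole_cole_params(
    eps_inf = b$eps_inf,
    delta_eps_1 = b$delta_eps_1 * m[["delta_eps_1"]] * profiles$mult_1[row],
    tau_1 = b$tau_1 * m[["tau_1"]],
    alpha_1 = min(max(b$alpha_1 + j[["alpha_1"]], 0), 0.3),
    delta_eps_2 = b$delta_eps_2 * m[["delta_eps_2"]] * profiles$mult_2[row],
    tau_2 = b$tau_2 * m[["tau_2"]],
    alpha_2 = min(max(b$alpha_2 + j[["alpha_2"]], 0), 0.3)
  )
}

#' Ground-truth parameters of one study cell
#'
#' The exact Cole-Cole parameters used to generate the spectra of one
#' liver at one (phase, hour): baseline, times the liver's seeded
#' variability multipliers, times the cell's trend adjustment.
#' Deterministic given the configuration (including its seed), so fitted
#' parameters can be checked against it.
#'
#' @param config A [study_config()].
#' @param group Group label.
#' @param liver Liver index within the group (1-based).
#' @param phase Phase label.
#' @param hour Hour 1-4.
#' @return A [cole_cole_params()] object.
#' @export
ground_truth <- function(config, group, liver, phase, hour) {
  stopifnot(inherits(config, "study_config"))
  if (!group %in% config$groups) stop("unknown group: ", group)
  if (!liver %in% seq_len(config$n_livers_per_group))
    stop("liver index out of range")
  if (!phase %in% config$phases) stop("unknown phase: ", phase)
  if (!hour %in% config$hours) stop("unknown hour: ", hour)
  .cell_params(config, .liver_multipliers(config),
               .profile_multipliers(config), group, liver, phase, hour)
}

#' Generate a synthetic liver DRS study
#'
#' Emulates the porcine experiment: for each (group, liver, phase, hour)
#' the liver's ground-truth Cole-Cole parameters are evaluated on the
#' grid and `n_sites x n_replicates` spectra are emitted with independent
#' multiplicative Gaussian noise on eps' and eps'', clipped to physical
#' ranges (eps' >= 1, eps'' >= 0). Per-liver pre/post machine-perfusion
#' weights are drawn as Normal around the group means. Identical
#' configurations (including seed) produce identical datasets.
#'
#' @param config A [study_config()].
#' @return A [drs_study()].
#' @export
#' @examples
#' cfg <- study_config(n_livers_per_group = 2, n_replicates = 2,
#'                     grid = drs_grid(n = 20), seed = 7)
#' study <- generate_study(cfg)
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  multipliers <- .liver_multipliers(config)
  profiles <- .profile_multipliers(config)
  grid <- config$grid
  nf <- length(grid)
  nrep <- config$n_sites * config$n_replicates

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 1L)

  wp <- config$weight_params
  weights <- do.call(rbind, lapply(config$groups, function(g) {
    w <- wp[wp$group == g, ]
    n <- config$n_livers_per_group
    data.frame(liver_id = paste0(g, "-", seq_len(n)), group = g,
               pre_g = rnorm(n, w$pre_mean_g, w$sd_g),
               post_g = rnorm(n, w$post_mean_g, w$sd_g))
  }))

  cells <- expand.grid(liver = seq_len(config$n_livers_per_group),
                       group = config$groups, phase = config$phases,
                       hour = config$hours, stringsAsFactors = FALSE)
  cells <- cells[order(cells$group, cells$liver, cells$phase, cells$hour), ]
  parts <- vector("list", nrow(cells))
  site_col <- rep(rep(seq_len(config$n_sites), each = config$n_replicates),
                  each = nf)
  rep_col <- rep(rep(seq_len(config$n_replicates), times = config$n_sites),
                 each = nf)
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    p <- .cell_params(config, multipliers, profiles, ci$group, ci$liver,
                      ci$phase, ci$hour)
    s <- cole_cole_forward(p, grid)
    er <- matrix(s$eps_real, nf, nrep)
    ei <- matrix(s$eps_imag, nf, nrep)
    if (config$noise_sd > 0) {
      er <- er * matrix(rnorm(nf * nrep, 1, config$noise_sd), nf)
      ei <- ei * matrix(rnorm(nf * nrep, 1, config$noise_sd), nf)
    }
    parts[[i]] <- data.frame(
      liver_id = paste0(ci$group, "-", ci$liver), group = ci$group,
      phase = ci$phase, hour = ci$hour, site = site_col,
      replicate = rep_col, frequency_hz = rep(grid, nrep),
      eps_real = pmax(as.vector(er), 1), eps_imag = pmax(as.vector(ei), 0)
    )
  }
  drs_study(do.call(rbind, parts), weights = weights, config = config)
}
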