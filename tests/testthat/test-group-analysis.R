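test_that("replicate averaging is the pointwise mean over sites/replicates", {
  grid <- c(1e9, 2e9)
  mk <- function(site, rep, ei) data.frame(
    liver_id = "CON-1", group = "CON", phase = "invivo", hour = 1,
    site = site, replicate = rep, frequency_hz = grid, eps_real = 50,
    eps_imag = ei)
  one <- drs_study(mk(1, 1, c(10, 5)))
  s1 <- average_replicates(one, "CON-1", "invivo", 1)
  expect_equal(s1$eps_imag, c(10, 5))
  two <- drs_study(rbind(mk(1, 1, c(10, 5)), mk(2, 1, c(20, 7))))
  s2 <- average_replicates(two, "CON-1", "invivo", 1)
  expect_equal(s2$eps_imag, c(15, 6))
  expect_error(average_replicates(two, "CON-9", "invivo", 1), "no records")
})

test_that("replicate averaging with zero-mean noise lands within 3 SE", {
  set.seed(21)
  grid <- drs_grid(n = 30)
  truth <- cole_cole_forward(liver_params(), grid)
  n_rep <- 20; sd_rel <- 0.01
  rows <- do.call(rbind, lapply(seq_len(n_rep), function(r) data.frame(
    liver_id = "CON-1", group = "CON", phase = "invivo", hour = 1,
    site = 1 + (r > 10), replicate = ((r - 1) %% 10) + 1,
    frequency_hz = grid,
    eps_real = truth$eps_real * rnorm(30, 1, sd_rel),
    eps_imag = truth$eps_imag * rnorm(30, 1, sd_rel))))
  avg <- average_replicates(drs_study(rows), "CON-1", "invivo", 1)
  se <- truth$eps_imag * sd_rel / sqrt(n_rep)
  dev <- abs(avg$eps_imag - truth$eps_imag)
  expect_lt(mean(dev > 3 * se), 0.05) # ~0.3% expected beyond 3 SE
  expect_lt(mean(dev / se), 1.5)
})

test_that("group summary returns mean and sd/sqrt(N)", {
  g <- group_summary(c(1, 2, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$se, 1 / sqrt(3))
  expect_equal(group_summary(c(5, 5, 5, 5))$se, 0)
  m <- rbind(c(1, 10), c(2, 20), c(3, 30))
  gm <- group_summary(m)
  expect_equal(gm$mean, c(2, 20))
  expect_equal(gm$se, c(1, 10) / sqrt(3))
  expect_error(group_summary(3), "N >= 2")
})

test_that("relative conductivity change follows its definition", {
  grid <- c(1e9, 2e9)
  s0 <- conductivity_spectrum(grid, c(2, 4))
  expect_equal(relative_change(s0, s0), c(0, 0))
  s1 <- conductivity_spectrum(grid, c(2.2, 4.4))
  expect_equal(relative_change(s1, s0), c(10, 10))
  expect_error(relative_change(s1, conductivity_spectrum(grid, c(0, 4))),
               "positive")
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0.05, 2), 1 - 0.95^2)
  expect_equal(sidak_adjust(0.05, 2), 0.0975)
  expect_equal(sidak_adjust(c(0.2, 0.7), 1), c(0.2, 0.7))
  expect_equal(sidak_adjust(0, 50), 0)
  expect_equal(sidak_adjust(1, 3), 1)
  p <- seq(0, 1, by = 0.05)
  for (m in c(1, 2, 6, 20))
    expect_true(all(sidak_adjust(p, m) >= p - 1e-12))
  expect_true(all(diff(vapply(1:10, function(m) sidak_adjust(0.03, m),
                              numeric(1))) >= 0))
  expect_error(sidak_adjust(1.2, 2), "\\[0, 1\\]")
  expect_error(sidak_adjust(0.5, 0), "m must be")
})

test_that("significant ranges are maximal runs, formatted like the tables", {
  f <- seq(1e9, 14e9, length.out = 14)
  all_sig <- merge_significant_ranges(rep(0.01, 14), f)
  expect_equal(nrow(all_sig), 1)
  expect_equal(all_sig$f_low_ghz, 1)
  expect_equal(all_sig$f_high_ghz, 14)
  none <- merge_significant_ranges(rep(0.2, 14), f)
  expect_equal(nrow(none), 0)
  expect_equal(format_ranges(none), "NS")
  top <- merge_significant_ranges(c(rep(0.5, 10), rep(0.01, 4)), f)
  expect_equal(format_ranges(top), "11-14 GHz")
  two <- merge_significant_ranges(c(0.01, 0.01, 0.5, 0.5, rep(0.01, 10)), f)
  expect_equal(nrow(two), 2)
  expect_equal(two$f_high_ghz[2], 14)
})

test_that("per-frequency ANOVA separates groups offset by 10x the noise SD", {
  set.seed(31)
  study <- tiny_study(n = 7, hours = 1:2,
                      value_fn = function(l, h)
                        10 + (h == 2) * 5 + rnorm(1, 0, 0.5))
  cmp <- per_frequency_anova(study, list("CON", 1, "CON", 2), "invivo")
  expect_equal(nrow(cmp$significant_ranges), 1)
  expect_equal(cmp$significant_ranges$f_low_ghz, 1)
  expect_equal(cmp$significant_ranges$f_high_ghz, 2)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw))
})

test_that("per-frequency ANOVA under the null rarely flags anything", {
  set.seed(32)
  hits <- 0
  for (r in 1:50) {
    study <- tiny_study(n = 7, hours = 1:2,
                        value_fn = function(l, h) 10 * rnorm(1, 1, 0.05))
    cmp <- per_frequency_anova(study, list("CON", 1, "CON", 2), "invivo",
                               family_size = 1)
    hits <- hits + (cmp$p_adjusted[1] < 0.05)
  }
  expect_lte(hits / 50, 0.12) # ~alpha = 0.05 plus Monte-Carlo slack
})

test_that("ANOVA validates its contrast and degenerate cells", {
  study <- tiny_study(n = 3, hours = 1:2, value_fn = function(l, h) 10 + h)
  expect_error(per_frequency_anova(study, list("CON", 1, "CON", 1), "invivo"),
               "itself")
  expect_error(per_frequency_anova(study, list("CON", 1, "AHEP", 2), "invivo"),
               "missing")
  expect_warning(
    cmp <- per_frequency_anova(study, list("CON", 1, "CON", 2), "invivo"),
    "zero residual variance")
  expect_true(all(cmp$p_adjusted == 0)) # means differ, zero variance
})

test_that("hourly family uses six pairs for four hours", {
  set.seed(33)
  study <- tiny_study(n = 4, hours = 1:4,
                      value_fn = function(l, h) 10 + rnorm(1, 0, 0.3))
  fam <- hourly_comparisons(study, "CON", "invivo")
  expect_length(fam, 6)
  expect_true(all(vapply(fam, `[[`, numeric(1), "family_size") == 6))
  expect_named(fam, c("1v2", "1v3", "1v4", "2v3", "2v4", "3v4"))
})

test_that("group pipeline output is invariant to record shuffling", {
  set.seed(34)
  cfg <- study_config(n_livers_per_group = 3, n_replicates = 2,
                      grid = drs_grid(n = 12), seed = 5)
  study <- generate_study(cfg)
  shuffled <- drs_study(study$spectra[sample(nrow(study$spectra)), ],
                        weights = study$weights)
  expect_equal(.subset2(study, "spectra"), .subset2(shuffled, "spectra"))
  m1 <- drsliver:::.liver_matrix(study, "invivo", 2, "AHEP", value = "sigma")
  m2 <- drsliver:::.liver_matrix(shuffled, "invivo", 2, "AHEP",
                                 value = "sigma")
  expect_identical(m1, m2)
})

test_that("weight summary reproduces the group mean increases exactly", {
  w <- data.frame(liver_id = c("A", "B"), group = "CON",
                  pre_g = c(1600, 1700), post_g = c(1700, 1820))
  ws <- weight_summary(w)
  expect_equal(ws$mean_increase, ws$mean_post - ws$mean_pre)
  expect_equal(ws$mean_increase, 110)
  same <- weight_summary(data.frame(liver_id = "A", group = "CON",
                                    pre_g = 1500, post_g = 1500))
  expect_equal(same$mean_increase, 0)
  w2 <- rbind(w, data.frame(liver_id = "C", group = "CON", pre_g = NA,
                            post_g = 1800))
  expect_warning(ws2 <- weight_summary(w2), "excluded")
  expect_equal(ws2$n, 2)
})
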