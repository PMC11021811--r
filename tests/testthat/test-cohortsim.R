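# Synthetic cohort generator: validation, determinism, variance
# calibration, DO admixture, curve and spectrum construction.

test_that("configuration validation names the offending field", {
  expect_error(trait_spec("x", var_frac_strain = 0.5, var_frac_sex = 0.2,
                          var_frac_res = 0.2, grand_mean = 1,
                          total_sd = 1),
               "sum to 1")
  expect_error(trait_spec("x", var_frac_strain = 0.5, var_frac_sex = 0.25,
                          var_frac_res = 0.25, grand_mean = 1,
                          total_sd = -1),
               "total_sd")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(do_admixture_concentration = 0),
               "do_admixture_concentration")
  expect_error(sim_config(strains = c("A", "A", "B")), "strains")
})

test_that("zero residual variance makes strain-sex mates identical and a fixed seed reproduces the table", {
  tr <- list(trait_spec("x", var_frac_strain = 0.8, var_frac_sex = 0.2,
                        var_frac_res = 0, grand_mean = 10, total_sd = 2))
  cfg <- sim_config(traits = tr, n_per_group = 4, seed = 5,
                    hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)
  spread <- tapply(tab$x, interaction(tab$strain, tab$sex),
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  expect_identical(tab, simulate_founder_cohort(cfg))
  do1 <- simulate_do_cohort(cfg, tab)
  do2 <- simulate_do_cohort(cfg, simulate_founder_cohort(cfg))
  expect_identical(do1, do2)
})

test_that("the ANOVA pipeline recovers the target variance fractions and the sample variance matches total_sd^2", {
  # large cohort: realized fractions and total variance both calibrated
  tr <- list(trait_spec("x", var_frac_strain = 0.8, var_frac_sex = 0.05,
                        var_frac_res = 0.15, grand_mean = 50,
                        total_sd = 5))
  fracs <- sapply(1:10, function(s) {
    cfg <- sim_config(traits = tr, n_per_group = 50, seed = s,
                      hyperglycemia = NULL)
    tab <- simulate_founder_cohort(cfg)
    o <- oracle_anova_ss(tab, "x")
    d <- anova_ss(tab, "x")
    # implementation agrees with the projection oracle on the cohort
    expect_lt(abs(d$SS_strain - o$SS_strain) / o$SS_strain, 1e-8)
    broad_sense_h2(d)$H2
  })
  expect_lt(abs(mean(fracs) - 0.8), 0.05)
  cfg <- sim_config(traits = tr, n_per_group = 63, seed = 2,
                    hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)  # 1008 animals
  expect_lt(abs(stats::var(tab$x) / 25 - 1), 0.10)
})

test_that("hyperglycemia shifts elevate the configured strain-sex groups", {
  cfg <- sim_config(seed = 3)
  tab <- simulate_founder_cohort(cfg)
  grp <- function(s, x) tab$fbg[tab$strain == s & tab$sex == x]
  expect_true(mean(grp("NOD", "F")) > 250)
  expect_true(mean(grp("NZO", "M")) > 250)
  expect_true(mean(grp("B6", "F")) < 250)
  expect_true(all(classify_glycemia(grp("NOD", "F")) == "hyperglycemic") ||
                mean(classify_glycemia(grp("NOD", "F")) ==
                       "hyperglycemic") > 0.8)
})

test_that("DO strain effects are convex combinations of founder effects, one-hot in the alpha -> 0 limit", {
  cfg <- sim_config(traits = small_panel(), n_per_group = 4,
                    n_do_per_sex = 10, seed = 9, hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)
  do_tab <- simulate_do_cohort(cfg, tab)
  model <- attr(tab, "sim_model")
  eff <- attr(do_tab, "strain_effects_applied")
  for (nm in colnames(eff)) {
    a <- model$traits[[nm]]$strain_effects
    expect_true(all(eff[, nm] >= min(a) - 1e-12))
    expect_true(all(eff[, nm] <= max(a) + 1e-12))
  }
  w <- attr(do_tab, "do_weights")
  expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-12)
  # degenerate Dirichlet: each animal's effect equals one founder's effect
  cfg0 <- sim_config(traits = small_panel(), n_per_group = 4,
                     n_do_per_sex = 10, seed = 9,
                     do_admixture_concentration = 1e-9,
                     hyperglycemia = NULL)
  do0 <- simulate_do_cohort(cfg0, simulate_founder_cohort(cfg0))
  eff0 <- attr(do0, "strain_effects_applied")
  a <- attr(simulate_founder_cohort(cfg0),
            "sim_model")$traits[["tA"]]$strain_effects
  expect_true(all(vapply(eff0[, "tA"], function(e)
    min(abs(e - a)) < 1e-9, TRUE)))
  expect_error(simulate_do_cohort(cfg, NULL), "founder_effects")
})

test_that("DO cohorts attenuate the extremes of strain-dominated traits", {
  strain_dom <- c("bmc", "ct_th", "tmd", "lc_n_density")
  res <- sapply(1:25, function(s) {
    cfg <- sim_config(seed = s)
    tab <- simulate_founder_cohort(cfg)
    do_tab <- simulate_do_cohort(cfg, tab)
    sapply(strain_dom, function(tr)
      c(contained = min(do_tab[[tr]]) >= min(tab[[tr]]) &&
          max(do_tab[[tr]]) <= max(tab[[tr]]),
        shrunk = stats::sd(do_tab[[tr]]) < stats::sd(tab[[tr]])))
  })
  contained <- res[seq(1, nrow(res), by = 2), ]
  shrunk <- res[seq(2, nrow(res), by = 2), ]
  expect_gte(mean(contained), 0.9)
  expect_gte(mean(shrunk), 0.9)
})

test_that("simulated bending curves are physically admissible and noiselessly exact", {
  truth <- mechanical_truth(K = 100, Fy = 6, Fu = 8, PYD = 0.3)
  cv <- simulate_bend_curve(truth, noise_sd = 0)
  expect_true(all(diff(cv$displacement) > 0))
  expect_identical(max(cv$force), 8)
  # least-squares slope of the elastic segment equals K to machine tol
  el <- cv$displacement <= 6 / 100
  slope <- stats::coef(stats::lm(cv$force[el] ~ cv$displacement[el]))[2]
  expect_equal(unname(slope), 100, tolerance = 1e-10)
  expect_error(mechanical_truth(K = 100, Fy = 9, Fu = 8, PYD = 0.3),
               "Fy")
  expect_error(simulate_bend_curve(truth, n_points = 20), "n_points")
  cvn <- simulate_bend_curve(truth, noise_sd = 0.05, seed = 1)
  expect_identical(cvn$force,
                   simulate_bend_curve(truth, noise_sd = 0.05,
                                       seed = 1)$force)
})

test_that("simulated Raman spectra integrate to the requested band areas", {
  flat <- simulate_raman_spectrum(c(v1_phosphate = 0), fwhm_v1 = 20,
                                  noise_sd = 0)
  expect_true(all(flat$intensity == 0))
  sp <- simulate_raman_spectrum(c(v1_phosphate = 10), fwhm_v1 = 20,
                                noise_sd = 0)
  expect_lt(abs(pracma::trapz(sp$wavenumber, sp$intensity) / 10 - 1),
            0.001)
  expect_error(simulate_raman_spectrum(c(v1_phosphate = -1),
                                       fwhm_v1 = 20), "areas")
  expect_error(simulate_raman_spectrum(c(v1_phosphate = 1), fwhm_v1 = 0),
               "fwhm_v1")
  expect_error(simulate_raman_spectrum(c(nope = 1), fwhm_v1 = 20),
               "unknown bands")
})
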