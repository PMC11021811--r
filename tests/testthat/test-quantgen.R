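# ANOVA decomposition, heritability, mass adjustment, covariate check,
# post hoc comparisons, glycemia classification.

test_that("anova_ss handles constructed and degenerate designs", {
  d <- expand.grid(rep = 1:2, sex = c("F", "M"), strain = c("A", "B"),
                   stringsAsFactors = FALSE)
  d$y <- 10 * (d$strain == "A")
  a <- anova_ss(d, "y")
  expect_equal(a$SS_strain, 200, tolerance = 1e-10)
  expect_equal(a$SS_sex, 0, tolerance = 1e-10)
  expect_equal(a$SS_res, 0, tolerance = 1e-10)
  d$y <- 5
  a0 <- anova_ss(d, "y")
  expect_true(a0$degenerate)
  expect_identical(c(a0$SS_strain, a0$SS_sex, a0$SS_res), c(0, 0, 0))
  d1 <- d
  d1$strain <- "A"
  expect_error(anova_ss(d1, "y"), "design error")
  d2 <- d
  d2$sex <- "F"
  expect_error(anova_ss(d2, "y"), "design error")
  # aliased layout: each strain observed in only one sex
  d3 <- data.frame(strain = rep(c("A", "B"), each = 4),
                   sex = rep(c("F", "M"), each = 4),
                   y = stats::rnorm(8))
  expect_error(anova_ss(d3, "y"), "aliased")
})

test_that("anova_ss equals the brute-force projection oracle on random unbalanced toys", {
  set.seed(71)
  for (i in 1:100) {
    d <- random_toy_design()
    for (tp in c("I", "III")) {
      a <- anova_ss(d, "y", ss_type = tp)
      o <- oracle_anova_ss(d, "y", tp)
      scale <- max(abs(unlist(o)), 1e-8)
      expect_lt(abs(a$SS_strain - o$SS_strain) / scale, 1e-8)
      expect_lt(abs(a$SS_sex - o$SS_sex) / scale, 1e-8)
      expect_lt(abs(a$SS_res - o$SS_res) / scale, 1e-8)
    }
  }
})

test_that("heritability components follow the sum-of-squares quotients and H2 stays in [0, 1]", {
  mk <- function(SSs, SSx, SSr, n_avg = 4, df_sex = 1, df_res = 10) {
    structure(list(trait = "x", SS_strain = SSs, SS_sex = SSx,
                   SS_res = SSr, n_avg = n_avg, df_sex = df_sex,
                   df_res = df_res, n_used = 32, model = "additive",
                   degenerate = FALSE),
              class = "anova_decomposition")
  }
  h <- broad_sense_h2(mk(80, 5, 30))
  expect_equal(h$sigma2_strain, 20)
  expect_equal(h$sigma2_sex, 5)
  expect_equal(h$sigma2_res, 3)
  expect_equal(h$H2, 20 / 28)
  expect_equal(broad_sense_h2(mk(10, 0, 0))$H2, 1)
  expect_equal(broad_sense_h2(mk(0, 5, 30))$H2, 0)
  h0 <- broad_sense_h2(mk(0, 0, 0))
  expect_equal(h0$H2, 0)
  expect_true(h0$degenerate)
  set.seed(5)
  for (i in 1:50) {
    d <- random_toy_design()
    h <- broad_sense_h2(anova_ss(d, "y"))
    expect_gte(h$H2, 0)
    expect_lte(h$H2, 1)
  }
})

test_that("simulated cohorts at a 0.9 strain-variance target recover H2 within 0.05", {
  tr <- list(trait_spec("x", var_frac_strain = 0.9, var_frac_sex = 0.02,
                        var_frac_res = 0.08, grand_mean = 10,
                        total_sd = 2))
  h2s <- sapply(1:30, function(s) {
    cfg <- sim_config(traits = tr, seed = s, hyperglycemia = NULL)
    broad_sense_h2(anova_ss(simulate_founder_cohort(cfg), "x"))$H2
  })
  expect_lt(abs(mean(h2s) - 0.9), 0.05)
})

test_that("mass slopes: exact allometry is kept, mean-of-means reference, small strains zeroed", {
  set.seed(21)
  d <- data.frame(
    strain = rep(c("s1", "s2"), each = 6),
    sex = rep(c("F", "M"), 6),
    population = "founder",
    body_mass = c(20, 22, 25, 27, 28, 30, 30, 32, 35, 36, 38, 40))
  d$y <- 2 * d$body_mass + ifelse(d$strain == "s1", 5, -5)
  m <- fit_mass_slopes(d, "y")
  expect_equal(m$slopes$slope, c(2, 2), tolerance = 1e-10)
  expect_false(any(m$slopes$zeroed))
  expect_equal(m$grand_mean_mass, mean(c(mean(d$body_mass[1:6]),
                                         mean(d$body_mass[7:12]))))
  adj <- apply_mass_adjustment(d, "y", m)
  expect_lt(max(tapply(adj, d$strain, function(v) diff(range(v)))), 1e-9)
  # toy from two strains with masses {20,25,30} and {30,35,40}
  d2 <- data.frame(strain = rep(c("a", "b"), each = 3),
                   sex = rep(c("F", "M", "F"), 2), population = "founder",
                   body_mass = c(20, 25, 30, 30, 35, 40))
  d2$y <- d2$body_mass * 3
  expect_equal(fit_mass_slopes(d2, "y")$grand_mean_mass, 30)
  # a strain with < 3 usable animals is zeroed with its own flag
  d3 <- rbind(d, data.frame(strain = "s3", sex = c("F", "M"),
                            population = "founder",
                            body_mass = c(25, 26), y = c(1, 2)))
  m3 <- fit_mass_slopes(d3, "y")
  row <- m3$slopes[m3$slopes$strain == "s3", ]
  expect_true(row$zeroed)
  expect_identical(row$reason, "insufficient_data")
})

test_that("adjustment follows the per-strain formula and zeroed strains pass through", {
  model <- structure(list(
    trait = "y", mass_col = "body_mass",
    slopes = data.frame(strain = c("a", "b"), slope = c(2, 0),
                        p = c(0.01, 0.5), n = c(5, 5),
                        zeroed = c(FALSE, TRUE),
                        reason = c("kept", "p_above_threshold")),
    grand_mean_mass = 30), class = "adjustment_model")
  d <- data.frame(strain = c("a", "b"), body_mass = c(35, 35),
                  y = c(100, 100))
  expect_equal(apply_mass_adjustment(d, "y", model), c(90, 100))
  d$strain <- c("a", "zz")
  expect_error(apply_mass_adjustment(d, "y", model), "zz")
})

test_that("adjusted traits are uncorrelated with mass within non-zeroed strains, and re-adjustment is idempotent", {
  tr <- list(trait_spec("x", var_frac_strain = 0.5, var_frac_sex = 0.02,
                        var_frac_res = 0.48, grand_mean = 10, total_sd = 2,
                        mass_slope = 0.8))
  cfg <- sim_config(traits = tr, seed = 13, hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)
  m <- fit_mass_slopes(tab, "x")
  tab$x_adj <- apply_mass_adjustment(tab, "x", m)
  for (s in m$slopes$strain[!m$slopes$zeroed]) {
    sel <- tab$strain == s
    expect_lt(abs(stats::cor(tab$x_adj[sel], tab$body_mass[sel])), 1e-9)
  }
  # noiseless linear data adjusts to constants; refitting zeroes all slopes
  d <- data.frame(strain = rep(letters[1:4], each = 6),
                  sex = rep(c("F", "M"), 12), population = "founder",
                  body_mass = stats::runif(24, 20, 40))
  d$y <- 3 * d$body_mass
  m2 <- fit_mass_slopes(d, "y")
  d$y2 <- apply_mass_adjustment(d, "y", m2)
  m3 <- fit_mass_slopes(d, "y2")
  expect_true(all(m3$slopes$zeroed | abs(m3$slopes$slope) < 1e-9))
})

test_that("null mass slopes are retained at about the 20% rate implied by p > 0.20", {
  tr <- list(trait_spec("x", var_frac_strain = 0.5, var_frac_sex = 0.02,
                        var_frac_res = 0.48, grand_mean = 10,
                        total_sd = 2))
  kept <- unlist(lapply(1:40, function(s) {
    cfg <- sim_config(traits = tr, seed = s, hyperglycemia = NULL)
    m <- fit_mass_slopes(simulate_founder_cohort(cfg), "x")
    !m$slopes$zeroed
  }))
  expect_lt(abs(mean(kept) - 0.20), 0.06)
})

test_that("body-mass covariate p-values are extreme for exact dependence and calibrated under the null", {
  d <- expand.grid(rep = 1:5, sex = c("F", "M"),
                   strain = letters[1:4], stringsAsFactors = FALSE)
  set.seed(3)
  d$body_mass <- stats::runif(nrow(d), 20, 40)
  d$y <- d$body_mass
  expect_lt(covariate_significance(d, "y")$p_value, 1e-10)
  d$body_mass <- 25
  expect_true(covariate_significance(d, "y")$degenerate)
  # type-I calibration at alpha = 0.05
  set.seed(17)
  rej <- sapply(1:500, function(i) {
    d$body_mass <- stats::runif(nrow(d), 20, 40)
    d$y <- stats::rnorm(nrow(d))
    covariate_significance(d, "y")$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Sidak post hoc: identity at m = 1, monotone in m, adjusted >= raw, and powered for 2-SD shifts", {
  expect_equal(bonephen:::.sidak(0.04, 1), 0.04)
  p <- 0.02
  adj <- sapply(1:10, function(m) bonephen:::.sidak(p, m))
  expect_true(all(diff(adj) >= 0))
  set.seed(2)
  d <- data.frame(strain = rep(c("B6", "X"), each = 18),
                  sex = rep(rep(c("F", "M"), each = 9), 2))
  d$y <- stats::rnorm(36)
  ct <- strain_sex_posthoc(d, "y", ref = "B6")
  expect_true(all(ct$p_adj >= ct$p - 1e-12))
  expect_equal(ct$p_adj, ct$p)  # one contrast per sex family
  # identical groups (X duplicates B6 exactly): adjusted p is 1
  d2 <- d
  d2$y <- rep(stats::rnorm(18), 2)
  ct2 <- strain_sex_posthoc(d2, "y", ref = "B6")
  expect_true(all(ct2$p_adj > 0.95))
  expect_error(strain_sex_posthoc(d, "y", ref = "nope"), "nope")
  power <- sapply(1:200, function(s) {
    set.seed(s)
    d$y <- stats::rnorm(36) + ifelse(d$strain == "X", 2, 0)
    all(strain_sex_posthoc(d, "y", ref = "B6")$p_adj < 0.05)
  })
  expect_gte(mean(power), 0.95)
})

test_that("founder-vs-DO comparisons use the population factor within sex", {
  cfg <- sim_config(traits = small_panel(), n_per_group = 5,
                    n_do_per_sex = 12, seed = 31, hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)
  do_tab <- simulate_do_cohort(cfg, tab)
  both <- rbind(as.data.frame(tab), as.data.frame(do_tab))
  ct <- strain_sex_posthoc(both, "tA", family = "founder_vs_do")
  expect_identical(nrow(ct), 2L)
  expect_setequal(ct$sex, c("F", "M"))
  expect_true(all(ct$p >= 0 & ct$p <= 1))
  expect_error(strain_sex_posthoc(tab, "tA", family = "founder_vs_do"),
               "population")
})

test_that("glycemia classification uses the strict 250 mg/dL cutoff", {
  expect_identical(classify_glycemia(c(251, 250, 100, NA)),
                   c("hyperglycemic", "normal", "normal", NA))
  expect_error(classify_glycemia(-5), ">= 0")
})
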