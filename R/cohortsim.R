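# Synthetic founder / DO cohort generator.
#
# The generator is "estimator-calibrated" by default: strain and sex effects
# are drawn, then exactly centered and rescaled, and residuals are
# orthogonalized against the strain x sex design and rescaled, so that the
# two-factor ANOVA variance decomposition (see anova_ss / broad_sense_h2)
# recovers the requested variance fractions while the total sample variance
# equals total_sd^2. See the methods vignette for the algebra.

# Scale a centered vector to a requested sum of squared deviations.
.scale_to_ss <- function(u, target_ss) {
  u <- u - mean(u)
  ss <- sum(u^2)
  if (target_ss <= 0) return(u * 0)
  if (ss < .Machine$double.eps) {
    stop("degenerate draw: cannot rescale a zero-variance effect vector",
         call. = FALSE)
  }
  u * sqrt(target_ss / ss)
}

# Per-trait effect scales for a balanced S x 2 x n design.
# Returns list(ss_strain = target sum((a - mean a)^2), delta = half the
# sex-effect gap, sd_res = residual SD, ss_res = target sum(r^2)).
.effect_scales <- function(spec, S, N, mode) {
  T2 <- spec$total_sd^2
  fa <- spec$var_frac_strain
  fx <- spec$var_frac_sex
  fe <- spec$var_frac_res
  if (mode == "anova") {
    n_g <- N / S
    df_res <- N - S - 1
    C <- (N - 1) * T2 / (n_g * fa + fx + df_res * fe)
    list(ss_strain = fa * C,
         delta = sqrt(fx * C / N),
         sd_res = sqrt(fe * C),
         ss_res = fe * C * df_res)
  } else {
    list(ss_strain = S * fa * T2,
         delta = sqrt(fx * T2),
         sd_res = sqrt(fe * T2),
         ss_res = NA_real_)
  }
}

# Draw a strain-effect vector (possibly latent-correlated), standardized to
# the target sum of squared deviations. Fixed user effects pass through.
.draw_strain_effects <- function(spec, strains, z_strain, ss_target) {
  if (!is.null(spec$strain_effects)) {
    miss <- setdiff(strains, names(spec$strain_effects))
    if (length(miss)) {
      stop("trait '", spec$name, "': fixed strain_effects missing strains: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(spec$strain_effects[strains])
  }
  lam <- spec$latent_loading
  own <- stats::rnorm(length(strains))
  u <- if (!is.null(spec$latent_factor)) {
    lam * z_strain[[spec$latent_factor]] + sqrt(1 - lam^2) * own
  } else {
    own
  }
  a <- .scale_to_ss(u, ss_target)
  names(a) <- strains
  a
}

# Residual vector: latent-mixed iid noise; in "anova" mode orthogonalized
# against the strain x sex cells and rescaled to the exact target SS.
.draw_residuals <- function(spec, n, cell, z_res, scales, mode) {
  lam <- spec$latent_loading
  own <- stats::rnorm(n)
  r <- if (!is.null(spec$latent_factor)) {
    lam * z_res[[spec$latent_factor]] + sqrt(1 - lam^2) * own
  } else {
    own
  }
  if (mode == "anova") {
    r <- r - stats::ave(r, cell)
    if (scales$ss_res <= 0) return(r * 0)
    ss <- sum(r^2)
    if (ss < .Machine$double.eps) return(r * 0)
    r * sqrt(scales$ss_res / ss)
  } else {
    r * scales$sd_res
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hyper_shift <- function(hyper, strain, sex) {
  if (is.null(hyper) || nrow(hyper) == 0L) return(numeric(length(strain)))
  out <- numeric(length(strain))
  for (i in seq_len(nrow(hyper))) {
    out[strain == hyper$strain[i] & sex == hyper$sex[i]] <- hyper$shift[i]
  }
  out
}

#' Simulate an inbred founder cohort with known variance structure
#'
#' Generates one row per animal for `strains x {F, M} x n_per_group`,
#' with each trait built as
#' `grand_mean + strain effect + sex effect + mass_slope * (body mass - mean
#' body mass) + residual`. Strain effects are shared by strain-mates and, in
#' the default `variance_mode = "anova"`, all effects are standardized so the
#' realized two-factor ANOVA variance decomposition matches the
#' [trait_spec()] targets exactly and the total sample variance equals
#' `total_sd^2` (for traits with `mass_slope = 0`). Hyperglycemia shifts are
#' added to the `fbg` trait for the configured strain-sex groups.
#'
#' The returned table carries the generating model (strain effects, sex
#' effects, residual scales, reference body mass) as attribute
#' `"sim_model"`, consumed by [simulate_do_cohort()] and useful as ground
#' truth in validation studies.
#'
#' @param config A [sim_config()].
#' @return A `cohort_table` data frame: `animal_id`, `population` (
#'   `"founder"`), `strain`, `sex`, `body_mass`, then one column per trait.
#' @examples
#' cfg <- sim_config(n_per_group = 3, traits = default_trait_specs()[1:4],
#'                   seed = 42)
#' tab <- simulate_founder_cohort(cfg)
#' dim(tab)
#' @export
simulate_founder_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("simulate_founder_cohort: 'config' must be a sim_config",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  strains <- config$strains
  S <- length(strains)
  n <- config$n_per_group
  sexes <- c("F", "M")
  grid <- expand.grid(rep = seq_len(n), sex = sexes, strain = strains,
                      stringsAsFactors = FALSE)
  N <- nrow(grid)
  cell <- interaction(grid$strain, grid$sex, drop = TRUE)
  sex_sign <- ifelse(grid$sex == "M", 1, -1)

  all_specs <- c(list(config$mass_spec), config$traits)
  factors <- unique(unlist(lapply(all_specs, `[[`, "latent_factor")))
  z_strain <- stats::setNames(
    lapply(factors, function(f) stats::rnorm(S)), factors)
  z_res <- stats::setNames(
    lapply(factors, function(f) stats::rnorm(N)), factors)

  mode <- config$variance_mode
  model <- list(strains = strains, sexes = sexes, mode = mode,
                hyperglycemia = config$hyperglycemia, traits = list())

  # body mass first: other traits couple to it
  ms <- config$mass_spec
  msc <- .effect_scales(ms, S, N, mode)
  a_mass <- .draw_strain_effects(ms, strains, z_strain, msc$ss_strain)
  r_mass <- .draw_residuals(ms, N, cell, z_res, msc, mode)
  body_mass <- ms$grand_mean + a_mass[grid$strain] + msc$delta * sex_sign +
    r_mass
  if (any(body_mass <= 0)) {
    warning("simulated body masses <= 0 truncated to 1 g")
    body_mass <- pmax(body_mass, 1)
  }
  mass_ref <- mean(body_mass)
  model$mass <- list(spec = ms, strain_effects = a_mass, delta = msc$delta,
                     sd_res = msc$sd_res, mass_ref = mass_ref)

  out <- data.frame(
    animal_id = sprintf("F%03d", seq_len(N)),
    population = "founder",
    strain = grid$strain,
    sex = grid$sex,
    body_mass = as.numeric(body_mass),
    stringsAsFactors = FALSE)

  for (spec in config$traits) {
    sc <- .effect_scales(spec, S, N, mode)
    a <- .draw_strain_effects(spec, strains, z_strain, sc$ss_strain)
    r <- .draw_residuals(spec, N, cell, z_res, sc, mode)
    val <- spec$grand_mean + a[grid$strain] + sc$delta * sex_sign +
      spec$mass_slope * (body_mass - mass_ref) + r
    if (spec$name == "fbg") {
      val <- val + .hyper_shift(config$hyperglycemia, grid$strain, grid$sex)
    }
    out[[spec$name]] <- as.numeric(val)
    model$traits[[spec$name]] <-
      list(spec = spec, strain_effects = a, delta = sc$delta,
           sd_res = sc$sd_res)
  }

  if (config$dropout_rate > 0) {
    keep <- stats::runif(N) >= config$dropout_rate
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, sim_model = model, config = config,
            class = c("cohort_table", "data.frame"))
}

# Dirichlet(alpha) weight matrix (rows = animals). The alpha -> 0 limit is a
# one-hot draw (degenerate Dirichlet: all mass on a single founder).
.dirichlet_weights <- function(n, S, alpha) {
  if (alpha < 1e-6) {
    w <- matrix(0, n, S)
    w[cbind(seq_len(n), sample.int(S, n, replace = TRUE))] <- 1
    return(w)
  }
  g <- matrix(stats::rgamma(n * S, shape = alpha, rate = 1), n, S)
  rs <- rowSums(g)
  bad <- rs < 1e-100
  if (any(bad)) {
    g[bad, ] <- 0
    g[cbind(which(bad), sample.int(S, sum(bad), replace = TRUE))] <- 1
    rs <- rowSums(g)
  }
  g / rs
}

#' Simulate a Diversity Outbred cohort as founder admixtures
#'
#' Each DO animal receives one Dirichlet(alpha)-distributed weight vector
#' over the founder strains, shared across all traits (preserving trait
#' correlations), and its strain-level effect is the corresponding convex
#' combination of the founder strain effects (including any strain-sex
#' hyperglycemia shifts). Residual noise is drawn at the founder residual
#' scale. Convex mixing produces hybrid phenotypes whose strain-effect
#' components always lie inside the founder effect range, so extreme founder
#' phenotypes are attenuated in the DO population.
#'
#' @param config A [sim_config()]; `n_do_per_sex` and
#'   `do_admixture_concentration` control the cohort.
#' @param founder_effects The `"sim_model"` attribute of a
#'   [simulate_founder_cohort()] result (or that table itself).
#' @return A `cohort_table` with `population = "DO"`, `strain = "DO"`.
#'   Attributes: `"do_weights"` (animals x strains admixture matrix) and
#'   `"strain_effects_applied"` (animals x traits matrix of the convex
#'   strain-effect component), for validation.
#' @export
simulate_do_cohort <- function(config, founder_effects) {
  if (!inherits(config, "sim_config")) {
    stop("simulate_do_cohort: 'config' must be a sim_config", call. = FALSE)
  }
  if (missing(founder_effects) || is.null(founder_effects)) {
    stop("simulate_do_cohort: 'founder_effects' is required - run ",
         "simulate_founder_cohort first", call. = FALSE)
  }
  if (inherits(founder_effects, "cohort_table")) {
    founder_effects <- attr(founder_effects, "sim_model")
  }
  if (is.null(founder_effects$mass) || is.null(founder_effects$traits)) {
    stop("simulate_do_cohort: 'founder_effects' does not look like a ",
         "sim_model (missing mass/traits components)", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  fe <- founder_effects
  strains <- fe$strains
  S <- length(strains)
  n_do <- 2L * config$n_do_per_sex
  if (n_do == 0L) {
    stop("simulate_do_cohort: n_do_per_sex is 0", call. = FALSE)
  }
  sex <- rep(c("F", "M"), each = config$n_do_per_sex)
  sex_sign <- ifelse(sex == "M", 1, -1)
  w <- .dirichlet_weights(n_do, S, config$do_admixture_concentration)
  colnames(w) <- strains

  # DO residuals share the founder latent-factor structure so the outbred
  # environmental covariance matches the founders'
  all_specs <- c(list(fe$mass$spec), lapply(fe$traits, `[[`, "spec"))
  factors <- unique(unlist(lapply(all_specs, `[[`, "latent_factor")))
  z_res <- stats::setNames(
    lapply(factors, function(f) stats::rnorm(n_do)), factors)
  mix_resid <- function(spec, sd_res) {
    lam <- spec$latent_loading
    own <- stats::rnorm(n_do)
    r <- if (!is.null(spec$latent_factor)) {
      lam * z_res[[spec$latent_factor]] + sqrt(1 - lam^2) * own
    } else {
      own
    }
    sd_res * r
  }

  m <- fe$mass
  mass <- m$spec$grand_mean + as.numeric(w %*% m$strain_effects) +
    m$delta * sex_sign + mix_resid(m$spec, m$sd_res)
  mass <- pmax(mass, 1)

  out <- data.frame(
    animal_id = sprintf("DO%03d", seq_len(n_do)),
    population = "DO", strain = "DO", sex = sex,
    body_mass = as.numeric(mass), stringsAsFactors = FALSE)

  eff_applied <- matrix(NA_real_, n_do, length(fe$traits),
                        dimnames = list(NULL, names(fe$traits)))
  for (nm in names(fe$traits)) {
    tr <- fe$traits[[nm]]
    a <- tr$strain_effects[strains]
    if (nm == "fbg" && !is.null(fe$hyperglycemia) &&
        nrow(fe$hyperglycemia) > 0L) {
      # strain-sex shifts enter the mixed effect per animal's own sex
      shift_mat <- sapply(strains, function(s)
        .hyper_shift(fe$hyperglycemia, rep(s, n_do), sex))
      eff <- rowSums(w * sweep(shift_mat, 2, a, `+`))
    } else {
      eff <- as.numeric(w %*% a)
    }
    eff_applied[, nm] <- eff
    out[[nm]] <- tr$spec$grand_mean + eff + tr$delta * sex_sign +
      tr$spec$mass_slope * (mass - m$mass_ref) +
      mix_resid(tr$spec, tr$sd_res)
  }
  structure(out, do_weights = w, strain_effects_applied = eff_applied,
            class = c("cohort_table", "data.frame"))
}

#' Ground-truth mechanical parameters for a simulated bending test
#'
#' @param K Stiffness, N/mm (> 0).
#' @param Fy Yield force, N (0 < Fy <= Fu).
#' @param Fu Ultimate force, N.
#' @param PYD Post-yield displacement, mm (>= 0).
#' @param geometry Optional [beam_geometry()].
#' @return Object of class `mechanical_truth`.
#' @export
mechanical_truth <- function(K, Fy, Fu, PYD, geometry = NULL) {
  if (!all(is.finite(c(K, Fy, Fu, PYD))) || K <= 0 || Fy <= 0 || Fu <= 0 ||
      PYD < 0) {
    stop("mechanical_truth: K, Fy, Fu must be > 0 and PYD >= 0",
         call. = FALSE)
  }
  if (Fy > Fu) {
    stop("mechanical_truth: Fy must be <= Fu", call. = FALSE)
  }
  structure(list(K = K, Fy = Fy, Fu = Fu, PYD = PYD, geometry = geometry),
            class = "mechanical_truth")
}

#' Simulate a three-point-bending force-displacement curve
#'
#' Builds a piecewise test record from ground truth: a linear elastic
#' segment of slope `K` up to the yield point (`Fy`, at `Fy/K` mm), linear
#' hardening to the ultimate force `Fu` at half the post-yield displacement,
#' gentle softening to 90% of `Fu` at the fracture displacement
#' (`Fy/K + PYD`), then an abrupt drop to 2% of `Fu` (fracture). Breakpoint
#' displacements are inserted into the sampling grid so the noiseless curve
#' attains `Fu` exactly. Additive Gaussian force noise emulates load-cell
#' noise.
#'
#' @param truth A [mechanical_truth()].
#' @param noise_sd Gaussian force noise SD, N.
#' @param n_points Number of samples (>= 50).
#' @param seed Optional integer seed.
#' @param span Support span, mm (metadata; default 7).
#' @return An [fd_curve()].
#' @export
simulate_bend_curve <- function(truth, noise_sd = 0, n_points = 600L,
                                seed = NULL, span = 7) {
  if (!inherits(truth, "mechanical_truth")) {
    stop("simulate_bend_curve: 'truth' must be a mechanical_truth",
         call. = FALSE)
  }
  if (n_points < 50) {
    stop("simulate_bend_curve: n_points must be >= 50", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d_y <- truth$Fy / truth$K
  d_peak <- d_y + 0.5 * truth$PYD
  d_fail <- d_y + truth$PYD
  d_end <- d_fail * 1.04 + 1e-4
  d <- sort(unique(c(seq(0, d_end, length.out = n_points - 3L),
                     d_y, d_peak, d_fail)))
  d <- d[c(TRUE, diff(d) > 1e-12)]
  f <- numeric(length(d))
  el <- d <= d_y
  f[el] <- truth$K * d[el]
  if (d_peak > d_y) {
    hd <- d > d_y & d <= d_peak
    f[hd] <- truth$Fy +
      (truth$Fu - truth$Fy) * (d[hd] - d_y) / (d_peak - d_y)
  }
  if (d_fail > d_peak) {
    sf <- d > d_peak & d <= d_fail
    f[sf] <- truth$Fu * (1 - 0.10 * (d[sf] - d_peak) / (d_fail - d_peak))
  }
  f[d > d_fail] <- 0.02 * truth$Fu
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  fd_curve(displacement = d, force = f, span = span)
}

# canonical bone Raman band centers (cm^-1) for the synthetic generator
.default_band_centers <- function() {
  c(v2_phosphate = 431, proline = 857, v1_phosphate = 960,
    v1_carbonate = 1072, amideIII = 1250)
}

.default_band_sigmas <- function() {
  c(v2_phosphate = 10, proline = 9, v1_phosphate = 8,
    v1_carbonate = 10, amideIII = 18)
}

#' Simulate a bone Raman spectrum with known band areas
#'
#' The spectrum is a sum of Gaussian bands at canonical bone-matrix band
#' centers (v2 phosphate 431, proline/hydroxyproline 857, v1 phosphate 960,
#' v1 carbonate 1072, amide III 1250 cm-1) with the requested integrated
#' areas, the v1 phosphate band given the requested full-width at
#' half-maximum, plus an optional polynomial baseline and Gaussian noise.
#'
#' @param band_areas Named numeric vector of integrated areas (a.u. * cm-1);
#'   names among `v1_phosphate`, `v2_phosphate`, `amideIII`, `proline`,
#'   `v1_carbonate`. All areas must be >= 0.
#' @param fwhm_v1 Full-width at half-maximum of the v1 phosphate band,
#'   cm-1 (> 0).
#' @param baseline_coeffs Polynomial coefficients (constant first) of the
#'   baseline, evaluated in the scaled coordinate
#'   `x = (wavenumber - 1050) / 750` (so coefficients stay O(1)).
#' @param noise_sd Gaussian intensity noise SD (a.u.).
#' @param seed Optional integer seed.
#' @param wavenumber Sampling grid, cm-1 (default 300-1800 in 1 cm-1 steps).
#' @return A [raman_spectrum()].
#' @export
simulate_raman_spectrum <- function(band_areas, fwhm_v1,
                                    baseline_coeffs = 0, noise_sd = 0,
                                    seed = NULL,
                                    wavenumber = seq(300, 1800, by = 1)) {
  if (is.null(names(band_areas)) || !is.numeric(band_areas)) {
    stop("simulate_raman_spectrum: band_areas must be a named numeric ",
         "vector", call. = FALSE)
  }
  if (any(band_areas < 0)) {
    stop("simulate_raman_spectrum: band areas must be >= 0", call. = FALSE)
  }
  if (!is.finite(fwhm_v1) || fwhm_v1 <= 0) {
    stop("simulate_raman_spectrum: fwhm_v1 must be > 0", call. = FALSE)
  }
  centers <- .default_band_centers()
  sigmas <- .default_band_sigmas()
  unknown <- setdiff(names(band_areas), names(centers))
  if (length(unknown)) {
    stop("simulate_raman_spectrum: unknown bands: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sigmas["v1_phosphate"] <- fwhm_v1 / (2 * sqrt(2 * log(2)))
  if (!is.null(seed)) set.seed(seed)
  y <- numeric(length(wavenumber))
  for (b in names(band_areas)) {
    y <- y + band_areas[[b]] *
      stats::dnorm(wavenumber, centers[[b]], sigmas[[b]])
  }
  x <- (wavenumber - 1050) / 750
  y <- y + as.numeric(outer(x, seq_along(baseline_coeffs) - 1, `^`) %*%
                        baseline_coeffs)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  raman_spectrum(wavenumber, y)
}
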