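#' Trait specification for the synthetic cohort generator
#'
#' A `trait_spec` declares one phenotype to simulate: its grand mean, total
#' standard deviation across the founder cohort, the target variance
#' fractions attributed to strain, sex and residual by the two-factor ANOVA
#' decomposition, an optional allometric coupling to body mass, and an
#' optional shared latent factor inducing cross-trait correlation.
#'
#' The three variance fractions must sum to 1. How they are realized in the
#' simulated data depends on the generator's `variance_mode`; see
#' [simulate_founder_cohort()].
#'
#' @param name Trait (column) label.
#' @param units Unit string, informational.
#' @param var_frac_strain,var_frac_sex,var_frac_res Target variance fractions
#'   in `[0, 1]`, summing to 1.
#' @param grand_mean Population grand mean, in trait units.
#' @param total_sd Total phenotypic standard deviation (> 0), trait units.
#' @param mass_slope Allometric coupling, trait units per gram of body mass;
#'   the trait gains `mass_slope * (body_mass - mean body mass)`.
#' @param latent_factor Optional label (`"size"`, `"material"`, or any other
#'   string) naming a latent factor shared with other traits, or `NULL`.
#' @param latent_loading Loading in `[-1, 1]` on the latent factor.
#' @param strain_effects Optional named numeric vector of fixed per-strain
#'   effects (trait units). When supplied the generator uses these verbatim
#'   ("fixed-effects" mode for this trait) instead of drawing random strain
#'   effects.
#' @return An object of class `trait_spec`.
#' @seealso [sim_config()], [default_trait_specs()]
#' @export
trait_spec <- function(name, units = "",
                       var_frac_strain, var_frac_sex, var_frac_res,
                       grand_mean, total_sd,
                       mass_slope = 0,
                       latent_factor = NULL, latent_loading = 0,
                       strain_effects = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  fr <- c(var_frac_strain, var_frac_sex, var_frac_res)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("trait_spec '", name,
         "': variance fractions must be finite and in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("trait_spec '", name, "': var_frac_strain + var_frac_sex + ",
         "var_frac_res must sum to 1 (got ", signif(sum(fr), 10), ")",
         call. = FALSE)
  }
  if (!is.finite(total_sd) || total_sd <= 0) {
    stop("trait_spec '", name, "': total_sd must be > 0", call. = FALSE)
  }
  if (!is.null(latent_factor)) {
    stopifnot(is.character(latent_factor), length(latent_factor) == 1L)
    if (abs(latent_loading) > 1) {
      stop("trait_spec '", name, "': latent_loading must be in [-1, 1]",
           call. = FALSE)
    }
  }
  if (!is.null(strain_effects) &&
      (is.null(names(strain_effects)) || !is.numeric(strain_effects))) {
    stop("trait_spec '", name,
         "': strain_effects must be a named numeric vector", call. = FALSE)
  }
  structure(
    list(name = name, units = units,
         var_frac_strain = var_frac_strain,
         var_frac_sex = var_frac_sex,
         var_frac_res = var_frac_res,
         grand_mean = grand_mean, total_sd = total_sd,
         mass_slope = mass_slope,
         latent_factor = latent_factor,
         latent_loading = if (is.null(latent_factor)) 0 else latent_loading,
         strain_effects = strain_effects),
    class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat(sprintf("<trait_spec> %s [%s]: mean %g, sd %g, fractions (%.3f, %.3f, %.3f)\n",
              x$name, x$units, x$grand_mean, x$total_sd,
              x$var_frac_strain, x$var_frac_sex, x$var_frac_res))
  invisible(x)
}

# Canonical 8 founder strain labels (short forms).
founder_strains <- function() {
  c("A/J", "B6", "129S1", "NOD", "NZO", "CAST", "PWK", "WSB")
}

#' Default synthetic trait panel
#'
#' The default panel mirrors a multi-scale cortical-bone study: whole-body
#' traits (body mass handled separately, bone mineral content, fasting blood
#' glucose), radial cortical morphology from microCT, whole-bone and
#' tissue-level mechanics from three-point bending, osteocyte lacunar
#' morphometry, and Raman compositional ratios. The strain-variance fraction
#' targets are the broad-sense heritability values typical of an inbred
#' founder panel (BMC most heritable at 0.993, post-yield displacement least
#' at 0.209); within-strain standard deviations are plausible defaults only,
#' since per-strain dispersions are rarely published.
#'
#' Size-related traits load on a shared `"size"` latent factor and
#' mineral/material traits on a `"material"` factor, reproducing the
#' block-correlation structure seen in founder panels (size, morphology and
#' strength co-vary; tissue mineral density and material properties co-vary).
#'
#' @param sex_frac Default sex-variance fraction used for every trait.
#' @return A list of [trait_spec()] objects.
#' @export
default_trait_specs <- function(sex_frac = 0.02) {
  spec <- function(name, units, h2, mean, sd, slope = 0, fac = NULL, load = 0) {
    sf <- min(sex_frac, (1 - h2) / 2)  # keep residual fraction positive
    trait_spec(name, units,
               var_frac_strain = h2, var_frac_sex = sf,
               var_frac_res = 1 - h2 - sf,
               grand_mean = mean, total_sd = sd, mass_slope = slope,
               latent_factor = fac, latent_loading = load)
  }
  list(
    # whole body
    spec("bmc", "mg", 0.993, 480, 60, slope = 8, fac = "size", load = 0.85),
    spec("fbg", "mg/dL", 0.91, 150, 30),
    # radius cortical morphology (microCT)
    spec("ct_th", "mm", 0.985, 0.26, 0.04, slope = 0.003, fac = "size", load = 0.7),
    spec("tmd", "mgHA/cm3", 0.967, 1150, 60, fac = "material", load = 0.85),
    spec("ct_ar", "mm2", 0.884, 0.55, 0.09, slope = 0.008, fac = "size", load = 0.85),
    spec("tt_ar", "mm2", 0.799, 1.05, 0.15, slope = 0.012, fac = "size", load = 0.8),
    spec("ma_ar", "mm2", 0.722, 0.50, 0.10, slope = 0.004, fac = "size", load = 0.5),
    spec("pmoi", "mm4", 0.799, 0.16, 0.04, slope = 0.004, fac = "size", load = 0.8),
    # whole-bone mechanics (3-point bending, radius)
    spec("stiffness", "N/mm", 0.776, 80, 18, slope = 1.2, fac = "size", load = 0.8),
    spec("ult_force", "N", 0.836, 8, 1.6, slope = 0.15, fac = "size", load = 0.8),
    spec("yield_force", "N", 0.718, 5.6, 1.2, slope = 0.10, fac = "size", load = 0.75),
    spec("pyd", "mm", 0.209, 0.30, 0.10),
    spec("work_to_fx", "mJ", 0.741, 2.2, 0.6, slope = 0.04, fac = "size", load = 0.6),
    # tissue-level material properties (beam theory)
    spec("ult_stress", "MPa", 0.746, 150, 25, fac = "material", load = 0.75),
    spec("yield_stress", "MPa", 0.717, 105, 20, fac = "material", load = 0.7),
    spec("modulus", "MPa", 0.684, 9000, 1800, fac = "material", load = 0.7),
    # osteocyte lacunar morphometry (XRM)
    spec("lc_n_density", "1/mm3", 0.966, 62000, 9000),
    spec("lc_sphericity", "", 0.887, 0.82, 0.03),
    spec("lc_sd_phi", "deg", 0.835, 20, 3),
    spec("v_vol_density", "%", 0.827, 0.55, 0.12),
    spec("lc_aspect_ratio", "", 0.755, 2.6, 0.25),
    spec("porosity", "%", 0.689, 1.3, 0.3),
    spec("lc_max_feret", "um", 0.634, 15, 1.5),
    spec("lc_vol_sa", "um", 0.535, 1.05, 0.08),
    spec("lc_vol_density", "%", 0.516, 1.1, 0.2),
    spec("lc_vol", "um3", 0.383, 280, 40),
    # Raman composition
    spec("mm_v1_proline", "", 0.80, 10, 1.2, fac = "material", load = 0.6),
    spec("mm_v2_amide3", "", 0.80, 1.1, 0.15, fac = "material", load = 0.6),
    spec("carb_phos", "", 0.75, 0.30, 0.04, fac = "material", load = 0.5),
    spec("crystallinity", "cm", 0.70, 0.056, 0.004, fac = "material", load = 0.5)
  )
}

#' Default body-mass specification
#'
#' Body mass is simulated first and other traits may couple to it through
#' their `mass_slope`. The strain fraction target matches the body-weight
#' heritability typical of founder panels (0.84).
#'
#' @return A [trait_spec()] for `body_mass` (grams).
#' @export
default_mass_spec <- function() {
  trait_spec("body_mass", "g",
             var_frac_strain = 0.84, var_frac_sex = 0.04,
             var_frac_res = 0.12,
             grand_mean = 27, total_sd = 6, mass_slope = 0,
             latent_factor = "size", latent_loading = 0.9)
}

#' Simulation configuration
#'
#' Bundles everything the cohort generator needs: strain labels, group
#' sizes, the trait panel, the Dirichlet admixture concentration for the DO
#' cohort, hyperglycemia shifts, optional dropout, and the seed.
#'
#' @param strains Character vector of strain labels (default: the 8 founder
#'   strains A/J, B6, 129S1, NOD, NZO, CAST, PWK, WSB).
#' @param n_per_group Animals per strain-by-sex cell (>= 2; default 9).
#' @param n_do_per_sex DO animals per sex (default 25).
#' @param traits List of [trait_spec()] objects (default panel:
#'   [default_trait_specs()]).
#' @param mass_spec A [trait_spec()] for body mass.
#' @param do_admixture_concentration Dirichlet concentration alpha > 0 for
#'   DO founder-admixture weights (default 0.5).
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @param variance_mode `"anova"` (default) calibrates effect scales so the
#'   two-factor ANOVA variance decomposition recovers the target fractions;
#'   `"population"` makes the fractions plain per-animal variance shares.
#' @param hyperglycemia Data frame with columns `strain`, `sex`, `shift`
#'   (mg/dL) of per-group fasting-blood-glucose mean shifts, applied to the
#'   `fbg` trait. Default: diabetes-prone groups NOD females (+250) and NZO
#'   males (+300). Magnitudes are free parameters of the generator.
#' @param dropout_rate Probability in `[0, 1)` of dropping each animal
#'   (uniform thinning emulating mortality); default 0.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(strains = founder_strains(),
                       n_per_group = 9L,
                       n_do_per_sex = 25L,
                       traits = default_trait_specs(),
                       mass_spec = default_mass_spec(),
                       do_admixture_concentration = 0.5,
                       seed = 1L,
                       variance_mode = c("anova", "population"),
                       hyperglycemia = data.frame(
                         strain = c("NOD", "NZO"), sex = c("F", "M"),
                         shift = c(250, 300)),
                       dropout_rate = 0) {
  variance_mode <- match.arg(variance_mode)
  if (length(strains) < 2L || anyDuplicated(strains)) {
    stop("sim_config: 'strains' must be >= 2 unique labels", call. = FALSE)
  }
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop("sim_config: 'n_per_group' must be >= 2 ",
         "(variance components need replicates)", call. = FALSE)
  }
  if (!is.numeric(n_do_per_sex) || n_do_per_sex < 0) {
    stop("sim_config: 'n_do_per_sex' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(do_admixture_concentration) ||
      do_admixture_concentration <= 0) {
    stop("sim_config: 'do_admixture_concentration' must be > 0",
         call. = FALSE)
  }
  if (!is.list(traits) || !all(vapply(traits, inherits, TRUE, "trait_spec"))) {
    stop("sim_config: 'traits' must be a list of trait_spec objects",
         call. = FALSE)
  }
  if (!inherits(mass_spec, "trait_spec")) {
    stop("sim_config: 'mass_spec' must be a trait_spec", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("sim_config: 'dropout_rate' must be in [0, 1)", call. = FALSE)
  }
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("sim_config: duplicate trait names in 'traits'", call. = FALSE)
  }
  structure(
    list(strains = as.character(strains),
         n_per_group = as.integer(n_per_group),
         n_do_per_sex = as.integer(n_do_per_sex),
         traits = traits, mass_spec = mass_spec,
         do_admixture_concentration = do_admixture_concentration,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         variance_mode = variance_mode,
         hyperglycemia = hyperglycemia,
         dropout_rate = dropout_rate),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d strains x 2 sexes x %d, DO %d/sex, ",
                     "%d traits, alpha = %g, seed = %s, mode = %s\n"),
              length(x$strains), x$n_per_group, x$n_do_per_sex,
              length(x$traits), x$do_admixture_concentration,
              if (is.null(x$seed)) "none" else x$seed, x$variance_mode))
  invisible(x)
}

#' Trait registry bundled with the package
#'
#' Reads the editable registry of recognized trait columns (name, units,
#' length-scale tag) shipped in `inst/extdata/trait_registry.csv`.
#'
#' @return Data frame with columns `name`, `units`, `scale`.
#' @export
trait_registry <- function() {
  path <- system.file("extdata", "trait_registry.csv", package = "bonephen")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
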