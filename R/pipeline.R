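# End-to-end pipeline driver, configuration and run report.

#' Pipeline configuration
#'
#' Exactly one input mode is active per run: either `simulation` (a
#' [sim_config()]) or `cohort_csv` (+ optional curve/spectra directories).
#'
#' @param simulation A [sim_config()], or `NULL` for file input.
#' @param cohort_csv Path to a cohort CSV, or `NULL` for simulation mode.
#' @param curves_dir Optional directory of curve CSVs (file name stem =
#'   `animal_id`).
#' @param spectra_dir Optional directory of spectrum CSVs.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of analysis stages to run, from
#'   `c("mechanics", "heritability", "adjustment", "correlations",
#'   "clustering", "pca", "raman", "posthoc")`.
#' @param traits Traits analyzed by the statistical stages; `NULL` means
#'   all numeric trait columns.
#' @param pca_traits Traits entering PCA; `NULL` means the radial +
#'   whole-body panel present in the table.
#' @param cluster_k Number of trait clusters (default 3).
#' @param adjust_traits Traits to body-mass-adjust; `NULL` means `traits`.
#' @param seed Integer seed for the run.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            cohort_csv = NULL,
                            curves_dir = NULL,
                            spectra_dir = NULL,
                            out_dir = tempfile("bonephen_run_"),
                            stages = c("mechanics", "heritability",
                                       "adjustment", "correlations",
                                       "clustering", "pca", "raman",
                                       "posthoc"),
                            traits = NULL,
                            pca_traits = NULL,
                            cluster_k = 3L,
                            adjust_traits = NULL,
                            seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(simulation) == is.null(cohort_csv)) {
    stop("pipeline_config: exactly one of 'simulation' or 'cohort_csv' ",
         "must be set", call. = FALSE)
  }
  if (cluster_k < 1) {
    stop("pipeline_config: cluster_k must be >= 1", call. = FALSE)
  }
  known <- c("mechanics", "heritability", "adjustment", "correlations",
             "clustering", "pca", "raman", "posthoc")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("pipeline_config: unknown stage(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(simulation = simulation, cohort_csv = cohort_csv,
                 curves_dir = curves_dir, spectra_dir = spectra_dir,
                 out_dir = out_dir, stages = stages, traits = traits,
                 pca_traits = pca_traits, cluster_k = as.integer(cluster_k),
                 adjust_traits = adjust_traits, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `simulation`
#' block mirrors [sim_config()] fields (with `traits` as a list of
#' trait-spec field maps).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    traits <- if (is.null(s$traits)) {
      default_trait_specs()
    } else {
      lapply(s$traits, function(t) do.call(trait_spec, t))
    }
    sim <- sim_config(
      strains = s$strains %||% founder_strains(),
      n_per_group = s$n_per_group %||% 9L,
      n_do_per_sex = s$n_do_per_sex %||% 25L,
      traits = traits,
      do_admixture_concentration = s$do_admixture_concentration %||% 0.5,
      seed = s$seed %||% y$seed %||% 1L,
      variance_mode = s$variance_mode %||% "anova",
      dropout_rate = s$dropout_rate %||% 0)
  }
  args <- y[intersect(names(y),
                      c("cohort_csv", "curves_dir", "spectra_dir",
                        "out_dir", "stages", "traits", "pca_traits",
                        "cluster_k", "adjust_traits", "seed",
                        "log_level"))]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

.default_pca_panel <- c("body_mass", "bmc", "fbg", "tt_ar", "ct_ar",
                        "ma_ar", "ct_th", "pmoi", "tmd", "stiffness",
                        "ult_force", "yield_force", "pyd", "work_to_fx",
                        "modulus")

.log <- function(state, ...) {
  msg <- sprintf(...)
  state$log <- c(state$log, msg)
  if (state$verbose) message("[bonephen] ", msg)
  state
}

.emit <- function(state, name, obj) {
  path <- file.path(state$out_dir, name)
  utils::write.csv(obj, path, row.names = FALSE, na = "")
  state$outputs <- c(state$outputs, path)
  state
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate or ingest the
#' cohort; per-animal curve analysis (mechanics); broad-sense heritability;
#' body-mass adjustment; trait correlations and Ward.D2 clustering; PCA on
#' founders with DO projection and 1-SD strain ellipses; Raman ratio
#' extraction; founder-vs-reference and founder-vs-DO post hoc tables.
#' Every stage writes CSV outputs into `config$out_dir`; with a fixed seed
#' the outputs are bit-identical across runs. A stage failure aborts its
#' dependents but the report records partial completion.
#'
#' In simulation mode the mechanics and Raman stages generate per-animal
#' raw records (bending curves from each animal's mechanical traits, one
#' spectrum per founder from its compositional traits), re-analyze them,
#' and merge measured values back as `*_meas` columns, exercising the full
#' measurement chain.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: output manifest, per-stage counts,
#'   warnings, log, package version and config hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(out_dir = config$out_dir, outputs = character(),
                log = character(), warnings = character(),
                counts = list(), verbose = config$log_level == "info",
                failed = character())
  set.seed(config$seed)

  # --- ingest / simulate -------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    founders <- simulate_founder_cohort(sim)
    do_tab <- if (sim$n_do_per_sex > 0) {
      simulate_do_cohort(sim, attr(founders, "sim_model"))
    } else {
      NULL
    }
    cohort <- rbind(as.data.frame(founders),
                    if (!is.null(do_tab)) as.data.frame(do_tab))
    class(cohort) <- c("cohort_table", "data.frame")
    state <- .log(state, "simulated %d founder + %d DO animals",
                  nrow(founders), if (is.null(do_tab)) 0 else nrow(do_tab))
  } else {
    cohort <- withCallingHandlers(
      read_cohort(config$cohort_csv),
      warning = function(w) {
        state$warnings <<- c(state$warnings,
                             paste0("ingest: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    founders <- cohort[cohort$population == "founder", , drop = FALSE]
    state <- .log(state, "read %d animals from %s", nrow(cohort),
                  config$cohort_csv)
  }
  state$counts$animals_in <- nrow(cohort)
  state <- .emit(state, "cohort.csv", as.data.frame(cohort))

  meta_cols <- .required_cohort_cols
  numeric_traits <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
  numeric_traits <- setdiff(numeric_traits, meta_cols)
  traits <- config$traits %||% numeric_traits

  run_stage <- function(name, deps = character(), fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    if (length(intersect(deps, state$failed))) {
      state <<- .log(state, "stage %s skipped (failed dependency)", name)
      state$failed <<- c(state$failed, name)
      return(invisible(NULL))
    }
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        state$failed <<- c(state$failed, name)
        state$warnings <<- c(state$warnings,
                             paste0("stage ", name, " failed: ",
                                    conditionMessage(e)))
        state <<- .log(state, "stage %s FAILED: %s", name,
                       conditionMessage(e))
      }),
      warning = function(w) {
        state$warnings <<- c(state$warnings,
                             paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    invisible(NULL)
  }

  # --- mechanics ---------------------------------------------------------
  run_stage("mechanics", fun = function() {
    mech_traits <- c("stiffness", "yield_force", "ult_force", "pyd")
    curves <- list()
    if (!is.null(config$curves_dir)) {
      files <- sort(list.files(config$curves_dir, pattern = "\\.csv$",
                               full.names = TRUE))
      curves <- stats::setNames(lapply(files, read_curve),
                                sub("\\.csv$", "", basename(files)))
    } else if (!is.null(config$simulation) &&
               all(mech_traits %in% names(cohort))) {
      ok <- stats::complete.cases(cohort[, mech_traits]) &
        cohort$yield_force <= cohort$ult_force &
        cohort$stiffness > 0 & cohort$yield_force > 0 & cohort$pyd >= 0
      rows <- which(ok)
      curves <- stats::setNames(lapply(rows, function(i) {
        simulate_bend_curve(
          mechanical_truth(K = cohort$stiffness[i],
                           Fy = cohort$yield_force[i],
                           Fu = cohort$ult_force[i],
                           PYD = cohort$pyd[i]),
          noise_sd = 0.005 * cohort$ult_force[i], n_points = 400L)
      }), cohort$animal_id[rows])
    }
    if (!length(curves)) {
      state <<- .log(state, "mechanics: no curves available, skipped")
      return(invisible(NULL))
    }
    res <- analyze_curves(curves)
    state$counts$curves <<- nrow(res)
    state <<- .emit(state, "mechanics.csv", res)
    merged <- res[match(cohort$animal_id, res$id),
                  c("K", "Fy", "Fu", "PYD", "work")]
    names(merged) <- paste0(c("stiffness", "yield_force", "ult_force",
                              "pyd", "work_to_fx"), "_meas")
    cohort[names(merged)] <<- merged
    state <<- .log(state, "mechanics: analyzed %d curves", nrow(res))
  })

  # --- heritability ------------------------------------------------------
  run_stage("heritability", fun = function() {
    h2 <- h2_table(cohort, traits)
    state$counts$h2_traits <<- nrow(h2)
    state <<- .emit(state, "h2.csv", h2)
    state <<- .log(state, "heritability: %d traits, top = %s (H2 = %.3f)",
                   nrow(h2), h2$trait[1], h2$H2[1])
  })

  # --- adjustment --------------------------------------------------------
  run_stage("adjustment", fun = function() {
    adj_traits <- setdiff(config$adjust_traits %||% traits, "body_mass")
    adj <- as.data.frame(cohort)
    slope_rows <- list()
    founders_only <- cohort[cohort$population == "founder", , drop = FALSE]
    for (tr in adj_traits) {
      m <- fit_mass_slopes(founders_only, tr)
      sl <- m$slopes
      sl$trait <- tr
      sl$grand_mean_mass <- m$grand_mean_mass
      slope_rows[[tr]] <- sl
      fo <- adj$population == "founder"
      adj[fo, paste0(tr, "_adj")] <-
        apply_mass_adjustment(adj[fo, , drop = FALSE], tr, m)
    }
    state <<- .emit(state, "mass_slopes.csv", do.call(rbind, slope_rows))
    state <<- .emit(state, "adjusted.csv", adj)
    state <<- .log(state, "adjustment: %d traits adjusted",
                   length(adj_traits))
  })

  # --- correlations / clustering ----------------------------------------
  corr <- NULL
  run_stage("correlations", fun = function() {
    fo <- cohort[cohort$population == "founder", , drop = FALSE]
    usable <- traits[vapply(traits, function(tr)
      sum(!is.na(fo[[tr]])) >= 3 &&
        stats::var(fo[[tr]], na.rm = TRUE) > 0, TRUE)]
    corr <<- pearson_matrix(fo, usable)
    state <<- .emit(state, "correlation_r.csv",
                    data.frame(trait = rownames(corr$r), corr$r,
                               check.names = FALSE))
    state <<- .emit(state, "correlation_p.csv",
                    data.frame(trait = rownames(corr$p), corr$p,
                               check.names = FALSE))
    state <<- .log(state, "correlations: %d traits", length(usable))
  })
  run_stage("clustering", deps = "correlations", fun = function() {
    if (is.null(corr)) stop("correlation stage did not run")
    cl <- cluster_traits(corr, k = config$cluster_k)
    state <<- .emit(state, "trait_clusters.csv",
                    data.frame(trait = names(cl), cluster = as.integer(cl)))
    state <<- .log(state, "clustering: k = %d", config$cluster_k)
  })

  # --- pca ---------------------------------------------------------------
  run_stage("pca", fun = function() {
    panel <- config$pca_traits %||%
      intersect(.default_pca_panel, names(cohort))
    panel <- panel[vapply(panel, function(tr)
      stats::var(cohort[[tr]], na.rm = TRUE) > 0, TRUE)]
    fo <- cohort[cohort$population == "founder", , drop = FALSE]
    model <- fit_pca(fo, panel)
    state <<- .emit(state, "pca_loadings.csv",
                    data.frame(trait = rownames(model$weightings),
                               model$weightings, check.names = FALSE))
    state <<- .emit(state, "pca_explained.csv",
                    data.frame(PC = seq_along(model$explained),
                               proportion = model$explained))
    fo_cc <- fo[stats::complete.cases(fo[, panel]), , drop = FALSE]
    sc <- data.frame(animal_id = fo_cc$animal_id, strain = fo_cc$strain,
                     sex = fo_cc$sex, model$scores, check.names = FALSE)
    state <<- .emit(state, "pca_scores_founder.csv", sc)
    ell <- normal_ellipse(model$scores[, 1:2], fo_cc$strain, level = 1)
    state <<- .emit(state, "pca_ellipses.csv", as.data.frame(ell))
    do_rows <- cohort[cohort$population == "DO", , drop = FALSE]
    if (nrow(do_rows)) {
      pr <- project_onto_pca(model, do_rows)
      kept <- setdiff(seq_len(nrow(do_rows)), attr(pr, "skipped"))
      state <<- .emit(state, "pca_scores_do.csv",
                      data.frame(animal_id = do_rows$animal_id[kept],
                                 sex = do_rows$sex[kept], pr,
                                 check.names = FALSE))
      state <<- .log(state, "pca: projected %d DO animals", nrow(pr))
    } else {
      state <<- .log(state,
                     "pca: no DO rows, projection skipped with warning")
      state$warnings <<- c(state$warnings,
                           "pca: no DO rows; projection skipped")
    }
    state$counts$pca_rows <<- nrow(model$scores)
  })

  # --- raman -------------------------------------------------------------
  run_stage("raman", fun = function() {
    spec_list <- list()
    if (!is.null(config$spectra_dir)) {
      files <- sort(list.files(config$spectra_dir, pattern = "\\.csv$",
                               full.names = TRUE))
      spec_list <- stats::setNames(lapply(files, read_spectrum),
                                   sub("\\.csv$", "", basename(files)))
    } else if (!is.null(config$simulation) &&
               all(c("mm_v1_proline", "mm_v2_amide3", "carb_phos",
                     "crystallinity") %in% names(cohort))) {
      fo <- which(cohort$population == "founder")
      spec_list <- stats::setNames(lapply(fo, function(i) {
        v1 <- 10
        v2 <- 4.5
        areas <- c(v1_phosphate = v1,
                   proline = v1 / cohort$mm_v1_proline[i],
                   v2_phosphate = v2,
                   amideIII = v2 / cohort$mm_v2_amide3[i],
                   v1_carbonate = v1 * cohort$carb_phos[i])
        simulate_raman_spectrum(areas,
                                fwhm_v1 = 1 / cohort$crystallinity[i],
                                baseline_coeffs = c(2, 1, 0.5),
                                noise_sd = 0.002)
      }), cohort$animal_id[fo])
    }
    if (!length(spec_list)) {
      state <<- .log(state, "raman: no spectra available, skipped")
      return(invisible(NULL))
    }
    res <- do.call(rbind, lapply(names(spec_list), function(id) {
      sp <- subtract_baseline(spec_list[[id]])
      cbind(data.frame(animal_id = id), as.data.frame(compute_ratios(sp)))
    }))
    state$counts$spectra <<- nrow(res)
    state <<- .emit(state, "raman.csv", res)
    state <<- .log(state, "raman: processed %d spectra", nrow(res))
  })

  # --- posthoc -----------------------------------------------------------
  run_stage("posthoc", fun = function() {
    fo <- cohort[cohort$population == "founder", , drop = FALSE]
    ref <- if ("B6" %in% fo$strain) "B6" else fo$strain[1]
    comp <- list()
    for (tr in traits) {
      ct <- strain_sex_posthoc(cohort, tr, family = "strain_vs_ref",
                               ref = ref)
      ct$trait <- tr
      comp[[tr]] <- ct
    }
    out <- do.call(rbind, comp)
    rownames(out) <- NULL
    state <<- .emit(state, "posthoc_strain.csv", out)
    if (all(c("founder", "DO") %in% cohort$population)) {
      pd <- do.call(rbind, lapply(traits, function(tr) {
        ct <- strain_sex_posthoc(cohort, tr, family = "founder_vs_do")
        ct$trait <- tr
        ct
      }))
      rownames(pd) <- NULL
      state <<- .emit(state, "posthoc_population.csv", pd)
    }
    state <<- .log(state, "posthoc: reference %s", ref)
  })

  # --- report ------------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_path)
  report <- structure(
    list(outputs = state$outputs,
         counts = state$counts,
         warnings = state$warnings,
         failed_stages = state$failed,
         log = state$log,
         version = as.character(utils::packageVersion("bonephen")),
         config_hash = unname(tools::md5sum(cfg_path)),
         out_dir = config$out_dir),
    class = "run_report")
  jsonlite::write_json(
    report[c("outputs", "counts", "warnings", "failed_stages", "version",
             "config_hash")],
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE)
  writeLines(state$log, file.path(config$out_dir, "run.log"))
  report
}

.config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) {
    sim <- unclass(out$simulation)
    sim$traits <- lapply(sim$traits, function(t)
      Filter(Negate(is.null), unclass(t)))
    sim$mass_spec <- Filter(Negate(is.null), unclass(sim$mass_spec))
    sim$hyperglycemia <- as.list(sim$hyperglycemia)
    out$simulation <- sim
  }
  Filter(Negate(is.null), out)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> bonephen %s: %d outputs in %s\n", x$version,
              length(x$outputs), x$out_dir))
  if (length(x$failed_stages)) {
    cat("  failed stages:", paste(x$failed_stages, collapse = ", "), "\n")
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  }
  invisible(x)
}
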