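# Correlation matrices, trait clustering, PCA and projection, ellipses.

test_that("Pearson matrix matches the explicit formula and keeps its invariants", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 3, 5, 4, 6)
  d <- data.frame(a = x, b = y, c = -x)
  cm <- pearson_matrix(d, c("a", "b", "c"))
  # hand/brute-force evaluation of the covariance/SD quotient
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$r["a", "b"], r_hand, tolerance = 1e-12)
  expect_equal(cm$r["a", "c"], -1, tolerance = 1e-12)
  expect_identical(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_identical(diag(cm$p), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(cm$r))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
  expect_false(any(diag(cm$mask)))
  # mask marks p > 0.05
  expect_identical(unname(cm$mask["a", "b"]),
                   unname(cm$p["a", "b"] > 0.05))
})

test_that("constant traits and short pairs are unavailable with a warning", {
  d <- data.frame(a = 1:6, b = rep(2, 6), c = c(1, 2, NA, NA, NA, NA))
  expect_warning(cm <- pearson_matrix(d, c("a", "b", "c")), "unavailable")
  expect_true(is.na(cm$r["a", "b"]))
  expect_true(is.na(cm$r["a", "c"]))
  expect_identical(unname(cm$n["a", "c"]), 2L)
})

test_that("Ward.D2 clustering recovers block structure and validates inputs", {
  r <- diag(6)
  r[1:3, 1:3] <- 1
  r[4:6, 4:6] <- 1
  traits <- paste0("t", 1:6)
  dimnames(r) <- list(traits, traits)
  cm <- structure(list(traits = traits, r = r,
                       p = matrix(0, 6, 6, dimnames = dimnames(r)),
                       n = matrix(10L, 6, 6), mask = r > 2),
                  class = "correlation_matrix")
  cl <- cluster_traits(cm, 2)
  expect_identical(unname(cl[1:3]), rep(unname(cl[1]), 3))
  expect_identical(unname(cl[4:6]), rep(unname(cl[4]), 3))
  expect_false(cl[1] == cl[4])
  expect_identical(as.integer(cluster_traits(cm, 1)), rep(1L, 6))
  expect_error(cluster_traits(cm, 7), "k must be")
  cm$r[1, 2] <- cm$r[2, 1] <- NA
  expect_error(cluster_traits(cm, 2), "unavailable")
})

test_that("clusters recover a known 3-latent-factor structure", {
  mk_traits <- function() {
    unlist(lapply(1:3, function(f) {
      lapply(1:3, function(i)
        trait_spec(paste0("f", f, "_t", i), var_frac_strain = 0.6,
                   var_frac_sex = 0.02, var_frac_res = 0.38,
                   grand_mean = 10, total_sd = 2,
                   latent_factor = paste0("fac", f),
                   latent_loading = 0.9))
    }), recursive = FALSE)
  }
  truth <- rep(1:3, each = 3)
  hits <- sapply(1:20, function(s) {
    cfg <- sim_config(traits = mk_traits(), seed = s,
                      hyperglycemia = NULL)
    tab <- simulate_founder_cohort(cfg)
    cm <- pearson_matrix(tab, sapply(cfg$traits, `[[`, "name"))
    cl <- cluster_traits(cm, 3)
    identical(outer(truth, truth, "=="),
              outer(as.integer(cl), as.integer(cl), "=="))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("PCA centering, scaling, sign convention and eigen oracle agree", {
  set.seed(8)
  x <- matrix(stats::rnorm(12), 4, 3)
  d <- as.data.frame(x)
  names(d) <- c("a", "b", "c")
  m <- fit_pca(d, c("a", "b", "c"))
  # eigenvalues match a brute-force eigendecomposition of cor(x)
  ev <- eigen(stats::cor(x), symmetric = TRUE)$values
  expect_equal(m$sdev^2, ev, tolerance = 1e-10)
  expect_equal(sum(m$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_lt(max(abs(colMeans(m$scores))), 1e-8)
  # orthonormal loadings, largest-magnitude entry positive
  expect_equal(crossprod(m$weightings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:3) {
    expect_gt(m$weightings[which.max(abs(m$weightings[, j])), j], 0)
  }
  # reconstruction of the standardized data from all PCs
  xs <- scale(x)
  expect_equal(m$scores %*% t(m$weightings), xs, tolerance = 1e-8,
               ignore_attr = TRUE)
  # two perfectly correlated traits: PC1 explains everything
  d2 <- data.frame(a = 1:10, b = 2 * (1:10) + 3)
  m2 <- fit_pca(d2, c("a", "b"))
  expect_equal(m2$explained[1], 1, tolerance = 1e-9)
  d2$c <- 5
  expect_error(fit_pca(d2, c("a", "b", "c")), "constant")
})

test_that("explained variance is invariant to trait order", {
  cfg <- sim_config(traits = small_panel(), n_per_group = 5, seed = 12,
                    hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)
  m1 <- fit_pca(tab, c("tA", "tB", "tC"))
  m2 <- fit_pca(tab, c("tC", "tA", "tB"))
  expect_equal(m1$explained, m2$explained, tolerance = 1e-10)
})

test_that("projection is consistent on training rows, zero at the founder mean, and linear", {
  cfg <- sim_config(traits = small_panel(), n_per_group = 6, seed = 15,
                    hyperglycemia = NULL)
  tab <- simulate_founder_cohort(cfg)
  traits <- c("tA", "tB", "tC")
  m <- fit_pca(tab, traits)
  pr <- project_onto_pca(m, tab)
  expect_lt(max(abs(pr - m$scores)), 1e-10)
  mean_row <- as.data.frame(as.list(m$center))
  expect_lt(max(abs(project_onto_pca(m, mean_row))), 1e-12)
  r1 <- tab[3, traits]
  r2 <- tab[40, traits]
  alpha <- 0.3
  mix <- alpha * r1 + (1 - alpha) * r2
  expect_equal(project_onto_pca(m, mix),
               alpha * project_onto_pca(m, r1) +
                 (1 - alpha) * project_onto_pca(m, r2),
               tolerance = 1e-10, ignore_attr = TRUE)
  # rows with missing traits are skipped, not fatal
  tab2 <- tab[1:5, ]
  tab2$tA[2] <- NA
  expect_message(pr2 <- project_onto_pca(m, tab2), "skipping")
  expect_identical(nrow(pr2), 4L)
  expect_error(project_onto_pca(m, tab[, c("tA", "tB")]), "lacks")
})

test_that("DO strain-effect components project inside the founder effect hull", {
  # exact consequence of convex admixture + linear projection
  cfg <- sim_config(seed = 19)
  tab <- simulate_founder_cohort(cfg)
  do_tab <- simulate_do_cohort(cfg, tab)
  model <- attr(tab, "sim_model")
  panel <- c("bmc", "ct_th", "tmd", "ct_ar", "tt_ar", "stiffness",
             "ult_force", "lc_n_density")
  m <- fit_pca(tab, panel)
  eff_founder <- sapply(panel, function(tr)
    model$traits[[tr]]$strain_effects + model$traits[[tr]]$spec$grand_mean)
  eff_do <- attr(do_tab, "strain_effects_applied")[, panel] +
    rep(sapply(panel, function(tr) model$traits[[tr]]$spec$grand_mean),
        each = nrow(do_tab))
  pf <- project_onto_pca(m, as.data.frame(eff_founder))
  pd <- project_onto_pca(m, as.data.frame(eff_do))
  expect_true(all(points_in_hull(pd[, 1:2], pf[, 1:2])))
  # and the full DO cohort is overwhelmingly central: pooled containment
  pr_do <- project_onto_pca(m, do_tab)
  expect_gte(mean(points_in_hull(pr_do[, 1:2], m$scores[, 1:2])), 0.9)
})

test_that("normal data ellipses recover known covariance and flag degeneracy", {
  set.seed(33)
  n <- 10000
  xy <- cbind(stats::rnorm(n, 0, 2), stats::rnorm(n, 0, 0.5))
  ell <- normal_ellipse(xy, rep("g", n), level = 1)
  expect_lt(abs(ell$a / 2 - 1), 0.05)
  expect_lt(abs(ell$b / 0.5 - 1), 0.05)
  expect_false(ell$degenerate)
  # isotropic cloud: near-circular with unit semi-axes
  xy2 <- cbind(stats::rnorm(n), stats::rnorm(n))
  e2 <- normal_ellipse(xy2, rep("g", n))
  expect_lt(abs(e2$a - 1), 0.05)
  expect_lt(abs(e2$b - 1), 0.05)
  # collinear points are degenerate; tiny groups are an error
  line <- cbind(1:20, 2 * (1:20))
  expect_true(normal_ellipse(line, rep("g", 20))$degenerate)
  expect_error(normal_ellipse(xy[1:2, ], rep("g", 2)), "fewer than 3")
  path <- ellipse_path(ell[1, ], n_points = 64)
  expect_identical(nrow(path), 64L)
})
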