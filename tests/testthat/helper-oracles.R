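# Independent oracles and small builders used across the suite.

# Brute-force two-factor sum-of-squares via explicit projections onto
# design-matrix column spaces (pseudo-inverse based; independent of lm /
# car::Anova).
oracle_anova_ss <- function(d, trait, type = "III") {
  y <- d[[trait]]
  A <- stats::model.matrix(~ 0 + factor(d$strain))
  B <- stats::model.matrix(~ 0 + factor(d$sex))
  one <- matrix(1, nrow(d), 1)
  rss <- function(X) {
    P <- X %*% pracma::pinv(X)
    sum((y - P %*% y)^2)
  }
  full <- cbind(one, A[, -1, drop = FALSE], B[, -1, drop = FALSE])
  noA <- cbind(one, B[, -1, drop = FALSE])
  noB <- cbind(one, A[, -1, drop = FALSE])
  if (type == "I") {
    list(SS_strain = rss(one) - rss(noB),
         SS_sex = rss(noB) - rss(full),
         SS_res = rss(full))
  } else {
    list(SS_strain = rss(noA) - rss(full),
         SS_sex = rss(noB) - rss(full),
         SS_res = rss(full))
  }
}

# random small (possibly unbalanced) two-factor design with a usable layout
random_toy_design <- function(max_rows = 20) {
  repeat {
    n <- sample(8:max_rows, 1)
    d <- data.frame(
      strain = sample(letters[1:sample(2:4, 1)], n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      y = stats::rnorm(n))
    if (length(unique(d$strain)) < 2 || length(unique(d$sex)) < 2) next
    if (max(table(d$strain, d$sex)) < 2) next
    # skip aliased layouts (a factor level seen in only one level of the
    # other factor everywhere)
    ct <- table(d$strain, d$sex)
    if (any(rowSums(ct > 0) == 0) || qr(stats::model.matrix(
      ~ factor(strain) + factor(sex), d))$rank <
      length(unique(d$strain)) + 1) next
    return(d)
  }
}

# point-in-convex-hull test in 2D (counter-clockwise hull walk)
points_in_hull <- function(pts, cloud) {
  h <- cloud[rev(grDevices::chull(cloud)), , drop = FALSE]
  apply(pts, 1, function(p) {
    n <- nrow(h)
    for (i in seq_len(n)) {
      a <- h[i, ]
      b <- h[i %% n + 1, ]
      if ((b[1] - a[1]) * (p[2] - a[2]) -
          (b[2] - a[2]) * (p[1] - a[1]) < 0) return(FALSE)
    }
    TRUE
  })
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)

# compact founder panel used where the full default panel is unnecessary
small_panel <- function() {
  list(
    trait_spec("tA", var_frac_strain = 0.9, var_frac_sex = 0.02,
               var_frac_res = 0.08, grand_mean = 100, total_sd = 10),
    trait_spec("tB", var_frac_strain = 0.5, var_frac_sex = 0.05,
               var_frac_res = 0.45, grand_mean = 10, total_sd = 2),
    trait_spec("tC", var_frac_strain = 0.2, var_frac_sex = 0.02,
               var_frac_res = 0.78, grand_mean = 0, total_sd = 1))
}
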