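# Variance decomposition, broad-sense heritability, allometric body-mass
# adjustment, covariate checks, post hoc comparisons and glycemia
# classification on a cohort table.

.check_design <- function(tab, trait, strain_col = "strain",
                          sex_col = "sex") {
  if (!trait %in% names(tab)) {
    stop("trait '", trait, "' not found in table", call. = FALSE)
  }
  use <- !is.na(tab[[trait]]) & !is.na(tab[[strain_col]]) &
    !is.na(tab[[sex_col]])
  d <- tab[use, , drop = FALSE]
  if (length(unique(d[[strain_col]])) < 2L) {
    stop("design error: need >= 2 strains with data for trait '", trait,
         "'", call. = FALSE)
  }
  if (length(unique(d[[sex_col]])) < 2L) {
    stop("design error: need both sexes with data for trait '", trait, "'",
         call. = FALSE)
  }
  n_cell <- table(d[[strain_col]], d[[sex_col]])
  if (max(n_cell) < 2L) {
    stop("design error: need >= 2 replicates in at least one strain-sex ",
         "cell for trait '", trait, "'", call. = FALSE)
  }
  list(data = d, dropped = sum(!use))
}

#' Two-factor (strain x sex) sum-of-squares decomposition
#'
#' Least-squares ANOVA of one trait on strain and sex. The additive model
#' partitions the total sum of squares into strain, sex and residual; the
#' interaction model adds a strain:sex term (reported separately). For
#' unbalanced data the partition is governed by `ss_type` (Type III with
#' sum-to-zero contrasts by default, matching common commercial statistics
#' software; Types I and II selectable). Rows missing the trait are dropped
#' and counted.
#'
#' @param table A cohort table (data frame with `strain`, `sex` columns).
#' @param trait Trait column name.
#' @param model `"additive"` (default) or `"interaction"`.
#' @param ss_type `"III"` (default), `"II"`, or `"I"`.
#' @param group Grouping used for the average group size `n_avg`:
#'   `"strain"` (default; animals with the trait divided by the number of
#'   strains) or `"cell"` (strain x sex cells).
#' @return Object of class `anova_decomposition`: sums of squares
#'   `SS_strain`, `SS_sex`, `SS_res` (and `SS_interaction` for the
#'   interaction model), degrees of freedom, `n_avg`, `n_used`, `dropped`,
#'   and a `degenerate` flag (all SS zero).
#' @export
anova_ss <- function(table, trait, model = c("additive", "interaction"),
                     ss_type = c("III", "II", "I"),
                     group = c("strain", "cell")) {
  model <- match.arg(model)
  ss_type <- match.arg(ss_type)
  group <- match.arg(group)
  chk <- .check_design(table, trait)
  d <- chk$data
  d$strain <- factor(d$strain)
  d$sex <- factor(d$sex)
  y <- d[[trait]]
  n_used <- nrow(d)
  n_groups <- if (group == "strain") {
    nlevels(d$strain)
  } else {
    nlevels(droplevels(interaction(d$strain, d$sex)))
  }
  n_avg <- n_used / n_groups

  degenerate <- stats::var(y) < .Machine$double.eps
  form <- if (model == "additive") {
    y ~ strain + sex
  } else {
    y ~ strain * sex
  }
  environment(form) <- environment()
  fit <- stats::lm(form, data = d,
                   contrasts = list(strain = "contr.sum", sex = "contr.sum"))
  if (anyNA(stats::coef(fit))) {
    stop("design error: strain and sex are aliased (rank-deficient ",
         "design) for trait '", trait, "'", call. = FALSE)
  }
  if (ss_type == "I") {
    a <- stats::anova(fit)
    tabSS <- stats::setNames(a$`Sum Sq`, rownames(a))
    df <- stats::setNames(a$Df, rownames(a))
  } else {
    a <- tryCatch(car::Anova(fit, type = ss_type), error = function(e) NULL)
    if (!is.null(a)) {
      tabSS <- stats::setNames(a$`Sum Sq`, rownames(a))
      df <- stats::setNames(a$Df, rownames(a))
    } else {
      # car::Anova refuses perfect fits (zero residual SS); compute the
      # marginal SS directly as RSS differences on the sum-to-zero design
      X <- stats::model.matrix(fit)
      asgn <- attr(X, "assign")
      labs <- attr(stats::terms(fit), "term.labels")
      yv <- stats::model.response(stats::model.frame(fit))
      rss <- function(M) {
        if (ncol(M) == 0L) return(sum((yv - mean(yv))^2))
        sum(qr.resid(qr(M), yv)^2)
      }
      rss_full <- rss(X)
      tabSS <- c(vapply(seq_along(labs), function(k)
        max(0, rss(X[, asgn != k, drop = FALSE]) - rss_full), 0),
        rss_full)
      names(tabSS) <- c(labs, "Residuals")
      df <- c(vapply(seq_along(labs), function(k) sum(asgn == k), 0L),
              nrow(X) - ncol(X))
      names(df) <- names(tabSS)
    }
  }
  res <- structure(
    list(trait = trait,
         SS_strain = max(0, unname(tabSS["strain"])),
         SS_sex = max(0, unname(tabSS["sex"])),
         SS_res = max(0, unname(tabSS["Residuals"])),
         SS_interaction = if (model == "interaction")
           max(0, unname(tabSS["strain:sex"])) else NA_real_,
         df_strain = unname(df["strain"]),
         df_sex = unname(df["sex"]),
         df_res = unname(df["Residuals"]),
         df_interaction = if (model == "interaction")
           unname(df["strain:sex"]) else NA_integer_,
         n_avg = n_avg, n_used = n_used, dropped = chk$dropped,
         model = model, ss_type = ss_type, group = group,
         degenerate = degenerate),
    class = "anova_decomposition")
  if (degenerate) {
    res$SS_strain <- res$SS_sex <- res$SS_res <- 0
    if (model == "interaction") res$SS_interaction <- 0
  }
  res
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<anova_decomposition> %s (%s, type %s): SS strain ",
                     "%.4g (df %d), sex %.4g (df %d), residual %.4g (df ",
                     "%d); n_avg = %.3g\n"),
              x$trait, x$model, x$ss_type, x$SS_strain, x$df_strain,
              x$SS_sex, x$df_sex, x$SS_res, x$df_res, x$n_avg))
  invisible(x)
}

#' Broad-sense heritability from an ANOVA decomposition
#'
#' Variance components follow the sum-of-squares quotients used for inbred
#' strain panels: `sigma2_strain = SS_strain / n_avg` (average group size),
#' `sigma2_sex = SS_sex / df_sex`, `sigma2_res = SS_res / df_res`, and
#' broad-sense heritability is the strain share,
#' `H2 = sigma2_strain / (sigma2_strain + sigma2_sex + sigma2_res)`.
#' All components are nonnegative, so `H2` always lies in `[0, 1]`; a fully
#' degenerate trait (zero total variance) returns `H2 = 0` with a flag.
#'
#' @param decomp An [anova_ss()] result.
#' @return Object of class `h2_result`: `trait`, `sigma2_strain`,
#'   `sigma2_sex`, `sigma2_res`, `H2`, `n_used`, `degenerate`.
#' @export
broad_sense_h2 <- function(decomp) {
  if (!inherits(decomp, "anova_decomposition")) {
    stop("broad_sense_h2: 'decomp' must come from anova_ss()",
         call. = FALSE)
  }
  s_strain <- decomp$SS_strain / decomp$n_avg
  s_sex <- decomp$SS_sex / decomp$df_sex
  s_res <- decomp$SS_res / decomp$df_res
  tot <- s_strain + s_sex + s_res
  h2 <- if (tot <= 0) 0 else s_strain / tot
  structure(list(trait = decomp$trait,
                 sigma2_strain = s_strain, sigma2_sex = s_sex,
                 sigma2_res = s_res, H2 = h2,
                 n_used = decomp$n_used,
                 degenerate = decomp$degenerate || tot <= 0),
            class = "h2_result")
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("<h2_result> %s: H2 = %.3f (sigma2 strain %.4g, sex %.4g, residual %.4g)%s\n",
              x$trait, x$H2, x$sigma2_strain, x$sigma2_sex, x$sigma2_res,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Heritability table for many traits
#'
#' Convenience wrapper running [anova_ss()] and [broad_sense_h2()] per
#' trait.
#'
#' @param table Cohort table (founder rows are selected when a
#'   `population` column is present).
#' @param traits Character vector of trait columns.
#' @param ... Passed to [anova_ss()].
#' @return Data frame sorted by decreasing `H2`.
#' @export
h2_table <- function(table, traits, ...) {
  if ("population" %in% names(table)) {
    table <- table[table$population == "founder", , drop = FALSE]
  }
  rows <- lapply(traits, function(tr) {
    h <- broad_sense_h2(anova_ss(table, tr, ...))
    data.frame(trait = tr, sigma2_strain = h$sigma2_strain,
               sigma2_sex = h$sigma2_sex, sigma2_res = h$sigma2_res,
               H2 = h$H2, n = h$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$H2), , drop = FALSE]
}

#' Per-strain allometric regression of a trait on body mass
#'
#' Fits an ordinary least-squares regression of the trait on body mass
#' within each strain. To keep only statistically meaningful relationships,
#' a strain's slope is set to 0 when its regression p-value exceeds 0.20
#' (strictly; a boundary p of exactly 0.20 keeps the slope). Strains with
#' fewer than 3 usable animals are zeroed with a distinct flag. The
#' reference mass for adjustment is the unweighted mean of the strain mean
#' masses ("mean of the 8 means").
#'
#' @param table Cohort table; founder rows are used when a `population`
#'   column is present.
#' @param trait Trait column name.
#' @param mass_col Body-mass column (default `"body_mass"`).
#' @param p_threshold Zeroing threshold (default 0.20).
#' @return Object of class `adjustment_model`: data frame `slopes`
#'   (`strain`, `slope`, `p`, `n`, `zeroed`, `reason`) and
#'   `grand_mean_mass` (g).
#' @export
fit_mass_slopes <- function(table, trait, mass_col = "body_mass",
                            p_threshold = 0.20) {
  if ("population" %in% names(table)) {
    table <- table[table$population == "founder", , drop = FALSE]
  }
  if (!trait %in% names(table)) {
    stop("trait '", trait, "' not found", call. = FALSE)
  }
  if (!mass_col %in% names(table)) {
    stop("mass column '", mass_col, "' not found", call. = FALSE)
  }
  strains <- unique(table$strain)
  rows <- lapply(strains, function(s) {
    d <- table[table$strain == s & !is.na(table[[trait]]) &
                 !is.na(table[[mass_col]]), , drop = FALSE]
    n <- nrow(d)
    if (n < 3L || stats::var(d[[mass_col]]) < .Machine$double.eps) {
      return(data.frame(strain = s, slope = 0, p = NA_real_, n = n,
                        zeroed = TRUE, reason = "insufficient_data",
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(d[[trait]] ~ d[[mass_col]])
    # noiseless inputs give a perfect fit; the p-value (~0) is still valid
    co <- suppressWarnings(summary(fit))$coefficients
    slope <- co[2L, 1L]
    p <- co[2L, 4L]
    if (is.na(p)) p <- 1
    zero <- p > p_threshold
    data.frame(strain = s, slope = if (zero) 0 else slope, p = p, n = n,
               zeroed = zero,
               reason = if (zero) "p_above_threshold" else "kept",
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, rows)
  strain_means <- tapply(table[[mass_col]], table$strain, mean,
                         na.rm = TRUE)
  structure(list(trait = trait, slopes = slopes,
                 grand_mean_mass = mean(strain_means),
                 p_threshold = p_threshold, mass_col = mass_col),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("<adjustment_model> %s: %d strains (%d zeroed), reference mass %.3g g\n",
              x$trait, nrow(x$slopes), sum(x$slopes$zeroed),
              x$grand_mean_mass))
  invisible(x)
}

#' Apply per-strain body-mass adjustment to a trait
#'
#' `Trait_adjusted = Trait_unadjusted - slope * (body mass - mean body
#' mass)`, with each animal adjusted by its own strain's slope and the
#' mean body mass taken as the model's mean of strain means. Strains with
#' zeroed slopes pass through unchanged.
#'
#' @param table Cohort table.
#' @param trait Trait column name.
#' @param model An [fit_mass_slopes()] result for the same trait.
#' @return Numeric vector of adjusted values, one per row of `table`.
#' @export
apply_mass_adjustment <- function(table, trait, model) {
  if (!inherits(model, "adjustment_model")) {
    stop("apply_mass_adjustment: 'model' must come from fit_mass_slopes()",
         call. = FALSE)
  }
  unknown <- setdiff(unique(table$strain), model$slopes$strain)
  if (length(unknown)) {
    stop("apply_mass_adjustment: strains absent from the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  slope <- model$slopes$slope[match(table$strain, model$slopes$strain)]
  table[[trait]] - slope * (table[[model$mass_col]] - model$grand_mean_mass)
}

#' Body mass as a covariate in a general linear model
#'
#' Fits `trait ~ strain + sex + body mass` and reports the two-sided
#' p-value for the body-mass coefficient.
#'
#' @param table Cohort table.
#' @param trait Trait column name.
#' @param mass_col Body-mass column.
#' @param alpha Significance threshold reported alongside (default 0.05).
#' @return List: `p_value`, `coefficient`, `significant`, `threshold`,
#'   `degenerate` (TRUE when mass is collinear/constant, with `p_value`
#'   `NA`).
#' @export
covariate_significance <- function(table, trait, mass_col = "body_mass",
                                   alpha = 0.05) {
  chk <- .check_design(table, trait)
  d <- chk$data
  d <- d[!is.na(d[[mass_col]]), , drop = FALSE]
  if (stats::var(d[[mass_col]]) < .Machine$double.eps) {
    return(list(p_value = NA_real_, coefficient = NA_real_,
                significant = NA, threshold = alpha, degenerate = TRUE))
  }
  d$strain <- factor(d$strain)
  d$sex <- factor(d$sex)
  d$..mass <- d[[mass_col]]
  d$..y <- d[[trait]]
  fit <- stats::lm(..y ~ strain + sex + ..mass, data = d)
  co <- suppressWarnings(summary(fit))$coefficients
  if (!"..mass" %in% rownames(co)) {
    return(list(p_value = NA_real_, coefficient = NA_real_,
                significant = NA, threshold = alpha, degenerate = TRUE))
  }
  p <- co["..mass", 4L]
  list(p_value = p, coefficient = co["..mass", 1L],
       significant = p < alpha, threshold = alpha, degenerate = FALSE)
}

.sidak <- function(p, m) pmin(1, 1 - (1 - p)^m)

#' Post hoc group comparisons with Sidak correction
#'
#' t-type contrasts of cell means using the pooled residual variance of a
#' two-factor linear model (factor x sex, with interaction). Two contrast
#' families are built in: each strain versus a reference strain within each
#' sex (`family = "strain_vs_ref"`, model strain x sex on founder rows),
#' and the pooled founder population versus the DO population within each
#' sex (`family = "founder_vs_do"`, model population x sex). Within each
#' sex the Sidak adjustment `p_adj = 1 - (1 - p)^m` is applied over that
#' sex's `m` contrasts.
#'
#' @param table Cohort table.
#' @param trait Trait column name.
#' @param family `"strain_vs_ref"` or `"founder_vs_do"`.
#' @param ref Reference strain for `"strain_vs_ref"` (default `"B6"`).
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame (class `comparison_table`): one row per contrast with
#'   group means, mean difference, t, df, raw and Sidak-adjusted p, and a
#'   significance flag.
#' @export
strain_sex_posthoc <- function(table, trait,
                               family = c("strain_vs_ref", "founder_vs_do"),
                               ref = "B6", alpha = 0.05) {
  family <- match.arg(family)
  if (family == "strain_vs_ref") {
    d <- if ("population" %in% names(table)) {
      table[table$population == "founder", , drop = FALSE]
    } else {
      table
    }
    if (!ref %in% d$strain) {
      stop("strain_sex_posthoc: reference group '", ref,
           "' absent from the table", call. = FALSE)
    }
    d$..g <- factor(d$strain)
    groups <- setdiff(levels(d$..g), ref)
    ref_lab <- ref
  } else {
    if (!"population" %in% names(table) ||
        !all(c("founder", "DO") %in% table$population)) {
      stop("strain_sex_posthoc: founder_vs_do family needs both ",
           "populations", call. = FALSE)
    }
    d <- table
    d$..g <- factor(d$population, levels = c("founder", "DO"))
    groups <- "DO"
    ref_lab <- "founder"
  }
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  d$sex <- factor(d$sex)
  d$..y <- d[[trait]]
  fit <- stats::lm(..y ~ ..g * sex, data = d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  dfres <- fit$df.residual
  cellmean <- tapply(d$..y, list(d$..g, d$sex), mean)
  celln <- base::table(d$..g, d$sex)
  rows <- list()
  for (sx in levels(d$sex)) {
    fam <- lapply(groups, function(g) {
      m1 <- cellmean[g, sx]; m2 <- cellmean[ref_lab, sx]
      n1 <- celln[g, sx]; n2 <- celln[ref_lab, sx]
      if (is.na(m1) || is.na(m2) || n1 < 1L || n2 < 1L) return(NULL)
      se <- sqrt(mse * (1 / n1 + 1 / n2))
      tt <- (m1 - m2) / se
      p <- 2 * stats::pt(-abs(tt), dfres)
      data.frame(contrast = paste0(g, " vs ", ref_lab, " (", sx, ")"),
                 sex = sx, group = g, reference = ref_lab,
                 mean_group = m1, mean_ref = m2, diff = m1 - m2, se = se,
                 t = tt, df = dfres, p = p, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, fam)
    if (is.null(fam)) next
    fam$m <- nrow(fam)
    fam$p_adj <- .sidak(fam$p, nrow(fam))
    rows[[sx]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- out$p_adj < alpha
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Classify fasting blood glucose
#'
#' Hyperglycemia is defined as fasting blood glucose strictly above
#' 250 mg/dL.
#'
#' @param fbg Numeric vector of fasting blood glucose values, mg/dL
#'   (>= 0; `NA` allowed and propagated).
#' @param threshold Cutoff, mg/dL (default 250).
#' @return Character vector, `"hyperglycemic"` or `"normal"`.
#' @export
classify_glycemia <- function(fbg, threshold = 250) {
  if (any(fbg < 0, na.rm = TRUE)) {
    stop("classify_glycemia: fasting blood glucose must be >= 0",
         call. = FALSE)
  }
  ifelse(is.na(fbg), NA_character_,
         ifelse(fbg > threshold, "hyperglycemic", "normal"))
}
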