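# Conventional inference: Gaussian / quasi-Poisson treatment contrasts,
# Benjamini-Hochberg FDR adjustment, and Yates-corrected chi-squared tests
# of female mortality.

#' Benjamini-Hochberg step-up adjustment
#'
#' Direct implementation of the step-up rule: sort p ascending, multiply
#' p_(i) by m/i, enforce monotonicity from the largest rank down, cap at 1,
#' return in the input order. Idempotent, order-preserving, p_adj >= p_raw.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled))) # step-up monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pearson chi-squared test on a mortality table
#'
#' Pearson statistic on an r x k contingency table (typically survived vs
#' died across treatments), with the Yates continuity correction applied to
#' 2 x 2 tables when `yates = TRUE`. Degrees of freedom are the conventional
#' (r - 1)(k - 1); the sample-size based df (n - 1) that some reports print
#' is returned alongside as `df_nminus1` for comparability.
#'
#' @param table Matrix of nonnegative integer counts, at least 2 x 2.
#' @param yates Apply the continuity correction for 2 x 2 tables.
#' @return List with `chi2`, `df`, `p`, `df_nminus1`, `yates_applied`.
#' @export
chisq_mortality <- function(table, yates = TRUE) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("chisq_mortality: need >= 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("chisq_mortality: counts must be nonnegative integers")
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chisq_mortality: zero row or column margin (degenerate table)")
  }
  expected <- outer(rs, cs) / n
  apply_yates <- yates && nrow(tab) == 2 && ncol(tab) == 2
  dev <- abs(tab - expected)
  if (apply_yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       df_nminus1 = n - 1,
       yates_applied = apply_yates)
}

#' Female mortality table for one flour type
#'
#' Counts of survived vs died focal females per yeast level.
#'
#' @param data A `fitness_data` object.
#' @param flour Flour type.
#' @param assay Optional assay filter (default both assays combined).
#' @return 2 x k integer matrix (rows survived/died, columns yeast levels).
#' @export
mortality_table <- function(data, flour, assay = NULL) {
  fem <- cell_subset(data, sex = "female", flour = flour, assay = assay)
  lev <- intersect(fitness_levels$yeast, unique(fem$yeast))
  tab <- vapply(lev, function(y) {
    s <- fem$survived[fem$yeast == y]
    c(survived = sum(s), died = sum(!s))
  }, numeric(2))
  matrix(as.integer(tab), nrow = 2,
         dimnames = list(c("survived", "died"), lev))
}

glm_response <- function(data, response) {
  switch(response,
    offspring = reproductive_success(data),
    body_mass = data$body_mass_mg,
    mating_success = {
      stopifnot(all(data$sex == "male"))
      male_fitness_components(data)$MS # row order preserved
    },
    stop("unknown response: ", response)
  )
}

pairwise_contrasts <- function(fit, factor_name, levels_present) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  dfres <- fit$df.residual
  rows <- list()
  for (i in seq_along(levels_present)) {
    for (j in seq_along(levels_present)) {
      if (j <= i) next
      # estimate = level_j minus level_i on the link scale (a "A - B"
      # contrast label with the sign convention of treatment coding)
      ci <- paste0(factor_name, levels_present[i])
      cj <- paste0(factor_name, levels_present[j])
      k <- stats::setNames(numeric(length(beta)), names(beta))
      if (cj %in% names(beta)) k[cj] <- 1
      if (ci %in% names(beta)) k[ci] <- -1
      est <- sum(k * beta)
      se <- sqrt(drop(t(k) %*% V %*% k))
      tval <- est / se
      rows[[length(rows) + 1]] <- data.frame(
        contrast = paste(levels_present[i], "-", levels_present[j]),
        estimate = est, se = se, t = tval,
        p_raw = 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Treatment-contrast GLM for one design cell
#'
#' Fits `response ~ yeast` (or `~ laying_week`) by IRLS with the Gaussian or
#' quasi-Poisson family, and reports all pairwise treatment contrasts on the
#' link scale with dispersion-scaled standard errors, t statistics, raw and
#' BH-adjusted p-values, plus the omnibus F test. The quasi-Poisson
#' dispersion is the Pearson estimator, so quasi-Poisson SEs equal Poisson
#' SEs times sqrt(dispersion).
#'
#' @param data A `fitness_data` object.
#' @param response "offspring", "body_mass" or "mating_success" (males only).
#' @param family "gaussian" or "quasipoisson". Defaults follow the
#'   conventions of these assays: Gaussian for body mass, quasi-Poisson for
#'   counts.
#' @param sex,flour,assay Cell selectors (body-mass analyses conventionally
#'   combine both assays: pass `assay = NULL`).
#' @param predictor Factor to contrast: "yeast" (default) or "laying_week"
#'   (the week-1 vs week-2 female recovery sub-assay).
#' @param include_dead Include dead females (default `TRUE`).
#' @return A `contrast_table` data.frame with columns `family`, `response`,
#'   `sex`, `flour`, `assay`, `contrast`, `estimate`, `se`, `t`, `p_raw`,
#'   `p_adj`, and attributes `omnibus` (list F, df, p) and `fit`.
#' @export
fit_treatment_glm <- function(data, response,
                              family = if (response == "body_mass")
                                "gaussian" else "quasipoisson",
                              sex = NULL, flour = NULL, assay = NULL,
                              predictor = c("yeast", "laying_week"),
                              include_dead = TRUE) {
  predictor <- match.arg(predictor)
  family <- match.arg(family, c("gaussian", "quasipoisson"))
  cell <- cell_subset(data, sex = sex, flour = flour, assay = assay,
                      include_dead = include_dead)
  if (response == "mating_success") {
    cell <- cell_subset(cell, sex = "male")
  }
  y <- glm_response(cell, response)
  x <- cell[[predictor]]
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  lev <- intersect(
    if (predictor == "yeast") fitness_levels$yeast
    else fitness_levels$laying_week, unique(x)
  )
  if (length(lev) < 2) stop("fit_treatment_glm: need >= 2 ", predictor,
                            " levels in this cell (design error)")
  if (family == "quasipoisson" && all(y == 0)) {
    stop("fit_treatment_glm: all counts zero (degenerate)")
  }
  x <- factor(x, levels = lev)
  fam <- if (family == "gaussian") stats::gaussian() else
    stats::quasipoisson()
  fit <- stats::glm(y ~ x, family = fam)
  names(fit$coefficients) <- sub("^x", predictor, names(fit$coefficients))

  contrasts <- pairwise_contrasts(fit, predictor, lev)
  contrasts$p_adj <- bh_adjust(contrasts$p_raw)
  an <- stats::anova(fit, test = "F")
  omnibus <- list(F = an$F[2], df = c(an$Df[2], fit$df.residual),
                  p = an$`Pr(>F)`[2])

  out <- cbind(
    data.frame(family = family, response = response,
               sex = if (is.null(sex)) "both" else sex,
               flour = if (is.null(flour)) "both" else flour,
               assay = if (is.null(assay)) "both" else assay,
               stringsAsFactors = FALSE),
    contrasts
  )
  attr(out, "omnibus") <- omnibus
  attr(out, "fit") <- fit
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Sex-by-treatment interaction on relativized response
#'
#' Tests whether a treatment effect differs between the sexes by fitting
#' `relativized response ~ sex * yeast`, where the response of each sex is
#' first divided by that sex's control-cell mean (so a sex:treatment
#' interaction coefficient measures the sex difference in proportional
#' response). Also reports the per-sex proportional reduction relative to
#' control.
#'
#' @param data A `fitness_data` object.
#' @param response "body_mass" or "offspring".
#' @param flour Flour type.
#' @param stressed_yeast Stressed level contrasted against the control.
#' @param assay Optional assay filter (`NULL` combines assays).
#' @return List with `t`, `df`, `p` of the interaction coefficient and
#'   `reduction_pct` (named vector, per-sex percent reduction vs control).
#' @export
sex_treatment_interaction <- function(data, response, flour,
                                      stressed_yeast = "none", assay = NULL) {
  cell <- cell_subset(data, flour = flour,
                      yeast = c("control_5pct", stressed_yeast),
                      assay = assay)
  y <- glm_response(cell, response)
  keep <- !is.na(y)
  y <- y[keep]
  sex <- factor(cell$sex[keep], levels = fitness_levels$sex)
  yeast <- factor(cell$yeast[keep],
                  levels = c("control_5pct", stressed_yeast))
  # relativize within sex by control mean
  yr <- y
  red <- c(male = NA_real_, female = NA_real_)
  for (s in levels(sex)) {
    ctrl_mean <- mean(y[sex == s & yeast == "control_5pct"])
    yr[sex == s] <- y[sex == s] / ctrl_mean
    red[s] <- 100 * (1 - mean(y[sex == s & yeast == stressed_yeast]) /
                       ctrl_mean)
  }
  fit <- stats::glm(yr ~ sex * yeast, family = stats::gaussian())
  sm <- stats::summary.glm(fit)$coefficients
  irow <- grep(":", rownames(sm))
  list(
    estimate = sm[irow, "Estimate"],
    t = sm[irow, "t value"],
    df = fit$df.residual,
    p = sm[irow, "Pr(>|t|)"],
    reduction_pct = red,
    fit = fit
  )
}
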