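# Relativized fitness, selection coefficients against stressed individuals,
# and the opportunity for selection (Crow's I).

#' Relativize fitness values by their group mean
#'
#' Divides each value by the group mean, so the relativized values average
#' exactly 1. The variance of this vector is the opportunity for selection.
#'
#' @param values Nonnegative numeric vector, length >= 2.
#' @return Numeric vector with mean exactly 1.
#' @export
relativize <- function(values) {
  if (length(values) < 2) {
    stop("relativize: need at least 2 values (insufficient data)")
  }
  if (anyNA(values) || any(values < 0)) {
    stop("relativize: values must be nonnegative and non-missing")
  }
  m <- mean(values)
  if (m <= 0) degenerate_error("relativize: group mean is zero")
  values / m
}

#' Selection coefficient against stressed individuals
#'
#' s = 1 - mean(W_stressed) / mean(W_control): the proportional fitness
#' deficit of the stressed class relative to the control class. s <= 1
#' always; negative values mean stressed individuals outperform controls.
#' Invariant to multiplying both groups by a common positive constant.
#'
#' @param control_W,stressed_W Nonnegative fitness vectors (offspring counts).
#' @return Scalar s.
#' @export
selection_coefficient <- function(control_W, stressed_W) {
  if (length(control_W) == 0 || length(stressed_W) == 0) {
    stop("selection_coefficient: both groups must be nonempty")
  }
  mc <- mean(control_W)
  if (mc <= 0) degenerate_error("selection_coefficient: control mean is zero")
  1 - mean(stressed_W) / mc
}

#' Opportunity for selection
#'
#' I = sample variance (n - 1 denominator) of mean-relativized fitness,
#' equivalently var(values) / mean(values)^2. Zero iff fitness is constant;
#' an upper bound on the strength of directional selection.
#'
#' @param values Nonnegative fitness vector, length >= 2, positive mean.
#' @return Scalar I >= 0.
#' @export
opportunity_for_selection <- function(values) {
  stats::var(relativize(values))
}

new_selection_estimate <- function(boot, n_control, n_stressed, cell,
                                   n_boot, seed) {
  structure(list(
    cell = cell,
    s_point = unname(boot$point),
    s_boot_mean = unname(boot$boot_mean),
    ci_low = if (is.null(boot$ci)) NA_real_ else unname(boot$ci["low", 1]),
    ci_high = if (is.null(boot$ci)) NA_real_ else unname(boot$ci["high", 1]),
    replicates = boot$replicates,
    n_control = n_control, n_stressed = n_stressed,
    n_boot = as.integer(n_boot), n_degenerate = boot$n_degenerate,
    seed = seed
  ), class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("Selection estimate [%s]\n", paste(unlist(x$cell),
                                                 collapse = " / ")))
  cat(sprintf("  s = %.4f", x$s_point))
  if (!is.null(x$s_boot_mean)) {
    cat(sprintf("  (boot mean %.4f, 95%% CI %.4f to %.4f, %d replicates)",
                x$s_boot_mean, x$ci_low, x$ci_high, x$n_boot))
  }
  cat(sprintf("\n  n_control = %d, n_stressed = %d\n",
              x$n_control, x$n_stressed))
  invisible(x)
}

#' Estimate the selection coefficient for one design cell
#'
#' Compares stressed focal individuals to the control treatment within one
#' (assay, sex, flour) cell. The bootstrap resamples the control and
#' stressed groups independently with replacement at their original sizes;
#' replicates whose resampled control mean is zero are redrawn and counted.
#'
#' @param data A `fitness_data` object.
#' @param sex "male" or "female".
#' @param flour "wheat" or "whole_wheat".
#' @param stressed_yeast Stressed treatment level ("none" or "low_1pct").
#' @param assay Assay arm (default "focal_only", the arm in which only the
#'   focal individual is treated).
#' @param control_yeast Control level (default "control_5pct").
#' @param n_boot Bootstrap replicates (default 10000); 0 gives the point
#'   estimate only.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param include_dead Include focal individuals that died during laying.
#' @return A `selection_estimate`.
#' @export
estimate_selection <- function(data, sex, flour, stressed_yeast,
                               assay = "focal_only",
                               control_yeast = "control_5pct",
                               n_boot = 10000, level = 0.95, seed = NULL,
                               include_dead = TRUE) {
  ctrl <- cell_subset(data, sex, flour, control_yeast, assay, include_dead)
  strs <- cell_subset(data, sex, flour, stressed_yeast, assay, include_dead)
  if (nrow(ctrl) == 0 || nrow(strs) == 0) {
    stop("estimate_selection: empty control or stressed cell")
  }
  w <- list(control = reproductive_success(ctrl),
            stressed = reproductive_success(strs))
  boot <- bootstrap(w, function(g) selection_coefficient(g[[1]], g[[2]]),
                    n = n_boot, level = level, seed = seed)
  new_selection_estimate(
    boot, length(w$control), length(w$stressed),
    cell = list(assay = assay, sex = sex, flour = flour,
                yeast = stressed_yeast),
    n_boot = n_boot, seed = seed
  )
}

#' Estimate the opportunity for selection for one design cell
#'
#' I with a percentile bootstrap CI from resampling focal individuals with
#' replacement.
#'
#' @inheritParams estimate_selection
#' @param yeast Treatment level of the cell.
#' @param assay Assay arm (default "whole_group", the population-level
#'   manipulation used to measure I).
#' @return An `opportunity_estimate`: list with `I_point`, `I_boot_mean`,
#'   `ci_low`, `ci_high`, `n`, `n_boot`, `seed`, `cell`.
#' @export
estimate_opportunity <- function(data, sex, flour, yeast,
                                 assay = "whole_group", n_boot = 10000,
                                 level = 0.95, seed = NULL,
                                 include_dead = TRUE) {
  cell <- cell_subset(data, sex, flour, yeast, assay, include_dead)
  if (nrow(cell) < 2) stop("estimate_opportunity: need >= 2 focals in cell")
  w <- reproductive_success(cell)
  boot <- bootstrap(w, function(g) opportunity_for_selection(g[[1]]),
                    n = n_boot, level = level, seed = seed)
  structure(list(
    cell = list(assay = assay, sex = sex, flour = flour, yeast = yeast),
    I_point = unname(boot$point),
    I_boot_mean = unname(boot$boot_mean),
    ci_low = if (is.null(boot$ci)) NA_real_ else unname(boot$ci["low", 1]),
    ci_high = if (is.null(boot$ci)) NA_real_ else unname(boot$ci["high", 1]),
    n = length(w), n_boot = as.integer(n_boot),
    n_degenerate = boot$n_degenerate, seed = seed
  ), class = "opportunity_estimate")
}

#' @export
print.opportunity_estimate <- function(x, ...) {
  cat(sprintf("Opportunity for selection [%s]\n  I = %.4f",
              paste(unlist(x$cell), collapse = " / "), x$I_point))
  if (!is.null(x$I_boot_mean)) {
    cat(sprintf(" (boot mean %.4f, 95%% CI %.4f to %.4f)",
                x$I_boot_mean, x$ci_low, x$ci_high))
  }
  cat(sprintf("\n  n = %d\n", x$n))
  invisible(x)
}

#' Sex difference in the selection coefficient
#'
#' delta = s_male - s_female for a shared (flour, stressed treatment, assay)
#' cell pair. The CI comes from a joint bootstrap over all four groups
#' (male/female x control/stressed); the p-value from a permutation test
#' that shuffles sex labels among focal individuals within each treatment
#' stratum (control and stressed separately, so group sizes and treatment
#' composition are preserved) and recomputes s per pseudo-sex. Two-sided
#' add-one-smoothed p.
#'
#' @inheritParams estimate_selection
#' @param n_perm Number of permutations (default 10000).
#' @return List with `delta` (plug-in s_male - s_female), `delta_boot_mean`,
#'   `ci` (length-2 vector), `p`, per-sex point estimates, and sizes.
#' @export
sex_difference_in_s <- function(data, flour, stressed_yeast,
                                assay = "focal_only",
                                control_yeast = "control_5pct",
                                n_boot = 10000, n_perm = 10000, level = 0.95,
                                seed = NULL, include_dead = TRUE) {
  grab <- function(sex, yeast) {
    reproductive_success(cell_subset(data, sex, flour, yeast, assay,
                                     include_dead))
  }
  g <- list(mc = grab("male", control_yeast),
            ms = grab("male", stressed_yeast),
            fc = grab("female", control_yeast),
            fs = grab("female", stressed_yeast))
  if (any(vapply(g, length, 1L) == 0)) {
    stop("sex_difference_in_s: one or more cells are empty")
  }
  delta_stat <- function(gr) {
    selection_coefficient(gr[[1]], gr[[2]]) -
      selection_coefficient(gr[[3]], gr[[4]])
  }
  boot_seed <- if (is.null(seed)) NULL else spawn_seed(seed, "sexdiff/boot")
  perm_seed <- if (is.null(seed)) NULL else spawn_seed(seed, "sexdiff/perm")
  boot <- bootstrap(g, delta_stat, n = n_boot, level = level,
                    seed = boot_seed)

  # Permutation: rows are (W, stratum); sex labels shuffled within stratum.
  males <- data.frame(w = c(g$mc, g$ms),
                      stratum = rep(c("control", "stressed"),
                                    c(length(g$mc), length(g$ms))))
  females <- data.frame(w = c(g$fc, g$fs),
                        stratum = rep(c("control", "stressed"),
                                      c(length(g$fc), length(g$fs))))
  stat <- function(a, b) {
    tryCatch(
      selection_coefficient(a$w[a$stratum == "control"],
                            a$w[a$stratum == "stressed"]) -
        selection_coefficient(b$w[b$stratum == "control"],
                              b$w[b$stratum == "stressed"]),
      oppsel_degenerate = function(e) NA_real_
    )
  }
  perm <- if (n_perm >= 1) {
    permutation_test(males, females, stat, n = n_perm,
                     alternative = "two_sided", seed = perm_seed,
                     strata = c(males$stratum, females$stratum))
  }

  list(
    cell = list(assay = assay, flour = flour, yeast = stressed_yeast),
    s_male = selection_coefficient(g$mc, g$ms),
    s_female = selection_coefficient(g$fc, g$fs),
    delta = unname(boot$point),
    delta_boot_mean = unname(boot$boot_mean),
    ci = if (is.null(boot$ci)) c(NA_real_, NA_real_) else
      unname(boot$ci[, 1]),
    p = if (is.null(perm)) NA_real_ else perm$p,
    n = vapply(g, length, 1L),
    n_boot = as.integer(n_boot), n_perm = as.integer(n_perm), seed = seed
  )
}
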