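# Synthetic competitive mating-assay data.
#
# The generator emulates the mating-group design of the diet-quality
# experiment: 2 flour types x yeast treatments (control 5%, 1% in
# whole-wheat only, none), two assay arms (focal-only treated vs whole-group
# treated), groups of 1 focal + 1 marked competitor + 2 partner females.
# Offspring counts are negative binomial (the generative stand-in for the
# quasi-Poisson family used at analysis time, which has no generative form);
# paternity under sperm competition is beta-binomial around the focal's
# competitive weight share; mating failure is Bernoulli per partner; female
# mortality truncates the laying window by a uniform fraction.

yeast_cells <- function() {
  data.frame(
    flour = c("wheat", "wheat", "whole_wheat", "whole_wheat", "whole_wheat"),
    yeast = c("control_5pct", "none", "control_5pct", "low_1pct", "none"),
    stringsAsFactors = FALSE
  )
}

cell_key <- function(flour, yeast) paste(flour, yeast, sep = ".")

#' Simulation parameters for the mating-assay generator
#'
#' Defaults are calibrated to the published regime of this assay design
#' (documented in the methods vignette): control fecundity of ~50 adult
#' offspring per female over the laying period with negative-binomial
#' dispersion theta = 5.5 (so control I is near 0.2), a ~14-fold fecundity
#' drop under yeast deprivation in wheat (log contrast -2.64), male mating
#' probabilities mirroring the mating-success contrasts, a competitor
#' paternity weight of 0.35 (the marker strain sires ~65% fewer offspring),
#' body masses near 2 mg with the observed percent reductions, and female
#' laying-period mortality of 4%/19% (wheat) and 0/0.5/1.1% (whole-wheat).
#'
#' @param n_focal Focal individuals per (sex x flour x yeast) cell.
#' @param mu Named vector of mean fecundity per female (adult offspring over
#'   the laying period), keyed `"<flour>.<yeast>"`.
#' @param theta Negative-binomial size (dispersion; smaller = more
#'   overdispersed).
#' @param p_mate Named vector: probability that a given male (of that
#'   treatment) inseminates a given partner female.
#' @param w_mult Named vector: multiplicative effect of treatment on a
#'   male's competitive paternity weight (control = 1).
#' @param w_competitor Baseline paternity weight of the marked competitor
#'   strain relative to a control wildtype male (1).
#' @param kappa Beta-binomial concentration of the paternity share (larger =
#'   closer to the deterministic weight share; `Inf` allowed).
#' @param mass_mean List with `male` and `female` named vectors of mean body
#'   mass (mg) per cell.
#' @param mass_sd Body-mass standard deviation (mg).
#' @param mortality Named vector: probability a focal female dies before the
#'   end of the laying period.
#' @param seed Default seed for [simulate_experiment()].
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n_focal = 50,
                       mu = c(wheat.control_5pct = 50, wheat.none = 3.6,
                              whole_wheat.control_5pct = 50,
                              whole_wheat.low_1pct = 43.5,
                              whole_wheat.none = 40),
                       theta = 5.5,
                       p_mate = c(wheat.control_5pct = 0.95,
                                  wheat.none = 0.67,
                                  whole_wheat.control_5pct = 0.95,
                                  whole_wheat.low_1pct = 0.86,
                                  whole_wheat.none = 0.74),
                       w_mult = c(wheat.control_5pct = 1, wheat.none = 0.028,
                                  whole_wheat.control_5pct = 1,
                                  whole_wheat.low_1pct = 1,
                                  whole_wheat.none = 0.9),
                       w_competitor = 0.35,
                       kappa = 10,
                       mass_mean = list(
                         male = c(wheat.control_5pct = 1.85,
                                  wheat.none = 1.77,
                                  whole_wheat.control_5pct = 1.85,
                                  whole_wheat.low_1pct = 1.85,
                                  whole_wheat.none = 1.85),
                         female = c(wheat.control_5pct = 2.10,
                                    wheat.none = 1.91,
                                    whole_wheat.control_5pct = 2.10,
                                    whole_wheat.low_1pct = 2.10,
                                    whole_wheat.none = 2.10)),
                       mass_sd = 0.12,
                       mortality = c(wheat.control_5pct = 0.04,
                                     wheat.none = 0.19,
                                     whole_wheat.control_5pct = 0,
                                     whole_wheat.low_1pct = 0.005,
                                     whole_wheat.none = 0.011),
                       seed = NULL) {
  p <- list(n_focal = n_focal, mu = mu, theta = theta, p_mate = p_mate,
            w_mult = w_mult, w_competitor = w_competitor, kappa = kappa,
            mass_mean = mass_mean, mass_sd = mass_sd, mortality = mortality,
            seed = seed)
  keys <- cell_key(yeast_cells()$flour, yeast_cells()$yeast)
  for (field in c("mu", "p_mate", "w_mult", "mortality")) {
    missing <- setdiff(keys, names(p[[field]]))
    if (length(missing)) stop("sim_params: ", field, " missing cell(s) ",
                              paste(missing, collapse = ", "))
  }
  stopifnot(
    n_focal >= 1, all(p$mu > 0), p$theta > 0,
    all(p$p_mate >= 0 & p$p_mate <= 1),
    all(p$w_mult >= 0), p$w_competitor >= 0, p$kappa > 0,
    p$mass_sd > 0, all(p$mortality >= 0 & p$mortality <= 1)
  )
  class(p) <- "sim_params"
  p
}

# Beta-binomial paternity draw: n trials, mean share m, concentration kappa.
# kappa = Inf collapses to Binomial(n, m); m in {0, 1} is deterministic.
rbetabinom <- function(k, n, m, kappa) {
  share <- if (is.infinite(kappa)) {
    rep(m, length.out = k)
  } else {
    m <- rep(m, length.out = k)
    out <- numeric(k)
    det <- m <= 0 | m >= 1
    out[det] <- m[det]
    out[!det] <- stats::rbeta(sum(!det), m[!det] * kappa,
                              (1 - m[!det]) * kappa)
    out
  }
  stats::rbinom(k, size = n, prob = share)
}

simulate_males <- function(p, flour, yeast, assay, ids) {
  n <- length(ids)
  focal_cell <- cell_key(flour, yeast)
  other_cell <- if (assay == "focal_only") {
    cell_key(flour, "control_5pct") # competitors & partners on control diet
  } else {
    focal_cell # whole-group manipulation: everyone treated
  }
  mu_partner <- p$mu[other_cell]
  p_f <- p$p_mate[focal_cell]
  p_c <- p$p_mate[other_cell]
  w_f <- 1 * p$w_mult[focal_cell]
  w_c <- p$w_competitor * p$w_mult[other_cell]

  draw_partner <- function() {
    N <- stats::rnbinom(n, size = p$theta, mu = mu_partner)
    mate_f <- stats::runif(n) < p_f
    mate_c <- stats::runif(n) < p_c
    total <- ifelse(mate_f | mate_c, N, 0L)
    sired <- integer(n)
    only_f <- mate_f & !mate_c
    both <- mate_f & mate_c
    sired[only_f] <- total[only_f]
    if (any(both)) {
      m <- if (w_f + w_c > 0) w_f / (w_f + w_c) else 0
      sired[both] <- rbetabinom(sum(both), total[both], m, p$kappa)
    }
    list(total = as.integer(total), sired = as.integer(sired))
  }
  p1 <- draw_partner()
  p2 <- draw_partner()
  data.frame(
    focal_id = ids, sex = "male", flour = flour, yeast = yeast,
    assay = assay, genotype = "wildtype",
    body_mass_mg = round(stats::rnorm(n, p$mass_mean$male[focal_cell],
                                      p$mass_sd), 2),
    survived = TRUE,
    p1_total = p1$total, p1_sired = p1$sired,
    p2_total = p2$total, p2_sired = p2$sired,
    laying_week = NA_character_,
    stringsAsFactors = FALSE
  )
}

simulate_females <- function(p, flour, yeast, assay, ids) {
  n <- length(ids)
  focal_cell <- cell_key(flour, yeast)
  male_cell <- if (assay == "focal_only") {
    cell_key(flour, "control_5pct")
  } else {
    focal_cell
  }
  # fertilized if at least one of the two partner males inseminates her
  p_fert <- 1 - (1 - p$p_mate[male_cell])^2
  clutch <- stats::rnbinom(n, size = p$theta, mu = p$mu[focal_cell])
  clutch[stats::runif(n) >= p_fert] <- 0L
  died <- stats::runif(n) < p$mortality[focal_cell]
  # death truncates the laying window at a uniform point
  clutch[died] <- as.integer(floor(clutch[died] * stats::runif(sum(died))))
  data.frame(
    focal_id = ids, sex = "female", flour = flour, yeast = yeast,
    assay = assay, genotype = "wildtype",
    body_mass_mg = round(stats::rnorm(n, p$mass_mean$female[focal_cell],
                                      p$mass_sd), 2),
    survived = !died,
    p1_total = as.integer(clutch), p1_sired = as.integer(clutch),
    p2_total = NA_integer_, p2_sired = NA_integer_,
    laying_week = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a competitive mating-assay experiment
#'
#' Generates one assay arm across all flour x yeast cells and both sexes.
#' Per focal male, each of his 2 partner females draws a clutch
#' NegBin(mu, theta) with mu taken from the partners' treatment under the
#' assay rule (partners on control diet in `focal_only`, treated in
#' `whole_group`); the focal and the competitor each inseminate her with
#' their treatment's mating probability; under double mating the focal's
#' sired count is beta-binomial around his competitive weight share. Per
#' focal female, a NegBin clutch with her own treatment's mean, zeroed if
#' neither partner male inseminates her, truncated uniformly on death.
#' Body mass is Gaussian per (sex, cell). The result passes dataset
#' validation and is byte-deterministic given the seed.
#'
#' @param params A [sim_params()] object.
#' @param assay "focal_only" or "whole_group".
#' @param seed Integer seed (falls back to `params$seed`).
#' @return A `fitness_data` object.
#' @export
simulate_experiment <- function(params = sim_params(),
                                assay = c("focal_only", "whole_group"),
                                seed = params$seed) {
  assay <- match.arg(assay)
  stopifnot(inherits(params, "sim_params"))
  cells <- yeast_cells()
  with_seed(seed, {
    parts <- list()
    for (i in seq_len(nrow(cells))) {
      fl <- cells$flour[i]; ye <- cells$yeast[i]
      tag <- function(sex) sprintf("%s_%s_%s_%s_%03d",
                                   substr(assay, 1, 1), fl, ye, sex,
                                   seq_len(params$n_focal))
      parts[[length(parts) + 1]] <-
        simulate_males(params, fl, ye, assay, tag("m"))
      parts[[length(parts) + 1]] <-
        simulate_females(params, fl, ye, assay, tag("f"))
    }
    as_fitness_data(do.call(rbind, parts),
                    provenance = sprintf("simulated (assay=%s, seed=%s)",
                                         assay, format(seed)))
  })
}

#' Opportunity for selection of negative-binomial fitness
#'
#' Closed form on the relativized scale: var/mean^2 = 1/mu + 1/theta.
#'
#' @param mu,theta Negative-binomial mean and size.
#' @return Expected I.
#' @export
negbin_opportunity <- function(mu, theta) 1 / mu + 1 / theta

#' Generative ground truth for a parameter set
#'
#' Closed-form expectations implied by the generator, for parameter-recovery
#' checks. Selection coefficients follow from expected fitness per cell:
#' for females E[W] = p_fert * mu * (1 - q/2) (uniform truncation halves a
#' dying female's expected clutch), for males
#' E[W] = 2 * mu_partner * [p_f (1 - p_c) + p_f p_c share]. Female I is the
#' negative-binomial closed form 1/mu + 1/theta, exact when mating failure
#' and mortality are switched off; male expectations beyond E[W] are
#' obtained by a Monte-Carlo oracle (`oppsel:::simulate_males` at large n).
#'
#' @param params A [sim_params()] object.
#' @param assay Assay arm.
#' @return List with `expected_W` (per sex/cell), `s` (per sex and stressed
#'   cell vs control, focal-only logic), and `I_female_nb` (closed form,
#'   valid when p_mate = 1 and mortality = 0).
#' @export
ground_truth <- function(params, assay = "focal_only") {
  cells <- yeast_cells()
  keys <- cell_key(cells$flour, cells$yeast)
  male_env <- function(key, flour) {
    if (assay == "focal_only") cell_key(flour, "control_5pct") else key
  }
  EW_f <- EW_m <- stats::setNames(numeric(length(keys)), keys)
  for (i in seq_along(keys)) {
    key <- keys[i]; fl <- cells$flour[i]
    env <- male_env(key, fl)
    p_fert <- 1 - (1 - params$p_mate[env])^2
    q <- params$mortality[key]
    EW_f[i] <- p_fert * params$mu[key] * (1 - q / 2)
    p_f <- params$p_mate[key]
    p_c <- params$p_mate[env]
    w_f <- params$w_mult[key]
    w_c <- params$w_competitor * params$w_mult[env]
    share <- if (w_f + w_c > 0) w_f / (w_f + w_c) else 0
    EW_m[i] <- 2 * params$mu[env] * (p_f * (1 - p_c) + p_f * p_c * share)
  }
  s_tab <- do.call(rbind, lapply(c("wheat", "whole_wheat"), function(fl) {
    stressed <- setdiff(cells$yeast[cells$flour == fl], "control_5pct")
    ctrl <- cell_key(fl, "control_5pct")
    data.frame(flour = fl, yeast = stressed,
               s_male = 1 - EW_m[cell_key(fl, stressed)] / EW_m[ctrl],
               s_female = 1 - EW_f[cell_key(fl, stressed)] / EW_f[ctrl],
               row.names = NULL)
  }))
  list(
    expected_W = data.frame(cell = keys, male = unname(EW_m),
                            female = unname(EW_f)),
    s = s_tab,
    I_female_nb = stats::setNames(
      negbin_opportunity(params$mu, params$theta), names(params$mu))
  )
}
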