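test_that("bh_adjust matches the step-up rule and stats::p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)                    # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))      # ties
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # oracle: p.adjust on random vectors; monotone in input ranks
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0)) # rank-monotone, order kept
  }
})

test_that("chi-squared mortality test: closed forms and oracle", {
  # homogeneous table
  h <- chisq_mortality(matrix(10, 2, 2), yates = FALSE)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)

  # frozen direct-formula values for [[20,5],[10,15]]
  tab <- matrix(c(20, 10, 5, 15), 2)
  expect_equal(chisq_mortality(tab, yates = TRUE)$chi2, 6.75)
  expect_equal(chisq_mortality(tab, yates = FALSE)$chi2, 25 / 3)

  # oracle: stats::chisq.test across random tables; Yates <= uncorrected
  set.seed(7)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 20) + 1, 2)
    ours <- chisq_mortality(t2, yates = TRUE)
    ref <- suppressWarnings(chisq.test(t2, correct = TRUE))
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$p, unname(ref$p.value))
    expect_lte(ours$chi2, chisq_mortality(t2, yates = FALSE)$chi2)
  }

  # conventional df plus the n-1 variant logged alongside
  t3 <- matrix(c(40, 2, 38, 4, 35, 6), 2) # 2 x 3
  r3 <- chisq_mortality(t3)
  expect_equal(r3$df, 2)
  expect_equal(r3$df_nminus1, sum(t3) - 1)
  expect_false(r3$yates_applied) # correction is 2x2-only

  expect_error(chisq_mortality(matrix(c(0, 0, 5, 5), 2)), "zero row")
  expect_error(chisq_mortality(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("p decreases as off-diagonal imbalance grows at fixed margins", {
  ps <- sapply(0:5, function(k) {
    chisq_mortality(matrix(c(10 + k, 10 - k, 10 - k, 10 + k), 2),
                    yates = FALSE)$p
  })
  expect_true(all(diff(ps) < 0))
})

test_that("Gaussian treatment GLM recovers group mean differences exactly", {
  p <- clean_params(n_focal = 25)
  d <- simulate_experiment(p, "focal_only", seed = 13)
  tab <- fit_treatment_glm(d, "body_mass", sex = "female", flour = "whole_wheat")
  cell_mean <- function(ye) {
    mean(cell_subset(d, "female", "whole_wheat", ye)$body_mass_mg)
  }
  row <- tab[tab$contrast == "control_5pct - none", ]
  expect_equal(row$estimate, cell_mean("none") - cell_mean("control_5pct"))
  expect_equal(nrow(tab), 3) # all pairwise contrasts of 3 levels
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15) && all(tab$p_adj <= 1))
  expect_false(is.null(attr(tab, "omnibus")$F))
})

test_that("quasi-Poisson contrast recovers a simulated log-fold effect", {
  pars <- clean_params(mu_control = 50, mu_stressed = 50 * exp(-2.6),
                       theta = 8, n_focal = 50)
  d <- simulate_experiment(pars, "focal_only", seed = 29)
  tab <- fit_treatment_glm(d, "offspring", sex = "female", flour = "wheat",
                           assay = "focal_only")
  row <- tab[tab$contrast == "control_5pct - none", ]
  # estimate is on the link (log) scale; true effect -2.6
  expect_lt(abs(row$estimate - (-2.6)), 3 * row$se)
  expect_equal(row$family, "quasipoisson")

  # quasi-Poisson SE = Poisson SE * sqrt(Pearson dispersion)
  fit <- attr(tab, "fit")
  pois <- glm(y ~ x, data = fit$model, family = poisson())
  disp <- sum(residuals(fit, "pearson")^2) / fit$df.residual
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(vcov(pois))) * sqrt(disp)), tolerance = 1e-6)
})

test_that("null simulation: Gaussian contrasts centred with ~nominal size", {
  set.seed(17)
  n_rep <- 200
  reject <- 0L
  ests <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    df <- data.frame(y = rnorm(60), g = rep(c("control_5pct", "none"), 30))
    d <- toy_fitness_df()[rep(1, 60), ]
    d$focal_id <- sprintf("f%02d", 1:60)
    d$sex <- "female"
    d$yeast <- df$g
    d$body_mass_mg <- df$y + 10
    d$p1_total <- d$p1_sired <- 1
    d$p2_total <- d$p2_sired <- NA
    tab <- fit_treatment_glm(as_fitness_data(d), "body_mass")
    ests[i] <- tab$estimate[1]
    reject <- reject + (tab$p_raw[1] < 0.05)
  }
  expect_lt(abs(mean(ests)), 0.05)        # centred at zero
  expect_lt(abs(reject / n_rep - 0.05), 0.045) # type-I error ~ nominal
})

test_that("mating-success GLM and design errors", {
  d <- simulate_experiment(sim_params(n_focal = 30), "focal_only", seed = 3)
  tab <- fit_treatment_glm(d, "mating_success", sex = "male", flour = "wheat",
                           assay = "focal_only")
  expect_equal(tab$response[1], "mating_success")
  # stressed wheat males mate less by construction: negative log contrast
  expect_lt(tab$estimate[tab$contrast == "control_5pct - none"], 0)

  one_level <- cell_subset(d, "male", "wheat", "control_5pct")
  expect_error(fit_treatment_glm(one_level, "offspring"), "design error")
})

test_that("laying-week contrast: the female recovery sub-assay", {
  # week-1 vs week-2 clutches of recovered females as separate records
  set.seed(23)
  n <- 30
  clutch <- c(rpois(n, 20), rpois(n, 20)) # no recovery effect simulated
  df <- data.frame(
    focal_id = c(sprintf("f%02d_w1", 1:n), sprintf("f%02d_w2", 1:n)),
    sex = "female", flour = "whole_wheat", yeast = "none",
    assay = "focal_only", genotype = "wildtype", body_mass_mg = 2,
    survived = TRUE, p1_total = clutch, p1_sired = clutch,
    p2_total = NA, p2_sired = NA,
    laying_week = rep(c("week1", "week2"), each = n),
    stringsAsFactors = FALSE
  )
  tab <- fit_treatment_glm(as_fitness_data(df), "offspring",
                           predictor = "laying_week")
  expect_equal(tab$contrast, "week1 - week2")
  # null effect: log contrast near zero, not significant
  expect_lt(abs(tab$estimate), 3 * tab$se)
  expect_gt(tab$p_raw, 0.01)
})

test_that("sex-by-treatment interaction on relativized body mass", {
  pars <- sim_params(n_focal = 80)
  d <- simulate_experiment(pars, "focal_only", seed = 41)
  r <- sex_treatment_interaction(d, "body_mass", flour = "wheat")
  # generator: females lose 9.05% of mass, males 4.3% (wheat, no yeast)
  expect_lt(abs(r$reduction_pct["female"] - 9.05), 3)
  expect_lt(abs(r$reduction_pct["male"] - 4.3), 3)
  expect_true(is.finite(r$t) && r$df > 0 && r$p >= 0 && r$p <= 1)
})
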