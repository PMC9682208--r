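# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal well-formed fitness table: 2 males + 2 females in one cell.
toy_fitness_df <- function() {
  data.frame(
    focal_id = c("m1", "m2", "f1", "f2"),
    sex = c("male", "male", "female", "female"),
    flour = "wheat",
    yeast = "control_5pct",
    assay = "focal_only",
    genotype = "wildtype",
    body_mass_mg = c(1.85, 1.92, 2.10, NA),
    survived = c(TRUE, TRUE, TRUE, FALSE),
    p1_total = c(20, 8, 12, 0),
    p1_sired = c(10, 8, 12, 0),
    p2_total = c(10, 12, NA, NA),
    p2_sired = c(5, 0, NA, NA),
    laying_week = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Random male records with per-partner counts, one design cell.
random_male_records <- function(n, seed = NULL) {
  draw <- function() {
    tot <- rpois(2, 25)
    sired <- rbinom(2, tot, runif(1, 0.2, 0.9))
    c(tot, sired)
  }
  gen <- function() {
    m <- t(replicate(n, draw()))
    data.frame(
      focal_id = sprintf("m%03d", seq_len(n)),
      sex = "male", flour = "wheat", yeast = "control_5pct",
      assay = "whole_group", genotype = "wildtype",
      body_mass_mg = round(rnorm(n, 1.85, 0.1), 2), survived = TRUE,
      p1_total = m[, 1], p1_sired = m[, 3],
      p2_total = m[, 2], p2_sired = m[, 4],
      laying_week = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) gen() else oppsel:::with_seed(seed, gen())
}

# Brute-force decomposition oracle: every term written out directly from
# its definition, independent of the package's decomposition code path.
oracle_decomposition <- function(MS, Fec, PS) {
  T_ <- MS * Fec * PS
  rel <- function(v) v / mean(v)
  ms <- rel(MS); f <- rel(Fec); p <- rel(PS); t <- rel(T_)
  n <- length(MS)
  v <- function(x) sum((x - mean(x))^2) / (n - 1)
  cv <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  out <- c(I_total = v(t), I_MS = v(ms), I_Fec = v(f), I_PS = v(p),
           cov_MS_Fec = cv(ms, f), cov_MS_PS = cv(ms, p),
           cov_Fec_PS = cv(f, p))
  c(out, remainder = unname(
    out["I_total"] - out["I_MS"] - out["I_Fec"] - out["I_PS"] -
      2 * (out["cov_MS_Fec"] + out["cov_MS_PS"] + out["cov_Fec_PS"])))
}

# Params with all nuisance processes switched off: every mating succeeds,
# nobody dies, so female fitness is exactly NegBin(mu, theta).
clean_params <- function(mu_control = 20, mu_stressed = 2, theta = 5,
                         n_focal = 50, ...) {
  args <- list(
    n_focal = n_focal,
    mu = c(wheat.control_5pct = mu_control, wheat.none = mu_stressed,
           whole_wheat.control_5pct = 10, whole_wheat.low_1pct = 10,
           whole_wheat.none = 10),
    theta = theta,
    p_mate = c(wheat.control_5pct = 1, wheat.none = 1,
               whole_wheat.control_5pct = 1, whole_wheat.low_1pct = 1,
               whole_wheat.none = 1),
    mortality = c(wheat.control_5pct = 0, wheat.none = 0,
                  whole_wheat.control_5pct = 0, whole_wheat.low_1pct = 0,
                  whole_wheat.none = 0)
  )
  do.call(sim_params, utils::modifyList(args, list(...)))
}
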