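make_male <- function(id, tot, sired) {
  data.frame(focal_id = id, sex = "male", flour = "wheat",
             yeast = "control_5pct", assay = "whole_group",
             genotype = "wildtype", body_mass_mg = 1.9, survived = TRUE,
             p1_total = tot[1], p1_sired = sired[1],
             p2_total = tot[2], p2_sired = sired[2],
             laying_week = NA_character_, stringsAsFactors = FALSE)
}

test_that("fitness components: hand cases and the exact product identity", {
  d <- as_fitness_data(rbind(
    make_male("a", c(20, 10), c(10, 5)),  # both partners fertilized
    make_male("b", c(8, 12), c(8, 0)),    # single partner, full share
    make_male("c", c(15, 9), c(0, 0))     # total mating failure
  ))
  comp <- male_fitness_components(d)
  expect_equal(comp$MS, c(2L, 1L, 0L))
  expect_equal(comp$Fec, c(15, 8, 0))
  expect_equal(comp$PS, c(0.5, 1, 0))
  expect_equal(comp$T, c(15, 8, 0))
  expect_equal(comp$residual, c(0, 0, 0)) # T = MS*Fec*PS exactly
  expect_equal(comp$MS * comp$Fec * comp$PS, comp$T)

  # identity holds on random records too (property)
  for (s in 1:10) {
    comp <- male_fitness_components(as_fitness_data(random_male_records(
      12, seed = s)))
    expect_equal(comp$T, comp$MS * comp$Fec * comp$PS)
  }

  # MS = 0 exclusion flag
  comp2 <- male_fitness_components(d, include_ms0 = FALSE)
  expect_equal(comp2$focal_id, c("a", "b"))
})

test_that("per-partner-mean variant reports its nonzero identity residual", {
  d <- as_fitness_data(rbind(
    make_male("a", c(20, 10), c(10, 5)),
    make_male("b", c(30, 10), c(3, 9))
  ))
  comp <- male_fitness_components(d, pooled = FALSE)
  # male b: per-partner shares 0.1 and 0.9 -> PS = 0.5, Fec = 20, T = 12
  expect_equal(comp$PS[2], 0.5)
  expect_equal(comp$Fec[2], 20)
  expect_equal(comp$T[2], 12)
  expect_equal(comp$residual[2], 12 - 2 * 20 * 0.5) # identity residual -8
})

test_that("decomposition matches the brute-force oracle on small cells", {
  for (s in 1:8) {
    d <- as_fitness_data(random_male_records(6, seed = s))
    comp <- male_fitness_components(d)
    if (mean(comp$MS) == 0) next
    got <- decompose_opportunity(comp, n_boot = 0)$terms
    want <- oracle_decomposition(comp$MS, comp$Fec, comp$PS)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("conservation identity holds to machine precision (property)", {
  for (s in 1:50) {
    comp <- male_fitness_components(as_fitness_data(
      random_male_records(10, seed = 100 + s)))
    terms <- decompose_opportunity(comp, n_boot = 0)$terms
    lhs <- terms["I_MS"] + terms["I_Fec"] + terms["I_PS"] +
      2 * (terms["cov_MS_Fec"] + terms["cov_MS_PS"] + terms["cov_Fec_PS"]) +
      terms["remainder"]
    expect_lt(abs(lhs - terms["I_total"]), 1e-12)
  }
})

test_that("degenerate and trivial populations behave as defined", {
  # all males identical -> every term zero
  d <- as_fitness_data(rbind(make_male("a", c(20, 10), c(10, 5)),
                             make_male("b", c(20, 10), c(10, 5))))
  d$p1_total <- c(20, 20); # identical rows except id
  terms <- decompose_opportunity(male_fitness_components(d), n_boot = 0)$terms
  expect_true(all(abs(terms) < 1e-15))

  # all-zero males: component means zero -> degenerate cell error
  dz <- as_fitness_data(rbind(make_male("a", c(5, 5), c(0, 0)),
                              make_male("b", c(4, 4), c(0, 0))))
  expect_error(decompose_opportunity(male_fitness_components(dz)),
               "zero mean")
})

test_that("MS constant and PS = 1 collapses I_total onto I_Fec", {
  set.seed(9)
  tot <- rpois(30, 40) + 1
  rows <- lapply(seq_along(tot), function(i) {
    make_male(sprintf("m%d", i), c(tot[i], tot[i]), c(tot[i], tot[i]))
  })
  comp <- male_fitness_components(as_fitness_data(do.call(rbind, rows)))
  expect_true(all(comp$MS == 2) && all(comp$PS == 1))
  terms <- decompose_opportunity(comp, n_boot = 0)$terms
  expect_equal(unname(terms["I_MS"]), 0)
  expect_equal(unname(terms["I_PS"]), 0)
  expect_equal(unname(terms["I_total"]),
               unname(terms["I_Fec"] + terms["remainder"]))
  expect_lt(abs(terms["remainder"]), 1e-12) # relativized T == relativized Fec
})

test_that("bootstrap CIs per term and tidy output table", {
  comp <- male_fitness_components(as_fitness_data(
    random_male_records(25, seed = 77)))
  dec <- decompose_opportunity(comp, n_boot = 150, seed = 8)
  expect_equal(colnames(dec$ci), names(dec$terms))
  tab <- decomposition_table(dec, cell = list(flour = "wheat"))
  expect_equal(nrow(tab), 8)
  cov_rows <- grepl("^cov_", tab$term)
  expect_equal(tab$contribution[cov_rows], 2 * tab$estimate[cov_rows])
  expect_equal(tab$contribution[!cov_rows], tab$estimate[!cov_rows])
  expect_equal(sum(tab$contribution[tab$term != "I_total"]),
               tab$estimate[tab$term == "I_total"], tolerance = 1e-12)
})
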