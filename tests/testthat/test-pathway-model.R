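defs <- default_metabolites()
trp_tr <- tracer_spec("13C11-Trp", "tryptophan", 11L, isotopic_purity = 1,
                      medium_concentration_mM = 0.08)
ser_tr <- tracer_spec("13C3-Ser", "serine", 3L, isotopic_purity = 1,
                      medium_concentration_mM = 0.4, extra_heavy_atoms = 1L)

test_that("one-carbon pool fraction is the purity-weighted matching share", {
  p <- one_carbon_params(f_trp = 1, trp_intracellular_labeled = 1)
  expect_equal(one_carbon_pool_fraction(p, trp_tr), 1)

  dead <- tracer_spec("dead", "tryptophan", 11L, isotopic_purity = 0)
  expect_equal(one_carbon_pool_fraction(p, dead), 0)

  mix <- one_carbon_params(f_trp = 0.5, f_ser = 0.5)
  tr99 <- tracer_spec("t", "tryptophan", 11L, isotopic_purity = 0.99)
  expect_equal(one_carbon_pool_fraction(mix, tr99), 0.495)

  # only the source carrying the tracer's label contributes
  expect_equal(one_carbon_pool_fraction(mix, ser_tr), 0.5)
  form <- one_carbon_params(f_exo_formate = 0.4, f_other = 0.6)
  expect_equal(one_carbon_pool_fraction(form, trp_tr), 0)
  expect_equal(one_carbon_pool_fraction(
    form, tracer_spec("f", "formate", 1L, isotopic_purity = 1)), 0.4)
})

test_that("IDO1 inactivation zeroes the tryptophan contribution", {
  p <- one_carbon_params(f_trp = 0.7, f_other = 0.3, ido1_active = FALSE)
  expect_equal(one_carbon_pool_fraction(p, trp_tr), 0)
  p_on <- one_carbon_params(f_trp = 0.7, f_other = 0.3)
  expect_equal(one_carbon_pool_fraction(p_on, trp_tr), 0.7)
})

test_that("invalid mixing parameters are rejected", {
  expect_error(one_carbon_params(f_trp = 0.5, f_ser = 0.6, f_other = 0.2),
               "sum to 1")
  expect_error(one_carbon_params(f_trp = -0.1, f_other = 1.1), "\\[0, 1\\]")
})

test_that("fully unlabeled pools leave every metabolite at m+0", {
  p0 <- one_carbon_params(f_other = 1)
  sims <- simulate_labeling(p0, trp_tr, defs)
  for (s in sims) {
    expect_equal(as.numeric(s)[1], 1, tolerance = 1e-12)
  }
})

test_that("kynurenine carries ten of the eleven tryptophan carbons as a block", {
  p <- one_carbon_params(f_trp = 1, trp_intracellular_labeled = 1)
  sims <- simulate_labeling(p, trp_tr, defs)
  kyn <- as.numeric(sims$kynurenine)
  expect_length(kyn, 11)          # m+0 .. m+10
  expect_equal(kyn[11], 1)        # all mass at m+10
  expect_equal(sum(kyn[1:10]), 0)

  # partial pool labeling splits between m+0 and m+10 only
  p2 <- one_carbon_params(f_trp = 1, trp_intracellular_labeled = 0.8)
  kyn2 <- as.numeric(simulate_labeling(p2, trp_tr, defs)$kynurenine)
  expect_equal(kyn2[c(1, 11)], c(0.2, 0.8))
  expect_equal(sum(kyn2[2:10]), 0)
})

test_that("purine labeling is binomial over its two one-carbon positions", {
  p <- one_carbon_params(f_trp = 0.5, f_other = 0.5)
  sims <- simulate_labeling(p, trp_tr, defs)
  atp <- as.numeric(sims$ATP)
  expect_equal(atp[1:3], c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(sum(atp[4:11]), 0)
})

test_that("metabolite definitions reject unknown pools and overfull slots", {
  expect_error(metabolite_def("x", "C5H5", list(list(pool = "mystery", n_positions = 1L))),
               "unknown pool")
  expect_error(metabolite_def("x", "C2H2", list(list(pool = "glycine", n_positions = 3L))),
               "exceed carbon count")
})

test_that("simulated MIDs are normalized and nonnegative for random params", {
  set.seed(101)
  for (i in 1:100) {
    sims <- simulate_labeling(random_valid_params(), random_tracer(), defs)
    for (s in sims) {
      expect_true(all(as.numeric(s) >= 0))
      expect_equal(sum(s), 1, tolerance = 1e-9)
    }
  }
})

test_that("summed purine labeling is nondecreasing in the one-carbon fraction", {
  labeled_sum <- function(p) {
    pars <- one_carbon_params(f_trp = p, f_other = 1 - p)
    sum(as.numeric(simulate_labeling(pars, trp_tr, defs["ATP"])$ATP)[-1])
  }
  grid <- vapply(seq(0, 1, by = 0.05), labeled_sum, numeric(1))
  expect_true(all(diff(grid) >= -1e-12))
})

test_that("provenance slot order does not change the distribution", {
  pars <- one_carbon_params(f_ser = 0.4, f_other = 0.6, q_gly = 0.25)
  fwd <- metabolite_def("ATP", "C10H16N5O13P3",
                        list(list(pool = "one_carbon", n_positions = 2L),
                             list(pool = "glycine", n_positions = 2L)))
  rev <- metabolite_def("ATP", "C10H16N5O13P3",
                        list(list(pool = "glycine", n_positions = 2L),
                             list(pool = "one_carbon", n_positions = 2L)))
  a <- simulate_labeling(pars, ser_tr, list(fwd))$ATP
  b <- simulate_labeling(pars, ser_tr, list(rev))$ATP
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-14)
})

test_that("IDO1 inhibition leaves one-carbon fates unlabeled under the Trp tracer", {
  pars <- one_carbon_params(f_trp = 0.8, f_other = 0.2, q_gly = 0,
                            trp_intracellular_labeled = 0.99,
                            ido1_active = FALSE)
  sims <- simulate_labeling(pars, trp_tr, defs)
  for (met in c("ATP", "GTP", "serine", "methionine", "formate")) {
    expect_equal(as.numeric(sims[[met]])[1], 1, tolerance = 1e-12, label = met)
  }
  # kynurenine formation itself is upstream of the formate release step
  expect_gt(as.numeric(sims$kynurenine)[11], 0.9)
})

test_that("noiseless inversion recovers the pool fractions", {
  pars <- one_carbon_params(f_ser = 0.3, f_other = 0.7, q_gly = 0.1)
  sims <- simulate_labeling(pars, ser_tr, defs)
  est <- estimate_pool_fractions(sims$ATP, sims$serine, defs$ATP, defs$serine)
  expect_false(est$uninformative)
  expect_equal(est$p_hat, 0.3, tolerance = 1e-6)
  expect_equal(est$q_gly_hat, 0.1, tolerance = 1e-6)
  expect_lt(est$residual, 1e-12)
})

test_that("inversion agrees with a dense grid-search oracle", {
  pars <- one_carbon_params(f_ser = 0.42, f_other = 0.58, q_gly = 0.17)
  sims <- simulate_labeling(pars, ser_tr, defs)
  est <- estimate_pool_fractions(sims$ATP, sims$serine, defs$ATP, defs$serine)
  oracle <- grid_search_pq(as.numeric(sims$ATP), as.numeric(sims$serine),
                           step = 0.001)
  expect_equal(est$p_hat, unname(oracle["p"]), tolerance = 1e-3)
  expect_equal(est$q_gly_hat, unname(oracle["q"]), tolerance = 1e-3)
})

test_that("all-m+0 observations are flagged uninformative", {
  est <- estimate_pool_fractions(mid(c(1, 0, 0)), mid(c(1, 0, 0, 0)),
                                 defs$ATP, defs$serine)
  expect_true(est$uninformative)
  expect_equal(c(est$p_hat, est$q_gly_hat, est$residual), c(0, 0, 0))
})

test_that("measured-space inversion is exact through natural abundance", {
  pars <- one_carbon_params(f_ser = 0.35, f_other = 0.65, q_gly = 0.2)
  sims <- simulate_labeling(pars, ser_tr, defs)
  nat_atp <- natural_abundance_distribution(defs$ATP$formula, n_max = 10)
  nat_ser <- natural_abundance_distribution(defs$serine$formula, n_max = 3)
  meas_atp <- convolve_mid(sims$ATP, nat_atp, n_max = 10)
  meas_ser <- convolve_mid(sims$serine, nat_ser, n_max = 3)
  est <- estimate_pool_fractions_measured(meas_atp, meas_ser,
                                          nat_atp, nat_ser,
                                          defs$ATP, defs$serine)
  expect_equal(est$p_hat, 0.35, tolerance = 1e-6)
  expect_equal(est$q_gly_hat, 0.2, tolerance = 1e-6)
})
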