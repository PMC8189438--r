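defs <- default_metabolites()
ser_tr <- tracer_spec("13C3-Ser", "serine", 3L, isotopic_purity = 1,
                      medium_concentration_mM = 0.4, extra_heavy_atoms = 1L)
pars <- one_carbon_params(f_ser = 0.4, f_other = 0.6, q_gly = 0.15)

small_cfg <- function(noise_cv = 0, seed = 11, ...) {
  experiment_config(ser_tr, pars, defs[c("ATP", "serine", "kynurenine")],
                    noise_cv = noise_cv, seed = seed, ...)
}

test_that("identical seeds give identical tables, different seeds differ", {
  a <- generate_lcms_tables(small_cfg(noise_cv = 0.05, seed = 3))
  b <- generate_lcms_tables(small_cfg(noise_cv = 0.05, seed = 3))
  expect_identical(a$labeled, b$labeled)
  expect_identical(a$control, b$control)
  c <- generate_lcms_tables(small_cfg(noise_cv = 0.05, seed = 4))
  expect_false(isTRUE(all.equal(a$labeled$peak_area, c$labeled$peak_area)))
})

test_that("zero-noise tables invert to the true pool fractions", {
  out <- generate_lcms_tables(small_cfg(noise_cv = 0))
  est <- estimate_pool_fractions_measured(
    table_fractions(out$labeled, "ATP", "labeled_rep1"),
    table_fractions(out$labeled, "serine", "labeled_rep1"),
    table_fractions(out$control, "ATP", "control_rep1"),
    table_fractions(out$control, "serine", "control_rep1"),
    defs$ATP, defs$serine)
  expect_equal(est$p_hat, out$ground_truth$p, tolerance = 1e-6)
  expect_equal(est$q_gly_hat, out$ground_truth$q_gly, tolerance = 1e-6)
})

test_that("control tables carry only natural abundance", {
  out <- generate_lcms_tables(small_cfg(noise_cv = 0))
  corrected <- correct_table(out$control, out$control)
  expect_true(all(abs(corrected$summed_labeled_fraction) < 1e-12))

  # with noise, replicate-averaged self-correction stays near zero
  outn <- generate_lcms_tables(small_cfg(noise_cv = 0.05))
  cn <- correct_table(outn$control, outn$control)
  expect_true(all(cn$summed_labeled_fraction < 0.05))
})

test_that("noisy single-seed recovery lands near the truth", {
  out <- generate_lcms_tables(small_cfg(noise_cv = 0.05, seed = 21))
  est <- estimate_pool_fractions_measured(
    table_mean_fractions(out$labeled, "ATP"),
    table_mean_fractions(out$labeled, "serine"),
    table_mean_fractions(out$control, "ATP"),
    table_mean_fractions(out$control, "serine"),
    defs$ATP, defs$serine)
  expect_lt(abs(est$p_hat - out$ground_truth$p), 0.05)
})

test_that("zero-noise GC-MS samples quantify back exactly", {
  gcms <- generate_gcms_samples(small_cfg(noise_cv = 0),
                                true_c12_um = c(ifng = 30),
                                true_c13_um = c(ifng = 12))
  out <- quantify_formate_table(gcms)
  expect_equal(out$c12_formate_um, rep(30, 3), tolerance = 1e-9)
  expect_equal(out$c13_formate_um, rep(12, 3), tolerance = 1e-9)

  # zero concentrations produce blank-equivalent samples
  g0 <- generate_gcms_samples(small_cfg(noise_cv = 0), 0, 0)
  exps <- g0[!g0$is_standard & !g0$is_blank, ]
  blanks <- g0[g0$is_blank, ]
  expect_equal(exps$pa_136, rep(blanks$pa_136[1], 3), tolerance = 1e-9)
  expect_equal(exps$pa_137, rep(blanks$pa_137[1], 3), tolerance = 1e-9)
})

test_that("zero-noise standards ladder fits through the origin", {
  gcms <- generate_gcms_samples(small_cfg(noise_cv = 0), 10, 5)
  stds <- gcms[gcms$is_standard, ]
  blank <- gcms[gcms$is_blank, ][1, ]
  cal <- fit_calibration(
    stds$standard_um,
    lapply(seq_len(nrow(stds)), function(i) {
      gcms_sample(stds$pa_136[i], stds$pa_137[i], stds$pa_138[i])
    }),
    gcms_sample(blank$pa_136, blank$pa_137, blank$pa_138, is_blank = TRUE))
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$slope, 50, tolerance = 1e-9)
})

test_that("noisy GC-MS quantification stays within three CVs", {
  gcms <- generate_gcms_samples(small_cfg(noise_cv = 0.05, seed = 5),
                                true_c12_um = 40, true_c13_um = 20)
  out <- quantify_formate_table(gcms)
  expect_true(all(abs(out$c12_formate_um - 40) / 40 < 3 * 0.05))
  expect_true(all(abs(out$c13_formate_um - 20) / 20 < 3 * 0.05))
})

test_that("medium time course round-trips through exchange_rate", {
  rates <- tibble::tibble(metabolite = c("kynurenine", "formate", "tryptophan"),
                          rate_fmol_cell_h = c(20, 13.5, 13),
                          direction = c("efflux", "efflux", "consumption"),
                          c0_mM = c(0, 0, 0.4))
  # no growth: delta_c = r * n0 * T / (V * 1e9)
  cfg <- small_cfg(noise_cv = 0, doubling_time_h = Inf, true_rates = rates)
  tc <- generate_medium_timecourse(cfg)
  expect_equal(tc$ct_mM[tc$metabolite == "kynurenine"][1],
               20 * cfg$n0 * 24 / (2 * 1e9), tolerance = 1e-12)
  est <- compute_rates_table(tc)
  expect_equal(est$rate_fmol_cell_h,
               rep(rates$rate_fmol_cell_h, each = cfg$n_replicates),
               tolerance = 1e-9)

  # growth at one doubling per window: integral n0 * T / ln 2 over the window
  cfg2 <- small_cfg(noise_cv = 0, doubling_time_h = 24, true_rates = rates)
  tc2 <- generate_medium_timecourse(cfg2)
  expect_equal(tc2$ct_mM[tc2$metabolite == "formate"][1],
               13.5 * cfg2$n0 * 24 / log(2) / (2 * 1e9), tolerance = 1e-12)
  est2 <- compute_rates_table(tc2)
  expect_equal(est2$rate_fmol_cell_h,
               rep(rates$rate_fmol_cell_h, each = cfg2$n_replicates),
               tolerance = 1e-9)
})

test_that("zero rates leave the medium unchanged and depletion is flagged", {
  rates <- tibble::tibble(metabolite = c("serine", "tryptophan"),
                          rate_fmol_cell_h = c(0, 100),
                          direction = c("efflux", "consumption"),
                          c0_mM = c(0.4, 0.001))
  cfg <- small_cfg(noise_cv = 0, true_rates = rates)
  tc <- generate_medium_timecourse(cfg)
  expect_equal(tc$ct_mM[tc$metabolite == "serine"], rep(0.4, 3))
  expect_true(all(tc$depleted[tc$metabolite == "tryptophan"]))
  expect_equal(tc$ct_mM[tc$metabolite == "tryptophan"], rep(0, 3))
})

test_that("full pipeline medians stay within three CVs of truth", {
  rates <- tibble::tibble(metabolite = c("kynurenine", "formate"),
                          rate_fmol_cell_h = c(20, 13.5),
                          direction = "efflux", c0_mM = 0)
  cfg <- small_cfg(noise_cv = 0.05, seed = 31, true_rates = rates)
  out <- generate_lcms_tables(cfg)
  est <- estimate_pool_fractions_measured(
    table_mean_fractions(out$labeled, "ATP"),
    table_mean_fractions(out$labeled, "serine"),
    table_mean_fractions(out$control, "ATP"),
    table_mean_fractions(out$control, "serine"),
    defs$ATP, defs$serine)
  expect_lt(abs(est$p_hat - cfg$params$f_ser * 1), 3 * 0.05)

  tc <- generate_medium_timecourse(cfg)
  rr <- compute_rates_table(tc)
  med <- tapply(rr$rate_fmol_cell_h, rr$metabolite, stats::median)
  expect_lt(abs(med[["kynurenine"]] - 20) / 20, 3 * 0.05)
  expect_lt(abs(med[["formate"]] - 13.5) / 13.5, 3 * 0.05)
  ret <- retention_fraction(med[["kynurenine"]], med[["formate"]])
  expect_lt(abs(ret - retention_fraction(20, 13.5)), 3 * 0.05)
})
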