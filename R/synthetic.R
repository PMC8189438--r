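#' Configure a synthetic tracing experiment
#'
#' Bundles the ground truth and design of a simulated experiment: the
#' tracer, the pool-labeling parameters, the metabolite panel, replicate
#' structure (default n = 3 biological replicates), multiplicative
#' log-normal instrument noise on peak areas, culture geometry and growth,
#' and the true medium exchange rates to emulate.
#'
#' @param tracer A [tracer_spec()].
#' @param params A [one_carbon_params()].
#' @param metabolites List of [metabolite_def()]s.
#' @param n_replicates Biological replicates per condition (default 3).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise applied per isotopologue area (default 0.05).
#' @param total_area_scale Total peak area per metabolite (arbitrary units).
#' @param n0 Cells at the start of the window.
#' @param doubling_time_h Doubling time (h); `Inf` for no growth.
#' @param volume_mL Medium volume (mL).
#' @param hours Labeling / exchange window (h, default 24).
#' @param true_rates Data frame with columns `metabolite`,
#'   `rate_fmol_cell_h`, `direction` (`"efflux"`/`"consumption"`), `c0_mM`.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(tracer, params,
                              metabolites = default_metabolites(),
                              n_replicates = 3L, noise_cv = 0.05,
                              total_area_scale = 1e6,
                              n0 = 5e5, doubling_time_h = 24,
                              volume_mL = 2, hours = 24,
                              true_rates = NULL, seed = 1L) {
  stopifnot(inherits(tracer, "tracer_spec"), inherits(params, "one_carbon_params"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  structure(list(tracer = tracer, params = params, metabolites = metabolites,
                 n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
                 total_area_scale = total_area_scale, n0 = n0,
                 doubling_time_h = doubling_time_h, volume_mL = volume_mL,
                 hours = hours, true_rates = true_rates,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

## multiplicative log-normal noise factors with mean 1 and CV cv
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate synthetic LC-MS isotopologue peak-area tables
#'
#' Emulates the LC-MS measurement of labeled and unlabeled cultures: per
#' metabolite and replicate, tracer-derived labeling (forward model) is
#' convolved with the metabolite's natural-abundance envelope, scaled to
#' the configured total area, and perturbed by multiplicative log-normal
#' noise per isotopologue. The unlabeled-control table is generated with
#' all tracer labeling off, so it carries natural abundance only.
#'
#' @param cfg An [experiment_config()].
#' @return List: `labeled` and `control` tibbles in the long peak-table
#'   schema (`sample_id`, `group`, `metabolite`, `isotopologue`,
#'   `peak_area`), and `ground_truth` (true pool fractions, tracer-derived
#'   MIDs and seed).
#' @export
generate_lcms_tables <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$seed)
  td <- simulate_labeling(cfg$params, cfg$tracer, cfg$metabolites)
  unlabeled <- one_carbon_params(f_other = 1)
  td0 <- simulate_labeling(unlabeled, cfg$tracer, cfg$metabolites)

  one_table <- function(mids, prefix) {
    rows <- list()
    for (def in cfg$metabolites) {
      nat <- natural_abundance_distribution(def$formula, metabolite = def$name)
      measured <- convolve_mid(mids[[def$name]], nat, n_max = def$n_carbons)
      for (r in seq_len(cfg$n_replicates)) {
        areas <- cfg$total_area_scale * as.numeric(measured) *
          lognormal_factors(length(measured), cfg$noise_cv)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sprintf("%s_rep%d", prefix, r),
          group = "tracer",
          metabolite = def$name,
          isotopologue = seq_along(areas) - 1L,
          peak_area = areas)
      }
    }
    dplyr::bind_rows(rows)
  }

  labeled <- one_table(td, "labeled")
  control <- one_table(td0, "control")
  p <- one_carbon_pool_fraction(cfg$params, cfg$tracer)
  list(labeled = labeled, control = control,
       ground_truth = list(p = p, q_gly = cfg$params$q_gly,
                           trp_intracellular_labeled = cfg$params$trp_intracellular_labeled,
                           tracer_derived = lapply(td, as.numeric),
                           seed = cfg$seed))
}

#' Generate synthetic GC-MS formate samples
#'
#' Emulates the derivatized GC-MS design: every sample (experimental,
#' standard and water blank) carries the d2-formate internal standard, and
#' channel areas are proportional to concentration over internal-standard
#' concentration, on top of a constant instrument background that the
#' blanks expose. A standards ladder and blanks are always included.
#'
#' @param cfg An [experiment_config()] (supplies `n_replicates`, `noise_cv`
#'   and `seed`).
#' @param true_c12_um,true_c13_um True 12C and 13C formate concentrations
#'   (uM) per experimental condition; equal-length vectors, optionally
#'   named with group labels.
#' @param standards_um Standards ladder (uM).
#' @param istd_um Internal-standard concentration (uM, default 50).
#' @return Tibble in the `gcms_samples` schema: `sample_id`, `group`,
#'   `pa_136`, `pa_137`, `pa_138`, `is_blank`, `is_standard`,
#'   `standard_um`.
#' @export
generate_gcms_samples <- function(cfg, true_c12_um, true_c13_um,
                                  standards_um = c(0, 10, 25, 50, 100),
                                  istd_um = 50) {
  stopifnot(inherits(cfg, "experiment_config"),
            length(true_c12_um) == length(true_c13_um),
            all(true_c12_um >= 0), all(true_c13_um >= 0))
  set.seed(cfg$seed + 1L)
  base_area <- 2e5   # ISTD channel area, arbitrary units
  bg <- c(pa_136 = 800, pa_137 = 300, pa_138 = 0)  # instrument background
  groups <- names(true_c12_um)
  if (is.null(groups)) groups <- sprintf("cond%d", seq_along(true_c12_um))

  mk_row <- function(id, group, c12, c13, is_blank, is_standard, standard_um) {
    noise <- lognormal_factors(3, cfg$noise_cv)
    a138 <- base_area * noise[3]
    tibble::tibble(
      sample_id = id, group = group,
      pa_136 = (a138 * c12 / istd_um) * noise[1] + bg[["pa_136"]],
      pa_137 = (a138 * c13 / istd_um) * noise[2] + bg[["pa_137"]],
      pa_138 = a138,
      is_blank = is_blank, is_standard = is_standard,
      standard_um = standard_um)
  }

  rows <- list()
  for (b in seq_len(2)) {
    rows[[length(rows) + 1L]] <- mk_row(sprintf("blank%d", b), "blank",
                                        0, 0, TRUE, FALSE, NA_real_)
  }
  for (s in seq_along(standards_um)) {
    rows[[length(rows) + 1L]] <- mk_row(sprintf("std%d", s), "standard",
                                        standards_um[s], 0, FALSE, TRUE,
                                        standards_um[s])
  }
  for (g in seq_along(true_c12_um)) {
    for (r in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1L]] <- mk_row(
        sprintf("%s_rep%d", groups[g], r), groups[g],
        true_c12_um[g], true_c13_um[g], FALSE, FALSE, NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

## time integral of exponential cell growth over the window, in cell-hours;
## equals n_avg * hours with n_avg = (nt - n0)/ln(nt/n0)
cell_hours <- function(n0, doubling_time_h, hours) {
  if (!is.finite(doubling_time_h)) return(n0 * hours)
  k <- log(2) / doubling_time_h
  n0 * (exp(k * hours) - 1) / k
}

#' Generate a synthetic medium time course
#'
#' Produces start/end medium concentrations consistent with the configured
#' true per-cell rates under exponential growth: the exchanged amount is
#' rate x integral of N(t) dt over the window, so [exchange_rate()]'s
#' log-mean cell-number normalization recovers the true rate exactly at
#' zero noise. Concentrations that would fall below zero are floored at
#' zero and flagged `depleted` (nutrient exhaustion).
#'
#' @param cfg An [experiment_config()] with `true_rates` set.
#' @return Tibble in the `rates_input` schema: `sample_id`, `metabolite`,
#'   `c0_mM`, `ct_mM`, `volume_mL`, `n0`, `nt`, `hours`, `direction`,
#'   `depleted`.
#' @export
generate_medium_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(cfg$true_rates)) stop("cfg$true_rates is not set")
  set.seed(cfg$seed + 2L)
  tr <- cfg$true_rates
  nt <- if (is.finite(cfg$doubling_time_h)) {
    cfg$n0 * 2^(cfg$hours / cfg$doubling_time_h)
  } else cfg$n0
  ch <- cell_hours(cfg$n0, cfg$doubling_time_h, cfg$hours)
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    for (r in seq_len(cfg$n_replicates)) {
      delta_mM <- tr$rate_fmol_cell_h[i] * ch / (cfg$volume_mL * 1e9) *
        lognormal_factors(1, cfg$noise_cv)
      ct <- if (identical(tr$direction[i], "consumption")) {
        tr$c0_mM[i] - delta_mM
      } else {
        tr$c0_mM[i] + delta_mM
      }
      depleted <- ct < 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("%s_rep%d", tr$metabolite[i], r),
        metabolite = tr$metabolite[i],
        c0_mM = tr$c0_mM[i], ct_mM = max(ct, 0),
        volume_mL = cfg$volume_mL, n0 = cfg$n0, nt = nt,
        hours = cfg$hours, direction = tr$direction[i],
        depleted = depleted)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compute exchange rates for a rates-input table
#'
#' Applies [exchange_rate()] row-wise to a `rates_input` table.
#'
#' @param rates_input Tibble with columns `sample_id`, `metabolite`,
#'   `c0_mM`, `ct_mM`, `volume_mL`, `n0`, `nt`, `hours` and optionally
#'   `direction`.
#' @return Tibble `sample_id`, `metabolite`, `rate_fmol_cell_h`,
#'   `direction`, `n_avg_cells`.
#' @export
compute_rates_table <- function(rates_input) {
  rows <- lapply(seq_len(nrow(rates_input)), function(i) {
    x <- rates_input[i, ]
    rr <- exchange_rate(x$c0_mM, x$ct_mM, x$volume_mL, x$n0, x$nt, x$hours,
                        direction = if ("direction" %in% names(x)) x$direction else NULL,
                        metabolite = x$metabolite)
    tibble::tibble(sample_id = x$sample_id, metabolite = x$metabolite,
                   rate_fmol_cell_h = rr$rate, direction = rr$direction,
                   n_avg_cells = rr$n_avg_cells)
  })
  dplyr::bind_rows(rows)
}
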