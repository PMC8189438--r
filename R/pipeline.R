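## Orchestration layer: a plain YAML run configuration drives simulate /
## correct / formate / rates / report steps, each writing CSV or JSON with a
## provenance header (package version, seed, config hash).

#' Read a run configuration
#'
#' A single human-editable YAML file with sections `simulate` (tracer name,
#' pool fractions, replicates, noise), `paths` (input/output files) and
#' `options` (clamping, group comparisons). Missing fields fall back to the
#' documented defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with `$config_hash` recorded.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  cfg$config_hash <- text_hash(paste(readLines(path), collapse = "\n"))
  class(cfg) <- "run_config"
  cfg
}

## small stable polynomial rolling hash, hex string; provenance only
text_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_header <- function(cfg, seed) {
  c(sprintf("# package: kyntrace %s",
            as.character(utils::packageVersion("kyntrace"))),
    sprintf("# seed: %d", seed),
    sprintf("# config_hash: %s",
            if (!is.null(cfg$config_hash)) cfg$config_hash else "unset"))
}

config_tracer <- function(cfg) {
  name <- if (!is.null(cfg$simulate$tracer)) cfg$simulate$tracer else "tryptophan"
  switch(name,
         tryptophan = tracer_trp(), serine = tracer_ser(),
         formate = tracer_formate(),
         stop(sprintf("unknown tracer '%s'", name)))
}

config_experiment <- function(cfg, seed) {
  sim <- cfg$simulate
  g <- function(field, default) if (!is.null(sim[[field]])) sim[[field]] else default
  params <- one_carbon_params(
    f_trp = g("f_trp", 0.5), f_ser = g("f_ser", 0.3),
    f_exo_formate = g("f_exo_formate", 0),
    q_gly = g("q_gly", 0),
    trp_intracellular_labeled = g("trp_intracellular_labeled", 0.99),
    ido1_active = g("ido1_active", TRUE))
  true_rates <- if (!is.null(sim$true_rates)) {
    dplyr::bind_rows(lapply(sim$true_rates, tibble::as_tibble))
  } else NULL
  experiment_config(
    tracer = config_tracer(cfg), params = params,
    n_replicates = g("n_replicates", 3L), noise_cv = g("noise_cv", 0.05),
    n0 = g("n0", 5e5), doubling_time_h = g("doubling_time_h", 24),
    volume_mL = g("volume_mL", 2), hours = g("hours", 24),
    true_rates = true_rates, seed = seed)
}

#' Simulate a complete synthetic experiment to disk
#'
#' Writes `labeled.csv`, `control.csv`, `gcms.csv`, `rates_input.csv` and
#' `ground_truth.json` under `out_dir`, all with provenance headers.
#'
#' @param cfg A `run_config` (from [read_run_config()]) or a list with the
#'   same structure.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; overrides any seed in the config.
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(cfg, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ec <- config_experiment(cfg, seed)
  hdr <- provenance_header(cfg, seed)
  lcms <- generate_lcms_tables(ec)
  true_c13 <- if (!is.null(cfg$simulate$true_c13_formate_um)) {
    cfg$simulate$true_c13_formate_um
  } else 25
  true_c12 <- if (!is.null(cfg$simulate$true_c12_formate_um)) {
    cfg$simulate$true_c12_formate_um
  } else 25
  gcms <- generate_gcms_samples(ec, true_c12, true_c13)
  paths <- c(labeled = file.path(out_dir, "labeled.csv"),
             control = file.path(out_dir, "control.csv"),
             gcms = file.path(out_dir, "gcms.csv"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  write_peak_table(lcms$labeled, paths[["labeled"]], hdr)
  write_peak_table(lcms$control, paths[["control"]], hdr)
  write_peak_table(gcms, paths[["gcms"]], hdr)
  if (!is.null(ec$true_rates)) {
    paths[["rates_input"]] <- file.path(out_dir, "rates_input.csv")
    write_peak_table(generate_medium_timecourse(ec), paths[["rates_input"]], hdr)
  }
  gt <- lcms$ground_truth
  gt$true_c12_formate_um <- true_c12
  gt$true_c13_formate_um <- true_c13
  gt$config_hash <- cfg$config_hash
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Baseline-correct simulated or measured peak tables
#'
#' Reads the labeled and unlabeled-control tables, applies the empirical
#' baseline subtraction, and writes `corrected.csv` (per-isotopologue) plus
#' `corrected_summary.csv` (group means and SDs of the summed labeled
#' fraction).
#'
#' @inheritParams run_simulate
#' @param labeled_path,control_path Input CSVs (default: the files
#'   [run_simulate()] wrote under `out_dir`).
#' @return Invisibly, a list with `corrected` and `summary` tibbles.
#' @export
run_correct <- function(cfg, out_dir, seed = 1L,
                        labeled_path = file.path(out_dir, "labeled.csv"),
                        control_path = file.path(out_dir, "control.csv")) {
  labeled <- read_peak_table(labeled_path)
  control <- read_peak_table(control_path)
  corrected <- correct_table(labeled, control)
  smry <- summarize_labeled_fractions(corrected)
  hdr <- provenance_header(cfg, seed)
  write_peak_table(corrected, file.path(out_dir, "corrected.csv"), hdr)
  write_peak_table(smry, file.path(out_dir, "corrected_summary.csv"), hdr)
  invisible(list(corrected = corrected, summary = smry))
}

#' Quantify formate from a GC-MS sample table
#'
#' @inheritParams run_simulate
#' @param gcms_path Input CSV (default: the file [run_simulate()] wrote).
#' @return Invisibly, the concentrations tibble.
#' @export
run_formate <- function(cfg, out_dir, seed = 1L,
                        gcms_path = file.path(out_dir, "gcms.csv")) {
  gcms <- read_peak_table(gcms_path)
  conc <- quantify_formate_table(gcms)
  write_peak_table(conc, file.path(out_dir, "formate_um.csv"),
                   provenance_header(cfg, seed))
  invisible(conc)
}

#' Compute exchange rates and derived one-carbon bookkeeping
#'
#' Computes per-sample exchange rates from a `rates_input` table and, when
#' both kynurenine and formate efflux are present, the intracellular
#' formate retention fraction per replicate pairing of group means.
#'
#' @inheritParams run_simulate
#' @param rates_path Input CSV (default: the file [run_simulate()] wrote).
#' @return Invisibly, a list with `rates` tibble and `derived` list.
#' @export
run_rates <- function(cfg, out_dir, seed = 1L,
                      rates_path = file.path(out_dir, "rates_input.csv")) {
  rates_input <- read_peak_table(rates_path)
  rates <- compute_rates_table(rates_input)
  hdr <- provenance_header(cfg, seed)
  write_peak_table(rates, file.path(out_dir, "rates.csv"), hdr)
  mean_rate <- function(met) {
    x <- rates[rates$metabolite == met & rates$direction == "efflux", ]
    if (nrow(x) == 0L) NA_real_ else mean(x$rate_fmol_cell_h)
  }
  derived <- list()
  kyn <- mean_rate("kynurenine"); fo <- mean_rate("formate")
  if (is.finite(kyn) && is.finite(fo) && kyn > 0) {
    derived$retention_fraction <- retention_fraction(kyn, fo)
  }
  fo13 <- mean_rate("formate_13c")
  if (is.finite(fo13) && is.finite(fo) && fo > 0) {
    derived$tracer_share_pct <- tracer_share_of_efflux(fo13, fo)
  }
  jsonlite::write_json(c(list(seed = seed), derived),
                       file.path(out_dir, "rates_derived.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(rates = rates, derived = derived))
}

#' Summary report with group comparisons
#'
#' Compares summed labeled fractions between configured group pairs with
#' two-sided t tests and writes `report.json`.
#'
#' @inheritParams run_simulate
#' @param corrected_summary Optional tibble (default: read from
#'   `corrected.csv` under `out_dir`).
#' @param comparisons List of `list(a =, b =, paired =)` group pairs
#'   (default: taken from `cfg$options$comparisons`, if any).
#' @return Invisibly, the report list.
#' @export
run_report <- function(cfg, out_dir, seed = 1L, corrected_summary = NULL,
                       comparisons = NULL) {
  corrected <- if (is.null(corrected_summary)) {
    read_peak_table(file.path(out_dir, "corrected.csv"))
  } else corrected_summary
  if (is.null(comparisons)) comparisons <- cfg$options$comparisons
  per_sample <- corrected |>
    dplyr::distinct(.data$sample_id, .data$group, .data$metabolite,
                    .data$summed_labeled_fraction)
  tests <- list()
  for (cmp in comparisons) {
    for (met in unique(per_sample$metabolite)) {
      a <- per_sample$summed_labeled_fraction[
        per_sample$group == cmp$a & per_sample$metabolite == met]
      b <- per_sample$summed_labeled_fraction[
        per_sample$group == cmp$b & per_sample$metabolite == met]
      if (length(a) >= 2L && length(b) >= 2L) {
        gt <- group_compare(a, b, paired = isTRUE(cmp$paired))
        tests[[length(tests) + 1L]] <- list(
          metabolite = met, group_a = cmp$a, group_b = cmp$b,
          paired = isTRUE(cmp$paired), t = gt$statistic, p = gt$p_value)
      }
    }
  }
  report <- list(seed = seed,
                 config_hash = if (!is.null(cfg$config_hash)) cfg$config_hash else "unset",
                 n_samples = length(unique(per_sample$sample_id)),
                 comparisons = tests)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
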