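#' A GC-MS formate measurement
#'
#' One derivatized sample measured at three m/z channels: 136 (12C formate),
#' 137 (13C formate) and 138 (the d2-formate internal standard spiked at a
#' known concentration into every sample, standard and blank).
#'
#' @param pa_136,pa_137,pa_138 Peak areas (nonnegative).
#' @param istd_concentration_um Internal-standard concentration, uM
#'   (default 50).
#' @param is_blank Whether this is a water blank.
#' @return A `gcms_sample`.
#' @export
gcms_sample <- function(pa_136, pa_137, pa_138, istd_concentration_um = 50,
                        is_blank = FALSE) {
  areas <- c(pa_136, pa_137, pa_138)
  if (anyNA(areas) || any(areas < 0)) stop("peak areas must be nonnegative")
  if (istd_concentration_um <= 0) stop("istd_concentration_um must be positive")
  structure(list(pa_136 = pa_136, pa_137 = pa_137, pa_138 = pa_138,
                 istd_concentration_um = istd_concentration_um,
                 is_blank = isTRUE(is_blank)),
            class = "gcms_sample")
}

#' Fit a GC-MS calibration line
#'
#' Ordinary least squares of known standard concentration on the
#' blank-subtracted analyte/internal-standard area ratio. The fitted line
#' maps ratio to concentration (uM): conc = intercept + slope * ratio.
#'
#' @param known_um Standard concentrations (uM); at least two distinct.
#' @param standards List of [gcms_sample()]s, same length as `known_um`.
#' @param blank A [gcms_sample()] blank (mean the replicates beforehand if
#'   several were run).
#' @return A `gcms_calibration` with `slope` (> 0) and `intercept`.
#' @export
fit_calibration <- function(known_um, standards, blank) {
  if (length(known_um) != length(standards)) {
    stop("known_um and standards must have equal length")
  }
  if (length(unique(known_um)) < 2L) {
    stop("singular fit: need at least two distinct standard concentrations")
  }
  ratio <- vapply(standards, function(s) {
    if (s$pa_138 <= 0) stop("standard has zero internal-standard area")
    (s$pa_136 - blank$pa_136) / s$pa_138
  }, numeric(1))
  fit <- stats::lm(known_um ~ ratio)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("singular fit: calibration slope is not positive")
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 n_standards = length(known_um)),
            class = "gcms_calibration")
}

#' Quantify 12C and 13C formate in one sample
#'
#' Per channel, the blank's raw peak area is subtracted, the result is
#' ratioed against the sample's internal-standard (m/z 138) area, and the
#' calibration line converts the ratio to a concentration, clamped at zero.
#'
#' @param sample,blank [gcms_sample()]s.
#' @param cal A [fit_calibration()] result.
#' @return Named numeric: `c12_formate_um`, `c13_formate_um`.
#' @export
quantify_formate <- function(sample, blank, cal) {
  stopifnot(inherits(cal, "gcms_calibration"))
  if (sample$pa_138 <= 0) stop("quantification error: zero internal-standard area")
  conc <- function(pa, blank_pa) {
    ratio <- (pa - blank_pa) / sample$pa_138
    max(cal$intercept + cal$slope * ratio, 0)
  }
  c(c12_formate_um = conc(sample$pa_136, blank$pa_136),
    c13_formate_um = conc(sample$pa_137, blank$pa_137))
}

#' Quantify formate across a GC-MS sample table
#'
#' Fits the calibration from the table's standards (blank-subtracted,
#' against the mean blank), then quantifies every non-standard, non-blank
#' row.
#'
#' @param gcms Tibble with columns `sample_id`, `group`, `pa_136`, `pa_137`,
#'   `pa_138`, `is_blank`, `is_standard`, `standard_um`.
#' @return Tibble `sample_id`, `group`, `c12_formate_um`, `c13_formate_um`.
#' @export
quantify_formate_table <- function(gcms) {
  blanks <- gcms[gcms$is_blank, , drop = FALSE]
  if (nrow(blanks) == 0L) stop("no blank samples in GC-MS table")
  blank <- gcms_sample(mean(blanks$pa_136), mean(blanks$pa_137),
                       mean(blanks$pa_138), is_blank = TRUE)
  stds <- gcms[gcms$is_standard & !gcms$is_blank, , drop = FALSE]
  cal <- fit_calibration(
    stds$standard_um,
    lapply(seq_len(nrow(stds)), function(i) {
      gcms_sample(stds$pa_136[i], stds$pa_137[i], stds$pa_138[i])
    }),
    blank)
  exps <- gcms[!gcms$is_standard & !gcms$is_blank, , drop = FALSE]
  res <- lapply(seq_len(nrow(exps)), function(i) {
    q <- quantify_formate(
      gcms_sample(exps$pa_136[i], exps$pa_137[i], exps$pa_138[i]), blank, cal)
    tibble::tibble(sample_id = exps$sample_id[i], group = exps$group[i],
                   c12_formate_um = q[["c12_formate_um"]],
                   c13_formate_um = q[["c13_formate_um"]])
  })
  dplyr::bind_rows(res)
}

#' Per-cell medium exchange rate
#'
#' Converts a medium concentration change over a culture window into a
#' per-cell, per-hour rate: fmol = delta_mM x volume_mL x 1e9, divided by
#' the time-averaged cell number and the window length. Cell number over
#' the window is averaged assuming exponential growth,
#' n_avg = (nt - n0) / ln(nt / n0), which reduces to n0 when growth is nil.
#' Direction is inferred from the sign of the concentration change
#' (increase = efflux, decrease = consumption).
#'
#' @param c0_mM,ct_mM Medium concentration at the start and end (mM).
#' @param volume_mL Medium volume (mL).
#' @param n0,nt Cell counts at start and end.
#' @param hours Window length (h).
#' @param direction Optional expected direction (`"efflux"` or
#'   `"consumption"`); a mismatch with the inferred direction warns.
#' @param metabolite Optional name carried in the result.
#' @return A `rate_result`: `metabolite`, `rate` (fmol/cell/h, >= 0),
#'   `direction`, `n_avg_cells`, `window_h`.
#' @export
exchange_rate <- function(c0_mM, ct_mM, volume_mL, n0, nt, hours,
                          direction = NULL, metabolite = "") {
  if (hours <= 0) stop("hours must be positive")
  if (n0 <= 0 || nt <= 0) stop("cell counts must be positive")
  if (volume_mL <= 0) stop("volume_mL must be positive")
  n_avg <- if (nt == n0) n0 else (nt - n0) / log(nt / n0)
  delta_fmol <- abs(ct_mM - c0_mM) * volume_mL * 1e9
  inferred <- if (ct_mM > c0_mM) "efflux" else if (ct_mM < c0_mM) "consumption" else
    if (is.null(direction)) "efflux" else direction
  if (!is.null(direction) && ct_mM != c0_mM && !identical(direction, inferred)) {
    warning(sprintf("requested direction '%s' but concentration change implies '%s'",
                    direction, inferred))
  }
  structure(list(metabolite = metabolite,
                 rate = delta_fmol / (n_avg * hours),
                 direction = inferred, n_avg_cells = n_avg, window_h = hours),
            class = "rate_result")
}

rate_value <- function(x) if (inherits(x, "rate_result")) x$rate else as.numeric(x)

#' Intracellular formate retention fraction
#'
#' Each kynurenine produced by IDO1 releases one formate, so kynurenine
#' efflux bounds IDO1-derived formate production; the share of that formate
#' retained for intracellular use is 1 - formate_efflux / kynurenine_efflux,
#' clamped to \[0, 1\].
#'
#' @param kyn_efflux,formate_efflux [exchange_rate()] results or plain
#'   rates (fmol/cell/h).
#' @return Retention fraction in \[0, 1\].
#' @export
retention_fraction <- function(kyn_efflux, formate_efflux) {
  k <- rate_value(kyn_efflux); f <- rate_value(formate_efflux)
  if (k <= 0) stop("undefined retention: kynurenine efflux must be positive")
  min(max(1 - f / k, 0), 1)
}

#' Tracer-derived share of a total efflux
#'
#' @param tracer_derived,total [exchange_rate()] results or plain rates for
#'   the same metabolite and direction.
#' @return Percentage, 100 x tracer_derived / total. Values above 100%
#'   (isotope effects or noise) are returned with a warning.
#' @export
tracer_share_of_efflux <- function(tracer_derived, total) {
  td <- rate_value(tracer_derived); tt <- rate_value(total)
  if (tt <= 0) stop("total rate must be positive")
  share <- 100 * td / tt
  if (share > 100) warning(sprintf("tracer-derived share %.1f%% exceeds 100%%", share))
  share
}

#' Two-group comparison by Student t test
#'
#' Classical two-sided t test: pooled-variance for independent groups,
#' difference-based for paired data. Degenerate data with zero variance and
#' equal means returns t = 0, p = 1.
#'
#' @param values_a,values_b Numeric vectors, n >= 2 each (equal length if
#'   paired).
#' @param paired Paired test?
#' @return List with `statistic`, `p_value`, `df`, `method`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least two observations per group")
  }
  if (paired && length(values_a) != length(values_b)) {
    stop("paired test requires equal group sizes")
  }
  degenerate <- if (paired) {
    stats::var(values_a - values_b) == 0
  } else {
    stats::var(values_a) == 0 && stats::var(values_b) == 0
  }
  if (degenerate) {
    equal <- if (paired) all(values_a == values_b) else
      mean(values_a) == mean(values_b)
    if (equal) {
      return(list(statistic = 0, p_value = 1,
                  df = if (paired) length(values_a) - 1L else
                    length(values_a) + length(values_b) - 2L,
                  method = if (paired) "paired t" else "pooled t"))
    }
    stop("zero within-group variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(values_a, values_b, paired = paired,
                      var.equal = !paired, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       method = if (paired) "paired t" else "pooled t")
}
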