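#' Raw isotopologue peak areas for one metabolite in one sample
#'
#' @param metabolite Metabolite name.
#' @param areas Nonnegative peak areas for m+0 ... m+n_max.
#' @param sample_id,group Sample metadata.
#' @return A `peak_area_vector`.
#' @export
peak_area_vector <- function(metabolite, areas, sample_id = "", group = "") {
  areas <- as.numeric(areas)
  if (length(areas) < 1L || anyNA(areas)) stop("areas must be numeric, no NAs")
  if (any(areas < 0)) stop("peak areas must be nonnegative")
  names(areas) <- paste0("m+", seq_along(areas) - 1L)
  structure(list(metabolite = metabolite, areas = areas,
                 sample_id = sample_id, group = group),
            class = "peak_area_vector")
}

#' Isotopologue fractions from raw peak areas
#'
#' Each isotopologue's fraction is its peak area over the summed areas of
#' all isotopologues of the metabolite: fraction_n = PA_n / sum_k PA_k.
#'
#' @param pa A [peak_area_vector()] or plain nonnegative area vector.
#' @return Named fraction vector summing to one.
#' @export
fractions_from_areas <- function(pa) {
  areas <- if (inherits(pa, "peak_area_vector")) pa$areas else as.numeric(pa)
  if (any(areas < 0)) stop("peak areas must be nonnegative")
  s <- sum(areas)
  if (s <= 0) stop("empty signal: all peak areas are zero")
  out <- areas / s
  names(out) <- paste0("m+", seq_along(out) - 1L)
  out
}

#' Empirical baseline subtraction of natural 13C abundance
#'
#' Corrects measured labeled fractions using an unlabeled (12C) control
#' culture of the same metabolite: per isotopologue n >= 1,
#' corrected_n = sample_fraction_n - control_fraction_n, where fractions
#' are peak-area shares. The control fractions are empirical 13C baselines;
#' negative corrected values are clamped to zero (fractions are physical
#' proportions), and the summed labeled fraction is the sum of the clamped
#' per-isotopologue values.
#'
#' @param sample,control [peak_area_vector()]s for the same metabolite with
#'   identical isotopologue range.
#' @return A `corrected_fractions` list: `metabolite`, `corrected` (named
#'   vector over m+1 ... m+n_max), `summed_labeled_fraction`.
#' @export
baseline_correct <- function(sample, control) {
  stopifnot(inherits(sample, "peak_area_vector"),
            inherits(control, "peak_area_vector"))
  if (!identical(sample$metabolite, control$metabolite)) {
    stop(sprintf("pairing error: sample metabolite '%s' vs control '%s'",
                 sample$metabolite, control$metabolite))
  }
  if (length(sample$areas) != length(control$areas)) {
    stop("pairing error: sample and control cover different isotopologue ranges")
  }
  fs <- fractions_from_areas(sample)
  fc <- fractions_from_areas(control)
  corrected <- pmax(fs[-1] - fc[-1], 0)
  structure(list(metabolite = sample$metabolite, corrected = corrected,
                 summed_labeled_fraction = min(sum(corrected), 1)),
            class = "corrected_fractions")
}

#' Baseline-correct a long-format peak-area table
#'
#' Table-level driver for [baseline_correct()]. Control peak areas are
#' averaged across replicate unlabeled samples of the same group and
#' metabolite before subtraction; every (group, metabolite) present in the
#' labeled table must have a control counterpart.
#'
#' @param labeled,control Tibbles/data frames with columns `sample_id`,
#'   `group`, `metabolite`, `isotopologue` (integer, 0-based), `peak_area`.
#' @return Tibble with columns `sample_id`, `group`, `metabolite`,
#'   `isotopologue` (n >= 1), `corrected_fraction`,
#'   `summed_labeled_fraction` (repeated per sample/metabolite).
#' @export
correct_table <- function(labeled, control) {
  required <- c("sample_id", "group", "metabolite", "isotopologue", "peak_area")
  for (tab in list(labeled, control)) {
    if (!all(required %in% names(tab))) {
      stop("tables need columns: ", paste(required, collapse = ", "))
    }
  }
  ctrl_mean <- control |>
    dplyr::group_by(.data$group, .data$metabolite, .data$isotopologue) |>
    dplyr::summarise(peak_area = mean(.data$peak_area), .groups = "drop")

  combos <- labeled |>
    dplyr::distinct(.data$sample_id, .data$group, .data$metabolite)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    key <- combos[i, ]
    samp <- labeled |>
      dplyr::filter(.data$sample_id == key$sample_id,
                    .data$group == key$group,
                    .data$metabolite == key$metabolite) |>
      dplyr::arrange(.data$isotopologue)
    ctrl <- ctrl_mean |>
      dplyr::filter(.data$group == key$group,
                    .data$metabolite == key$metabolite) |>
      dplyr::arrange(.data$isotopologue)
    if (nrow(ctrl) == 0L) {
      stop(sprintf("pairing error: no unlabeled control for group '%s', metabolite '%s'",
                   key$group, key$metabolite))
    }
    if (!identical(samp$isotopologue, ctrl$isotopologue)) {
      stop(sprintf("pairing error: isotopologue ranges differ for '%s'/'%s'",
                   key$group, key$metabolite))
    }
    cf <- baseline_correct(
      peak_area_vector(key$metabolite, samp$peak_area, key$sample_id, key$group),
      peak_area_vector(key$metabolite, ctrl$peak_area, "control_mean", key$group))
    tibble::tibble(sample_id = key$sample_id, group = key$group,
                   metabolite = key$metabolite,
                   isotopologue = samp$isotopologue[-1],
                   corrected_fraction = unname(cf$corrected),
                   summed_labeled_fraction = cf$summed_labeled_fraction)
  })
  dplyr::bind_rows(out)
}

#' Summarize corrected labeled fractions by group
#'
#' Group means and SDs of the summed labeled fraction per metabolite, the
#' per-condition quantity plotted as labeled-fraction bars.
#'
#' @param corrected Output of [correct_table()].
#' @return Tibble with `group`, `metabolite`, `n`, `mean_labeled_fraction`,
#'   `sd_labeled_fraction`.
#' @export
summarize_labeled_fractions <- function(corrected) {
  corrected |>
    dplyr::distinct(.data$sample_id, .data$group, .data$metabolite,
                    .data$summed_labeled_fraction) |>
    dplyr::group_by(.data$group, .data$metabolite) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_labeled_fraction = mean(.data$summed_labeled_fraction),
                     sd_labeled_fraction = stats::sd(.data$summed_labeled_fraction),
                     .groups = "drop")
}

#' Read / write long-format peak-area tables
#'
#' CSV with columns `sample_id`, `group`, `metabolite`, `isotopologue`,
#' `peak_area`. Lines starting with `#` (provenance headers) are skipped.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_peak_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' @rdname read_peak_table
#' @param x Table to write.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines written before the CSV header.
#' @export
write_peak_table <- function(x, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
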