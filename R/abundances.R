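#' Natural isotope abundances by element
#'
#' Standard terrestrial isotopic abundances used to predict the natural
#' mass-shift distribution of a molecular formula. Each element maps to a
#' data frame of nominal mass shifts and their abundances (summing to one).
#' Defaults: 13C 0.0107, 2H 0.000115, 15N 0.00364, 17O 0.00038, 18O 0.00205,
#' 33S 0.0075, 34S 0.0425, 36S 0.0001; phosphorus is monoisotopic.
#'
#' @param scale_13c Multiplier applied to the 13C abundance (the 12C share
#'   absorbs the difference). Used mainly to study how the empirical
#'   baseline-subtraction error shrinks as natural 13C abundance goes to zero.
#' @return Named list of data frames with columns `shift` and `abundance`.
#' @export
element_abundances <- function(scale_13c = 1) {
  stopifnot(scale_13c >= 0, scale_13c * 0.0107 <= 1)
  a13 <- 0.0107 * scale_13c
  list(
    C = data.frame(shift = c(0L, 1L), abundance = c(1 - a13, a13)),
    H = data.frame(shift = c(0L, 1L), abundance = c(0.999885, 0.000115)),
    N = data.frame(shift = c(0L, 1L), abundance = c(0.99636, 0.00364)),
    O = data.frame(shift = c(0L, 1L, 2L), abundance = c(0.99757, 0.00038, 0.00205)),
    P = data.frame(shift = 0L, abundance = 1),
    S = data.frame(shift = c(0L, 1L, 2L, 4L), abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
  )
}

#' Parse a molecular formula
#'
#' @param formula Formula string such as `"C10H12N2O3"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stop("formula must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!identical(paste(tokens, collapse = ""), formula)) {
    stop(sprintf("cannot parse formula '%s'", formula))
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  sums <- tapply(counts, elems, sum)
  out <- stats::setNames(as.integer(sums), names(sums))
  out[order(names(out))]
}

## n-fold self-convolution of one atom's mass-shift distribution
atom_power_distribution <- function(shift, abundance, n) {
  single <- numeric(max(shift) + 1L)
  single[shift + 1L] <- abundance
  out <- 1
  for (i in seq_len(n)) out <- as.numeric(convolve_mid(out, single))
  out
}

#' Natural-abundance mass-shift distribution of a formula
#'
#' Predicts the isotopologue envelope of an unlabeled molecule from
#' independent per-atom isotope draws: per-element binomial/multinomial
#' expansion followed by cross-element convolution. This is the theoretical
#' counterpart of the empirical unlabeled-control baseline measured in
#' experiments.
#'
#' @param formula Molecular formula string or parsed element-count vector.
#' @param abundances Output of [element_abundances()].
#' @param n_max Truncate at this mass shift and renormalize (default: the
#'   maximum shift the formula supports).
#' @param metabolite Name stored on the returned `mid`.
#' @return A `mid` with `basis = "measured"`.
#' @export
natural_abundance_distribution <- function(formula,
                                           abundances = element_abundances(),
                                           n_max = NULL, metabolite = "") {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) stop("formula must contain at least one atom")
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown) > 0L) {
    stop(sprintf("no isotope abundances for element(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  out <- 1
  for (el in names(counts)) {
    iso <- abundances[[el]]
    out <- as.numeric(convolve_mid(
      out, atom_power_distribution(iso$shift, iso$abundance, counts[[el]])))
  }
  if (!is.null(n_max)) out <- out[seq_len(min(n_max + 1L, length(out)))]
  mid(out, metabolite = metabolite, basis = "measured", normalize = TRUE)
}
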