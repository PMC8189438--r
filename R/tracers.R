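#' Define a stable-isotope tracer
#'
#' Describes the labeled nutrient supplied to the culture: which metabolite
#' it replaces, how many carbons carry 13C, its isotopic purity, its medium
#' concentration, and any nominal mass shift from non-carbon heavy atoms
#' (e.g. the 15N of 13C3-15N1-serine, which travels with the intact tracer
#' molecule but is never transferred with a donated one-carbon unit).
#'
#' @param name Display name.
#' @param target_metabolite Metabolite the tracer replaces in the medium
#'   (`"tryptophan"`, `"serine"` or `"formate"` for the built-in network).
#' @param n_labeled_carbons Number of 13C positions.
#' @param isotopic_purity Fraction of tracer molecules fully labeled, in
#'   \[0, 1\]. Default 0.99 (vendor-grade 99%).
#' @param medium_concentration_mM Tracer concentration in the medium, mM.
#' @param extra_heavy_atoms Nominal mass shift from non-carbon heavy isotopes
#'   carried by the intact tracer.
#' @return A `tracer_spec` list.
#' @export
tracer_spec <- function(name, target_metabolite, n_labeled_carbons,
                        isotopic_purity = 0.99, medium_concentration_mM = 0,
                        extra_heavy_atoms = 0L) {
  stopifnot(is.character(name), is.character(target_metabolite))
  n_labeled_carbons <- as.integer(n_labeled_carbons)
  extra_heavy_atoms <- as.integer(extra_heavy_atoms)
  if (is.na(isotopic_purity) || isotopic_purity < 0 || isotopic_purity > 1) {
    stop("isotopic_purity must lie in [0, 1]")
  }
  if (n_labeled_carbons < 0L) stop("n_labeled_carbons must be nonnegative")
  if (medium_concentration_mM < 0) stop("medium_concentration_mM must be nonnegative")
  structure(list(name = name, target_metabolite = target_metabolite,
                 n_labeled_carbons = n_labeled_carbons,
                 isotopic_purity = isotopic_purity,
                 medium_concentration_mM = medium_concentration_mM,
                 extra_heavy_atoms = extra_heavy_atoms),
            class = "tracer_spec")
}

#' Built-in tracers
#'
#' The three tracers of the experimental design: uniformly labeled
#' 13C11-tryptophan (0.08 mM), 13C3-15N1-serine (0.4 mM, the 15N adds one
#' nominal mass unit to the intact molecule), and 13C1-formate.
#'
#' @param medium_concentration_mM Override the default medium concentration.
#' @return A `tracer_spec`.
#' @export
tracer_trp <- function(medium_concentration_mM = 0.08) {
  tracer_spec("13C11-tryptophan", "tryptophan", 11L, 0.99, medium_concentration_mM, 0L)
}

#' @rdname tracer_trp
#' @export
tracer_ser <- function(medium_concentration_mM = 0.4) {
  tracer_spec("13C3-15N1-serine", "serine", 3L, 0.99, medium_concentration_mM, 1L)
}

#' @rdname tracer_trp
#' @export
tracer_formate <- function(medium_concentration_mM = 0.5) {
  tracer_spec("13C1-formate", "formate", 1L, 0.99, medium_concentration_mM, 0L)
}

#' Nominal mass shift of the intact tracer molecule
#'
#' @param tracer A `tracer_spec`.
#' @return Integer shift (e.g. 11 for 13C11-Trp, 4 for 13C3-15N1-Ser).
#' @export
tracer_intact_mass_shift <- function(tracer) {
  tracer$n_labeled_carbons + tracer$extra_heavy_atoms
}
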