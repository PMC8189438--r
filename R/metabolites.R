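## Recognized carbon-provenance pools.
##  one_carbon       - 10-formyl-THF / 5,10-CH2-THF pool feeding purine C2/C8,
##                     serine C3 and (as its methyl derivative) methionine
##  methyl           - 5-CH3-THF pool; modeled at the same labeled fraction as
##                     one_carbon (single one-carbon pool, no compartmentation)
##  glycine          - glycine pool (2 carbons of purines and serine)
##  trp_intracellular- intracellular tryptophan pool; transferred as an intact
##                     block (e.g. the 10 kynurenine carbons after the formyl
##                     carbon is released as formate)
KNOWN_POOLS <- c("one_carbon", "methyl", "glycine", "trp_intracellular")
BLOCK_POOLS <- "trp_intracellular"

#' Define a measured metabolite and its carbon provenance
#'
#' A metabolite is described by its elemental formula and a set of
#' provenance slots: groups of carbon positions fed by a named labeled pool.
#' Positions not covered by any slot are implicitly unlabeled (they never
#' receive tracer carbon; natural abundance still applies to the whole
#' formula). Slots drawing on the intracellular tryptophan pool are labeled
#' all-or-nothing (the carbon skeleton is transferred intact); all other
#' slots label each position independently (binomial mixing).
#'
#' @param name Metabolite name.
#' @param formula Elemental formula string, e.g. `"C10H12N2O3"`.
#' @param slots List of `list(pool =, n_positions =)` entries;
#'   total positions must not exceed the carbon count.
#' @return A `metabolite_def` list with fields `name`, `formula`,
#'   `n_carbons`, `slots`.
#' @export
metabolite_def <- function(name, formula, slots = list()) {
  counts <- parse_formula(formula)
  n_carbons <- if ("C" %in% names(counts)) counts[["C"]] else 0L
  if (n_carbons < 1L) stop(sprintf("metabolite '%s' has no carbon", name))
  total <- 0L
  for (s in slots) {
    if (!all(c("pool", "n_positions") %in% names(s))) {
      stop("each slot needs fields 'pool' and 'n_positions'")
    }
    if (!s$pool %in% KNOWN_POOLS) {
      stop(sprintf("unknown pool '%s' for metabolite '%s' (known: %s)",
                   s$pool, name, paste(KNOWN_POOLS, collapse = ", ")))
    }
    if (s$n_positions < 0L) stop("slot n_positions must be nonnegative")
    total <- total + as.integer(s$n_positions)
  }
  if (total > n_carbons) {
    stop(sprintf("metabolite '%s': slot positions (%d) exceed carbon count (%d)",
                 name, total, n_carbons))
  }
  structure(list(name = name, formula = formula, n_carbons = n_carbons,
                 slots = slots),
            class = "metabolite_def")
}

parse_slot_string <- function(x) {
  if (is.na(x) || !nzchar(x) || x == "-") return(list())
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("bad slot entry '%s'", p))
    list(pool = kv[1], n_positions = as.integer(kv[2]))
  })
}

#' Default metabolite panel
#'
#' Loads the shipped atom-bookkeeping table: kynurenine (10 carbons from the
#' intracellular tryptophan pool; the eleventh tryptophan carbon leaves as
#' formate), formate itself, serine (one one-carbon position plus two glycine
#' positions), methionine (one methyl position), the purine nucleotides
#' AMP/ADP/ATP/GMP/GDP/GTP (C2 and C8 of the purine ring from the one-carbon
#' pool, two glycine positions; ribose and the remaining ring carbons
#' unlabeled), and acetyl-CoA (labeled only through the adenine ring of the
#' CoA moiety).
#'
#' @param path Optional path to a user table (TSV with columns `name`,
#'   `formula`, `slots`; slots formatted `pool:n;pool:n`).
#' @return Named list of `metabolite_def` objects.
#' @export
default_metabolites <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolite_defs.tsv", package = "kyntrace")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  defs <- lapply(seq_len(nrow(tab)), function(i) {
    metabolite_def(tab$name[i], tab$formula[i], parse_slot_string(tab$slots[i]))
  })
  stats::setNames(defs, tab$name)
}
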