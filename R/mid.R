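#' Mass isotopomer distribution (MID) vector
#'
#' An isotopologue-fraction vector for one metabolite, covering nominal mass
#' shifts m+0 ... m+n_max. Fractions must be nonnegative and sum to one.
#' The `basis` records whether the vector describes tracer-derived labeling
#' only (`"tracer_derived"`) or the as-measured distribution that also carries
#' natural isotope abundance (`"measured"`).
#'
#' @param fractions Numeric vector of isotopologue fractions, index 1 = m+0.
#' @param metabolite Metabolite name.
#' @param basis Either `"tracer_derived"` or `"measured"`.
#' @param normalize If `TRUE`, rescale `fractions` to sum to one instead of
#'   erroring on an off-by-epsilon sum.
#' @return An object of class `mid`: the fraction vector with names
#'   `m+0 ... m+n`, and attributes `metabolite` and `basis`.
#' @export
mid <- function(fractions, metabolite = "", basis = c("tracer_derived", "measured"),
                normalize = FALSE) {
  basis <- match.arg(basis)
  fractions <- as.numeric(fractions)
  if (length(fractions) < 1L || anyNA(fractions)) {
    stop("MID fractions must be a non-empty numeric vector without NAs")
  }
  if (any(fractions < -1e-12)) stop("MID fractions must be nonnegative")
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero MID")
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("MID fractions must sum to 1 (got %.12g)", s))
  }
  names(fractions) <- paste0("m+", seq_along(fractions) - 1L)
  structure(fractions, metabolite = metabolite, basis = basis, class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s (%s), m+0..m+%d\n", attr(x, "metabolite"),
              attr(x, "basis"), length(x) - 1L))
  print(round(unclass(x), 6))
  invisible(x)
}

is_mid <- function(x) inherits(x, "mid")

#' Discrete convolution of two isotopologue distributions
#'
#' Combines two independent mass-shift distributions (e.g. tracer-derived
#' labeling with natural abundance). The result is truncated at `n_max`
#' (default: combined maximum shift) and renormalized after truncation.
#'
#' @param x,y `mid` objects or plain fraction vectors (index 1 = m+0).
#' @param n_max Optional maximum shift of the output (length `n_max + 1`).
#' @param metabolite,basis Metadata for the result; defaults taken from `x`.
#' @return A `mid`.
#' @export
convolve_mid <- function(x, y, n_max = NULL,
                         metabolite = NULL, basis = "measured") {
  a <- as.numeric(x); b <- as.numeric(y)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] > 0) {
      idx <- i + seq_along(b) - 1L
      out[idx] <- out[idx] + a[i] * b
    }
  }
  if (!is.null(n_max)) {
    keep <- seq_len(min(length(out), n_max + 1L))
    out <- out[keep]
    if (length(out) < n_max + 1L) out <- c(out, numeric(n_max + 1L - length(out)))
  }
  if (is.null(metabolite)) {
    metabolite <- if (is_mid(x)) attr(x, "metabolite") else ""
  }
  mid(out, metabolite = metabolite, basis = basis, normalize = TRUE)
}

## binomial labeling distribution over a slot of n positions, each labeled
## independently with probability f
binom_mid_fractions <- function(n_positions, f) {
  stats::dbinom(0:n_positions, size = n_positions, prob = f)
}

## all-or-nothing labeling of an n-carbon unit transferred intact
block_mid_fractions <- function(n_positions, f) {
  out <- numeric(n_positions + 1L)
  out[1L] <- 1 - f
  out[n_positions + 1L] <- out[n_positions + 1L] + f
  out
}
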