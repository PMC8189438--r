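# Independent oracles used across the suite. These deliberately avoid the
# package's convolution code paths.

# Exhaustive enumeration of per-atom isotope outcomes for a carbon-only
# molecule: every subset of n carbons may be 13C.
enumerate_carbon_natural <- function(n_carbons, p13 = 0.0107) {
  out <- numeric(n_carbons + 1L)
  for (k in 0:n_carbons) {
    out[k + 1L] <- choose(n_carbons, k) * p13^k * (1 - p13)^(n_carbons - k)
  }
  # choose() form is itself closed form; cross-check tiny cases by literal
  # enumeration over atom assignments
  if (n_carbons <= 8L) {
    lit <- numeric(n_carbons + 1L)
    grid <- expand.grid(rep(list(c(0L, 1L)), n_carbons))
    for (i in seq_len(nrow(grid))) {
      labs <- as.integer(grid[i, ])
      k <- sum(labs)
      lit[k + 1L] <- lit[k + 1L] + prod(ifelse(labs == 1L, p13, 1 - p13))
    }
    stopifnot(max(abs(lit - out)) < 1e-14)
    out <- lit
  }
  out
}

# Exhaustive multi-element enumeration for very small formulas: each atom
# independently draws a mass shift from its element's isotope table.
enumerate_formula_natural <- function(counts, abundances) {
  atoms <- list()
  for (el in names(counts)) {
    iso <- abundances[[el]]
    atoms <- c(atoms, rep(list(iso), counts[[el]]))
  }
  n_atoms <- length(atoms)
  stopifnot(n_atoms <= 12L)
  max_shift <- sum(vapply(atoms, function(a) max(a$shift), numeric(1)))
  out <- numeric(max_shift + 1L)
  grid <- expand.grid(lapply(atoms, function(a) seq_len(nrow(a))))
  for (i in seq_len(nrow(grid))) {
    idx <- as.integer(grid[i, ])
    shift <- sum(vapply(seq_len(n_atoms), function(j) atoms[[j]]$shift[idx[j]], numeric(1)))
    prob <- prod(vapply(seq_len(n_atoms), function(j) atoms[[j]]$abundance[idx[j]], numeric(1)))
    out[shift + 1L] <- out[shift + 1L] + prob
  }
  out
}

# Dense grid search over (p, q) for the pool-fraction inversion; vectorized
# closed-form binomial terms, no calls into the fitted code path.
grid_search_pq <- function(obs_purine, obs_serine, step = 0.001) {
  p <- seq(0, 1, by = step)
  q <- seq(0, 1, by = step)
  b2 <- function(x, k) choose(2, k) * x^k * (1 - x)^(2 - k)
  # purine: conv(Binom(2,p), Binom(2,q)) over m+0..m+4 (padded to obs length)
  ss <- matrix(0, length(p), length(q))
  for (m in 0:4) {
    comp <- matrix(0, length(p), length(q))
    for (i in max(0, m - 2):min(2, m)) {
      comp <- comp + outer(b2(p, i), b2(q, m - i))
    }
    obs_m <- if (m + 1 <= length(obs_purine)) obs_purine[m + 1] else 0
    ss <- ss + (comp - obs_m)^2
  }
  # serine: conv(Binom(1,p), Binom(2,q)) over m+0..m+3
  b1 <- function(x, k) if (k == 0) 1 - x else x
  for (m in 0:3) {
    comp <- matrix(0, length(p), length(q))
    for (i in max(0, m - 2):min(1, m)) {
      comp <- comp + outer(b1(p, i), b2(q, m - i))
    }
    obs_m <- if (m + 1 <= length(obs_serine)) obs_serine[m + 1] else 0
    ss <- ss + (comp - obs_m)^2
  }
  hit <- which(ss == min(ss), arr.ind = TRUE)[1, ]
  c(p = p[hit[1]], q = q[hit[2]])
}

# measured-basis fraction vector for one metabolite/sample from a long table
table_fractions <- function(tab, metabolite, sample_id) {
  x <- tab[tab$metabolite == metabolite & tab$sample_id == sample_id, ]
  x <- x[order(x$isotopologue), ]
  fractions_from_areas(x$peak_area)
}

# mean-area fraction vector across all replicates of a metabolite
table_mean_fractions <- function(tab, metabolite) {
  x <- tab[tab$metabolite == metabolite, ]
  m <- tapply(x$peak_area, x$isotopologue, mean)
  fractions_from_areas(as.numeric(m[order(as.integer(names(m)))]))
}

random_valid_params <- function() {
  w <- stats::runif(4)
  w <- w / sum(w)
  one_carbon_params(f_trp = w[1], f_ser = w[2], f_exo_formate = w[3],
                    f_other = w[4], q_gly = stats::runif(1),
                    trp_intracellular_labeled = stats::runif(1),
                    ido1_active = stats::runif(1) > 0.2)
}

random_tracer <- function() {
  target <- sample(c("tryptophan", "serine", "formate"), 1)
  n_lab <- switch(target, tryptophan = 11L, serine = 3L, formate = 1L)
  tracer_spec(paste0("rnd-", target), target, n_lab,
              isotopic_purity = stats::runif(1, 0.9, 1),
              medium_concentration_mM = stats::runif(1, 0.05, 1),
              extra_heavy_atoms = if (target == "serine") 1L else 0L)
}
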