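# Shared fixtures for the test suite: all data are generated in code.

APO_WT <- 12652.3
APO_KN <- 12638.2

# A random preparation config whose species are pairwise separated by more
# than `min_sep` Da, for round-trip assignment checks.
random_prep_config <- function(seed, min_sep = 30, table = mass_table()) {
  set.seed(seed)
  prep <- sample(c("Zn", "Cd"), 1)
  repeat {
    k <- sample(2:6, 1)
    if (prep == "Zn") {
      counts <- sort(sample(0:16, k))
      comps <- lapply(counts, function(n) species_composition(n_zn = n))
    } else {
      counts <- sort(sample(0:16, k))
      comps <- lapply(counts, function(n) {
        s <- if (n >= 7 && stats::runif(1) < 0.3) 1L else 0L
        species_composition(n_cd = n, n_sulfide = s)
      })
    }
    masses <- vapply(comps, function(c) species_mass(APO_WT, c, table), numeric(1))
    if (length(masses) < 2 || min(diff(sort(masses))) > min_sep) break
  }
  w <- stats::runif(k, 0.5, 1.5)
  list(prep = prep,
       config = sim_config(seed = seed, apo_mass = APO_WT,
                           species_weights = species_mix(comps, w)))
}

expect_composition_equal <- function(row, truth_row) {
  expect_identical(c(row$n_zn, row$n_cd, row$n_cu, row$n_sulfide),
                   c(truth_row$n_zn, truth_row$n_cd, truth_row$n_cu,
                     truth_row$n_sulfide))
}
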