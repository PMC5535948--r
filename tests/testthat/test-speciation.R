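test_that("assign_species matches observed masses against candidates", {
  cand <- enumerate_candidates(APO_WT, prep_context("Zn"))
  st <- assign_species(data.frame(mass = c(13286, 12652.3),
                                  intensity = c(5, 1)), cand)
  expect_equal(st$label, c("apo", "Zn10"))   # sorted by observed mass
  expect_true(st$major[st$label == "Zn10"])
  expect_true(all(st$relative_error <= 0.001))

  # a mass with no candidate within tolerance stays unassigned
  st2 <- assign_species(13000, cand)
  expect_false(st2$assigned)
  expect_true(is.na(st2$label))
})

test_that("acidic pH excludes Zn and sulfide-free Cd species", {
  cand <- enumerate_candidates(APO_WT, prep_context("Cd", max_sulfide = 2L))
  obs <- c(12652, 13457, 13567)  # apo, Cd7S, Cd8S
  st <- assign_species(obs, cand, ph = "acidic")
  expect_true(all(st$assigned))
  expect_equal(st$label, c("apo", "Cd7S", "Cd8S"))
  # a sulfide-free Cd12 mass finds no admissible acid-stable candidate
  cd12 <- species_mass(APO_WT, species_composition(n_cd = 12))
  st3 <- assign_species(cd12, cand, ph = "acidic")
  expect_false(st3$assigned)
})

test_that("mixed Zn/Cu contexts report the heteronuclear ambiguity set", {
  cand <- enumerate_candidates(APO_WT, prep_context("Cu", max_metals = 16L))
  st <- assign_species(13467, cand)
  expect_true(st$assigned)
  expect_true(st$ambiguous)
  expect_equal(st$label, "M13")
  sp <- attr(st, "splits")[[1]]
  expect_gt(nrow(sp), 1)
  expect_true(all(sp$n_zn + sp$n_cu == 13))
  expect_true(all(abs(sp$delta) <= max(0.001 * 13467, 0.5)))
})

test_that("assignment is deterministic and order-independent", {
  cand <- enumerate_candidates(APO_WT, prep_context("Cd", max_sulfide = 2L))
  masses <- c(13977, 14090, 14229, 14341, 14418)
  inten <- c(1, 2, 5, 2, 1)
  st1 <- assign_species(data.frame(mass = masses, intensity = inten), cand)
  perm <- c(3, 1, 5, 2, 4)
  st2 <- assign_species(data.frame(mass = masses[perm], intensity = inten[perm]),
                        cand)
  expect_equal(as.data.frame(st1), as.data.frame(st2))
})

test_that("duplicate observed masses are collapsed with a warning", {
  cand <- enumerate_candidates(APO_WT, prep_context("Zn"))
  expect_warning(st <- assign_species(
    data.frame(mass = c(13286.20, 13286.25), intensity = c(1, 2)), cand),
    "collapsed")
  expect_equal(nrow(st), 1)
  expect_equal(st$intensity, 3)
})

test_that("mutation_consistency pairs shared species and flags outliers", {
  shift <- substitution_shift("K", "N")
  ref <- reference_speciation()
  wt_zn <- ref[ref$protein == "BgwtMT" & ref$prep == "Zn" & ref$ph == 7.0, ]
  kn_zn <- ref[ref$protein == "BgKNMT" & ref$prep == "Zn" & ref$ph == 7.0, ]
  cand_wt <- enumerate_candidates(APO_WT, prep_context("Zn"))
  cand_kn <- enumerate_candidates(APO_KN, prep_context("Zn"))
  st_wt <- assign_species(data.frame(mass = wt_zn$exp_mm, intensity = 1), cand_wt)
  st_kn <- assign_species(data.frame(mass = kn_zn$exp_mm, intensity = 1), cand_kn)
  rep <- mutation_consistency(st_wt, st_kn, shift)
  expect_equal(nrow(rep), 4)                 # Zn9 .. Zn12
  expect_true(all(rep$consistent))

  # identity: same table against itself with zero shift
  rep0 <- mutation_consistency(st_wt, st_wt, 0)
  expect_true(all(rep0$consistent))

  # a corrupted mutant mass is flagged
  st_bad <- assign_species(data.frame(mass = kn_zn$exp_mm + 3, intensity = 1),
                           cand_kn)
  rep_bad <- mutation_consistency(st_wt, st_bad, shift)
  expect_false(any(rep_bad$consistent))

  cand_cu <- enumerate_candidates(APO_WT, prep_context("Cu"))
  st_other <- assign_species(13403, cand_cu)
  expect_warning(empty <- mutation_consistency(st_wt, st_other, shift),
                 "no shared")
  expect_equal(nrow(empty), 0)
})

test_that("titration occupancies are intensity-weighted and saturation is found", {
  config <- sim_config(seed = 11)
  pts <- make_titration(config, seq(0, 18, by = 2))
  cand <- enumerate_candidates(config$apo_mass,
                               prep_context("Cd", max_sulfide = 0L))
  tables <- lapply(pts, function(p)
    assign_species(data.frame(mass = p$peaks$mz, intensity = p$peaks$intensity),
                   cand))
  curve <- titration_series(vapply(pts, `[[`, numeric(1), "equivalents"),
                            tables)
  expect_equal(curve$cd_occupancy[1], 0)
  expect_gt(curve$zn_occupancy[1], 10)       # starts Zn-loaded
  expect_lt(abs(tail(curve$cd_occupancy, 1) - config$capacity), 1)
  sat <- detect_saturation(curve)
  expect_lte(abs(sat - 12), 2)               # within one grid step
})

test_that("detect_saturation handles flat, linear and degenerate curves", {
  flat <- data.frame(equivalents = c(0, 2, 4), cd_occupancy = c(5, 5, 5))
  expect_equal(detect_saturation(flat), 0)
  linear <- data.frame(equivalents = seq(0, 10, 2),
                       cd_occupancy = seq(0, 10, 2))
  expect_true(is.na(detect_saturation(linear)))
  expect_error(detect_saturation(data.frame(equivalents = c(0, 2, 1),
                                            cd_occupancy = c(0, 1, 2))),
               "strictly increasing")
})
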