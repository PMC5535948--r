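# Run a generator under a local RNG state so generators are pure functions
# of (config, seed) and leave the caller's RNG untouched.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Species mixture specification for the synthetic generators
#'
#' @param compositions List of [species_composition()] objects (or lists of
#'   counts).
#' @param weights Relative abundances; normalized to sum to 1.
#' @return Data frame with composition counts, `label` and `weight`.
#' @export
species_mix <- function(compositions, weights) {
  stopifnot(length(compositions) == length(weights), all(weights > 0))
  weights <- weights / sum(weights)
  do.call(rbind, lapply(seq_along(compositions), function(i) {
    comp <- compositions[[i]]
    if (!inherits(comp, "species_composition")) {
      comp <- do.call(species_composition, as.list(comp))
    }
    data.frame(n_zn = comp$n_zn, n_cd = comp$n_cd, n_cu = comp$n_cu,
               n_sulfide = comp$n_sulfide, label = species_label(comp),
               weight = weights[i])
  }))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators. The defaults emulate the
#' study conditions: a ~12.65 kDa apo protein, a Zn-supplemented preparation
#' dominated by the 10- and 11-metal species, m/z jitter small enough that
#' recovered masses stay within the 0.1% instrument error contract, a
#' displacement capacity of 12 divalent ions, ~96% PCR efficiency, and a
#' 500-fold tissue accumulation factor.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param apo_mass Apo protein mass in Da.
#' @param species_weights A [species_mix()]; default Zn9/Zn10/Zn11/Zn12 at
#'   0.15/0.35/0.35/0.15.
#' @param mz_noise_sd Gaussian m/z jitter sd in Th (raw mode); 0.05 by
#'   default, which at charges 5-9 propagates to < 0.5 Da on the neutral
#'   mass, two orders below the 0.1% contract.
#' @param mass_noise_sd Jitter sd in Da for deconvoluted-mode output
#'   (default `mz_noise_sd * 7`).
#' @param charge_range Integer `c(min, max)` charge states (default 5:9).
#' @param icp_noise_cv Lognormal coefficient of variation of elemental
#'   readouts (default 0.05).
#' @param capacity Divalent-metal capacity of the titration model (default 12).
#' @param initial_zn Initial Zn load of the titrated preparation (default 11).
#' @param affinity_bias Cd-over-Zn preference factor scaling how fast added
#'   equivalents convert to bound Cd (default 1: stoichiometric displacement).
#' @param qpcr List: `efficiency` (default 0.96), `intercept` (Cq at one
#'   copy, default 38), `cq_noise_sd` (default 0.15).
#' @param tissue List: `control_mean` (default 2 ug/g), `factor` (default
#'   500), `cv` (default 0.3).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       apo_mass = 12652.3,
                       species_weights = NULL,
                       mz_noise_sd = 0.05,
                       mass_noise_sd = NULL,
                       charge_range = c(5L, 9L),
                       icp_noise_cv = 0.05,
                       capacity = 12L,
                       initial_zn = 11L,
                       affinity_bias = 1,
                       qpcr = list(efficiency = 0.96, intercept = 38,
                                   cq_noise_sd = 0.15),
                       tissue = list(control_mean = 2, factor = 500,
                                     cv = 0.3)) {
  if (is.null(species_weights)) {
    species_weights <- species_mix(
      list(species_composition(n_zn = 9), species_composition(n_zn = 10),
           species_composition(n_zn = 11), species_composition(n_zn = 12)),
      c(0.15, 0.35, 0.35, 0.15))
  }
  if (is.null(mass_noise_sd)) mass_noise_sd <- mz_noise_sd * 7
  stopifnot(abs(sum(species_weights$weight) - 1) < 1e-8,
            mz_noise_sd >= 0, capacity >= 1, affinity_bias > 0)
  structure(list(seed = as.integer(seed), apo_mass = apo_mass,
                 species_weights = species_weights,
                 mz_noise_sd = mz_noise_sd, mass_noise_sd = mass_noise_sd,
                 charge_range = as.integer(charge_range),
                 icp_noise_cv = icp_noise_cv, capacity = capacity,
                 initial_zn = initial_zn, affinity_bias = affinity_bias,
                 qpcr = qpcr, tissue = tissue),
            class = "sim_config")
}

#' Simulate one recombinant preparation
#'
#' Forward model of a native ESI-MS measurement of a metallated-species
#' mixture: each species in the configured mixture gets, in raw mode, a
#' charge-state envelope over `charge_range` with Gaussian m/z jitter and a
#' triangular intensity profile scaled by its weight; in deconvoluted mode,
#' a single neutral-mass peak with Gaussian jitter. Species whose true
#' masses lie closer than 3x the effective mass noise are recorded as
#' overlapping in the truth metadata (with a warning).
#'
#' @param config A [sim_config()].
#' @param mode `"deconvoluted_mass"` (the primary path) or `"raw_mz"`.
#' @param table [mass_table()] used for the true species masses.
#' @return List with `truth` (species data frame with `true_mass`,
#'   `weight`, `overlapping`) and `peaks` (a [peak_list()]).
#' @export
make_prep <- function(config, mode = c("deconvoluted_mass", "raw_mz"),
                      table = mass_table()) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  sw <- config$species_weights
  truth <- sw
  truth$true_mass <- vapply(seq_len(nrow(sw)), function(i) {
    species_mass(config$apo_mass,
                 species_composition(sw$n_zn[i], sw$n_cd[i], sw$n_cu[i],
                                     sw$n_sulfide[i]), table)
  }, numeric(1))
  noise_scale <- if (mode == "deconvoluted_mass") config$mass_noise_sd
                 else config$mz_noise_sd * mean(config$charge_range)
  sep <- if (nrow(truth) > 1) min(diff(sort(truth$true_mass))) else Inf
  truth$overlapping <- sep < 3 * noise_scale
  if (any(truth$overlapping)) {
    warning("species masses closer than 3x the mass noise; truth flagged")
  }
  peaks <- .with_seed(config$seed, {
    if (mode == "deconvoluted_mass") {
      peak_list(truth$true_mass + stats::rnorm(nrow(truth), 0, config$mass_noise_sd),
                truth$weight, mode = "deconvoluted_mass")
    } else {
      zs <- config$charge_range[1]:config$charge_range[2]
      prof <- 1 - abs(zs - mean(zs)) / (diff(range(zs)) / 2 + 1)
      mz <- c(); inten <- c(); ch <- c()
      for (i in seq_len(nrow(truth))) {
        mz <- c(mz, theoretical_mz(truth$true_mass[i], zs) +
                  stats::rnorm(length(zs), 0, config$mz_noise_sd))
        inten <- c(inten, truth$weight[i] * prof)
        ch <- c(ch, zs)
      }
      peak_list(mz, inten, mode = "raw_mz", charge = ch)
    }
  })
  list(truth = truth, peaks = peaks)
}

#' Simulate a Zn-to-Cd displacement titration
#'
#' Deterministic competitive-exchange toy model: at `e` added equivalents
#' the expected Cd load is `min(e * affinity_bias, capacity)`; the per-point
#' species distribution places geometrically decaying weight on Cd loads
#' around the expectation (window of +/-2 ions, decay 0.2), each Cd load
#' paired with `max(initial_zn - n_cd, 0)` residual Zn — producing the
#' heteronuclear Cd/Zn intermediates seen mid-titration. Intensities are a
#' multinomial draw (n = 1000) over that distribution; masses carry
#' Gaussian jitter.
#'
#' @param config A [sim_config()].
#' @param equivalents_grid Increasing equivalents starting at 0.
#' @param table [mass_table()].
#' @return List of per-point lists: `equivalents`, `truth` (species with
#'   weights and true masses), `peaks` (deconvoluted [peak_list()]).
#' @export
make_titration <- function(config, equivalents_grid = seq(0, 18, by = 2),
                           table = mass_table()) {
  stopifnot(inherits(config, "sim_config"), all(equivalents_grid >= 0),
            !is.unsorted(equivalents_grid, strictly = TRUE))
  cap <- config$capacity
  .with_seed(config$seed, lapply(equivalents_grid, function(e) {
    mu <- min(e * config$affinity_bias, cap)
    center <- round(mu)
    if (e == 0) {
      loads <- 0L; w <- 1
    } else {
      loads <- max(0L, center - 2L):min(cap, center + 2L)
      w <- 0.2^abs(loads - center)
      w <- w / sum(w)
    }
    counts <- as.numeric(stats::rmultinom(1, size = 1000, prob = w))
    keep <- counts > 0
    loads <- loads[keep]; counts <- counts[keep]
    truth <- do.call(rbind, lapply(seq_along(loads), function(i) {
      n_cd <- loads[i]
      n_zn <- max(config$initial_zn - n_cd, 0L)
      comp <- species_composition(n_zn = n_zn, n_cd = n_cd)
      data.frame(n_zn = n_zn, n_cd = n_cd, n_cu = 0L, n_sulfide = 0L,
                 label = species_label(comp),
                 weight = counts[i] / sum(counts),
                 true_mass = species_mass(config$apo_mass, comp, table))
    }))
    peaks <- peak_list(truth$true_mass +
                         stats::rnorm(nrow(truth), 0, config$mass_noise_sd),
                       truth$weight, mode = "deconvoluted_mass")
    list(equivalents = e, truth = truth, peaks = peaks)
  }))
}

#' Simulate an elemental (ICP-AES style) readout
#'
#' Sulfur is peptide-borne (`protein_uM * n_sulfur_per_protein`); each metal
#' concentration is the protein concentration times the weight-averaged
#' stoichiometry of the true species list. All channels carry mean-one
#' lognormal noise with coefficient of variation `icp_noise_cv` (zero noise
#' gives exact values).
#'
#' @param truth Species data frame as produced by [make_prep()] (`n_zn`,
#'   `n_cd`, `n_cu`, `weight`).
#' @param protein_uM True protein concentration, micromolar.
#' @param n_sulfur_per_protein Sulfur atoms per protein.
#' @param config A [sim_config()].
#' @return An [element_readout()].
#' @export
make_icp <- function(truth, protein_uM, n_sulfur_per_protein, config) {
  stopifnot(protein_uM > 0)
  mean_st <- function(col) sum(truth$weight * truth[[col]]) / sum(truth$weight)
  conc <- c(S = protein_uM * n_sulfur_per_protein,
            Zn = protein_uM * mean_st("n_zn"),
            Cd = protein_uM * mean_st("n_cd"),
            Cu = protein_uM * mean_st("n_cu"))
  cv <- config$icp_noise_cv
  if (cv > 0) {
    sigma <- sqrt(log(1 + cv^2))
    conc <- .with_seed(config$seed + 1L,
                       conc * exp(stats::rnorm(length(conc), 0, sigma) - sigma^2 / 2))
  }
  element_readout(conc, n_sulfur_per_protein)
}

#' Simulate qPCR measurements and a dilution-series calibration
#'
#' Cq values follow the log-linear model
#' `Cq = intercept + slope * log10(copies) + N(0, cq_noise_sd)` with
#' `slope = -1 / log10(1 + efficiency)`; at 96% efficiency ten-fold
#' dilutions are 3.42 cycles apart.
#'
#' @param copies True template copies per sample (> 0).
#' @param config A [sim_config()] (fields under `config$qpcr`).
#' @param dilution_log10 log10 copies of the calibration dilution series
#'   (default 1:7).
#' @return List with `cq` (per-sample Cq), `calibration` (data frame
#'   `log10_copies`, `cq`), `slope`, `intercept`.
#' @export
make_qpcr <- function(copies, config, dilution_log10 = 1:7) {
  stopifnot(all(copies > 0))
  q <- config$qpcr
  slope <- -1 / log10(1 + q$efficiency)
  .with_seed(config$seed + 2L, {
    cq <- q$intercept + slope * log10(copies) +
      stats::rnorm(length(copies), 0, q$cq_noise_sd)
    cal_cq <- q$intercept + slope * dilution_log10 +
      stats::rnorm(length(dilution_log10), 0, q$cq_noise_sd)
    list(cq = cq,
         calibration = data.frame(log10_copies = dilution_log10, cq = cal_cq),
         slope = slope, intercept = q$intercept)
  })
}

#' Simulate tissue-metal concentrations for control and exposed groups
#'
#' @param config A [sim_config()] (fields under `config$tissue`).
#' @param n Animals per group (default 4, the study's sampling).
#' @return List with numeric vectors `control` and `exposed` (ug/g).
#' @export
make_tissue <- function(config, n = 4L) {
  tt <- config$tissue
  .with_seed(config$seed + 3L, {
    ctrl <- pmax(stats::rnorm(n, tt$control_mean, tt$cv * tt$control_mean), 1e-6)
    expo <- pmax(stats::rnorm(n, tt$control_mean * tt$factor,
                              tt$cv * tt$control_mean * tt$factor), 1e-6)
    list(control = ctrl, exposed = expo)
  })
}
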