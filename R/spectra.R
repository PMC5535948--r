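PROTON_MASS <- 1.00728

#' m/z of a neutral mass at a given positive charge
#'
#' Standard positive-mode electrospray relation: `(M + z * 1.00728) / z`,
#' with the proton as the charge carrier.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Integer charge >= 1.
#' @return m/z in Thomson.
#' @export
theoretical_mz <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge must be a positive integer")
  (neutral_mass + z * PROTON_MASS) / z
}

#' Peak list container
#'
#' @param mz Numeric vector of m/z (raw mode) or neutral masses
#'   (deconvoluted mode); must be positive.
#' @param intensity Non-negative intensities.
#' @param mode `"raw_mz"` or `"deconvoluted_mass"`.
#' @param charge Optional integer charges (raw mode, if known).
#' @return A data frame of class `peak_list`, sorted by m/z.
#' @export
peak_list <- function(mz, intensity, mode = c("raw_mz", "deconvoluted_mass"),
                      charge = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity), all(mz > 0), all(intensity >= 0))
  df <- data.frame(mz = mz, intensity = intensity)
  if (!is.null(charge)) df$charge <- as.integer(charge)
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_list", "data.frame"), mode = mode)
}

#' Read a peak list from CSV
#'
#' Accepts either `mz,intensity[,charge]` (raw mode) or `mass,intensity`
#' (deconvoluted mode); the header decides the mode.
#'
#' @param path CSV path.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  if ("mass" %in% nm) {
    peak_list(df[[which(nm == "mass")]], df[[which(nm == "intensity")]],
              mode = "deconvoluted_mass")
  } else if ("mz" %in% nm) {
    ch <- if ("charge" %in% nm) df[[which(nm == "charge")]] else NULL
    peak_list(df[[which(nm == "mz")]], df[[which(nm == "intensity")]],
              mode = "raw_mz", charge = ch)
  } else {
    stop("peak CSV must have a 'mass' or 'mz' column plus 'intensity': ", path)
  }
}

#' Infer charge states from adjacent peaks of one envelope
#'
#' For two adjacent charge states z+1 and z of the same neutral species at
#' m/z values a < b, `z = (a - proton) / (b - a)`. The function assumes the
#' peaks are consecutive charge states of one species (ascending m/z means
#' descending charge), derives the ladder from the first adjacent pair, and
#' verifies that every (m/z, z) back-computes to the same neutral mass
#' within 0.2%; otherwise the envelope is rejected as ambiguous.
#'
#' @param peaks A raw-mode [peak_list()] with >= 2 peaks.
#' @param max_charge Largest admissible charge state (default 50); a ladder
#'   implying more charges than this is rejected as ambiguous.
#' @return The peak list with an added integer `charge` column.
#' @export
infer_charges <- function(peaks, max_charge = 50L) {
  stopifnot(inherits(peaks, "peak_list"))
  if (identical(attr(peaks, "mode"), "deconvoluted_mass")) {
    stop("charge inference applies to raw m/z peak lists only")
  }
  if (nrow(peaks) < 2) stop("ambiguous envelope: need >= 2 peaks to infer charges")
  mz <- peaks$mz  # ascending
  a <- mz[1]; b <- mz[2]
  z_b <- round((a - PROTON_MASS) / (b - a))
  if (!is.finite(z_b) || z_b < 1 || z_b + 1L > max_charge) {
    stop("ambiguous envelope: no consistent charge ladder")
  }
  # ascending m/z <=> descending charge, consecutive states
  charges <- (z_b + 1L) - (seq_len(nrow(peaks)) - 1L)
  if (any(charges < 1)) stop("ambiguous envelope: ladder runs below charge 1")
  masses <- charges * (mz - PROTON_MASS)
  spread <- (max(masses) - min(masses)) / stats::median(masses)
  if (spread > 0.002) stop("ambiguous envelope: neutral-mass spread exceeds 0.2%")
  peaks$charge <- as.integer(charges)
  peaks
}

#' Neutral mass from a charge-assigned envelope
#'
#' Intensity-weighted mean of `z * (mz - proton)` over the envelope's peaks,
#' with the (unweighted) standard deviation of the per-peak estimates as the
#' mass uncertainty. Pairwise inconsistency beyond 0.2% rejects the envelope.
#'
#' @param env_peaks Data frame with columns `mz`, `charge` and optionally
#'   `intensity` (defaults to equal weights); e.g. the output of
#'   [infer_charges()].
#' @return List with `mass` (Da), `sd` (Da), `n_peaks`.
#' @export
neutral_mass_from_envelope <- function(env_peaks) {
  stopifnot(nrow(env_peaks) >= 1, all(c("mz", "charge") %in% names(env_peaks)))
  w <- if ("intensity" %in% names(env_peaks)) env_peaks$intensity else rep(1, nrow(env_peaks))
  if (all(w == 0)) w <- rep(1, length(w))
  m <- env_peaks$charge * (env_peaks$mz - PROTON_MASS)
  if (length(m) > 1) {
    spread <- (max(m) - min(m)) / stats::median(m)
    if (spread > 0.002) stop("inconsistent envelope: pairwise neutral-mass spread > 0.2%")
  }
  list(mass = sum(w * m) / sum(w),
       sd = if (length(m) > 1) stats::sd(m) else 0,
       n_peaks = length(m))
}

#' Group raw peaks into envelopes and deconvolute to neutral masses
#'
#' Infers charges pairwise across the peak list, clusters peaks greedily into
#' envelopes whose per-peak neutral masses agree within 0.1% (ties broken by
#' higher summed intensity), and returns one neutral mass per envelope.
#' Deconvoluted-mode peak lists pass through unchanged (each peak already is
#' a neutral mass).
#'
#' @param peaks A [peak_list()].
#' @return Data frame with columns `mass`, `sd`, `intensity`, `n_peaks`.
#' @export
deconvolute <- function(peaks) {
  stopifnot(inherits(peaks, "peak_list"))
  if (identical(attr(peaks, "mode"), "deconvoluted_mass")) {
    return(data.frame(mass = peaks$mz, sd = 0, intensity = peaks$intensity,
                      n_peaks = 1L))
  }
  if (!"charge" %in% names(peaks)) {
    # assign charges per peak by testing integer charges against neighbours
    peaks <- .assign_charges_multi(peaks)
  }
  m <- peaks$charge * (peaks$mz - PROTON_MASS)
  ord <- order(m)
  groups <- integer(nrow(peaks)); gid <- 0L; ref <- -Inf
  for (i in ord) {
    if (gid == 0L || (m[i] - ref) / ref > 0.001) {
      gid <- gid + 1L; ref <- m[i]
    }
    groups[i] <- gid
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(peaks)), groups), function(idx) {
    est <- neutral_mass_from_envelope(peaks[idx, , drop = FALSE])
    data.frame(mass = est$mass, sd = est$sd,
               intensity = sum(peaks$intensity[idx]), n_peaks = est$n_peaks)
  }))
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Charge assignment for a possibly multi-species raw peak list.
# Candidate neutral masses come from the implied charge of every peak pair
# (adjacent-charge spacing relation); candidates are clustered within 0.1%
# and each cluster is scored by the longest run of consecutive charge
# states among the peaks it explains. Clusters are consumed greedily by
# (score, smaller mass).
.assign_charges_multi <- function(peaks, max_charge = 50L) {
  mz <- peaks$mz
  n <- length(mz)
  cand <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mz[i]; b <- mz[j]
      z_b <- round((a - PROTON_MASS) / (b - a))
      if (is.finite(z_b) && z_b >= 1 && z_b + 1 <= max_charge) {
        cand <- c(cand, z_b * (b - PROTON_MASS))
      }
    }
  }
  if (!length(cand)) stop("ambiguous envelope: no consistent charge ladder")
  cand <- sort(cand)
  centers <- c()
  k <- 1
  while (k <= length(cand)) {
    grp <- cand[cand >= cand[k] & cand <= cand[k] * 1.001]
    centers <- c(centers, stats::median(grp))
    k <- k + length(grp)
  }

  peak_charge_for <- function(M) {
    z <- round(M / (mz - PROTON_MASS))
    ok <- z >= 1 & z <= max_charge &
      abs(z * (mz - PROTON_MASS) - M) / M < 0.001
    list(z = z, ok = ok)
  }
  # score a cluster by the longest run of consecutive charges it explains:
  # a genuine envelope occupies adjacent charge states, whereas k-fold
  # harmonics and rational-ratio coincidences support scattered charges only
  run_score <- function(M) {
    h <- peak_charge_for(M)
    z <- sort(unique(h$z[h$ok]))
    if (!length(z)) return(0L)
    max(tabulate(cumsum(c(1L, as.integer(diff(z) != 1L)))))
  }
  support <- vapply(centers, run_score, numeric(1))
  charge <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  ord <- order(-support, centers)
  for (ci in ord) {
    hit <- peak_charge_for(centers[ci])
    take <- hit$ok & remaining
    if (sum(take) >= 2) {
      charge[take] <- as.integer(hit$z[take])
      remaining[take] <- FALSE
    }
    if (!any(remaining)) break
  }
  if (all(is.na(charge))) stop("ambiguous envelope: no consistent charge ladder")
  if (any(is.na(charge))) {
    warning(sum(is.na(charge)), " peak(s) without a consistent charge dropped")
    peaks <- peaks[!is.na(charge), , drop = FALSE]
    charge <- charge[!is.na(charge)]
  }
  peaks$charge <- charge
  peaks
}

#' Pick peaks from a sampled intensity trace
#'
#' Local maxima above a relative-intensity threshold, with the apex position
#' refined by three-point parabolic interpolation.
#'
#' @param x Sampled positions (m/z axis), strictly increasing.
#' @param y Intensities (same length).
#' @param min_rel_intensity Fraction of the global maximum below which local
#'   maxima are ignored (default 0.05).
#' @param mode Mode label for the returned [peak_list()].
#' @return A [peak_list()]; empty for a flat trace.
#' @export
pick_peaks <- function(x, y, min_rel_intensity = 0.05, mode = "raw_mz") {
  stopifnot(length(x) == length(y), length(x) >= 3, all(diff(x) > 0))
  ymax <- max(y)
  if (ymax <= 0) {
    return(peak_list(numeric(0), numeric(0), mode = mode))
  }
  thr <- min_rel_intensity * ymax
  n <- length(y)
  core <- 2:(n - 1)
  is_max <- y[core] >= y[core - 1] & y[core] > y[core + 1] & y[core] >= thr
  idx <- core[is_max]
  if (!length(idx)) return(peak_list(numeric(0), numeric(0), mode = mode))
  apex <- vapply(idx, function(i) {
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
    # uniform spacing assumed locally
    x[i] + delta * (x[i + 1] - x[i])
  }, numeric(1))
  peak_list(apex, y[idx], mode = mode)
}
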