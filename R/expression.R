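#' Fit a qPCR calibration line
#'
#' Least-squares fit of Cq against log10 template copies over a dilution
#' series. The amplification efficiency follows from the slope:
#' `efficiency = 10^(-1/slope) - 1`, so perfect doubling gives a slope of
#' -3.3219 and efficiency 1; the study's assay ran at ~96% (slope ~ -3.42).
#'
#' @param log10_copies Numeric vector, log10 of template copies; >= 3
#'   distinct values.
#' @param cq Quantification cycles, same length.
#' @return Object of class `qpcr_calibration` with `slope`, `intercept`,
#'   `efficiency`, `r_squared` and the underlying `lm` fit.
#' @export
fit_calibration <- function(log10_copies, cq) {
  stopifnot(length(log10_copies) == length(cq))
  if (length(unique(log10_copies)) < 3) {
    stop("need >= 3 distinct dilution points")
  }
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("calibration slope must be negative (Cq falls with copies)")
  eff <- 10^(-1 / slope) - 1
  if (eff <= 0 || eff > 1.1) {
    warning(sprintf("implausible PCR efficiency %.2f from slope %.3f", eff, slope))
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = eff,
                 # summary.lm warns on exact fits; noiseless calibrations are valid
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 range = range(log10_copies),
                 fit = fit),
            class = "qpcr_calibration")
}

#' @export
print.qpcr_calibration <- function(x, ...) {
  cat(sprintf("qPCR calibration: Cq = %.3f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.3f (%.1f%%), R^2 %.4f\n",
              x$efficiency, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' @export
coef.qpcr_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict Cq from copies with a fitted calibration
#' @param object A [fit_calibration()] result.
#' @param copies Template copy numbers.
#' @param ... Unused.
#' @return Predicted Cq values.
#' @export
predict.qpcr_calibration <- function(object, copies, ...) {
  object$intercept + object$slope * log10(copies)
}

#' Absolute copy number from a Cq value
#'
#' Inverts the calibration line: `copies = 10^((cq - intercept) / slope)`.
#' Extrapolation beyond the fitted dilution range triggers a warning.
#'
#' @param cq Quantification cycle(s).
#' @param cal A [fit_calibration()] result.
#' @return Copy numbers.
#' @export
copies_from_cq <- function(cq, cal) {
  stopifnot(inherits(cal, "qpcr_calibration"))
  lg <- (cq - cal$intercept) / cal$slope
  if (any(lg < cal$range[1] - 1e-9 | lg > cal$range[2] + 1e-9)) {
    warning("Cq outside the calibrated dilution range; extrapolating")
  }
  10^lg
}

#' Two-group comparison with a normality gate
#'
#' Applies Shapiro-Wilk at alpha 0.05 to each group; if both pass, a
#' two-sided Welch t-test is used, otherwise the two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test. A group with (near-)zero variance fails the
#' gate. Significance is declared at `p <= alpha`.
#'
#' @param a,b Numeric vectors, each n >= 3.
#' @param alpha Significance level (default 0.05).
#' @param normality_alpha Gate level for Shapiro-Wilk (default 0.05).
#' @return Object of class `group_comparison`: list with `test_used`
#'   (`"t"` or `"mann-whitney"`), `p_value`, `significant`, `alpha`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, normality_alpha = 0.05) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  normal <- function(x) {
    if (stats::sd(x) < .Machine$double.eps^0.5) return(FALSE)
    stats::shapiro.test(x)$p.value > normality_alpha
  }
  if (normal(a) && normal(b)) {
    test_used <- "t"
    p <- stats::t.test(a, b)$p.value
  } else {
    test_used <- "mann-whitney"
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
    if (!is.finite(p)) p <- 1   # all observations tied
  }
  structure(list(test_used = test_used, p_value = p,
                 significant = p <= alpha, alpha = alpha,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test (n = %d vs %d): p = %.4g (%ssignificant at %.2g)\n",
              x$test_used, x$n_a, x$n_b, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Tissue-metal concentration factor
#'
#' Ratio of mean exposed to mean control tissue metal concentration; the
#' midgut gland of Cd-exposed snails accumulates Cd roughly 500-fold over
#' controls.
#'
#' @param exposed,control Tissue metal concentrations (e.g. ug/g dry weight).
#' @return The fold ratio `mean(exposed) / mean(control)`.
#' @export
concentration_factor <- function(exposed, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) stop("control mean must be > 0")
  mean(exposed) / mc
}

#' Amplicon length defined by a primer pair on a template
#'
#' The sense primer must match the forward strand exactly once; the
#' antisense primer (given 5'->3') must match as its reverse complement
#' exactly once, downstream of the sense site. The amplicon spans from the
#' sense 5' start through the antisense 5' start inclusive of both primer
#' footprints (the standard qPCR convention; the study's assay amplifies a
#' 107 bp product).
#'
#' @param template Nucleotide sequence (5'->3').
#' @param sense_primer,antisense_primer Primer sequences, 5'->3'.
#' @return Amplicon length in bp.
#' @export
amplicon_length <- function(template, sense_primer, antisense_primer) {
  template <- toupper(gsub("\\s", "", template))
  sense <- toupper(sense_primer)
  anti_rc <- .revcomp(toupper(antisense_primer))
  find_once <- function(pat, what) {
    hits <- gregexpr(pat, template, fixed = TRUE)[[1]]
    if (hits[1] == -1) stop(what, " primer not found in template")
    if (length(hits) > 1) stop(what, " primer matches template more than once")
    hits[1]
  }
  s <- find_once(sense, "sense")
  a <- find_once(anti_rc, "antisense")
  anti_end <- a + nchar(anti_rc) - 1L
  if (a <= s) stop("antisense site lies upstream of the sense site")
  anti_end - s + 1L
}

.revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTUacgtu", "TGCAAtgcaa", x), "")[[1]]),
        collapse = "")
}
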