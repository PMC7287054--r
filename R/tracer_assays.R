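# Isotopologue, cofactor-ratio, qPCR and dose-response calculators.

#' Mass-isotopologue fractions
#'
#' Normalizes an intensity vector indexed by mass shift (M+0 ... M+k) to
#' fractions summing to one. Natural-abundance correction is assumed done
#' upstream; an optional correction matrix is applied to the intensities
#' first.
#'
#' @param intensities non-negative intensity vector (M+0 first).
#' @param correction optional square correction matrix applied as
#'   `correction %*% intensities`.
#' @return numeric vector of fractions (same names as the input).
#' @export
isotopologue_fractions <- function(intensities, correction = NULL) {
  if (!is.null(correction)) {
    stopifnot(is.matrix(correction),
              nrow(correction) == length(intensities))
    intensities <- as.vector(correction %*% intensities)
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  tot <- sum(intensities)
  if (tot <= 0) stop("total intensity must be positive")
  intensities / tot
}

#' Mitochondrial fraction of labeled dTTP synthesis
#'
#' With a heavy-serine tracer, cytosolic one-carbon units give dTTP a +3
#' mass shift and mitochondrial ones +2, so the mitochondrial share of
#' labeled thymidylate synthesis is `M+2 / (M+2 + M+3)`. Unlabeled M+0
#' background is excluded from the denominator.
#'
#' @param intensities intensity vector of the dTTP isotopologue profile.
#' @param mass_shift integer mass shifts matching `intensities` (defaults to
#'   names, else 0, 1, 2, ...).
#' @return fraction in \[0, 1\], or `NA` (with a warning) when both labeled
#'   channels are zero.
#' @export
mitochondrial_dttp_fraction <- function(intensities, mass_shift = NULL) {
  if (is.null(mass_shift)) {
    mass_shift <- if (!is.null(names(intensities)))
      as.integer(names(intensities)) else seq_along(intensities) - 1L
  }
  stopifnot(length(mass_shift) == length(intensities))
  if (any(intensities < 0)) stop("intensities must be non-negative")
  m2 <- sum(intensities[mass_shift == 2L])
  m3 <- sum(intensities[mass_shift == 3L])
  if (m2 + m3 <= 0) {
    warning("both labeled dTTP channels (M+2, M+3) are zero; fraction undefined")
    return(NA_real_)
  }
  m2 / (m2 + m3)
}

#' Internal-standard quantification
#'
#' `amount = (analyte_area / is_area) * is_amount` for a spiked-in labeled
#' internal standard of known amount.
#'
#' @param analyte_area,is_area integrated peak areas of analyte and internal
#'   standard.
#' @param is_amount amount of internal standard added (any unit; the result
#'   carries the same unit).
#' @return estimated analyte amount.
#' @export
quantify_with_internal_standard <- function(analyte_area, is_area, is_amount) {
  if (any(is_area <= 0)) stop("internal-standard area must be positive")
  if (any(analyte_area < 0)) stop("analyte area must be non-negative")
  (analyte_area / is_area) * is_amount
}

#' Metabolite pool fold-change with t-test
#'
#' Fold-change of mean treated over mean control amounts with a two-sided
#' equal-variance Student t-test on the amounts.
#'
#' @param treated,control replicate amount vectors (>= 2 each).
#' @return list with `fold_change`, `p`, `mean_treated`, `mean_control`,
#'   `n_treated`, `n_control`.
#' @export
pool_fold_change <- function(treated, control) {
  if (length(treated) < 2L || length(control) < 2L)
    stop("need >= 2 replicates per condition")
  if (mean(control) == 0) stop("control mean is zero; fold-change undefined")
  tt <- stats::t.test(treated, control, var.equal = TRUE)
  list(fold_change = mean(treated) / mean(control),
       p = unname(tt$p.value),
       mean_treated = mean(treated), mean_control = mean(control),
       n_treated = length(treated), n_control = length(control))
}

#' NADP+/NADPH ratio from paired luminescence signals
#'
#' Luminescence is proportional to cofactor concentration (acid-treated
#' aliquots report NADP+, base-treated aliquots NADPH), so the redox ratio
#' is the simple signal ratio.
#'
#' @param nadp_signal,nadph_signal positive luminescence signals.
#' @return `nadp_signal / nadph_signal`.
#' @export
nadp_ratio <- function(nadp_signal, nadph_signal) {
  if (any(nadp_signal <= 0) || any(nadph_signal <= 0))
    stop("signals must be positive")
  nadp_signal / nadph_signal
}

#' Efficiency-corrected relative qPCR quantification (Pfaffl model)
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref` with
#' `dCt = Ct_control - Ct_sample` for each amplicon; reduces exactly to
#' `2^-ddCt` when both efficiencies are 2.
#'
#' @param ct_target_control,ct_target_sample target-gene Ct in the control
#'   and the sample of interest.
#' @param ct_ref_control,ct_ref_sample reference-gene (e.g. GAPDH) Ct.
#' @param e_target,e_ref amplification efficiencies in (1, 2.2\].
#' @return relative expression ratio of the target, normalized to the
#'   reference gene and relative to the control.
#' @export
pfaffl_ratio <- function(ct_target_control, ct_target_sample,
                         ct_ref_control, ct_ref_sample,
                         e_target = 2, e_ref = 2) {
  if (any(c(e_target, e_ref) <= 1) || any(c(e_target, e_ref) > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  cts <- c(ct_target_control, ct_target_sample, ct_ref_control, ct_ref_sample)
  if (any(cts <= 0)) stop("Ct values must be positive")
  e_target^(ct_target_control - ct_target_sample) /
    e_ref^(ct_ref_control - ct_ref_sample)
}

#' Primer efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10 input; `E = 10^(-1/slope)`. A
#' slope of -3.3219 corresponds to perfect doubling (E = 2).
#'
#' @param ct_values Ct values (>= 3 points).
#' @param log10_input log10 relative template input.
#' @return list with `efficiency`, `slope`, `r_squared`.
#' @export
efficiency_from_dilution <- function(ct_values, log10_input) {
  if (length(ct_values) < 3L || length(ct_values) != length(log10_input))
    stop("need >= 3 matched dilution points")
  if (length(unique(log10_input)) < 2L) stop("singular fit: inputs identical")
  fit <- stats::lm(ct_values ~ log10_input)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("Ct must decrease with template input (negative slope)")
  ord <- order(log10_input)
  if (is.unsorted(-ct_values[ord]) && stats::cor(ct_values, log10_input) > -0.9)
    stop("dilution series is not monotone decreasing in input")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct_values - mean(ct_values))^2)
  list(efficiency = 10^(-1 / slope), slope = slope,
       r_squared = 1 - ss_res / ss_tot)
}

fourpl <- function(d, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (log(d) - log_ic50)))
}

#' Four-parameter-logistic dose-response fit and IC50
#'
#' Least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`, multi-started
#' from quartile-spaced IC50 initializations to avoid local minima
#' (convergence tolerance 1e-8 on relative residual change). Flat responses
#' (viability range below `flat_tol`) are flagged instead of fitted.
#'
#' @param doses positive dose vector (>= 5 points spanning the transition).
#' @param viabilities survival percentages matching `doses`.
#' @param flat_tol minimal viability range (same unit as `viabilities`)
#'   required to attempt a fit.
#' @return list of class `ic50_fit`: `bottom`, `top`, `hill`, `ic50`,
#'   `converged`, `residual_norm`, `no_fit`.
#' @export
fit_4pl_ic50 <- function(doses, viabilities, flat_tol = 5) {
  stopifnot(length(doses) == length(viabilities))
  if (length(unique(doses)) < 5L)
    stop("need >= 5 distinct dose points")
  if (any(doses <= 0)) stop("doses must be positive")
  if (diff(range(viabilities)) < flat_tol) {
    return(structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                          ic50 = NA_real_, converged = FALSE,
                          residual_norm = NA_real_, no_fit = TRUE),
                     class = "ic50_fit"))
  }
  dat <- data.frame(d = doses, v = viabilities)
  starts <- stats::quantile(log(doses), c(0.25, 0.5, 0.75), names = FALSE)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ fourpl(d, bottom, top, log_ic50, hill), data = dat,
        start = list(bottom = min(viabilities), top = max(viabilities),
                     log_ic50 = s, hill = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                          ic50 = NA_real_, converged = FALSE,
                          residual_norm = NA_real_, no_fit = TRUE),
                     class = "ic50_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                 hill = unname(cf["hill"]),
                 ic50 = exp(unname(cf["log_ic50"])),
                 converged = best$fit$convInfo$isConv %||% TRUE,
                 residual_norm = best$rn, no_fit = FALSE),
            class = "ic50_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' IC50 fold-change between two fitted dose-response curves
#' @param fit_reference,fit_treated `ic50_fit` objects (reference first).
#' @return `fit_treated$ic50 / fit_reference$ic50`.
#' @export
ic50_fold_change <- function(fit_reference, fit_treated) {
  stopifnot(inherits(fit_reference, "ic50_fit"), inherits(fit_treated, "ic50_fit"))
  if (isTRUE(fit_reference$no_fit) || isTRUE(fit_treated$no_fit))
    stop("cannot form a fold-change from a flagged no-fit curve")
  fit_treated$ic50 / fit_reference$ic50
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (isTRUE(x$no_fit)) {
    cat("ic50_fit: flat response, no fit\n")
  } else {
    cat(sprintf("ic50_fit: ic50 = %.4g, hill = %.3g, span [%.3g, %.3g], resid %.3g\n",
                x$ic50, x$hill, x$bottom, x$top, x$residual_norm))
  }
  invisible(x)
}
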