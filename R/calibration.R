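#' Construct a calibration curve
#'
#' A monotone map between analyte concentration and fluorescence readout.
#' Two forms are supported, matching the two in-droplet assays:
#'
#' * `igg_relocation`: saturating exponential
#'   `R(c) = baseline + span * (1 - exp(-c / c0))`, the relocation ratio of
#'   the sandwich immunoassay as captured IgG accumulates on the
#'   nanoparticle beadline. Concentration in mol/L.
#' * `lactate_linear`: `R(c) = intercept + slope * c`, the fluorometric
#'   lactate probe readout. Concentration in micromolar (umol/L).
#'
#' Both are strictly monotone increasing on their valid range, so the
#' inverse map [concentration()] is well defined on the forward image.
#'
#' @param kind `"igg_relocation"` or `"lactate_linear"`.
#' @param baseline,span,c0 Saturating-exponential parameters (IgG form).
#'   `baseline` is the relocation at zero analyte, `span` the asymptotic
#'   rise above baseline and `c0` the concentration scale (mol/L).
#' @param intercept,slope Linear parameters (lactate form); slope in
#'   a.u. per uM must be positive.
#' @param conc_range Valid concentration range (same unit as the curve).
#' @return An object of class `calibration_curve`.
#' @examples
#' cv <- calibration_curve("igg_relocation", baseline = 1, span = 4, c0 = 1.5e-8)
#' predict(cv, concentration = 1.5e-8)  # baseline + span*(1 - exp(-1))
#' @export
calibration_curve <- function(kind = c("igg_relocation", "lactate_linear"),
                              baseline = NULL, span = NULL, c0 = NULL,
                              intercept = NULL, slope = NULL,
                              conc_range = NULL) {
  kind <- match.arg(kind)
  if (kind == "igg_relocation") {
    stopifnot(is.numeric(baseline), is.numeric(span), is.numeric(c0),
              span > 0, c0 > 0)
    pars <- c(baseline = baseline, span = span, c0 = c0)
    if (is.null(conc_range)) conc_range <- c(0, 5 * c0)
  } else {
    stopifnot(is.numeric(intercept), is.numeric(slope), slope > 0)
    pars <- c(intercept = intercept, slope = slope)
    if (is.null(conc_range)) conc_range <- c(0, Inf)
  }
  stopifnot(length(conc_range) == 2, conc_range[1] >= 0,
            conc_range[1] < conc_range[2])
  structure(list(kind = kind, parameters = pars, conc_range = conc_range,
                 fit = NULL),
            class = "calibration_curve")
}

#' Default IgG relocation calibration
#'
#' Baseline relocation 1.0 (beadline indistinguishable from the droplet at
#' zero IgG), span 4.0 and concentration scale 15 nM, which keeps the whole
#' IgG quantitative range on the invertible part of the curve for a 50 pL
#' droplet observed over 50 min.
#' @return A `calibration_curve` of kind `igg_relocation`.
#' @export
default_igg_calibration <- function() {
  calibration_curve("igg_relocation", baseline = 1.0, span = 4.0, c0 = 1.5e-8)
}

#' Default linear lactate calibration
#'
#' Intercept 100 a.u. at zero lactate, slope 20 a.u. per uM.
#' @return A `calibration_curve` of kind `lactate_linear`.
#' @export
default_lactate_calibration <- function() {
  calibration_curve("lactate_linear", intercept = 100, slope = 20)
}

#' Forward-evaluate a calibration curve
#'
#' @param object A [calibration_curve()].
#' @param concentration Concentrations (mol/L for IgG relocation, uM for
#'   lactate).
#' @param ... Unused.
#' @return Readout values (relocation ratio or a.u.).
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  if (any(concentration < 0, na.rm = TRUE))
    stop("concentrations must be >= 0")
  p <- object$parameters
  if (object$kind == "igg_relocation") {
    unname(p["baseline"] + p["span"] * (1 - exp(-concentration / p["c0"])))
  } else {
    unname(p["intercept"] + p["slope"] * concentration)
  }
}

#' Invert a calibration curve
#'
#' Maps readout back to concentration. Readouts below the zero-concentration
#' readout clamp to 0 and readouts above the forward image of the valid
#' range clamp to its upper end; clamped positions are reported in the
#' `"clamped"` attribute.
#'
#' @param curve A [calibration_curve()].
#' @param readout Readout values.
#' @return Concentrations (same unit as the curve), with attribute
#'   `"clamped"`: a logical vector marking out-of-image readouts.
#' @export
concentration <- function(curve, readout) {
  stopifnot(inherits(curve, "calibration_curve"))
  p <- curve$parameters
  if (curve$kind == "igg_relocation") {
    lo <- p[["baseline"]]
    hi <- predict(curve, curve$conc_range[2])
    clamped <- readout < lo | readout > hi
    r <- pmin(pmax(readout, lo), hi)
    frac <- (r - p[["baseline"]]) / p[["span"]]
    conc <- -p[["c0"]] * log1p(-frac)
  } else {
    lo <- p[["intercept"]]
    clamped <- readout < lo
    conc <- pmax(readout - lo, 0) / p[["slope"]]
  }
  conc <- pmin(pmax(conc, curve$conc_range[1]), curve$conc_range[2])
  attr(conc, "clamped") <- clamped
  conc
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve (", x$kind, ")\n", sep = "")
  print(x$parameters)
  cat("valid concentration range:", format(x$conc_range[1]), "-",
      format(x$conc_range[2]),
      if (x$kind == "igg_relocation") "mol/L" else "uM", "\n")
  if (!is.null(x$fit))
    cat("fit residual SD:", format(x$fit$sigma, digits = 4),
        if (isTRUE(x$fit$monotone_warning)) "(non-monotone standards)" else "",
        "\n")
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) object$parameters

#' Fit the IgG relocation calibration from standards
#'
#' Least-squares fit of the saturating exponential
#' `R(c) = baseline + span * (1 - exp(-c / c0))` to a standards table of
#' known IgG concentrations and measured relocation readouts
#' (Levenberg-Marquardt). A warning flag is set when the mean readouts are
#' not monotone in concentration beyond what the replicate scatter explains.
#'
#' @param standards Data frame with columns `concentration` (mol/L) and
#'   `readout`; replicate rows are allowed.
#' @return A `calibration_curve` of kind `igg_relocation` carrying a `fit`
#'   element (residual `sigma`, `monotone_warning`, `nls` object).
#' @export
fit_igg_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "readout") %in% names(standards)))
  conc <- standards$concentration
  if (any(conc < 0)) stop("standard concentrations must be >= 0")
  uc <- sort(unique(conc))
  if (length(uc) < 4 || uc[1] != 0)
    stop("need standards at >= 4 distinct concentrations including 0")
  means <- tapply(standards$readout, standards$concentration, mean)
  means <- means[order(as.numeric(names(means)))]
  resid_sd <- stats::sd(unlist(tapply(standards$readout,
                                      standards$concentration,
                                      function(v) v - mean(v))))
  if (!is.finite(resid_sd)) resid_sd <- 0
  monotone_warning <- any(diff(means) < -3 * max(resid_sd, 1e-12))

  start <- list(baseline = means[[1]],
                span = max(max(means) - means[[1]], 1e-6),
                c0 = max(stats::median(uc[uc > 0]), .Machine$double.eps))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      readout ~ baseline + span * (1 - exp(-concentration / c0)),
      data = standards, start = start,
      lower = c(-Inf, 1e-12, .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    sigma <- stats::sigma(fit)
  } else {
    # degenerate standards (e.g. grossly non-monotone): direct
    # least-squares on (baseline, log span, log c0)
    obj <- function(p) {
      pred <- p[1] + exp(p[2]) * (1 - exp(-standards$concentration / exp(p[3])))
      sum((standards$readout - pred)^2)
    }
    op <- stats::optim(c(start$baseline, log(start$span), log(start$c0)),
                       obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    cf <- c(baseline = op$par[1], span = exp(op$par[2]), c0 = exp(op$par[3]))
    sigma <- sqrt(op$value / max(nrow(standards) - 3, 1))
  }
  curve <- calibration_curve("igg_relocation",
                             baseline = cf[["baseline"]],
                             span = cf[["span"]], c0 = cf[["c0"]],
                             conc_range = c(0, max(uc)))
  curve$fit <- list(sigma = sigma,
                    monotone_warning = monotone_warning, nls = fit)
  if (monotone_warning)
    warning("standards are non-monotone beyond replicate noise")
  curve
}

#' Fit the linear lactate calibration from standards
#'
#' Straight-line least squares; the intercept is fixed to the mean readout
#' of the zero-concentration standards when they are present, so the blank
#' anchors the curve.
#'
#' @param standards Data frame with columns `concentration` (uM) and
#'   `readout`.
#' @return A `calibration_curve` of kind `lactate_linear` with a `fit`
#'   element.
#' @export
fit_lactate_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "readout") %in% names(standards)))
  if (any(standards$concentration < 0))
    stop("standard concentrations must be >= 0")
  has_zero <- any(standards$concentration == 0)
  if (has_zero) {
    b0 <- mean(standards$readout[standards$concentration == 0])
    pos <- standards[standards$concentration > 0, , drop = FALSE]
    slope <- sum(pos$concentration * (pos$readout - b0)) /
      sum(pos$concentration^2)
    resid <- standards$readout - (b0 + slope * standards$concentration)
  } else {
    fit <- stats::lm(readout ~ concentration, data = standards)
    b0 <- stats::coef(fit)[[1]]
    slope <- stats::coef(fit)[[2]]
    resid <- stats::residuals(fit)
  }
  if (slope <= 0) stop("fitted lactate slope is not positive")
  curve <- calibration_curve("lactate_linear", intercept = b0, slope = slope,
                             conc_range = c(0, max(standards$concentration)))
  curve$fit <- list(sigma = stats::sd(resid), monotone_warning = FALSE)
  curve
}
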