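# Extract-level photoactivity quantification: radiant exposure, relative
# singlet-oxygen yield from DMA (9,10-dimethylanthracene) photobleaching
# kinetics at 377 nm, Hill-equation EC50 fits with censoring at the top tested
# dose, selectivity indices, and (photo)cytotoxicity activity bands.

#' Radiant exposure of an irradiation step
#'
#' Dose (J cm^-2) delivered by a light source of constant irradiance over a
#' given time. The blue LED panel used for the assays delivers
#' 1.24 J cm^-2 min^-1 (468 nm), the green one 1.34 J cm^-2 min^-1 (519 nm).
#'
#' @param irradiance Irradiance in J cm^-2 min^-1, >= 0.
#' @param time Irradiation time in minutes, >= 0.
#' @return Dose in J cm^-2 (unrounded; round at presentation).
#' @export
radiant_exposure <- function(irradiance, time) {
  if (any(irradiance < 0) || any(time < 0))
    stop("irradiance and time must be non-negative", call. = FALSE)
  irradiance * time
}

#' Construct a DMA kinetics series
#'
#' Absorbance of the DMA reporter at 377 nm versus cumulative irradiation
#' time; singlet oxygen bleaches the anthracene chromophore, so photoactive
#' wells decay faster.
#'
#' @param extract_id Extract (or positive-control) identifier.
#' @param light \code{"blue"} or \code{"green"}.
#' @param condition One of \code{"blank"}, \code{"DMA"}, \code{"AA"},
#'   \code{"DMA+AA"}.
#' @param time Cumulative irradiation times in minutes, non-decreasing,
#'   starting at 0.
#' @param a377 Absorbances at 377 nm, same length as \code{time}.
#' @param replicate Replicate id(s), recycled; defaults to 1.
#' @return Object of class \code{dma_kinetics} (a data.frame).
#' @export
dma_kinetics <- function(extract_id, light, condition, time, a377,
                         replicate = 1L) {
  light <- match.arg(light, c("blue", "green"))
  condition <- match.arg(condition, c("blank", "DMA", "AA", "DMA+AA"))
  stopifnot(length(time) == length(a377), length(time) >= 2L)
  df <- data.frame(extract_id = extract_id, light = light,
                   condition = condition, replicate = replicate,
                   time = as.numeric(time), a377 = as.numeric(a377),
                   stringsAsFactors = FALSE)
  for (r in split(df, df$replicate)) {
    if (r$time[1L] != 0 || is.unsorted(r$time))
      stop("times must be non-decreasing and start at 0 within each replicate",
           call. = FALSE)
    if (nrow(r) < 2L) stop("each replicate needs >= 2 timepoints", call. = FALSE)
  }
  class(df) <- c("dma_kinetics", "data.frame")
  df
}

# Per-replicate bleaching rate: negative slope of the least-squares line
# A377 ~ time, optionally after subtracting the blank's drift (blank A377
# linearly interpolated at the sample's timepoints). Returns mean rate and
# standard error over replicates (lm slope SE when only one replicate).
dma_slopes <- function(kin, blank = NULL) {
  drift <- function(t) {
    if (is.null(blank)) return(0)
    # average the blank replicates before interpolating the drift
    b <- stats::aggregate(a377 ~ time, data = blank, FUN = mean)
    stats::approx(b$time, b$a377 - b$a377[1L], xout = t, rule = 2)$y
  }
  reps <- split(kin, kin$replicate)
  ks <- ses <- numeric(length(reps))
  for (i in seq_along(reps)) {
    r <- reps[[i]]
    x <- r$time
    y <- r$a377 - drift(r$time)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - slope * (x - mean(x))
    ks[i] <- -slope
    ses[i] <- sqrt(sum(res^2) / max(length(x) - 2L, 1L) / sxx)
  }
  if (length(ks) > 1L)
    list(k = mean(ks), se = stats::sd(ks) / sqrt(length(ks)))
  else
    list(k = ks, se = ses)
}

#' Relative singlet-oxygen yield from DMA bleaching kinetics
#'
#' The bleaching rate k is the negative slope of the least-squares fit of
#' A377 versus cumulative irradiation time (blank-drift-corrected when a blank
#' series is supplied). The yield is reported relative to the positive control
#' (berberine for blue light, rose bengal for green light):
#' yield = 100 * k_sample / k_control. Values above 100 indicate stronger
#' bleaching than the reference photosensitizer.
#'
#' @param sample,control \code{dma_kinetics} objects (condition \code{"DMA"})
#'   sharing the light source.
#' @param blank Optional \code{dma_kinetics} blank series for drift
#'   correction.
#' @return List with \code{yield} (percent), \code{se} (standard error,
#'   propagated from the slope errors), \code{k_sample}, \code{k_control}.
#' @export
dma_relative_yield <- function(sample, control, blank = NULL) {
  stopifnot(inherits(sample, "dma_kinetics"), inherits(control, "dma_kinetics"))
  if (sample$light[1L] != control$light[1L])
    stop("sample and control must share the light source", call. = FALSE)
  ks <- dma_slopes(sample, blank)
  kc <- dma_slopes(control, blank)
  if (kc$k <= 0) stop("inactive positive control (non-positive bleaching rate)",
                      call. = FALSE)
  yield <- 100 * ks$k / kc$k
  se <- 100 * sqrt((ks$se / kc$k)^2 + (ks$k * kc$se / kc$k^2)^2)
  list(yield = yield, se = se, k_sample = ks$k, k_control = kc$k)
}

#' Ascorbate protection of DMA bleaching (Type I diagnostic)
#'
#' Fraction of the DMA bleaching rate suppressed by co-incubation with
#' L-ascorbic acid, 1 - k_DMA+AA / k_DMA, clipped to [0, 1]. A reducing
#' quencher intercepts radical (Type I) chemistry, so high protection hints at
#' a radical contribution; reported as a diagnostic only.
#'
#' @param dma \code{dma_kinetics} for the DMA-only condition.
#' @param dma_aa \code{dma_kinetics} for the DMA + ascorbic acid condition.
#' @return Protection fraction in [0, 1], or \code{NA} when the DMA rate is
#'   non-positive.
#' @export
type1_protection <- function(dma, dma_aa) {
  k1 <- dma_slopes(dma)$k
  k2 <- dma_slopes(dma_aa)$k
  if (k1 <= 0) return(NA_real_)
  min(max(1 - k2 / k1, 0), 1)
}

#' Fit a four-parameter Hill (log-logistic) dose-response curve
#'
#' Fits viability = bottom + (top - bottom) / (1 + (c / EC50)^h) by nonlinear
#' least squares (Levenberg-Marquardt), with the EC50 estimated on the log
#' scale. Starting values: top 100, bottom 0, h 1, EC50 at the geometric
#' mid-dose; a few perturbed restarts are tried on non-convergence. If the
#' fitted curve has not dropped to 50% of control anywhere in (0, c_max], the
#' EC50 is censored at \code{c_max} (reported as "> c_max"). The 95% CI comes
#' from the Wald interval on log EC50.
#'
#' @param concentration Dose vector in ug/mL, > 0 (replicate points allowed).
#' @param viability Viability in percent of untreated control, same length.
#' @param c_max Top tested dose in ug/mL used for censoring; defaults to the
#'   maximum concentration present.
#' @return Object of class \code{hill_fit} with elements \code{ec50},
#'   \code{ci95}, \code{hill_slope}, \code{top}, \code{bottom},
#'   \code{censored}, \code{c_max}, \code{fit} (the underlying \code{nls}
#'   object), \code{data}.
#' @export
fit_hill <- function(concentration, viability, c_max = max(concentration)) {
  stopifnot(length(concentration) == length(viability))
  if (any(concentration <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(concentration)) < 4L)
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  df <- data.frame(conc = as.numeric(concentration), viab = as.numeric(viability))
  lc <- log(df$conc)
  starts <- list(
    c(top = 100, bottom = 0, h = 1, lec50 = mean(range(lc))),
    c(top = 100, bottom = 0, h = 1, lec50 = stats::median(lc)),
    c(top = 100, bottom = 0, h = 2, lec50 = min(lc) + diff(range(lc)) / 3),
    c(top = 100, bottom = 0, h = 0.5, lec50 = max(lc) - diff(range(lc)) / 3)
  )
  # viability is percent of untreated control, so the plateaus are bounded a
  # priori: without the bounds, ladders that miss the upper plateau can send
  # top and EC50 running away together
  lower <- c(top = 50, bottom = -50, h = 1e-3, lec50 = log(1e-8))
  upper <- c(top = 150, bottom = 50, h = 100, lec50 = log(1e8))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viab ~ bottom + (top - bottom) / (1 + exp(h * (log(conc) - lec50))),
        data = df, start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Hill fit did not converge after restarts; inspect the dose-response data",
         call. = FALSE)
  cf <- stats::coef(fit)
  ec50 <- exp(unname(cf["lec50"]))
  # Wald CI on log EC50
  se <- tryCatch(sqrt(diag(stats::vcov(fit))["lec50"]), error = function(e) NA_real_)
  dfree <- max(length(df$conc) - 4L, 1L)
  tq <- stats::qt(0.975, dfree)
  ci <- if (is.finite(se)) exp(unname(cf["lec50"]) + c(-1, 1) * tq * se)
        else c(NA_real_, NA_real_)
  pred <- function(c0) unname(cf["bottom"] +
    (cf["top"] - cf["bottom"]) / (1 + exp(cf["h"] * (log(c0) - cf["lec50"]))))
  censored <- pred(c_max) > 50 || ec50 > c_max
  out <- list(ec50 = if (censored) c_max else ec50,
              ci95 = if (censored) c(NA_real_, NA_real_) else ci,
              hill_slope = unname(cf["h"]),
              top = unname(cf["top"]), bottom = unname(cf["bottom"]),
              censored = censored, c_max = c_max, fit = fit, data = df)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Hill fit: EC50 > %.3g ug/mL (censored at top tested dose)\n",
                x$c_max))
  } else {
    cat(sprintf("Hill fit: EC50 = %.3g ug/mL (95%% CI %.3g-%.3g), slope %.2f\n",
                x$ec50, x$ci95[1L], x$ci95[2L], x$hill_slope))
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill_slope = object$hill_slope,
    top = object$top, bottom = object$bottom)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) newdata$conc else newdata
  cf <- stats::coef(object$fit)
  unname(cf["bottom"] + (cf["top"] - cf["bottom"]) /
           (1 + exp(cf["h"] * (log(conc) - cf["lec50"]))))
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  top %.1f, bottom %.1f, n = %d points\n",
              object$top, object$bottom, nrow(object$data)))
  invisible(object)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$viab - predict(object)
}

#' Selectivity index of light-dependent cytotoxicity
#'
#' S.I. = EC50(dark) / EC50(irradiated). When the dark EC50 is censored at the
#' top tested dose the index is a lower bound and is reported as ">=".
#'
#' @param dark,irr \code{hill_fit} objects (or lists with \code{ec50} and
#'   \code{censored}) for the dark and irradiated condition of the same
#'   extract and cell line.
#' @return Object of class \code{selectivity_index}: list with \code{value}
#'   and \code{lower_bound}.
#' @export
selectivity_index <- function(dark, irr) {
  if (!is.numeric(irr$ec50) || irr$ec50 <= 0)
    stop("irradiated EC50 must be positive", call. = FALSE)
  out <- list(value = dark$ec50 / irr$ec50,
              lower_bound = isTRUE(dark$censored))
  class(out) <- "selectivity_index"
  out
}

#' @export
print.selectivity_index <- function(x, ...) {
  cat(sprintf("S.I. %s %.1f\n", if (x$lower_bound) ">=" else "=", x$value))
  invisible(x)
}

#' Censored EC50 placeholder
#'
#' Represents an EC50 known only to exceed the top tested dose (e.g. a dark
#' control with no measurable toxicity), usable wherever a \code{hill_fit}
#' result is expected by \code{\link{selectivity_index}}.
#'
#' @param c_max Top tested dose in ug/mL.
#' @return List with \code{ec50 = c_max} and \code{censored = TRUE}.
#' @export
censored_ec50 <- function(c_max = 37.5) {
  list(ec50 = c_max, censored = TRUE, c_max = c_max)
}

#' Classify (photo)cytotoxic potency
#'
#' Activity bands on the EC50: > 20 ug/mL no/low, 5-20 ug/mL (inclusive)
#' high, < 5 ug/mL very high.
#'
#' @param ec50 EC50 in ug/mL, > 0 (vectorized).
#' @return Character vector in \code{c("no/low", "high", "very high")}.
#' @export
classify_photocytotoxicity <- function(ec50) {
  if (any(ec50 <= 0)) stop("ec50 must be positive", call. = FALSE)
  ifelse(ec50 < 5, "very high", ifelse(ec50 <= 20, "high", "no/low"))
}

#' Reference photosensitizers used as positive controls
#'
#' Rose bengal (green-light reference) and berberine (blue-light reference)
#' with their absorption maxima and singlet-oxygen quantum yields, tagged by
#' solvent (berberine's yield is strongly solvent-dependent).
#'
#' @return data.frame with columns \code{name}, \code{lambda_max},
#'   \code{phi_delta}, \code{solvent}.
#' @export
reference_photosensitizers <- function() {
  data.frame(name = c("rose bengal", "berberine", "berberine"),
             lambda_max = c(555, 420, 420),
             phi_delta = c(0.86, 0.04, 0.25),
             solvent = c("EtOH", "EtOH", "DCM"),
             stringsAsFactors = FALSE)
}
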