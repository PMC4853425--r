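## Beer-Lambert quantification, binding stoichiometry, and size-exclusion
## chromatography calibration.

#' Beer-Lambert concentration
#'
#' c = A / (epsilon l).
#'
#' @param absorbance absorbance, AU
#' @param epsilon molar extinction coefficient, M^-1 cm^-1
#' @param path optical path length, cm
#' @return molar concentration
#' @examples
#' beerLambert(0.3, 49000, 1)
#' @export
beerLambert <- function(absorbance, epsilon, path = 1) {
  if (epsilon <= 0 || path <= 0)
    stop("epsilon and path must be positive")
  absorbance / (epsilon * path)
}

#' Predicted absorbance from a concentration
#' @param concentration molar concentration
#' @param epsilon molar extinction, M^-1 cm^-1
#' @param path path length, cm
#' @return absorbance, AU
#' @export
absorbanceFromConc <- function(concentration, epsilon, path = 1) {
  if (epsilon <= 0 || path <= 0)
    stop("epsilon and path must be positive")
  concentration * epsilon * path
}

#' Oligomer-per-ligand stoichiometry
#'
#' Converts a monomer concentration into oligomer units and divides by the
#' ligand concentration: (monomer / n) / ligand. With 585 uM peptide as
#' tetramers against 6.22 uM fullerene this gives about 23.5 tetramers per
#' fullerene.
#'
#' @param monomer monomer concentration, M
#' @param n subunits per oligomer (>= 1)
#' @param ligand ligand concentration, M (> 0)
#' @return oligomers per ligand molecule
#' @export
stoichiometryRatio <- function(monomer, n, ligand) {
  stopifnot(monomer > 0, n >= 1)
  if (ligand <= 0) stop("ligand concentration must be positive")
  (monomer / n) / ligand
}

#' Calibrate a size-exclusion column
#'
#' Ordinary least squares of log10(molar mass) on elution volume over the
#' standards, the usual SEC calibration model.
#'
#' @param standards data.frame with columns \code{mass} (Da) and
#'   \code{volume} (mL), at least two distinct volumes
#' @return object of class \code{SecCalibration}: slope, intercept, r2, and
#'   the standards range
#' @export
secCalibrate <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("mass", "volume") %in% names(standards)),
            nrow(standards) >= 2)
  if (anyDuplicated(standards$volume))
    stop("duplicate elution volumes make the calibration singular")
  fit <- stats::lm(log10(mass) ~ volume, data = standards)
  r2 <- summary(fit)$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, range = range(standards$volume),
                 massRange = range(standards$mass)),
            class = "SecCalibration")
}

#' @export
print.SecCalibration <- function(x, ...) {
  cat(sprintf(
    "SEC calibration: log10(mass) = %.4f V %+.4f (r^2 = %.4f)\n",
    x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Apparent molar mass at an elution volume
#'
#' 10^(slope V + intercept); queries outside the calibrated volume range are
#' flagged with a warning (extrapolation beyond the standards).
#'
#' @param calibration a \code{SecCalibration}
#' @param volume elution volume, mL
#' @return apparent molar mass, Da
#' @export
secApparentMass <- function(calibration, volume) {
  stopifnot(inherits(calibration, "SecCalibration"))
  if (any(volume < calibration$range[1] | volume > calibration$range[2]))
    warning("elution volume outside the calibrated range; extrapolating")
  10^(calibration$slope * volume + calibration$intercept)
}

#' Find peaks in a SEC trace
#'
#' Moving-average smoothing (window \code{window} points) followed by local
#' maxima above \code{minFraction} of the global maximum of the smoothed
#' trace.
#'
#' @param volume elution volumes, mL
#' @param signal detector signal
#' @param window smoothing window, points (odd)
#' @param minFraction minimum peak height, fraction of global maximum
#' @return data.frame with columns volume, height, ordered by volume
#' @export
secFindPeaks <- function(volume, signal, window = 5, minFraction = 0.1) {
  stopifnot(length(volume) == length(signal), window >= 1)
  if (window %% 2 == 0) window <- window + 1
  sm <- stats::filter(signal, rep(1 / window, window), sides = 2)
  sm[is.na(sm)] <- signal[is.na(sm)]
  sm <- as.numeric(sm)
  thr <- minFraction * max(sm)
  n <- length(sm)
  peak <- which(sm >= thr &
                sm > c(-Inf, sm[-n]) &
                sm >= c(sm[-1], -Inf))
  data.frame(volume = volume[peak], height = sm[peak])
}
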