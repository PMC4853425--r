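## Sedimentation-equilibrium simulation and global fitting for a
## self-associating (n-mer <-> 2n-mer) system.

#' Reduced buoyant-mass exponent sigma
#'
#' sigma = M (1 - vbar rho) omega^2 / (2 R T), the coefficient such that a
#' single ideal species at equilibrium follows
#' c(r) = c_ref exp(sigma (r^2 - r_ref^2)) with r in cm. Computed in CGS
#' units (R = 8.3145e7 erg/mol/K).
#'
#' @param mass molar mass, Da (g/mol)
#' @param vbar partial specific volume, mL/g
#' @param rho solvent density, g/mL
#' @param rpm rotor speed, r.p.m.
#' @param temperature temperature, K
#' @return sigma in cm^-2
#' @examples
#' reducedMassSigma(13000, 0.73, 1.0, 25000)
#' @export
reducedMassSigma <- function(mass, vbar, rho, rpm, temperature = 298.15) {
  stopifnot(mass > 0, vbar > 0, rho > 0, rpm >= 0, temperature > 0)
  if (vbar * rho >= 1)
    stop("vbar * rho >= 1: species does not sediment")
  omega <- rpm * 2 * pi / 60
  mass * (1 - vbar * rho) * omega^2 / (2 * .RGAS_CGS * temperature)
}

## base-species concentration profile and (for scheme "self") the linked
## 2n-mer profile; the link c_2n(r) = c_n(r)^2 / Kd holds at every radius
## because sigma_2n = 2 sigma_n when vbar is shared
speciesProfiles <- function(model, rpm, radii, cref, temperature, rref) {
  sigma <- reducedMassSigma(model@baseMass, model@vbar, model@rho, rpm,
                            temperature)
  cb <- cref * exp(sigma * (radii^2 - rref^2))
  if (model@scheme == "self") {
    c2 <- (cref^2 / model@kd) * exp(2 * sigma * (radii^2 - rref^2))
    list(base = cb, dimerized = c2, sigma = sigma)
  } else list(base = cb, dimerized = rep(0, length(radii)), sigma = sigma)
}

#' Simulate one sedimentation-equilibrium scan
#'
#' Generates the equilibrium absorbance profile of the model at one rotor
#' speed. For the self-associating scheme the 2n-mer is thermodynamically
#' linked to the base species (c_2n = c_n^2 / Kd at the reference radius)
#' and follows its own exponential gradient with twice the reduced mass, so
#' the mass-action link holds at every radius by construction. Absorbance is
#' epsilon * path * (c_n + 2 c_2n) + baseline + Gaussian noise.
#'
#' @param model an \linkS4class{AssociationModel}
#' @param rpm rotor speed, r.p.m.
#' @param radii radii in cm (strictly increasing)
#' @param cref base-species molar concentration at the first radius
#' @param baseline baseline offset, AU
#' @param noise Gaussian noise s.d., AU
#' @param seed RNG seed (used only when noise > 0)
#' @param wavelength detection wavelength, nm
#' @param temperature temperature, K
#' @return an \linkS4class{AucScan}
#' @export
simulateScan <- function(model, rpm, radii = seq(6.9, 7.15, length.out = 60),
                         cref = 5e-5, baseline = 0.02, noise = 0,
                         seed = 1, wavelength = 340, temperature = 298.15) {
  stopifnot(is(model, "AssociationModel"))
  pr <- speciesProfiles(model, rpm, radii, cref, temperature, radii[1])
  a <- model@epsilon * model@path * (pr$base + 2 * pr$dimerized) + baseline
  if (noise > 0) {
    set.seed(seed)
    a <- a + stats::rnorm(length(a), 0, noise)
  }
  AucScan(rpm, radii, a, wavelength, temperature)
}

#' Globally fit sedimentation-equilibrium scans
#'
#' Nonlinear least squares over all scans simultaneously
#' (Levenberg-Marquardt via \pkg{minpack.lm}). The \code{"self"} template
#' fits a shared dissociation constant (as log10 Kd) plus per-scan reference
#' concentration and baseline; the \code{"single"} template fits a shared
#' molar mass plus the same per-scan nuisance parameters. Masses, vbar, rho
#' and the extinction coefficient are taken from \code{model} and not
#' fitted. Parameter standard errors come from the Jacobian at the optimum;
#' non-convergence is flagged on the returned object, never silent.
#'
#' @param scans list of \linkS4class{AucScan}s
#' @param model an \linkS4class{AssociationModel} carrying the fixed
#'   constants and the fitted template via its \code{scheme}
#' @param start optional named list of start values (kd, mass)
#' @return object of class \code{AucFitResult}: fitted \code{kd} or
#'   \code{mass} with standard error, per-scan \code{cref} and
#'   \code{baseline}, \code{residuals} per scan, global \code{rms},
#'   \code{converged}
#' @export
fitGlobalAuc <- function(scans, model, start = list()) {
  stopifnot(length(scans) >= 1, is(model, "AssociationModel"))
  for (s in scans) stopifnot(is(s, "AucScan"))
  nsc <- length(scans)
  self <- model@scheme == "self"
  epsl <- model@epsilon * model@path

  ## start values: baseline near the scan minimum, cref from absorbance at
  ## the reference radius assuming the base species dominates
  b0 <- vapply(scans, function(s) min(s@absorbance), numeric(1))
  c0 <- vapply(seq_len(nsc), function(i)
    max(scans[[i]]@absorbance[1] - b0[i], 1e-4) / epsl, numeric(1))
  par0 <- c(if (self) log10(if (!is.null(start$kd)) start$kd else 1e-4)
            else log10(if (!is.null(start$mass)) start$mass
                       else model@baseMass),
            log10(c0), b0)

  modelFor <- function(par) {
    shared <- par[1]
    crefs <- 10^par[1 + seq_len(nsc)]
    bases <- par[1 + nsc + seq_len(nsc)]
    m <- model
    if (self) m@kd <- 10^shared else m@baseMass <- 10^shared
    lapply(seq_len(nsc), function(i) {
      s <- scans[[i]]
      pr <- speciesProfiles(m, s@speed, s@radii, crefs[i], s@temperature,
                            s@radii[1])
      epsl * (pr$base + 2 * pr$dimerized) + bases[i]
    })
  }
  resFn <- function(par) {
    pred <- modelFor(par)
    unlist(lapply(seq_len(nsc), function(i) scans[[i]]@absorbance - pred[[i]]))
  }
  fit <- minpack.lm::nls.lm(par0, fn = resFn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  converged <- fit$info %in% 1:4
  par <- fit$par
  ## s.e. from the Gauss-Newton approximation cov = s2 (J'J)^-1, where
  ## nls.lm returns J'J as $hessian
  dof <- length(fit$fvec) - length(par)
  s2 <- sum(fit$fvec^2) / max(dof, 1)
  covm <- tryCatch(s2 * solve(fit$hessian),
                   error = function(e) matrix(NA, length(par), length(par)))
  seLog <- sqrt(diag(covm))[1]
  shared <- 10^par[1]
  ## delta method on the log10 scale
  seShared <- abs(shared * log(10) * seLog)
  pred <- modelFor(par)
  residuals <- lapply(seq_len(nsc), function(i)
    scans[[i]]@absorbance - pred[[i]])
  rms <- sqrt(mean(unlist(residuals)^2))
  out <- list(scheme = model@scheme,
              cref = 10^par[1 + seq_len(nsc)],
              baseline = par[1 + nsc + seq_len(nsc)],
              residuals = residuals, rms = rms, converged = converged,
              info = fit$info, message = fit$message)
  if (self) { out$kd <- shared; out$kdSE <- seShared }
  else { out$mass <- shared; out$massSE <- seShared }
  structure(out, class = "AucFitResult")
}

#' @export
print.AucFitResult <- function(x, ...) {
  cat(sprintf("Global sedimentation-equilibrium fit (%s model)\n", x$scheme))
  if (!is.null(x$kd))
    cat(sprintf("  Kd = %.4g M (s.e. %.2g)\n", x$kd, x$kdSE))
  if (!is.null(x$mass))
    cat(sprintf("  mass = %.5g Da (s.e. %.2g)\n", x$mass, x$massSE))
  cat(sprintf("  global rms residual = %.3g AU; converged: %s\n",
              x$rms, x$converged))
  invisible(x)
}

#' Write or read a sedimentation scan as CSV
#'
#' Plain CSV with columns \code{radius_cm}, \code{absorbance_AU}, preceded
#' by commented header lines (\code{# speed_rpm:}, \code{# wavelength_nm:},
#' \code{# temperature_K:}) carrying the scan metadata.
#'
#' @param scan an \linkS4class{AucScan}
#' @param path file path
#' @return the reader returns an \linkS4class{AucScan}; the writer returns
#'   the path invisibly
#' @export
writeAucScan <- function(scan, path) {
  stopifnot(is(scan, "AucScan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# speed_rpm: %.10g", scan@speed),
               sprintf("# wavelength_nm: %.10g", scan@wavelength),
               sprintf("# temperature_K: %.10g", scan@temperature),
               "radius_cm,absorbance_AU"), con)
  writeLines(sprintf("%.12g,%.12g", scan@radii, scan@absorbance), con)
  invisible(path)
}

#' @rdname writeAucScan
#' @export
readAucScan <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  getH <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(hit)) stop("missing scan header field: ", key)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", hit[1]))
  }
  body <- utils::read.csv(text = ln[!grepl("^#", ln)])
  AucScan(getH("speed_rpm"), body$radius_cm, body$absorbance_AU,
          getH("wavelength_nm"), getH("temperature_K"))
}

#' Compare single-species and self-association fits
#'
#' Fits both templates and accepts the self-association model only when its
#' global rms residual improves on the single-species fit by more than
#' \code{improvement} (fractional) and the Kd standard error is finite.
#'
#' @param scans list of \linkS4class{AucScan}s
#' @param model an \linkS4class{AssociationModel} (constants source)
#' @param improvement required fractional rms improvement
#' @return list with both fits and the accepted \code{model} name
#' @export
selectAucModel <- function(scans, model, improvement = 0.10) {
  mSingle <- model; mSingle@scheme <- "none"
  mSelf <- model; mSelf@scheme <- "self"
  fitS <- fitGlobalAuc(scans, mSingle)
  fitA <- fitGlobalAuc(scans, mSelf)
  accept <- fitA$converged && is.finite(fitA$kdSE) &&
    fitA$rms < (1 - improvement) * fitS$rms
  list(single = fitS, self = fitA,
       model = if (accept) "self" else "single")
}

#' Species distribution of a self-associating model
#'
#' Solves the mass-action equilibrium c_total = c_n + 2 c_2n with
#' c_2n = c_n^2 / Kd at each total concentration (expressed in
#' base-species molar equivalents) and reports molar-equivalent fractions.
#'
#' @param model an \linkS4class{AssociationModel} with scheme "self"
#' @param ctotal vector of total concentrations, base-species equivalents, M
#' @return data.frame: ctotal, cBase, cDimer, fracBase, fracDimer
#' @export
speciesDistribution <- function(model, ctotal) {
  stopifnot(is(model, "AssociationModel"))
  if (model@scheme != "self")
    stop("model has no association scheme")
  kd <- model@kd
  cb <- (-1 + sqrt(1 + 8 * ctotal / kd)) * kd / 4
  c2 <- cb^2 / kd
  data.frame(ctotal = ctotal, cBase = cb, cDimer = c2,
             fracBase = cb / ctotal, fracDimer = 2 * c2 / ctotal)
}
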