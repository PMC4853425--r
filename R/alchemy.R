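## Free-energy estimation and the dummy-atom double-decoupling cycle.
##
## Convention: the decoupling progress lambda runs from 0 (ligand fully
## coupled) to 1 (fully decoupled). Within a transformation step the
## decoupling set fades out with strength 1 - lambda while the coupling set
## (the dummy particle) fades in with strength lambda.

#' Uniform lambda schedule for an alchemical step
#'
#' \code{nWindows} windows with boundaries uniform on [0, 1]; each window is
#' sampled at one boundary and perturbed to the other. Window lengths are in
#' Monte Carlo sweeps; the defaults mirror a 10:190 equilibration:collection
#' split.
#'
#' @param nWindows number of windows (>= 2)
#' @param equilSweeps equilibration sweeps per window
#' @param collectSweeps data-collection sweeps per window
#' @param sampleEvery sweeps between collected samples
#' @return object of class \code{LambdaSchedule}
#' @export
lambdaSchedule <- function(nWindows = 20, equilSweeps = 1000,
                           collectSweeps = 19000, sampleEvery = 10) {
  if (nWindows < 2) stop("need at least 2 windows")
  structure(list(nWindows = as.integer(nWindows),
                 lambdas = seq(0, 1, length.out = nWindows + 1),
                 equilSweeps = as.integer(equilSweeps),
                 collectSweeps = as.integer(collectSweeps),
                 sampleEvery = as.integer(sampleEvery)),
            class = "LambdaSchedule")
}

#' Zwanzig (exponential-averaging) free-energy estimate
#'
#' Delta G = -RT log < exp(-Delta U / RT) >, computed with an
#' overflow-safe log-sum-exp so that extreme perturbation energies cannot
#' overflow.
#'
#' @param deltaU perturbation energies, kcal/mol
#' @param temperature temperature, K
#' @return free-energy difference, kcal/mol
#' @examples
#' zwanzig(rep(1.5, 100), 298.15)  # 1.5
#' @export
zwanzig <- function(deltaU, temperature = 298.15) {
  deltaU <- deltaU[!is.na(deltaU)]
  if (length(deltaU) == 0) stop("no perturbation samples supplied")
  RT <- thermalRT(temperature)
  -RT * (logSumExp(-deltaU / RT) - log(length(deltaU)))
}

#' Restraint force-constant schedule
#'
#' Force constant of the ligand-dummy centring restraint as a function of
#' decoupling progress: zero when fully coupled, \code{kMax} when fully
#' decoupled, monotone in between. The default shape is linear,
#' k(lambda) = kMax * lambda; any monotone shape with the same endpoints
#' yields the same end-state physics and may be supplied via \code{form}.
#'
#' @param lam decoupling progress in [0, 1]
#' @param kMax force constant in the decoupled state, kcal/mol/A^2
#' @param form monotone shape function on [0, 1] with form(0)=0, form(1)=1
#' @return force constant, kcal/mol/A^2
#' @export
restraintSchedule <- function(lam, kMax = 10, form = identity) {
  if (any(lam < 0 | lam > 1)) stop("lam must lie in [0, 1]")
  kMax * form(lam)
}

#' Standard-state correction for a harmonically restrained ligand
#'
#' A ligand decoupled under a harmonic centring restraint of force constant
#' k samples the configurational volume V_k = (2 pi RT / k)^(3/2); releasing
#' it to the volume per molecule at the standard concentration (1661 A^3 at
#' 1 M) contributes RT log(V_standard / V_k) to the binding free energy.
#' This term enters the cycle with a positive sign for V_standard > V_k
#' (binding is penalized by the entropy of release); its k-dependence
#' cancels the confinement work inside the restrained decoupling leg, which
#' is the self-consistency the toy host-guest cycle verifies.
#'
#' @param k restraint force constant in the decoupled state, kcal/mol/A^2
#' @param temperature temperature, K
#' @param cStandard standard-state concentration, M
#' @return correction, kcal/mol
#' @export
standardStateCorrection <- function(k, temperature = 298.15, cStandard = 1) {
  if (k <= 0) stop("k must be positive (the restraint volume diverges)")
  if (cStandard <= 0) stop("cStandard must be positive")
  RT <- thermalRT(temperature)
  vk <- restraintVolume(k, temperature)
  vstd <- .V_STANDARD_A3 / cStandard
  RT * log(vstd / vk)
}

#' Configurational volume of a 3-D harmonic restraint
#'
#' V_k = integral exp(-k r^2 / 2RT) d^3 r = (2 pi RT / k)^(3/2).
#'
#' @param k force constant, kcal/mol/A^2
#' @param temperature temperature, K
#' @return volume, cubic Angstrom
#' @export
restraintVolume <- function(k, temperature = 298.15) {
  if (k <= 0) stop("k must be positive")
  (2 * pi * thermalRT(temperature) / k)^(3 / 2)
}

#' Importance-sampling reweighting of a biased expectation
#'
#' Removes a known bias potential from an expectation sampled under it:
#' <A>_unbiased = <A exp(+U_bias/RT)>_biased / <exp(+U_bias/RT)>_biased,
#' evaluated with a shifted exponential for stability.
#'
#' @param observable sampled observable values
#' @param biasEnergy bias energies of the same samples, kcal/mol
#' @param temperature temperature, K
#' @return unbiased expectation
#' @export
importanceReweight <- function(observable, biasEnergy,
                               temperature = 298.15) {
  if (length(observable) != length(biasEnergy))
    stop("observable and biasEnergy must have equal length")
  lw <- biasEnergy / thermalRT(temperature)
  w <- exp(lw - max(lw))
  sum(observable * w) / sum(w)
}

## replace particle positions, keeping everything else
withPositions <- function(system, pos) {
  system@positions <- pos
  system
}

#' Run one alchemical transformation step
#'
#' Samples every lambda window of \code{schedule} with Metropolis Monte
#' Carlo, estimating the per-window free-energy change to the neighbouring
#' window by \code{\link{zwanzig}}. In the forward direction windows run
#' from coupled (lambda 0) to decoupled (lambda 1); in reverse the windows
#' are traversed backwards and the cumulative value is negated on reporting
#' so all results are expressed in the decoupling direction. Positions are
#' carried from window to window. Constant restraints drop out of the
#' perturbation differences automatically; lambda-coupled restraints enter
#' them, as required for a restraint whose work must be part of the
#' transformation free energy.
#'
#' @param systemFactory function(transformation, step) returning the
#'   end-state-correct \linkS4class{ParticleSystem} for that leg
#' @param schedule a \code{\link{lambdaSchedule}}
#' @param transformation 1 (with receptor) or 2 (solvent only)
#' @param step 1 (ligand out / dummy in) or 2 (dummy out)
#' @param direction "forward" or "reverse"
#' @param seed RNG seed for this replicate
#' @param shiftCoeff soft-core shift for this step, A^2 (8 for step 1 and
#'   20 for step 2 by default)
#' @param stepSize MC displacement, Angstrom
#' @param scheduleFn restraint schedule shape (default linear)
#' @return object of class \code{TransformationResult}: list with
#'   \code{perWindow} free energies, \code{deltaG} (raw, in the sampled
#'   direction), \code{deltaGDecoupling} (negated for reverse runs),
#'   \code{acceptance}, and identifiers
#' @export
runTransformation <- function(systemFactory, schedule, transformation, step,
                              direction = c("forward", "reverse"), seed = 1,
                              shiftCoeff = if (step == 1) 8 else 20,
                              stepSize = 0.35, scheduleFn = identity) {
  direction <- match.arg(direction)
  if (!inherits(schedule, "LambdaSchedule"))
    stop("schedule must come from lambdaSchedule()")
  system <- systemFactory(transformation, step)
  if (!is(system, "ParticleSystem"))
    stop("systemFactory must return a ParticleSystem")
  lams <- schedule$lambdas
  idx <- if (direction == "forward") seq_len(schedule$nWindows)
         else rev(seq_len(schedule$nWindows) + 1L)
  perWindow <- numeric(length(idx))
  acc <- numeric(length(idx))
  temperature <- system@temperature
  pos <- system@positions
  for (w in seq_along(idx)) {
    i <- idx[w]
    lam <- lams[i]
    target <- if (direction == "forward") lams[i + 1L] else lams[i - 1L]
    sys <- withPositions(system, pos)
    eq <- mcSample(sys, lam = lam, nsweeps = schedule$equilSweeps,
                   stepSize = stepSize, seed = seed * 1000L + 2L * i,
                   sampleEvery = max(1L, schedule$equilSweeps),
                   shiftCoeff = shiftCoeff, scheduleFn = scheduleFn)
    sys <- withPositions(sys, eq$positions)
    run <- mcSample(sys, lam = lam, nsweeps = schedule$collectSweeps,
                    stepSize = stepSize, seed = seed * 1000L + 2L * i + 1L,
                    lamNext = target, sampleEvery = schedule$sampleEvery,
                    shiftCoeff = shiftCoeff, scheduleFn = scheduleFn)
    pos <- run$positions
    perWindow[w] <- zwanzig(run$samples[, "dU_next"], temperature)
    acc[w] <- run$acceptance
  }
  deltaG <- sum(perWindow)
  structure(list(transformation = transformation, step = step,
                 direction = direction, seed = seed,
                 perWindow = perWindow, deltaG = deltaG,
                 deltaGDecoupling = if (direction == "forward") deltaG
                                    else -deltaG,
                 acceptance = mean(acc), temperature = temperature),
            class = "TransformationResult")
}

#' @export
print.TransformationResult <- function(x, ...) {
  cat(sprintf(
    "Transformation %d step %d (%s, seed %d): dG(decoupling) = %.3f kcal/mol\n",
    x$transformation, x$step, x$direction, x$seed, x$deltaGDecoupling))
  invisible(x)
}

## pool replicate results of one (transformation, step): mean and s.e. of
## the decoupling-direction free energies over all runs
stepSummary <- function(results, transformation, step) {
  vals <- vapply(Filter(function(r)
    r$transformation == transformation && r$step == step, results),
    `[[`, numeric(1), "deltaGDecoupling")
  if (!length(vals))
    stop(sprintf("incomplete cycle: no results for transformation %d step %d",
                 transformation, step))
  list(mean = mean(vals),
       se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
       n = length(vals))
}

#' Combine the double-decoupling cycle
#'
#' Computes the standard-state binding free energy from the two decoupling
#' transformations: Delta-G_bind = Delta-G(transformation 2) -
#' Delta-G(transformation 1) + standard-state correction, where each
#' transformation is the sum of its two steps (ligand out / dummy in, then
#' dummy out) pooled over replicates and directions. The gas-phase dummy
#' reference is present in both transformations, so its contribution
#' cancels in the difference. The standard error combines the four
#' step-level standard errors in quadrature, and the dissociation constant
#' is Kd = cStandard * exp(Delta-G_bind / RT).
#'
#' @param trans1 list of \code{TransformationResult}s for transformation 1
#' @param trans2 list of \code{TransformationResult}s for transformation 2
#' @param correction standard-state correction, kcal/mol (see
#'   \code{\link{standardStateCorrection}})
#' @param temperature temperature, K
#' @param cStandard standard concentration, M
#' @return object of class \code{CycleResult}
#' @export
combineCycle <- function(trans1, trans2, correction,
                         temperature = 298.15, cStandard = 1) {
  steps <- list(t1s1 = stepSummary(trans1, 1, 1),
                t1s2 = stepSummary(trans1, 1, 2),
                t2s1 = stepSummary(trans2, 2, 1),
                t2s2 = stepSummary(trans2, 2, 2))
  dG1 <- steps$t1s1$mean + steps$t1s2$mean
  dG2 <- steps$t2s1$mean + steps$t2s2$mean
  dGbind <- dG2 - dG1 + correction
  se <- sqrt(sum(vapply(steps, function(s) s$se^2, numeric(1))))
  kd <- deltaGtoKd(dGbind, temperature, cStandard)
  structure(list(steps = steps, deltaG1 = dG1, deltaG2 = dG2,
                 correction = correction, deltaGBind = dGbind, se = se,
                 kd = kd, temperature = temperature,
                 cStandard = cStandard),
            class = "CycleResult")
}

#' @export
print.CycleResult <- function(x, ...) {
  cat(sprintf("Double-decoupling cycle: dG_bind = %.2f +/- %.2f kcal/mol",
              x$deltaGBind, x$se))
  cat(sprintf(" (Kd = %.3g M at %.2f K)\n", x$kd, x$temperature))
  invisible(x)
}

#' Convert a binding free energy to a dissociation constant
#'
#' Kd = cStandard * exp(Delta-G / RT); the inverse is
#' \code{kdToDeltaG}.
#'
#' @param deltaG standard-state binding free energy, kcal/mol
#' @param temperature temperature, K
#' @param cStandard standard concentration, M
#' @return dissociation constant, M
#' @examples
#' deltaGtoKd(-9.8) * 1e9   # about 65 nM
#' @export
deltaGtoKd <- function(deltaG, temperature = 298.15, cStandard = 1) {
  cStandard * exp(deltaG / thermalRT(temperature))
}

#' @rdname deltaGtoKd
#' @param kd dissociation constant, M
#' @export
kdToDeltaG <- function(kd, temperature = 298.15, cStandard = 1) {
  thermalRT(temperature) * log(kd / cStandard)
}

#' Forward/reverse convergence (hysteresis) report
#'
#' For each (transformation, step) with at least one forward and one reverse
#' replicate, reports the mean forward and mean negated-reverse decoupling
#' free energies, their standard errors, the absolute discrepancy and a
#' flag for steps whose discrepancy exceeds twice the combined standard
#' error.
#'
#' @param results list of \code{TransformationResult}s
#' @return data.frame, one row per step
#' @export
hysteresisReport <- function(results) {
  keyOf <- function(r) sprintf("%d.%d", r$transformation, r$step)
  keys <- unique(vapply(results, keyOf, ""))
  rows <- lapply(sort(keys), function(k) {
    grp <- Filter(function(r) keyOf(r) == k, results)
    fwd <- vapply(Filter(function(r) r$direction == "forward", grp),
                  `[[`, numeric(1), "deltaGDecoupling")
    rev <- vapply(Filter(function(r) r$direction == "reverse", grp),
                  `[[`, numeric(1), "deltaGDecoupling")
    if (!length(fwd) || !length(rev))
      stop("need at least one forward and one reverse replicate per step")
    seF <- if (length(fwd) > 1) stats::sd(fwd) / sqrt(length(fwd)) else 0
    seR <- if (length(rev) > 1) stats::sd(rev) / sqrt(length(rev)) else 0
    disc <- abs(mean(fwd) - mean(rev))
    seC <- sqrt(seF^2 + seR^2)
    data.frame(transformation = as.integer(substr(k, 1, 1)),
               step = as.integer(substr(k, 3, 3)),
               forward = mean(fwd), reverse = mean(rev),
               seForward = seF, seReverse = seR,
               discrepancy = disc, flagged = disc > 2 * seC)
  })
  do.call(rbind, rows)
}

#' Total simulated time implied by a window/replicate protocol
#'
#' Book-keeping helper: with \code{nWindows} windows of
#' \code{equilPs + collectPs} picoseconds each, \code{preEquilPs} of
#' pre-equilibration per simulation, \code{steps} transformation steps each
#' run \code{replicates} times in \code{directions} directions, the total
#' campaign is steps x replicates x directions x (nWindows x window + preEquil)
#' picoseconds.
#'
#' @param nWindows windows per step
#' @param equilPs,collectPs per-window equilibration / collection, ps
#' @param preEquilPs pre-equilibration per simulation, ps
#' @param steps number of transformation steps (2 transformations x 2 steps)
#' @param replicates replicates per step and direction
#' @param directions sampled directions
#' @return total simulation time in nanoseconds
#' @examples
#' fepCampaignTime()  # 336
#' @export
fepCampaignTime <- function(nWindows = 20, equilPs = 10, collectPs = 190,
                            preEquilPs = 200, steps = 4, replicates = 10,
                            directions = 2) {
  ps <- steps * replicates * directions *
    (nWindows * (equilPs + collectPs) + preEquilPs)
  ps / 1000
}
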