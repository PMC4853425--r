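## R surface of the toy particle engine.

#' @useDynLib fullerkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a toy particle system
#'
#' See \linkS4class{ParticleSystem} for the energy model and slot
#' conventions.
#'
#' @param positions N x 3 matrix of coordinates, Angstrom
#' @param epsilon LJ well depth(s), kcal/mol (recycled to N)
#' @param rmin LJ like-pair minimum distance(s), Angstrom (recycled to N)
#' @param bonds data.frame (i, j, k, r0) of harmonic bonds, or NULL
#' @param restraints list of restraints (see \code{\link{harmonicRestraint}})
#' @param box numeric(3) periodic box edges, or NULL for an open system
#' @param decoupleSet indices of particles decoupled as lambda -> 1
#' @param coupleSet indices of particles coupled as lambda -> 1
#' @param fixed indices of immobile particles
#' @param temperature temperature, K
#' @return a \linkS4class{ParticleSystem}
#' @export
particleSystem <- function(positions, epsilon = 0.2, rmin = 3.5,
                           bonds = NULL, restraints = list(), box = NULL,
                           decoupleSet = integer(0), coupleSet = integer(0),
                           fixed = integer(0), temperature = 298.15) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  n <- nrow(positions)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0), k = numeric(0),
                        r0 = numeric(0))
  fx <- logical(n); fx[fixed] <- TRUE
  new("ParticleSystem", positions = positions,
      epsilon = rep_len(epsilon, n), rmin = rep_len(rmin, n),
      bonds = bonds, restraints = restraints,
      box = if (is.null(box)) numeric(0) else as.numeric(box),
      decoupleSet = as.integer(decoupleSet),
      coupleSet = as.integer(coupleSet), fixed = fx,
      temperature = temperature)
}

#' Harmonic distance restraint specification
#'
#' Energy (k_eff/2)(r - r0)^2 where r is the atom-atom or centroid-centroid
#' distance. \code{mode} selects how the force constant follows the
#' decoupling progress lambda: \code{"constant"} (k throughout; its energy
#' cancels out of perturbation differences automatically), \code{"lambda"}
#' (k_eff = k * s(lambda), the growing restraint applied to a ligand as it
#' is decoupled) or \code{"one_minus_lambda"} (k_eff = k * s(1 - lambda)).
#' The schedule shape s defaults to linear, see \code{\link{restraintSchedule}}.
#'
#' @param i,j member particle indices (vectors for kind "centroid")
#' @param k force constant, kcal/mol/A^2
#' @param r0 equilibrium distance, Angstrom
#' @param kind "atom" or "centroid"
#' @param mode "constant", "lambda" or "one_minus_lambda"
#' @return restraint specification list
#' @export
harmonicRestraint <- function(i, j, k, r0 = 0,
                              kind = c("atom", "centroid"),
                              mode = c("constant", "lambda",
                                       "one_minus_lambda")) {
  kind <- match.arg(kind); mode <- match.arg(mode)
  list(kind = kind, i = as.integer(i), j = as.integer(j), k = k, r0 = r0,
       mode = mode)
}

## internal: translate a ParticleSystem into cpp_* arguments
systemArgs <- function(system) {
  role <- integer(nrow(system@positions))
  role[system@decoupleSet] <- 1L
  role[system@coupleSet] <- 2L
  rl <- lapply(system@restraints, function(r)
    list(kind = if (r$kind == "centroid") 1L else 0L, i = r$i, j = r$j,
         r0 = r$r0))
  list(role = role, restraints = rl)
}

## effective restraint force constants at decoupling progress lam
restraintK <- function(system, lam, scheduleFn = identity) {
  vapply(system@restraints, function(r) {
    switch(r$mode,
           constant = r$k,
           lambda = r$k * scheduleFn(lam),
           one_minus_lambda = r$k * scheduleFn(1 - lam))
  }, numeric(1))
}

#' Potential energy of a toy particle system
#'
#' Evaluates the engine's energy model (see \linkS4class{ParticleSystem})
#' at decoupling progress \code{lam}: particles in the decoupling set
#' interact with coupling strength 1 - lam and particles in the coupling set
#' with strength lam through the soft-core Lennard-Jones kernel in which the
#' squared distance is shifted by \code{shiftCoeff * (1 - strength)};
#' uninvolved pairs use plain switched Lennard-Jones (10 A cutoff, switching
#' from 6 A).
#'
#' @param system a \linkS4class{ParticleSystem}
#' @param lam decoupling progress in [0, 1] (0 = fully coupled)
#' @param shiftCoeff soft-core squared-distance shift coefficient, A^2
#' @param scheduleFn restraint schedule shape on [0, 1] (default linear)
#' @return named numeric: vdw, bonded, restraint, total (kcal/mol)
#' @export
systemEnergy <- function(system, lam = 0, shiftCoeff = 8,
                         scheduleFn = identity) {
  stopifnot(is(system, "ParticleSystem"))
  if (!is.numeric(lam) || lam < 0 || lam > 1)
    stop("lam must lie in [0, 1]")
  if (shiftCoeff < 0) stop("shiftCoeff must be >= 0")
  sa <- systemArgs(system)
  b <- system@bonds
  cpp_energy(system@positions, system@epsilon, system@rmin, sa$role,
             as.integer(b$i), as.integer(b$j), as.numeric(b$k),
             as.numeric(b$r0), sa$restraints,
             restraintK(system, lam, scheduleFn), system@box, lam,
             shiftCoeff)
}

#' Soft-core pair energy (reference closed form)
#'
#' The documented alchemical pair kernel, evaluated directly in R for one
#' pair: \code{lc * eps * ((rmin^2/(r^2 + shift (1 - lc)))^6 -
#' 2 (rmin^2/(r^2 + shift (1 - lc)))^3) * S(r)} with the CHARMM switching
#' function S between 6 and 10 Angstrom. Exposed for testing and
#' documentation; \code{\link{systemEnergy}} computes the same form in
#' compiled code.
#'
#' @param r pair distance, Angstrom
#' @param eps mixed well depth, kcal/mol
#' @param rmin mixed minimum-energy distance, Angstrom
#' @param coupling coupling strength lc in [0, 1]
#' @param shiftCoeff soft-core shift, A^2
#' @return pair energy, kcal/mol
#' @export
softcorePairEnergy <- function(r, eps, rmin, coupling, shiftCoeff = 8) {
  stopifnot(coupling >= 0, coupling <= 1)
  if (r >= 10) return(0)
  sw <- if (r <= 6) 1 else {
    (100 - r^2)^2 * (100 + 2 * r^2 - 3 * 36) / (100 - 36)^3
  }
  r2eff <- r^2 + shiftCoeff * (1 - coupling)
  s3 <- (rmin^2 / r2eff)^3
  coupling * eps * (s3^2 - 2 * s3) * sw
}

#' Metropolis Monte Carlo sampling of a toy system
#'
#' Runs single-particle-displacement Metropolis Monte Carlo in the canonical
#' (NVT) ensemble at the system temperature and decoupling progress
#' \code{lam}. Every \code{sampleEvery} sweeps (one sweep = one attempted
#' move per movable particle) the energy breakdown is recorded together with
#' the perturbation energies Delta-U to the neighbouring lambda values
#' \code{lamPrev} / \code{lamNext} (NA where not requested). Deterministic
#' given \code{seed}.
#'
#' @param system a \linkS4class{ParticleSystem}
#' @param lam decoupling progress in [0, 1]
#' @param nsweeps number of MC sweeps (> 0)
#' @param stepSize maximum per-axis displacement, Angstrom
#' @param seed RNG seed
#' @param lamPrev,lamNext neighbouring lambda values for Delta-U records
#' @param sampleEvery sweeps between samples
#' @param shiftCoeff soft-core shift coefficient, A^2
#' @param scheduleFn restraint schedule shape (default linear)
#' @param trackPair optional integer pair (i, j): record their distance per
#'   sample in the \code{dist} column
#' @param trackPair2 optional second tracked pair (\code{dist2} column)
#' @return list with \code{samples} (matrix: sweep, total, vdw, bonded,
#'   restraint, dU_prev, dU_next, dist, dist2), \code{acceptance} rate, and
#'   final \code{positions}
#' @export
mcSample <- function(system, lam = 0, nsweeps = 1000, stepSize = 0.5,
                     seed = 1, lamPrev = NA, lamNext = NA,
                     sampleEvery = 1, shiftCoeff = 8,
                     scheduleFn = identity, trackPair = NULL,
                     trackPair2 = NULL) {
  stopifnot(is(system, "ParticleSystem"))
  if (nsweeps <= 0) stop("nsweeps must be positive")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  if (nrow(system@positions) == 0) stop("zero-particle system")
  sa <- systemArgs(system)
  b <- system@bonds
  beta <- 1 / thermalRT(system@temperature)
  kcur <- restraintK(system, lam, scheduleFn)
  kprev <- if (is.finite(lamPrev)) restraintK(system, lamPrev, scheduleFn)
           else kcur
  knext <- if (is.finite(lamNext)) restraintK(system, lamNext, scheduleFn)
           else kcur
  set.seed(seed)
  cpp_mc(system@positions, system@epsilon, system@rmin, sa$role,
         system@fixed, as.integer(b$i), as.integer(b$j), as.numeric(b$k),
         as.numeric(b$r0), sa$restraints, kcur, kprev, knext, system@box,
         lam, as.numeric(lamPrev), as.numeric(lamNext),
         as.integer(nsweeps), as.integer(sampleEvery), stepSize, beta,
         shiftCoeff,
         if (is.null(trackPair)) 0L else as.integer(trackPair[1]),
         if (is.null(trackPair)) 0L else as.integer(trackPair[2]),
         if (is.null(trackPair2)) 0L else as.integer(trackPair2[1]),
         if (is.null(trackPair2)) 0L else as.integer(trackPair2[2]))
}

#' Write or read a particle-system YAML config
#'
#' @param system a \linkS4class{ParticleSystem}
#' @param path file path
#' @return \code{readParticleSystem} returns a
#'   \linkS4class{ParticleSystem}; the writer returns the path invisibly
#' @export
writeParticleSystem <- function(system, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config I/O")
  obj <- list(positions = lapply(seq_len(nrow(system@positions)),
                                 function(i) as.numeric(system@positions[i, ])),
              epsilon = as.list(system@epsilon),
              rmin = as.list(system@rmin),
              bonds = if (nrow(system@bonds)) system@bonds else NULL,
              restraints = system@restraints,
              box = if (length(system@box)) as.list(system@box) else NULL,
              decoupleSet = as.list(system@decoupleSet),
              coupleSet = as.list(system@coupleSet),
              fixed = as.list(which(system@fixed)),
              temperature = system@temperature)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname writeParticleSystem
#' @export
readParticleSystem <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config I/O")
  obj <- yaml::read_yaml(path)
  pos <- do.call(rbind, lapply(obj$positions, unlist))
  bonds <- if (!is.null(obj$bonds)) as.data.frame(obj$bonds) else NULL
  restraints <- lapply(obj$restraints, function(r)
    harmonicRestraint(unlist(r$i), unlist(r$j), r$k, r$r0, r$kind, r$mode))
  particleSystem(pos, unlist(obj$epsilon), unlist(obj$rmin), bonds,
                 restraints,
                 box = if (!is.null(obj$box)) unlist(obj$box) else NULL,
                 decoupleSet = unlist(obj$decoupleSet),
                 coupleSet = unlist(obj$coupleSet),
                 fixed = unlist(obj$fixed),
                 temperature = obj$temperature)
}
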