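## Seeded synthetic-data generators. Every generator is a pure function of
## its arguments (bit-identical reruns) and derives a named RNG substream
## from the master seed, so adding generators never perturbs existing
## fixtures. Each returns machine-readable ground truth alongside the data.

## deterministic substream seed: master seed plus a name hash, kept < 2^31
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

## Ideal alpha-helix backbone cylindrical parameters (radius Angstrom,
## phase offset degrees relative to CA, axial offset Angstrom), derived
## once from standard internal coordinates (N-CA 1.458, CA-C 1.525,
## C-N 1.329, C-O 1.231 A; phi -57, psi -47, omega 180 degrees).
.HELIX_PARAMS <- data.frame(
  atom = c("N", "CA", "C", "O"),
  radius = c(1.551, 2.276, 1.666, 1.921),
  dphase = c(-26.77, 0, 26.74, 20.34),
  dz = c(-0.919, 0, 1.069, 2.257))

#' Generate an idealized four-helix bundle
#'
#' Places four ideal alpha-helical backbones (N, CA, C, O from standard
#' internal geometry) antiparallel on a square: chains A and C run along +z,
#' B and D along -z, with helix axes at \code{bundleRadius} from the bundle
#' centre. Residues are numbered from 1; the sequence defaults to
#' poly-alanine.
#'
#' @param nres residues per chain
#' @param rise helical rise per residue, Angstrom
#' @param resPerTurn residues per helical turn
#' @param bundleRadius axis-to-centre distance, Angstrom
#' @param sequence optional one-letter sequence (recycled per chain)
#' @return a \linkS4class{Structure} with chains A-D
#' @export
generateHelixBundle <- function(nres = 30, rise = 1.5, resPerTurn = 3.6,
                                bundleRadius = 7.5, sequence = NULL) {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
           G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
           M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
           S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  seq1 <- if (is.null(sequence)) rep("A", nres)
          else rep_len(strsplit(sequence, "")[[1]], nres)
  twist <- 2 * pi / resPerTurn
  chainAxes <- rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1)) *
    bundleRadius / sqrt(2)
  chains <- c("A", "B", "C", "D")
  up <- c(TRUE, FALSE, TRUE, FALSE)
  rows <- vector("list", 4 * nres * 4)
  ri <- 0
  for (ci in 1:4) {
    for (res in seq_len(nres)) {
      i <- res - 1
      for (ai in seq_len(4)) {
        p <- .HELIX_PARAMS[ai, ]
        phase <- i * twist + p$dphase * pi / 180
        local <- c(p$radius * cos(phase), p$radius * sin(phase),
                   i * rise + p$dz)
        if (!up[ci]) local <- c(local[1], -local[2], -local[3])
        ri <- ri + 1
        rows[[ri]] <- data.frame(
          chain = chains[ci], resno = res, resname = aa3[[seq1[res]]],
          atom = p$atom, element = substr(p$atom, 1, 1),
          x = local[1] + chainAxes[ci, 1],
          y = local[2] + chainAxes[ci, 2],
          z = local[3], stringsAsFactors = FALSE)
      }
    }
  }
  Structure(do.call(rbind, rows))
}

#' Plant a motif copy into a target structure
#'
#' Rigidly superposes the query backbone onto chosen windows of the target
#' (preserving the query's internal geometry exactly), replaces those window
#' coordinates with the transformed query atoms, and adds i.i.d. Gaussian
#' coordinate noise of s.d. \code{sigma}. The returned ground-truth record
#' gives the planted segments and noise level.
#'
#' @param target a \linkS4class{Structure} large enough to host the query
#' @param query a \linkS4class{MotifQuery}
#' @param sigma coordinate noise s.d., Angstrom
#' @param seed RNG seed
#' @param segments optional data.frame (chain, start) choosing the host
#'   windows per query segment; defaults to the first residues of distinct
#'   chains
#' @return list with \code{structure} (modified target) and \code{truth}
#'   (list: segments data.frame with chain/start/len, sigma, seed)
#' @export
plantMotif <- function(target, query, sigma = 0, seed = 1, segments = NULL) {
  stopifnot(is(target, "Structure"), is(query, "MotifQuery"))
  segLen <- query@segments$end - query@segments$start + 1
  at <- atoms(target)
  if (is.null(segments)) {
    chains <- unique(at$chain)
    if (length(chains) < nrow(query@segments))
      stop("target has too few chains to host the query segments")
    segments <- data.frame(chain = chains[seq_along(segLen)],
                           start = vapply(chains[seq_along(segLen)],
                                          function(ch)
                                            min(at$resno[at$chain == ch]),
                                          numeric(1)))
  }
  ## collect target window backbone coordinates
  hostSeg <- data.frame(chain = segments$chain, start = segments$start,
                        end = segments$start + segLen - 1)
  host <- extractMotif(target, hostSeg)
  ## rigid transform of the query onto the host windows
  sp <- kabschSuperpose(host@coords, query@coords)
  placed <- t(sp$rotation %*% t(query@coords)) +
    rep(sp$translation, each = nrow(query@coords))
  set.seed(substreamSeed(seed, "plant_motif"))
  if (sigma > 0)
    placed <- placed + matrix(stats::rnorm(length(placed), 0, sigma),
                              ncol = 3)
  ## write the placed coordinates back into the target atoms
  k <- 0
  for (si in seq_len(nrow(hostSeg))) {
    for (res in hostSeg$start[si]:hostSeg$end[si]) {
      for (an in .BACKBONE) {
        k <- k + 1
        row <- which(at$chain == hostSeg$chain[si] & at$resno == res &
                     at$atom == an)
        if (length(row) != 1)
          stop("target window lacks a complete backbone")
        at[row, c("x", "y", "z")] <- placed[k, ]
      }
    }
  }
  list(structure = Structure(at, cell = cellParams(target),
                             spaceGroup = spaceGroup(target)),
       truth = list(segments = data.frame(chain = hostSeg$chain,
                                          start = hostSeg$start,
                                          len = segLen),
                    sigma = sigma, seed = seed))
}

#' Toy systems for the double-decoupling free-energy cycle
#'
#' Returns a system factory (a function of transformation and step) plus
#' ground-truth metadata, for three fixture kinds:
#' \describe{
#'   \item{harmonic}{a single particle switched between two harmonic wells
#'     (force constants \code{kCoupled} -> \code{kDecoupled}); the
#'     decoupling free energy has the closed form
#'     (3/2) RT log(kDecoupled / kCoupled), attached as
#'     \code{meta$analyticDeltaG}.}
#'   \item{lj-solute}{a Lennard-Jones solute (dummy-like parameters,
#'     rmin 4.5 A, eps 1 kcal/mol) decoupling from a small periodic solvent
#'     box; both cycle transformations are available (transformation 2 has
#'     no receptor either way).}
#'   \item{host-guest}{the full cycle: a fixed host site with a deep
#'     attractive well in a solvent box. Transformation 1 decouples the
#'     ligand from the bound state while a single dummy particle (rmin
#'     4.5 A, eps 1 kcal/mol) couples in its place, held at the site by a
#'     constant harmonic restraint; step 2 removes the dummy. Transformation
#'     2 repeats both steps without the host, the ligand held to the dummy
#'     by a constant restraint. The ligand-dummy centring restraint of
#'     transformation 1 grows with the restraint schedule (0 ->
#'     \code{kRestraint}) and enters the perturbation energies; constant
#'     restraints cancel within each transformation.}
#' }
#'
#' @param kind "harmonic", "lj-solute" or "host-guest"
#' @param seed RNG seed for initial solvent placement
#' @param nSolvent solvent particles (lj-solute, host-guest)
#' @param boxEdge periodic box edge, Angstrom (> 20)
#' @param kRestraint decoupled-state centring force constant, kcal/mol/A^2
#' @param hostEpsilon host well depth parameter, kcal/mol
#' @param kCoupled,kDecoupled harmonic-kind force constants, kcal/mol/A^2
#' @param temperature temperature, K
#' @return list with \code{factory(transformation, step)} and \code{meta}
#' @export
generateFepFixture <- function(kind = c("harmonic", "lj-solute",
                                        "host-guest"),
                               seed = 1, nSolvent = 18, boxEdge = 22,
                               kRestraint = 10, hostEpsilon = 2,
                               kCoupled = 20, kDecoupled = 10,
                               temperature = 298.15) {
  kind <- match.arg(kind)
  set.seed(substreamSeed(seed, paste0("fep_", kind)))

  if (kind == "harmonic") {
    pos <- rbind(c(0, 0, 0), c(0.5, 0, 0))  # anchor + particle
    factory <- function(transformation, step) {
      particleSystem(pos, epsilon = 0, rmin = 3,
        restraints = list(
          harmonicRestraint(1, 2, kCoupled, 0, "atom", "one_minus_lambda"),
          harmonicRestraint(1, 2, kDecoupled, 0, "atom", "lambda")),
        fixed = 1, temperature = temperature)
    }
    return(list(factory = factory,
                meta = list(kind = kind,
                            analyticDeltaG = 1.5 * thermalRT(temperature) *
                              log(kDecoupled / kCoupled))))
  }

  ## random non-overlapping solvent positions on a jittered grid
  solventPositions <- function(n, edge, exclude = NULL, minDist = 3.0) {
    pts <- matrix(stats::runif(3 * n * 30, 0, edge), ncol = 3)
    keep <- matrix(numeric(0), 0, 3)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      ok <- TRUE
      allp <- rbind(keep, exclude)
      if (nrow(allp)) {
        d <- sqrt(rowSums((allp - rep(p, each = nrow(allp)))^2))
        ok <- all(d > minDist)
      }
      if (ok) keep <- rbind(keep, p)
      if (nrow(keep) == n) break
    }
    if (nrow(keep) < n) stop("could not place solvent without overlap")
    keep
  }

  centre <- rep(boxEdge / 2, 3)
  ## three-atom host: an equilateral triangle in the yz plane whose pocket
  ## (on the +x axis) binds the ligand at a unique, non-degenerate pose;
  ## the dummy is pinned there by constant restraints to all three atoms,
  ## the same triangulation the binding-site restraints of a real
  ## double-decoupling setup use
  triSide <- 3.5
  circ <- triSide / sqrt(3)
  hostAtoms <- rbind(centre + c(0, circ, 0),
                     centre + c(0, -circ / 2 * 1, circ * sqrt(3) / 2),
                     centre + c(0, -circ / 2 * 1, -circ * sqrt(3) / 2))
  site <- centre + c(3.45, 0, 0)
  ligand0 <- site
  dummy0 <- site + c(0.3, 0, 0)
  solv <- solventPositions(nSolvent, boxEdge,
                           exclude = rbind(hostAtoms, ligand0, dummy0))
  solvEps <- 0.15; solvRmin <- 3.4
  ligEps <- 1.0; ligRmin <- 4.5     # dummy-like large particle
  hostRmin <- 3.5
  dummyR0 <- sqrt(rowSums((hostAtoms - rep(site, each = 3))^2))

  if (kind == "lj-solute") {
    factory <- function(transformation, step) {
      if (step == 1) {
        pos <- rbind(solv, ligand0, dummy0)
        n <- nrow(pos)
        particleSystem(pos,
          epsilon = c(rep(solvEps, nSolvent), ligEps, ligEps),
          rmin = c(rep(solvRmin, nSolvent), ligRmin, ligRmin),
          restraints = list(harmonicRestraint(n - 1L, n, kRestraint, 0,
                                              "atom", "constant")),
          box = rep(boxEdge, 3), decoupleSet = n - 1L, coupleSet = n,
          temperature = temperature)
      } else {
        pos <- rbind(solv, dummy0)
        n <- nrow(pos)
        particleSystem(pos,
          epsilon = c(rep(solvEps, nSolvent), ligEps),
          rmin = c(rep(solvRmin, nSolvent), ligRmin),
          box = rep(boxEdge, 3), decoupleSet = n,
          temperature = temperature)
      }
    }
    return(list(factory = factory,
                meta = list(kind = kind, nSolvent = nSolvent,
                            boxEdge = boxEdge)))
  }

  ## host-guest: host atoms 1:3 (epsilon 0 in transformation 2, where they
  ## act only as fixed restraint anchors), then solvent, ligand, dummy
  factory <- function(transformation, step) {
    host <- transformation == 1
    epsH <- rep(if (host) hostEpsilon else 0, 3)
    dummyRestraints <- function(dum)
      lapply(1:3, function(a)
        harmonicRestraint(a, dum, kRestraint, dummyR0[a], "atom",
                          "constant"))
    if (step == 1) {
      pos <- rbind(hostAtoms, solv, ligand0, dummy0)
      n <- nrow(pos)
      lig <- n - 1L; dum <- n
      restr <- c(dummyRestraints(dum), list(
        if (host)
          harmonicRestraint(lig, dum, kRestraint, 0, "atom", "lambda")
        else
          harmonicRestraint(lig, dum, kRestraint, 0, "atom", "constant")))
      particleSystem(pos,
        epsilon = c(epsH, rep(solvEps, nSolvent), ligEps, ligEps),
        rmin = c(rep(hostRmin, 3), rep(solvRmin, nSolvent), ligRmin,
                 ligRmin),
        restraints = restr, box = rep(boxEdge, 3),
        decoupleSet = lig, coupleSet = dum, fixed = 1:3,
        temperature = temperature)
    } else {
      pos <- rbind(hostAtoms, solv, dummy0)
      n <- nrow(pos)
      particleSystem(pos,
        epsilon = c(epsH, rep(solvEps, nSolvent), ligEps),
        rmin = c(rep(hostRmin, 3), rep(solvRmin, nSolvent), ligRmin),
        restraints = dummyRestraints(n), box = rep(boxEdge, 3),
        decoupleSet = n, fixed = 1:3, temperature = temperature)
    }
  }
  ## an unrestrained bound-state system for the occupancy oracle; particle 4
  ## is a non-interacting marker at the host centre so the sampler can track
  ## the ligand-to-centre distance
  unrestrained <- function() {
    pos <- rbind(hostAtoms, centre, solv, ligand0)
    particleSystem(pos,
      epsilon = c(rep(hostEpsilon, 3), 0, rep(solvEps, nSolvent), ligEps),
      rmin = c(rep(hostRmin, 3), 3, rep(solvRmin, nSolvent), ligRmin),
      box = rep(boxEdge, 3), fixed = 1:4, temperature = temperature)
  }
  list(factory = factory,
       meta = list(kind = kind, nSolvent = nSolvent, boxEdge = boxEdge,
                   kRestraint = kRestraint, hostEpsilon = hostEpsilon,
                   centreIndexUnrestrained = 4L,
                   ligandIndexUnrestrained = nSolvent + 5L,
                   hostCentroid = colMeans(hostAtoms), site = site),
       unrestrained = unrestrained)
}

#' Generate a synthetic sedimentation-equilibrium dataset
#'
#' Simulates one scan per rotor speed for a tetramer-octamer (or generally
#' n-mer <-> 2n-mer) system, conserving the loading concentration across
#' speeds: the reference concentration of each scan is solved so that the
#' window-average base-equivalent concentration equals \code{cLoad},
#' emulating radial redistribution of a fixed sample. Gaussian noise is
#' added per scan from a seeded substream. The defaults are the four-speed,
#' Kd = 118 uM tetramer-octamer protocol.
#'
#' @param kd dissociation constant, M
#' @param baseMass base-species (tetramer) molar mass, Da
#' @param speeds rotor speeds, r.p.m.
#' @param cLoad loading concentration, base-species molar
#' @param noise absorbance noise s.d., AU
#' @param seed master seed
#' @param radii radii grid, cm
#' @param vbar,rho,epsilon,path,temperature model constants (see
#'   \linkS4class{AssociationModel})
#' @param baseline baseline offset applied to every scan, AU
#' @return list with \code{scans} (list of \linkS4class{AucScan}) and
#'   \code{truth} (kd, baseMass, crefs, baseline, noise, seed, model)
#' @export
generateAucDataset <- function(kd = 118e-6, baseMass = 13400,
                               speeds = c(25000, 30000, 35000, 40000),
                               cLoad = 5e-5, noise = 0.005, seed = 1,
                               radii = seq(6.9, 7.15, length.out = 60),
                               vbar = 0.73, rho = 1.0, epsilon = 3000,
                               path = 1.2, temperature = 298.15,
                               baseline = 0.02) {
  model <- AssociationModel(baseMass, vbar, rho, scheme = "self", kd = kd,
                            epsilon = epsilon, path = path)
  crefs <- vapply(speeds, function(sp) {
    f <- function(cr) {
      pr <- speciesProfiles(model, sp, radii, cr, temperature, radii[1])
      mean(pr$base + 2 * pr$dimerized) - cLoad
    }
    stats::uniroot(f, c(cLoad * 1e-6, cLoad * 10), tol = 1e-14)$root
  }, numeric(1))
  scans <- lapply(seq_along(speeds), function(i)
    simulateScan(model, speeds[i], radii, crefs[i], baseline, noise,
                 seed = substreamSeed(seed, paste0("auc_scan_", i)),
                 temperature = temperature))
  list(scans = scans,
       truth = list(kd = kd, baseMass = baseMass, crefs = crefs,
                    baseline = baseline, noise = noise, seed = seed,
                    cLoad = cLoad, vbar = vbar, rho = rho,
                    epsilon = epsilon, path = path,
                    speeds = speeds))
}

#' Generate a crystal fixture with atoms near cell faces
#'
#' Small deterministic structure in a given cell and space group whose
#' chains sit near the cell boundary, so that symmetry images make contacts
#' under the lattice retention rule. Used to exercise
#' \code{\link{expandLattice}} against brute-force enumeration.
#'
#' @param cell numeric(6) cell parameters
#' @param spaceGroup space-group symbol
#' @param nAtomsPerCluster atoms per corner cluster
#' @param seed RNG seed for jitter
#' @return a \linkS4class{Structure}
#' @export
generateLatticeFixture <- function(cell = c(30, 30, 40, 90, 90, 120),
                                   spaceGroup = "P 62",
                                   nAtomsPerCluster = 4, seed = 1) {
  set.seed(substreamSeed(seed, "lattice_fixture"))
  M <- fracToCart(cell)
  fracCentres <- rbind(c(0.08, 0.10, 0.05), c(0.90, 0.12, 0.45),
                       c(0.12, 0.88, 0.80))
  rows <- list()
  id <- 0
  for (ci in seq_len(nrow(fracCentres))) {
    ctr <- as.vector(M %*% fracCentres[ci, ])
    for (ai in seq_len(nAtomsPerCluster)) {
      id <- id + 1
      p <- ctr + stats::rnorm(3, 0, 1.2)
      rows[[id]] <- data.frame(chain = LETTERS[ci], resno = ai,
                               resname = "GLY", atom = "CA", element = "C",
                               x = p[1], y = p[2], z = p[3],
                               stringsAsFactors = FALSE)
    }
  }
  Structure(do.call(rbind, rows), cell = cell, spaceGroup = spaceGroup)
}
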