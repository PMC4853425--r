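#' @import methods
NULL

## ---------------------------------------------------------------------------
## Structure: an atomic model with optional crystallographic metadata
## ---------------------------------------------------------------------------

#' Atomic structure with optional unit cell and space group
#'
#' A light container for atomic models read from PDB/mmCIF files or built by
#' the synthetic generators. The \code{atoms} slot is a data.frame with one
#' row per atom and columns \code{chain}, \code{resno} (1-based, as
#' deposited), \code{resname} (3-letter code), \code{atom} (PDB atom name),
#' \code{element}, and Cartesian coordinates \code{x}, \code{y}, \code{z} in
#' Angstrom. \code{cell} is either empty or a length-6 numeric
#' (a, b, c in Angstrom; alpha, beta, gamma in degrees); \code{spaceGroup}
#' is empty or a Hermann-Mauguin symbol.
#'
#' @slot atoms data.frame of atom records (see Description)
#' @slot cell numeric(0) or numeric(6) unit-cell parameters
#' @slot spaceGroup character(0) or character(1) Hermann-Mauguin symbol
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", cell = "numeric",
                 spaceGroup = "character"),
  prototype(atoms = data.frame(), cell = numeric(0),
            spaceGroup = character(0)))

setValidity("Structure", function(object) {
  msgs <- character(0)
  at <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (nrow(at) > 0) {
    if (!all(need %in% names(at)))
      msgs <- c(msgs, paste("atoms must have columns:",
                            paste(need, collapse = ", ")))
    else {
      if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
        msgs <- c(msgs, "atom coordinates must be finite")
      if (any(!nzchar(at$element)))
        msgs <- c(msgs, "element symbols must be non-empty")
      key <- paste(at$chain, at$resno, at$atom)
      if (anyDuplicated(key))
        msgs <- c(msgs, "chain/residue/atom-name triples must be unique")
    }
  }
  if (length(object@cell) > 0) {
    if (length(object@cell) != 6)
      msgs <- c(msgs, "cell must be numeric(6): a, b, c, alpha, beta, gamma")
    else {
      if (any(object@cell[1:3] <= 0))
        msgs <- c(msgs, "cell lengths must be positive")
      if (any(object@cell[4:6] <= 0 | object@cell[4:6] >= 180))
        msgs <- c(msgs, "cell angles must lie in (0, 180) degrees")
    }
  }
  if (length(object@spaceGroup) > 1)
    msgs <- c(msgs, "spaceGroup must be absent or a single symbol")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Structure
#'
#' @param atoms data.frame of atom records (see \linkS4class{Structure})
#' @param cell optional numeric(6) cell parameters
#' @param spaceGroup optional Hermann-Mauguin space-group symbol
#' @return a \linkS4class{Structure}
#' @examples
#' s <- Structure(data.frame(chain = "A", resno = 1, resname = "GLY",
#'                           atom = "CA", element = "C", x = 0, y = 0, z = 0))
#' @export
Structure <- function(atoms, cell = numeric(0), spaceGroup = character(0)) {
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- as.character(atoms$element)
  new("Structure", atoms = atoms, cell = as.numeric(cell),
      spaceGroup = as.character(spaceGroup))
}

## ---------------------------------------------------------------------------
## FullereneTopology
## ---------------------------------------------------------------------------

#' Truncated-icosahedron C60 geometry and topology
#'
#' @slot vertices 60 x 3 matrix of carbon positions (Angstrom)
#' @slot edges 90 x 2 integer matrix of bonded vertex pairs
#' @slot faces list of 32 integer rings: 12 pentagons then 20 hexagons
#' @slot centroid numeric(3) cage centroid
#' @exportClass FullereneTopology
setClass("FullereneTopology",
  representation(vertices = "matrix", edges = "matrix", faces = "list",
                 centroid = "numeric"))

setValidity("FullereneTopology", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@vertices), c(60L, 3L)))
    msgs <- c(msgs, "vertices must be a 60 x 3 matrix")
  if (!identical(dim(object@edges), c(90L, 2L)))
    msgs <- c(msgs, "edges must be a 90 x 2 matrix")
  if (length(object@faces) != 32)
    msgs <- c(msgs, "there must be 32 faces (12 pentagons, 20 hexagons)")
  else {
    sizes <- lengths(object@faces)
    if (sum(sizes == 5) != 12 || sum(sizes == 6) != 20)
      msgs <- c(msgs, "faces must be 12 pentagons and 20 hexagons")
  }
  ## Euler characteristic of the closed cage
  if (60 - nrow(object@edges) + length(object@faces) != 2)
    msgs <- c(msgs, "V - E + F must equal 2")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## LatticeAssembly
## ---------------------------------------------------------------------------

#' Symmetry-expanded crystal lattice neighbourhood
#'
#' Result of \code{\link{expandLattice}}: the initial (identity) unit plus
#' every symmetry/translation image passing the contact retention rule.
#' Each element of \code{images} is a list with \code{op} (operator index),
#' \code{shift} (integer lattice translation), \code{atoms} (transformed
#' atom data.frame) and \code{contacts} (atoms within the cutoff of the
#' initial unit).
#'
#' @slot source the input \linkS4class{Structure}
#' @slot images list of retained images (identity first)
#' @slot cutoff numeric contact distance cutoff (Angstrom)
#' @slot minAtoms integer minimum in-contact atom count for retention
#' @exportClass LatticeAssembly
setClass("LatticeAssembly",
  representation(source = "Structure", images = "list", cutoff = "numeric",
                 minAtoms = "integer"))

setValidity("LatticeAssembly", function(object) {
  msgs <- character(0)
  if (length(object@images) < 1)
    msgs <- c(msgs, "identity image must always be present")
  else {
    id <- object@images[[1]]
    if (!(id$op == 1L && all(id$shift == 0L)))
      msgs <- c(msgs, "first image must be the identity (op 1, zero shift)")
    if (length(object@images) > 1) {
      ok <- vapply(object@images[-1], function(im)
        im$contacts >= object@minAtoms, logical(1))
      if (!all(ok))
        msgs <- c(msgs, "a retained non-identity image violates the retention rule")
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## MotifQuery
## ---------------------------------------------------------------------------

#' Disjoint-segment backbone motif query
#'
#' Ordered backbone segments (chain, residue start/end, inclusive) with their
#' N, CA, C, O coordinates flattened segment-major, atom order N, CA, C, O
#' within each residue.
#'
#' @slot segments data.frame with columns chain, start, end
#' @slot coords (4 x total residues) x 3 coordinate matrix
#' @slot sequence character(1) concatenated one-letter sequence (may be NA)
#' @exportClass MotifQuery
setClass("MotifQuery",
  representation(segments = "data.frame", coords = "matrix",
                 sequence = "character"))

setValidity("MotifQuery", function(object) {
  msgs <- character(0)
  seg <- object@segments
  if (nrow(seg) > 0) {
    if (!all(c("chain", "start", "end") %in% names(seg)))
      msgs <- c(msgs, "segments needs columns chain, start, end")
    else {
      if (any(seg$end < seg$start))
        msgs <- c(msgs, "segment end must be >= start")
      ## overlap check within a chain
      for (ch in unique(seg$chain)) {
        s <- seg[seg$chain == ch, , drop = FALSE]
        if (nrow(s) > 1) {
          s <- s[order(s$start), ]
          if (any(s$start[-1] <= s$end[-nrow(s)]))
            msgs <- c(msgs, sprintf("segments overlap within chain %s", ch))
        }
      }
      nres <- sum(seg$end - seg$start + 1)
      if (nrow(object@coords) != 4 * nres)
        msgs <- c(msgs, "coordinate count must be 4 x total residue count")
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ParticleSystem
## ---------------------------------------------------------------------------

#' Toy particle system for the Monte Carlo / alchemy engine
#'
#' Lennard-Jones particles with optional harmonic bonds, harmonic restraints,
#' an optional periodic orthorhombic box, and alchemical role assignments.
#' Per-particle LJ parameters are \code{epsilon} (well depth, kcal/mol,
#' positive) and \code{rmin} (position of the pair minimum for a like pair,
#' Angstrom); unlike pairs use Lorentz-Berthelot mixing (arithmetic rmin,
#' geometric epsilon). Particles in \code{decoupleSet} carry coupling
#' strength 1 - lambda and particles in \code{coupleSet} carry lambda, where
#' lambda in [0, 1] is the decoupling progress variable of the alchemical
#' transformation; cross interactions between the two sets are excluded.
#'
#' Restraints are lists with fields \code{kind} ("atom" or "centroid"),
#' \code{i}, \code{j} (index vectors; centroids of each group for "centroid"),
#' \code{k} (kcal/mol/A^2, energy (k/2)(r - r0)^2), \code{r0} (Angstrom) and
#' \code{mode} ("constant", "lambda" for k scaled by the restraint schedule,
#' or "one_minus_lambda").
#'
#' @slot positions N x 3 matrix, Angstrom
#' @slot epsilon numeric(N) LJ well depths, kcal/mol
#' @slot rmin numeric(N) LJ like-pair minimum distances, Angstrom
#' @slot bonds data.frame (i, j, k, r0) harmonic bonds, energy (k/2)(r-r0)^2
#' @slot restraints list of restraint specifications
#' @slot box numeric(0) for an open system or numeric(3) periodic edges
#' @slot decoupleSet integer indices whose interactions vanish as lambda -> 1
#' @slot coupleSet integer indices whose interactions appear as lambda -> 1
#' @slot fixed logical(N), TRUE for immobile particles
#' @slot temperature numeric(1), K
#' @exportClass ParticleSystem
setClass("ParticleSystem",
  representation(positions = "matrix", epsilon = "numeric", rmin = "numeric",
                 bonds = "data.frame", restraints = "list", box = "numeric",
                 decoupleSet = "integer", coupleSet = "integer",
                 fixed = "logical", temperature = "numeric"))

setValidity("ParticleSystem", function(object) {
  msgs <- character(0)
  n <- nrow(object@positions)
  if (n < 1) msgs <- c(msgs, "system must contain at least one particle")
  if (ncol(object@positions) != 3)
    msgs <- c(msgs, "positions must be N x 3")
  if (length(object@epsilon) != n || length(object@rmin) != n)
    msgs <- c(msgs, "epsilon and rmin must have one entry per particle")
  if (any(object@epsilon < 0)) msgs <- c(msgs, "epsilon must be >= 0")
  if (any(object@rmin <= 0)) msgs <- c(msgs, "rmin must be > 0")
  if (nrow(object@bonds) > 0) {
    b <- object@bonds
    if (anyDuplicated(cbind(pmin(b$i, b$j), pmax(b$i, b$j))))
      msgs <- c(msgs, "duplicate bonds are not allowed")
    if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n | b$i == b$j))
      msgs <- c(msgs, "bond indices out of range")
  }
  for (r in object@restraints) {
    if (!is.list(r) || !all(c("kind", "i", "j", "k", "r0", "mode") %in% names(r)))
      msgs <- c(msgs, "malformed restraint specification")
    else {
      if (r$k < 0 || r$r0 < 0)
        msgs <- c(msgs, "restraint k and r0 must be non-negative")
      if (any(c(r$i, r$j) < 1 | c(r$i, r$j) > n))
        msgs <- c(msgs, "restraint member index out of range")
    }
  }
  if (!(length(object@box) %in% c(0L, 3L)))
    msgs <- c(msgs, "box must be absent or numeric(3)")
  if (length(object@box) == 3 && any(object@box <= 2 * 10))
    msgs <- c(msgs, "periodic box edges must exceed twice the 10 A cutoff")
  if (any(object@decoupleSet %in% object@coupleSet))
    msgs <- c(msgs, "a particle cannot be in both alchemical sets")
  if (any(c(object@decoupleSet, object@coupleSet) < 1) ||
      any(c(object@decoupleSet, object@coupleSet) > n))
    msgs <- c(msgs, "alchemical set indices out of range")
  if (length(object@fixed) != n)
    msgs <- c(msgs, "fixed flags must have one entry per particle")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    msgs <- c(msgs, "temperature must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## AucScan and AssociationModel
## ---------------------------------------------------------------------------

#' One sedimentation-equilibrium absorbance scan
#'
#' @slot speed rotor speed, r.p.m.
#' @slot radii radii in cm, strictly increasing
#' @slot absorbance absorbance, AU
#' @slot wavelength detection wavelength, nm
#' @slot temperature temperature, K
#' @exportClass AucScan
setClass("AucScan",
  representation(speed = "numeric", radii = "numeric", absorbance = "numeric",
                 wavelength = "numeric", temperature = "numeric"))

setValidity("AucScan", function(object) {
  msgs <- character(0)
  if (length(object@radii) != length(object@absorbance))
    msgs <- c(msgs, "radii and absorbance must have equal length")
  if (length(object@radii) > 1 && any(diff(object@radii) <= 0))
    msgs <- c(msgs, "radii must be strictly increasing")
  if (!all(is.finite(object@absorbance)))
    msgs <- c(msgs, "absorbance values must be finite")
  if (object@speed < 0) msgs <- c(msgs, "speed must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Sedimenting self-association model
#'
#' Describes a base species of molar mass \code{baseMass} (Da) that may
#' self-associate as n-mer <-> 2n-mer with dissociation constant
#' Kd = [n-mer]^2 / [2n-mer] in molar units. \code{epsilon} is the molar
#' extinction (AU cm^-1 M^-1) of the base species at the detection
#' wavelength; the 2n-mer extinction is \code{2 * epsilon} (twice the
#' chromophores). \code{path} is the optical path length, cm.
#'
#' @slot baseMass molar mass of the base (sedimenting) species, Da
#' @slot vbar partial specific volume, mL/g (shared by both species)
#' @slot rho solvent density, g/mL
#' @slot scheme "none" or "self" (n-mer <-> 2n-mer)
#' @slot kd dissociation constant, M (ignored for scheme "none")
#' @slot epsilon base-species molar extinction, AU cm^-1 M^-1
#' @slot path optical path length, cm
#' @exportClass AssociationModel
setClass("AssociationModel",
  representation(baseMass = "numeric", vbar = "numeric", rho = "numeric",
                 scheme = "character", kd = "numeric", epsilon = "numeric",
                 path = "numeric"))

setValidity("AssociationModel", function(object) {
  msgs <- character(0)
  if (object@baseMass <= 0) msgs <- c(msgs, "baseMass must be positive")
  vr <- object@vbar * object@rho
  if (vr <= 0 || vr >= 1)
    msgs <- c(msgs, "vbar * rho must lie in (0, 1) for a sedimenting species")
  if (!object@scheme %in% c("none", "self"))
    msgs <- c(msgs, "scheme must be 'none' or 'self'")
  if (object@scheme == "self" && object@kd <= 0)
    msgs <- c(msgs, "kd must be positive")
  if (object@epsilon <= 0 || object@path <= 0)
    msgs <- c(msgs, "epsilon and path must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationModel
#' @param baseMass base-species molar mass, Da
#' @param vbar partial specific volume, mL/g
#' @param rho solvent density, g/mL
#' @param scheme "none" (single species) or "self" (n-mer <-> 2n-mer)
#' @param kd dissociation constant, M
#' @param epsilon base-species molar extinction, AU cm^-1 M^-1
#' @param path optical path length, cm
#' @return an \linkS4class{AssociationModel}
#' @export
AssociationModel <- function(baseMass, vbar = 0.73, rho = 1.0,
                             scheme = c("self", "none"), kd = 118e-6,
                             epsilon = 3000, path = 1.2) {
  scheme <- match.arg(scheme)
  new("AssociationModel", baseMass = baseMass, vbar = vbar, rho = rho,
      scheme = scheme, kd = kd, epsilon = epsilon, path = path)
}

#' Construct an AucScan
#' @param speed rotor speed, r.p.m.
#' @param radii radii, cm (strictly increasing)
#' @param absorbance absorbance, AU
#' @param wavelength detection wavelength, nm
#' @param temperature temperature, K
#' @return an \linkS4class{AucScan}
#' @export
AucScan <- function(speed, radii, absorbance, wavelength = 340,
                    temperature = 298.15) {
  new("AucScan", speed = speed, radii = as.numeric(radii),
      absorbance = as.numeric(absorbance), wavelength = wavelength,
      temperature = temperature)
}
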