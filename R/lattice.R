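## Crystallographic lattice expansion, Matthews/solvent arithmetic, and
## inter-fullerene channel geometry.

## ---------------------------------------------------------------------------
## Space-group operators
## ---------------------------------------------------------------------------

## Embedded coordinate-triplet tables for the groups exercised here. General
## symmetry can be supplied directly as "x,y,z"-style strings (e.g. copied
## from mmCIF _symmetry_equiv or PDB REMARK 290 records).
.SG_TABLE <- list(
  "P 1" = c("x,y,z"),
  "P 2" = c("x,y,z", "-x,y,-z"),
  "P 21" = c("x,y,z", "-x,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
                   "-x+1/2,-y,z+1/2"),
  "P 6" = c("x,y,z", "x-y,x,z", "-y,x-y,z", "-x,-y,z", "-x+y,-x,z",
            "y,-x+y,z"),
  "P 62" = c("x,y,z", "x-y,x,z+1/3", "-y,x-y,z+2/3", "-x,-y,z",
             "-x+y,-x,z+1/3", "y,-x+y,z+2/3")
)

normalizeSgSymbol <- function(symbol) {
  s <- toupper(gsub("\\s+", "", symbol))
  ## map compact forms like "P62", "P212121" onto spaced table keys
  key <- names(.SG_TABLE)[vapply(names(.SG_TABLE),
    function(k) gsub("\\s+", "", k) == s, logical(1))]
  if (length(key)) key[1] else NA_character_
}

#' Symmetry operators of a space group
#'
#' Returns the operators of one of the embedded space groups (P1, P2, P21,
#' P212121, P6, P62), or parses operators given directly as coordinate
#' triplets such as \code{"-y,x-y,z+2/3"}. Each operator is a list with a
#' 3 x 3 integer rotation matrix \code{R} and translation \code{t}, both in
#' fractional coordinates: x' = R x + t.
#'
#' @param symbol Hermann-Mauguin symbol (spacing optional), or a character
#'   vector of coordinate triplets
#' @return list of operators
#' @examples
#' length(spaceGroupOperators("P 62"))  # 6
#' @export
spaceGroupOperators <- function(symbol) {
  trips <- if (length(symbol) > 1 || grepl(",", symbol[1])) symbol else {
    key <- normalizeSgSymbol(symbol)
    if (is.na(key))
      stop("unsupported space group symbol: ", symbol,
           " (supply operators as coordinate triplets instead)")
    .SG_TABLE[[key]]
  }
  lapply(trips, parseSymop)
}

## parse one "x-y, x, z+1/3" triplet into R (3x3) and t (length 3)
parseSymop <- function(triplet) {
  parts <- strsplit(gsub("\\s+", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", triplet)
  R <- matrix(0, 3, 3); tvec <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    ## tokenize into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        R[i, match(tm, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        fr <- as.numeric(strsplit(tm, "/")[[1]])
        tvec[i] <- tvec[i] + sign * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        tvec[i] <- tvec[i] + sign * as.numeric(tm)
      } else stop("cannot parse symmetry term '", tm, "' in ", triplet)
    }
  }
  list(R = R, t = tvec)
}

## ---------------------------------------------------------------------------
## Cell geometry
## ---------------------------------------------------------------------------

#' Fractional-to-Cartesian matrix of a unit cell
#'
#' Standard PDB orthogonalization: a along x, b in the xy plane.
#'
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees)
#' @return 3 x 3 matrix M such that cartesian = M \%*\% fractional
#' @export
fracToCart <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0))
  ca <- cos(cell[4] * pi / 180); cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180); sg <- sin(cell[6] * pi / 180)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  cx <- cc * cb
  cy <- cc * (ca - cb * cg) / sg
  cz <- sqrt(cc^2 - cx^2 - cy^2)
  matrix(c(a, b * cg, cx,
           0, b * sg, cy,
           0, 0, cz), 3, 3, byrow = TRUE)
}

#' Unit-cell volume
#' @param cell numeric(6) cell parameters (Angstrom, degrees)
#' @return volume in cubic Angstrom
#' @export
cellVolume <- function(cell) {
  abs(det(fracToCart(cell)))
}

## ---------------------------------------------------------------------------
## Lattice expansion
## ---------------------------------------------------------------------------

#' Expand a crystal lattice around the deposited unit
#'
#' Applies every space-group operator and lattice translation to the initial
#' unit and retains, besides the identity, each image that has at least
#' \code{minAtoms} atoms within \code{cutoff} Angstrom of any atom of the
#' initial unit. The lattice-translation search range is derived from the
#' cell geometry (cutoff plus the structure diameter, converted to
#' fractional units and rounded up per axis), so every image that can
#' satisfy the rule is provably inside the searched range.
#'
#' @param structure a \linkS4class{Structure} with cell and space group
#' @param cutoff contact distance cutoff in Angstrom
#' @param minAtoms minimum number of in-contact atoms for retention
#' @param operators optional list of operators (overrides the space-group
#'   lookup; accepts \code{\link{spaceGroupOperators}} output)
#' @return a \linkS4class{LatticeAssembly}
#' @export
expandLattice <- function(structure, cutoff = 16, minAtoms = 3,
                          operators = NULL) {
  stopifnot(is(structure, "Structure"))
  cell <- cellParams(structure)
  if (length(cell) != 6)
    stop("structure has no unit cell; cannot expand lattice")
  if (is.null(operators)) {
    sg <- spaceGroup(structure)
    if (!length(sg)) stop("structure has no space group")
    operators <- spaceGroupOperators(sg)
  }
  M <- fracToCart(cell)
  Minv <- solve(M)
  xyz <- as.matrix(atoms(structure)[, c("x", "y", "z")])
  frac <- t(Minv %*% t(xyz))

  ## translation bound: an image can touch the initial unit only if its
  ## centroid is within (diameter + cutoff) of the unit's centroid
  ctr <- colMeans(xyz)
  rad <- sqrt(max(rowSums((xyz - rep(ctr, each = nrow(xyz)))^2)))
  reach <- 2 * rad + cutoff
  ## perpendicular spacing of the lattice planes along each axis
  V <- abs(det(M))
  av <- M[, 1]; bv <- M[, 2]; cv <- M[, 3]
  areas <- c(sqrt(sum(crossVec(bv, cv)^2)), sqrt(sum(crossVec(av, cv)^2)),
             sqrt(sum(crossVec(av, bv)^2)))
  dperp <- V / areas
  nmax <- ceiling(reach / dperp) + 1L

  images <- list(list(op = 1L, shift = c(0L, 0L, 0L),
                      atoms = atoms(structure), contacts = nrow(xyz)))
  for (oi in seq_along(operators)) {
    op <- operators[[oi]]
    fr2 <- t(op$R %*% t(frac) + op$t)
    for (tx in -nmax[1]:nmax[1]) for (ty in -nmax[2]:nmax[2])
      for (tz in -nmax[3]:nmax[3]) {
        if (oi == 1L && tx == 0L && ty == 0L && tz == 0L) next
        shifted <- fr2 + rep(c(tx, ty, tz), each = nrow(fr2))
        cart <- t(M %*% t(shifted))
        nc <- countContacts(cart, xyz, cutoff)
        if (nc >= minAtoms) {
          at2 <- atoms(structure)
          at2$x <- cart[, 1]; at2$y <- cart[, 2]; at2$z <- cart[, 3]
          images[[length(images) + 1L]] <-
            list(op = as.integer(oi), shift = as.integer(c(tx, ty, tz)),
                 atoms = at2, contacts = nc)
        }
      }
  }
  new("LatticeAssembly", source = structure, images = images,
      cutoff = cutoff, minAtoms = as.integer(minAtoms))
}

crossVec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## number of atoms in `img` within cutoff of any atom in `ref`
countContacts <- function(img, ref, cutoff) {
  ## cheap prefilter on bounding boxes
  lo <- apply(ref, 2, min) - cutoff; hi <- apply(ref, 2, max) + cutoff
  cand <- img[, 1] >= lo[1] & img[, 1] <= hi[1] &
          img[, 2] >= lo[2] & img[, 2] <= hi[2] &
          img[, 3] >= lo[3] & img[, 3] <= hi[3]
  if (!any(cand)) return(0L)
  sub <- img[cand, , drop = FALSE]
  c2 <- cutoff^2
  n <- 0L
  for (i in seq_len(nrow(sub))) {
    d2 <- (ref[, 1] - sub[i, 1])^2 + (ref[, 2] - sub[i, 2])^2 +
          (ref[, 3] - sub[i, 3])^2
    if (any(d2 <= c2)) n <- n + 1L
  }
  n
}

## ---------------------------------------------------------------------------
## Matthews coefficient and solvent content
## ---------------------------------------------------------------------------

#' Matthews coefficient and solvent content
#'
#' V_M = cell volume / (Z * asuMass) with Z the space-group operator count,
#' and solvent fraction 1 - 1.23 / V_M (the 1.23 A^3/Da constant is the
#' conventional inverse of a 0.813 specific-volume packing estimate),
#' clamped to [0, 1).
#'
#' @param cell numeric(6) cell parameters
#' @param spaceGroup Hermann-Mauguin symbol or operator triplets
#' @param asuMass protein mass of the asymmetric unit, Da. By convention this
#'   excludes ligand and solvent mass; include ligand mass explicitly in
#'   \code{asuMass} if desired.
#' @return list with \code{vm} (A^3/Da) and \code{solvent} (fraction)
#' @examples
#' matthewsSolvent(c(42.1, 42.1, 66.7, 90, 90, 120), "P 62", 6718)
#' @export
matthewsSolvent <- function(cell, spaceGroup, asuMass) {
  if (!is.numeric(asuMass) || asuMass <= 0) stop("asuMass must be positive")
  Z <- length(spaceGroupOperators(spaceGroup))
  vm <- cellVolume(cell) / (Z * asuMass)
  solv <- 1 - 1.23 / vm
  if (solv < 0) {
    warning("V_M <= 1.23 A^3/Da implies non-physical negative solvent; ",
            "clamping to 0")
    solv <- 0
  }
  list(vm = vm, solvent = solv)
}

#' Solvent fraction from a Matthews coefficient
#' @param vm Matthews coefficient, A^3/Da
#' @return solvent fraction in [0, 1)
#' @export
solventFromVm <- function(vm) {
  stopifnot(vm > 0)
  max(0, 1 - 1.23 / vm)
}

## ---------------------------------------------------------------------------
## Inter-fullerene channel distances
## ---------------------------------------------------------------------------

#' Fullerene centroids in a structure or lattice assembly
#'
#' The centroid of each fullerene is the mean of its carbon positions,
#' grouped by (image, chain, residue number) for residues matching
#' \code{resname}.
#'
#' @param x a \linkS4class{Structure} or \linkS4class{LatticeAssembly}
#' @param resname residue name of the fullerene hetero-compound
#' @return matrix of centroids (one row each)
#' @export
fullereneCentroids <- function(x, resname = "C60") {
  tabs <- if (is(x, "LatticeAssembly"))
    lapply(latticeImages(x), `[[`, "atoms") else list(atoms(x))
  out <- NULL
  for (ti in seq_along(tabs)) {
    at <- tabs[[ti]]
    sel <- at[at$resname == resname, , drop = FALSE]
    if (!nrow(sel)) next
    key <- paste(sel$chain, sel$resno)
    for (k in unique(key)) {
      s <- sel[key == k, , drop = FALSE]
      out <- rbind(out, c(mean(s$x), mean(s$y), mean(s$z)))
    }
  }
  out
}

#' Nearest-neighbour distances along a fullerene channel
#'
#' Orders fullerene centroids by their coordinate along the channel axis and
#' reports consecutive centre-to-centre distances, the quantity whose
#' alternation (about 12 and 17 Angstrom in the co-crystal) characterizes the
#' helical fullerene channel.
#'
#' @param x a \linkS4class{LatticeAssembly}, \linkS4class{Structure}, or a
#'   numeric matrix of centroids
#' @param resname fullerene residue name (ignored for a centroid matrix)
#' @param axis channel axis direction (default crystallographic c, i.e. z)
#' @return numeric vector of consecutive centre-to-centre distances, Angstrom
#' @export
fullereneChannelDistances <- function(x, resname = "C60", axis = c(0, 0, 1)) {
  cen <- if (is.matrix(x)) x else fullereneCentroids(x, resname)
  if (is.null(cen) || nrow(cen) < 2)
    stop("need at least two fullerene centroids to measure channel distances")
  axis <- axis / sqrt(sum(axis^2))
  ord <- order(cen %*% axis)
  cen <- cen[ord, , drop = FALSE]
  sqrt(rowSums((cen[-1, , drop = FALSE] -
                cen[-nrow(cen), , drop = FALSE])^2))
}
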