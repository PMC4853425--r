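## Accessors and show methods.

#' Atom table of a Structure
#' @param x a \linkS4class{Structure}
#' @return data.frame of atom records
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' Unit-cell parameters
#' @param x a \linkS4class{Structure}
#' @return numeric(6) (a, b, c, alpha, beta, gamma) or numeric(0)
#' @export
setGeneric("cellParams", function(x) standardGeneric("cellParams"))

#' @rdname cellParams
#' @export
setMethod("cellParams", "Structure", function(x) x@cell)

#' Space-group symbol
#' @param x a \linkS4class{Structure}
#' @return character Hermann-Mauguin symbol, or character(0)
#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))

#' @rdname spaceGroup
#' @export
setMethod("spaceGroup", "Structure", function(x) x@spaceGroup)

#' Particle positions
#' @param x a \linkS4class{ParticleSystem} or \linkS4class{FullereneTopology}
#' @return numeric matrix of Cartesian coordinates (Angstrom)
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname positions
#' @export
setMethod("positions", "ParticleSystem", function(x) x@positions)

#' @rdname positions
#' @export
setMethod("positions", "FullereneTopology", function(x) x@vertices)

#' Coordinates of a motif query
#' @param x a \linkS4class{MotifQuery}
#' @return coordinate matrix, 4 atoms (N, CA, C, O) per residue, segment-major
#' @export
setGeneric("motifCoords", function(x) standardGeneric("motifCoords"))

#' @rdname motifCoords
#' @export
setMethod("motifCoords", "MotifQuery", function(x) x@coords)

#' Segment table of a motif query
#' @param x a \linkS4class{MotifQuery}
#' @return data.frame with columns chain, start, end
#' @export
setGeneric("motifSegments", function(x) standardGeneric("motifSegments"))

#' @rdname motifSegments
#' @export
setMethod("motifSegments", "MotifQuery", function(x) x@segments)

#' Retained images of a lattice assembly
#' @param x a \linkS4class{LatticeAssembly}
#' @return list of images; each has op, shift, atoms, contacts
#' @export
setGeneric("latticeImages", function(x) standardGeneric("latticeImages"))

#' @rdname latticeImages
#' @export
setMethod("latticeImages", "LatticeAssembly", function(x) x@images)

#' @export
setMethod("show", "Structure", function(object) {
  at <- object@atoms
  cat(sprintf("Structure: %d atoms, %d chains",
              nrow(at), length(unique(at$chain))))
  if (length(object@cell) == 6)
    cat(sprintf(" | cell %.1f %.1f %.1f A", object@cell[1], object@cell[2],
                object@cell[3]))
  if (length(object@spaceGroup) == 1)
    cat(sprintf(" | %s", object@spaceGroup))
  cat("\n")
})

#' @export
setMethod("show", "FullereneTopology", function(object) {
  d <- object@edges
  bl <- sqrt(rowSums((object@vertices[d[, 1], ] - object@vertices[d[, 2], ])^2))
  cat(sprintf("C60 cage: 60 vertices, 90 edges (mean bond %.4f A), 32 faces\n",
              mean(bl)))
})

#' @export
setMethod("show", "LatticeAssembly", function(object) {
  cat(sprintf("LatticeAssembly: %d images retained (cutoff %.1f A, >= %d atoms)\n",
              length(object@images), object@cutoff, object@minAtoms))
})

#' @export
setMethod("show", "MotifQuery", function(object) {
  cat(sprintf("MotifQuery: %d segments, %d backbone atoms\n",
              nrow(object@segments), nrow(object@coords)))
})

#' @export
setMethod("show", "ParticleSystem", function(object) {
  cat(sprintf(
    "ParticleSystem: %d particles (%d decoupling, %d coupling), %s, T = %.2f K\n",
    nrow(object@positions), length(object@decoupleSet),
    length(object@coupleSet),
    if (length(object@box) == 3) sprintf("box %.0fx%.0fx%.0f A",
      object@box[1], object@box[2], object@box[3]) else "open boundary",
    object@temperature))
})

#' @export
setMethod("show", "AucScan", function(object) {
  cat(sprintf("AucScan: %d points, %g r.p.m., %g nm, %.2f K\n",
              length(object@radii), object@speed, object@wavelength,
              object@temperature))
})

#' @export
setMethod("show", "AssociationModel", function(object) {
  cat(sprintf("AssociationModel: base %g Da, scheme %s", object@baseMass,
              object@scheme))
  if (object@scheme == "self")
    cat(sprintf(" (Kd = %.3g M)", object@kd))
  cat("\n")
})
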