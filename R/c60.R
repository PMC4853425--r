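#' Build an idealized C60 cage (truncated icosahedron)
#'
#' Constructs Buckminsterfullerene as the Archimedean truncated icosahedron
#' with all 90 edges of identical length \code{bondLength}, centred at the
#' origin. This is the uniform-bond idealization used when a single
#' equilibrium carbon-carbon bond length (default 1.4392 Angstrom, the
#' experimental average over the two chemical bond classes) parameterizes the
#' cage. All 60 vertices are equidistant from the centroid at circumradius
#' (bondLength / 4) * sqrt(58 + 18 sqrt(5)).
#'
#' @param bondLength carbon-carbon bond length in Angstrom (> 0)
#' @return a \linkS4class{FullereneTopology}
#' @examples
#' c60 <- buildC60()
#' mean(fullereneBondLengths(c60))  # 1.4392
#' @export
buildC60 <- function(bondLength = 1.4392) {
  if (!is.numeric(bondLength) || length(bondLength) != 1 || bondLength <= 0)
    stop("bondLength must be a positive scalar")
  phi <- (1 + sqrt(5)) / 2
  ## vertex orbit of the truncated icosahedron with edge length 2:
  ## even (cyclic) permutations of three sign-varied seeds
  seeds <- rbind(c(0, 1, 3 * phi),
                 c(1, 2 + phi, 2 * phi),
                 c(2, 1 + 2 * phi, phi))
  verts <- NULL
  for (s in seq_len(nrow(seeds))) {
    base <- seeds[s, ]
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      v <- base * c(sx, sy, sz)
      for (perm in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)))
        verts <- rbind(verts, v[perm])
    }
  }
  verts <- unique(round(verts, 12))
  stopifnot(nrow(verts) == 60)
  verts <- verts * (bondLength / 2)

  d <- as.matrix(stats::dist(verts))
  dmin <- min(d[d > 0])
  edges <- which(upper.tri(d) & abs(d - dmin) < 1e-9 * max(1, dmin),
                 arr.ind = TRUE)
  edges <- cbind(as.integer(edges[, 1]), as.integer(edges[, 2]))
  stopifnot(nrow(edges) == 90)

  ## Faces from the parent icosahedron: pentagon centres point along
  ## icosahedron vertices, hexagon centres along icosahedron face centres.
  ico <- NULL
  for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
    v <- c(0, sy, sz * phi)
    for (perm in list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)))
      ico <- rbind(ico, v[perm])
  }
  ico <- unique(round(ico, 12))            # 12 icosahedron vertices
  hexc <- NULL
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    trio <- ico[c(i, j, k), ]
    dd <- c(sum((trio[1, ] - trio[2, ])^2), sum((trio[1, ] - trio[3, ])^2),
            sum((trio[2, ] - trio[3, ])^2))
    if (all(abs(dd - 4) < 1e-9)) hexc <- rbind(hexc, colMeans(trio))
  }
  stopifnot(nrow(hexc) == 20)

  faceRing <- function(centre, nsides) {
    u <- centre / sqrt(sum(centre^2))
    cosang <- verts %*% u / sqrt(rowSums(verts^2))
    idx <- order(-cosang)[seq_len(nsides)]
    ## order ring members by angle around the face normal
    pts <- verts[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    e1 <- pts[1, ] - ctr; e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ang <- atan2((pts - rep(ctr, each = nsides)) %*% e2,
                 (pts - rep(ctr, each = nsides)) %*% e1)
    as.integer(idx[order(ang)])
  }
  pentagons <- lapply(seq_len(12), function(i) faceRing(ico[i, ], 5L))
  hexagons <- lapply(seq_len(20), function(i) faceRing(hexc[i, ], 6L))

  new("FullereneTopology", vertices = verts, edges = edges,
      faces = c(pentagons, hexagons), centroid = colMeans(verts))
}

#' Bond lengths of a fullerene cage
#' @param x a \linkS4class{FullereneTopology}
#' @return numeric(90) edge lengths in Angstrom
#' @export
fullereneBondLengths <- function(x) {
  stopifnot(is(x, "FullereneTopology"))
  e <- x@edges
  sqrt(rowSums((x@vertices[e[, 1], ] - x@vertices[e[, 2], ])^2))
}

#' Convert a fullerene cage to a Structure
#'
#' Atoms are named C1..C60 with residue name \code{resname} so the cage can
#' be embedded in crystal models and selected by the centroid utilities.
#'
#' @param x a \linkS4class{FullereneTopology}
#' @param chain chain identifier
#' @param resno residue number
#' @param resname hetero-compound residue name
#' @return a \linkS4class{Structure}
#' @export
fullereneAsStructure <- function(x, chain = "X", resno = 1L,
                                 resname = "C60") {
  stopifnot(is(x, "FullereneTopology"))
  Structure(data.frame(chain = chain, resno = resno, resname = resname,
                       atom = paste0("C", 1:60), element = "C",
                       x = x@vertices[, 1], y = x@vertices[, 2],
                       z = x@vertices[, 3], stringsAsFactors = FALSE))
}
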