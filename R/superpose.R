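## Kabsch superposition and backbone motif extraction.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimizing the r.m.s.
#' deviation between \code{coordsA} and \code{R coordsB + t} over paired
#' points, via SVD of the cross-covariance with a determinant sign
#' correction so that det(R) = +1 (no reflection).
#'
#' @param coordsA n x 3 reference coordinates
#' @param coordsB n x 3 mobile coordinates
#' @return object of class \code{SuperpositionResult}: list with
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length 3),
#'   \code{rmsd} (Angstrom) and \code{atomCount}
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabschSuperpose(a, a)$rmsd  # 0
#' @export
kabschSuperpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!identical(dim(coordsA), dim(coordsB)))
    stop("coordinate sets must have identical dimensions")
  n <- nrow(coordsA)
  if (n < 3) stop("need at least 3 paired points")
  ## collinearity guard: rank of centred reference must exceed 1
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- coordsA - rep(ca, each = n)
  B <- coordsB - rep(cb, each = n)
  if (qr(A)$rank < 2) stop("reference points are collinear")
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- ca - as.vector(R %*% cb)
  fitB <- t(R %*% t(coordsB)) + rep(tvec, each = n)
  rmsd <- sqrt(sum((coordsA - fitB)^2) / n)
  structure(list(rotation = R, translation = tvec, rmsd = rmsd,
                 atomCount = n), class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: rmsd = %.4f A\n",
              x$atomCount, x$rmsd))
  invisible(x)
}

## minimal superposition SSD (sum of squared deviations), used by the motif
## search inner loop; same algebra as kabschSuperpose without building R
superposeSSD <- function(A, B) {
  n <- nrow(A)
  A <- A - rep(colMeans(A), each = n)
  B <- B - rep(colMeans(B), each = n)
  H <- t(B) %*% A
  sv <- svd(H)
  s <- sv$d
  if (det(sv$v %*% t(sv$u)) < 0) s[3] <- -s[3]
  max(0, sum(A^2) + sum(B^2) - 2 * sum(s))
}

.BACKBONE <- c("N", "CA", "C", "O")

#' Extract backbone coordinates of ordered motif segments
#'
#' Collects the N, CA, C, O backbone atoms of each requested residue range,
#' segment-major, atom order N, CA, C, O within a residue. Any residue
#' lacking a backbone atom raises an error naming the chain and residue.
#'
#' @param structure a \linkS4class{Structure}
#' @param segments data.frame with columns \code{chain}, \code{start},
#'   \code{end} (residue ranges, inclusive)
#' @return a \linkS4class{MotifQuery}
#' @examples
#' ## residues 2-9 on one chain contribute 8 x 4 = 32 atoms
#' @export
extractMotif <- function(structure, segments) {
  stopifnot(is(structure, "Structure"))
  if (is.null(segments) || nrow(segments) == 0)
    return(new("MotifQuery",
               segments = data.frame(chain = character(0), start = integer(0),
                                     end = integer(0)),
               coords = matrix(numeric(0), 0, 3), sequence = NA_character_))
  at <- atoms(structure)
  coords <- NULL
  seqc <- character(0)
  for (si in seq_len(nrow(segments))) {
    ch <- as.character(segments$chain[si])
    for (res in segments$start[si]:segments$end[si]) {
      rows <- at[at$chain == ch & at$resno == res, , drop = FALSE]
      for (an in .BACKBONE) {
        hit <- rows[rows$atom == an, , drop = FALSE]
        if (nrow(hit) != 1)
          stop(sprintf("incomplete residue: chain %s residue %d missing %s",
                       ch, res, an))
        coords <- rbind(coords, c(hit$x, hit$y, hit$z))
      }
      seqc <- c(seqc, threeToOne(rows$resname[1]))
    }
  }
  seg <- data.frame(chain = as.character(segments$chain),
                    start = as.integer(segments$start),
                    end = as.integer(segments$end),
                    stringsAsFactors = FALSE)
  new("MotifQuery", segments = seg, coords = coords,
      sequence = paste(seqc, collapse = ""))
}

threeToOne <- function(resname) {
  out <- suppressWarnings(bio3d::aa321(resname))
  ifelse(is.na(out) | out == "X", "X", out)
}
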