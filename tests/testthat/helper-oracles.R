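## Independent oracles and shared fixtures for the test suite.

## Brute-force lattice expansion: exhaustive operator x translation
## enumeration over [-2, 2]^3 with direct distance checks.
bruteForceLatticeCount <- function(structure, cutoff, minAtoms) {
  ops <- spaceGroupOperators(spaceGroup(structure))
  M <- fracToCart(cellParams(structure))
  xyz <- as.matrix(atoms(structure)[, c("x", "y", "z")])
  frac <- t(solve(M) %*% t(xyz))
  cnt <- 1L   # identity
  for (oi in seq_along(ops)) for (tx in -2:2) for (ty in -2:2)
    for (tz in -2:2) {
      if (oi == 1 && tx == 0 && ty == 0 && tz == 0) next
      fr2 <- t(ops[[oi]]$R %*% t(frac) + ops[[oi]]$t) +
        rep(c(tx, ty, tz), each = nrow(frac))
      cart <- t(M %*% t(fr2))
      natoms <- sum(apply(cart, 1, function(p)
        any(sqrt(colSums((t(xyz) - p)^2)) <= cutoff)))
      if (natoms >= minAtoms) cnt <- cnt + 1L
    }
  cnt
}

## Brute-force motif search with bio3d's superposition as the independent
## r.m.s.d. engine. Implements the same placement semantics as searchMotif:
## any segment-to-window assignment with matching lengths, residue-disjoint,
## symmetric window sets collapsed to the best representative.
bruteForceMotifSearch <- function(query, database, cutoff) {
  segs <- motifSegments(query)
  segLen <- segs$end - segs$start + 1
  qxyz <- as.vector(t(motifCoords(query)))
  out <- NULL
  for (tid in names(database)) {
    st <- database[[tid]]
    at <- atoms(st)
    bb <- at[at$atom %in% c("N", "CA", "C", "O"), ]
    windows <- list()
    for (ch in unique(bb$chain)) {
      sub <- bb[bb$chain == ch, ]
      resnos <- sort(unique(sub$resno))
      for (L in unique(segLen)) {
        for (s0 in resnos) {
          run <- s0:(s0 + L - 1)
          if (!all(run %in% resnos)) next
          coords <- NULL
          ok <- TRUE
          for (r in run) for (an in c("N", "CA", "C", "O")) {
            hit <- sub[sub$resno == r & sub$atom == an, ]
            if (nrow(hit) != 1) { ok <- FALSE; break }
            coords <- rbind(coords, c(hit$x, hit$y, hit$z))
          }
          if (ok)
            windows[[length(windows) + 1]] <-
              list(chain = ch, start = s0, len = L, coords = coords)
        }
      }
    }
    if (!length(windows)) next
    nseg <- length(segLen)
    pick <- function(si, chosen) {
      if (si > nseg) {
        tc <- do.call(rbind, lapply(chosen, `[[`, "coords"))
        fitted <- suppressWarnings(bio3d::fit.xyz(qxyz, as.vector(t(tc))))
        r <- sqrt(mean((qxyz - fitted)^2) * 3)
        if (r <= cutoff + 1e-9) {
          key <- paste(sort(sprintf("%s:%d:%d",
            vapply(chosen, `[[`, "", "chain"),
            vapply(chosen, `[[`, 0, "start"),
            vapply(chosen, `[[`, 0, "len"))), collapse = "+")
          out <<- rbind(out, data.frame(target = tid, rmsd = r, key = key))
        }
        return(invisible())
      }
      for (w in windows) {
        if (w$len != segLen[si]) next
        clash <- FALSE
        for (c0 in chosen)
          if (c0$chain == w$chain && w$start <= c0$start + c0$len - 1 &&
              c0$start <= w$start + w$len - 1) { clash <- TRUE; break }
        if (!clash) pick(si + 1, c(chosen, list(w)))
      }
      invisible()
    }
    pick(1, list())
  }
  if (is.null(out)) return(out)
  ## collapse symmetric duplicates per (target, window set)
  out$grp <- paste(out$target, out$key)
  out <- do.call(rbind, lapply(split(out, out$grp), function(g)
    g[which.min(g$rmsd), ]))
  out <- out[order(out$rmsd, out$target, out$key), ]
  rownames(out) <- NULL
  out
}

## four-chain fixture with the residue numbering of the binding motif
## (ranges 2-9 on two chains and 19-24 on the other two)
makeMotifHost <- function() {
  generateHelixBundle(nres = 26, sequence = "AYKLQESV")
}

## helical arrangement of point centroids whose consecutive centre-to-centre
## distances alternate d1 / d2 exactly (axial steps chosen to compensate the
## in-plane chord)
makeAlternatingChannel <- function(n = 8, d1 = 12, d2 = 17, radius = 8) {
  ang <- seq(0, by = 2 * pi / 6, length.out = n)
  chord <- 2 * radius * sin(pi / 6)
  dz <- sqrt(rep(c(d1, d2), length.out = n - 1)^2 - chord^2)
  z <- cumsum(c(0, dz))
  cbind(radius * cos(ang), radius * sin(ang), z)
}

## standard error helper
se <- function(x) stats::sd(x) / sqrt(length(x))
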