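## Disjoint-segment backbone-RMSD motif search with deduplication and
## sequence-logo construction. The search is exhaustive over all consistent
## placements, with an early-abort bound on the partial superposition SSD
## (the minimal SSD over a subset of atom pairs can never exceed the minimal
## SSD over a superset, so partial SSD > cutoff^2 * N_total prunes safely).

#' Search a backbone motif against a structure database
#'
#' Enumerates every placement of the query segments onto contiguous backbone
#' runs of matching length in the target structures (segments may map to any
#' chains, in any assignment consistent with the segment lengths; placements
#' must be residue-disjoint) and returns those whose full-backbone
#' (N, CA, C, O) optimal-superposition r.m.s.d. is at most \code{cutoff}.
#' Placements that use the same set of windows under the motif's internal
#' symmetry are collapsed to the lowest-rmsd representative of the canonical
#' window ordering. Results are sorted by ascending rmsd, ties broken by
#' (target id, first placement).
#'
#' @param query a \linkS4class{MotifQuery}
#' @param database a \linkS4class{Structure}, or a (preferably named) list of
#'   them; names are the target ids
#' @param cutoff backbone r.m.s.d. cutoff in Angstrom (> 0)
#' @return data.frame with columns \code{target}, \code{rmsd},
#'   \code{sequence}, \code{placement} (readable "chain:start:len+..."), and
#'   a list-column \code{placements} of per-segment (chain, start, len)
#'   data.frames
#' @export
searchMotif <- function(query, database, cutoff) {
  stopifnot(is(query, "MotifQuery"))
  if (nrow(query@coords) == 0) stop("query is empty")
  if (!is.numeric(cutoff) || cutoff < 0) stop("cutoff must be >= 0")
  if (is(database, "Structure")) database <- list(database)
  if (is.null(names(database)) || any(!nzchar(names(database))))
    names(database) <- sprintf("target%03d", seq_along(database))

  segLen <- query@segments$end - query@segments$start + 1
  nseg <- length(segLen)
  qcoords <- query@coords
  qoff <- c(0, cumsum(segLen * 4))   # atom offsets per segment
  ntot <- nrow(qcoords)

  rows <- list()
  for (tid in names(database)) {
    st <- database[[tid]]
    cand <- backboneWindows(st, unique(segLen))
    if (is.null(cand)) next
    hits <- placeSegments(qcoords, qoff, segLen, cand, cutoff, ntot)
    for (h in hits) {
      pl <- h$placements
      key <- paste(sort(sprintf("%s:%d:%d", pl$chain, pl$start, pl$len)),
                   collapse = "+")
      rows[[length(rows) + 1L]] <-
        list(target = tid, rmsd = h$rmsd, sequence = h$sequence,
             placement = paste(sprintf("%s:%d:%d", pl$chain, pl$start,
                                       pl$len), collapse = "+"),
             key = paste(tid, key), placements = pl)
    }
  }
  if (!length(rows))
    return(data.frame(target = character(0), rmsd = numeric(0),
                      sequence = character(0), placement = character(0)))
  df <- data.frame(target = vapply(rows, `[[`, "", "target"),
                   rmsd = vapply(rows, `[[`, 0, "rmsd"),
                   sequence = vapply(rows, `[[`, "", "sequence"),
                   placement = vapply(rows, `[[`, "", "placement"),
                   stringsAsFactors = FALSE)
  df$placements <- I(lapply(rows, `[[`, "placements"))
  key <- vapply(rows, `[[`, "", "key")
  ## collapse symmetric duplicates (same window set) to the best rmsd
  keep <- !logical(nrow(df))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    keep[idx[-which.min(df$rmsd[idx])]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$rmsd, df$target, df$placement), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Per-chain contiguous backbone runs; returns, for each needed window
## length, a list of candidate windows with prefetched coordinates.
backboneWindows <- function(structure, lengths) {
  at <- atoms(structure)
  bb <- at[at$atom %in% .BACKBONE, , drop = FALSE]
  if (!nrow(bb)) return(NULL)
  out <- list()
  for (ch in unique(bb$chain)) {
    sub <- bb[bb$chain == ch, , drop = FALSE]
    resnos <- sort(unique(sub$resno))
    complete <- vapply(resnos, function(r)
      all(.BACKBONE %in% sub$atom[sub$resno == r]), logical(1))
    resnos <- resnos[complete]
    if (!length(resnos)) next
    ## coordinates per residue in N, CA, C, O order
    coordOf <- lapply(resnos, function(r) {
      s <- sub[sub$resno == r, , drop = FALSE]
      as.matrix(s[match(.BACKBONE, s$atom), c("x", "y", "z")])
    })
    seqOf <- vapply(resnos, function(r)
      threeToOne(sub$resname[sub$resno == r][1]), "")
    ## contiguous runs
    runs <- split(seq_along(resnos), cumsum(c(1, diff(resnos) != 1)))
    for (run in runs) {
      rr <- resnos[run]
      for (L in lengths) {
        if (length(rr) < L) next
        for (s0 in seq_len(length(rr) - L + 1)) {
          ridx <- run[s0:(s0 + L - 1)]
          out[[length(out) + 1L]] <- list(
            chain = ch, start = rr[s0], len = L,
            coords = do.call(rbind, coordOf[ridx]),
            seq = paste(seqOf[ridx], collapse = ""))
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  out
}

## depth-first assembly of one window per query segment with SSD pruning
placeSegments <- function(qcoords, qoff, segLen, cand, cutoff, ntot) {
  nseg <- length(segLen)
  budget <- cutoff^2 * ntot
  hits <- list()
  candByLen <- split(cand, vapply(cand, `[[`, 0, "len"))

  recurse <- function(si, chosen, tcoords) {
    if (si > nseg) {
      ## fast trace-formula screen (absolute SSD error ~1e-10 from
      ## cancellation), then a numerically stable rmsd for survivors
      ssdFast <- superposeSSD(qcoords, tcoords)
      if (sqrt(ssdFast / ntot) > cutoff + 1e-6) return(invisible())
      ssd <- kabschSuperpose(qcoords, tcoords)$rmsd^2 * ntot
      if (ssd <= budget + 1e-12) {
        pl <- do.call(rbind, lapply(chosen, function(w)
          data.frame(chain = w$chain, start = w$start, len = w$len,
                     stringsAsFactors = FALSE)))
        hits[[length(hits) + 1L]] <<- list(
          rmsd = sqrt(ssd / ntot), placements = pl,
          sequence = paste(vapply(chosen, `[[`, "", "seq"), collapse = ""))
      }
      return(invisible())
    }
    pool <- candByLen[[as.character(segLen[si])]]
    if (is.null(pool)) return(invisible())
    for (w in pool) {
      ## disjointness within a chain
      clash <- FALSE
      for (c0 in chosen) {
        if (c0$chain == w$chain &&
            w$start <= c0$start + c0$len - 1 &&
            c0$start <= w$start + w$len - 1) { clash <- TRUE; break }
      }
      if (clash) next
      tc <- rbind(tcoords, w$coords)
      if (si >= 2) {  # partial bound only meaningful with >= 2 segments
        npart <- nrow(tc)
        ssd <- superposeSSD(qcoords[seq_len(npart), , drop = FALSE], tc)
        if (ssd > budget + 1e-12) next
      }
      recurse(si + 1, c(chosen, list(w)), tc)
    }
    invisible()
  }
  recurse(1L, list(), matrix(numeric(0), 0, 3))
  hits
}

#' Drop matches with duplicate sequences
#'
#' Among matches sharing an identical concatenated sequence, only the
#' lowest-rmsd one is retained; the order of the survivors is preserved.
#'
#' @param matches a match data.frame from \code{\link{searchMotif}}
#' @return filtered match data.frame
#' @export
dedupeMatches <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(matches)
  keep <- !logical(nrow(matches))
  for (s in unique(matches$sequence)) {
    idx <- which(matches$sequence == s)
    if (length(idx) > 1) keep[idx[-which.min(matches$rmsd[idx])]] <- FALSE
  }
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Per-position amino-acid frequencies of close matches
#'
#' Builds a sequence-logo frequency table from the deduplicated matches with
#' r.m.s.d. at or below \code{threshold} (default 0.3 Angstrom). Each column
#' is one query position; frequencies over the 20 standard amino acids sum
#' to 1 wherever at least one match contributes. Positions with no
#' contributing matches are all-NA and reported in the \code{empty}
#' attribute.
#'
#' @param matches a match data.frame from \code{\link{searchMotif}}
#' @param threshold r.m.s.d. inclusion threshold, Angstrom
#' @return 20 x P numeric matrix (rows named by amino acid), with
#'   attributes \code{n} (contributing matches) and \code{empty}
#' @export
buildLogo <- function(matches, threshold = 0.3) {
  matches <- dedupeMatches(matches)
  use <- matches[matches$rmsd <= threshold, , drop = FALSE]
  if (nrow(use) == 0) {
    out <- matrix(NA_real_, length(.AA1), 0,
                  dimnames = list(.AA1, NULL))
    attr(out, "n") <- 0L
    attr(out, "empty") <- integer(0)
    return(out)
  }
  P <- nchar(use$sequence[1])
  if (any(nchar(use$sequence) != P))
    stop("matches have inconsistent sequence lengths")
  freq <- matrix(0, length(.AA1), P, dimnames = list(.AA1, NULL))
  counts <- integer(P)
  for (s in use$sequence) {
    aa <- strsplit(s, "")[[1]]
    for (p in seq_len(P)) {
      ri <- match(aa[p], .AA1)
      if (!is.na(ri)) {
        freq[ri, p] <- freq[ri, p] + 1
        counts[p] <- counts[p] + 1L
      }
    }
  }
  empty <- which(counts == 0)
  for (p in seq_len(P)) {
    if (counts[p] > 0) freq[, p] <- freq[, p] / counts[p]
    else freq[, p] <- NA_real_
  }
  attr(freq, "n") <- nrow(use)
  attr(freq, "empty") <- empty
  freq
}
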