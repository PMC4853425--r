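## Reading and writing structures. File parsing is delegated to bio3d;
## this layer only maps to/from the Structure container.

#' Read a structure from a PDB or mmCIF file
#'
#' Parsing is delegated to \pkg{bio3d} (\code{read.pdb} / \code{read.cif});
#' hydrogens are kept as read. Residue insertion codes are not supported and
#' raise an error. Unit-cell parameters and the space-group symbol are taken
#' from the CRYST1 record when present.
#'
#' @param path path to a .pdb or .cif file
#' @return a \linkS4class{Structure}
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  at <- pdb$atom
  if (!is.null(at$insert) && any(nzchar(trimws(at$insert)) &
                                 !is.na(at$insert)))
    stop("residue insertion codes are not supported")
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resname = as.character(at$resid),
                      atom = as.character(at$elety),
                      element = elementFromRecord(at),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  cell <- numeric(0); sg <- character(0)
  cr <- extractCryst1(path, ext)
  if (!is.null(cr)) { cell <- cr$cell; sg <- cr$sg }
  Structure(atoms, cell = cell, spaceGroup = sg)
}

## bio3d drops the element column for some inputs; fall back on the first
## alphabetic character of the atom name (adequate for C/N/O/S backbones).
elementFromRecord <- function(at) {
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el <- trimws(el)
  miss <- is.na(el) | !nzchar(el)
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", trimws(at$elety[miss]))
    el[miss] <- substr(guess, 1, 1)
  }
  el
}

extractCryst1 <- function(path, ext) {
  if (ext %in% c("cif", "mmcif")) {
    ln <- readLines(path, warn = FALSE)
    g <- function(tag) {
      hit <- grep(paste0("^", tag, "\\s"), ln, value = TRUE)
      if (!length(hit)) return(NA)
      sub(paste0("^", tag, "\\s+"), "", hit[1])
    }
    cellv <- suppressWarnings(as.numeric(c(g("_cell.length_a"),
      g("_cell.length_b"), g("_cell.length_c"), g("_cell.angle_alpha"),
      g("_cell.angle_beta"), g("_cell.angle_gamma"))))
    sg <- g("_symmetry.space_group_name_H-M")
    if (all(is.finite(cellv)))
      return(list(cell = cellv,
                  sg = gsub("'", "", if (is.na(sg)) character(0) else sg)))
    return(NULL)
  }
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  l <- ln[1]
  cellv <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                        substr(l, 25, 33), substr(l, 34, 40),
                        substr(l, 41, 47), substr(l, 48, 54)))
  sg <- trimws(substr(l, 56, 66))
  if (!all(is.finite(cellv))) return(NULL)
  list(cell = cellv, sg = if (nzchar(sg)) sg else character(0))
}

#' Write a Structure (or lattice assembly) to a PDB file
#'
#' For a \linkS4class{LatticeAssembly}, each image is written with a distinct
#' chain identifier and a sidecar JSON file (\code{<path>.images.json}) maps
#' the new chain letters to (operator index, lattice translation, original
#' chain).
#'
#' @param x a \linkS4class{Structure} or \linkS4class{LatticeAssembly}
#' @param path output PDB path
#' @return invisibly, the path written
#' @export
writeStructurePDB <- function(x, path) {
  if (is(x, "LatticeAssembly")) return(writeAssemblyPDB(x, path))
  at <- atoms(x)
  writePdbAtoms(at, path, cell = cellParams(x), sg = spaceGroup(x))
  invisible(path)
}

writePdbAtoms <- function(at, path, cell = numeric(0), sg = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(cell) == 6) {
    sgs <- if (length(sg)) sg else "P 1"
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s", cell[1], cell[2],
      cell[3], cell[4], cell[5], cell[6], sgs), con)
  }
  nm <- ifelse(nchar(at$atom) < 4, sprintf(" %-3s", at$atom),
               sprintf("%-4s", at$atom))
  writeLines(sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)) %% 100000, nm, at$resname,
    substr(at$chain, 1, 1), at$resno, at$x, at$y, at$z, at$element), con)
  writeLines("END", con)
}

writeAssemblyPDB <- function(asm, path) {
  letters62 <- c(LETTERS, letters, 0:9)
  imgs <- latticeImages(asm)
  allAtoms <- NULL
  mapping <- list()
  li <- 0
  for (ii in seq_along(imgs)) {
    im <- imgs[[ii]]
    for (ch in unique(im$atoms$chain)) {
      li <- li + 1
      if (li > length(letters62)) stop("too many chains to encode in PDB")
      sub <- im$atoms[im$atoms$chain == ch, , drop = FALSE]
      mapping[[letters62[li]]] <- list(image = ii, op = im$op,
                                       shift = im$shift, chain = ch)
      sub$chain <- letters62[li]
      allAtoms <- rbind(allAtoms, sub)
    }
  }
  writePdbAtoms(allAtoms, path, cell = cellParams(asm@source),
                sg = spaceGroup(asm@source))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(mapping, paste0(path, ".images.json"),
                         auto_unbox = TRUE)
  invisible(path)
}
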