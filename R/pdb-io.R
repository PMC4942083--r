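## PDB coordinate I/O.  Parsing and record formatting delegate to bio3d;
## this layer adds record validation, the alternate-location policy,
## multi-MODEL bookkeeping and element inference.

.ELEMENTS_2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NI", "CU", "CO")

.inferElement <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% .ELEMENTS_2, two, substr(nm, 1, 1))
}

#' Read a PDB coordinate file
#'
#' Parses fixed-column ATOM/HETATM records; MODEL/ENDMDL blocks become the
#' models of the returned \linkS4class{StructureModel}.  HETATM records are
#' retained and flagged (waters and ions stay identifiable by residue name).
#' Alternate locations are resolved at parse time: for each
#' (chain, resseq, icode, name) the highest-occupancy location is kept, ties
#' going to altloc 'A' (blank preferred over lettered); the policy is
#' recorded in the model metadata.  Blank element fields are inferred from
#' the atom name.
#'
#' @param file path to a PDB file.
#' @return A \linkS4class{StructureModel}.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writePDB(makeToyChain(3), f)
#' readPDB(f)
#' @export
readPDB <- function(file) {
  if (!file.exists(file))
    stop("cannot open PDB file '", file, "'")
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  short <- isAtom & nchar(lines) < 54
  if (any(short))
    stop("PDB parse error: ATOM/HETATM record shorter than the coordinate ",
         "columns at line ", which(short)[1])
  if (!any(isAtom))
    stop("no ATOM/HETATM records found in '", file, "'")

  p <- bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- p$atom
  atoms <- data.frame(
    serial    = as.integer(a$eleno),
    name      = as.character(a$elety),
    altloc    = ifelse(is.na(a$alt), "", as.character(a$alt)),
    resname   = as.character(a$resid),
    chain     = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resseq    = as.integer(a$resno),
    icode     = ifelse(is.na(a$insert), "", as.character(a$insert)),
    occupancy = ifelse(is.na(a$o), 1, as.numeric(a$o)),
    bfactor   = ifelse(is.na(a$b), 0, as.numeric(a$b)),
    element   = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                       .inferElement(a$elety), trimws(as.character(a$elesy))),
    het       = a$type == "HETATM",
    stringsAsFactors = FALSE)

  # altloc policy: highest occupancy wins, ties to blank then 'A'
  ord <- order(atoms$chain, atoms$resseq, atoms$icode, atoms$name,
               -atoms$occupancy, atoms$altloc)
  key <- with(atoms, paste(chain, resseq, icode, name, sep = "\r"))
  keepSorted <- ord[!duplicated(key[ord])]
  keep <- sort(keepSorted)                       # restore file order

  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- bio3d::atom2xyz(keep)
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    mat <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
    colnames(mat) <- c("x", "y", "z")
    mat
  })

  new("StructureModel", atoms = atoms[keep, , drop = FALSE],
      coords = coords,
      altlocPolicy = "highest occupancy, ties to altloc 'A'",
      source = basename(file))
}

#' Write a StructureModel as a PDB file
#'
#' Standard fixed-column ATOM/HETATM records (coordinates to 3 decimals);
#' multi-model structures are wrapped in MODEL/ENDMDL blocks.
#'
#' @param model \linkS4class{StructureModel}.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writePDB <- function(model, file) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (any(a$resseq > 9999L))
    stop("residue number exceeds the 4-column PDB field (resseq > 9999)")
  if (any(abs(unlist(model@coords)) >= 1e4))
    stop("coordinate exceeds the 8-column PDB field")
  xyz <- do.call(rbind, lapply(model@coords, function(m) as.numeric(t(m))))
  bio3d::write.pdb(
    pdb = NULL, file = file, xyz = xyz,
    type = ifelse(a$het, "HETATM", "ATOM"),
    eleno = seq_len(nrow(a)), elety = a$name,
    resid = a$resname, chain = ifelse(nzchar(a$chain), a$chain, " "),
    resno = a$resseq,
    insert = ifelse(nzchar(a$icode), a$icode, NA),
    alt = ifelse(nzchar(a$altloc), a$altloc, NA),
    o = a$occupancy, b = a$bfactor, elesy = a$element)
  invisible(file)
}

#' Assemble a StructureModel from an atom table and coordinates
#'
#' Programmatic constructor used by the synthetic generators and tests.
#'
#' @param atoms data.frame with (at least) name, resname, chain, resseq
#'   columns; missing bookkeeping columns are filled with defaults.
#' @param coords N x 3 matrix, or list of N x 3 matrices for a multi-model
#'   structure.
#' @param source source label.
#' @return A \linkS4class{StructureModel}.
#' @export
structureModel <- function(atoms, coords, source = "constructed") {
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); colnames(m) <- c("x", "y", "z"); m
  })
  n <- nrow(atoms)
  defaults <- list(serial = seq_len(n), altloc = "", icode = "",
                   occupancy = 1, bfactor = 0, het = FALSE)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep_len(defaults[[col]], n)
  if (is.null(atoms$element)) atoms$element <- .inferElement(atoms$name)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resseq <- as.integer(atoms$resseq)
  cols <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "occupancy", "bfactor", "element", "het")
  new("StructureModel", atoms = atoms[, cols], coords = coords,
      altlocPolicy = "as constructed", source = source)
}
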