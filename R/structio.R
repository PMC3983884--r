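#' @useDynLib c2s, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd median rnorm runif setNames
NULL

# ---- Structure data model ------------------------------------------------

#' Construct a Structure object
#'
#' A `Structure` is the hierarchical chain/residue/atom model used by every
#' stage of the pipeline. It wraps a flat atom table (one row per heavy atom)
#' plus free-form provenance metadata. Chain order in the table defines the
#' concatenation order used by contact maps; the "concatenated index" of a
#' residue is its 1-based position when all chains are laid end to end.
#'
#' @param atoms data.frame with columns `chain` (single-character id),
#'   `resno` (integer residue number, 1-based within chain), `resname`
#'   (3-letter residue code), `atom` (atom name, e.g. "CA"), `element`
#'   (element symbol), `x`, `y`, `z` (coordinates, Angstrom), and optionally
#'   `occ`, `b`.
#' @param metadata named list of provenance (source file, seed, ...).
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  req <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("Structure must contain at least one atom")
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  # sort residues by resno within chain, keeping chain order of first appearance
  ord_chain <- match(atoms$chain, unique(atoms$chain))
  atoms <- atoms[order(ord_chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc) length(unique(x$atoms$resno[x$atoms$chain == cc])), 1L)
  cat("Structure:", length(ch), "chain(s),", sum(nres), "residues,",
      nrow(x$atoms), "atoms\n")
  cat("  chains:", paste(sprintf("%s(%d)", ch, nres), collapse = " "), "\n")
  invisible(x)
}

#' Chain identifiers in concatenation (file) order
#' @param s Structure
#' @return character vector
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Residue table in concatenated-index order
#'
#' One row per residue: chain, resno, resname and the 1..L concatenated index.
#' @param s Structure
#' @return data.frame
#' @export
residue_table <- function(s) {
  key <- paste(s$atoms$chain, s$atoms$resno, sep = "|")
  first <- !duplicated(key)
  out <- data.frame(chain = s$atoms$chain[first], resno = s$atoms$resno[first],
                    resname = s$atoms$resname[first], stringsAsFactors = FALSE)
  out$index <- seq_len(nrow(out))
  out
}

#' Number of residues in a Structure
#' @param s Structure
#' @return integer
#' @export
n_residues <- function(s) sum(!duplicated(paste(s$atoms$chain, s$atoms$resno)))

#' Per-chain residue sequences (3-letter codes)
#' @param s Structure
#' @return named list of character vectors, one per chain
#' @export
structure_sequence <- function(s) {
  rt <- residue_table(s)
  lapply(setNames(nm = chain_ids(s)), function(cc) rt$resname[rt$chain == cc])
}

#' Extract one chain as a single-chain Structure
#' @param s Structure
#' @param chain chain id
#' @return Structure
#' @export
get_chain <- function(s, chain) {
  if (!chain %in% chain_ids(s)) stop("chain '", chain, "' not present")
  new_structure(s$atoms[s$atoms$chain == chain, , drop = FALSE], s$metadata)
}

#' Coordinate matrix of a Structure
#' @param s Structure
#' @return n_atoms x 3 numeric matrix (no dimnames)
#' @export
coords <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

#' Replace the coordinates of a Structure
#' @param s Structure
#' @param xyz n_atoms x 3 matrix
#' @return Structure
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# ---- PDB I/O (bio3d-backed) ----------------------------------------------

.standard_aa <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                  "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
                  "MSE","UNK")

#' Read a protein Structure from a PDB file
#'
#' Heavy atoms of protein ATOM records only: hydrogens, waters, ions and
#' HETATM records are dropped; alternate locations resolve to the
#' highest-occupancy conformer.
#'
#' @param path PDB file path
#' @param model model number to read (default 1)
#' @param chains optional character vector restricting to these chain ids
#' @return Structure
#' @export
read_pdb <- function(path, model = 1L, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model > nmod) stop("model ", model, " not present (file has ", nmod, ")")
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at <- at[at$type == "ATOM" & at$resid %in% .standard_aa, , drop = FALSE]
  if (!nrow(at)) stop("no protein ATOM records in ", path)
  # drop hydrogens by element symbol (fall back to name heuristics)
  elt <- toupper(trimws(at$elesy))
  elt[is.na(elt) | elt == ""] <- toupper(substr(trimws(at$elety[is.na(elt) | elt == ""]), 1, 1))
  at <- at[!elt %in% c("H", "D"), , drop = FALSE]
  if (!is.null(chains)) {
    absent <- setdiff(chains, unique(at$chain))
    if (length(absent)) stop("requested chain(s) absent: ", paste(absent, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  # altloc: keep highest occupancy per (chain, resno, insert, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) i[which.max(occ[i])]))
    at <- at[sort(keep), , drop = FALSE]
  }
  elt <- toupper(trimws(at$elesy))
  elt[is.na(elt) | elt == ""] <- toupper(substr(trimws(at$elety), 1, 1))[is.na(elt) | elt == ""]
  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      atom = trimws(at$elety), element = elt,
                      x = at$x, y = at$y, z = at$z,
                      occ = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  new_structure(atoms, metadata = list(source = path, model = as.integer(model)))
}

#' Write a Structure to a PDB file
#'
#' Fixed-width ATOM records with TER after each chain; coordinates to
#' 3 decimals (the PDB column definition).
#'
#' @param s Structure
#' @param path output file
#' @return invisibly, `path`
#' @export
write_pdb <- function(s, path) {
  at <- s$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$atom, chain = at$chain,
                   o = at$occ, b = at$b, elesy = at$element)
  invisible(path)
}

# ---- CaTrace --------------------------------------------------------------

#' Construct a CaTrace
#'
#' Ordered C-alpha coordinates with chain-break bookkeeping. `chain_breaks`
#' holds indices i such that no virtual bond constraint applies between
#' points i and i+1.
#'
#' @param xyz L x 3 matrix of coordinates (Angstrom)
#' @param chain_breaks integer vector of break positions (possibly empty)
#' @param provenance named list (seed, sweeps, satisfaction, ...)
#' @return object of class `CaTrace`
#' @export
new_ca_trace <- function(xyz, chain_breaks = integer(0), provenance = list()) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, chain_breaks = as.integer(sort(chain_breaks)),
                 provenance = provenance), class = "CaTrace")
}

#' @export
print.CaTrace <- function(x, ...) {
  cat("CaTrace:", nrow(x$xyz), "points,", length(x$chain_breaks), "chain break(s)\n")
  if (!is.null(x$provenance$satisfaction))
    cat("  satisfaction:", format(x$provenance$satisfaction, digits = 4), "\n")
  invisible(x)
}

#' Length of a CaTrace
#' @param x CaTrace
#' @param ... ignored
#' @export
length.CaTrace <- function(x) nrow(x$xyz)

#' Extract the C-alpha trace of a Structure
#'
#' Points come out in concatenated-index order; chain boundaries are recorded
#' as chain breaks.
#'
#' @param s Structure
#' @return CaTrace
#' @export
extract_ca_trace <- function(s) {
  rt <- residue_table(s)
  at <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
  key_rt <- paste(rt$chain, rt$resno)
  key_ca <- paste(at$chain, at$resno)
  hit <- match(key_rt, key_ca)
  if (anyNA(hit)) {
    bad <- rt[is.na(hit), ][1, ]
    stop("residue ", bad$resname, " ", bad$resno, " chain ", bad$chain, " lacks a CA atom")
  }
  xyz <- as.matrix(at[hit, c("x", "y", "z")])
  nper <- table(factor(rt$chain, levels = chain_ids(s)))
  cb <- cumsum(as.integer(nper))
  cb <- cb[-length(cb)]
  new_ca_trace(xyz, chain_breaks = cb,
               provenance = list(source = s$metadata$source))
}

# ---- small geometry helpers (shared) --------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 3-vectors
#' @return signed angle in degrees, in (-180, 180]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  -atan2(y, x) * 180 / pi
}
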