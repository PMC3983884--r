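# Ternary contact maps: 1 = contact, 0 = non-contact, -1 = unknown.
# The diagonal is self-contact (always 1) and excluded from every count,
# reduction and flip. Symmetry is structural: perturbations act on the upper
# triangle and are mirrored.

#' Construct a ContactMap
#'
#' @param M L x L integer matrix over \{1, 0, -1\}, symmetric, diagonal 1
#' @param chain_layout data.frame with columns `chain`, `length` giving the
#'   concatenation order of real chains (dummy positions excluded)
#' @param dummy_mask logical length-L vector marking inserted dummy positions
#' @param meta named list of derivation parameters (threshold, atom mode, ...)
#' @return object of class `ContactMap`
#' @export
new_contact_map <- function(M, chain_layout = NULL, dummy_mask = NULL, meta = list()) {
  M <- as.matrix(M)
  L <- nrow(M)
  if (ncol(M) != L) stop("contact map must be square")
  storage.mode(M) <- "integer"
  if (!all(M %in% c(-1L, 0L, 1L))) stop("contact map entries must be in {1, 0, -1}")
  if (!isTRUE(all(M == t(M)))) stop("contact map must be symmetric")
  diag(M) <- 1L
  if (is.null(dummy_mask)) dummy_mask <- rep(FALSE, L)
  if (length(dummy_mask) != L) stop("dummy_mask length mismatch")
  if (is.null(chain_layout))
    chain_layout <- data.frame(chain = "A", length = L - sum(dummy_mask),
                               stringsAsFactors = FALSE)
  if (sum(chain_layout$length) + sum(dummy_mask) != L)
    stop("chain_layout lengths + dummy count must equal L")
  dimnames(M) <- NULL
  structure(list(L = L, M = M, chain_layout = chain_layout,
                 dummy_mask = dummy_mask, meta = meta), class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  ut <- x$M[upper.tri(x$M)]
  cat("ContactMap: L =", x$L,
      sprintf("(%d contacts, %d non-contacts, %d unknown in upper triangle)\n",
              sum(ut == 1), sum(ut == 0), sum(ut == -1)))
  cat("  chains:", paste(sprintf("%s(%d)", x$chain_layout$chain,
                                 x$chain_layout$length), collapse = " "),
      if (any(x$dummy_mask)) sprintf("+ %d dummy", sum(x$dummy_mask)) else "", "\n")
  invisible(x)
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a contact map from a structure
#'
#' A pair of residues is in contact when the distance between their
#' representative atoms is at or below `threshold`. All sequence separations
#' count; the diagonal is self-contact.
#'
#' @param s Structure
#' @param threshold contact distance threshold, Angstrom (default 8)
#' @param atom_mode "CA" or "CB" (CB falls back to CA for glycine or when
#'   absent)
#' @return ContactMap with no unknown entries
#' @export
derive_cmap <- function(s, threshold = 8, atom_mode = c("CA", "CB")) {
  atom_mode <- match.arg(atom_mode)
  if (threshold <= 0) stop("threshold must be positive")
  rt <- residue_table(s)
  at <- s$atoms
  pick <- function(cc, rn) {
    rows <- at[at$chain == cc & at$resno == rn, , drop = FALSE]
    r <- if (atom_mode == "CB") rows[rows$atom == "CB", , drop = FALSE] else rows[0, ]
    if (!nrow(r)) r <- rows[rows$atom == "CA", , drop = FALSE]
    if (!nrow(r)) stop("residue ", rn, " chain ", cc, " lacks ", atom_mode, "/CA atom")
    as.numeric(r[1, c("x", "y", "z")])
  }
  P <- t(mapply(pick, rt$chain, rt$resno))
  D <- as.matrix(stats::dist(P))
  M <- ifelse(D <= threshold, 1L, 0L)
  diag(M) <- 1L
  ch <- chain_ids(s)
  layout <- data.frame(chain = ch,
                       length = vapply(ch, function(cc) sum(rt$chain == cc), 1L),
                       stringsAsFactors = FALSE)
  new_contact_map(M, chain_layout = layout,
                  meta = list(threshold = threshold, atom_mode = atom_mode))
}

#' Contact density
#'
#' CD = (1/L) * sum_i c_i, where c_i counts the off-diagonal contacts
#' (entries equal to 1) that residue i participates in. Unknown entries do
#' not count; dummy positions are excluded.
#'
#' @param cmap ContactMap
#' @return scalar contacts/residue
#' @export
contact_density <- function(cmap) {
  keep <- !cmap$dummy_mask
  M <- cmap$M[keep, keep, drop = FALSE]
  L <- nrow(M)
  if (!L) stop("empty contact map")
  ci <- rowSums(M == 1L) - 1  # drop the diagonal self-contact
  sum(ci) / L
}

#' Erase non-contact information
#'
#' Every known non-contact (0) becomes unknown (-1); contacts are kept.
#' Models built from such maps lack the repulsive information that keeps
#' structures from collapsing.
#'
#' @param cmap ContactMap
#' @return ContactMap
#' @export
positive_only <- function(cmap) {
  M <- cmap$M
  M[M == 0L] <- -1L
  out <- cmap
  out$M <- M
  out$meta$perturbation <- c(out$meta$perturbation, list(list(kind = "positive_only")))
  out
}

# indices (i < j) of upper-triangle entries of an L x L matrix
.ut_index <- function(L) which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)

.apply_pairs <- function(M, pairs, value) {
  M[pairs] <- value
  M[pairs[, c(2, 1), drop = FALSE]] <- value
  M
}

#' Randomly reduce a contact map
#'
#' A fraction (1 - `fraction`) of the known off-diagonal entries (both
#' contacts and non-contacts), chosen uniformly without replacement from the
#' upper triangle, is set to unknown (-1) and mirrored.
#'
#' @param cmap ContactMap
#' @param fraction fraction of known entries retained, in `[0, 1]`
#' @param seed integer RNG seed (reproducible)
#' @return ContactMap
#' @export
reduce_cmap <- function(cmap, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  ut <- .ut_index(cmap$L)
  known <- ut[cmap$M[ut] != -1L, , drop = FALSE]
  K <- nrow(known)
  ndrop <- as.integer(round_half_away((1 - fraction) * K))
  out <- cmap
  if (ndrop > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    idx <- sample.int(K, ndrop)
    out$M <- .apply_pairs(cmap$M, known[idx, , drop = FALSE], -1L)
  }
  out$meta$perturbation <- c(out$meta$perturbation,
                             list(list(kind = "reduce", fraction = fraction, seed = seed)))
  out
}

# Seed-scoped RNG: set the seed, return a restorer for the previous state.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Inject errors into a contact map
#'
#' `flip_ones` flips a fraction (1 - `fraction_correct`) of the contacts to
#' non-contacts. `flip_both` flips that fraction of all known entries to their
#' opposite label (1 <-> 0). Selection is uniform over the upper triangle and
#' mirrored.
#'
#' @param cmap ContactMap
#' @param fraction_correct fraction of entries left correct, in `[0, 1]`
#' @param mode "flip_ones" (default) or "flip_both"
#' @param seed integer RNG seed
#' @return ContactMap
#' @export
inject_errors <- function(cmap, fraction_correct, mode = c("flip_ones", "flip_both"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (fraction_correct < 0 || fraction_correct > 1)
    stop("fraction_correct must be in [0, 1]")
  ut <- .ut_index(cmap$L)
  pool <- if (mode == "flip_ones") ut[cmap$M[ut] == 1L, , drop = FALSE]
          else ut[cmap$M[ut] != -1L, , drop = FALSE]
  K <- nrow(pool)
  nflip <- as.integer(round_half_away((1 - fraction_correct) * K))
  out <- cmap
  if (nflip > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    idx <- sample.int(K, nflip)
    sel <- pool[idx, , drop = FALSE]
    out$M <- .apply_pairs(cmap$M, sel, 1L - cmap$M[sel])
  }
  out$meta$perturbation <- c(out$meta$perturbation,
                             list(list(kind = "erroneous", fraction_correct = fraction_correct,
                                       mode = mode, seed = seed)))
  out
}

#' Insert dummy amino-acid loops between chains
#'
#' In the concatenated map of a multimer, the C-terminus of one chain and the
#' N-terminus of the next sit in adjacent rows although they can be far apart
#' in space. A block of `loop_length` all-unknown rows/columns is inserted at
#' each chain junction so the trace reconstructor, which bonds consecutive
#' rows, does not pull the termini together. The loops are trimmed from the
#' trace after reconstruction ([trim_dummy()]).
#'
#' @param cmap ContactMap without dummies
#' @param loop_length number of dummy positions per junction (default 15)
#' @return list with elements `cmap` (augmented ContactMap) and `mapping`
#'   (integer vector: original concatenated index -> new index)
#' @export
insert_dummy_loops <- function(cmap, loop_length = 15L) {
  if (any(cmap$dummy_mask)) stop("map already contains dummy positions")
  nch <- nrow(cmap$chain_layout)
  if (nch < 2) {
    warning("single-chain map: no dummy loops inserted")
    return(list(cmap = cmap, mapping = seq_len(cmap$L)))
  }
  if (loop_length < 1) stop("loop_length must be >= 1")
  lens <- cmap$chain_layout$length
  L <- cmap$L
  Lp <- L + loop_length * (nch - 1L)
  # new index of each original position
  ends <- cumsum(lens)
  shift <- rep(0L, L)
  for (k in seq_len(nch - 1L)) shift[(ends[k] + 1L):L] <- shift[(ends[k] + 1L):L] + loop_length
  mapping <- seq_len(L) + shift
  Mp <- matrix(-1L, Lp, Lp)
  Mp[mapping, mapping] <- cmap$M
  diag(Mp) <- 1L
  dmask <- rep(TRUE, Lp)
  dmask[mapping] <- FALSE
  out <- new_contact_map(Mp, chain_layout = cmap$chain_layout, dummy_mask = dmask,
                         meta = c(cmap$meta, list(loop_length = loop_length)))
  list(cmap = out, mapping = mapping)
}

#' Read a contact map from file
#'
#' `matrix` format: L whitespace-separated lines of L entries in \{1, 0, -1\}.
#' `rr_list` format: CASP-RR-style lines "i j label" (1-based, upper
#' triangle); unlisted pairs default to unknown and L is taken from the
#' largest index unless given.
#'
#' @param path input file
#' @param format "matrix" or "rr_list"
#' @param L map size (required information for rr_list if larger than the
#'   largest listed index)
#' @return ContactMap
#' @export
read_cmap <- function(path, format = c("matrix", "rr_list"), L = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    M <- as.matrix(utils::read.table(path, header = FALSE))
    if (nrow(M) != ncol(M)) stop("non-square matrix in ", path)
    if (!all(M %in% c(-1, 0, 1))) stop("entries outside {1, 0, -1} in ", path)
    if (!isTRUE(all(M == t(M)))) stop("asymmetric contact matrix in ", path)
    new_contact_map(M)
  } else {
    tb <- utils::read.table(path, header = FALSE)
    if (ncol(tb) < 3) stop("rr_list needs 'i j label' triplets")
    i <- as.integer(tb[[1]]); j <- as.integer(tb[[2]]); lab <- as.integer(tb[[3]])
    if (!all(lab %in% c(-1L, 0L, 1L))) stop("labels outside {1, 0, -1}")
    n <- if (is.null(L)) max(i, j) else as.integer(L)
    M <- matrix(-1L, n, n)
    M[cbind(i, j)] <- lab
    M[cbind(j, i)] <- lab
    diag(M) <- 1L
    new_contact_map(M)
  }
}

#' Write a contact map to file
#' @param cmap ContactMap
#' @param path output file
#' @param format "matrix" or "rr_list" (rr_list writes known upper-triangle
#'   entries only)
#' @return invisibly, `path`
#' @export
write_cmap <- function(cmap, path, format = c("matrix", "rr_list")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(cmap$M, path, row.names = FALSE, col.names = FALSE)
  } else {
    ut <- .ut_index(cmap$L)
    known <- ut[cmap$M[ut] != -1L, , drop = FALSE]
    df <- data.frame(i = known[, 1], j = known[, 2], label = cmap$M[known])
    utils::write.table(df, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
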