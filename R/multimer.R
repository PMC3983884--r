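# Multimer-specific steps: dummy-loop trimming, channel-axis alignment,
# C4 symmetric projection and averaged-subunit channel generation.

#' Symmetry frame of a cyclic assembly
#'
#' @param axis 3-vector, normalized internally
#' @param center 3-vector, Angstrom
#' @param order cyclic order n (4 for a KcsA-like channel)
#' @return list of class `SymmetryFrame`
#' @export
symmetry_frame <- function(axis = c(0, 0, 1), center = c(0, 0, 0), order = 4L) {
  if (order < 2) stop("symmetry order must be >= 2")
  structure(list(axis = unitv(axis), center = as.numeric(center),
                 order = as.integer(order)), class = "SymmetryFrame")
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues formula; the axis is normalized internally.
#'
#' @param axis 3-vector
#' @param angle radians
#' @return 3 x 3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Trim dummy loops from a reconstructed trace
#'
#' Inverse of the bookkeeping of [insert_dummy_loops()]: dummy points are
#' removed, real-residue order is preserved, and a chain break is recorded
#' wherever a loop was excised.
#'
#' @param trace CaTrace built from a dummy-augmented map
#' @param mapping integer vector from [insert_dummy_loops()] (original
#'   index -> augmented index)
#' @return CaTrace of the real residues only
#' @export
trim_dummy <- function(trace, mapping) {
  L <- nrow(trace$xyz)
  if (max(mapping) > L) stop("mapping exceeds trace length")
  xyz <- trace$xyz[mapping, , drop = FALSE]
  gaps <- which(diff(mapping) > 1L)
  new_ca_trace(xyz, chain_breaks = gaps, provenance = trace$provenance)
}

# chain centroids (CA atoms if present, else all atoms)
.chain_centroids <- function(s) {
  t(vapply(chain_ids(s), function(cc) {
    a <- s$atoms[s$atoms$chain == cc, , drop = FALSE]
    ca <- a[a$atom == "CA", , drop = FALSE]
    if (nrow(ca)) a <- ca
    c(mean(a$x), mean(a$y), mean(a$z))
  }, numeric(3)))
}

#' Align the channel axis with z
#'
#' With a reference structure (assumed z-aligned) the model is superposed
#' onto it by least-squares rigid fit on shared CA atoms. Without one, the
#' pore axis is estimated as the normal of the best-fit plane through the
#' chain centroids (>= 3 chains required), rotated onto z, and the centroid
#' mean is moved to the origin.
#'
#' @param s Structure with >= 2 chains (or any structure plus `reference`)
#' @param reference optional z-aligned Structure to superpose onto
#' @return transformed Structure
#' @export
align_axis_to_z <- function(s, reference = NULL) {
  if (!is.null(reference)) {
    pr <- pair_coords(s, reference, atoms = "CA")
    fit <- kabsch_superpose(pr$mobile, pr$target)
    xyz <- coords(s) %*% t(fit$rotation)
    xyz <- sweep(xyz, 2, fit$translation, "+")
    return(set_coords(s, xyz))
  }
  cent <- .chain_centroids(s)
  if (nrow(cent) < 3) stop("axis estimation needs >= 3 chains or a reference")
  cmean <- colMeans(cent)
  cc <- sweep(cent, 2, cmean)
  sv <- svd(cc)
  if (sv$d[2] < 1e-6) stop("degenerate chain-centroid geometry (collinear)")
  axis <- sv$v[, 3]
  if (axis[3] < 0) axis <- -axis
  v <- cross3(axis, c(0, 0, 1))
  s2 <- vnorm(v)
  R <- if (s2 < 1e-12) diag(3) else
    rotation_about_axis(v / s2, atan2(s2, sum(axis * c(0, 0, 1))))
  xyz <- sweep(coords(s), 2, cmean) %*% t(R)
  set_coords(s, xyz)
}

#' Project a subunit n times about a symmetry axis
#'
#' Copies of the single-chain subunit rotated by k*360/n degrees about the
#' frame axis, k = 0..n-1, labelled A, B, C, ...
#'
#' @param subunit single-chain Structure
#' @param frame [symmetry_frame()]
#' @return Structure with `frame$order` chains, exactly Cn-symmetric
#' @export
c_n_project <- function(subunit, frame) {
  if (length(chain_ids(subunit)) != 1) stop("subunit must be a single chain")
  n <- frame$order
  pieces <- vector("list", n)
  base <- sweep(coords(subunit), 2, frame$center)
  for (k in seq_len(n)) {
    R <- rotation_about_axis(frame$axis, 2 * pi * (k - 1) / n)
    at <- subunit$atoms
    xyz <- sweep(base %*% t(R), 2, frame$center, "+")
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at$chain <- LETTERS[k]
    pieces[[k]] <- at
  }
  new_structure(do.call(rbind, pieces),
                metadata = c(subunit$metadata, list(symmetry = paste0("C", n))))
}

#' Average superposed subunits
#'
#' Each subunit is superposed onto the first (least-squares rigid fit on all
#' shared atoms) and coordinates are averaged atom-wise.
#'
#' @param subunits list of single-chain Structures with identical sequences
#'   and atom sets
#' @return Structure (the averaged subunit, in the first subunit's frame)
#' @export
average_subunit <- function(subunits) {
  ref <- subunits[[1]]
  key <- function(s) paste(s$atoms$resno, s$atoms$atom)
  acc <- coords(ref)
  for (k in seq_along(subunits)[-1]) {
    s <- subunits[[k]]
    if (!identical(key(s), key(ref))) stop("subunit atom sets differ")
    fit <- kabsch_superpose(coords(s), coords(ref))
    acc <- acc + sweep(coords(s) %*% t(fit$rotation), 2, fit$translation, "+")
  }
  set_coords(ref, acc / length(subunits))
}

#' Estimate the symmetry frame of an assembled multimer
#'
#' The cyclic-symmetry transform is estimated by least-squares superposition
#' of each chain onto the next (wrapping around): the averaged rotation axis
#' of those fits is the pore axis, and the rotation's fixed point (solved by
#' pseudo-inverse of `I - R`, which is singular along the axis) gives the
#' center. Falls back to the normal of the best-fit plane through the chain
#' centroids when chains do not share an atom set.
#'
#' @param s Structure with `order` chains
#' @param order symmetry order
#' @return SymmetryFrame
#' @export
estimate_symmetry_frame <- function(s, order = 4L) {
  ch <- chain_ids(s)
  if (length(ch) < 3) stop("frame estimation needs >= 3 chains")
  cent <- .chain_centroids(s)
  cmean <- colMeans(cent)
  key <- function(cc) {
    a <- s$atoms[s$atoms$chain == cc, ]
    paste(a$resno, a$atom)
  }
  same_atoms <- all(vapply(ch[-1], function(cc) identical(key(cc), key(ch[1])), TRUE))
  if (!same_atoms) {
    sv <- svd(sweep(cent, 2, cmean))
    axis <- sv$v[, 3]
    if (axis[3] < 0) axis <- -axis
    return(symmetry_frame(axis = axis, center = cmean, order = order))
  }
  axes <- NULL; centers <- NULL
  for (k in seq_along(ch)) {
    k2 <- if (k == length(ch)) 1L else k + 1L
    A <- coords(get_chain(s, ch[k])); B <- coords(get_chain(s, ch[k2]))
    fit <- kabsch_superpose(A, B)
    R <- fit$rotation
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (vnorm(ax) < 1e-8) next  # ~180-degree rotation, skip
    ax <- unitv(ax)
    # fixed point of x -> R x + t, least squares through the pseudo-inverse
    sv <- svd(diag(3) - R)
    dinv <- ifelse(sv$d > 1e-6, 1 / sv$d, 0)
    cc <- sv$v %*% (dinv * (t(sv$u) %*% fit$translation))
    # pin the free axial component to the centroid plane
    cc <- cc + sum((cmean - cc) * ax) * ax
    if (!is.null(axes) && sum(ax * axes[1, ]) < 0) ax <- -ax
    axes <- rbind(axes, ax)
    centers <- rbind(centers, as.numeric(cc))
  }
  if (is.null(axes)) stop("degenerate chain geometry: no rotation axis found")
  axis <- unitv(colMeans(axes))
  if (axis[3] < 0) axis <- -axis
  symmetry_frame(axis = axis, center = colMeans(centers), order = order)
}

#' Assemble symmetric channels from per-chain models
#'
#' Each subunit is projected `order` times about the frame axis, giving
#' `order` symmetric channels; one more comes from the averaged subunit.
#' Every output is z-aligned (the frame axis is rotated onto z first).
#'
#' @param per_chain_models list of single-chain Structures, length =
#'   `frame$order`
#' @param frame [symmetry_frame()]
#' @return list of `order + 1` Structures
#' @export
assemble_channels <- function(per_chain_models, frame) {
  n <- frame$order
  if (length(per_chain_models) != n)
    stop("need exactly ", n, " per-chain models")
  # move into the frame where axis = z, center = origin
  v <- cross3(frame$axis, c(0, 0, 1))
  s2 <- vnorm(v)
  R <- if (s2 < 1e-12) diag(3) else
    rotation_about_axis(v / s2, atan2(s2, frame$axis[3]))
  to_z <- function(s) set_coords(s, sweep(coords(s), 2, frame$center) %*% t(R))
  zframe <- symmetry_frame(order = n)
  subs <- lapply(per_chain_models, to_z)
  out <- lapply(subs, c_n_project, frame = zframe)
  c(out, list(c_n_project(average_subunit(subs), zframe)))
}

#' Symmetry-preserving side-chain completion of a channel
#'
#' Greedy rotamer placement (and clash-relief sweeps) on a z-aligned,
#' exactly Cn-symmetric channel backbone. Every decision made for the first
#' chain's residue is applied simultaneously to all n symmetry copies, and
#' clashes are counted against the full replicated context (including
#' between copies, which matters for pore-lining residues), so the output
#' remains exactly Cn-symmetric.
#'
#' @param s backbone-only Structure, chains A..LETTERS[n], z-aligned with
#'   the symmetry axis through the origin
#' @param order symmetry order n
#' @param rotamers rotamer library
#' @param relief_iters clash-relief sweeps after initial placement
#' @return full heavy-atom Structure, exactly Cn-symmetric
#' @export
complete_channel_symmetric <- function(s, order = 4L,
                                       rotamers = default_rotamers(),
                                       relief_iters = 10L) {
  chains <- chain_ids(s)
  if (length(chains) != order) stop("channel must have exactly ", order, " chains")
  Rk <- lapply(seq_len(order) - 1L,
               function(k) rotation_about_axis(c(0, 0, 1), 2 * pi * k / order))
  rtA <- residue_table(get_chain(s, chains[1]))
  at <- s$atoms[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z")]

  ctx_mask <- function(at, resno) {
    # exclude, in every chain copy, this residue and its neighbours' backbones
    keep <- !(at$resno == resno)
    nb <- at$resno %in% c(resno - 1L, resno + 1L) &
      at$atom %in% c("N", "CA", "C", "O")
    keep & !nb
  }
  replicate_sc <- function(sc) {
    # side-chain table for chain A -> all order copies
    xyz <- as.matrix(sc[, c("x", "y", "z")])
    do.call(rbind, lapply(seq_len(order), function(k) {
      p <- xyz %*% t(Rk[[k]])
      data.frame(chain = chains[k], atom = sc$atom, element = sc$element,
                 x = p[, 1], y = p[, 2], z = p[, 3], stringsAsFactors = FALSE)
    }))
  }
  clash_count <- function(rep_sc, ctx_at) {
    n <- .count_clashes(as.matrix(rep_sc[, c("x", "y", "z")]), rep_sc$element,
                        as.matrix(ctx_at[, c("x", "y", "z")]), ctx_at$element)
    # plus clashes between distinct copies (count unordered pairs once)
    a_rows <- rep_sc$chain == chains[1]
    if (any(!a_rows))
      n <- n + .count_clashes(as.matrix(rep_sc[a_rows, c("x", "y", "z")]),
                              rep_sc$element[a_rows],
                              as.matrix(rep_sc[!a_rows, c("x", "y", "z")]),
                              rep_sc$element[!a_rows])
    n
  }
  bb_frame <- function(at, resno) {
    r <- at[at$chain == chains[1] & at$resno == resno, ]
    list(N = as.numeric(r[r$atom == "N", c("x", "y", "z")][1, ]),
         CA = as.numeric(r[r$atom == "CA", c("x", "y", "z")][1, ]),
         C = as.numeric(r[r$atom == "C", c("x", "y", "z")][1, ]))
  }

  pick <- function(at, resno, resname, skip_clashfree = FALSE) {
    rots <- rotamers[[resname]]
    ctx <- at[ctx_mask(at, resno), ]
    bb <- bb_frame(at, resno)
    ord <- order(vapply(rots, `[[`, 1, "weight"), decreasing = TRUE)
    best <- NULL; best_cl <- Inf
    for (k in ord) {
      sc <- .build_sidechain(resname, bb, rots[[k]]$chi)
      if (is.null(sc)) return(NULL)
      rep_sc <- replicate_sc(sc)
      ncl <- clash_count(rep_sc, ctx)
      if (ncl < best_cl) { best <- rep_sc; best_cl <- ncl }
      if (ncl == 0L) break
    }
    list(sc = best, clashes = best_cl)
  }

  # initial placement
  for (ri in seq_len(nrow(rtA))) {
    resname <- rtA$resname[ri]
    if (!resname %in% names(rotamers)) {
      warning("unknown residue type ", resname, " placed as alanine")
      resname <- "ALA"
    }
    res <- pick(at, rtA$resno[ri], resname)
    if (is.null(res)) next
    add <- res$sc
    add$resno <- rtA$resno[ri]; add$resname <- rtA$resname[ri]
    at <- rbind(at, add[, c("chain", "resno", "resname", "atom", "element",
                            "x", "y", "z")])
  }
  # symmetric clash-relief sweeps
  for (it in seq_len(relief_iters)) {
    improved <- FALSE
    for (ri in seq_len(nrow(rtA))) {
      resname <- rtA$resname[ri]
      if (!resname %in% names(rotamers) || length(rotamers[[resname]]) < 2) next
      sc_rows <- at$resno == rtA$resno[ri] & !at$atom %in% c("N", "CA", "C", "O")
      if (!any(sc_rows)) next
      cur <- at[sc_rows, ]
      cur_cl <- clash_count(cur, at[ctx_mask(at, rtA$resno[ri]), ])
      if (cur_cl == 0L) next
      res <- pick(at, rtA$resno[ri], resname)
      if (!is.null(res) && res$clashes < cur_cl) {
        hit <- order(match(paste(at$chain[sc_rows], at$atom[sc_rows]),
                           paste(res$sc$chain, res$sc$atom)))
        at[which(sc_rows)[order(hit)], c("x", "y", "z")] <-
          res$sc[match(paste(at$chain[sc_rows], at$atom[sc_rows]),
                       paste(res$sc$chain, res$sc$atom)), c("x", "y", "z")]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  new_structure(at, metadata = c(s$metadata, list(sidechains = "symmetric rotamer")))
}
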