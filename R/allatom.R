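# Completion of a C-alpha trace to a full heavy-atom model:
#   1. fix_chirality  - contact maps carry no handedness; mirror if needed
#   2. build_backbone - deterministic ideal peptide-plane geometry
#   3. place_sidechains / relieve_clashes - minimal embedded rotamer library
#      with greedy hard-sphere clash relief
# C-alpha coordinates are never modified by any of these stages.

# ---- chirality ------------------------------------------------------------

#' Resolve the handedness of a reconstructed trace
#'
#' A contact map is invariant under reflection, so a refined trace and its
#' mirror image satisfy identical constraints. Protein geometry is not:
#' alpha-helical C-alpha pseudo-dihedrals (4-residue windows) are
#' right-handed, about +50 degrees. If the left-handed sign dominates the
#' mean signed pseudo-dihedral, the mirror image (x negated) is returned.
#'
#' @param trace CaTrace, length >= 5
#' @return CaTrace with the dominant-handedness convention
#' @export
fix_chirality <- function(trace) {
  X <- trace$xyz
  L <- nrow(X)
  if (L < 5) {
    warning("trace too short for chirality analysis; returned unchanged")
    return(trace)
  }
  nobond <- trace$chain_breaks
  dih <- numeric(0)
  for (i in seq_len(L - 3)) {
    if (any(nobond >= i & nobond < i + 3)) next  # window crosses a chain break
    dih <- c(dih, dihedral(X[i, ], X[i + 1, ], X[i + 2, ], X[i + 3, ]))
  }
  if (length(dih) && mean(dih) < 0) {
    X[, 1] <- -X[, 1]
    trace$xyz <- X
    trace$provenance$mirrored <- TRUE
  } else {
    trace$provenance$mirrored <- FALSE
  }
  trace
}

# ---- internal-coordinate atom placement (NeRF) ----------------------------

# Place a new atom bonded to c, given reference atoms a-b-c, a bond length,
# the angle b-c-new and the dihedral a-b-c-new (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# ---- backbone building ----------------------------------------------------

# Ideal peptide geometry (Angstrom / degrees). Fixed constants of the
# builder; the trans peptide bond (omega = 180) is assumed throughout.
backbone_geometry <- function() {
  list(n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23,
       ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
       ang_ca_c_o = 120.5)
}

# Peptide-unit template between two CA positions a distance d apart, in plane
# coordinates (u along CA_i -> CA_{i+1}, w perpendicular in-plane).
# Returns C and N offsets: C = CA_i + cu*u + cw*w ; N = CA_{i+1} - nu*u + nw*w.
# Solved once per (rounded) d and cached.
.peptide_template_cache <- new.env(parent = emptyenv())
peptide_template <- function(d, geo = backbone_geometry()) {
  key <- sprintf("%.3f", d)
  hit <- .peptide_template_cache[[key]]
  if (!is.null(hit)) return(hit)
  # unknowns: alpha (CA_i->C elevation), beta (CA_{i+1}->N elevation)
  resid_fun <- function(p) {
    Cp <- c(geo$ca_c * cos(p[1]), geo$ca_c * sin(p[1]))
    Np <- c(d - geo$c_n_anchor * cos(p[2]), geo$c_n_anchor * sin(p[2]))
    v1 <- -Cp                      # C -> CA_i
    v2 <- Np - Cp                  # C -> N
    ang <- acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2))) * 180 / pi
    c(vnorm(v2) - geo$c_n, ang - geo$ang_ca_c_n)
  }
  geo$c_n_anchor <- geo$n_ca
  obj <- function(p) sum(resid_fun(p)^2)
  fit <- stats::optim(c(0.35, 0.35), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  p <- fit$par
  out <- list(cu = geo$ca_c * cos(p[1]), cw = geo$ca_c * sin(p[1]),
              nu = geo$n_ca * cos(p[2]), nw = geo$n_ca * sin(p[2]))
  .peptide_template_cache[[key]] <- out
  out
}

# Place the peptide unit between CA_i and CA_{i+1} at in-plane rotation theta
# (radians) about the CA-CA axis. w0/n0: orthonormal basis normal to u.
.unit_atoms <- function(ca_i, ca_j, w0, n0, theta, tpl) {
  w <- cos(theta) * w0 + sin(theta) * n0
  u <- unitv(ca_j - ca_i)
  C <- ca_i + tpl$cu * u + tpl$cw * w
  N <- ca_j - tpl$nu * u + tpl$nw * w
  list(C = C, N = N)
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
}

# Build N/C/O backbone atoms for one contiguous segment of CA positions.
# Returns a list per residue: list(N=, CA=, C=, O=).
.build_segment <- function(X, geo = backbone_geometry()) {
  n <- nrow(X)
  if (n < 2) stop("segment of length < 2 cannot be built")
  # peptide-plane rotation about the CA-CA axis: in protein-like (trans,
  # L-amino-acid) conformations the carbonyl offset stays on one side of the
  # chain, theta in roughly [20, 160] degrees of the next-step in-plane
  # basis; restricting the scan to that window rejects the mirror solution
  thetas <- seq(20, 160, by = 2) * pi / 180
  res <- vector("list", n)
  for (i in seq_len(n)) res[[i]] <- list(CA = X[i, ])

  # orthonormal in-plane bases per unit
  basis <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    u <- unitv(X[i + 1, ] - X[i, ])
    ref <- if (i + 2 <= n) X[i + 2, ] - X[i + 1, ] else X[max(i - 1, 1), ] - X[i, ]
    w0 <- ref - sum(ref * u) * u
    if (vnorm(w0) < 1e-6) w0 <- cross3(u, c(0, 0, 1))
    if (vnorm(w0) < 1e-6) w0 <- cross3(u, c(0, 1, 0))
    w0 <- unitv(w0)
    basis[[i]] <- list(u = u, w0 = w0, n0 = cross3(u, w0))
  }
  tpls <- lapply(seq_len(n - 1), function(i)
    peptide_template(round(vnorm(X[i + 1, ] - X[i, ]), 2), geo))

  # first unit: choose theta_1 (jointly with a coarse theta_2) so the
  # N-CA-C angle at residue 2 comes out ideal
  pick_theta <- function(i, N_prev) {
    b <- basis[[i]]
    errs <- vapply(thetas, function(th) {
      at <- .unit_atoms(X[i, ], X[i + 1, ], b$w0, b$n0, th, tpls[[i]])
      abs(.angle_deg(N_prev, X[i, ], at$C) - geo$ang_n_ca_c)
    }, 1)
    thetas[which.min(errs)]
  }
  if (n >= 3) {
    coarse <- seq(20, 160, by = 10) * pi / 180
    # steric guard: the first unit's carbonyl O must not point into the body
    # of the chain (the joint angle criterion alone leaves it free)
    later_ca <- X[3:min(n, 10), , drop = FALSE]
    steric <- function(C, N2) {
      O <- C - geo$c_o * unitv(unitv(X[1, ] - C) + unitv(N2 - C))
      d <- sqrt(rowSums(sweep(later_ca, 2, O)^2))
      100 * sum(pmax(0, 3.0 - d)^2)
    }
    best <- c(Inf, 0, 0)
    for (t1 in coarse) {
      a1 <- .unit_atoms(X[1, ], X[2, ], basis[[1]]$w0, basis[[1]]$n0, t1, tpls[[1]])
      pen <- steric(a1$C, a1$N)
      for (t2 in coarse) {
        a2 <- .unit_atoms(X[2, ], X[3, ], basis[[2]]$w0, basis[[2]]$n0, t2, tpls[[2]])
        e <- abs(.angle_deg(a1$N, X[2, ], a2$C) - geo$ang_n_ca_c) + pen
        if (e < best[1]) best <- c(e, t1, t2)
      }
    }
    theta1 <- best[2]
  } else theta1 <- 0
  at1 <- .unit_atoms(X[1, ], X[2, ], basis[[1]]$w0, basis[[1]]$n0, theta1, tpls[[1]])
  res[[1]]$C <- at1$C
  res[[2]]$N <- at1$N
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      th <- pick_theta(i, res[[i]]$N)
      at <- .unit_atoms(X[i, ], X[i + 1, ], basis[[i]]$w0, basis[[i]]$n0, th, tpls[[i]])
      res[[i]]$C <- at$C
      res[[i + 1]]$N <- at$N
    }
  }
  # terminal N of residue 1: ideal angle, anti to the psi direction
  res[[1]]$N <- place_atom(res[[2]]$N, res[[1]]$C, res[[1]]$CA,
                           geo$n_ca, geo$ang_n_ca_c, 180)
  # terminal C/O of residue n
  res[[n]]$C <- place_atom(res[[n - 1]]$C, res[[n]]$N, res[[n]]$CA,
                           geo$ca_c, geo$ang_n_ca_c, -120)
  # carbonyl O: bisects CA and next-N directions in the peptide plane
  for (i in seq_len(n - 1)) {
    C <- res[[i]]$C
    res[[i]]$O <- C - geo$c_o * unitv(unitv(res[[i]]$CA - C) + unitv(res[[i + 1]]$N - C))
  }
  res[[n]]$O <- place_atom(res[[n]]$N, res[[n]]$CA, res[[n]]$C,
                           geo$c_o, geo$ang_ca_c_o, 0)
  res
}

#' Build an ideal-geometry backbone on a C-alpha trace
#'
#' Every residue gains N, C and O atoms placed by ideal trans-peptide
#' geometry in local C-alpha frames; the C-alpha coordinates themselves are
#' preserved exactly. Chain breaks in the trace start new chains (A, B, ...).
#'
#' @param trace CaTrace with consecutive bonded distances in `[2.8, 4.8]` A
#' @param sequence character vector of 3-letter residue codes, one per trace
#'   point
#' @return Structure with N, CA, C, O per residue
#' @export
build_backbone <- function(trace, sequence) {
  X <- trace$xyz
  L <- nrow(X)
  if (length(sequence) != L) stop("sequence length != trace length")
  bonded <- .bond_mask(L, trace$chain_breaks)
  if (L > 1) {
    d <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-L, , drop = FALSE])^2))
    bad <- which(bonded & (d < 2.8 | d > 4.8))
    if (length(bad))
      stop("bonded C-alpha distances outside [2.8, 4.8] A at indices: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  seg_start <- c(1L, trace$chain_breaks + 1L)
  seg_end <- c(trace$chain_breaks, L)
  rows <- list()
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    built <- .build_segment(X[idx, , drop = FALSE])
    cid <- LETTERS[s]
    for (k in seq_along(idx)) {
      for (an in c("N", "CA", "C", "O")) {
        p <- built[[k]][[an]]
        rows[[length(rows) + 1L]] <- data.frame(
          chain = cid, resno = k, resname = sequence[idx[k]], atom = an,
          element = substr(an, 1, 1), x = p[1], y = p[2], z = p[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  new_structure(do.call(rbind, rows),
                metadata = list(stage = "backbone", source = trace$provenance$source))
}

# ---- side chains ----------------------------------------------------------

# van der Waals radii (Angstrom) for clash detection
.vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# canonical local frame: N, CA, C at standard positions; dihedral C-N-CA-CB
# of an L-amino acid in that frame defines CB placement for every type
.cb_dihedral <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      N <- c(-0.525, 1.363, 0); CA <- c(0, 0, 0)
      C <- c(1.526, 0, 0); CB <- c(-0.532, -0.774, -1.205)
      val <<- dihedral(C, N, CA, CB)
    }
    val
  }
})

# Side-chain topology: one row per atom beyond CB.
#   parents: a, b, c atom names (new atom bonds c)
#   chi: which chi angle supplies the dihedral (0 = constant)
#   offset: degrees added to the chi angle (or the full constant when chi = 0)
.topology_cache <- new.env(parent = emptyenv())
.sidechain_topology <- function() {
  hit <- .topology_cache$topo
  if (!is.null(hit)) return(hit)
  .topology_cache$topo <- .sidechain_topology_build()
  .topology_cache$topo
}
.sidechain_topology_build <- function() {
  row <- function(name, a, b, c, bond, angle, chi, offset = 0, elem = substr(name, 1, 1))
    data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
               chi = chi, offset = offset, element = elem, stringsAsFactors = FALSE)
  list(
    ALA = NULL, GLY = NULL,
    SER = row("OG", "N", "CA", "CB", 1.42, 110.8, 1),
    CYS = row("SG", "N", "CA", "CB", 1.81, 113.8, 1),
    THR = rbind(row("OG1", "N", "CA", "CB", 1.43, 109.6, 1),
                row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -120)),
    VAL = rbind(row("CG1", "N", "CA", "CB", 1.52, 110.5, 1),
                row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, 120)),
    LEU = rbind(row("CG", "N", "CA", "CB", 1.53, 116.3, 1),
                row("CD1", "CA", "CB", "CG", 1.52, 110.7, 2),
                row("CD2", "CA", "CB", "CG", 1.52, 110.7, 2, 120)),
    ILE = rbind(row("CG1", "N", "CA", "CB", 1.53, 110.4, 1),
                row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -120),
                row("CD1", "CA", "CB", "CG1", 1.52, 113.8, 2)),
    MET = rbind(row("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                row("SD", "CA", "CB", "CG", 1.81, 112.7, 2),
                row("CE", "CB", "CG", "SD", 1.79, 100.2, 3)),
    ASP = rbind(row("CG", "N", "CA", "CB", 1.52, 112.6, 1),
                row("OD1", "CA", "CB", "CG", 1.25, 118.5, 2),
                row("OD2", "CA", "CB", "CG", 1.25, 118.5, 2, 180)),
    ASN = rbind(row("CG", "N", "CA", "CB", 1.52, 112.6, 1),
                row("OD1", "CA", "CB", "CG", 1.23, 120.8, 2),
                row("ND2", "CA", "CB", "CG", 1.33, 116.5, 2, 180)),
    GLU = rbind(row("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                row("CD", "CA", "CB", "CG", 1.52, 112.6, 2),
                row("OE1", "CB", "CG", "CD", 1.25, 118.5, 3),
                row("OE2", "CB", "CG", "CD", 1.25, 118.5, 3, 180)),
    GLN = rbind(row("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                row("CD", "CA", "CB", "CG", 1.52, 112.6, 2),
                row("OE1", "CB", "CG", "CD", 1.23, 120.8, 3),
                row("NE2", "CB", "CG", "CD", 1.33, 116.5, 3, 180)),
    LYS = rbind(row("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                row("CD", "CA", "CB", "CG", 1.52, 111.3, 2),
                row("CE", "CB", "CG", "CD", 1.52, 111.3, 3),
                row("NZ", "CG", "CD", "CE", 1.49, 111.9, 4)),
    ARG = rbind(row("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                row("CD", "CA", "CB", "CG", 1.52, 111.3, 2),
                row("NE", "CB", "CG", "CD", 1.46, 112.0, 3),
                row("CZ", "CG", "CD", "NE", 1.33, 124.2, 4),
                row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0, 0),
                row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0, 180)),
    PHE = rbind(row("CG", "N", "CA", "CB", 1.51, 113.8, 1),
                row("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
                row("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
                row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0, 180),
                row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0, 180),
                row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0, 0)),
    TYR = rbind(row("CG", "N", "CA", "CB", 1.51, 113.8, 1),
                row("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
                row("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
                row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0, 180),
                row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0, 180),
                row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
                row("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 0, 180)),
    TRP = rbind(row("CG", "N", "CA", "CB", 1.50, 113.8, 1),
                row("CD1", "CA", "CB", "CG", 1.37, 126.9, 2),
                row("CD2", "CA", "CB", "CG", 1.43, 126.6, 2, 180),
                row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0, 180),
                row("CE2", "CB", "CG", "CD2", 1.40, 107.2, 0, 180),
                row("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0, 0),
                row("CZ2", "CG", "CD2", "CE2", 1.39, 122.4, 0, 180),
                row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 0, 180),
                row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0, 0)),
    HIS = rbind(row("CG", "N", "CA", "CB", 1.49, 113.8, 1),
                row("ND1", "CA", "CB", "CG", 1.38, 122.7, 2),
                row("CD2", "CA", "CB", "CG", 1.36, 131.1, 2, 180),
                row("CE1", "CB", "CG", "ND1", 1.32, 109.2, 0, 180),
                row("NE2", "CB", "CG", "CD2", 1.37, 107.2, 0, 180)),
    PRO = rbind(row("CG", "N", "CA", "CB", 1.50, 104.5, 1),
                row("CD", "CA", "CB", "CG", 1.50, 105.5, 2))
  )
}

# number of chi angles per residue type
.n_chi <- c(ALA = 0, GLY = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, LEU = 2,
            ILE = 2, MET = 3, ASP = 2, ASN = 2, GLU = 3, GLN = 3, LYS = 4,
            ARG = 4, PHE = 2, TYR = 2, TRP = 2, HIS = 2, PRO = 2)

#' Minimal embedded rotamer library
#'
#' Per residue type, a short list of chi-angle tuples with prior weights
#' (weights sum to 1). Chi1 takes the three staggered wells (gauche-, trans,
#' gauche+) at typical prior weights; higher chi angles default to trans,
#' with ring residues using the common perpendicular chi2 and the proline
#' ring fixed at its single pucker.
#'
#' @return named list: per type, list of `list(chi = numeric, weight = scalar)`
#' @export
default_rotamers <- function() {
  base1 <- c(-65, 180, 62)
  w1 <- c(0.5, 0.3, 0.2)
  mk <- function(nchi, chi2 = 180) {
    lapply(seq_along(base1), function(k) {
      chi <- c(base1[k], rep(180, max(0, nchi - 1)))
      if (nchi >= 2) chi[2] <- chi2
      list(chi = chi, weight = w1[k])
    })
  }
  out <- list(
    ALA = list(list(chi = numeric(0), weight = 1)),
    GLY = list(list(chi = numeric(0), weight = 1)),
    SER = mk(1), CYS = mk(1), THR = mk(1), VAL = mk(1),
    LEU = mk(2, chi2 = 175), ILE = mk(2, chi2 = 170), MET = mk(3),
    ASP = mk(2, chi2 = -20), ASN = mk(2, chi2 = -20),
    GLU = mk(3), GLN = mk(3), LYS = mk(4), ARG = mk(4),
    PHE = mk(2, chi2 = 90), TYR = mk(2, chi2 = 90),
    TRP = mk(2, chi2 = 90), HIS = mk(2, chi2 = 90),
    PRO = list(list(chi = c(30, -35), weight = 1))
  )
  out
}

# backbone + CB coordinates for one residue -> full side-chain atom table
# bb: named list with N, CA, C 3-vectors; returns data.frame(atom, element, x, y, z)
.build_sidechain <- function(resname, bb, chi) {
  topo <- .sidechain_topology()[[resname]]
  atoms <- list(N = bb$N, CA = bb$CA, C = bb$C)
  out <- NULL
  if (resname != "GLY") {
    cb <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.4, .cb_dihedral())
    atoms$CB <- cb
    out <- data.frame(atom = "CB", element = "C", x = cb[1], y = cb[2], z = cb[3],
                      stringsAsFactors = FALSE)
  }
  if (!is.null(topo)) {
    for (k in seq_len(nrow(topo))) {
      tr <- topo[k, ]
      dih <- if (tr$chi > 0) chi[tr$chi] + tr$offset else tr$offset
      p <- place_atom(atoms[[tr$a]], atoms[[tr$b]], atoms[[tr$c]],
                      tr$bond, tr$angle, dih)
      atoms[[tr$name]] <- p
      out <- rbind(out, data.frame(atom = tr$name, element = tr$element,
                                   x = p[1], y = p[2], z = p[3],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Count hard-sphere overlaps of candidate atom coordinates (matrix, with
# element vector) against context atoms. Pairs closer than
# 0.8 * (vdW_i + vdW_j) count as one clash each.
.count_clashes <- function(cand_xyz, cand_elem, ctx_xyz, ctx_elem) {
  if (is.null(ctx_xyz) || !nrow(ctx_xyz) || is.null(cand_xyz) || !nrow(cand_xyz))
    return(0L)
  ri <- .vdw[cand_elem]; ri[is.na(ri)] <- 1.7
  rj <- .vdw[ctx_elem]; rj[is.na(rj)] <- 1.7
  n <- 0L
  for (k in seq_len(nrow(cand_xyz))) {
    d2 <- (ctx_xyz[, 1] - cand_xyz[k, 1])^2 + (ctx_xyz[, 2] - cand_xyz[k, 2])^2 +
          (ctx_xyz[, 3] - cand_xyz[k, 3])^2
    lim <- (0.8 * (ri[k] + rj))^2
    n <- n + sum(d2 < lim)
  }
  n
}

# context rows for clash-checking residue `ri` of residue table `rt`:
# everything except residue ri itself and the backbones of its sequence
# neighbours (bonded within < 4 bonds of CB).
.clash_context <- function(atoms, rt, ri) {
  own <- atoms$chain == rt$chain[ri] & atoms$resno == rt$resno[ri]
  nb <- rep(FALSE, nrow(atoms))
  for (dd in c(-1L, 1L)) {
    j <- ri + dd
    if (j >= 1 && j <= nrow(rt) && rt$chain[j] == rt$chain[ri])
      nb <- nb | (atoms$chain == rt$chain[j] & atoms$resno == rt$resno[j] &
                  atoms$atom %in% c("N", "CA", "C", "O"))
  }
  !(own | nb)
}

#' Add side chains from the embedded rotamer library
#'
#' Every residue with a complete backbone (N, CA, C) gains its side-chain
#' heavy atoms, built in internal coordinates from the highest-weight
#' rotamer that creates no hard-sphere clash with the rest of the structure;
#' if every rotamer clashes, the least-clashing one is used. Deterministic
#' given its input. Unknown residue types are placed as alanine with a
#' warning.
#'
#' @param s Structure with backbone atoms
#' @param rotamers rotamer library, see [default_rotamers()]
#' @return Structure with side-chain heavy atoms added
#' @export
place_sidechains <- function(s, rotamers = default_rotamers()) {
  rt <- residue_table(s)
  at <- s$atoms
  unknown <- setdiff(unique(rt$resname), names(rotamers))
  if (length(unknown)) {
    warning("unknown residue type(s) placed as alanine: ",
            paste(unknown, collapse = ", "))
    rt$resname[rt$resname %in% unknown] <- "ALA"
  }
  added <- list()
  cur_xyz <- as.matrix(at[, c("x", "y", "z")])
  cur_elem <- at$element
  cur_chain <- at$chain; cur_resno <- at$resno; cur_atom <- at$atom
  for (ri in seq_len(nrow(rt))) {
    resname <- rt$resname[ri]
    rows <- which(at$chain == rt$chain[ri] & at$resno == rt$resno[ri])
    nm <- at$atom[rows]
    if (!all(c("N", "CA", "C") %in% nm)) {
      warning("incomplete backbone at residue ", rt$resno[ri], " chain ",
              rt$chain[ri], "; side chain skipped")
      next
    }
    bb <- list(N = as.numeric(at[rows[nm == "N"][1], c("x", "y", "z")]),
               CA = as.numeric(at[rows[nm == "CA"][1], c("x", "y", "z")]),
               C = as.numeric(at[rows[nm == "C"][1], c("x", "y", "z")]))
    rots <- rotamers[[resname]]
    ord <- order(vapply(rots, `[[`, 1, "weight"), decreasing = TRUE)
    ctx <- .clash_context(data.frame(chain = cur_chain, resno = cur_resno,
                                     atom = cur_atom, stringsAsFactors = FALSE),
                          rt, ri)
    best <- NULL; best_clash <- Inf
    for (k in ord) {
      sc <- .build_sidechain(resname, bb, rots[[k]]$chi)
      ncl <- if (is.null(sc)) 0L else
        .count_clashes(as.matrix(sc[, c("x", "y", "z")]), sc$element,
                       cur_xyz[ctx, , drop = FALSE], cur_elem[ctx])
      if (ncl < best_clash) { best <- sc; best_clash <- ncl; best_k <- k }
      if (ncl == 0L) break
    }
    if (!is.null(best)) {
      best$chain <- rt$chain[ri]; best$resno <- rt$resno[ri]
      best$resname <- resname
      added[[length(added) + 1L]] <- best
      cur_xyz <- rbind(cur_xyz, as.matrix(best[, c("x", "y", "z")]))
      cur_elem <- c(cur_elem, best$element)
      cur_chain <- c(cur_chain, best$chain)
      cur_resno <- c(cur_resno, best$resno)
      cur_atom <- c(cur_atom, best$atom)
    }
  }
  if (length(added)) {
    add <- do.call(rbind, added)
    add <- add[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z")]
    all_at <- rbind(at[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z")], add)
  } else all_at <- at[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z")]
  new_structure(all_at, metadata = c(s$metadata, list(sidechains = "rotamer")))
}

#' Total hard-sphere clash count of a structure
#'
#' Counts side-chain-involving atom pairs (different residues, neighbouring
#' backbone exclusion as in placement) closer than 0.8 x the sum of their
#' van der Waals radii.
#'
#' @param s Structure
#' @return integer clash count
#' @export
count_clashes <- function(s) {
  rt <- residue_table(s)
  at <- s$atoms
  total <- 0L
  for (ri in seq_len(nrow(rt))) {
    own <- at$chain == rt$chain[ri] & at$resno == rt$resno[ri]
    sc <- own & !at$atom %in% c("N", "CA", "C", "O")
    if (!any(sc)) next
    ctx <- .clash_context(at, rt, ri) & !(seq_len(nrow(at)) %in% which(own))
    # count each pair once: only against later residues' atoms or backbone
    later <- (match(paste(at$chain, at$resno), paste(rt$chain, rt$resno)) > ri) |
             at$atom %in% c("N", "CA", "C", "O")
    ctx <- ctx & later
    total <- total + .count_clashes(as.matrix(at[sc, c("x", "y", "z")]),
                                    at$element[sc],
                                    as.matrix(at[ctx, c("x", "y", "z")]),
                                    at$element[ctx])
  }
  total
}

#' Greedy rotamer-swap clash relief
#'
#' Sweeps over residues with clashes, re-placing each side chain with the
#' rotamer that minimizes the structure's clash count; a swap is kept only
#' if it strictly reduces clashes, so the count is monotone non-increasing.
#' Backbone atoms are never moved. Stops at zero clashes, a sweep with no
#' improvement, or `max_iters` sweeps.
#'
#' @param s full heavy-atom Structure
#' @param max_iters maximum sweeps
#' @param rotamers rotamer library
#' @return Structure
#' @export
relieve_clashes <- function(s, max_iters = 10L, rotamers = default_rotamers()) {
  rt <- residue_table(s)
  for (it in seq_len(max_iters)) {
    improved <- FALSE
    at <- s$atoms
    for (ri in seq_len(nrow(rt))) {
      resname <- rt$resname[ri]
      if (!resname %in% names(rotamers) || length(rotamers[[resname]]) < 2) next
      own <- which(at$chain == rt$chain[ri] & at$resno == rt$resno[ri])
      sc_rows <- own[!at$atom[own] %in% c("N", "CA", "C", "O")]
      if (!length(sc_rows)) next
      ctx <- .clash_context(at, rt, ri)
      cur_cl <- .count_clashes(as.matrix(at[sc_rows, c("x", "y", "z")]),
                               at$element[sc_rows],
                               as.matrix(at[ctx, c("x", "y", "z")]), at$element[ctx])
      if (cur_cl == 0L) next
      nm <- at$atom[own]
      bb <- list(N = as.numeric(at[own[nm == "N"][1], c("x", "y", "z")]),
                 CA = as.numeric(at[own[nm == "CA"][1], c("x", "y", "z")]),
                 C = as.numeric(at[own[nm == "C"][1], c("x", "y", "z")]))
      best_sc <- NULL; best_cl <- cur_cl
      for (rot in rotamers[[resname]]) {
        sc <- .build_sidechain(resname, bb, rot$chi)
        ncl <- .count_clashes(as.matrix(sc[, c("x", "y", "z")]), sc$element,
                              as.matrix(at[ctx, c("x", "y", "z")]), at$element[ctx])
        if (ncl < best_cl) { best_cl <- ncl; best_sc <- sc }
      }
      if (!is.null(best_sc)) {
        hit <- match(best_sc$atom, at$atom[sc_rows])
        at[sc_rows[hit], c("x", "y", "z")] <- best_sc[, c("x", "y", "z")]
        improved <- TRUE
      }
    }
    s$atoms <- at
    if (!improved || count_clashes(s) == 0L) break
  }
  s
}
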