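# Deterministic synthetic systems so every pipeline stage can be built and
# tested without downloads: an ideal alpha-helix, a beta-hairpin-like chain,
# a compact random coil, a C4 toy tetramer with a pore, and a +/- charge
# pair for the Poisson solver. Fixtures are poly-alanine except designated
# charged residues, keeping side-chain placement trivial in pipeline tests.

# CA coordinates of a right-handed alpha-helix along +z
.helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3, phase = 0) {
  i <- seq_len(n) - 1
  th <- (phase + twist * i) * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

#' Ideal alpha-helix fixture
#'
#' Right-handed helical C-alpha geometry (rise 1.5 A, 100 degrees/residue,
#' radius 2.3 A; consecutive CA distance about 3.8 A), completed to a
#' poly-alanine backbone with CB atoms.
#'
#' @param n number of residues (>= 4)
#' @param sequence optional 3-letter codes (default all "ALA")
#' @return Structure
#' @export
make_ideal_helix <- function(n, sequence = NULL) {
  if (n < 4) stop("need n >= 4")
  if (is.null(sequence)) sequence <- rep("ALA", n)
  tr <- new_ca_trace(.helix_ca(n))
  place_sidechains(build_backbone(tr, sequence))
}

#' Beta-hairpin-like fixture
#'
#' Two anti-parallel pleated strands joined by a two-residue turn, completed
#' to a poly-alanine backbone.
#'
#' @param n total residues (>= 8)
#' @return Structure
#' @export
make_hairpin <- function(n = 40) {
  if (n < 8) stop("need n >= 8")
  n1 <- (n - 2) %/% 2
  n2 <- n - 2 - n1
  rise <- 3.65; pleat <- 0.53; sep <- 4.8
  up <- cbind(0, pleat * (-1)^(seq_len(n1)), rise * (seq_len(n1) - 1))
  ztop <- rise * (n1 - 1)
  turn <- rbind(c(0.9, 0, ztop + 3.4), c(sep - 0.9, 0, ztop + 3.4))
  down <- cbind(sep, pleat * (-1)^(seq_len(n2)), ztop - rise * (seq_len(n2) - 1))
  tr <- new_ca_trace(rbind(up, turn, down))
  place_sidechains(build_backbone(tr, rep("ALA", n)))
}

#' Compact random-coil fixture
#'
#' A seeded random walk with fixed 3.8 A steps confined to a compact ball,
#' lightly pushed apart so no two non-bonded residues overlap, completed to
#' a poly-alanine backbone. Emulates a collapsed globular chain.
#'
#' @param n residues
#' @param seed RNG seed
#' @return Structure
#' @export
make_compact_coil <- function(n = 60, seed = 7L) {
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  R <- (3 / (4 * pi))^(1 / 3) * n^(1 / 3) * 4
  X <- matrix(0, n, 3)
  for (i in 2:n) {
    best_cand <- NULL; best_sep <- -Inf
    for (try in seq_len(60)) {
      dir <- unitv(rnorm(3))
      cand <- X[i - 1, ] + 3.8 * dir
      if (vnorm(cand) > R) {
        dir <- unitv(dir + 2 * unitv(-X[i - 1, ]))
        cand <- X[i - 1, ] + 3.8 * dir
      }
      sep <- if (i < 3) Inf else
        min(sqrt(rowSums(sweep(X[1:(i - 2), , drop = FALSE], 2, cand)^2)))
      if (sep > best_sep) { best_sep <- sep; best_cand <- cand }
      if (sep > 3.5) break
    }
    X[i, ] <- best_cand
  }
  tr <- new_ca_trace(X)
  place_sidechains(build_backbone(tr, rep("ALA", n)))
}

#' Toy C4 tetramer with a central pore
#'
#' Four helix-turn-helix subunits with exact C4 symmetry about z: an inner
#' (pore-lining) helix running up, a short turn, and an outer helix packed
#' antiparallel against it -- the topology of a small tetrameric channel,
#' desk-scale. The antiparallel helix pairing and inter-subunit packing give
#' the contact map enough long-range information to pin the fold, which a
#' bundle of isolated straight helices would not. The middle residue of the
#' inner helix is the diameter marker; its CA points radially outward, at
#' distance `pore_radius + 2 * helix_radius` from the axis, so the
#' marker-to-marker distance across the pore is
#' `2 * (pore_radius + 2 * 2.3)` by construction. Glu/Lys rings on the inner
#' helix give the pore a nontrivial electrostatic profile.
#'
#' @param n_per_chain residues per chain (>= 16)
#' @param pore_radius distance from the z axis to the inner helix surface, A
#' @param charged place Glu/Lys rings for electrostatics work
#' @return Structure with chains A-D, exactly C4-symmetric
#' @export
make_toy_tetramer <- function(n_per_chain = 40L, pore_radius = 3.5, charged = TRUE) {
  if (n_per_chain < 16) stop("need n_per_chain >= 16")
  helix_radius <- 2.3
  r_in <- pore_radius + helix_radius       # inner helix axis radius
  r_out <- r_in + 8.5                      # antiparallel packing distance
  n_turn <- 3L
  n_in <- (n_per_chain - n_turn) %/% 2L
  n_out <- n_per_chain - n_turn - n_in
  marker <- (n_in + 1L) %/% 2L
  # inner helix, axis up at angle 0; marker CA points along +x
  ca_in <- .helix_ca(n_in, phase = -100 * (marker - 1))
  ca_in[, 1] <- ca_in[, 1] + r_in
  # outer helix, axis down at 45 degrees, packed against the inner helix
  ca_out <- .helix_ca(n_out)
  ca_out[, 3] <- -ca_out[, 3]  # descend
  rot45 <- rotation_about_axis(c(0, 0, 1), pi / 4)
  ca_out <- sweep(ca_out %*% t(rot45), 2, c(0, 0, 0), "+")
  ca_out <- ca_out + matrix(c(r_out * cos(pi / 4), r_out * sin(pi / 4),
                              1.5 * (n_out - 1)), n_out, 3, byrow = TRUE)
  # short turn bridging the inner top to the outer top
  p_from <- ca_in[n_in, ]; p_to <- ca_out[1, ]
  fr <- seq_len(n_turn) / (n_turn + 1)
  turn <- t(vapply(fr, function(f) {
    p <- (1 - f) * p_from + f * p_to
    p[3] <- p[3] + 2.5 * sin(pi * f)  # arc over the top
    p
  }, numeric(3)))
  ca <- rbind(ca_in, turn, ca_out)
  ca[, 3] <- ca[, 3] - 1.5 * (n_in - 1) / 2  # center the pore on z = 0
  seqs <- rep("ALA", n_per_chain)
  if (charged) {
    # charged rings on outward-facing positions of both helices (net 0 per
    # chain). Two deliberate choices mirror real channels: charges are
    # spread over several rings (a couple of charges would make the axial
    # profile track single rotamer flips rather than structure), and none
    # point into the pore (an inward charged side chain near the axis turns
    # the profile into a naked point-charge spike). On the inner helix,
    # offsets of -7/+4/+7 from the outward-facing marker keep the phase
    # within ~40 degrees of outward.
    o1 <- n_in + n_turn + 1L
    glu <- c(max(1, marker - 7), min(n_in, marker + 4),
             min(n_per_chain, o1 + 8))
    lys <- c(min(n_in, marker + 7), min(n_per_chain, o1 + 3),
             min(n_per_chain, o1 + 13))
    seqs[glu] <- "GLU"
    seqs[setdiff(lys, glu)] <- "LYS"
  }
  chainA <- place_sidechains(build_backbone(new_ca_trace(ca), seqs))
  st <- c_n_project(chainA, symmetry_frame(order = 4L))
  st$metadata$marker_resno <- marker
  st$metadata$pore_radius <- pore_radius
  st
}

#' Opposite point charges on the pore axis
#'
#' A +1/-1 e pair on the z axis, symmetric about the origin: the minimal
#' test system for the Poisson solver (zero net charge, antisymmetric axial
#' profile, zero mid-plane potential).
#'
#' @param separation distance between the charges, Angstrom
#' @param radius atom radius used for the dielectric map (0 = no protein
#'   region)
#' @return data.frame usable as [solve_poisson()] input
#' @export
make_charge_pair <- function(separation = 10, radius = 0) {
  if (separation <= 0) stop("separation must be positive")
  data.frame(x = c(0, 0), y = c(0, 0),
             z = c(separation / 2, -separation / 2),
             q = c(1, -1), radius = radius)
}
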