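test_that("chirality resolution keeps right-handed traces and mirrors left-handed ones", {
  h <- fx_helix30()
  tr <- extract_ca_trace(h)
  fixed <- fix_chirality(tr)
  expect_equal(fixed$xyz, tr$xyz)
  expect_false(fixed$provenance$mirrored)

  mir <- tr
  mir$xyz[, 1] <- -mir$xyz[, 1]
  back <- fix_chirality(mir)
  expect_true(back$provenance$mirrored)
  expect_equal(kabsch_superpose(back$xyz, tr$xyz)$rmsd, 0, tolerance = 1e-8)

  short <- new_ca_trace(tr$xyz[1:4, ])
  expect_warning(out <- fix_chirality(short), "short")
  expect_equal(out$xyz, tr$xyz[1:4, ])
})

test_that("refined traces of a fold-determining map end up better than their mirror", {
  # the check needs a map that actually pins local geometry: traces refined
  # against an isolated helix map come out as handedness patchworks (contacts
  # are chirality-blind at every scale), which no global mirror can repair
  tt <- fx_tetramer()
  aug <- insert_dummy_loops(fx_tetramer_map(), 15)
  native <- extract_ca_trace(tt)
  hits <- 0
  for (k in 1:8) {
    tr <- reconstruct_ca(aug$cmap, recon_config(seed = 400 + k), 1)[[1]]
    tr <- fix_chirality(trim_dummy(tr, aug$mapping))
    d <- kabsch_superpose(tr$xyz, native$xyz)$rmsd
    dm <- kabsch_superpose(cbind(-tr$xyz[, 1], tr$xyz[, 2:3]), native$xyz)$rmsd
    if (d <= dm) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("build_backbone preserves CA atoms and yields helical dihedrals on a helix", {
  h <- fx_helix30()
  tr <- extract_ca_trace(h)
  s <- build_backbone(tr, rep("ALA", 30))
  at <- s$atoms
  expect_true(all(c("N", "CA", "C", "O") %in% at$atom))
  ca <- unname(as.matrix(at[at$atom == "CA", c("x", "y", "z")]))
  expect_equal(ca, unname(tr$xyz), tolerance = 0)
  g <- function(rn, an) as.numeric(at[at$resno == rn & at$atom == an,
                                      c("x", "y", "z")])
  phi <- vapply(5:25, function(i)
    dihedral(g(i - 1, "C"), g(i, "N"), g(i, "CA"), g(i, "C")), 1)
  psi <- vapply(5:25, function(i)
    dihedral(g(i, "N"), g(i, "CA"), g(i, "C"), g(i + 1, "N")), 1)
  expect_true(all(abs(phi - (-57)) < 40))
  expect_true(all(abs(psi - (-47)) < 40))
})

test_that("rebuilding the backbone from a native CA trace stays below 1 A", {
  for (s in list(fx_helix30(), fx_coil60())) {
    tr <- extract_ca_trace(s)
    rebuilt <- build_backbone(tr, residue_table(s)$resname)
    pr <- pair_coords(rebuilt, s, atoms = c("N", "CA", "C"))
    expect_lt(kabsch_superpose(pr$mobile, pr$target)$rmsd, 1.0)
  }
})

test_that("build_backbone validates bonded distances and round-trips through PDB", {
  stretched <- new_ca_trace(rbind(c(0, 0, 0), c(3.8, 0, 0), c(10, 0, 0)))
  expect_error(build_backbone(stretched, rep("ALA", 3)), "\\[2.8, 4.8\\]")
  tr <- extract_ca_trace(fx_helix30())
  s <- build_backbone(tr, rep("ALA", 30))
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(n_residues(s2), 30)
  expect_equal(coords(s2), round(coords(s), 3), tolerance = 1e-8)
})

test_that("poly-alanine gains one CB per residue at tetrahedral geometry", {
  tr <- extract_ca_trace(fx_helix30())
  s <- place_sidechains(build_backbone(tr, rep("ALA", 30)))
  at <- s$atoms
  expect_equal(sum(at$atom == "CB"), 30)
  for (rn in c(2, 15, 29)) {
    r <- at[at$resno == rn, ]
    g <- function(an) as.numeric(r[r$atom == an, c("x", "y", "z")])
    ang <- function(a, b, c) {
      v1 <- a - b; v2 <- c - b
      acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2))) * 180 / pi
    }
    expect_equal(vnorm(g("CB") - g("CA")), 1.53, tolerance = 0.01)
    expect_equal(ang(g("N"), g("CA"), g("CB")), 110.4, tolerance = 1.5)
    expect_equal(ang(g("C"), g("CA"), g("CB")), 110.4, tolerance = 2.5)
    # L-amino acid: improper N-C-CA-CB dihedral ~ +122.7 degrees
    expect_equal(dihedral(g("N"), g("C"), g("CA"), g("CB")), 122.7, tolerance = 0.5)
  }
})

test_that("an unobstructed side chain takes the highest-weight rotamer", {
  s <- place_sidechains(build_backbone(new_ca_trace(.hx(6)),
                                       c("ALA", "LYS", rep("ALA", 4))))
  lys <- s$atoms[s$atoms$resno == 2, ]
  expect_true(all(c("CB", "CG", "CD", "CE", "NZ") %in% lys$atom))
  g <- function(an) as.numeric(lys[lys$atom == an, c("x", "y", "z")])
  bb <- s$atoms[s$atoms$resno == 2 & s$atoms$atom %in% c("N", "CA"), ]
  chi1 <- dihedral(as.numeric(bb[bb$atom == "N", c("x", "y", "z")]),
                   as.numeric(bb[bb$atom == "CA", c("x", "y", "z")]),
                   g("CB"), g("CG"))
  expect_equal(chi1, -65, tolerance = 1)
})

test_that("a forced clash switches the rotamer away from the highest weight", {
  base <- build_backbone(new_ca_trace(.hx(5)), c("ALA", "SER", rep("ALA", 3)))
  og_at <- function(s) as.numeric(s$atoms[s$atoms$resno == 2 & s$atoms$atom == "OG",
                                          c("x", "y", "z")])
  free <- place_sidechains(base)
  og_free <- og_at(free)
  # OG site of the second-ranked rotamer, via a restricted library
  rots2 <- default_rotamers()
  rots2$SER <- rots2$SER[2]
  og_alt <- og_at(place_sidechains(base, rots2))
  # park a blocking atom just off the preferred OG site, on the side away
  # from the alternative rotamer, so only the preferred rotamer clashes
  blocker <- og_free + 1.3 * unitv(og_free - og_alt)
  blocked <- new_structure(rbind(
    base$atoms[, c("chain", "resno", "resname", "atom", "element", "x", "y", "z")],
    data.frame(chain = "A", resno = 9L, resname = "ALA", atom = "CB",
               element = "C", x = blocker[1], y = blocker[2], z = blocker[3])))
  out <- suppressWarnings(place_sidechains(blocked))
  expect_gt(vnorm(og_at(out) - og_free), 0.5)
})

test_that("clash relief is monotone and reaches zero on an easy case", {
  tr <- extract_ca_trace(fx_helix30())
  s <- place_sidechains(build_backbone(tr, rep(c("ALA", "LEU"), 15)))
  c0 <- count_clashes(s)
  r1 <- relieve_clashes(s, max_iters = 3)
  expect_lte(count_clashes(r1), c0)
  # a clash-free extended chain is a fixed point of relief
  i <- 1:12
  ext <- cbind(0.53 * (-1)^i, 0, 3.65 * i)
  clean <- place_sidechains(build_backbone(new_ca_trace(ext), rep("ALA", 12)))
  expect_equal(count_clashes(clean), 0)
  expect_equal(relieve_clashes(clean)$atoms, clean$atoms)
})

test_that("CA coordinates survive the whole completion stack bit-identically", {
  tr <- extract_ca_trace(fx_coil60())
  s <- relieve_clashes(place_sidechains(build_backbone(
    tr, rep(c("ALA", "SER", "LEU", "GLU"), 15))))
  ca <- unname(as.matrix(s$atoms[s$atoms$atom == "CA", c("x", "y", "z")]))
  expect_identical(ca, unname(tr$xyz))
})

test_that("unknown residue types fall back to alanine with a warning", {
  tr <- new_ca_trace(.hx(5))
  s <- build_backbone(tr, c("ALA", "XXX", "ALA", "ALA", "ALA"))
  expect_warning(out <- place_sidechains(s), "XXX")
  expect_equal(sum(out$atoms$atom == "CB"), 5)
})
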