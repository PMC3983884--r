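# Shared fixtures, built once per test run (generation is deterministic).
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

fx_helix30 <- function() fx("helix30", function() make_ideal_helix(30))
fx_coil60 <- function() fx("coil60", function() make_compact_coil(60, seed = 7))
fx_tetramer <- function() fx("tetramer", function() make_toy_tetramer(40))
fx_tetramer_map <- function() fx("tetramer_map", function() derive_cmap(fx_tetramer(), 8, "CA"))

# a tiny hand-written PDB (3 residues, one chain)
fx_mini_pdb <- function() {
  f <- file.path(tempdir(), "mini_fixture.pdb")
  if (!file.exists(f)) {
    lines <- c(
      "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
      "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
      "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
      "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
      "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
      "ATOM      6  CA  GLY A   2       3.966   2.849   0.000  1.00  0.00           C",
      "ATOM      7  C   GLY A   2       5.480   2.706   0.000  1.00  0.00           C",
      "ATOM      8  O   GLY A   2       6.021   1.600   0.000  1.00  0.00           O",
      "ATOM      9  N   SER A   3       6.170   3.840   0.000  1.00  0.00           N",
      "ATOM     10  CA  SER A   3       7.625   3.853   0.000  1.00  0.00           C",
      "ATOM     11  C   SER A   3       8.174   5.273   0.000  1.00  0.00           C",
      "ATOM     12  O   SER A   3       7.425   6.253   0.000  1.00  0.00           O",
      "TER", "END")
    writeLines(lines, f)
  }
  f
}

# random symmetric ternary map for property tests
random_ternary_map <- function(L, seed, p_contact = 0.2, p_unknown = 0) {
  set.seed(seed)
  M <- matrix(0L, L, L)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  lab <- sample(c(1L, 0L, -1L), nrow(ut), replace = TRUE,
                prob = c(p_contact, 1 - p_contact - p_unknown, p_unknown))
  M[ut] <- lab
  M[ut[, c(2, 1)]] <- lab
  diag(M) <- 1L
  new_contact_map(M, meta = list(threshold = 8))
}

# mirror-aware CA RMSD between a trace and a native trace
mirror_rmsd <- function(xyz, native_xyz) {
  min(kabsch_superpose(xyz, native_xyz)$rmsd,
      kabsch_superpose(cbind(-xyz[, 1], xyz[, 2:3]), native_xyz)$rmsd)
}

vnorm <- function(v) sqrt(sum(v * v))

# bare helical CA coordinates for small ad-hoc traces
.hx <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  th <- (phase + 100 * i) * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

unitv <- function(v) v / sqrt(sum(v * v))

# The perturbation experiment used by the acceptance checks: one shared run
# (complete / positive-only / reduced sweep / erroneous maps) on the toy
# tetramer with electrostatic profiles for the averaged channels.
fx_acceptance_experiment <- function() {
  fx("acceptance_experiment", function() {
    tt <- fx_tetramer()
    mk <- tt$metadata$marker_resno
    vars <- list(
      complete = list(kind = "complete"),
      positive_only = list(kind = "positive_only"),
      reduced_90 = list(kind = "reduce", fraction = 0.9),
      reduced_70 = list(kind = "reduce", fraction = 0.7),
      reduced_50 = list(kind = "reduce", fraction = 0.5),
      reduced_30 = list(kind = "reduce", fraction = 0.3),
      erroneous_70 = list(kind = "erroneous", fraction = 0.7, mode = "flip_ones"),
      erroneous_30 = list(kind = "erroneous", fraction = 0.3, mode = "flip_ones"))
    cfg <- experiment_config(
      variants = vars, n_random_maps = 2, n_models_per_map = 3, seed = 42,
      electro = TRUE, electro_grid = grid_config(dims = 57L),
      electro_channels = "averaged", diameter_residue = mk,
      filter_residues = (mk - 2):(mk + 2))
    run_experiment(tt, cfg)
  })
}
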