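test_that("trim_dummy inverts the dummy-loop bookkeeping", {
  M <- matrix(0L, 4, 4); diag(M) <- 1L
  cm <- new_contact_map(M, chain_layout = data.frame(chain = c("A", "B"),
                                                     length = c(2L, 2L)))
  aug <- insert_dummy_loops(cm, 3)
  tr <- new_ca_trace(matrix(seq_len(21), 7, 3))
  out <- trim_dummy(tr, aug$mapping)
  expect_equal(nrow(out$xyz), 4)
  expect_equal(out$chain_breaks, 2L)
  expect_equal(out$xyz, tr$xyz[c(1, 2, 6, 7), ])

  # identity mapping is the identity transform
  id <- trim_dummy(tr, 1:7)
  expect_equal(id$xyz, tr$xyz)
  expect_length(id$chain_breaks, 0)

  cm4 <- fx_tetramer_map()
  aug4 <- insert_dummy_loops(cm4, 15)
  big <- new_ca_trace(matrix(rnorm(3 * aug4$cmap$L), ncol = 3))
  t4 <- trim_dummy(big, aug4$mapping)
  expect_equal(nrow(t4$xyz), 160)
  expect_equal(t4$chain_breaks, c(40L, 80L, 120L))
  expect_error(trim_dummy(new_ca_trace(matrix(0, 3, 3)), aug4$mapping), "mapping")
})

test_that("c_n_project produces exactly symmetric assemblies", {
  pt <- new_structure(data.frame(chain = "A", resno = 1, resname = "ALA",
                                 atom = "CA", element = "C", x = 1, y = 0, z = 0))
  out <- c_n_project(pt, symmetry_frame(order = 4))
  expect_equal(chain_ids(out), c("A", "B", "C", "D"))
  xyz <- coords(out)
  expect_equal(xyz, rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)),
               tolerance = 1e-12)

  sub <- get_chain(fx_tetramer(), "A")
  ch <- c_n_project(sub, symmetry_frame(order = 4))
  R <- rotation_about_axis(c(0, 0, 1), pi / 2)
  for (k in 2:4) {
    Rk <- rotation_about_axis(c(0, 0, 1), (k - 1) * pi / 2)
    expect_equal(coords(get_chain(ch, LETTERS[k])),
                 coords(get_chain(ch, "A")) %*% t(Rk), tolerance = 1e-10)
  }
  expect_error(c_n_project(ch, symmetry_frame(order = 4)), "single chain")
})

test_that("order-2 projection of a 2-atom chain gives mirror-pair geometry", {
  two <- new_structure(data.frame(chain = "A", resno = c(1, 2), resname = "ALA",
                                  atom = "CA", element = "C",
                                  x = c(2, 3), y = c(0, 1), z = c(0, 0.5)))
  out <- c_n_project(two, symmetry_frame(order = 2))
  expect_equal(nrow(out$atoms), 4)
  expect_equal(coords(get_chain(out, "B")),
               coords(get_chain(out, "A")) %*% diag(c(-1, -1, 1)),
               tolerance = 1e-12)
})

test_that("average_subunit removes rigid offsets and averages noise", {
  sub <- get_chain(fx_tetramer(), "A")
  same <- average_subunit(list(sub, sub, sub, sub))
  expect_equal(coords(same), coords(sub), tolerance = 1e-10)

  R <- rotation_about_axis(c(0, 1, 0), 0.7)
  moved <- set_coords(sub, sweep(coords(sub) %*% t(R), 2, c(3, -2, 5), "+"))
  avg2 <- average_subunit(list(sub, moved))
  expect_equal(coords(avg2), coords(sub), tolerance = 1e-6)

  set.seed(42)
  noisy <- lapply(1:4, function(k)
    set_coords(sub, coords(sub) + matrix(rnorm(length(coords(sub)), sd = 0.5),
                                         ncol = 3)))
  avg <- average_subunit(noisy)
  err_avg <- kabsch_superpose(coords(avg), coords(sub))$rmsd
  errs <- vapply(noisy, function(s) kabsch_superpose(coords(s), coords(sub))$rmsd, 1)
  expect_lt(err_avg, min(errs))
})

test_that("align_axis_to_z restores rotated assemblies and is idempotent", {
  tt <- fx_tetramer()
  al <- align_axis_to_z(tt)
  fr <- estimate_symmetry_frame(al, 4)
  expect_gte(abs(sum(fr$axis * c(0, 0, 1))), 0.999)

  R <- rotation_about_axis(c(1, 0, 0), pi / 2)
  rot <- set_coords(tt, coords(tt) %*% t(R))
  back <- align_axis_to_z(rot)
  fr2 <- estimate_symmetry_frame(back, 4)
  expect_gte(abs(sum(fr2$axis * c(0, 0, 1))), 0.999)

  twice <- align_axis_to_z(back)
  expect_equal(coords(twice), coords(back), tolerance = 1e-6)

  # reference route: superposition onto a z-aligned native is the Kabsch fit
  ref_al <- align_axis_to_z(rot, reference = tt)
  pr <- pair_coords(ref_al, tt)
  expect_lt(kabsch_superpose(pr$mobile, pr$target)$rmsd, 1e-8)
})

test_that("the symmetry frame of an exact C4 assembly is recovered", {
  fr <- estimate_symmetry_frame(fx_tetramer(), 4)
  expect_equal(abs(sum(fr$axis * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_equal(fr$center[1:2], c(0, 0), tolerance = 1e-9)
})

test_that("assemble_channels returns order + 1 exactly symmetric channels", {
  tt <- fx_tetramer()
  subs <- lapply(chain_ids(tt), function(cc) get_chain(tt, cc))
  fr <- estimate_symmetry_frame(tt, 4)
  out <- assemble_channels(subs, fr)
  expect_length(out, 5)
  for (ch in out) {
    expect_equal(length(chain_ids(ch)), 4)
    xyzA <- coords(get_chain(ch, "A"))
    for (k in 2:4) {
      Rk <- rotation_about_axis(c(0, 0, 1), (k - 1) * pi / 2)
      expect_equal(coords(get_chain(ch, LETTERS[k])), xyzA %*% t(Rk),
                   tolerance = 1e-8)
    }
  }
  # identical subunits: all five channels coincide up to rigid motion
  same <- assemble_channels(list(subs[[1]], subs[[1]], subs[[1]], subs[[1]]), fr)
  for (k in 2:5) {
    pr <- pair_coords(same[[k]], same[[1]])
    expect_lt(kabsch_superpose(pr$mobile, pr$target)$rmsd, 1e-6)
  }
  expect_error(assemble_channels(subs[1:3], fr), "exactly 4")
})
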