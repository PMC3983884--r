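test_that("contact-map construction enforces the ternary contract", {
  expect_error(new_contact_map(matrix(0, 2, 3)), "square")
  M <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(new_contact_map(M), "entries")
  M <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_error(new_contact_map(M), "symmetric")
})

test_that("derive_cmap matches plain geometry and a brute-force oracle", {
  collinear <- new_structure(data.frame(
    chain = "A", resno = 1:3, resname = "ALA", atom = "CA", element = "C",
    x = c(0, 3.8, 7.6), y = 0, z = 0))
  m8 <- derive_cmap(collinear, 8)$M
  expect_true(all(m8 == 1L))
  m5 <- derive_cmap(collinear, 5)$M
  expect_equal(m5[1, 2], 1L); expect_equal(m5[2, 3], 1L)
  expect_equal(m5[1, 3], 0L)
  expect_error(derive_cmap(collinear, -1), "positive")

  h <- fx_helix30()
  cm <- derive_cmap(h, 8, "CA")
  tr <- extract_ca_trace(h)
  oracle <- matrix(0L, 30, 30)
  for (i in 1:30) for (j in 1:30)
    oracle[i, j] <- as.integer(sqrt(sum((tr$xyz[i, ] - tr$xyz[j, ])^2)) <= 8)
  expect_equal(cm$M, oracle)
  # helical signature: (i, i+3) and (i, i+4) in contact, (i, i+6) not
  expect_true(all(cm$M[cbind(1:26, 4:29)] == 1L))
  expect_true(all(cm$M[cbind(1:26, 5:30)] == 1L))
  expect_true(all(cm$M[cbind(1:24, 7:30)] == 0L))
})

test_that("contact density equals the row-count mean", {
  all3 <- new_contact_map(matrix(1L, 3, 3))
  expect_equal(contact_density(all3), 2)
  expect_equal(contact_density(new_contact_map(diag(1L, 3))), 0)
  cm <- random_ternary_map(50, seed = 3)
  ci <- rowSums(cm$M == 1L) - 1
  expect_equal(contact_density(cm), mean(ci))
})

test_that("positive_only erases exactly the non-contacts and is idempotent", {
  cm <- random_ternary_map(40, seed = 5)
  po <- positive_only(cm)
  expect_equal(sum(po$M == 1L), sum(cm$M == 1L))
  expect_equal(sum(po$M == 0L), 0L)
  expect_equal(po$M[cm$M == 1L], cm$M[cm$M == 1L])
  expect_equal(positive_only(po)$M, po$M)
  expect_true(all(po$M == t(po$M)))
})

test_that("reduce_cmap removes the exact count, uniformly and reproducibly", {
  cm <- random_ternary_map(30, seed = 9)
  expect_equal(reduce_cmap(cm, 1.0, seed = 1)$M, cm$M)
  r0 <- reduce_cmap(cm, 0.0, seed = 1)$M
  expect_true(all(r0[upper.tri(r0)] == -1L))
  K <- sum(cm$M[upper.tri(cm$M)] != -1L)
  r <- reduce_cmap(cm, 0.3, seed = 4)
  kept <- sum(r$M[upper.tri(r$M)] != -1L)
  expect_equal(kept, K - floor(0.7 * K + 0.5))  # counts round half away from zero
  expect_true(all(r$M == t(r$M)))
  # known entries never change label, only become unknown
  ut <- upper.tri(cm$M)
  changed <- which(cm$M[ut] != r$M[ut])
  expect_true(all(r$M[ut][changed] == -1L))
  expect_equal(reduce_cmap(cm, 0.3, seed = 4)$M, r$M)
  expect_false(identical(reduce_cmap(cm, 0.3, seed = 5)$M, r$M))
  expect_error(reduce_cmap(cm, 1.2, seed = 1), "fraction")
})

test_that("inject_errors flips the exact count in both modes", {
  cm <- random_ternary_map(30, seed = 13)
  ut <- upper.tri(cm$M)
  expect_equal(inject_errors(cm, 1.0, "flip_ones", seed = 2)$M, cm$M)
  expect_equal(inject_errors(cm, 1.0, "flip_both", seed = 2)$M, cm$M)

  n1 <- sum(cm$M[ut] == 1L)
  e1 <- inject_errors(cm, 0.5, "flip_ones", seed = 2)
  expect_equal(sum(e1$M[ut] == 1L), n1 - round(0.5 * n1))
  expect_equal(sum(e1$M[ut] == -1L), sum(cm$M[ut] == -1L))

  K <- sum(cm$M[ut] != -1L)
  eb <- inject_errors(cm, 0.6, "flip_both", seed = 2)
  flipped <- sum(eb$M[ut] != cm$M[ut])
  expect_equal(flipped, round(0.4 * K))
  expect_true(all(eb$M == t(eb$M)))
  expect_equal(inject_errors(cm, 0.6, "flip_both", seed = 2)$M, eb$M)
})

test_that("perturbations preserve the symmetric ternary invariant", {
  for (seed in 1:5) {
    cm <- random_ternary_map(25, seed = seed, p_unknown = 0.1)
    for (out in list(positive_only(cm), reduce_cmap(cm, 0.5, seed),
                     inject_errors(cm, 0.7, "flip_ones", seed),
                     inject_errors(cm, 0.7, "flip_both", seed))) {
      expect_true(all(out$M %in% c(-1L, 0L, 1L)))
      expect_true(all(out$M == t(out$M)))
      expect_true(all(diag(out$M) == 1L))
    }
  }
})

test_that("dummy loops insert all-unknown blocks with invertible bookkeeping", {
  M <- matrix(0L, 4, 4); diag(M) <- 1L
  M[1, 3] <- M[3, 1] <- 1L
  cm <- new_contact_map(M, chain_layout = data.frame(chain = c("A", "B"),
                                                     length = c(2L, 2L)))
  aug <- insert_dummy_loops(cm, loop_length = 3)
  expect_equal(aug$cmap$L, 7)
  expect_equal(aug$mapping, c(1L, 2L, 6L, 7L))
  expect_equal(sum(aug$cmap$dummy_mask), 3)
  dummy_rows <- aug$cmap$M[3:5, -(3:5)]
  expect_true(all(dummy_rows == -1L))
  # restriction to real positions reproduces the input exactly
  expect_equal(aug$cmap$M[aug$mapping, aug$mapping], cm$M)

  cm4 <- fx_tetramer_map()
  aug4 <- insert_dummy_loops(cm4, 15)
  expect_equal(aug4$cmap$L, 160 + 15 * 3)
  expect_equal(aug4$cmap$M[aug4$mapping, aug4$mapping], cm4$M)
  expect_warning(insert_dummy_loops(random_ternary_map(5, 1), 3), "single-chain")
})

test_that("matrix and rr-list formats round-trip and validate", {
  cm <- random_ternary_map(20, seed = 21, p_unknown = 0.2)
  f <- tempfile()
  write_cmap(cm, f, "matrix")
  expect_equal(read_cmap(f, "matrix")$M, cm$M)
  f2 <- tempfile()
  write_cmap(cm, f2, "rr_list")
  expect_equal(read_cmap(f2, "rr_list", L = 20)$M, cm$M)

  f3 <- tempfile()
  writeLines(c("1 3 1"), f3)
  m <- read_cmap(f3, "rr_list", L = 3)$M
  expect_equal(m[1, 3], 1L); expect_equal(m[3, 1], 1L)
  expect_equal(m[1, 2], -1L); expect_equal(m[2, 3], -1L)

  f4 <- tempfile()
  writeLines(c("1 2", "2 1"), f4)
  expect_error(read_cmap(f4, "matrix"), "outside")
  f5 <- tempfile()
  writeLines(c("1 1 0", "0 1 1", "1 1 1"), f5)
  expect_error(read_cmap(f5, "matrix"), "symmetric|asymmetric")
})
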