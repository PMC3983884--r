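test_that("Kabsch superposition is exact on identical and rigidly moved sets", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)

  R <- rotation_about_axis(c(0, 0, 1), 37 * pi / 180)
  Q <- sweep(P %*% t(R), 2, c(1, -2, 3), "+")
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, R, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("Kabsch matches an independent numeric optimizer on random points", {
  set.seed(7)
  P <- matrix(rnorm(15), 5, 3)
  Q <- matrix(rnorm(15), 5, 3)
  fit <- kabsch_superpose(P, Q)
  # oracle: direct minimization over an axis-angle parameterization
  obj <- function(par) {
    ax <- par[1:3]; th <- sqrt(sum(ax^2))
    R <- if (th < 1e-12) diag(3) else rotation_about_axis(ax / th, th)
    moved <- sweep(P %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - Q)^2)))
  }
  best <- Inf
  for (k in 1:20) {
    o <- optim(c(rnorm(3), rnorm(3)), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-5)
  expect_lte(fit$rmsd, best + 1e-8)
  # fewer than 3 points: translation-only fallback, flagged
  d <- kabsch_superpose(P[1:2, ], Q[1:2, ])
  expect_true(d$degenerate)
})

test_that("global RMSD recognizes mirrors and cyclic chain relabelings", {
  tt <- fx_tetramer()
  expect_equal(as.numeric(global_rmsd(tt, tt)), 0, tolerance = 1e-10)

  mir <- set_coords(tt, coords(tt) %*% diag(c(-1, 1, 1)))
  expect_gt(as.numeric(global_rmsd(mir, tt)), 1)
  expect_equal(as.numeric(global_rmsd(mir, tt, mirror_aware = TRUE)), 0,
               tolerance = 1e-8)

  at <- tt$atoms
  at$chain <- c(B = "A", C = "B", D = "C", A = "D")[at$chain]
  relab <- new_structure(at[order(match(at$chain, LETTERS)), ])
  expect_equal(as.numeric(global_rmsd(relab, tt, permute_chains = TRUE)), 0,
               tolerance = 1e-8)
  # minimizing over more equivalences can only help
  m <- set_coords(tt, coords(tt) + matrix(rnorm(length(coords(tt))), ncol = 3))
  expect_lte(as.numeric(global_rmsd(m, tt, mirror_aware = TRUE, permute_chains = TRUE)),
             as.numeric(global_rmsd(m, tt)) + 1e-12)
})

test_that("RMSD is invariant under simultaneous rigid motion", {
  tt <- fx_tetramer()
  set.seed(3)
  m <- set_coords(tt, coords(tt) + matrix(rnorm(length(coords(tt)), sd = 0.7),
                                          ncol = 3))
  r0 <- as.numeric(global_rmsd(m, tt))
  R <- rotation_about_axis(unitv(c(1, 2, 3)), 1.1)
  mv <- function(s) set_coords(s, sweep(coords(s) %*% t(R), 2, c(5, 6, 7), "+"))
  expect_equal(as.numeric(global_rmsd(mv(m), mv(tt))), r0, tolerance = 1e-9)
})

test_that("subset RMSD reduces to the global one and isolates good cores", {
  tt <- fx_tetramer()
  set.seed(5)
  m <- set_coords(tt, coords(tt) + matrix(rnorm(length(coords(tt)), sd = 0.3),
                                          ncol = 3))
  all_res <- sort(unique(tt$atoms$resno))
  expect_equal(subset_rmsd(m, tt, all_res, align_on = "subset"),
               as.numeric(global_rmsd(m, tt)), tolerance = 1e-9)
  expect_equal(subset_rmsd(tt, tt, 5:10), 0, tolerance = 1e-10)

  # displace one loop region rigidly: core-aligned subset beats global
  at <- tt$atoms
  shift <- at$resno %in% 18:21
  disp <- tt; disp$atoms[shift, c("x", "y", "z")] <-
    disp$atoms[shift, c("x", "y", "z")] + 3
  core <- setdiff(all_res, 18:21)
  expect_lt(subset_rmsd(disp, tt, core, align_on = "subset"),
            as.numeric(global_rmsd(disp, tt)))
})

test_that("local RMSD localizes a constructed displacement", {
  tt <- fx_tetramer()
  expect_true(all(local_rmsd(tt, tt)$rmsd < 1e-9))

  disp <- tt
  mask <- disp$atoms$chain == "A" & disp$atoms$resno == 10
  disp$atoms[mask, c("x", "y", "z")] <- disp$atoms[mask, c("x", "y", "z")] + 2 / sqrt(3)
  lr <- local_rmsd(disp, tt)
  hit <- lr$rmsd[lr$chain == "A" & lr$resno == 10]
  expect_gt(hit, 1.5)
  expect_lt(max(lr$rmsd[!(lr$chain == "A" & lr$resno == 10)]), 0.5)
  # alignment leakage keeps the mean bounded by the global value
  expect_lte(mean(lr$rmsd), as.numeric(global_rmsd(disp, tt)) * 4)
})

test_that("structure diameter is plain marker-atom distance with symmetry", {
  tt <- fx_tetramer()
  mk <- tt$metadata$marker_resno
  d_ac <- structure_diameter(tt, mk, c("A", "C"))
  d_bd <- structure_diameter(tt, mk, c("B", "D"))
  expect_equal(d_ac, 2 * (tt$metadata$pore_radius + 4.6), tolerance = 1e-6)
  expect_equal(d_ac, d_bd, tolerance = 1e-9)
  a <- tt$atoms[tt$atoms$chain == "A" & tt$atoms$resno == mk & tt$atoms$atom == "CA", ]
  c_ <- tt$atoms[tt$atoms$chain == "C" & tt$atoms$resno == mk & tt$atoms$atom == "CA", ]
  expect_equal(d_ac, vnorm(as.numeric(a[, c("x", "y", "z")]) -
                           as.numeric(c_[, c("x", "y", "z")])))
  expect_error(structure_diameter(tt, 9999), "absent")
})

test_that("Kendall tau equals exhaustive pair counting for short vectors", {
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  brute_tau_b <- function(x, y) {
    n <- length(x); conc <- disc <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    tx <- sum(choose(table(x), 2)); ty <- sum(choose(table(y), 2))
    n0 <- choose(n, 2)
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  }
  set.seed(11)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, brute_tau_b(x, y), tolerance = 1e-12)
  }
  expect_true(kendall_tau(rep(1, 5), 1:5)$constant)
})

test_that("rank-sum z matches the closed form and the permutation law", {
  same <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0, tolerance = 1e-9)

  sep <- ranksum_test(1:10, 11:20)
  expect_equal(abs(sep$z), (sum(1:10) - 10 * 21 / 2) / sqrt(10 * 10 * 21 / 12) * -1,
               tolerance = 1e-9)

  # agreement with the exact permutation distribution at n = m = 8
  set.seed(19)
  a <- rnorm(8); b <- rnorm(8, mean = 0.8)
  rs <- ranksum_test(a, b)
  pool <- c(a, b)
  W_obs <- sum(rank(pool)[1:8])
  combs <- combn(16, 8)
  Ws <- apply(combs, 2, function(idx) sum(rank(pool)[idx]))
  mu <- 8 * 17 / 2
  p_exact <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
  expect_lt(abs(rs$p_value - p_exact), 0.02)
  # and with the standard implementation's p-value
  wt <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(rs$p_value, wt$p.value, tolerance = 1e-9)
})
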