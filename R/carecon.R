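# C-alpha trace reconstruction from a ternary contact map: a seeded random
# compact chain first, then iterative constraint projection against the map
# (contacts pulled inside the threshold, non-contacts pushed just beyond it,
# virtual bonds reset), with Gaussian kicks on stagnation and the best-ever
# trace kept. Contact maps carry no chirality, so every result is defined up
# to a rigid motion plus a possible reflection; handedness is resolved
# downstream by fix_chirality().

#' Reconstruction configuration
#'
#' @param bond_length virtual C-alpha/C-alpha bond length, Angstrom
#' @param contact_threshold contact distance threshold, Angstrom; defaults to
#'   the threshold recorded in the map being reconstructed
#' @param max_sweeps maximum refinement sweeps
#' @param satisfaction_target stop when this fraction of known pair
#'   constraints is satisfied
#' @param perturb_sigma std. dev. (Angstrom) of the Gaussian kick applied when
#'   refinement stagnates
#' @param move_fraction fraction of a pair violation corrected per sweep
#' @param push_margin non-contacts are pushed to threshold + margin, Angstrom
#' @param soft_margin width (Angstrom) of the hinge buffer around the
#'   threshold within which satisfied pairs are still nudged away from it;
#'   lifts the bent-solution degeneracy of maps whose information sits near
#'   the threshold
#' @param soft_weight strength of the buffer nudge relative to a full
#'   violation correction (0 disables)
#' @param polish_sweeps extra sweeps after convergence that anneal the trace
#'   toward the interior of the feasible set using the hinge buffer
#' @param restart_count independent restarts per model (best kept)
#' @param seed integer RNG seed
#' @return list of class `ReconConfig`
#' @export
recon_config <- function(bond_length = 3.8, contact_threshold = NULL,
                         max_sweeps = 1500L, satisfaction_target = 1.0,
                         perturb_sigma = 1.0, move_fraction = 0.5,
                         push_margin = 0.1, soft_margin = 1.0,
                         soft_weight = 0.1, polish_sweeps = 200L,
                         restart_count = 3L, seed = 1L) {
  stopifnot(bond_length > 0, max_sweeps >= 1, satisfaction_target > 0,
            satisfaction_target <= 1, perturb_sigma > 0, restart_count >= 1)
  structure(list(bond_length = bond_length, contact_threshold = contact_threshold,
                 max_sweeps = as.integer(max_sweeps),
                 satisfaction_target = satisfaction_target,
                 perturb_sigma = perturb_sigma, move_fraction = move_fraction,
                 push_margin = push_margin, soft_margin = soft_margin,
                 soft_weight = soft_weight,
                 polish_sweeps = as.integer(polish_sweeps),
                 restart_count = as.integer(restart_count),
                 seed = as.integer(seed)), class = "ReconConfig")
}

.cmap_threshold <- function(cmap, config) {
  thr <- config$contact_threshold
  if (is.null(thr)) thr <- cmap$meta$threshold
  if (is.null(thr)) thr <- 8
  thr
}

# bond mask: TRUE at i when points i, i+1 are bonded (no chain break between)
.bond_mask <- function(L, chain_breaks) {
  m <- rep(TRUE, L - 1L)
  cb <- chain_breaks[chain_breaks >= 1 & chain_breaks < L]
  m[cb] <- FALSE
  m
}

#' Generate the initial partially random trace
#'
#' A seeded self-avoiding-ish random walk with the virtual bond length fixed,
#' biased to stay inside a compact ball of radius
#' (3/(4*pi))^(1/3) * L^(1/3) * 4 Angstrom (volume scaling of globular
#' proteins), so refinement starts from a collapsed rather than extended
#' state.
#'
#' @param cmap ContactMap (only its size and chain structure are used)
#' @param config [recon_config()]
#' @return CaTrace
#' @export
initialize_trace <- function(cmap, config = recon_config()) {
  L <- cmap$L
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  R <- (3 / (4 * pi))^(1 / 3) * L^(1 / 3) * 4
  X <- matrix(0, L, 3)
  X[1, ] <- runif(3, -R / 4, R / 4)
  if (L > 1) {
    for (i in 2:L) {
      dir <- unitv(rnorm(3))
      prev <- X[i - 1, ]
      cand <- prev + config$bond_length * dir
      if (vnorm(cand) > R) { # steer back toward the ball center
        dir <- unitv(dir + 2 * unitv(-prev))
        cand <- prev + config$bond_length * dir
      }
      X[i, ] <- cand
    }
  }
  new_ca_trace(X, chain_breaks = integer(0),
               provenance = list(seed = config$seed, stage = "init"))
}

#' Refine a trace against its contact map
#'
#' Iterative correction sweeps over every known residue pair: a contact pair
#' beyond the threshold is pulled together by `move_fraction` of the excess;
#' a non-contact pair inside the threshold is pushed just beyond it; bonded
#' consecutive pairs are reset to the virtual bond length. Unknown (-1) pairs
#' impose nothing. When satisfaction stagnates the working copy receives a
#' Gaussian kick; the best-ever trace is returned with its satisfaction and
#' sweep count recorded.
#'
#' @param trace CaTrace of length cmap$L
#' @param cmap ContactMap
#' @param config [recon_config()]
#' @return refined CaTrace
#' @export
refine_trace <- function(trace, cmap, config = recon_config()) {
  if (nrow(trace$xyz) != cmap$L) stop("trace length != map size")
  thr <- .cmap_threshold(cmap, config)
  bonded <- .bond_mask(cmap$L, trace$chain_breaks)
  res <- .refine_cpp(trace$xyz, cmap$M, bonded, thr, config$bond_length,
                     config$max_sweeps, config$satisfaction_target,
                     config$move_fraction, config$push_margin,
                     config$perturb_sigma, 5L, config$seed,
                     config$soft_margin, config$soft_weight,
                     config$polish_sweeps)
  new_ca_trace(res$xyz, chain_breaks = trace$chain_breaks,
               provenance = list(seed = config$seed, sweeps = res$sweeps,
                                 satisfaction = res$satisfaction,
                                 threshold = thr))
}

#' Fraction of known pair constraints a trace satisfies
#'
#' @param trace CaTrace
#' @param cmap ContactMap
#' @param threshold contact threshold, Angstrom (default: from map metadata)
#' @return fraction in `[0, 1]`; an all-unknown map gives 1 (vacuous)
#' @export
contact_satisfaction <- function(trace, cmap, threshold = NULL) {
  if (nrow(trace$xyz) != cmap$L) stop("trace length != map size")
  thr <- if (is.null(threshold)) .cmap_threshold(cmap, recon_config()) else threshold
  .satisfaction_cpp(trace$xyz, cmap$M, thr)
}

#' Reconstruct an ensemble of C-alpha traces from a contact map
#'
#' Each model is an independent initialize + refine run with seeds
#' `seed, seed + 1, ...`. With `restart_count > 1` each model keeps the best
#' of several restarts. Dummy positions (all-unknown rows) take part in the
#' bonded chain but impose no contact constraints.
#'
#' @param cmap ContactMap
#' @param config [recon_config()]
#' @param n_models number of independent models
#' @return list of CaTrace
#' @export
reconstruct_ca <- function(cmap, config = recon_config(), n_models = 1L) {
  if (n_models < 1) stop("n_models must be >= 1")
  lapply(seq_len(n_models), function(m) {
    best <- NULL
    for (r in seq_len(config$restart_count)) {
      cfg <- config
      cfg$seed <- config$seed + (m - 1L) + 100003L * (r - 1L)
      tr <- refine_trace(initialize_trace(cmap, cfg), cmap, cfg)
      if (is.null(best) || tr$provenance$satisfaction > best$provenance$satisfaction)
        best <- tr
    }
    best$provenance$model <- m
    best
  })
}
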