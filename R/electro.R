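# Electrostatic functional assessment of channel models: formal-charge (or
# PQR) charge assignment, a two-dielectric finite-difference Poisson solve
# (zero ionic strength, so the linearized Poisson-Boltzmann equation reduces
# to the variable-dielectric Poisson equation), the pore-axis potential
# profile and its descriptors (Fmax, Fmin, zmin, RMSE vs a template).

#' Poisson grid configuration
#'
#' Defaults follow the channel assessment setup: a cubic 129 x 129 x 129
#' grid at 1 Angstrom spacing, protein dielectric 4, solvent dielectric 80.
#'
#' @param dims points per axis (odd, so the center lies on a node)
#' @param spacing grid spacing, Angstrom
#' @param eps_protein relative dielectric inside any atom's vdW sphere
#' @param eps_solvent relative dielectric elsewhere (electrolyte, pore)
#' @param center grid center, Angstrom
#' @return list of class `GridConfig`
#' @export
grid_config <- function(dims = 129L, spacing = 1, eps_protein = 4,
                        eps_solvent = 80, center = c(0, 0, 0)) {
  if (dims %% 2 == 0) stop("dims must be odd (center on a node)")
  if (spacing <= 0 || eps_protein <= 0 || eps_solvent <= 0)
    stop("spacing and dielectric constants must be positive")
  structure(list(dims = as.integer(dims), spacing = spacing,
                 eps_protein = eps_protein, eps_solvent = eps_solvent,
                 center = as.numeric(center)), class = "GridConfig")
}

#' Assign per-atom charges for the Poisson solve
#'
#' `formal` places integer formal charges on titratable groups: -1 e split
#' over Asp OD1/OD2 and Glu OE1/OE2, +1 e on Lys NZ, +0.5 e on each Arg
#' NH1/NH2, +1 e on each chain's N-terminal N and -1 e over the C-terminal
#' O/OXT. `pqr` reads per-atom charges and radii from a PQR file instead.
#' Radii for the formal scheme come from the embedded van der Waals table.
#'
#' @param s Structure (z-aligned for profile work)
#' @param scheme "formal" or "pqr"
#' @param pqr_path PQR file (required for scheme "pqr")
#' @return data.frame: x, y, z, q (e), radius (Angstrom) for every atom
#' @export
assign_charges <- function(s, scheme = c("formal", "pqr"), pqr_path = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "pqr") {
    if (is.null(pqr_path)) stop("scheme 'pqr' needs pqr_path")
    pq <- bio3d::read.pqr(pqr_path)
    return(data.frame(x = pq$atom$x, y = pq$atom$y, z = pq$atom$z,
                      q = pq$atom$o, radius = pq$atom$b))
  }
  at <- s$atoms
  q <- rep(0, nrow(at))
  q[at$resname == "ASP" & at$atom %in% c("OD1", "OD2")] <- -0.5
  q[at$resname == "GLU" & at$atom %in% c("OE1", "OE2")] <- -0.5
  q[at$resname == "LYS" & at$atom == "NZ"] <- 1
  q[at$resname == "ARG" & at$atom %in% c("NH1", "NH2")] <- 0.5
  for (cc in chain_ids(s)) {
    rows <- which(at$chain == cc)
    rn <- at$resno[rows]
    nterm <- rows[rn == min(rn) & at$atom[rows] == "N"]
    if (length(nterm)) q[nterm[1]] <- q[nterm[1]] + 1
    cres <- rows[rn == max(rn)]
    oxt <- cres[at$atom[cres] == "OXT"]
    oo <- cres[at$atom[cres] == "O"]
    if (length(oxt) && length(oo)) {
      q[oxt[1]] <- q[oxt[1]] - 0.5; q[oo[1]] <- q[oo[1]] - 0.5
    } else if (length(oo)) q[oo[1]] <- q[oo[1]] - 1
  }
  rad <- .vdw[at$element]
  rad[is.na(rad)] <- 1.7
  data.frame(x = at$x, y = at$y, z = at$z, q = q, radius = unname(rad))
}

#' Solve the variable-dielectric Poisson equation
#'
#' 7-point finite differences with harmonic-mean dielectric on half-edges;
#' charges are trilinearly splatted to grid nodes; the Dirichlet boundary is
#' the Coulomb sum in the solvent dielectric. Iterated (red-black SOR) to a
#' relative residual below `tol`.
#'
#' @param charges data.frame from [assign_charges()] (columns x, y, z, q,
#'   radius)
#' @param config [grid_config()]
#' @param tol relative residual tolerance
#' @param max_iter iteration cap; exceeding it is an error
#' @return list of class `PotentialGrid`: `values` (3D array, mV), `origin`,
#'   `spacing`, `iterations`, `residual`
#' @export
solve_poisson <- function(charges, config = grid_config(), tol = 1e-6,
                          max_iter = 20000L) {
  n <- config$dims
  half <- (n - 1) / 2 * config$spacing
  origin <- config$center - half
  if (nrow(charges)) {
    mins <- apply(charges[, c("x", "y", "z")], 2, min)
    maxs <- apply(charges[, c("x", "y", "z")], 2, max)
    if (any(mins < origin + 10) || any(maxs > origin + 2 * half - 10))
      warning("grid margin around charges is below 10 Angstrom")
  }
  res <- .poisson_cpp(as.matrix(charges[, c("x", "y", "z")]), charges$q,
                      charges$radius, n, config$spacing, origin,
                      config$eps_protein, config$eps_solvent, tol,
                      as.integer(max_iter))
  if (res$residual > tol && nrow(charges))
    stop("Poisson solve did not converge: residual ", format(res$residual))
  structure(list(values = res$phi, origin = origin, spacing = config$spacing,
                 iterations = res$iterations, residual = res$residual),
            class = "PotentialGrid")
}

# trilinear interpolation of a PotentialGrid at points (n x 3 matrix)
interp_grid <- function(grid, pts) {
  n <- dim(grid$values)[1]
  g <- (pts - matrix(grid$origin, nrow(pts), 3, byrow = TRUE)) / grid$spacing
  if (any(g < 0) || any(g > n - 1)) stop("point outside grid")
  i <- pmin(floor(g[, 1]), n - 2); fx <- g[, 1] - i
  j <- pmin(floor(g[, 2]), n - 2); fy <- g[, 2] - j
  k <- pmin(floor(g[, 3]), n - 2); fz <- g[, 3] - k
  v <- numeric(nrow(pts))
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di == 1) fx else 1 - fx) * (if (dj == 1) fy else 1 - fy) *
         (if (dk == 1) fz else 1 - fz)
    v <- v + w * grid$values[cbind(i + di + 1, j + dj + 1, k + dk + 1)]
  }
  v
}

#' Pore-axis potential profile
#'
#' The potential sampled by trilinear interpolation along the vertical line
#' (x0, y0, z), one sample per grid spacing.
#'
#' @param grid PotentialGrid
#' @param axis_xy (x0, y0) of the pore axis, Angstrom
#' @param z_range (zlo, zhi); default the grid extent
#' @return data.frame of class `AxialProfile`: z, phi (mV)
#' @export
axial_profile <- function(grid, axis_xy = c(0, 0), z_range = NULL) {
  n <- dim(grid$values)[1]
  zmax <- grid$origin[3] + (n - 1) * grid$spacing
  if (is.null(z_range)) z_range <- c(grid$origin[3], zmax)
  z <- seq(max(z_range[1], grid$origin[3]), min(z_range[2], zmax),
           by = grid$spacing)
  pts <- cbind(axis_xy[1], axis_xy[2], z)
  out <- data.frame(z = z, phi = interp_grid(grid, pts))
  class(out) <- c("AxialProfile", "data.frame")
  out
}

#' Profile descriptors
#'
#' @param profile AxialProfile
#' @return list of class `ProfileParams`: `Fmax`, `Fmin` (mV), `zmin`
#'   (Angstrom, first occurrence on ties, flagged), `tie` flag
#' @export
profile_params <- function(profile) {
  if (!nrow(profile)) stop("empty profile")
  imin <- which(profile$phi == min(profile$phi))
  structure(list(Fmax = max(profile$phi), Fmin = min(profile$phi),
                 zmin = profile$z[imin[1]], tie = length(imin) > 1),
            class = "ProfileParams")
}

#' Distance between a profile and a template
#'
#' Both profiles restricted to their common z grid; RMSE of the potential
#' plus the relative deviations of Fmax, Fmin and zmin from the template
#' values.
#'
#' @param profile,template AxialProfile
#' @return list: `rmse` (mV), `dFmax`, `dFmin`, `dzmin` (relative, unitless)
#' @export
profile_distance <- function(profile, template) {
  zp <- round(profile$z, 6); zt <- round(template$z, 6)
  common <- intersect(zp, zt)
  if (!length(common)) stop("no z overlap between profiles")
  p <- profile$phi[match(common, zp)]
  t <- template$phi[match(common, zt)]
  pp <- profile_params(profile[profile$z %in% common, , drop = FALSE])
  tp <- profile_params(template[template$z %in% common, , drop = FALSE])
  rel <- function(a, b) if (abs(b) < 1e-12) NA_real_ else abs(a - b) / abs(b)
  list(rmse = sqrt(mean((p - t)^2)),
       dFmax = rel(pp$Fmax, tp$Fmax),
       dFmin = rel(pp$Fmin, tp$Fmin),
       dzmin = rel(pp$zmin, tp$zmin))
}

#' Write a PotentialGrid in OpenDX scalar format
#'
#' @param grid PotentialGrid
#' @param path output file
#' @return invisibly, `path`
#' @export
write_dx <- function(grid, path) {
  n <- dim(grid$values)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n, n, n),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n, n, n),
    sprintf("object 3 class array type double rank 0 items %d data follows", n^3)
  ), con)
  # dx convention: z varies fastest
  flat <- numeric(n^3)
  c0 <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    flat[c0:(c0 + n - 1L)] <- grid$values[i, j, ]
    c0 <- c0 + n
  }
  pad <- ceiling(length(flat) / 3) * 3
  flat <- c(flat, rep(NA_real_, pad - length(flat)))
  m <- matrix(flat, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(format(r[!is.na(r)], digits = 6),
                                         collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
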