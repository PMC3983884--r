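# Structural quality metrics: least-squares superposition and the RMSD
# family (global, subset, per-residue), the structure diameter, and the rank
# statistics used to relate structural and electrostatic quality.

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation + translation mapping `mobile` onto `target` in
#' the least-squares sense. Reflections are excluded (det R = +1). With
#' fewer than 3 points the fit degenerates to a translation and is flagged.
#'
#' @param mobile n x 3 matrix
#' @param target n x 3 matrix, paired row-wise with `mobile`
#' @return list: `rotation` (3x3), `translation` (length 3), `rmsd`,
#'   `degenerate` flag. The transform acts as `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) stop("point sets differ in size")
  n <- nrow(mobile)
  mc <- colMeans(mobile); tc <- colMeans(target)
  if (n < 3) {
    R <- diag(3)
    tr <- tc - mc
    moved <- sweep(mobile, 2, tr, "+")
    return(list(rotation = R, translation = tr,
                rmsd = sqrt(mean(rowSums((moved - target)^2))), degenerate = TRUE))
  }
  P <- sweep(mobile, 2, mc)
  Q <- sweep(target, 2, tc)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- tc - as.numeric(R %*% mc)
  moved <- sweep(mobile %*% t(R), 2, tr, "+")
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - target)^2))), degenerate = FALSE)
}

#' Pair the shared atoms of two structures
#'
#' Residues are matched by concatenated index under an optional cyclic chain
#' shift of the model; within a residue pair, atoms are matched by shared
#' heavy-atom name.
#'
#' @param model,native Structures with matching per-chain residue counts
#' @param shift cyclic chain shift applied to the model (0 = identity)
#' @param atoms optional atom-name restriction (e.g. "CA")
#' @param residues optional residue-number restriction (native numbering)
#' @param chains optional chain restriction (native chain ids)
#' @return list of matrices `mobile`, `target` and data.frame `info`
#'   (chain/resno of each paired atom, native labels)
#' @export
pair_coords <- function(model, native, shift = 0L, atoms = NULL,
                        residues = NULL, chains = NULL) {
  mch <- chain_ids(model); nch <- chain_ids(native)
  if (length(mch) != length(nch)) stop("chain counts differ")
  ord <- if (shift == 0L) seq_along(mch) else
    c((shift + 1L):length(mch), seq_len(shift))
  mob <- list(); tar <- list(); info <- list()
  for (k in seq_along(nch)) {
    na <- native$atoms[native$atoms$chain == nch[k], , drop = FALSE]
    ma <- model$atoms[model$atoms$chain == mch[ord[k]], , drop = FALSE]
    if (!is.null(chains) && !nch[k] %in% chains) next
    nres <- unique(na$resno); mres <- unique(ma$resno)
    if (length(nres) != length(mres)) stop("residue counts differ in chain ", nch[k])
    for (r in seq_along(nres)) {
      if (!is.null(residues) && !nres[r] %in% residues) next
      nr <- na[na$resno == nres[r], , drop = FALSE]
      mr <- ma[ma$resno == mres[r], , drop = FALSE]
      shared <- intersect(nr$atom, mr$atom)
      if (!is.null(atoms)) shared <- intersect(shared, atoms)
      if (!length(shared)) next
      mob[[length(mob) + 1L]] <- as.matrix(mr[match(shared, mr$atom), c("x", "y", "z")])
      tar[[length(tar) + 1L]] <- as.matrix(nr[match(shared, nr$atom), c("x", "y", "z")])
      info[[length(info) + 1L]] <- data.frame(chain = nch[k], resno = nres[r],
                                              atom = shared, stringsAsFactors = FALSE)
    }
  }
  if (!length(mob)) stop("no common atoms to pair")
  list(mobile = do.call(rbind, mob), target = do.call(rbind, tar),
       info = do.call(rbind, info))
}

.mirror <- function(xyz) { xyz[, 1] <- -xyz[, 1]; xyz }

#' Global full-atom RMSD after optimal superposition
#'
#' Minimum RMSD over the requested equivalences: optionally the mirror image
#' of the model (contact maps carry no handedness) and the cyclic chain
#' relabelings of a symmetric assembly.
#'
#' @param model,native Structures with matching sequences
#' @param mirror_aware also try the reflected model
#' @param permute_chains also try cyclic chain permutations
#' @param atoms optional atom-name restriction ("CA" for a C-alpha RMSD)
#' @return minimum RMSD (Angstrom), with the choices made in attributes
#'   `mirror` and `shift`
#' @export
global_rmsd <- function(model, native, mirror_aware = FALSE,
                        permute_chains = FALSE, atoms = NULL) {
  nch <- length(chain_ids(model))
  shifts <- if (permute_chains) 0:(nch - 1L) else 0L
  best <- Inf; best_m <- FALSE; best_s <- 0L
  for (sh in shifts) {
    pr <- pair_coords(model, native, shift = sh, atoms = atoms)
    for (mir in if (mirror_aware) c(FALSE, TRUE) else FALSE) {
      mob <- if (mir) .mirror(pr$mobile) else pr$mobile
      r <- kabsch_superpose(mob, pr$target)$rmsd
      if (r < best) { best <- r; best_m <- mir; best_s <- sh }
    }
  }
  structure(best, mirror = best_m, shift = best_s)
}

#' RMSD over a residue selection
#'
#' `align_on = "subset"` superposes on the selection atoms themselves (the
#' channel selectivity-filter convention); `align_on = "global"` superposes
#' on all shared atoms and then evaluates the selection.
#'
#' @param model,native Structures
#' @param residues residue numbers (native numbering) of the selection
#' @param chains optional chain restriction
#' @param align_on "subset" or "global"
#' @param mirror_aware also try the reflected model
#' @return RMSD (Angstrom) over the selection atoms
#' @export
subset_rmsd <- function(model, native, residues, chains = NULL,
                        align_on = c("subset", "global"), mirror_aware = FALSE) {
  align_on <- match.arg(align_on)
  sel <- pair_coords(model, native, residues = residues, chains = chains)
  if (!nrow(sel$mobile)) stop("empty selection")
  vals <- vapply(if (mirror_aware) c(FALSE, TRUE) else FALSE, function(mir) {
    selm <- if (mir) .mirror(sel$mobile) else sel$mobile
    if (align_on == "subset") {
      kabsch_superpose(selm, sel$target)$rmsd
    } else {
      pr <- pair_coords(model, native)
      fit <- kabsch_superpose(if (mir) .mirror(pr$mobile) else pr$mobile, pr$target)
      moved <- sweep(selm %*% t(fit$rotation), 2, fit$translation, "+")
      sqrt(mean(rowSums((moved - sel$target)^2)))
    }
  }, 1)
  min(vals)
}

#' Per-residue RMSD at global alignment
#'
#' One global full-atom superposition, then for every residue the RMSD over
#' its shared heavy atoms.
#'
#' @param model,native Structures
#' @param mirror_aware also try the reflected model for the global fit
#' @return data.frame: chain, resno, rmsd
#' @export
local_rmsd <- function(model, native, mirror_aware = FALSE) {
  pr <- pair_coords(model, native)
  fits <- lapply(if (mirror_aware) c(FALSE, TRUE) else FALSE, function(mir) {
    mob <- if (mir) .mirror(pr$mobile) else pr$mobile
    c(list(mir = mir), kabsch_superpose(mob, pr$target))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, 1, "rmsd"))]]
  mob <- if (fit$mir) .mirror(pr$mobile) else pr$mobile
  moved <- sweep(mob %*% t(fit$rotation), 2, fit$translation, "+")
  dev2 <- rowSums((moved - pr$target)^2)
  key <- paste(pr$info$chain, pr$info$resno)
  agg <- tapply(dev2, factor(key, levels = unique(key)), function(v) sqrt(mean(v)))
  first <- !duplicated(key)
  data.frame(chain = pr$info$chain[first], resno = pr$info$resno[first],
             rmsd = as.numeric(agg), stringsAsFactors = FALSE)
}

#' Structure diameter
#'
#' Distance between the same marker residue on two opposite chains of a
#' channel (for a KcsA-type tetramer, classically the ALA-50 pair across the
#' pore), measured on a named atom. A compactness gauge: collapsed models
#' show it immediately.
#'
#' @param s Structure
#' @param residue_number marker residue number
#' @param chain_pair two chain ids (default the A/C diagonal)
#' @param atom atom name (default "CA")
#' @return distance in Angstrom
#' @export
structure_diameter <- function(s, residue_number, chain_pair = c("A", "C"),
                               atom = "CA") {
  pick <- function(cc) {
    r <- s$atoms[s$atoms$chain == cc & s$atoms$resno == residue_number &
                 s$atoms$atom == atom, , drop = FALSE]
    if (!nrow(r)) stop("atom ", atom, " of residue ", residue_number,
                       " absent in chain ", cc)
    as.numeric(r[1, c("x", "y", "z")])
  }
  vnorm(pick(chain_pair[1]) - pick(chain_pair[2]))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau with a two-sided normal-approximation p-value.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @return list: `tau`, `p_value`, `constant` flag (tau undefined)
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need equal lengths >= 2")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(tau = NA_real_, p_value = NA_real_, constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE, continuity = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, constant = FALSE)
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Tie-corrected z statistic for the rank sum of `a`, with a two-sided
#' p-value.
#'
#' @param a,b numeric samples
#' @return list: `z`, `p_value`
#' @export
ranksum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tiecor)
  if (v <= 0) return(list(z = 0, p_value = 1))
  z <- (W - mu) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Summarize an ensemble metric as mean +/- sample SD
#' @param x numeric vector
#' @return named vector c(mean, sd)
#' @export
ensemble_summary <- function(x) c(mean = mean(x), sd = stats::sd(x))
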