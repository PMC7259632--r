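# Distance, turn-span, superposition, LRMSD and RMSF computations.

#' Calpha-Calpha span between two residues
#'
#' The distance between the Calpha atoms of the first and last residues of the
#' epitope turn is the sharpness measure used throughout the package: small
#' spans correspond to sharp turns that leave the key lysine side chain free.
#'
#' @param structure a `structure3d`.
#' @param chain chain identifier.
#' @param res_i,res_j author residue numbers.
#' @return Distance in Angstrom.
#' @export
ca_span <- function(structure, chain, res_i, res_j) {
  get_ca <- function(r) {
    at <- select_atoms(structure, chain = chain, res_range = c(r, r),
                       atom_names = "CA")
    if (nrow(at) == 0L)
      stop(sprintf("selection error: no CA atom for residue %d of chain %s",
                   r, chain))
    coords(at)[1, ]
  }
  sqrt(sum((get_ca(res_i) - get_ca(res_j))^2))
}

#' Classify a turn span as sharp, wide or extended
#'
#' Default thresholds place the boundaries between the clusters of spans seen
#' in published amyloid-beta aggregate models: sharp exemplars fall below
#' ~8 Angstrom, wide turns up to ~13 Angstrom, anything larger is effectively
#' an extended (non-turn) conformation.
#'
#' @param span Calpha-Calpha span in Angstrom (vectorized).
#' @param sharp_max upper bound of the sharp class (default 8.5).
#' @param wide_max upper bound of the wide class (default 13.5).
#' @return Character vector in `c("sharp", "wide", "extended")`.
#' @export
classify_turn <- function(span, sharp_max = 8.5, wide_max = 13.5) {
  stopifnot(sharp_max > 0, sharp_max < wide_max)
  if (any(span < 0)) stop("domain error: negative span")
  ifelse(span <= sharp_max, "sharp",
         ifelse(span <= wide_max, "wide", "extended"))
}

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `reference` (reflections are excluded by sign correction of the
#' smallest singular vector).
#'
#' @param mobile,reference n x 3 coordinate matrices, equal n >= 3.
#' @return List with `rotation` (3x3, applied as `sweep(mobile %*% t(R))`),
#'   `translation` (length-3), `rmsd` (Angstrom), and `transform(xyz)`, a
#'   function applying the fit to any n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("shape error: coordinate sets differ in size")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate input: need at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  if (qr(P)$rank < 2L || qr(Q)$rank < 2L)
    stop("degenerate input: collinear coordinates")
  H <- crossprod(P, Q)                      # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  translation <- as.numeric(cr - R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = function(xyz) sweep(as.matrix(xyz) %*% t(R), 2,
                                       translation, `+`))
}

.traj_selection <- function(traj, chain, res_range, atom_names) {
  sel <- lapply(traj$frames, select_atoms, chain = chain,
                res_range = res_range, atom_names = atom_names)
  n <- vapply(sel, nrow, integer(1))
  if (n[1] == 0L) stop("selection error: empty selection")
  key1 <- paste(sel[[1]]$chain, sel[[1]]$resseq, sel[[1]]$icode, sel[[1]]$name)
  for (s in sel[-1]) {
    if (!identical(paste(s$chain, s$resseq, s$icode, s$name), key1))
      stop("topology error: selection differs between frames")
  }
  sel
}

#' Per-frame LRMSD relative to the first frame
#'
#' Each frame's selection is optimally superposed onto frame 1 and the minimum
#' RMSD recorded; the first value is therefore 0.
#'
#' @param traj a `trajectory3d`.
#' @param chain,res_range,atom_names selection (default: all Calpha atoms).
#' @return data.frame with columns `frame` and `lrmsd` (Angstrom).
#' @export
lrmsd_series <- function(traj, chain = NULL, res_range = NULL,
                         atom_names = "CA") {
  sel <- .traj_selection(traj, chain, res_range, atom_names)
  ref <- coords(sel[[1]])
  lr <- vapply(sel, function(s) kabsch_superpose(coords(s), ref)$rmsd,
               double(1))
  data.frame(frame = seq_along(sel), lrmsd = lr)
}

#' Per-residue RMSF over superposed frames
#'
#' All frames are superposed onto frame 1 over the alignment selection
#' (default: all Calpha atoms); each profiled atom's RMSF is the root of its
#' mean squared deviation from its mean position across the superposed frames.
#'
#' @param traj a `trajectory3d` with >= 2 frames.
#' @param chain,res_range,atom_names profile selection (default: all Calpha
#'   atoms).
#' @param align optional list with entries `chain`, `res_range`, `atom_names`
#'   naming the superposition selection; defaults to the full Calpha set.
#' @return data.frame with columns `chain`, `resseq`, `icode`, `name`, `rmsf`.
#' @export
rmsf_profile <- function(traj, chain = NULL, res_range = NULL,
                         atom_names = "CA", align = NULL) {
  if (length(traj$frames) < 2L)
    stop("degenerate input: RMSF needs at least 2 frames")
  sel <- .traj_selection(traj, chain, res_range, atom_names)
  if (is.null(align)) align <- list(atom_names = "CA")
  asel <- .traj_selection(traj, align$chain, align$res_range,
                          align$atom_names)
  aref <- coords(asel[[1]])
  aligned <- lapply(seq_along(sel), function(k) {
    fit <- kabsch_superpose(coords(asel[[k]]), aref)
    fit$transform(coords(sel[[k]]))
  })
  n_at <- nrow(aligned[[1]])
  mean_pos <- Reduce(`+`, aligned) / length(aligned)
  sq <- matrix(0, n_at, length(aligned))
  for (k in seq_along(aligned))
    sq[, k] <- rowSums((aligned[[k]] - mean_pos)^2)
  rmsf <- unname(sqrt(rowMeans(sq)))
  out <- sel[[1]][, c("chain", "resseq", "icode", "name")]
  out$rmsf <- rmsf
  rownames(out) <- NULL
  out
}
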