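## Superposition, RMSD/RMSF, glycosidic torsions and contact counts.
## These are the per-structure analyses applied to the slipped-ensemble
## (basin C) conformations: geometric drift of the G-core, loop
## fluctuations, the anti/syn flip of the 5' adenine, and the
## K+-O6 / water-bridge coordination that stabilises the G-triad.

.as_coord_matrix <- function(x, indices = NULL) {
  m <- if (is(x, "G4Structure")) coords(x) else as.matrix(x)
  if (!is.null(indices)) m <- m[indices, , drop = FALSE]
  storage.mode(m) <- "double"
  m
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' \code{mobile} onto \code{reference}.
#'
#' @param mobile,reference n x 3 coordinate matrices (or structures),
#'   equal atom counts, n >= 3.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3) such that \code{mobile \%*\% t(rotation) + translation}
#'   superposes onto the reference, and the post-fit \code{rmsd} in
#'   Angstrom.
#' @export
superpose <- function(mobile, reference) {
  P <- .as_coord_matrix(mobile)
  Q <- .as_coord_matrix(reference)
  if (nrow(P) != nrow(Q))
    stop("superpose: coordinate sets differ in atom count (",
         nrow(P), " vs ", nrow(Q), ")", call. = FALSE)
  if (nrow(P) < 3)
    stop("superpose: need at least 3 atoms", call. = FALSE)
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  sv_check <- svd(Pc)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1))
    stop("superpose: degenerate (collinear) coordinates", call. = FALSE)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  fit <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Qc)^2)))
  list(rotation = R, translation = as.numeric(qbar - R %*% pbar),
       rmsd = rmsd)
}

#' Superposed RMSD of a subset along a trajectory
#'
#' Each frame's subset atoms are optimally superposed onto the same
#' subset of the reference structure; the post-fit RMSD is reported per
#' frame.
#'
#' @param traj a [G4Trajectory-class].
#' @param reference a [G4Structure-class] resolvable by the same
#'   selection.
#' @param subset selection string (see [selectAtoms()]).
#' @return data.frame with columns \code{time_ps}, \code{rmsd}.
#' @export
rmsdSeries <- function(traj, reference, subset) {
  it <- selectAtoms(traj@topology, subset)
  ir <- selectAtoms(reference, subset)
  if (!length(it) || !length(ir))
    stop("rmsdSeries: subset selects no atoms", call. = FALSE)
  if (length(it) != length(ir))
    stop("rmsdSeries: subset resolves to different atom counts",
         call. = FALSE)
  ref <- coords(reference)[ir, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(k)
    superpose(traj@coords[it, , k], ref)$rmsd, 0.0)
  data.frame(time_ps = traj@times, rmsd = vals)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed (on the subset) onto their time-mean
#' structure; the RMSF of each residue is the root-mean-square
#' deviation of its subset atoms from the mean over time.
#'
#' @param traj a [G4Trajectory-class] with at least 2 frames.
#' @param subset selection string; fluctuations are reported for the
#'   residues of these atoms.
#' @return data.frame with columns \code{resid}, \code{rmsf} (Angstrom).
#' @export
rmsf <- function(traj, subset) {
  if (nFrames(traj) < 2)
    stop("rmsf: need at least 2 frames", call. = FALSE)
  idx <- selectAtoms(traj@topology, subset)
  if (!length(idx)) stop("rmsf: subset selects no atoms", call. = FALSE)
  nf <- nFrames(traj)
  sub <- traj@coords[idx, , , drop = FALSE]
  ## two-pass: fit to first frame, average, re-fit to the mean
  ref <- sub[, , 1]
  fitted <- array(NA_real_, dim(sub))
  for (pass in 1:2) {
    for (k in seq_len(nf)) {
      sp <- superpose(sub[, , k], ref)
      fitted[, , k] <- sub[, , k] %*% t(sp$rotation) +
        matrix(sp$translation, nrow(ref), 3, byrow = TRUE)
    }
    ref <- apply(fitted, c(1, 2), mean)
  }
  dev2 <- sapply(seq_len(nf), function(k) rowSums((fitted[, , k] - ref)^2))
  msf_atom <- rowMeans(dev2)
  res <- traj@topology@atoms$resid[idx]
  out <- aggregate(msf_atom, list(resid = res), mean)
  data.frame(resid = out$resid, rmsf = sqrt(out$x))
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 coordinate vectors (length 3).
#' @return angle in degrees in (-180, 180].
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Glycosidic torsion and syn/anti label of a purine nucleotide
#'
#' chi is the O4'-C1'-N9-C4 dihedral; the base is labelled \code{syn}
#' for chi in (-90, +90] and \code{anti} otherwise (the standard
#' nucleic-acid convention).
#'
#' @param structure a [G4Structure-class].
#' @param residue_number residue to analyse (purine with O4', C1', N9,
#'   C4 present).
#' @return list with \code{residue_number}, \code{chi} (degrees),
#'   \code{label} ("syn"/"anti").
#' @export
glycosidicChi <- function(structure, residue_number) {
  a <- structure@atoms
  sel <- a$resid == residue_number
  pick <- function(nm) {
    i <- which(sel & a$name == nm)
    if (!length(i))
      stop("glycosidicChi: residue ", residue_number, " is missing atom ",
           nm, call. = FALSE)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  chi <- dihedralAngle(pick("O4'"), pick("C1'"), pick("N9"), pick("C4"))
  list(residue_number = residue_number, chi = chi,
       label = if (chi > -90 && chi <= 90) "syn" else "anti")
}

#' Hard contact count between two atom groups
#'
#' Number of (a, b) pairs at distance <= cutoff.  This is the
#' un-switched count used for reporting (e.g. K+ against guanine O6
#' oxygens); smooth switched counts are the CV layer's job.
#'
#' @param x a [G4Structure-class] or n x 3 coordinate matrix.
#' @param groupA,groupB integer atom indices.
#' @param cutoff distance cutoff, Angstrom (default 3.5).
#' @return integer pair count.
#' @export
contactCount <- function(x, groupA, groupB, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  if (!length(groupA) || !length(groupB)) return(0L)
  m <- .as_coord_matrix(x)
  A <- m[groupA, , drop = FALSE]
  B <- m[groupB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sum(d2 <= cutoff^2 + 1e-12)
}

#' Contact-count series over a trajectory
#'
#' @param traj a [G4Trajectory-class].
#' @param groupA,groupB integer atom indices.
#' @param cutoff Angstrom.
#' @return data.frame with \code{time_ps}, \code{count}.
#' @export
contactSeries <- function(traj, groupA, groupB, cutoff = 3.5) {
  vals <- vapply(seq_len(nFrames(traj)), function(k)
    contactCount(traj@coords[, , k], groupA, groupB, cutoff), 0L)
  data.frame(time_ps = traj@times, count = vals)
}

.polar_heavy <- function(a, residue) {
  which(a$resid == residue & grepl("^[NO]", a$name) &
          !a$resname %in% c("HOH", "K"))
}

#' Water bridges between two residues
#'
#' Counts waters (resname HOH) whose oxygen lies within \code{cutoff}
#' of a polar (N/O) heavy atom of \emph{both} residues - the
#' "two water molecules mimicking the slipped guanine" motif that
#' stabilises an open G-triad.
#'
#' @param structure a [G4Structure-class] containing waters.
#' @param residueX,residueY residue numbers to bridge.
#' @param cutoff Angstrom (default 3.5).
#' @return integer number of bridging waters.
#' @export
waterBridgeCount <- function(structure, residueX, residueY, cutoff = 3.5) {
  a <- structure@atoms
  wat <- which(a$resname == "HOH" & grepl("^O", a$name))
  if (!length(wat)) return(0L)
  ix <- .polar_heavy(a, residueX)
  iy <- .polar_heavy(a, residueY)
  if (!length(ix) || !length(iy)) return(0L)
  m <- coords(structure)
  n <- 0L
  for (w in wat) {
    dx <- sqrt(min(rowSums(sweep(m[ix, , drop = FALSE], 2, m[w, ])^2)))
    dy <- sqrt(min(rowSums(sweep(m[iy, , drop = FALSE], 2, m[w, ])^2)))
    if (dx <= cutoff && dy <= cutoff) n <- n + 1L
  }
  n
}
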