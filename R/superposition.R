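#' Pair residues of two models by residue number
#'
#' Builds the atom correspondence for superposition: the intersection of
#' author residue numbers (plus insertion codes) carrying the named atom in
#' both models, ordered ascending. For the FlgG20 crystal dimer this pairs
#' chains A (80-224) and B (72-227) over exactly the shared range 80-224.
#'
#' @param a,b \code{subunit_model} objects.
#' @param atom_name atom to pair on (default \code{"CA"}).
#' @param range optional \code{c(lo, hi)} residue-number window.
#' @return list with \code{pairs} (data.frame \code{resno}, \code{insert}),
#'   \code{unpaired_a}, \code{unpaired_b} (residue numbers present in only
#'   one model).
#' @export
pair_by_residue_number <- function(a, b, atom_name = "CA", range = NULL) {
  key <- function(m) {
    at <- m$atoms
    sel <- at$elety == atom_name & !at$is_het & !is_water_resid(at$resid)
    if (!is.null(range)) sel <- sel & at$resno >= range[1] & at$resno <= range[2]
    unique(data.frame(resno = at$resno[sel], insert = at$insert[sel]))
  }
  ka <- key(a); kb <- key(b)
  ida <- paste(ka$resno, ka$insert); idb <- paste(kb$resno, kb$insert)
  shared <- intersect(ida, idb)
  if (!length(shared))
    stop("no shared residues carrying atom '", atom_name, "'")
  pairs <- ka[ida %in% shared, , drop = FALSE]
  pairs <- pairs[order(pairs$resno, pairs$insert), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired_a = sort(ka$resno[!ida %in% shared]),
       unpaired_b = sort(kb$resno[!idb %in% shared]))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets. Returns the transform that moves \code{a} onto
#' \code{b} (mirroring "the donor was superimposed on the acceptor": the
#' first argument moves). The reflection branch of the SVD solution is
#' corrected by the determinant sign so the rotation is always proper.
#'
#' @param a,b numeric matrices (n x 3) of paired coordinates; n >= 3 and not
#'   collinear.
#' @param pairing optional record of the residue pairing used (stored in the
#'   result, not used in the computation).
#' @return An object of class \code{superposition_result}: list with
#'   \code{transform} (\code{rigid_transform} moving a onto b),
#'   \code{rmsd_A}, \code{n_pairs}, \code{pairing}.
#' @export
kabsch <- function(a, b, pairing = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, nrow(a) == nrow(b))
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 paired points, got ", n)
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  sv <- svd(crossprod(A, B))            # H = t(A) %*% B, 3x3
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set; rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, as.numeric(cb - R %*% ca), tol = 1e-6)
  rmsd <- sqrt(mean(rowSums((apply_transform(tr, a) - b)^2)))
  structure(list(transform = tr, rmsd_A = rmsd, n_pairs = n, pairing = pairing),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: rmsd %.4f A over %d pairs\n",
              x$rmsd_A, x$n_pairs))
  invisible(x)
}

#' Superpose two chains
#'
#' Pairs residues by number (\code{\link{pair_by_residue_number}}) and fits
#' the Kabsch superposition over the named atom. The default atom set is
#' C-alpha, the convention in which chain-comparison RMSDs are reported
#' (e.g. 0.60 Angstrom between the two FlgG20 molecules of the crystal
#' asymmetric unit); all-heavy-atom fitting is available via
#' \code{atom_name = NULL}.
#'
#' @param a,b \code{subunit_model} objects; the fitted transform moves
#'   \code{a} onto \code{b}.
#' @param atom_name atom name (default \code{"CA"}); \code{NULL} fits all
#'   heavy atoms of shared residues (requires equal atom counts per shared
#'   residue).
#' @param range optional residue-number window.
#' @return A \code{superposition_result}.
#' @export
superpose_chains <- function(a, b, atom_name = "CA", range = NULL) {
  if (is.null(atom_name)) {
    pr <- pair_by_residue_number(a, b, atom_name = "CA", range = range)
    sel <- function(m) {
      at <- m$atoms
      keep <- !at$is_het & !is_water_resid(at$resid) &
        toupper(at$elesy) != "H" &
        paste(at$resno, at$insert) %in% paste(pr$pairs$resno, pr$pairs$insert)
      at <- at[keep, , drop = FALSE]
      at <- at[order(at$resno, at$insert, at$elety), , drop = FALSE]
      at
    }
    aa <- sel(a); bb <- sel(b)
    shared <- intersect(paste(aa$resno, aa$insert, aa$elety),
                        paste(bb$resno, bb$insert, bb$elety))
    aa <- aa[paste(aa$resno, aa$insert, aa$elety) %in% shared, , drop = FALSE]
    bb <- bb[paste(bb$resno, bb$insert, bb$elety) %in% shared, , drop = FALSE]
    return(kabsch(as.matrix(aa[, c("x", "y", "z")]),
                  as.matrix(bb[, c("x", "y", "z")]), pairing = pr$pairs))
  }
  pr <- pair_by_residue_number(a, b, atom_name = atom_name, range = range)
  grab <- function(m) {
    at <- m$atoms
    sel <- at$elety == atom_name & !at$is_het & !is_water_resid(at$resid)
    at <- at[sel, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$insert)), , drop = FALSE]
    rownames(at) <- paste(at$resno, at$insert)
    as.matrix(at[paste(pr$pairs$resno, pr$pairs$insert), c("x", "y", "z")])
  }
  kabsch(grab(a), grab(b), pairing = pr$pairs)
}
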