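#' Canonical heavy-atom sets of the 20 amino acids
#'
#' PDB atom names of the sidechain heavy atoms per residue type; the
#' backbone set (N, CA, C, O, and terminal OXT) is always retained.
#' @keywords internal
aa_sidechain_atoms <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"))

backbone_atoms <- c("N", "CA", "C", "O", "OXT")

aa_one_to_three <- function(x) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[toupper(x)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Grafting plan
#'
#' Describes how to build a chimeric subunit: which shared domain to
#' superpose on (for the full-length FlgG model, the D1 domains of the
#' homolog and the crystal fragment), which donor segments to transfer
#' (D0 helices and the l-stretch), and optionally how to relabel the
#' transferred residues to the target sequence.
#'
#' @param align_segment segment name used for superposition (e.g.
#'   \code{"D1"}); must be annotated in both donor and acceptor.
#' @param graft_segments character vector of donor segment names to
#'   transfer (e.g. \code{c("D0N", "L_STRETCH", "D0C")}).
#' @param relabel_alignment optional \code{pairwise_alignment} (or
#'   data.frame with columns \code{pos_a}, \code{pos_b}) mapping donor
#'   residue positions to target-sequence positions; transferred residues
#'   are renumbered to \code{pos_b} and renamed to the target residue type.
#' @param target_seq optional one-letter target sequence (required with
#'   \code{relabel_alignment}).
#' @return An object of class \code{graft_plan}.
#' @export
graft_plan <- function(align_segment, graft_segments,
                       relabel_alignment = NULL, target_seq = NULL) {
  stopifnot(is.character(align_segment), length(align_segment) == 1L,
            is.character(graft_segments), length(graft_segments) >= 1L)
  if (!is.null(relabel_alignment) && is.null(target_seq))
    stop("relabel_alignment requires target_seq")
  structure(list(align_segment = align_segment,
                 graft_segments = graft_segments,
                 relabel_alignment = relabel_alignment,
                 target_seq = target_seq),
            class = "graft_plan")
}

segment_resnos <- function(model, segment) {
  s <- model$segments[[segment]]
  if (is.null(s)) stop("segment '", segment, "' not annotated in model")
  rn <- protein_resnos(model)
  keep <- rep(FALSE, length(rn))
  for (i in seq_len(nrow(s))) keep <- keep | (rn >= s[i, 1] & rn <= s[i, 2])
  rn[keep]
}

#' Graft donor segments onto an acceptor model
#'
#' Builds a chimeric subunit the way the full-length FlgG rod subunit model
#' was assembled from the crystal fragment and a homolog: the donor is
#' rigidly moved by the least-squares superposition of the shared alignment
#' segment (C-alpha atoms, paired by rank within the segment), the chosen
#' donor segments are spliced in, and (optionally) the transferred residues
#' are relabeled to the target sequence with sidechains truncated to the
#' shared atom set. Acceptor coordinates outside the grafted segments are
#' bit-identical to the input; junctions are reported, not regularized.
#'
#' @param acceptor \code{subunit_model} that keeps its coordinates.
#' @param donor \code{subunit_model} supplying the grafted segments.
#' @param plan a \code{\link{graft_plan}}.
#' @return An object of class \code{graft_result}: list with \code{model}
#'   (the chimera), and \code{report} (alignment RMSD and pair count,
#'   junction residues, dropped gap residues, collision check).
#' @export
graft <- function(acceptor, donor, plan) {
  stopifnot(inherits(acceptor, "subunit_model"), inherits(donor, "subunit_model"),
            inherits(plan, "graft_plan"))
  rn_a <- segment_resnos(acceptor, plan$align_segment)
  rn_d <- segment_resnos(donor, plan$align_segment)
  n <- min(length(rn_a), length(rn_d))
  if (n < 3L) stop("alignment segment '", plan$align_segment,
                   "' has fewer than 3 shared residues")
  truncated <- length(rn_a) != length(rn_d)
  ca_a <- model_coords(acceptor, "CA", resno = rn_a[seq_len(n)])
  ca_d <- model_coords(donor, "CA", resno = rn_d[seq_len(n)])
  fit <- kabsch(ca_d, ca_a)             # move donor onto acceptor
  moved <- donor
  xyz <- apply_transform(fit$transform,
                         as.matrix(moved$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]

  graft_rn <- sort(unique(unlist(lapply(plan$graft_segments,
                                        function(s) segment_resnos(moved, s)))))
  ga <- moved$atoms[moved$atoms$resno %in% graft_rn & !moved$atoms$is_het &
                      !is_water_resid(moved$atoms$resid), , drop = FALSE]
  dropped <- integer(0)
  if (!is.null(plan$relabel_alignment)) {
    piece <- subunit_model(ga, chain_id = donor$chain_id,
                           segments = moved$segments[plan$graft_segments])
    rel <- relabel_to_target(piece, plan$relabel_alignment, plan$target_seq)
    dropped <- attr(rel, "dropped_resno")
    seg_new <- rel$segments
    ga <- rel$atoms
  } else {
    seg_new <- lapply(plan$graft_segments, function(s) moved$segments[[s]])
    names(seg_new) <- plan$graft_segments
  }

  coll <- intersect(unique(ga$resno), protein_resnos(acceptor))
  if (length(coll))
    stop("graft/acceptor residue-number collision at: ",
         paste(coll, collapse = ", "))

  chim_atoms <- rbind(ga, acceptor$atoms)
  chim_atoms <- chim_atoms[order(chim_atoms$resno, chim_atoms$insert), , drop = FALSE]
  rownames(chim_atoms) <- NULL
  chim_atoms$eleno <- seq_len(nrow(chim_atoms))
  segs <- c(acceptor$segments, seg_new)
  chim <- subunit_model(chim_atoms, chain_id = acceptor$chain_id, segments = segs)

  grn <- sort(unique(ga$resno))
  arn <- protein_resnos(acceptor)
  junctions <- unique(c(
    grn[vapply(grn, function(r) any(abs(arn - r) == 1), TRUE)],
    arn[vapply(arn, function(r) any(abs(grn - r) == 1), TRUE)]))
  structure(list(model = chim,
                 report = list(align_segment = plan$align_segment,
                               align_rmsd_A = fit$rmsd_A,
                               n_align_pairs = fit$n_pairs,
                               align_pairs_truncated = truncated,
                               grafted_resno = grn,
                               junction_resno = sort(junctions),
                               dropped_resno = dropped,
                               collisions = coll)),
            class = "graft_result")
}

#' @export
print.graft_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("graft_result: %d residues grafted via %s fit (rmsd %.3f A, %d pairs)\n",
              length(r$grafted_resno), r$align_segment, r$align_rmsd_A,
              r$n_align_pairs))
  if (length(r$junction_resno))
    cat("  junction residues (unregularized):",
        paste(r$junction_resno, collapse = ", "), "\n")
  if (length(r$dropped_resno))
    cat("  gap residues dropped:", paste(r$dropped_resno, collapse = ", "), "\n")
  invisible(x)
}

#' Relabel a model to a target sequence
#'
#' Implements sidechain "replacement" as identity relabeling plus
#' truncation: each aligned residue takes the target's residue type and
#' target-sequence position as its number, and keeps only the atoms shared
#' between the old and new residue types (backbone always kept; e.g.
#' TRP to SER keeps backbone + CB). Rotamers are not rebuilt. Residues
#' aligned to a gap are dropped and reported via the \code{dropped_resno}
#' attribute.
#'
#' @param model a \code{subunit_model}.
#' @param alignment a \code{pairwise_alignment} or data.frame with columns
#'   \code{pos_a} (1-based position in the model's residue order) and
#'   \code{pos_b} (1-based position in \code{target_seq}).
#' @param target_seq one-letter target sequence.
#' @return The relabeled \code{subunit_model}; dropped residue numbers in
#'   attribute \code{dropped_resno}.
#' @export
relabel_to_target <- function(model, alignment, target_seq) {
  if (inherits(alignment, "pairwise_alignment")) alignment <- alignment$pairs
  stopifnot(all(c("pos_a", "pos_b") %in% names(alignment)))
  al <- alignment[!is.na(alignment$pos_a) & !is.na(alignment$pos_b), , drop = FALSE]
  tgt <- strsplit(toupper(target_seq), "")[[1]]
  if (nrow(al) && max(al$pos_b) > length(tgt))
    stop("alignment refers to target position ", max(al$pos_b),
         " beyond target sequence length ", length(tgt))
  rn <- protein_resnos(model)
  if (nrow(al) && max(al$pos_a) > length(rn))
    stop("alignment refers to model position ", max(al$pos_a),
         " but the model has only ", length(rn), " residues")
  a <- model$atoms
  keep_rows <- logical(nrow(a))
  out <- a[0, , drop = FALSE]
  dropped <- setdiff(rn, rn[al$pos_a])
  pieces <- vector("list", nrow(al))
  for (i in seq_len(nrow(al))) {
    old_rn <- rn[al$pos_a[i]]
    rows <- a[a$resno == old_rn & !a$is_het & !is_water_resid(a$resid), , drop = FALSE]
    new3 <- aa_one_to_three(tgt[al$pos_b[i]])
    allowed <- c(backbone_atoms,
                 intersect(aa_sidechain_atoms[[rows$resid[1]]] %||% character(0),
                           aa_sidechain_atoms[[new3]] %||% character(0)))
    rows <- rows[rows$elety %in% allowed, , drop = FALSE]
    rows$resid <- new3
    rows$resno <- al$pos_b[i]
    pieces[[i]] <- rows
  }
  out <- do.call(rbind, c(list(a[0, , drop = FALSE]), pieces))
  rownames(out) <- NULL
  out$eleno <- seq_len(nrow(out))
  # remap segment ranges through the position alignment
  old_segments <- model$segments
  map <- stats::setNames(al$pos_b, rn[al$pos_a])
  segs <- lapply(old_segments, function(s) {
    rr <- lapply(seq_len(nrow(s)), function(i) {
      covered <- rn[rn >= s[i, 1] & rn <= s[i, 2]]
      mm <- map[as.character(covered)]
      mm <- mm[!is.na(mm)]
      if (!length(mm)) return(NULL)
      c(min(mm), max(mm))
    })
    rr <- do.call(rbind, rr[!vapply(rr, is.null, TRUE)])
    rr
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  res <- subunit_model(out, chain_id = model$chain_id, segments = segs)
  attr(res, "dropped_resno") <- dropped
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Remove residue ranges from a model
#'
#' Explicit modeling of missing density: residues inside the given ranges
#' are removed and the numbering of the remainder is untouched, so the gap
#' is preserved (as for l-stretch tip residues 53-64, removed from the rod
#' model for poor density).
#'
#' @param model a \code{subunit_model}.
#' @param ranges numeric \code{c(start, end)} or a 2-column matrix of
#'   inclusive ranges.
#' @return The masked \code{subunit_model}; warns if the mask removes
#'   nothing or everything.
#' @export
apply_deletion_mask <- function(model, ranges) {
  if (is.null(dim(ranges))) ranges <- matrix(as.numeric(ranges), ncol = 2, byrow = TRUE)
  a <- model$atoms
  kill <- logical(nrow(a))
  for (i in seq_len(nrow(ranges)))
    kill <- kill | (a$resno >= ranges[i, 1] & a$resno <= ranges[i, 2] &
                      !a$is_het & !is_water_resid(a$resid))
  if (!any(kill)) {
    warning("deletion mask removed no residues")
    return(model)
  }
  out <- a[!kill, , drop = FALSE]
  rownames(out) <- NULL
  segs <- lapply(model$segments, function(s) s)  # ranges unchanged; gaps allowed
  res <- model
  res$atoms <- out
  if (!nrow(out) || !length(protein_resnos(res)))
    warning("deletion mask removed every residue")
  res
}
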