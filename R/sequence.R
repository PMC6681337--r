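#' Global pairwise sequence alignment
#'
#' Needleman-Wunsch global alignment with a substitution matrix and affine
#' gap penalties (dynamic programming via Biostrings). Defaults are
#' EMBOSS-needle style: BLOSUM62, gap open 10, gap extend 0.5 — the
#' convention under which the FlgG/FlgE pair aligns at about 39% identity.
#'
#' Percent identity is computed as identical aligned pairs divided by the
#' number of aligned columns excluding terminal overhangs but including
#' internal gaps; this denominator convention is recorded in the result.
#' Similarity counts aligned pairs with a positive substitution score.
#'
#' @param seq_a,seq_b amino-acid sequences (single strings, 20-letter
#'   alphabet; X tolerated and scored 0).
#' @param substitution_matrix name of a Biostrings matrix (default
#'   \code{"BLOSUM62"}) or a numeric matrix.
#' @param gap_open,gap_extend affine gap penalties (positive numbers;
#'   a gap of length L costs \code{gap_open + L * gap_extend}).
#' @return An object of class \code{pairwise_alignment}: list with
#'   \code{aligned_a}, \code{aligned_b} (gapped strings), \code{score},
#'   \code{identity_fraction}, \code{similarity_fraction},
#'   \code{n_columns} (denominator used), \code{identity_convention},
#'   and \code{pairs} (data.frame \code{pos_a}, \code{pos_b} of aligned,
#'   non-gap position pairs, strictly increasing in both).
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  seq_a <- toupper(gsub("\\s", "", seq_a))
  seq_b <- toupper(gsub("\\s", "", seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(al))
  gb <- as.character(Biostrings::alignedSubject(al))
  build_alignment(ga, gb, Biostrings::score(al), substitution_matrix)
}

build_alignment <- function(ga, gb, score, substitution_matrix = "BLOSUM62") {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  gap_a <- ca == "-"; gap_b <- cb == "-"
  aligned <- !(gap_a & gap_b)
  # terminal overhangs: leading/trailing runs of columns gapped in either seq
  non_gap <- which(!gap_a & !gap_b)
  if (length(non_gap)) {
    core <- seq(min(non_gap), max(non_gap))
  } else core <- integer(0)
  ident <- sum(ca[core] == cb[core] & !gap_a[core] & !gap_b[core])
  smat <- if (is.character(substitution_matrix))
    get_subst_matrix(substitution_matrix) else substitution_matrix
  simil <- 0L
  for (i in core) {
    if (!gap_a[i] && !gap_b[i] &&
        ca[i] %in% rownames(smat) && cb[i] %in% colnames(smat) &&
        smat[ca[i], cb[i]] > 0) simil <- simil + 1L
  }
  pos_a <- cumsum(!gap_a); pos_b <- cumsum(!gap_b)
  both <- !gap_a & !gap_b
  pairs <- data.frame(pos_a = pos_a[both], pos_b = pos_b[both])
  n_col <- length(core)
  structure(list(aligned_a = ga, aligned_b = gb, score = score,
                 identity_fraction = if (n_col) ident / n_col else 0,
                 similarity_fraction = if (n_col) simil / n_col else 0,
                 n_columns = n_col,
                 identity_convention = paste("identical pairs / aligned columns",
                                             "excluding terminal overhangs,",
                                             "including internal gaps"),
                 pairs = pairs),
            class = "pairwise_alignment")
}

get_subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("pairwise_alignment: identity %.1f%%, similarity %.1f%% over %d columns (score %.1f)\n",
              100 * x$identity_fraction, 100 * x$similarity_fraction,
              x$n_columns, x$score))
  cat("  convention:", x$identity_convention, "\n")
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    a <- substr(x$aligned_a, s, e); b <- substr(x$aligned_b, s, e)
    mid <- paste(ifelse(strsplit(a, "")[[1]] == strsplit(b, "")[[1]] &
                          strsplit(a, "")[[1]] != "-", "|", " "), collapse = "")
    cat(" ", a, "\n ", mid, "\n ", b, "\n\n", sep = "")
  }
  invisible(x)
}

#' Structure-based sequence alignment
#'
#' Pairs residues of two superposed models by mutual nearest C-alpha
#' neighbors within a distance cutoff, then enforces a monotone one-to-one
#' pairing (candidate pairs accepted in order of increasing distance;
#' crossing or duplicate pairs are dropped, i.e. the longer-distance member
#' of a conflict loses). This is the alignment style used to compare
#' homologous axial-protein domains after domain superposition.
#'
#' @param superposition a \code{superposition_result} whose transform moves
#'   \code{a} onto \code{b} (as returned by
#'   \code{\link{superpose_chains}(a, b)}).
#' @param a,b \code{subunit_model} objects.
#' @param dist_cutoff_A pairing cutoff in Angstrom (default 3.0).
#' @param atom_name atom used for pairing (default \code{"CA"}).
#' @return A \code{pairwise_alignment}; \code{pairs} holds 1-based residue
#'   positions, and the extra element \code{pair_table} maps paired author
#'   residue numbers and distances. Empty alignment (with a warning) when
#'   no pairs fall under the cutoff.
#' @export
structure_based_alignment <- function(superposition, a, b, dist_cutoff_A = 3.0,
                                      atom_name = "CA") {
  stopifnot(inherits(superposition, "superposition_result"))
  ta <- ca_table(a, atom_name); tb <- ca_table(b, atom_name)
  xa <- apply_transform(superposition$transform,
                        as.matrix(ta[, c("x", "y", "z")]))
  xb <- as.matrix(tb[, c("x", "y", "z")])
  rn_a <- ta$resno; rn_b <- tb$resno
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  # mutual nearest neighbors within cutoff
  nn_a <- apply(d2, 1L, which.min)
  nn_b <- apply(d2, 2L, which.min)
  cand <- which(nn_b[nn_a] == seq_len(nrow(d2)) &
                  d2[cbind(seq_len(nrow(d2)), nn_a)] <= dist_cutoff_A^2)
  if (!length(cand)) {
    warning("no residue pairs within ", dist_cutoff_A, " A after superposition")
    al <- build_alignment("", "", 0)
    al$pair_table <- data.frame(resno_a = integer(0), resno_b = integer(0),
                                dist_A = numeric(0))
    return(al)
  }
  cand <- data.frame(i = cand, j = nn_a[cand],
                     d = sqrt(d2[cbind(cand, nn_a[cand])]))
  cand <- cand[order(cand$d), , drop = FALSE]
  acc <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    ci <- cand$i[r]; cj <- cand$j[r]
    # monotone + one-to-one: no accepted pair may cross or duplicate
    if (!nrow(acc) ||
        all((acc$i - ci) * (acc$j - cj) > 0))
      acc <- rbind(acc, cand[r, ])
  }
  acc <- acc[order(acc$i), , drop = FALSE]
  # render as gapped strings over the matched span
  sa <- aa_three_to_one(ta$resid)
  sb <- aa_three_to_one(tb$resid)
  ga <- character(0); gb <- character(0)
  prev_i <- acc$i[1] - 1L; prev_j <- acc$j[1] - 1L
  for (r in seq_len(nrow(acc))) {
    gi <- seq(prev_i + 1L, acc$i[r] - 1L, length.out = max(0, acc$i[r] - 1L - prev_i))
    gj <- seq(prev_j + 1L, acc$j[r] - 1L, length.out = max(0, acc$j[r] - 1L - prev_j))
    ga <- c(ga, sa[gi], rep("-", length(gj)), sa[acc$i[r]])
    gb <- c(gb, rep("-", length(gi)), sb[gj], sb[acc$j[r]])
    prev_i <- acc$i[r]; prev_j <- acc$j[r]
  }
  al <- build_alignment(paste(ga, collapse = ""), paste(gb, collapse = ""), NA_real_)
  al$pairs <- data.frame(pos_a = acc$i, pos_b = acc$j)
  al$pair_table <- data.frame(resno_a = rn_a[acc$i], resno_b = rn_b[acc$j],
                              dist_A = acc$d)
  al
}

# one row per residue carrying the named atom, in residue order
ca_table <- function(model, atom_name = "CA") {
  a <- model$atoms
  sel <- a$elety == atom_name & !a$is_het & !is_water_resid(a$resid)
  a <- a[sel, , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$insert)), , drop = FALSE]
  a <- a[order(a$resno, a$insert), , drop = FALSE]
  data.frame(resno = a$resno, resid = a$resid, x = a$x, y = a$y, z = a$z)
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
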