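#' Inter-subunit contact network of an assembly
#'
#' Enumerates all heavy-atom pairs between different subunits within a
#' distance cutoff, using a spatial grid with cell size equal to the cutoff,
#' and aggregates them into edges per (subunit pair, segment pair). Edges
#' are emitted in both directions (a -> b and b -> a with mirrored fields)
#' so that every subunit's contact environment can be read off directly;
#' the \code{offset} column is \code{index_b - index_a}, the lattice-offset
#' label in which the rod l-stretch network reads -5/-10/-11/-16. Waters
#' and het groups are excluded.
#'
#' @param assembly an \code{axial_assembly}.
#' @param cutoff_A heavy-atom distance cutoff in Angstrom (default 4.0, a
#'   typical van der Waals contact criterion; the underlying papers state
#'   no cutoff, so report at several).
#' @param min_pairs minimum atom-pair count for an edge to be kept
#'   (default 1: "interacts" means at least one heavy-atom pair within
#'   cutoff).
#' @return data.frame of class \code{contact_edges} with columns
#'   \code{index_a}, \code{index_b}, \code{offset}, \code{segment_a},
#'   \code{segment_b}, \code{n_atom_pairs}, \code{min_dist_A}, ordered by
#'   (index_a, index_b, segment_a, segment_b). Attributes:
#'   \code{index_range}, \code{cutoff_A}.
#' @export
contact_map <- function(assembly, cutoff_A = 4.0, min_pairs = 1L) {
  stopifnot(inherits(assembly, "axial_assembly"))
  if (cutoff_A <= 0) stop("cutoff_A must be positive")
  if (length(assembly$indices) < 2L) stop("assembly must have at least 2 subunits")
  at <- as.data.frame(assembly)
  at <- at[!at$is_het & !is_water_resid(at$resid) & toupper(at$elesy) != "H", ,
           drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pr <- grid_pairs(xyz, cutoff_A)
  if (nrow(pr)) {
    keep <- at$subunit[pr[, 1]] != at$subunit[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
  }
  edges_from_pairs(at, pr, cutoff_A, min_pairs, assembly$indices)
}

# All index pairs (i < j) within cutoff, cell-list algorithm.
grid_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  cell <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  bucket <- split(seq_len(n), key)
  coords_of <- function(i) xyz[i, , drop = FALSE]
  # half-space neighbor offsets: same cell handled separately
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0))), ]
  res <- vector("list", length(bucket) * (nrow(offs) + 1L))
  k <- 0L
  cut2 <- cutoff^2
  cell_of_bucket <- do.call(rbind, lapply(strsplit(names(bucket), ","), as.numeric))
  for (bi in seq_along(bucket)) {
    ids <- bucket[[bi]]
    # within-cell pairs
    if (length(ids) > 1L) {
      cmb <- utils::combn(ids, 2L)
      d2 <- rowSums((xyz[cmb[1, ], , drop = FALSE] - xyz[cmb[2, ], , drop = FALSE])^2)
      sel <- d2 <= cut2
      if (any(sel)) {
        k <- k + 1L
        res[[k]] <- cbind(cmb[1, sel], cmb[2, sel], sqrt(d2[sel]))
      }
    }
    # cross-cell pairs, half space only
    for (oi in seq_len(nrow(offs))) {
      nb_key <- paste(cell_of_bucket[bi, 1] + offs$dx[oi],
                      cell_of_bucket[bi, 2] + offs$dy[oi],
                      cell_of_bucket[bi, 3] + offs$dz[oi], sep = ",")
      jds <- bucket[[nb_key]]
      if (is.null(jds)) next
      a <- xyz[ids, , drop = FALSE]; b <- xyz[jds, , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      sel <- which(d2 <= cut2, arr.ind = TRUE)
      if (nrow(sel)) {
        k <- k + 1L
        res[[k]] <- cbind(ids[sel[, 1]], jds[sel[, 2]],
                          sqrt(pmax(d2[sel], 0)))
      }
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  if (is.null(out)) matrix(numeric(0), ncol = 3) else out
}

edges_from_pairs <- function(at, pr, cutoff_A, min_pairs, indices) {
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      offset = integer(0), segment_a = character(0),
                      segment_b = character(0), n_atom_pairs = integer(0),
                      min_dist_A = numeric(0))
  if (!nrow(pr)) {
    out <- empty
  } else {
    i <- pr[, 1]; j <- pr[, 2]; d <- pr[, 3]
    both <- data.frame(
      index_a = c(at$subunit[i], at$subunit[j]),
      index_b = c(at$subunit[j], at$subunit[i]),
      segment_a = c(at$segment[i], at$segment[j]),
      segment_b = c(at$segment[j], at$segment[i]),
      dist = c(d, d))
    key <- paste(both$index_a, both$index_b, both$segment_a, both$segment_b,
                 sep = "\r")
    agg_n <- tapply(both$dist, key, length)
    agg_min <- tapply(both$dist, key, min)
    parts <- strsplit(names(agg_n), "\r", fixed = TRUE)
    out <- data.frame(
      index_a = as.integer(vapply(parts, `[`, "", 1L)),
      index_b = as.integer(vapply(parts, `[`, "", 2L)),
      segment_a = vapply(parts, `[`, "", 3L),
      segment_b = vapply(parts, `[`, "", 4L),
      n_atom_pairs = as.integer(agg_n),
      min_dist_A = as.numeric(agg_min))
    out$offset <- out$index_b - out$index_a
    out <- out[out$n_atom_pairs >= min_pairs, , drop = FALSE]
    out <- out[order(out$index_a, out$index_b, out$segment_a, out$segment_b), ,
               drop = FALSE]
    out <- out[, c("index_a", "index_b", "offset", "segment_a", "segment_b",
                   "n_atom_pairs", "min_dist_A")]
    rownames(out) <- NULL
  }
  attr(out, "index_range") <- range(indices)
  attr(out, "cutoff_A") <- cutoff_A
  class(out) <- c("contact_edges", "data.frame")
  out
}

#' Contact fingerprint of one segment
#'
#' The set of (lattice offset, partner segment) pairs a named segment of
#' the reference subunit touches. This is the quantity in which the rod and
#' hook l-stretch networks are described: on the rod the l-stretch touches
#' the D1 domains at offsets -5, -10, -11 and -16; on the hook at -5 and
#' -11 only. The reference subunit must be interior: every neighbor as far
#' away as the largest contact offset observed in the assembly must be
#' present, otherwise boundary truncation would silently shrink the
#' fingerprint.
#'
#' @param edges a \code{contact_edges} table from \code{\link{contact_map}}.
#' @param reference_index lattice index of the reference subunit.
#' @param segment segment name (e.g. \code{"L_STRETCH"}).
#' @param margin interior margin; default the largest \code{abs(offset)}
#'   in \code{edges}.
#' @return data.frame with columns \code{offset} and \code{partner_segment},
#'   sorted; zero rows if the segment makes no inter-subunit contact.
#' @export
segment_fingerprint <- function(edges, reference_index, segment, margin = NULL) {
  stopifnot(inherits(edges, "contact_edges"))
  rng <- attr(edges, "index_range")
  if (is.null(margin))
    margin <- if (nrow(edges)) max(abs(edges$offset)) else 1L
  missing_lo <- reference_index - margin < rng[1]
  missing_hi <- reference_index + margin > rng[2]
  if (missing_lo || missing_hi)
    stop("reference subunit ", reference_index, " is not interior: needs ",
         "neighbors ", reference_index - margin, "..", reference_index + margin,
         " but assembly spans ", rng[1], "..", rng[2])
  e <- edges[edges$index_a == reference_index & edges$segment_a == segment, ,
             drop = FALSE]
  fp <- unique(data.frame(offset = e$offset, partner_segment = e$segment_b))
  fp <- fp[order(fp$offset, fp$partner_segment), , drop = FALSE]
  rownames(fp) <- NULL
  fp
}

#' Fingerprint sensitivity table over cutoffs
#'
#' Reports the fingerprint of a segment at several contact cutoffs
#' (default 3.5, 4.0, 4.5 Angstrom), since published interaction
#' descriptions rarely state a cutoff.
#'
#' @param assembly an \code{axial_assembly}.
#' @param reference_index,segment as \code{\link{segment_fingerprint}}.
#' @param cutoffs numeric vector of cutoffs in Angstrom.
#' @return data.frame with columns \code{cutoff_A}, \code{offset},
#'   \code{partner_segment}.
#' @export
fingerprint_sensitivity <- function(assembly, reference_index, segment,
                                    cutoffs = c(3.5, 4.0, 4.5)) {
  do.call(rbind, lapply(cutoffs, function(cc) {
    fp <- segment_fingerprint(contact_map(assembly, cutoff_A = cc),
                              reference_index, segment)
    if (!nrow(fp)) return(NULL)
    cbind(cutoff_A = cc, fp)
  }))
}

#' Map mutation sites into their contact environment
#'
#' For each queried residue number of the reference subunit, reports
#' whether the residue is present in the model (sites inside removed
#' regions, such as the l-stretch tip 53-64, are flagged unmodeled) and
#' lists the neighboring subunits' residues within the cutoff. Unmodeled
#' sites inherit the environment of their nearest modeled flanking
#' residues, flagged approximate. Designed for the polyrod mutation sites
#' of FlgG (residues 52-66, plus D1 sites such as G183 and S197).
#'
#' @param assembly an \code{axial_assembly}.
#' @param sites integer residue numbers to query.
#' @param cutoff_A contact cutoff in Angstrom (default 4.0).
#' @param reference_index reference subunit; default the most interior
#'   index (closest to the middle of the range).
#' @return list of class \code{site_report}; one element per site with
#'   \code{site}, \code{modeled}, \code{approximate}, \code{segment}, and
#'   \code{environment} (data.frame offset, segment, resno, resid,
#'   min_dist_A).
#' @export
map_mutation_sites <- function(assembly, sites, cutoff_A = 4.0,
                               reference_index = NULL) {
  stopifnot(inherits(assembly, "axial_assembly"))
  if (is.null(reference_index)) {
    mid <- mean(range(assembly$indices))
    reference_index <- assembly$indices[which.min(abs(assembly$indices - mid))]
  }
  ref <- NULL
  for (s in assembly$subunits) if (s$index == reference_index) ref <- s$model
  if (is.null(ref)) stop("reference index ", reference_index, " not in assembly")
  rn <- protein_resnos(ref)
  # the queryable span includes segment annotations, so sites inside removed
  # (unmodeled) regions are still in range
  seq_span <- range(c(rn, unlist(lapply(ref$segments, function(s) c(s)))))
  bad <- sites[sites < seq_span[1] | sites > seq_span[2]]
  if (length(bad))
    stop("site(s) outside the subunit sequence range ", seq_span[1], "-",
         seq_span[2], ": ", paste(bad, collapse = ", "))
  at <- as.data.frame(assembly)
  at <- at[!at$is_het & !is_water_resid(at$resid) & toupper(at$elesy) != "H", ,
           drop = FALSE]
  other <- at[at$subunit != reference_index, , drop = FALSE]
  oxyz <- as.matrix(other[, c("x", "y", "z")])
  env_of <- function(resno_set) {
    a <- ref$atoms
    a <- a[a$resno %in% resno_set & !a$is_het & !is_water_resid(a$resid) &
             toupper(a$elesy) != "H", , drop = FALSE]
    if (!nrow(a)) return(empty_env())
    sx <- as.matrix(a[, c("x", "y", "z")])
    d2 <- outer(rowSums(sx^2), rowSums(oxyz^2), "+") - 2 * tcrossprod(sx, oxyz)
    hit <- which(d2 <= cutoff_A^2, arr.ind = TRUE)
    if (!nrow(hit)) return(empty_env())
    env <- data.frame(offset = other$subunit[hit[, 2]] - reference_index,
                      segment = other$segment[hit[, 2]],
                      resno = other$resno[hit[, 2]],
                      resid = other$resid[hit[, 2]],
                      dist = sqrt(pmax(d2[hit], 0)))
    key <- paste(env$offset, env$segment, env$resno, env$resid, sep = "\r")
    mn <- tapply(env$dist, key, min)
    parts <- strsplit(names(mn), "\r", fixed = TRUE)
    out <- data.frame(offset = as.integer(vapply(parts, `[`, "", 1L)),
                      segment = vapply(parts, `[`, "", 2L),
                      resno = as.integer(vapply(parts, `[`, "", 3L)),
                      resid = vapply(parts, `[`, "", 4L),
                      min_dist_A = as.numeric(mn))
    out <- out[order(out$offset, out$segment, out$resno), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  empty_env <- function() data.frame(offset = integer(0), segment = character(0),
                                     resno = integer(0), resid = character(0),
                                     min_dist_A = numeric(0))
  reports <- lapply(sites, function(s) {
    modeled <- s %in% rn
    if (modeled) {
      list(site = s, modeled = TRUE, approximate = FALSE,
           segment = segment_of(ref, s), environment = env_of(s))
    } else {
      lo <- rn[rn < s]; hi <- rn[rn > s]
      flank <- c(if (length(lo)) max(lo), if (length(hi)) min(hi))
      list(site = s, modeled = FALSE, approximate = TRUE,
           segment = segment_of(ref, s), flanking = flank,
           environment = env_of(flank))
    }
  })
  names(reports) <- as.character(sites)
  structure(reports, class = "site_report")
}

#' @export
print.site_report <- function(x, ...) {
  for (r in x) {
    cat(sprintf("site %d [%s]%s: ", r$site, r$segment,
                if (r$modeled) "" else " UNMODELED (approximate, from flanking residues)"))
    if (nrow(r$environment)) {
      off <- sort(unique(r$environment$offset))
      cat("contacts subunit offsets {", paste(off, collapse = ", "), "}, ",
          nrow(r$environment), " partner residues\n", sep = "")
    } else cat("no inter-subunit contacts within cutoff\n")
  }
  invisible(x)
}
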