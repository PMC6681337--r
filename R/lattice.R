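#' Screw symmetry of a helical assembly
#'
#' The generator of a 1-start helical lattice: every subunit is related to
#' the previous one by a rotation of \code{twist_deg} about the helix axis
#' and a translation of \code{rise_A} along it. For the Salmonella flagellar
#' distal rod the 1-start parameters are twist 64.75 degrees and rise
#' 4.13 Angstrom per subunit; for the hook, 64.78 degrees and 4.12 Angstrom.
#' The working frame places the helix axis on z with the distal direction at
#' +z; positive twist with \code{handedness = "right"} is a right-handed
#' screw about +z.
#'
#' @param twist_deg rotation per subunit in degrees, in (0, 360).
#' @param rise_A axial translation per subunit in Angstrom, > 0.
#' @param handedness \code{"right"} (default) or \code{"left"}; the sign
#'   convention of the rotation about +z.
#' @return An object of class \code{screw_symmetry}.
#' @export
screw_symmetry <- function(twist_deg, rise_A, handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(twist_deg), length(twist_deg) == 1L,
            is.numeric(rise_A), length(rise_A) == 1L)
  if (!(twist_deg > 0 && twist_deg < 360))
    stop("twist_deg must lie strictly between 0 and 360 degrees")
  if (rise_A <= 0) stop("rise_A must be positive")
  structure(list(twist_deg = twist_deg, rise_A = rise_A,
                 handedness = handedness),
            class = "screw_symmetry")
}

#' Rod and hook 1-start symmetries
#'
#' Convenience constructors for the published 1-start screw parameters of
#' the Salmonella distal rod (64.75 degrees / 4.13 Angstrom) and hook
#' (64.78 degrees / 4.12 Angstrom).
#' @return A \code{screw_symmetry}.
#' @export
rod_symmetry <- function() screw_symmetry(64.75, 4.13)

#' @rdname rod_symmetry
#' @export
hook_symmetry <- function() screw_symmetry(64.78, 4.12)

#' @export
print.screw_symmetry <- function(x, ...) {
  cat(sprintf("screw_symmetry: twist %.4f deg, rise %.4f A per subunit (%s-handed)\n",
              x$twist_deg, x$rise_A, x$handedness))
  invisible(x)
}

signed_twist <- function(sym)
  if (sym$handedness == "right") sym$twist_deg else -sym$twist_deg

#' Generator transform of a screw symmetry
#'
#' The rigid transform taking subunit n to subunit n+1: rotation by the
#' twist about +z composed with translation by the rise along +z.
#'
#' @param sym a \code{screw_symmetry}.
#' @return A \code{rigid_transform}.
#' @export
generator_transform <- function(sym) {
  stopifnot(inherits(sym, "screw_symmetry"))
  rigid_transform(rot_z(signed_twist(sym)), c(0, 0, sym$rise_A))
}

#' Lattice transform for index n
#'
#' The transform placing the reference subunit at lattice index \code{n}:
#' rotation by \code{n} times the twist, translation by \code{n} times the
#' rise. Computed in closed form; equals the n-fold composition of the
#' generator.
#'
#' @param sym a \code{screw_symmetry}.
#' @param n integer lattice index (negative = proximal).
#' @return A \code{rigid_transform}.
#' @export
lattice_transform <- function(sym, n) {
  stopifnot(inherits(sym, "screw_symmetry"))
  rigid_transform(rot_z(n * signed_twist(sym)), c(0, 0, n * sym$rise_A))
}

#' Build a helical assembly from one subunit
#'
#' Replicates a subunit, placed in the working frame (helix axis = z), over
#' a contiguous range of lattice indices. Copy n carries the lattice
#' transform for index n; chain ids are assigned deterministically in index
#' order from the PDB chain alphabet (A-Z, a-z, 0-9).
#'
#' @param subunit a \code{subunit_model} in the working frame.
#' @param sym a \code{screw_symmetry}.
#' @param index_range integer vector \code{c(n_min, n_max)}, inclusive. The
#'   published rod segment spans four turns of the 1-start helix: 22
#'   subunits, e.g. \code{c(-21, 0)}.
#' @return An object of class \code{axial_assembly}: list with
#'   \code{symmetry}, \code{indices}, and \code{subunits} (one element per
#'   index holding \code{index}, \code{transform}, and the placed
#'   \code{model}).
#' @export
build_assembly <- function(subunit, sym, index_range) {
  stopifnot(inherits(subunit, "subunit_model"), inherits(sym, "screw_symmetry"))
  if (length(index_range) != 2L || index_range[2] < index_range[1])
    stop("index_range must be c(n_min, n_max) with n_max >= n_min")
  idx <- seq(as.integer(index_range[1]), as.integer(index_range[2]))
  subs <- lapply(seq_along(idx), function(i) {
    n <- idx[i]
    tr <- lattice_transform(sym, n)
    m <- subunit
    xyz <- apply_transform(tr, as.matrix(m$atoms[, c("x", "y", "z")]))
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m$chain_id <- chain_id_for(i)
    list(index = n, transform = tr, model = m)
  })
  structure(list(symmetry = sym, indices = idx, subunits = subs),
            class = "axial_assembly")
}

# single characters for the first 62 chains (PDB-compatible), two-character
# ids beyond that (mmCIF only)
chain_id_for <- function(i) {
  ab <- pdb_chain_alphabet
  if (i <= length(ab)) return(ab[i])
  j <- i - length(ab) - 1L
  paste0(ab[j %/% length(ab) + 1L], ab[j %% length(ab) + 1L])
}

#' @export
print.axial_assembly <- function(x, ...) {
  cat(sprintf("axial_assembly: %d subunits, indices %d..%d\n",
              length(x$indices), min(x$indices), max(x$indices)))
  print(x$symmetry)
  invisible(x)
}

#' Flatten an assembly to one atom table
#'
#' @param x an \code{axial_assembly}.
#' @param ... unused.
#' @return data.frame of all atoms with added columns \code{subunit}
#'   (lattice index), \code{chain}, and \code{segment}.
#' @export
as.data.frame.axial_assembly <- function(x, ...) {
  do.call(rbind, lapply(x$subunits, function(s) {
    a <- s$model$atoms
    a$subunit <- s$index
    a$chain <- s$model$chain_id
    a$segment <- segment_of(s$model, a$resno)
    a
  }))
}

#' Subunits spanning a number of 1-start turns
#'
#' The counting convention of helical-lattice descriptions: the number of
#' subunits in \code{turns} turns of the 1-start helix is
#' \code{round(turns * 360 / twist)}. At the rod twist of 64.75 degrees this
#' gives 11 subunits in two turns and 22 in four.
#'
#' @param sym a \code{screw_symmetry}.
#' @param turns number of turns, >= 0.
#' @return integer subunit count.
#' @export
subunits_per_turns <- function(sym, turns) {
  stopifnot(inherits(sym, "screw_symmetry"), turns >= 0)
  as.integer(round(turns * 360 / sym$twist_deg))
}

wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # map -180 to +180: interval is (-180, 180]
  w[w == -180] <- 180
  w
}

#' Protofilament count of a helical lattice
#'
#' Protofilaments are the near-axial strands of subunits: the lattice offset
#' n whose cumulative rotation n x twist is closest to a whole number of
#' turns. Searches n in [2, n_max] minimizing the wrapped residual rotation
#' (wrapped to (-180, 180]); ties are broken toward the smaller n, with all
#' tied offsets reported. The 64.75-degree rod twist gives 11 protofilaments
#' with a residual of -7.75 degrees.
#'
#' @param sym a \code{screw_symmetry}.
#' @param n_max largest offset searched (default 30).
#' @return list with \code{n} (protofilament count), \code{residual_deg}
#'   (wrapped residual rotation at n), \code{ties} (all offsets achieving
#'   the minimal |residual|), and \code{table} (offset, residual for the
#'   full scan).
#' @export
protofilament_count <- function(sym, n_max = 30L) {
  stopifnot(inherits(sym, "screw_symmetry"), n_max >= 2)
  n <- 2:as.integer(n_max)
  res <- wrap_deg(n * sym$twist_deg)
  best <- min(abs(res))
  ties <- n[abs(abs(res) - best) < 1e-9]
  k <- ties[1]
  list(n = as.integer(k), residual_deg = res[n == k][1], ties = as.integer(ties),
       table = data.frame(offset = n, residual_deg = res))
}

#' n-start family table
#'
#' For each lattice offset k, the net rotation (wrapped to (-180, 180]) and
#' net rise between subunits n and n+k, with the standard family labels of
#' the 11-protofilament axial lattice attached: 5-start (k = +/-5), 6-start
#' (k = +/-6), and protofilament / 11-start (k = +/-11).
#'
#' @param sym a \code{screw_symmetry}.
#' @param offsets nonzero integer offsets.
#' @return data.frame with \code{offset}, \code{net_rotation_deg} (wrapped),
#'   \code{net_rise_A}, \code{family}.
#' @export
start_families <- function(sym, offsets = c(-16, -11, -10, -6, -5, -1, 1, 5, 6, 10, 11, 16)) {
  stopifnot(inherits(sym, "screw_symmetry"))
  offsets <- as.integer(offsets)
  if (any(offsets == 0L)) stop("offsets must be nonzero")
  fam <- rep("", length(offsets))
  fam[abs(offsets) == 5L] <- "5-start"
  fam[abs(offsets) == 6L] <- "6-start"
  fam[abs(offsets) == 11L] <- "protofilament (11-start)"
  fam[abs(offsets) == 1L] <- "1-start"
  data.frame(offset = offsets,
             net_rotation_deg = wrap_deg(offsets * signed_twist(sym)),
             net_rise_A = offsets * sym$rise_A,
             family = fam)
}

#' Recover screw symmetry from an assembly
#'
#' The inverse of \code{\link{build_assembly}}: fits the least-squares rigid
#' transform between each consecutive pair of subunits, decomposes it as a
#' screw motion (rotation angle about the fitted axis = twist, axial
#' translation = rise), and averages over the steps. The per-step
#' superposition RMSD is reported as a residual; a perfect helical assembly
#' gives residuals at floating-point round-off, while shuffled or broken
#' assemblies show large residuals.
#'
#' @param x an \code{axial_assembly}, or a list of coordinate matrices
#'   (n x 3, identical atom correspondence) in lattice-index order.
#' @return An object of class \code{screw_fit}: list with \code{symmetry}
#'   (the fitted \code{screw_symmetry}), \code{twist_deg}, \code{rise_A},
#'   \code{axis} (mean fitted axis), and \code{steps} (data.frame of
#'   per-step twist, rise, and RMSD residual).
#' @export
infer_symmetry <- function(x) {
  if (inherits(x, "axial_assembly"))
    x <- lapply(x$subunits, function(s)
      as.matrix(s$model$atoms[, c("x", "y", "z")]))
  stopifnot(is.list(x))
  if (length(x) < 2L) stop("need at least 2 subunits to infer symmetry")
  nr <- vapply(x, nrow, 0L)
  if (length(unique(nr)) != 1L)
    stop("subunits have inconsistent atom counts: ",
         paste(unique(nr), collapse = ", "))
  steps <- lapply(seq_len(length(x) - 1L), function(i) {
    fit <- kabsch(x[[i]], x[[i + 1L]])   # transform moving subunit i onto i+1
    sd <- screw_decompose(fit$transform)
    list(twist = sd$angle_deg, rise = sd$axial_translation, axis = sd$axis,
         rmsd = fit$rmsd_A)
  })
  tw <- vapply(steps, `[[`, 0, "twist")
  ri <- vapply(steps, `[[`, 0, "rise")
  ax <- colMeans(do.call(rbind, lapply(steps, `[[`, "axis")))
  ax <- ax / sqrt(sum(ax^2))
  fit_twist <- mean(tw)
  # congruent subunits superpose well in any order, so the step RMSD alone
  # cannot expose a broken index order; the spread of the per-step screw
  # parameters can
  spread <- list(twist_sd_deg = stats::sd(tw), rise_sd_A = stats::sd(ri))
  structure(list(symmetry = screw_symmetry(abs(fit_twist) %% 360, mean(ri),
                                           handedness = if (fit_twist >= 0) "right" else "left"),
                 twist_deg = fit_twist, rise_A = mean(ri), axis = ax,
                 twist_sd_deg = spread$twist_sd_deg,
                 rise_sd_A = spread$rise_sd_A,
                 steps = data.frame(step = seq_along(tw), twist_deg = tw,
                                    rise_A = ri,
                                    rmsd_A = vapply(steps, `[[`, 0, "rmsd"))),
            class = "screw_fit")
}

#' @export
print.screw_fit <- function(x, ...) {
  cat(sprintf("screw_fit: twist %.6f deg, rise %.6f A (over %d steps)\n",
              x$twist_deg, x$rise_A, nrow(x$steps)))
  cat(sprintf("  per-step residual RMSD: max %.4g A, mean %.4g A\n",
              max(x$steps$rmsd_A), mean(x$steps$rmsd_A)))
  cat(sprintf("  per-step spread: twist sd %.4g deg, rise sd %.4g A%s\n",
              x$twist_sd_deg, x$rise_sd_A,
              if (is.finite(x$twist_sd_deg) && x$twist_sd_deg > 1)
                "  ** inconsistent steps: check subunit order **" else ""))
  cat(sprintf("  mean axis: (%.4f, %.4f, %.4f)\n",
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
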