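#' Specification for a toy axial subunit
#'
#' Parameters of the synthetic stand-in for an axial-structure subunit: an
#' inner two-helix D0 element near the helix axis, an extended l-stretch
#' analog ("arm") reaching toward the D1 body of a designated lattice
#' neighbor, and a globular D1 body at a given radius. The defaults mirror
#' the distal-rod architecture: the arm is aimed at the -5 neighbor, the
#' direction in which the rod l-stretch runs, and the D1 body sits ~30
#' Angstrom from the axis.
#'
#' @param d0_helix_length residues per D0 helix (default 12).
#' @param arm_length_A reach budget of the arm in Angstrom; \code{NULL}
#'   (default) uses exactly the distance needed to touch the designated
#'   neighbor; 0 omits the arm entirely.
#' @param arm_direction lattice offset whose D1 body the arm tip should
#'   touch (default -5).
#' @param d1_radius_A radius of the globular D1 body (default 3).
#' @param radial_position_A distance of the D1 centroid from the helix
#'   axis (default 30).
#' @param seed integer seed controlling the (deterministic) generator.
#' @return An object of class \code{toy_subunit_spec}.
#' @export
toy_subunit_spec <- function(d0_helix_length = 12, arm_length_A = NULL,
                             arm_direction = -5, d1_radius_A = 3,
                             radial_position_A = 30, seed = 1) {
  stopifnot(d0_helix_length >= 2, d1_radius_A > 0, radial_position_A > 0,
            arm_direction == round(arm_direction), arm_direction != 0)
  if (!is.null(arm_length_A) && arm_length_A < 0)
    stop("arm_length_A must be >= 0")
  structure(list(d0_helix_length = as.integer(d0_helix_length),
                 arm_length_A = arm_length_A,
                 arm_direction = as.integer(arm_direction),
                 d1_radius_A = d1_radius_A,
                 radial_position_A = radial_position_A,
                 seed = as.integer(seed)),
            class = "toy_subunit_spec")
}

# ideal helix C-alpha trace: 1.5 A rise and 100 deg twist per residue about
# a local axis parallel to z
ideal_helix <- function(n, center_xy, z0, direction = +1, phase = 0,
                        helix_radius = 2.3) {
  i <- seq_len(n) - 1
  ang <- (phase + 100 * i) * pi / 180
  cbind(center_xy[1] + helix_radius * cos(ang),
        center_xy[2] + helix_radius * sin(ang),
        z0 + direction * 1.5 * i)
}

#' Generate a toy axial subunit
#'
#' Builds a C-alpha-only \code{subunit_model} from a
#' \code{\link{toy_subunit_spec}}, placed in the working frame (helix axis
#' = z) of the given screw symmetry. The arm is a straight C-alpha trace
#' (3.8 Angstrom spacing) from the D0 region toward the D1 centroid of the
#' subunit at lattice offset \code{arm_direction}, stopping 2.5 Angstrom
#' short of it, so that in a built assembly the arm tip is guaranteed to
#' lie within 3 Angstrom of that neighbor's D1 centroid atom. Fully
#' deterministic for a fixed spec and seed.
#'
#' Segments are annotated as \code{D0N} (residues 1..L), \code{L_STRETCH}
#' (the arm), \code{D1} (the body), \code{D0C} (residues at the end), with
#' L = \code{d0_helix_length}.
#'
#' @param spec a \code{toy_subunit_spec}.
#' @param sym the \code{screw_symmetry} of the lattice the subunit is
#'   designed for (default \code{\link{rod_symmetry}()}).
#' @return A \code{subunit_model} with attribute \code{design} recording
#'   the arm target offset and tip distance.
#' @export
make_toy_subunit <- function(spec, sym = rod_symmetry()) {
  stopifnot(inherits(spec, "toy_subunit_spec"), inherits(sym, "screw_symmetry"))
  L <- spec$d0_helix_length
  half <- 1.5 * (L - 1) / 2
  # two antiparallel D0 helices near the axis
  d0n <- ideal_helix(L, c(4.0,  2.2), -half, +1, phase = 0)
  d0c <- ideal_helix(L, c(4.0, -2.2),  half, -1, phase = 180)
  # D1 body: deterministic Fibonacci sphere around the centroid, plus the
  # centroid atom itself (the arm's design target)
  cen <- c(spec$radial_position_A, 0, 0)
  m <- 16L
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(m) - 1
  zs <- 1 - 2 * (k + 0.5) / m
  rr <- sqrt(pmax(0, 1 - zs^2))
  sphere <- cbind(cen[1] + spec$d1_radius_A * rr * cos(golden * k),
                  cen[2] + spec$d1_radius_A * rr * sin(golden * k),
                  cen[3] + spec$d1_radius_A * zs)
  # seeded jitter keeps the body irregular but reproducible
  set.seed(spec$seed)
  jit <- matrix(stats::runif(3 * m, -0.2, 0.2), ncol = 3)
  d1 <- rbind(cen, sphere + jit)

  # arm: straight trace from the D0 region toward the designated neighbor's
  # D1 centroid, stopping 2.5 A short
  target <- apply_transform(lattice_transform(sym, spec$arm_direction), cen)
  start <- c(11.59, 3.11, -4)           # just outside the D0 bundle
  v <- target - start
  needed <- sqrt(sum(v^2)) - 2.5
  arm <- NULL
  if (is.null(spec$arm_length_A) || spec$arm_length_A > 0) {
    if (!is.null(spec$arm_length_A) && spec$arm_length_A < needed)
      stop(sprintf(paste0("arm too short to reach offset %d at this symmetry: ",
                          "need at least %.1f A, got %.1f A"),
                   spec$arm_direction, needed, spec$arm_length_A))
    u <- v / sqrt(sum(v^2))
    n_arm <- max(2L, as.integer(ceiling(needed / 3.8)) + 1L)
    tpar <- seq(0, needed, length.out = n_arm)
    arm <- cbind(start[1] + u[1] * tpar, start[2] + u[2] * tpar,
                 start[3] + u[3] * tpar)
  }

  xyz <- rbind(d0n, arm, d1, d0c)
  n_arm <- if (is.null(arm)) 0L else nrow(arm)
  n_d1 <- nrow(d1)
  segs <- list(D0N = c(1, L))
  nxt <- L + 1
  if (n_arm) {
    segs$L_STRETCH <- c(nxt, nxt + n_arm - 1)
    nxt <- nxt + n_arm
  }
  segs$D1 <- c(nxt, nxt + n_d1 - 1)
  nxt <- nxt + n_d1
  segs$D0C <- c(nxt, nxt + L - 1)
  n <- nrow(xyz)
  atoms <- data.frame(eleno = seq_len(n), elety = "CA", resid = "ALA",
                      resno = seq_len(n), insert = "", alt = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      o = 1, b = 0, elesy = "C", is_het = FALSE,
                      stringsAsFactors = FALSE)
  model <- subunit_model(atoms, chain_id = "A", segments = segs)
  attr(model, "design") <- list(arm_direction = spec$arm_direction,
                                arm_needed_A = needed,
                                tip_to_target_A = if (n_arm) 2.5 else NA_real_)
  model
}

#' Build a noisy helical assembly
#'
#' An ideal assembly from \code{\link{build_assembly}} with i.i.d. Gaussian
#' displacement (standard deviation \code{sigma_A}) added to every atom
#' coordinate; seeded, so fully reproducible. Supports parameter-recovery
#' studies for \code{\link{infer_symmetry}}.
#'
#' @param subunit a \code{subunit_model} in the working frame.
#' @param sym a \code{screw_symmetry}.
#' @param n number of subunits; placed at indices \code{-(n-1)..0}
#'   (proximal indexing).
#' @param sigma_A per-coordinate Gaussian noise in Angstrom, >= 0.
#' @param seed integer seed.
#' @return An \code{axial_assembly}.
#' @export
make_noisy_assembly <- function(subunit, sym, n, sigma_A = 0, seed = 1) {
  stopifnot(sigma_A >= 0, n >= 1)
  asm <- build_assembly(subunit, sym, c(-(n - 1L), 0L))
  if (sigma_A > 0) {
    set.seed(seed)
    for (i in seq_along(asm$subunits)) {
      na <- nrow(asm$subunits[[i]]$model$atoms)
      noise <- matrix(stats::rnorm(3 * na, 0, sigma_A), ncol = 3)
      asm$subunits[[i]]$model$atoms$x <- asm$subunits[[i]]$model$atoms$x + noise[, 1]
      asm$subunits[[i]]$model$atoms$y <- asm$subunits[[i]]$model$atoms$y + noise[, 2]
      asm$subunits[[i]]$model$atoms$z <- asm$subunits[[i]]$model$atoms$z + noise[, 3]
    }
  }
  asm
}
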