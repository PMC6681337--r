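test_that("residue pairing takes the intersection of residue numbers", {
  sub <- make_toy_subunit(toy_subunit_spec())
  pr <- pair_by_residue_number(sub, sub)
  expect_equal(pr$pairs$resno, protein_resnos(sub))
  # offset copies share only the overlap
  a <- sub; a$atoms <- a$atoms[a$atoms$resno <= 30, ]
  b <- sub; b$atoms <- b$atoms[b$atoms$resno >= 21, ]
  pr2 <- pair_by_residue_number(a, b)
  expect_equal(pr2$pairs$resno, 21:30)
  expect_equal(pr2$unpaired_a, 1:20)
  c <- sub; c$atoms <- c$atoms[c$atoms$resno > 30, ]
  expect_error(pair_by_residue_number(a, c), "no shared residues")
})

test_that("kabsch recovers an applied rigid transform exactly", {
  set.seed(3)
  P <- matrix(rnorm(60), ncol = 3)
  self <- kabsch(P, P)
  expect_equal(self$rmsd_A, 0, tolerance = 1e-12)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)
  tr <- rigid_transform(axialkit:::rot_z(90), c(1, 2, 3))
  fit <- kabsch(P, apply_transform(tr, P))
  expect_equal(fit$rmsd_A, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(fit$transform$translation, tr$translation, tolerance = 1e-9)
})

test_that("kabsch rejects degenerate input and reflections never appear", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  # a mirrored cloud must still yield a proper rotation (det +1)
  set.seed(4)
  P <- matrix(rnorm(45), ncol = 3)
  Q <- P %*% diag(c(-1, 1, 1))
  fit <- kabsch(P, Q)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-12)
})

test_that("fitted RMSD beats thousands of sampled rotations (optimality)", {
  set.seed(12)
  n_rot <- 2000
  rots <- t(vapply(seq_len(n_rot), function(i) as.vector(random_rotation()),
                   numeric(9)))
  for (k in 1:5) {
    n <- sample(4:20, 1)
    P <- matrix(rnorm(3 * n), ncol = 3)
    Q <- matrix(rnorm(3 * n), ncol = 3)
    fit <- kabsch(P, Q)
    Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
    ssp <- sum(Pc^2); ssq <- sum(Qc^2)
    M <- crossprod(Pc, Qc)                       # sum_i p_i q_i^T
    cross <- rots %*% as.vector(t(M))            # tr(R M) per sampled R
    rmsd_sampled <- sqrt((ssp + ssq - 2 * cross) / n)
    expect_lte(fit$rmsd_A, min(rmsd_sampled) + 1e-12)
  }
})

test_that("superposition RMSD is symmetric and invariant to pre-rotation", {
  sub <- make_toy_subunit(toy_subunit_spec(seed = 2))
  noisy <- sub
  set.seed(8)
  noisy$atoms$x <- noisy$atoms$x + rnorm(nrow(noisy$atoms), 0, 0.5)
  noisy$atoms$y <- noisy$atoms$y + rnorm(nrow(noisy$atoms), 0, 0.5)
  noisy$atoms$z <- noisy$atoms$z + rnorm(nrow(noisy$atoms), 0, 0.5)
  ab <- superpose_chains(sub, noisy)
  ba <- superpose_chains(noisy, sub)
  expect_equal(ab$rmsd_A, ba$rmsd_A, tolerance = 1e-9)
  pre <- transform_model(sub, rigid_transform(random_rotation(), c(5, -3, 2)))
  expect_equal(superpose_chains(pre, noisy)$rmsd_A, ab$rmsd_A, tolerance = 1e-9)
  # model vs itself and vs a rigidly moved copy: zero
  expect_equal(superpose_chains(sub, sub)$rmsd_A, 0, tolerance = 1e-12)
  expect_equal(superpose_chains(sub, pre)$rmsd_A, 0, tolerance = 1e-9)
})

test_that("kabsch agrees with an independent least-squares fit (bio3d)", {
  set.seed(21)
  P <- matrix(rnorm(90), ncol = 3)
  Q <- P + matrix(rnorm(90, 0, 0.4), ncol = 3)
  fit <- kabsch(P, Q)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
  rmsd_ref <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(fit$rmsd_A, rmsd_ref, tolerance = 1e-6)
})
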