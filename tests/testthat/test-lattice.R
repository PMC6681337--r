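test_that("the generator transform is a screw about +z and its powers add up", {
  sym <- rod_symmetry()
  g <- generator_transform(sym)
  sd <- screw_decompose(g)
  expect_equal(sd$angle_deg, 64.75, tolerance = 1e-12)
  expect_equal(sd$axial_translation, 4.13, tolerance = 1e-12)
  # 11 applications: net rotation 11 x 64.75 = 712.25 (= -7.75 mod 360),
  # net rise 11 x 4.13 = 45.43
  t11 <- lattice_transform(sym, 11)
  sd11 <- screw_decompose(t11)
  expect_equal(sd11$angle_deg, 712.25 - 720, tolerance = 1e-9)
  expect_equal(sd11$axial_translation, 45.43, tolerance = 1e-9)
  # near-identity twist limit keeps the rise
  g2 <- generator_transform(screw_symmetry(360 - 1e-9, 4))
  expect_equal(screw_decompose(g2)$axial_translation, 4, tolerance = 1e-12)
})

test_that("transform composition matches index addition (group property)", {
  sym <- screw_symmetry(37.3, 2.9)
  set.seed(11)
  for (k in 1:10) {
    n <- sample(-20:20, 1); m <- sample(-20:20, 1)
    lhs <- rt_compose(lattice_transform(sym, n), lattice_transform(sym, m))
    rhs <- lattice_transform(sym, n + m)
    expect_equal(lhs$rotation, rhs$rotation, tolerance = 1e-9)
    expect_equal(lhs$translation, rhs$translation, tolerance = 1e-9)
  }
})

test_that("subunit counting per turns uses nearest-integer rounding", {
  sym <- rod_symmetry()
  expect_identical(subunits_per_turns(sym, 2), 11L)
  expect_identical(subunits_per_turns(sym, 4), 22L)
  expect_identical(subunits_per_turns(sym, 0), 0L)
})

test_that("protofilament search finds the most axial lattice offset", {
  pf <- protofilament_count(rod_symmetry())
  expect_identical(pf$n, 11L)
  expect_equal(pf$residual_deg, -7.75, tolerance = 1e-9)
  expect_identical(protofilament_count(hook_symmetry())$n, 11L)
  # exact 11-subunits-per-2-turns lattice: zero residual
  pf0 <- protofilament_count(screw_symmetry(720 / 11, 4))
  expect_identical(pf0$n, 11L)
  expect_equal(pf0$residual_deg, 0, tolerance = 1e-9)
})

test_that("start families report wrapped rotations and rises antisymmetrically", {
  sym <- rod_symmetry()
  fam <- start_families(sym, c(-11, -6, -5, 5, 6, 11))
  r5 <- fam[fam$offset == 5, ]
  expect_equal(r5$net_rotation_deg, -36.25, tolerance = 1e-9)  # 323.75 wrapped
  expect_equal(r5$net_rise_A, 20.65, tolerance = 1e-9)
  expect_identical(r5$family, "5-start")
  for (k in c(5, 6, 11)) {
    expect_equal(fam$net_rotation_deg[fam$offset == k],
                 -fam$net_rotation_deg[fam$offset == -k], tolerance = 1e-12)
    expect_equal(fam$net_rise_A[fam$offset == k],
                 -fam$net_rise_A[fam$offset == -k], tolerance = 1e-12)
  }
  expect_equal(start_families(screw_symmetry(720 / 11, 4), 11)$net_rotation_deg,
               0, tolerance = 1e-9)
  expect_error(start_families(sym, 0), "nonzero")
})

test_that("build_assembly places one copy per index with identical internal geometry", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-21, 0))
  expect_length(asm$subunits, 22L)
  expect_identical(asm$indices, -21:0)
  # index 0 is the reference placement
  asm0 <- build_assembly(sub, rod_symmetry(), c(0, 0))
  expect_equal(model_xyz(asm0$subunits[[1]]$model), model_xyz(sub))
  # all copies share the internal distance matrix
  d0 <- dist(model_xyz(asm$subunits[[1]]$model))
  for (i in c(7, 22))
    expect_equal(as.numeric(dist(model_xyz(asm$subunits[[i]]$model))),
                 as.numeric(d0), tolerance = 1e-6)
  expect_error(build_assembly(sub, rod_symmetry(), c(3, 1)), "n_max")
})

test_that("infer_symmetry inverts build_assembly exactly on noiseless assemblies", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-21, 0))
  fit <- infer_symmetry(asm)
  expect_equal(fit$twist_deg, 64.75, tolerance = 1e-9)
  expect_equal(fit$rise_A, 4.13, tolerance = 1e-9)
  expect_lt(max(fit$steps$rmsd_A), 1e-9)
})

test_that("infer_symmetry tolerates coordinate noise and flags shuffled order", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- make_noisy_assembly(sub, rod_symmetry(), 22, sigma_A = 0.2, seed = 5)
  fit <- infer_symmetry(asm)
  expect_lt(abs(fit$twist_deg - 64.75), 0.1)
  expect_lt(abs(fit$rise_A - 4.13), 0.05)
  # shuffled subunit order: congruent copies still superpose, so the flag is
  # the per-step parameter spread, not the fit RMSD
  coords <- lapply(asm$subunits, function(s) model_xyz(s$model))
  set.seed(1)
  fit_bad <- infer_symmetry(sample(coords))
  expect_gt(fit_bad$twist_sd_deg, 1)
  expect_lt(fit$twist_sd_deg, 1)
  expect_error(infer_symmetry(coords[1]), "at least 2")
  expect_error(infer_symmetry(list(coords[[1]], coords[[2]][-1, ])),
               "inconsistent")
})

test_that("build->infer round trip recovers random screw parameters", {
  sub <- make_toy_subunit(toy_subunit_spec())
  set.seed(99)
  for (k in 1:8) {
    tw <- runif(1, 30, 120); ri <- runif(1, 2, 8)
    sym <- screw_symmetry(tw, ri)
    fit <- infer_symmetry(build_assembly(sub, sym, c(-5, 0)))
    expect_equal(fit$twist_deg, tw, tolerance = 1e-9)
    expect_equal(fit$rise_A, ri, tolerance = 1e-9)
  }
})

test_that("protofilament count is stable under sub-residual twist perturbation", {
  base <- protofilament_count(rod_symmetry())
  for (d in c(-0.05, 0.05))
    expect_identical(protofilament_count(screw_symmetry(64.75 + d, 4.13))$n,
                     base$n)
})
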