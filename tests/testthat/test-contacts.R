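two_far_subunits <- function(gap = 100) {
  atoms <- data.frame(eleno = 1:4, elety = "CA", resid = "ALA", resno = 1:4,
                      insert = "", alt = "", x = c(0, 1, 2, 3), y = 0, z = 0,
                      o = 1, b = 0, elesy = "C", is_het = FALSE)
  sub <- subunit_model(atoms, "A", segments = list(D1 = c(1, 4)))
  build_assembly(sub, screw_symmetry(60, gap), c(0, 1))
}

test_that("subunits farther apart than the cutoff yield no edges", {
  cm <- contact_map(two_far_subunits(), 4.0)
  expect_identical(nrow(cm), 0L)
  expect_error(contact_map(two_far_subunits(), -1), "positive")
})

test_that("grid contact map equals the all-pairs brute force (oracle)", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-11, 0))  # ~590 atoms
  for (cutoff in c(3.5, 4.0, 4.5)) {
    grid <- normalize_edges(contact_map(asm, cutoff))
    brute <- normalize_edges(brute_contact_edges(asm, cutoff))
    expect_equal(grid, brute, tolerance = 1e-12)
  }
  # and on an irregular random-cloud assembly
  set.seed(31)
  atoms <- data.frame(eleno = 1:40, elety = "CA", resid = "ALA", resno = 1:40,
                      insert = "", alt = "", x = rnorm(40, 0, 6),
                      y = rnorm(40, 0, 6), z = rnorm(40, 0, 6),
                      o = 1, b = 0, elesy = "C", is_het = FALSE)
  cloud <- subunit_model(atoms, "A", segments = list(D1 = c(1, 40)))
  asm2 <- build_assembly(cloud, screw_symmetry(100, 3), c(0, 5))
  expect_equal(normalize_edges(contact_map(asm2, 4.0)),
               normalize_edges(brute_contact_edges(asm2, 4.0)),
               tolerance = 1e-12)
})

test_that("edge sets are symmetric and monotone in the cutoff", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-11, 0))
  e4 <- contact_map(asm, 4.0)
  # symmetry: (a,b) present iff (b,a) present with mirrored fields
  key_ab <- paste(e4$index_a, e4$index_b, e4$segment_a, e4$segment_b)
  key_ba <- paste(e4$index_b, e4$index_a, e4$segment_b, e4$segment_a)
  expect_setequal(key_ab, key_ba)
  # monotonicity: smaller cutoff's edges are a subset
  e3 <- contact_map(asm, 3.2)
  expect_true(all(paste(e3$index_a, e3$index_b, e3$segment_a, e3$segment_b)
                  %in% key_ab))
  expect_true(all(e4$min_dist_A <= 4.0))
  expect_true(all(e4$offset != 0))
})

test_that("the designed arm contacts exactly its target offset", {
  sub <- make_toy_subunit(toy_subunit_spec(arm_direction = -5))
  asm <- build_assembly(sub, rod_symmetry(), c(-21, 0))
  cm <- contact_map(asm, 4.0)
  fp <- segment_fingerprint(cm, -8, "L_STRETCH")
  expect_identical(unique(fp$offset), -5L)
  expect_identical(unique(fp$partner_segment), "D1")
  # nothing at -10 or -16
  expect_false(any(fp$offset %in% c(-10L, -16L)))
})

test_that("fingerprints are identical across all interior subunits", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-21, 0))
  cm <- contact_map(asm, 4.0)
  margin <- max(abs(cm$offset))
  interior <- asm$indices[asm$indices - margin >= min(asm$indices) &
                            asm$indices + margin <= max(asm$indices)]
  expect_gt(length(interior), 3)
  fps <- lapply(interior, function(i) segment_fingerprint(cm, i, "L_STRETCH"))
  for (fp in fps[-1]) expect_identical(fp, fps[[1]])
  # boundary subunits are rejected, naming the missing neighbors
  expect_error(segment_fingerprint(cm, 0, "L_STRETCH"), "not interior")
})

test_that("mutation sites map to their contact environment", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-21, 0))
  arm <- sub$segments$L_STRETCH
  tip <- arm[2]            # arm tip touches the -5 neighbor's D1
  rep1 <- map_mutation_sites(asm, tip, 4.0, reference_index = -8)
  expect_true(rep1[[1]]$modeled)
  expect_identical(rep1[[1]]$segment, "L_STRETCH")
  expect_true(-5L %in% rep1[[1]]$environment$offset)
  # a site far from every neighbor has an empty environment
  mid_d1 <- sub$segments$D0N[1]
  rep2 <- map_mutation_sites(asm, mid_d1, 0.5, reference_index = -8)
  expect_identical(nrow(rep2[[1]]$environment), 0L)
  expect_error(map_mutation_sites(asm, 10000, 4.0, reference_index = -8),
               "outside")
})

test_that("sites inside a deletion mask are flagged unmodeled with approximate environment", {
  sub <- make_toy_subunit(toy_subunit_spec())
  arm <- sub$segments$L_STRETCH
  tip <- as.integer(arm[2])
  masked <- apply_deletion_mask(sub, c(tip - 1, tip))
  masked$segments <- sub$segments   # annotation still covers the removed tip
  asm <- build_assembly(masked, rod_symmetry(), c(-21, 0))
  rep <- map_mutation_sites(asm, tip, 4.0, reference_index = -8)
  expect_false(rep[[1]]$modeled)
  expect_true(rep[[1]]$approximate)
  expect_identical(rep[[1]]$segment, "L_STRETCH")
  expect_true(all(rep[[1]]$flanking %in% protein_resnos(masked)))
})

test_that("fingerprint sensitivity table spans the requested cutoffs", {
  sub <- make_toy_subunit(toy_subunit_spec())
  asm <- build_assembly(sub, rod_symmetry(), c(-21, 0))
  sens <- fingerprint_sensitivity(asm, -8, "L_STRETCH", c(3.5, 4.0, 4.5))
  expect_setequal(unique(sens$cutoff_A), c(3.5, 4.0, 4.5))
  expect_true(all(sens$offset == -5))
})
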