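# acceptor lacking its arm + donor carrying it, both derived from one
# ground-truth toy subunit
split_toy <- function(seed = 1) {
  truth <- make_toy_subunit(toy_subunit_spec(seed = seed))
  arm <- truth$segments$L_STRETCH
  acc_atoms <- truth$atoms[!(truth$atoms$resno >= arm[1] &
                               truth$atoms$resno <= arm[2]), ]
  acceptor <- subunit_model(acc_atoms, "A",
                            segments = truth$segments[c("D0N", "D1", "D0C")])
  list(truth = truth, acceptor = acceptor, arm_range = arm)
}

test_that("grafting from an identical copy reproduces the ground truth arm", {
  fx <- split_toy()
  # donor = ground truth moved far away; the D1 fit must bring the arm back
  donor <- transform_model(fx$truth,
                           rigid_transform(random_rotation(), c(30, -12, 50)))
  res <- graft(fx$acceptor, donor, graft_plan("D1", "L_STRETCH"))
  chim <- res$model
  # acceptor coordinates outside the grafted segment are bit-identical
  keep <- !(chim$atoms$resno >= fx$arm_range[1] &
              chim$atoms$resno <= fx$arm_range[2])
  got <- as.matrix(chim$atoms[keep, c("x", "y", "z")])[order(chim$atoms$resno[keep]), ]
  want <- as.matrix(fx$acceptor$atoms[order(fx$acceptor$atoms$resno),
                                      c("x", "y", "z")])
  expect_identical(unname(got), unname(want))
  # grafted arm lands exactly on the ground-truth arm geometry
  arm_chim <- model_xyz(chim)[chim$atoms$resno >= fx$arm_range[1] &
                                chim$atoms$resno <= fx$arm_range[2], ]
  arm_true <- model_xyz(fx$truth)[fx$truth$atoms$resno >= fx$arm_range[1] &
                                    fx$truth$atoms$resno <= fx$arm_range[2], ]
  expect_equal(arm_chim, arm_true, tolerance = 1e-9)
  expect_equal(res$report$align_rmsd_A, 0, tolerance = 1e-9)
})

test_that("grafted segments are transferred rigidly (internal distances preserved)", {
  fx <- split_toy(seed = 3)
  donor <- transform_model(fx$truth,
                           rigid_transform(random_rotation(), c(-8, 4, 19)))
  res <- graft(fx$acceptor, donor, graft_plan("D1", "L_STRETCH"))
  arm_sel <- function(m) model_xyz(m)[m$atoms$resno >= fx$arm_range[1] &
                                        m$atoms$resno <= fx$arm_range[2], ]
  expect_equal(as.numeric(dist(arm_sel(res$model))),
               as.numeric(dist(arm_sel(donor))), tolerance = 1e-6)
})

test_that("graft then delete returns the acceptor exactly (round trip)", {
  fx <- split_toy(seed = 5)
  res <- graft(fx$acceptor, fx$truth, graft_plan("D1", "L_STRETCH"))
  undone <- apply_deletion_mask(res$model, fx$arm_range)
  expect_equal(protein_resnos(undone), protein_resnos(fx$acceptor))
  ord <- function(m) m$atoms[order(m$atoms$resno, m$atoms$elety),
                             c("resno", "elety", "x", "y", "z")]
  a <- ord(undone); b <- ord(fx$acceptor)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("residue-number collisions abort the graft with the offending residues", {
  truth <- make_toy_subunit(toy_subunit_spec())
  expect_error(graft(truth, truth, graft_plan("D1", "L_STRETCH")),
               "collision")
})

test_that("relabeling truncates sidechains to the shared atom set", {
  mk <- function(resid, atoms) {
    data.frame(eleno = seq_along(atoms), elety = atoms, resid = resid,
               resno = 1, insert = "", alt = "",
               x = seq_along(atoms), y = 0, z = 0, o = 1, b = 0,
               elesy = substr(atoms, 1, 1), is_het = FALSE)
  }
  trp <- subunit_model(mk("TRP", c("N", "CA", "C", "O", "CB", "CG", "CD1",
                                   "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                                   "CH2")))
  rel <- relabel_to_target(trp, data.frame(pos_a = 1, pos_b = 1), "S")
  expect_setequal(rel$atoms$elety, c("N", "CA", "C", "O", "CB"))
  expect_identical(rel$atoms$resid[1], "SER")
  ala <- subunit_model(mk("ALA", c("N", "CA", "C", "O", "CB")))
  relg <- relabel_to_target(ala, data.frame(pos_a = 1, pos_b = 1), "G")
  expect_setequal(relg$atoms$elety, c("N", "CA", "C", "O"))
  # identity alignment leaves the model unchanged
  sub <- make_toy_subunit(toy_subunit_spec())
  n <- length(protein_resnos(sub))
  ident <- relabel_to_target(sub, data.frame(pos_a = 1:n, pos_b = 1:n),
                             model_sequence(sub))
  expect_equal(model_xyz(ident), model_xyz(sub))
  expect_error(relabel_to_target(ala, data.frame(pos_a = 2, pos_b = 1), "G"),
               "model position")
})

test_that("deletion masks remove exact ranges and warn on degenerate masks", {
  sub <- make_toy_subunit(toy_subunit_spec())
  # the l-stretch tip mask: 53-64 removes exactly 12 residues from a model
  # spanning that range
  span <- range(protein_resnos(sub))
  masked <- apply_deletion_mask(sub, c(5, 16))
  expect_identical(length(protein_resnos(sub)) - length(protein_resnos(masked)),
                   12L)
  expect_equal(setdiff(protein_resnos(sub), protein_resnos(masked)), 5:16)
  expect_warning(apply_deletion_mask(sub, c(9000, 9010)), "no residues")
  expect_warning(empty <- apply_deletion_mask(sub, span), "every residue")
  expect_length(protein_resnos(empty), 0L)
})
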