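test_that("canonical frame realises its defining constraints", {
  # already-canonical points: identity
  tr <- canonical_frame(c(0, 0, 0), c(0, 5, 0), c(3, 1, 0))
  expect_equal(tr$R, diag(3), tolerance = 1e-9)
  expect_equal(tr$t, c(0, 0, 0), tolerance = 1e-9)
  # hand-constructed offset triplet
  tr2 <- canonical_frame(c(1, 1, 1), c(1, 4, 1), c(2, 1, 1))
  expect_equal(apply_transform(tr2, c(1, 1, 1)), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(apply_transform(tr2, c(1, 4, 1)), c(0, 3, 0),
               tolerance = 1e-9)
  a3 <- apply_transform(tr2, c(2, 1, 1))
  expect_equal(a3[3], 0, tolerance = 1e-9)
  expect_gt(a3[1], 0)
})

test_that("canonical frame is proper, rigid and idempotent on randoms", {
  set.seed(61)
  for (i in 1:25) {
    pts <- matrix(rnorm(9, sd = 5), 3)
    tr <- canonical_frame(pts[1, ], pts[2, ], pts[3, ])
    expect_lt(abs(det(tr$R) - 1), 1e-9)
    moved <- apply_transform(tr, pts)
    expect_lt(max(abs(dist(moved) - dist(pts))), 1e-6)
    expect_equal(moved[1, ], c(0, 0, 0), tolerance = 1e-9)
    expect_equal(moved[2, c(1, 3)], c(0, 0), tolerance = 1e-9)
    expect_gt(moved[2, 2], 0)
    expect_equal(moved[3, 3], 0, tolerance = 1e-9)
    expect_gt(moved[3, 1], 0)
    # applying the construction to canonical points gives the identity
    tr_id <- canonical_frame(moved[1, ], moved[2, ], moved[3, ])
    expect_equal(tr_id$R, diag(3), tolerance = 1e-9)
    expect_equal(tr_id$t, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("degenerate anchors are rejected", {
  expect_error(canonical_frame(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincide")
  expect_error(canonical_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  expect_error(rigid_transform(diag(3) * -1), "proper")
})

test_that("transform algebra: inverse and composition", {
  tr <- random_transform()
  id <- compose_transforms(invert_transform(tr), tr)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-9)
  p <- rnorm(3)
  expect_equal(apply_transform(invert_transform(tr),
                               apply_transform(tr, p)), p,
               tolerance = 1e-9)
})

test_that("self-docking leaves the ligand fixed", {
  fx <- make_binding_fixture(seed = 62)
  anchors <- fx$truth$motif_keys[1:3]
  pose <- dock_ligand(fx$holo, fx$ligand, anchors, fx$holo, anchors)
  expect_lt(max(abs(as.matrix(pose$ligand[, c("x", "y", "z")]) -
                    as.matrix(fx$ligand$atoms[, c("x", "y", "z")]))),
            1e-9)
  expect_lt(pose$anchor_rmsd, 1e-9)
})

test_that("moved-copy fixtures recover the ground-truth pose", {
  for (seed in c(63, 64, 65)) {
    fx <- make_binding_fixture(seed = seed)
    hk <- fx$truth$motif_keys[1:3]
    pose <- dock_ligand(fx$holo, fx$ligand, hk, fx$target, hk)
    expect_lt(max(abs(as.matrix(pose$ligand[, c("x", "y", "z")]) -
                      fx$truth$docked_xyz)), 1e-6)
    # ligand internal geometry untouched
    expect_lt(max(abs(dist(pose$ligand[, c("x", "y", "z")]) -
                      dist(fx$ligand$atoms[, c("x", "y", "z")]))), 1e-6)
    # k-point least-squares mode agrees on an exact copy
    hk4 <- fx$truth$motif_keys[1:4]
    pose_k <- dock_ligand(fx$holo, fx$ligand, hk4, fx$target, hk4,
                          method = "kabsch")
    expect_lt(max(abs(as.matrix(pose_k$ligand[, c("x", "y", "z")]) -
                      fx$truth$docked_xyz)), 1e-6)
  }
})

test_that("canonical and target frames differ by the target transform", {
  fx <- make_binding_fixture(seed = 66)
  hk <- fx$truth$motif_keys[1:3]
  pt <- dock_ligand(fx$holo, fx$ligand, hk, fx$target, hk,
                    frame = "target")
  pc <- dock_ligand(fx$holo, fx$ligand, hk, fx$target, hk,
                    frame = "canonical")
  back <- apply_transform(pt$transform_target,
                          as.matrix(pt$ligand[, c("x", "y", "z")]))
  expect_lt(max(abs(back - as.matrix(pc$ligand[, c("x", "y", "z")]))),
            1e-6)
})

test_that("anchor rmsd agrees with the congruence metric", {
  fx <- make_binding_fixture(seed = 67)
  hk <- fx$truth$motif_keys[1:3]
  # perturb the target anchors so the rmsd is nonzero
  a <- fx$target$atoms
  ik <- match(hk, paste(a$chain, a$resno, a$insert, a$resid, a$name,
                        sep = "/"))
  set.seed(67)
  a[ik, c("x", "y", "z")] <- a[ik, c("x", "y", "z")] +
    matrix(rnorm(9, sd = 0.3), 3)
  tgt <- new_structure3d(a, id = "perturbed")
  tk <- atom_keys(a[ik, ])
  pose <- dock_ligand(fx$holo, fx$ligand, hk, tgt, tk)
  qa <- fx$holo$atoms[match(hk, paste(fx$holo$atoms$chain,
                                      fx$holo$atoms$resno,
                                      fx$holo$atoms$insert,
                                      fx$holo$atoms$resid,
                                      fx$holo$atoms$name, sep = "/")), ]
  met <- congruence_metrics(
    motif_stub(as.matrix(dist(qa[, c("x", "y", "z")])),
               xyz = as.matrix(qa[, c("x", "y", "z")])),
    motif_stub(as.matrix(dist(a[ik, c("x", "y", "z")])),
               xyz = as.matrix(a[ik, c("x", "y", "z")])))
  expect_equal(pose$anchor_rmsd, met$rmsd, tolerance = 1e-6)
  expect_gte(pose$frame_rmsd, pose$anchor_rmsd - 1e-9)
})

test_that("clash report equals the brute-force pair count", {
  fx <- make_binding_fixture(seed = 68)
  hk <- fx$truth$motif_keys[1:3]
  pose <- dock_ligand(fx$holo, fx$ligand, hk, fx$target, hk)
  for (cutoff in c(2, 3.5, 5)) {
    cl <- clash_report(pose, fx$target, cutoff = cutoff)
    d <- as.matrix(dist(rbind(as.matrix(fx$target$atoms[, c("x", "y", "z")]),
                              as.matrix(pose$ligand[, c("x", "y", "z")]))))
    nt <- nrow(fx$target$atoms)
    cross <- d[seq_len(nt), nt + seq_len(nrow(pose$ligand)), drop = FALSE]
    expect_equal(cl$n_clashes, sum(cross < cutoff))
    expect_equal(cl$worst, min(cross), tolerance = 1e-12)
  }
  # a single atom at 1.5 A from the outermost ligand atom (placed
  # outward, so no other ligand atom comes closer) is exactly one clash
  lx <- as.matrix(pose$ligand[, c("x", "y", "z")])
  cen <- colMeans(lx)
  far <- which.max(rowSums(sweep(lx, 2, cen)^2))
  u <- (lx[far, ] - cen) / sqrt(sum((lx[far, ] - cen)^2))
  tgt1 <- new_structure3d(atoms_at(lx[far, ] + 1.5 * u, "OG", "SER"))
  cl1 <- clash_report(pose, tgt1, cutoff = 2)
  expect_equal(cl1$n_clashes, 1L)
  expect_equal(cl1$worst, 1.5, tolerance = 1e-9)
})

test_that("a far-away pose makes no contacts and no clashes", {
  fx <- make_binding_fixture(seed = 69)
  pose <- dock_ligand(fx$holo, fx$ligand, fx$truth$motif_keys[1:3],
                      fx$target, fx$truth$motif_keys[1:3])
  pose$ligand[, c("x", "y", "z")] <-
    pose$ligand[, c("x", "y", "z")] + 100
  expect_equal(clash_report(pose, fx$target)$n_clashes, 0L)
  expect_equal(nrow(pose_contacts(pose, fx$target)), 0L)
})

test_that("pose contacts recover the binding residues", {
  fx <- make_binding_fixture(seed = 70)
  pose <- dock_ligand(fx$holo, fx$ligand, fx$truth$motif_keys[1:3],
                      fx$target, fx$truth$motif_keys[1:3])
  pc <- pose_contacts(pose, fx$target, n = 10)
  truth_res <- as.integer(sub("^A/(\\d+)/.*", "\\1",
                              fx$truth$motif_keys))
  expect_true(all(truth_res %in% pc$resno))
  # one residue placed at exactly 3.0 A appears with that distance
  tgt1 <- new_structure3d(rbind(atoms_at(
    as.numeric(pose$ligand[pose$ligand$elem == "O", ][1, c("x", "y", "z")]) +
      c(3, 0, 0), "OG", "SER")))
  pc1 <- pose_contacts(pose, tgt1, n = 5)
  expect_equal(nrow(pc1), 1L)
  expect_equal(pc1$distance, 3.0, tolerance = 1e-6)
})

test_that("maximum intra-ligand distance is exact", {
  two <- structure(list(het_code = "LIG", chain = "A", resno = 1L,
                        atoms = atoms_at(rbind(c(0, 0, 0), c(4, 0, 0)),
                                         c("O1", "O2"), "LIG",
                                         het = TRUE)),
                   class = "ligand3d")
  sp <- max_intraligand_distance(two)
  expect_equal(sp$distance, 4.0)
  expect_setequal(sp$atoms, c("O1", "O2"))
  three <- structure(list(het_code = "LIG", chain = "A", resno = 1L,
                          atoms = atoms_at(rbind(c(0, 0, 0), c(1, 0, 0),
                                                 c(3, 0, 0)),
                                           c("C1", "C2", "C3"), "LIG",
                                           het = TRUE)),
                     class = "ligand3d")
  sp3 <- max_intraligand_distance(three)
  expect_equal(sp3$distance, 3.0)
  expect_setequal(sp3$atoms, c("C1", "C3"))
  one <- three; one$atoms <- one$atoms[1, ]
  expect_error(max_intraligand_distance(one), "at least 2")
})
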