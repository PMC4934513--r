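test_that("database enumeration is complete versus brute force", {
  for (seed in c(41, 42, 43, 44)) {
    fx <- make_binding_fixture(seed = seed, n_residues = 12,
                               n_binding = 4)
    for (cutoff in c(8, 15, 30)) {
      db <- build_motif_db(fx$apo, k = 4, cutoff = cutoff)
      orc <- oracle_cliques(as.matrix(db$atoms[, c("x", "y", "z")]),
                            4, cutoff)
      expect_equal(ncol(db$combos), ncol(orc),
                   info = paste("seed", seed, "cutoff", cutoff))
      if (ncol(orc)) {
        canon <- function(m) sort(apply(m, 2, paste, collapse = "-"))
        expect_equal(canon(db$combos), canon(orc))
      }
      # stored motifs respect the cutoff
      if (ncol(db$combos)) {
        D <- as.matrix(dist(db$atoms[, c("x", "y", "z")]))
        maxd <- apply(db$combos, 2, function(ix) max(D[ix, ix]))
        expect_true(all(maxd <= cutoff + 1e-9))
      }
    }
  }
})

test_that("tiny cutoffs and distant residues exclude motifs", {
  fx <- make_binding_fixture(seed = 45, n_residues = 8)
  db0 <- build_motif_db(fx$apo, k = 4, cutoff = 0.1)
  expect_equal(ncol(db0$combos), 0)
  # push one binding residue 50 A away: it may appear in no motif at 15 A
  a <- fx$apo$atoms
  far <- a$resno == 1
  a[far, c("x", "y", "z")] <- a[far, c("x", "y", "z")] + 50
  db <- build_motif_db(new_structure3d(a, id = "far"), k = 4, cutoff = 15)
  if (ncol(db$combos)) {
    far_idx <- which(db$atoms$resno == 1)
    expect_false(any(db$combos %in% far_idx))
  }
  # no qualifying residues at all -> empty database with warning
  gly <- new_structure3d(atoms_at(matrix(rnorm(9), 3), "CA", "GLY",
                                  elem = "C"))
  expect_warning(db_e <- build_motif_db(gly, k = 3), "empty")
  expect_equal(ncol(db_e$combos), 0)
})

test_that("cscore matches its formula on hand-built motifs", {
  tri <- function(v) { D <- diag(0, 3); D[upper.tri(D)] <- v; D + t(D) }
  q <- motif_stub(tri(c(4, 5, 6)))
  cc <- motif_stub(tri(c(5, 5, 6)))
  expect_equal(cscore(q, q)$score, 0)
  expect_equal(cscore(q, cc)$score, 0.25)  # |4-5|/4
  # PD dead-zone: |PD| deviation of 50 is ignored; 150 is charged
  pdm <- function(v) { M <- diag(0, 3); M[upper.tri(M)] <- v
                       M - t(M) }
  qp <- motif_stub(tri(c(4, 5, 6)), pds = pdm(c(300, 0, 0)))
  cp1 <- motif_stub(tri(c(4, 5, 6)), pds = pdm(c(250, 0, 0)))
  cp2 <- motif_stub(tri(c(4, 5, 6)), pds = pdm(c(450, 0, 0)))
  expect_equal(cscore(qp, cp1)$score, 0)
  expect_equal(cscore(qp, cp2)$score, (150 - 100) / 300)
  # sign of PD never matters: differences are taken on absolute values
  cp3 <- motif_stub(tri(c(4, 5, 6)), pds = pdm(c(-300, 0, 0)))
  expect_equal(cscore(qp, cp3)$score, 0)
  # scale sensitivity: growing one candidate distance strictly increases
  worse <- motif_stub(tri(c(5, 5, 12)))
  expect_gt(cscore(q, worse)$score, cscore(q, cc)$score)
  # degenerate query
  qz <- motif_stub(tri(c(0, 5, 6)))
  expect_error(cscore(qz, cc), "degenerate")
})

test_that("congruence metrics: rigid copies, edge stretch, arithmetic", {
  xyz_q <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  tr <- random_transform()
  q <- motif_stub(as.matrix(dist(xyz_q)), xyz = xyz_q)
  rot <- motif_stub(as.matrix(dist(apply_transform(tr, xyz_q))),
                    xyz = apply_transform(tr, xyz_q))
  met <- congruence_metrics(q, rot)
  expect_lt(met$rmsd, 1e-6)
  expect_lt(met$maxdev, 1e-9)
  # one edge stretched by 2 A dominates maxdev
  xyz_c <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 6, 0))
  cc <- motif_stub(as.matrix(dist(xyz_c)), xyz = xyz_c)
  expect_equal(congruence_metrics(q, cc)$maxdev, 2.0, tolerance = 1e-12)
  # maxdev is symmetric and equals the largest per-pair deviation
  expect_equal(congruence_metrics(cc, q)$maxdev, 2.0, tolerance = 1e-12)
  # arithmetic on two printed 4-atom distance sets
  dq <- c(9.5, 7.8, 11.2, 7.2, 6.6, 5.8)
  dc <- c(4.3, 6.7, 10.1, 6.7, 7.7, 4.9)
  expect_equal(max(abs(dq - dc)), 5.2, tolerance = 1e-9)
  # rmsd invariant under rigid motion of either motif
  met2 <- congruence_metrics(rot, cc)
  met3 <- congruence_metrics(q, cc)
  expect_equal(met2$rmsd, met3$rmsd, tolerance = 1e-6)
})

test_that("a database containing the query itself self-matches at 0", {
  fx <- make_binding_fixture(seed = 46)
  contacts <- get_motif(fx$holo, fx$ligand, n = 5)
  q <- assign_groups(as_motif(contacts[1:4, ], fx$apo))
  db <- build_motif_db(fx$apo, k = 4)
  res <- search_motifs(db, q, s_thresh = 5)
  expect_gt(length(res), 0)
  expect_lt(res[[1]]$cscore, 1e-9)
  expect_equal(sort(res[[1]]$motif$atoms$resno), sort(q$atoms$resno))
  expect_lt(res[[1]]$rmsd, 1e-6)
})

test_that("search equals exhaustive scoring of compatible candidates", {
  for (seed in c(51, 52)) {
    fx <- make_binding_fixture(seed = seed, n_residues = 9,
                               n_binding = 4)
    pot <- assign_potentials(fx$apo, "surrogate")
    contacts <- get_motif(fx$holo, fx$ligand, n = 4)
    q <- assign_groups(as_motif(contacts, fx$apo, potentials = pot))
    db <- build_motif_db(fx$apo, k = 4, cutoff = 20)
    res <- search_motifs(db, q, s_thresh = 8, potentials = pot,
                         max_results = 10000)
    orc <- oracle_search(db$atoms, q, k = 4, cutoff = 20, s_thresh = 8,
                         potentials = pot)
    expect_equal(length(res), length(orc), info = paste("seed", seed))
    expect_equal(vapply(res, `[[`, numeric(1), "cscore"),
                 vapply(orc, `[[`, numeric(1), "score"),
                 tolerance = 1e-9)
    # scores are sorted ascending; truncation keeps the prefix
    sc <- vapply(res, `[[`, numeric(1), "cscore")
    expect_true(all(diff(sc) >= -1e-12))
    res_lo <- search_motifs(db, q, s_thresh = sc[ceiling(length(sc) / 2)],
                            potentials = pot, max_results = 10000)
    expect_equal(vapply(res_lo, `[[`, numeric(1), "cscore"),
                 sc[sc <= sc[ceiling(length(sc) / 2)] + 1e-15],
                 tolerance = 1e-12)
  }
})

test_that("group-incompatible targets yield no matches", {
  fx <- make_binding_fixture(seed = 53,
                             binding_types = c("SER", "GLU", "TYR",
                                               "GLU", "TYR"))
  contacts <- get_motif(fx$holo, fx$ligand, n = 5)
  q <- assign_groups(as_motif(contacts[1:4, ], fx$apo))
  # a target made only of basic residues cannot satisfy {S,T}/{D,E}/{Y,W,F}
  basic <- make_binding_fixture(seed = 54,
                                binding_types = c("LYS", "ARG", "HIS",
                                                  "LYS", "ARG"),
                                types = c("LYS", "ARG", "HIS"))
  db <- build_motif_db(basic$target, k = 4)
  res <- search_motifs(db, q, s_thresh = 100)
  expect_length(res, 0)
})

test_that("database JSON round-trip preserves search results", {
  fx <- make_binding_fixture(seed = 55, n_residues = 8)
  db <- build_motif_db(fx$target, k = 4)
  p <- tempfile(fileext = ".json")
  db_to_json(db, p)
  db2 <- db_from_json(p)
  expect_equal(db2$k, db$k)
  expect_equal(ncol(db2$combos), ncol(db$combos))
  contacts <- get_motif(fx$holo, fx$ligand, n = 5)
  q <- assign_groups(as_motif(contacts[1:4, ], fx$apo))
  r1 <- search_motifs(db, q)
  r2 <- search_motifs(db2, q)
  expect_equal(vapply(r1, `[[`, numeric(1), "cscore"),
               vapply(r2, `[[`, numeric(1), "cscore"), tolerance = 1e-9)
})
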