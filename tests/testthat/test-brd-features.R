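em0 <- energy_model()

test_that("surface potentials follow the Coulomb closed form", {
  neutral <- charge_structure(c(0, 0, 0), charge = 0)
  s0 <- coulomb_samples(neutral, em0, density = 0.3)
  expect_true(all(s0$phi == 0))

  neg <- charge_structure(c(0, 0, 0), charge = -1)
  sn <- coulomb_samples(neg, em0, density = 0.3)
  expect_true(all(sn$phi < 0))

  # lone +1 charge: every sample sits at r = radius + 1.4 exactly, so
  # phi = 332 / (4 r^2); and a sample 4 A away would give 332/(4*16) = 5.1875
  pos <- charge_structure(c(0, 0, 0), charge = 1, radius = 2.6)
  sp <- coulomb_samples(pos, em0, density = 0.3)
  expect_equal(sp$phi, rep(332 / (4 * 4^2), nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$phi[1], 5.1875, tolerance = 1e-9)

  expect_error(coulomb_samples(pos, em0, density = 0), "positive")
})

test_that("buried sample points are discarded", {
  pair <- charge_structure(rbind(c(0, 0, 0), c(1, 0, 0)), charge = 0)
  smp <- coulomb_samples(pair, em0, density = 0.5)
  # every retained point is outside the other atom's extended sphere
  xyz <- coords(pair)
  for (j in 1:2) {
    other <- smp[smp$atom != j, ]
    d <- sqrt((other$x - xyz[j, 1])^2 + (other$y - xyz[j, 2])^2 +
                (other$z - xyz[j, 3])^2)
    expect_true(all(d > 1.7 + 1.4 - 1e-6))
  }
})

test_that("patch scores sum negative potential near a region", {
  s <- simulate_scaffold("good", jitter_sd = 0, seed = 1)
  ann <- scaffold_annotation(s)
  smp <- coulomb_samples(s, em0, density = 0.4)
  ps <- patch_score(smp, s, ann, "loopZA")
  expect_lt(ps$score, 0)
  expect_gt(ps$n_samples, 0)

  # a neutral scaffold has no negative potential anywhere
  sp <- simulate_scaffold("poor", jitter_sd = 0, seed = 1)
  smp_p <- coulomb_samples(sp, em0, density = 0.4)
  expect_equal(patch_score(smp_p, sp, scaffold_annotation(sp),
                           "loopZA")$score, 0)
  expect_error(patch_score(smp, s, ann, "alphaB"), "no region|alphaB")
})

test_that("patch score is additive over disjoint sample subsets", {
  s <- simulate_scaffold("good", jitter_sd = 0, seed = 1)
  ann <- scaffold_annotation(s)
  smp <- coulomb_samples(s, em0, density = 0.4)
  half <- seq_len(nrow(smp)) %% 2 == 0
  s1 <- patch_score(smp[half, ], s, ann)$score
  s2 <- patch_score(smp[!half, ], s, ann)$score
  expect_equal(s1 + s2, patch_score(smp, s, ann)$score, tolerance = 1e-10)
})

test_that("good scaffolds score more negative ZA patches than poor ones", {
  wins <- vapply(1:20, function(seed) {
    g <- simulate_scaffold("good", seed = seed)
    p <- simulate_scaffold("poor", seed = seed + 1000)
    sg <- patch_score(coulomb_samples(g, em0, density = 0.2), g,
                      scaffold_annotation(g))$score
    sp <- patch_score(coulomb_samples(p, em0, density = 0.2), p,
                      scaffold_annotation(p))$score
    sg < sp
  }, logical(1))
  expect_equal(sum(wins), 20L)
})

test_that("the asparagine check reads the helix C-terminus", {
  m <- toy_structure(c("ALA", "LEU", "ASN", "GLY"))
  ann_asn <- brd_annotation(alphaB = c(1, 3))
  expect_true(asn_at_helixB_cterm(m, ann_asn))
  ann_no <- brd_annotation(alphaB = c(1, 2))
  expect_false(asn_at_helixB_cterm(m, ann_no))
  expect_false(asn_at_helixB_cterm(m, ann_asn, window = 0))
  expect_true(asn_at_helixB_cterm(m, brd_annotation(alphaB = c(2, 4)),
                                  window = 2))  # ASN at position window-1
  expect_error(asn_at_helixB_cterm(m, brd_annotation(loopZA = c(1, 2))),
               "alphaB")
})

test_that("aromatic pocket counts find ring residues near the centroid", {
  none <- toy_structure(c("ALA", "GLY", "SER", "LEU"),
                        xyz = rbind(c(1, 0, 0), c(-1, 0, 0),
                                    c(0, 1, 0), c(0, -1, 0)),
                        names = rep("CB", 4))
  ann <- brd_annotation(loopZA = c(1, 2), loopBC = c(3, 4), pocket = 1:4)
  expect_equal(aromatic_pocket_count(none, ann), 0L)

  three <- toy_structure(c("PHE", "TYR", "TRP", "PHE", "ALA"),
                         xyz = rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
                                     c(50, 0, 0), c(0, -2, 0)),
                         names = rep("CZ", 5))
  ann3 <- brd_annotation(loopZA = c(1, 3), loopBC = c(4, 5),
                         pocket = c(1, 2, 3, 5))
  expect_equal(aromatic_pocket_count(three, ann3), 3L)
  expect_error(aromatic_pocket_count(three, brd_annotation(loopZA = c(1, 3))),
               "loopBC")
})

test_that("structure descriptors are rigid-motion invariant", {
  s <- simulate_scaffold("good", seed = 5)
  ann <- scaffold_annotation(s)
  base_patch <- patch_score(coulomb_samples(s, em0, density = 0.3), s,
                            ann)$score
  base_arom <- aromatic_pocket_count(s, ann)
  rot <- random_rotation(7)
  s2 <- s
  xyz <- coords(s) %*% t(rot) + matrix(c(4, -1, 9), nrow(coords(s)), 3,
                                       byrow = TRUE)
  s2$atom$x <- xyz[, 1]; s2$atom$y <- xyz[, 2]; s2$atom$z <- xyz[, 3]
  moved_patch <- patch_score(coulomb_samples(s2, em0, density = 0.3), s2,
                             ann)$score
  expect_equal(moved_patch, base_patch, tolerance = 1e-6)
  expect_equal(aromatic_pocket_count(s2, ann), base_arom)
})

test_that("the feature table separates planted classes", {
  ids <- c(paste0("good", 1:3), paste0("poor", 1:3))
  scaffolds <- lapply(seq_along(ids), function(i) {
    simulate_scaffold(if (i <= 3) "good" else "poor", seed = 100 + i,
                      id = ids[i])
  })
  names(scaffolds) <- ids
  ft <- feature_table(scaffolds, lapply(scaffolds, scaffold_annotation),
                      density = 0.2)
  expect_equal(ft$structure_id, ids)
  expect_true(max(ft$patch_score[ft$group == "good"]) <
                min(ft$patch_score[ft$group == "poor"]))
})
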