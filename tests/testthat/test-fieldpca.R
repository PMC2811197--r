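# small helper: wrap plain matrices as per-structure, per-probe field lists
fields_from_matrix <- function(m, probes = "N1+", shape = NULL) {
  n_nodes <- ncol(m) / length(probes)
  if (is.null(shape)) shape <- c(n_nodes, 1L, 1L)
  spec <- structure(list(origin = c(0, 0, 0), spacing = 1,
                         shape = as.integer(shape)), class = "grid_spec")
  out <- lapply(seq_len(nrow(m)), function(i) {
    fs <- lapply(seq_along(probes), function(b) {
      v <- m[i, (b - 1) * n_nodes + seq_len(n_nodes)]
      structure(list(spec = spec, probe = probes[b],
                     values = array(v, dim = shape)), class = "grid_field")
    })
    names(fs) <- probes
    fs
  })
  names(out) <- rownames(m)
  out
}

test_that("field matrices concatenate probe blocks and drop flat columns", {
  m <- matrix(rnorm(24), 3, 8, dimnames = list(c("a", "b", "c"), NULL))
  fm <- assemble_field_matrix(fields_from_matrix(m, shape = c(2, 2, 2)))
  expect_equal(dim(fm$x), c(3L, 8L))
  expect_equal(colMeans(fm$x), rep(0, 8), ignore_attr = TRUE)

  m2 <- m
  m2[, 4] <- 7  # constant across structures
  fm2 <- assemble_field_matrix(fields_from_matrix(m2, shape = c(2, 2, 2)))
  expect_equal(dim(fm2$x), c(3L, 7L))
  expect_false(fm2$kept[4])
})

test_that("probe blocks are scaled to equal total variance", {
  set.seed(6)
  m <- cbind(matrix(rnorm(20, sd = 10), 4, 5),
             matrix(rnorm(20, sd = 0.01), 4, 5))
  fm <- assemble_field_matrix(fields_from_matrix(m, probes = c("N1+", "DRY"),
                                                 shape = c(5, 1, 1)))
  v1 <- sum(fm$x[, fm$block == "N1+"]^2) / 3
  v2 <- sum(fm$x[, fm$block == "DRY"]^2) / 3
  expect_equal(v1, 1, tolerance = 1e-10)
  expect_equal(v2, 1, tolerance = 1e-10)
})

test_that("mismatched grids are rejected", {
  m <- matrix(rnorm(16), 2, 8, dimnames = list(c("a", "b"), NULL))
  fl <- fields_from_matrix(m, shape = c(2, 2, 2))
  fl[[2]][[1]]$spec$origin <- c(1, 0, 0)
  expect_error(assemble_field_matrix(fl), "common grid")
})

test_that("PCA conserves variance and orders components", {
  set.seed(9)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("s", 1:6), NULL))
  fm <- assemble_field_matrix(fields_from_matrix(m, shape = c(10, 1, 1)))
  pca <- run_pca(fm)
  expect_equal(sum(pca$var_explained), pca$total_var, tolerance = 1e-8)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(ncol(pca$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(run_pca(fm, k = 11), "rank")
})

test_that("PC1 captures a duplicated-row contrast completely", {
  m <- rbind(a = c(1, 0, 2), b = c(1, 0, 2), c = c(3, 4, 0), d = c(3, 4, 0))
  fm <- assemble_field_matrix(fields_from_matrix(m, shape = c(3, 1, 1)))
  pca <- run_pca(fm)
  expect_equal(pca$var_explained[1] / pca$total_var, 1, tolerance = 1e-10)
})

test_that("scores are stable under row permutation and positive scaling", {
  set.seed(12)
  m <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  fm1 <- assemble_field_matrix(fields_from_matrix(m, shape = c(10, 1, 1)))
  p1 <- run_pca(fm1, reference = "s1")
  perm <- c(3, 1, 5, 2, 4)
  fm2 <- assemble_field_matrix(fields_from_matrix(m[perm, ],
                                                  shape = c(10, 1, 1)))
  p2 <- run_pca(fm2, reference = "s1")
  expect_equal(abs(p2$scores[rownames(p1$scores), 1]),
               abs(p1$scores[, 1]), tolerance = 1e-8)
  expect_equal(classify_pc1(p2)[names(classify_pc1(p1))], classify_pc1(p1))
  # classification is invariant to multiplying all fields by a constant
  fm3 <- assemble_field_matrix(fields_from_matrix(10 * m,
                                                  shape = c(10, 1, 1)))
  p3 <- run_pca(fm3, reference = "s1")
  expect_equal(classify_pc1(p3), classify_pc1(p1))
})

test_that("PC1 classification respects reference anchor and threshold", {
  set.seed(2)
  m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  fm <- assemble_field_matrix(fields_from_matrix(m, shape = c(10, 1, 1)))
  pca <- run_pca(fm, reference = "s2")
  expect_gte(pca$scores["s2", 1], 0)
  expect_equal(as.character(classify_pc1(pca)[["s2"]]), "binder-like")
  expect_true(all(classify_pc1(pca, threshold = Inf) == "non-binder-like"))
})

test_that("neighbor joining reproduces closed-form and additive trees", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  # additive 4-taxon matrix from a known tree is reproduced exactly
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- 3; d4["A", "C"] <- 8; d4["A", "D"] <- 9
  d4["B", "C"] <- 9; d4["B", "D"] <- 10; d4["C", "D"] <- 9
  d4 <- d4 + t(d4)
  tr4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)

  asym <- d4; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
  expect_error(nj_tree(d4[1:2, 1:2]), "at least 3")
})

test_that("NJ on PC1 distances yields non-negative branch lengths", {
  cl <- classify_scaffold_set(n_good = 3, n_poor = 3, seed = 4)
  tr <- cl$tree
  expect_setequal(tr$tip.label, rownames(cl$pca$scores))
  expect_true(all(tr$edge.length >= 0))
})

test_that("loadings maps mark the planted high-loading nodes", {
  set.seed(20)
  base <- matrix(rnorm(80, sd = 0.01), 8, 10,
                 dimnames = list(paste0("s", 1:8), NULL))
  planted <- c(2, 7)
  base[1:4, planted] <- base[1:4, planted] + 5
  fm <- assemble_field_matrix(fields_from_matrix(base, shape = c(10, 1, 1)))
  pca <- run_pca(fm)
  mask <- loadings_map(pca, quantile = 1 - 2 / 10)[["N1+"]]
  expect_equal(which(mask), planted)

  # uniform loadings: deterministic size ceiling((1-q) n), empty at q = 1
  expect_equal(sum(unlist(loadings_map(pca, quantile = 1))), 0L)
  expect_error(loadings_map(pca, quantile = 0), "quantile")
  expect_error(loadings_map(pca, quantile = 1.2), "quantile")
  m05 <- loadings_map(pca, quantile = 0.5)[["N1+"]]
  expect_equal(sum(m05), ceiling(0.5 * 10))
})

test_that("block contributions are normalized shares", {
  set.seed(14)
  m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  fm1 <- assemble_field_matrix(fields_from_matrix(m, shape = c(10, 1, 1)))
  expect_equal(unname(block_contributions(run_pca(fm1))), 1,
               tolerance = 1e-10)
  m2 <- cbind(m, matrix(rnorm(40), 4, 10))
  fm2 <- assemble_field_matrix(fields_from_matrix(
    m2, probes = c("N1+", "DRY"), shape = c(10, 1, 1)))
  shares <- block_contributions(run_pca(fm2))
  expect_equal(sum(shares), 1, tolerance = 1e-10)
  expect_equal(names(shares), c("N1+", "DRY"))
})
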