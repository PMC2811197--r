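# Field PCA: concatenate per-structure, per-probe interaction fields into one
# matrix (one row per structure, one column per grid node and probe), run an
# exact SVD-based PCA after per-probe block scaling, classify structures by
# the sign of their PC1 score, cluster them by neighbor-joining on PC1
# distances, and map PC1 loadings back to grid regions and probe blocks.

#' Assemble per-structure fields into one matrix
#'
#' Rows are structures; columns are (grid node, probe) variables, probe blocks
#' concatenated. Every structure must carry fields on the same grid (the
#' common frame established by superposition). Pretreatment: columns with
#' standard deviation below `min_sd` are dropped, the rest are mean-centred,
#' and each probe block is scaled to unit total variance so no probe dominates
#' the PCA by its raw energy scale alone.
#'
#' @param fields Named list (one element per structure) of named lists of
#'   `grid_field`s (one per probe, same probe set everywhere).
#' @param min_sd Drop threshold on column standard deviation (kcal/mol),
#'   default 1e-6.
#' @return List of class `field_matrix`: `x` (pretreated matrix), `block`
#'   (probe name per retained column), `node` (grid node index per retained
#'   column), `center`, `block_scale`, `kept` (logical over raw columns),
#'   `spec` (the shared `grid_spec`), `probes`.
#' @export
assemble_field_matrix <- function(fields, min_sd = 1e-6) {
  stopifnot(length(fields) >= 1)
  probes <- names(fields[[1]])
  spec <- fields[[1]][[1]]$spec
  same_spec <- function(a, b) {
    identical(a$shape, b$shape) && isTRUE(all.equal(a$origin, b$origin)) &&
      isTRUE(all.equal(a$spacing, b$spacing))
  }
  rows <- lapply(fields, function(fs) {
    if (!identical(names(fs), probes)) {
      stop("all structures must carry the same probe set")
    }
    unlist(lapply(fs, function(f) {
      if (!same_spec(f$spec, spec)) {
        stop("fields are not on a common grid; superpose structures first")
      }
      as.vector(f$values)
    }), use.names = FALSE)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(fields)
  n_nodes <- prod(spec$shape)
  block <- rep(probes, each = n_nodes)
  node <- rep(seq_len(n_nodes), times = length(probes))

  sds <- apply(x, 2, stats::sd)
  kept <- sds >= min_sd
  x <- x[, kept, drop = FALSE]
  block_k <- block[kept]
  node_k <- node[kept]
  center <- colMeans(x)
  x <- sweep(x, 2, center)
  block_scale <- vapply(probes, function(p) {
    tot <- sum(x[, block_k == p, drop = FALSE]^2) / max(1, nrow(x) - 1)
    if (tot > 0) sqrt(tot) else 1
  }, numeric(1))
  for (p in probes) {
    x[, block_k == p] <- x[, block_k == p, drop = FALSE] / block_scale[[p]]
  }
  structure(list(x = x, block = block_k, node = node_k, center = center,
                 block_scale = block_scale, kept = kept, spec = spec,
                 probes = probes),
            class = "field_matrix")
}

#' PCA of a field matrix
#'
#' Exact singular-value decomposition of the pretreated matrix. Components are
#' ordered by decreasing variance; the sign of every component is fixed so the
#' designated reference structure's score is non-negative, which anchors the
#' binder-like direction of PC1 to a known good binder.
#'
#' @param fm A [assemble_field_matrix()] result.
#' @param k Number of components to keep, at most `min(nrow - 1, ncol)`.
#' @param reference Row name (or index) of the reference structure; default
#'   the first row.
#' @return List of class `field_pca`: `scores` (structures x k), `loadings`
#'   (variables x k, orthonormal columns), `var_explained` (length k),
#'   `total_var`, `block`, `node`, `spec`, `reference`.
#' @export
run_pca <- function(fm, k = NULL, reference = NULL) {
  x <- fm$x
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 structures")
  kmax <- min(n - 1L, ncol(x))
  if (is.null(k)) k <- kmax
  if (k > kmax) stop("k = ", k, " exceeds the rank bound ", kmax)
  if (is.null(reference)) reference <- rownames(x)[1]
  ri <- if (is.character(reference)) match(reference, rownames(x)) else reference
  if (is.na(ri)) stop("reference structure '", reference, "' not in matrix")

  s <- svd(x, nu = k, nv = k)
  scores <- s$u %*% diag(s$d[seq_len(k)], k, k)
  loadings <- s$v
  flip <- ifelse(scores[ri, ] < 0, -1, 1)
  scores <- sweep(scores, 2, flip, `*`)
  loadings <- sweep(loadings, 2, flip, `*`)
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = s$d[seq_len(k)]^2 / (n - 1),
                 total_var = sum(x^2) / (n - 1),
                 block = fm$block, node = fm$node, spec = fm$spec,
                 reference = rownames(x)[ri]),
            class = "field_pca")
}

#' Classify structures by their PC1 score
#'
#' Structures with PC1 at or above `threshold` (default 0: positive or zero
#' scores, with the sign convention anchored to a known binder) are called
#' binder-like; negative scores non-binder-like.
#'
#' @param pca A [run_pca()] result.
#' @param threshold PC1 threshold, default 0.
#' @return Named factor with levels `binder-like`, `non-binder-like`.
#' @export
classify_pc1 <- function(pca, threshold = 0) {
  lab <- ifelse(pca$scores[, 1] >= threshold, "binder-like",
                "non-binder-like")
  factor(stats::setNames(lab, rownames(pca$scores)),
         levels = c("binder-like", "non-binder-like"))
}

#' Pairwise PC1 distances
#'
#' @param pca A [run_pca()] result.
#' @return Symmetric matrix of `|PC1_i - PC1_j|`.
#' @export
pc1_distance <- function(pca) {
  p <- pca$scores[, 1]
  abs(outer(p, p, `-`))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining. The three-taxon case is solved by the
#' closed-form three-point formulas; larger matrices go through
#' [ape::nj()]. Negative branch-length estimates are clamped to zero (with a
#' message).
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column names,
#'   n >= 3.
#' @return An [ape::as.phylo()] `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) < 3) {
    stop("need a square distance matrix over at least 3 taxa")
  }
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 3) {
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    tr <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2,
                             byrow = TRUE),
               edge.length = c(a, b, c3),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
  } else {
    tr <- ape::nj(stats::as.dist(d))
  }
  if (any(tr$edge.length < 0)) {
    message("clamped ", sum(tr$edge.length < 0),
            " negative NJ branch length(s) to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Map PC1 loadings back to grid nodes
#'
#' Marks, per probe, the grid nodes whose |PC1 loading| is among the top
#' `ceiling((1 - quantile) * n)` of all retained variables (ties broken by
#' column index). Dropped columns are `FALSE`. The marked nodes are the
#' contour regions of the structure that drive the PC1-based clustering.
#'
#' @param pca A [run_pca()] result.
#' @param quantile Loading quantile in (0, 1], default 0.98.
#' @return Named list (per probe) of logical nx x ny x nz arrays.
#' @export
loadings_map <- function(pca, quantile = 0.98) {
  if (quantile <= 0 || quantile > 1) {
    stop("`quantile` must be in (0, 1]")
  }
  l1 <- abs(pca$loadings[, 1])
  n <- length(l1)
  m <- ceiling((1 - quantile) * n)
  sel <- logical(n)
  if (m > 0) sel[order(-l1, seq_len(n))[seq_len(m)]] <- TRUE
  probes <- unique(pca$block)
  out <- lapply(probes, function(p) {
    mask <- array(FALSE, dim = pca$spec$shape)
    i <- pca$block == p
    mask[pca$node[i][sel[i]]] <- TRUE
    mask
  })
  stats::setNames(out, probes)
}

#' Export a loadings mask as an OpenDX 0/1 field
#'
#' @param mask Logical array from [loadings_map()].
#' @param spec The `grid_spec` of the PCA variables.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mask_dx <- function(mask, spec, file) {
  f <- structure(list(spec = spec, probe = "mask",
                      values = array(as.numeric(mask), dim = spec$shape)),
                 class = "grid_field")
  write_dx(f, file)
}

#' Per-probe contribution to PC1
#'
#' The share of each probe block in PC1, computed as the sum of squared PC1
#' loadings over the block's columns; shares sum to 1. A dominant share for
#' the cationic probe indicates that binding of positively charged groups
#' drives the separation along PC1.
#'
#' @param pca A [run_pca()] result.
#' @return Named numeric vector of shares, one per probe.
#' @export
block_contributions <- function(pca) {
  l1 <- pca$loadings[, 1]
  shares <- tapply(l1^2, pca$block, sum)
  out <- as.numeric(shares) / sum(l1^2)
  stats::setNames(out, names(shares))[unique(pca$block)]
}
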