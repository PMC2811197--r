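# Seeded synthetic generators for every input the pipeline consumes:
# dot-blot membranes with empty-spot noise and GST calibration spots, planted
# BRD x peptide binding matrices, and pseudo-pocket scaffolds whose good and
# poor classes share geometry and differ only in a planted anionic ring
# charge, isolating electrostatics as the discriminating signal.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a dot-blot membrane
#'
#' Noise-free spot densities are `B0 + theta * G0` for peptide spots, `B0` for
#' EMPTY spots and `amount/5 * G0` for GST spots (linear in loaded amount,
#' with the 5 ng spot at `G0`). Every spot is then multiplied by `(1 + e)`,
#' `e ~ Normal(0, rel_sd)` -- the multiplicative noise whose empty-spot
#' relative standard deviation is the 3-10% range observed across membranes.
#'
#' @param layout A [membrane_layout()].
#' @param theta Non-negative true preference values, one per peptide spot in
#'   layout order (named or unnamed).
#' @param B0 Baseline (background) density, default 100.
#' @param G0 GST 5 ng density, default 1000.
#' @param rel_sd Relative noise SD, default 0.05 (the middle of the 3-10%
#'   empty-spot range).
#' @param seed Integer seed; the result is bit-reproducible given
#'   (arguments, seed).
#' @return A spot table (layout plus `density`), with attributes `subtype`,
#'   `theta`, `B0`, `G0`, `rel_sd`.
#' @export
simulate_membrane <- function(layout, theta, B0 = 100, G0 = 1000,
                              rel_sd = 0.05, seed = NULL) {
  if (any(theta < 0)) stop("`theta` must be non-negative")
  if (rel_sd < 0) stop("`rel_sd` must be non-negative")
  n_pep <- sum(layout$type == "peptide")
  if (length(theta) != n_pep) {
    stop("`theta` must have one value per peptide spot (", n_pep, ")")
  }
  dens <- numeric(nrow(layout))
  dens[layout$type == "EMPTY"] <- B0
  dens[layout$type == "peptide"] <- B0 + theta * G0
  g <- layout$type == "GST"
  dens[g] <- layout$gst_ng[g] / 5 * G0
  if (rel_sd > 0) {
    dens <- .with_seed(seed, dens * (1 + stats::rnorm(length(dens), 0, rel_sd)))
  }
  out <- as.data.frame(layout)
  out$density <- dens
  structure(out, subtype = attr(layout, "subtype"), theta = theta,
            B0 = B0, G0 = G0, rel_sd = rel_sd,
            class = c("spot_table", "data.frame"))
}

#' Render a spot table as a grayscale membrane image
#'
#' Draws each spot as a uniform disc centred on its grid cell, with pixel
#' values summing to the spot density, so that [integrate_spots()] recovers
#' the densities.
#'
#' @param spots A spot table.
#' @param px_per_cell Pixels per grid cell side, default 16.
#' @param spot_radius Disc radius in pixels, default `px_per_cell/4`.
#' @return Numeric matrix (rows*px_per_cell x cols*px_per_cell).
#' @export
render_membrane <- function(spots, px_per_cell = 16,
                            spot_radius = px_per_cell / 4) {
  rows <- max(spots$row); cols <- max(spots$col)
  img <- matrix(0, rows * px_per_cell, cols * px_per_cell)
  yy <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  xx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  for (i in seq_len(nrow(spots))) {
    cy <- (spots$row[i] - 0.5) * px_per_cell
    cx <- (spots$col[i] - 0.5) * px_per_cell
    disc <- (yy - cy)^2 + (xx - cx)^2 <= spot_radius^2
    img[disc] <- img[disc] + spots$density[i] / sum(disc)
  }
  img
}

#' Simulate a planted BRD x peptide binding matrix
#'
#' Rows (bromodomains) and columns (peptides) are partitioned into blocks;
#' each cell gets its block mean plus Gaussian noise. The planted memberships
#' are attached as attributes, giving clustering and binder-calling tests a
#' ground truth.
#'
#' @param n_brd,n_pep Matrix dimensions, defaults 14 x 32 (a family of 14
#'   domains against the 32-peptide library).
#' @param block_means Matrix of block means (row blocks x column blocks),
#'   >= 0; default a 2 x 2 contrast of strong (1) vs weak (0.05) binding.
#' @param noise_sd Additive Gaussian noise SD, default 0.
#' @param seed Integer seed.
#' @return Numeric matrix with `row_block` and `col_block` attributes.
#' @export
simulate_binding_matrix <- function(n_brd = 14, n_pep = 32,
                                    block_means = matrix(c(1, 0.05, 0.05, 0.8),
                                                         2, 2),
                                    noise_sd = 0, seed = NULL) {
  block_means <- as.matrix(block_means)
  if (any(block_means < 0)) stop("block means must be non-negative")
  rb <- sort(rep(seq_len(nrow(block_means)), length.out = n_brd))
  cb <- sort(rep(seq_len(ncol(block_means)), length.out = n_pep))
  m <- block_means[rb, cb, drop = FALSE]
  if (noise_sd > 0) {
    m <- .with_seed(seed, m + matrix(stats::rnorm(n_brd * n_pep, 0, noise_sd),
                                     n_brd, n_pep))
  }
  dimnames(m) <- list(sprintf("BRD%02d", seq_len(n_brd)),
                      sprintf("pep%02d", seq_len(n_pep)))
  structure(m, row_block = rb, col_block = cb)
}

#' Simulate a pseudo-pocket scaffold
#'
#' A concave desk-scale stand-in for a bromodomain binding site (synthetic; no
#' relation to any real protein geometry): a ring of Cbeta-like pseudo-atoms
#' around a cavity, a rim ring above it and a floor below. The `"good"` class
#' carries `charge_total` (negative) distributed evenly over the ring atoms --
#' the planted anionic patch -- while the `"poor"` class is everywhere
#' neutral. For a given `seed` both classes have *identical* jittered
#' coordinates, so the classes are indistinguishable by geometry and differ
#' only through the Coulomb field.
#'
#' @param class `"good"` (anionic ring) or `"poor"` (neutral).
#' @param n_ring Ring atom count, default 12.
#' @param ring_radius Ring radius in Angstrom, default 6.
#' @param charge_total Total ring charge in e for the good class, default -3.
#' @param jitter_sd Coordinate jitter SD in Angstrom, default 0.15.
#' @param seed Integer seed (drives the jitter only).
#' @param id Model id; default derived from class and seed.
#' @return A `brd_structure` with charges and generic-carbon radii assigned,
#'   and attribute `class` recording the planted label. Residues are numbered
#'   ring first, then rim, then floor (see [scaffold_annotation()]).
#' @export
simulate_scaffold <- function(class = c("good", "poor"), n_ring = 12,
                              ring_radius = 6, charge_total = -3,
                              jitter_sd = 0.15, seed = NULL, id = NULL) {
  class <- match.arg(class)
  if (is.null(id)) id <- paste0(class, "_", if (is.null(seed)) 0 else seed)
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ring <- cbind(ring_radius * cos(th), ring_radius * sin(th), 0)
  rim <- cbind(ring_radius * cos(th + pi / n_ring),
               ring_radius * sin(th + pi / n_ring), 2.2)
  th6 <- 2 * pi * (0:5) / 6
  floor_ <- rbind(c(0, 0, -2.5),
                  cbind(3 * cos(th6), 3 * sin(th6), -2.5))
  xyz <- rbind(ring, rim, floor_)
  if (jitter_sd > 0) {
    xyz <- xyz + .with_seed(seed, matrix(stats::rnorm(length(xyz), 0,
                                                      jitter_sd),
                                         nrow(xyz), 3))
  }
  n <- nrow(xyz)
  part <- rep(c("ring", "rim", "floor"),
              c(n_ring, n_ring, nrow(floor_)))
  q <- numeric(n)
  if (class == "good") q[part == "ring"] <- charge_total / n_ring
  atom <- data.frame(
    element = "C", name = "CB",
    resname = c(ring = "RNG", rim = "RIM", floor = "FLR")[part],
    resno = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = q, radius = 1.70, eps = 0.11,
    stringsAsFactors = FALSE
  )
  out <- new_structure(atom, id)
  attr(out, "class_label") <- class
  attr(out, "n_ring") <- n_ring
  out
}

#' Annotation of a simulated scaffold
#'
#' Maps the scaffold's parts onto the binding-site annotation vocabulary: the
#' charged ring plays the ZA loop, the rim the BC loop, and the floor the
#' pocket residues.
#'
#' @param scaffold A [simulate_scaffold()] result.
#' @return A [brd_annotation()].
#' @export
scaffold_annotation <- function(scaffold) {
  n_ring <- attr(scaffold, "n_ring")
  n <- nrow(scaffold$atom)
  brd_annotation(loopZA = c(1L, n_ring),
                 loopBC = c(n_ring + 1L, 2L * n_ring),
                 pocket = (2L * n_ring + 1L):n,
                 group = attr(scaffold, "class_label"))
}
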