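# Quantitative binder signatures on annotated bromodomain structures: the
# negative electrostatic patch around the ZA loop, the asparagine at the
# C-terminus of the third helix of the four-helix bundle, and the aromatic
# residues lining the acetyl-lysine pocket.

#' Annotate a bromodomain structure
#'
#' Residue-range annotation of the four helices (alphaZ, alphaA, alphaB,
#' alphaC), the two inter-helical loops (ZA, BC) that form the acetyl-lysine
#' pocket, and the pocket residues used to define the pocket centroid.
#'
#' @param alphaZ,alphaA,alphaB,alphaC,loopZA,loopBC Length-2 integer vectors
#'   `c(start, end)` in structure residue numbering (any may be `NULL`).
#' @param pocket Integer vector of pocket residue numbers.
#' @param group Optional binder group label (`"good"`, `"intermediate"`,
#'   `"poor"`).
#' @return List of class `brd_annotation`.
#' @export
brd_annotation <- function(alphaZ = NULL, alphaA = NULL, alphaB = NULL,
                           alphaC = NULL, loopZA = NULL, loopBC = NULL,
                           pocket = NULL, group = NULL) {
  rng <- list(alphaZ = alphaZ, alphaA = alphaA, alphaB = alphaB,
              alphaC = alphaC, loopZA = loopZA, loopBC = loopBC)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (!is.null(r) && (length(r) != 2 || r[1] > r[2])) {
      stop(nm, " must be c(start, end) with start <= end")
    }
  }
  structure(c(rng, list(pocket = pocket, group = group)),
            class = "brd_annotation")
}

.res_in_range <- function(model, range) {
  model$atom$resno >= range[1] & model$atom$resno <= range[2]
}

# intrinsic orthonormal frame from atom positions (equivariant under rigid
# motion): first axis towards the first atom off the centroid, second from
# the first non-parallel atom direction, third their cross product
.body_frame <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  dirs <- sweep(xyz, 2, ctr)
  norms <- sqrt(rowSums(dirs^2))
  ok <- which(norms > 1e-6)
  if (!length(ok)) return(diag(3))
  v1 <- dirs[ok[1], ] / norms[ok[1]]
  v2 <- NULL
  for (i in ok[-1]) {
    w <- dirs[i, ] - sum(dirs[i, ] * v1) * v1
    if (sqrt(sum(w^2)) > 1e-6) { v2 <- w / sqrt(sum(w^2)); break }
  }
  if (is.null(v2)) return(diag(3))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

#' Surface electrostatic potential samples
#'
#' Deterministic low-resolution surface sampling: points are placed on a
#' Fibonacci lattice on each atom's solvent-extended sphere (atom radius +
#' 1.4 A probe radius) at roughly `density` samples per square Angstrom;
#' points buried inside any other atom's extended sphere are discarded. The
#' potential at each point is the Coulomb sum under the same
#' distance-dependent dielectric as the interaction fields,
#' phi(p) = sum_i k q_i / (diel_coef * r_i^2).
#'
#' @param model A `brd_structure` with assigned parameters.
#' @param em An [energy_model()].
#' @param density Samples per square Angstrom, > 0 (default 0.5).
#' @return Data frame with columns `x`, `y`, `z`, `atom` (index of the parent
#'   atom) and `phi` (kcal/(mol e)).
#' @export
coulomb_samples <- function(model, em = energy_model(), density = 0.5) {
  if (density <= 0) stop("`density` must be positive")
  at <- model$atom
  if (any(is.na(at$charge)) || any(is.na(at$radius))) {
    stop("model has unassigned parameters; run assign_params() first")
  }
  rs <- at$radius + 1.4
  xyz <- coords(model)
  rot <- .body_frame(xyz)  # lattice co-rotates with the structure, so
                           # descriptors are rigid-motion invariant
  golden <- pi * (3 - sqrt(5))
  pts <- lapply(seq_len(nrow(at)), function(i) {
    n <- max(4L, ceiling(density * 4 * pi * rs[i]^2))
    k <- seq_len(n) - 0.5
    z <- 1 - 2 * k / n
    rad <- sqrt(pmax(0, 1 - z^2))
    th <- golden * (seq_len(n) - 1)
    unit <- cbind(rad * cos(th), rad * sin(th), z) %*% t(rot)
    cbind(x = xyz[i, 1] + rs[i] * unit[, 1],
          y = xyz[i, 2] + rs[i] * unit[, 2],
          z = xyz[i, 3] + rs[i] * unit[, 3], atom = i)
  })
  pts <- do.call(rbind, pts)
  # drop points buried inside any *other* extended sphere
  exposed <- rep(TRUE, nrow(pts))
  for (j in seq_len(nrow(at))) {
    d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
      (pts[, 3] - xyz[j, 3])^2
    exposed <- exposed & (pts[, 4] == j | d2 > (rs[j] - 1e-6)^2)
  }
  pts <- pts[exposed, , drop = FALSE]
  phi <- numeric(nrow(pts))
  for (j in which(at$charge != 0)) {
    r2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
      (pts[, 3] - xyz[j, 3])^2
    phi <- phi + em$coulomb_k * at$charge[j] / (em$diel_coef * r2)
  }
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             atom = as.integer(pts[, 4]), phi = phi)
}

#' Negative-potential patch score of a region
#'
#' Sums the negative-only surface potentials over samples lying within
#' `shell` Angstrom of any atom of the annotated region. A strongly negative
#' score marks the dense acidic patch that characterises good binders around
#' the ZA loop.
#'
#' @param samples Output of [coulomb_samples()].
#' @param model The sampled `brd_structure`.
#' @param annotation A [brd_annotation()].
#' @param region Region name in the annotation (e.g. `"loopZA"`).
#' @param shell Distance shell in Angstrom, default 6.
#' @return List of class `patch_descriptor`: `structure_id`, `region`,
#'   `score` (sum of negative potentials, <= 0), `n_samples`.
#' @export
patch_score <- function(samples, model, annotation, region = "loopZA",
                        shell = 6) {
  rng <- annotation[[region]]
  if (is.null(rng)) stop("annotation has no region '", region, "'")
  sel <- .res_in_range(model, rng)
  if (!any(sel)) stop("region '", region, "' matches no atoms")
  rxyz <- coords(model)[sel, , drop = FALSE]
  near <- rep(FALSE, nrow(samples))
  for (j in seq_len(nrow(rxyz))) {
    d2 <- (samples$x - rxyz[j, 1])^2 + (samples$y - rxyz[j, 2])^2 +
      (samples$z - rxyz[j, 3])^2
    near <- near | d2 <= shell^2
  }
  if (!any(near)) {
    return(structure(list(structure_id = model$id, region = region,
                          score = 0, n_samples = 0L),
                     class = "patch_descriptor"))
  }
  phi <- samples$phi[near]
  structure(list(structure_id = model$id, region = region,
                 score = sum(phi[phi < 0]), n_samples = sum(near)),
            class = "patch_descriptor")
}

#' Asparagine at the C-terminus of the third helix
#'
#' Tests whether any of the last `window` residues of helix alphaB (the third
#' helix of the alphaZ-alphaA-alphaB-alphaC bundle) is an asparagine -- the
#' conserved anchor whose side-chain amide hydrogen-bonds the acetyl-lysine
#' carbonyl in histone-binding bromodomains.
#'
#' @param model A `brd_structure`.
#' @param annotation A [brd_annotation()] with `alphaB` set.
#' @param window Number of C-terminal helix residues examined, default 2;
#'   `window = 0` always returns `FALSE`.
#' @return Logical.
#' @export
asn_at_helixB_cterm <- function(model, annotation, window = 2) {
  if (is.null(annotation$alphaB)) stop("annotation has no alphaB range")
  if (window <= 0) return(FALSE)
  sel <- .res_in_range(model, annotation$alphaB)
  if (!any(sel)) stop("alphaB range matches no atoms")
  res <- unique(model$atom[sel, c("resno", "resname")])
  res <- res[order(res$resno), ]
  tail_res <- utils::tail(res, window)
  any(tail_res$resname == "ASN")
}

#' Aromatic residues lining the acetyl-lysine pocket
#'
#' Counts Phe/Tyr/Trp residues within the ZA and BC loop ranges whose
#' side-chain atoms come within `radius` Angstrom of the pocket centroid
#' (centroid of the annotated pocket residues' atoms, or of the whole
#' structure when no pocket residues are annotated).
#'
#' @param model A `brd_structure`.
#' @param annotation A [brd_annotation()] with `loopZA` and `loopBC` set.
#' @param radius Distance from the pocket centroid, default 8 A.
#' @return Integer count.
#' @export
aromatic_pocket_count <- function(model, annotation, radius = 8) {
  if (is.null(annotation$loopZA) || is.null(annotation$loopBC)) {
    stop("annotation needs both loopZA and loopBC ranges")
  }
  at <- model$atom
  if (!is.null(annotation$pocket)) {
    pk <- at$resno %in% annotation$pocket
    if (!any(pk)) stop("pocket residues match no atoms")
    center <- colMeans(coords(model)[pk, , drop = FALSE])
  } else {
    center <- colMeans(coords(model))
  }
  in_loops <- .res_in_range(model, annotation$loopZA) |
    .res_in_range(model, annotation$loopBC)
  arom <- in_loops & at$resname %in% c("PHE", "TYR", "TRP")
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- arom & !(at$name %in% backbone)
  if (!any(side)) return(0L)
  xyz <- coords(model)[side, , drop = FALSE]
  d2 <- colSums((t(xyz) - center)^2)
  near_res <- unique(paste(at$chain[side][d2 <= radius^2],
                           at$resno[side][d2 <= radius^2]))
  length(near_res)
}

#' Tidy feature table for a set of annotated structures
#'
#' Computes the three binder signatures for each structure: the ZA-loop
#' negative patch score, the aromatic pocket count and the asparagine check,
#' one row per structure.
#'
#' @param models Named list of `brd_structure`s with assigned parameters.
#' @param annotations Named list of [brd_annotation()]s (matching names).
#' @param em An [energy_model()].
#' @param density Surface sample density for the patch score.
#' @return Data frame with columns `structure_id`, `group`, `patch_score`,
#'   `aromatic_count`, `asn_helixB`.
#' @export
feature_table <- function(models, annotations, em = energy_model(),
                          density = 0.5) {
  stopifnot(identical(names(models), names(annotations)))
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]; a <- annotations[[nm]]
    smp <- coulomb_samples(m, em, density)
    ps <- patch_score(smp, m, a)
    data.frame(
      structure_id = nm,
      group = if (is.null(a$group)) NA_character_ else a$group,
      patch_score = ps$score,
      aromatic_count = aromatic_pocket_count(m, a),
      asn_helixB = if (is.null(a$alphaB)) NA else asn_at_helixB_cterm(m, a),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
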