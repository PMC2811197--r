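# Molecular interaction fields: probe interaction energies on a regular
# lattice over a binding site. The energy model is a 12-6 Lennard-Jones term
# with Lorentz-Berthelot-style combination plus a Coulomb term under a
# distance-dependent dielectric eps(r) = 4r, clamped from above so that
# steric-clash nodes do not dominate downstream statistics.

#' Chemical probe parameters
#'
#' The packaged probe set: `"N1+"`, an sp3 amine NH cation (charge +1 e) whose
#' favourable field marks regions that attract positively charged groups;
#' `"DRY"`, a neutral hydrophobic probe (Lennard-Jones only); and `"OH2"`, a
#' small neutral water-like probe.
#'
#' @param name Probe name, or `NULL` for the table of all packaged probes.
#' @param charge,eps,radius Override the packaged charge (e), well depth
#'   (kcal/mol) and Lennard-Jones radius (Angstrom) to define a custom probe.
#' @return A list of class `probe_params` with `name`, `charge`, `eps`,
#'   `radius` (or a data frame of all probes when `name` is `NULL`).
#' @export
probe_params <- function(name = NULL, charge = NULL, eps = NULL,
                         radius = NULL) {
  tab <- data.frame(
    name = c("N1+", "DRY", "OH2"),
    charge = c(1, 0, 0),
    eps = c(0.16, 0.21, 0.15),
    radius = c(1.85, 1.70, 1.40),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(tab)
  i <- match(name, tab$name)
  p <- if (is.na(i)) {
    list(name = name, charge = 0, eps = 0, radius = 1.7)
  } else {
    as.list(tab[i, ])
  }
  if (!is.null(charge)) p$charge <- charge
  if (!is.null(eps)) p$eps <- eps
  if (!is.null(radius)) p$radius <- radius
  if (p$eps < 0 || p$radius <= 0) stop("invalid probe parameters")
  structure(p, class = "probe_params")
}

#' Interaction energy model
#'
#' @param coulomb_k Coulomb constant, 332.0 kcal A / (mol e^2).
#' @param diel_coef Coefficient of the distance-dependent dielectric
#'   eps(r) = `diel_coef` * r (default 4).
#' @param clamp_max Upper clamp on node energies, kcal/mol (default +5).
#' @param cutoff Optional atom-node distance cutoff in Angstrom (`Inf` keeps
#'   every pair).
#' @return List of class `energy_model`.
#' @export
energy_model <- function(coulomb_k = 332.0, diel_coef = 4, clamp_max = 5,
                         cutoff = Inf) {
  if (clamp_max <= 0) stop("`clamp_max` must be positive")
  structure(list(coulomb_k = coulomb_k, diel_coef = diel_coef,
                 clamp_max = clamp_max, cutoff = cutoff),
            class = "energy_model")
}

#' Build a grid specification over a binding site
#'
#' Axis-aligned box equal to the bounding box of the site atoms expanded by
#' `margin` on every side, discretised at `spacing`.
#'
#' @param model A `brd_structure`.
#' @param site A [select_site()] selection (default: all atoms).
#' @param spacing Node spacing in Angstrom, > 0 (default 1).
#' @param margin Box expansion in Angstrom (default 4).
#' @return List of class `grid_spec`: `origin` (xyz of the first node),
#'   `spacing`, `shape` (nx, ny, nz).
#' @export
make_grid <- function(model, site = NULL, spacing = 1, margin = 4) {
  if (spacing <= 0) stop("`spacing` must be positive")
  xyz <- coords(model)
  if (!is.null(site)) xyz <- xyz[site$indices, , drop = FALSE]
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  shape <- as.integer(floor((hi - lo) / spacing + 1e-9)) + 1L
  structure(list(origin = as.numeric(lo), spacing = spacing, shape = shape),
            class = "grid_spec")
}

#' Cartesian coordinates of all grid nodes
#'
#' Nodes are returned x-fastest, matching the storage order of the field
#' array (`as.vector` of the nx x ny x nz array).
#'
#' @param spec A `grid_spec`.
#' @return (nx*ny*nz) x 3 matrix.
#' @export
grid_nodes <- function(spec) {
  ax <- lapply(1:3, function(k) {
    spec$origin[k] + spec$spacing * (seq_len(spec$shape[k]) - 1)
  })
  cbind(
    rep(ax[[1]], times = spec$shape[2] * spec$shape[3]),
    rep(rep(ax[[2]], each = spec$shape[1]), times = spec$shape[3]),
    rep(ax[[3]], each = spec$shape[1] * spec$shape[2])
  )
}

#' Probe interaction energy at arbitrary points
#'
#' Sum over atoms of the 12-6 Lennard-Jones term (R_ij = r_probe + r_atom,
#' eps_ij = sqrt(eps_probe * eps_atom)) plus the Coulomb term
#' k * q_probe * q_atom / (diel_coef * r^2). Energies are clamped to
#' `em$clamp_max`; points closer than 0.05 A to any atom are set to the clamp.
#'
#' @param model A `brd_structure` with assigned parameters.
#' @param probe A [probe_params()] probe.
#' @param em An [energy_model()].
#' @param points n x 3 matrix of evaluation points.
#' @param clamp Set `FALSE` to return raw (unclamped) energies.
#' @return Numeric vector of energies, kcal/mol.
#' @export
field_at_points <- function(model, probe, em, points, clamp = TRUE) {
  at <- model$atom
  if (any(is.na(at$charge)) || any(is.na(at$radius))) {
    stop("model has unassigned parameters; run assign_params() first")
  }
  points <- as.matrix(points)
  e <- numeric(nrow(points))
  clash <- logical(nrow(points))
  for (j in seq_len(nrow(at))) {
    dx <- points[, 1] - at$x[j]
    dy <- points[, 2] - at$y[j]
    dz <- points[, 3] - at$z[j]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    interacts <- sqrt(probe$eps * at$eps[j]) > 0 ||
      probe$charge * at$charge[j] != 0
    if (interacts) clash <- clash | r < 0.05
    r <- pmax(r, 0.05)
    keep <- r <= em$cutoff
    rij <- probe$radius + at$radius[j]
    eij <- sqrt(probe$eps * at$eps[j])
    if (eij > 0) {
      sr6 <- (rij / r)^6
      e[keep] <- e[keep] + (eij * (sr6 * sr6 - 2 * sr6))[keep]
    }
    if (probe$charge != 0 && at$charge[j] != 0) {
      e[keep] <- e[keep] +
        (em$coulomb_k * probe$charge * at$charge[j] /
           (em$diel_coef * r * r))[keep]
    }
  }
  if (clamp) {
    e <- pmin(e, em$clamp_max)
    e[clash] <- em$clamp_max
  }
  e
}

#' Compute a molecular interaction field on a grid
#'
#' @inheritParams field_at_points
#' @param grid A [make_grid()] specification.
#' @return List of class `grid_field`: `spec`, `probe` (name), `values`
#'   (nx x ny x nz array, kcal/mol, clamped).
#' @export
compute_field <- function(model, probe, em, grid) {
  v <- field_at_points(model, probe, em, grid_nodes(grid))
  structure(list(spec = grid, probe = probe$name,
                 values = array(v, dim = grid$shape)),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat("<grid_field>", x$probe, paste(x$spec$shape, collapse = "x"),
      "nodes, spacing", x$spec$spacing, "A, range",
      paste(signif(range(x$values), 4), collapse = " .. "), "kcal/mol\n")
  invisible(x)
}

#' Write a field as an OpenDX regular-grid scalar file
#'
#' Standard OpenDX ordering: the z index varies fastest.
#'
#' @param field A `grid_field`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_dx <- function(field, file) {
  s <- field$spec
  n <- prod(s$shape)
  # reorder x-fastest storage to z-fastest output
  v <- as.vector(aperm(field$values, c(3, 2, 1)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            s$shape[1], s$shape[2], s$shape[3]),
    sprintf("origin %.6f %.6f %.6f", s$origin[1], s$origin[2], s$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", s$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", s$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", s$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            s$shape[1], s$shape[2], s$shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n)
  ), con)
  full <- seq_len(n %/% 3L * 3L)
  body <- character(0)
  if (length(full)) {
    body <- apply(matrix(sprintf("%.10g", v[full]), ncol = 3, byrow = TRUE),
                  1, paste, collapse = " ")
  }
  if (n %% 3L) {
    body <- c(body, paste(sprintf("%.10g", v[-full]), collapse = " "))
  }
  writeLines(body, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(file)
}

#' Read an OpenDX regular-grid scalar file
#'
#' @param file Path to a file written by [write_dx()] (or any OpenDX regular
#'   grid with uniform spacing).
#' @param probe Probe name to record on the field.
#' @return A `grid_field`.
#' @export
read_dx <- function(file, probe = "unknown") {
  lines <- readLines(file)
  g <- lines[grep("gridpositions counts", lines)[1]]
  shape <- as.integer(strsplit(trimws(sub(".*counts", "", g)), "\\s+")[[1]])
  o <- lines[grep("^origin", lines)[1]]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", o)), "\\s+")[[1]])
  deltas <- lines[grep("^delta", lines)]
  dmat <- t(vapply(deltas, function(l) {
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]])
  }, numeric(3)))
  spacing <- dmat[1, 1]
  start <- grep("data follows", lines)[1]
  stop_at <- grep("^attribute|^object \"", lines)
  stop_at <- c(stop_at[stop_at > start], length(lines) + 1L)[1]
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(start + 1L):(stop_at - 1L)]), "\\s+")))
  n <- prod(shape)
  if (length(vals) != n) {
    stop("expected ", n, " data values, found ", length(vals))
  }
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  structure(list(
    spec = structure(list(origin = origin, spacing = spacing, shape = shape),
                     class = "grid_spec"),
    probe = probe, values = arr), class = "grid_field")
}

#' Export a field as flat TSV (x, y, z, value)
#'
#' @param field A `grid_field`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_field_tsv <- function(field, file) {
  nodes <- grid_nodes(field$spec)
  utils::write.table(
    data.frame(x = nodes[, 1], y = nodes[, 2], z = nodes[, 3],
               value = as.vector(field$values)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
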