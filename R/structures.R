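# Structure handling: reading PDB models, assigning a minimal formal-charge /
# per-element Lennard-Jones parameter set, selecting binding-site atoms and
# rigid-body superposition into a common frame.

#' Read a structure from a PDB file
#'
#' Parses model 1 only (lines up to the first ENDMDL when MODEL records are
#' present), keeps atoms with blank or 'A' alternate-location codes, and drops
#' hydrogens. Parsing is done with [bio3d::read.pdb()].
#'
#' @param file Path to a PDB file.
#' @param id Model id; defaults to the file name without extension.
#' @return An object of class `brd_structure`: a list with `id` and `atom`, a
#'   data frame with columns `element`, `name`, `resname`, `resno`, `chain`,
#'   `x`, `y`, `z`, `charge`, `radius`, `eps` (parameters `NA` until
#'   [assign_params()] is called).
#' @export
read_structure <- function(file, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  if (any(grepl("^MODEL", lines))) {
    end <- grep("^ENDMDL", lines)[1]
    if (!is.na(end)) lines <- lines[seq_len(end)]
  }
  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    stop("no ATOM/HETATM records in ", file)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  elem[blank] <- toupper(substr(trimws(at$elety[blank]), 1, 1))
  keep <- elem != "H"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  atom <- data.frame(
    element = elem,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_, radius = NA_real_, eps = NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atom[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", file)
  }
  new_structure(atom, id)
}

#' Construct a structure object from an atom table
#'
#' @param atom Data frame with at least `element`, `name`, `resname`, `resno`,
#'   `chain`, `x`, `y`, `z`; `charge`/`radius`/`eps` added as `NA` if absent.
#' @param id Model id.
#' @return A `brd_structure`.
#' @export
new_structure <- function(atom, id = "model") {
  for (col in c("charge", "radius", "eps")) {
    if (is.null(atom[[col]])) atom[[col]] <- NA_real_
  }
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom), class = "brd_structure")
}

#' @export
print.brd_structure <- function(x, ...) {
  cat("<brd_structure>", x$id, ":", nrow(x$atom), "atoms,",
      length(unique(paste(x$atom$chain, x$atom$resno))), "residues\n")
  invisible(x)
}

#' Coordinates of a structure as a matrix
#'
#' @param model A `brd_structure`.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model) {
  as.matrix(model$atom[, c("x", "y", "z")])
}

#' Write a structure to a PDB file
#'
#' @param model A `brd_structure`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_structure <- function(model, file) {
  at <- model$atom
  bio3d::write.pdb(file = file, xyz = as.numeric(t(coords(model))),
                   type = rep("ATOM", nrow(at)), resno = at$resno,
                   resid = at$resname, eleno = seq_len(nrow(at)),
                   elety = at$name, chain = at$chain, elesy = at$element)
  invisible(file)
}

# per-element Lennard-Jones radii (Angstrom) and well depths (kcal/mol)
.default_radius_table <- data.frame(
  element = c("C", "N", "O", "S", "P"),
  radius = c(1.70, 1.55, 1.52, 1.80, 1.80),
  eps = c(0.11, 0.17, 0.21, 0.25, 0.20),
  stringsAsFactors = FALSE
)

#' Assign formal charges and per-element parameters
#'
#' A minimal formal-charge scheme: Asp/Glu carry -0.5 e on each carboxylate
#' oxygen (OD1/OD2, OE1/OE2), Lys +1 e on NZ, Arg +1 e split as +0.5 on each
#' of NH1/NH2; termini neutral; every other atom 0. Lennard-Jones radius and
#' well depth come from a per-element table. Unknown residues get zero charge
#' with a warning; unknown elements fall back to carbon parameters.
#'
#' @param model A `brd_structure`.
#' @param radius_table Data frame with columns `element`, `radius`, `eps`.
#' @return The model with `charge`, `radius` and `eps` filled in.
#' @export
assign_params <- function(model, radius_table = .default_radius_table) {
  at <- model$atom
  standard <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL")
  unknown <- setdiff(unique(at$resname), standard)
  if (length(unknown)) {
    warning("unknown residue(s) assigned zero charge: ",
            paste(unknown, collapse = ", "))
  }
  q <- numeric(nrow(at))
  q[at$resname %in% c("ASP") & at$name %in% c("OD1", "OD2")] <- -0.5
  q[at$resname %in% c("GLU") & at$name %in% c("OE1", "OE2")] <- -0.5
  q[at$resname == "LYS" & at$name == "NZ"] <- 1
  q[at$resname == "ARG" & at$name %in% c("NH1", "NH2")] <- 0.5
  at$charge <- q
  i <- match(at$element, radius_table$element)
  fallback <- match("C", radius_table$element)
  i[is.na(i)] <- fallback
  at$radius <- radius_table$radius[i]
  at$eps <- radius_table$eps[i]
  model$atom <- at
  model
}

#' Select binding-site atoms around a centre
#'
#' @param model A `brd_structure`.
#' @param center Numeric xyz of the pocket centre (default: centroid of all
#'   atoms).
#' @param radius Site radius in Angstrom, default 8.
#' @return List of class `site_selection`: `model_id`, `indices` (atom row
#'   indices), `centroid` (of the selected atoms).
#' @export
select_site <- function(model, center = NULL, radius = 8) {
  if (radius <= 0) stop("`radius` must be positive")
  xyz <- coords(model)
  if (is.null(center)) center <- colMeans(xyz)
  d2 <- colSums((t(xyz) - center)^2)
  idx <- which(d2 <= radius^2)
  if (!length(idx)) stop("no atoms within ", radius, " A of the site centre")
  structure(list(model_id = model$id, indices = idx,
                 centroid = colMeans(xyz[idx, , drop = FALSE])),
            class = "site_selection")
}

#' Least-squares rigid-body superposition
#'
#' Optimal rotation by the standard SVD (Kabsch) construction with a
#' determinant correction so the result is a proper rotation. Returns the
#' transform mapping `mobile` onto `reference` and the residual RMSD.
#'
#' @param mobile,reference n x 3 matrices of paired coordinates, n >= 3,
#'   non-degenerate (not all collinear).
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd`. Transformed coordinates are
#'   `mobile %*% t(rotation) + translation` (see [apply_superposition()]).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("`mobile` and `reference` must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  h <- t(a) %*% b
  s <- svd(h)
  if (s$d[2] < 1e-10 * max(s$d[1], 1)) {
    stop("degenerate (collinear) geometry: superposition is ill-posed")
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cr - rot %*% cm)
  fitted <- mobile %*% t(rot) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates or a structure
#'
#' @param x n x 3 coordinate matrix or a `brd_structure`.
#' @param sp A [superpose()] result.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_superposition <- function(x, sp) {
  if (inherits(x, "brd_structure")) {
    xyz <- apply_superposition(coords(x), sp)
    x$atom$x <- xyz[, 1]; x$atom$y <- xyz[, 2]; x$atom$z <- xyz[, 3]
    return(x)
  }
  x <- as.matrix(x)
  x %*% t(sp$rotation) + matrix(sp$translation, nrow(x), 3, byrow = TRUE)
}
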