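# Shared fixtures: toy structures built in code and an independent
# brute-force field oracle.

toy_structure <- function(resnames, xyz = NULL, names = NULL, id = "toy") {
  n <- length(resnames)
  if (is.null(xyz)) xyz <- cbind(3 * seq_len(n), 0, 0)
  if (is.null(names)) names <- rep("CA", n)
  new_structure(data.frame(
    element = substr(names, 1, 1),
    name = names, resname = resnames, resno = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  ), id)
}

# point-charge structure: atoms fully parameterised by hand
charge_structure <- function(xyz, charge, radius = 1.7, eps = 0.11,
                             id = "charges") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  new_structure(data.frame(
    element = "C", name = "CB", resname = "UNK", resno = seq_len(n),
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), radius = rep_len(radius, n),
    eps = rep_len(eps, n), stringsAsFactors = FALSE
  ), id)
}

# independent brute-force oracle: naive double loop, scalar arithmetic only
brute_force_field <- function(model, probe, em, grid) {
  nodes <- grid_nodes(grid)
  at <- model$atom
  out <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    e <- 0
    clash <- FALSE
    for (j in seq_len(nrow(at))) {
      r <- sqrt((nodes[i, 1] - at$x[j])^2 + (nodes[i, 2] - at$y[j])^2 +
                  (nodes[i, 3] - at$z[j])^2)
      if (r < 0.05) { clash <- TRUE; r <- 0.05 }
      if (r > em$cutoff) next
      rij <- probe$radius + at$radius[j]
      eij <- sqrt(probe$eps * at$eps[j])
      e <- e + eij * ((rij / r)^12 - 2 * (rij / r)^6) +
        em$coulomb_k * probe$charge * at$charge[j] / (em$diel_coef * r^2)
    }
    out[i] <- if (clash) em$clamp_max else min(e, em$clamp_max)
  }
  array(out, dim = grid$shape)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

default_layout <- function(ids = sprintf("pep%02d", 1:32), subtype = 1) {
  membrane_layout(ids, rows = 5, cols = 8, subtype = subtype)
}
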