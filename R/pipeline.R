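# End-to-end orchestration: the scaffold classification experiment (fields ->
# PCA -> PC1 labels -> NJ tree) and a pipeline driver that writes every
# artifact of a full synthetic run to disk with a manifest.

#' Field-PCA classification of a synthetic scaffold set
#'
#' Generates `n_good` anionic-pocket and `n_poor` neutral-pocket scaffolds
#' (jitter-matched), superposes each onto the first scaffold over paired
#' pseudo-atoms, computes interaction fields for the probe set on a common
#' grid, assembles the block-scaled field matrix, and classifies scaffolds by
#' the sign of PC1 (sign convention anchored to the first good scaffold).
#'
#' @param n_good,n_poor Scaffolds per class, defaults 7 + 7 (a 14-member
#'   family).
#' @param seed Integer seed controlling every random draw.
#' @param probes Probe names, default `c("N1+", "DRY", "OH2")`.
#' @param jitter_sd,charge_total,n_ring,ring_radius Passed to
#'   [simulate_scaffold()].
#' @param spacing,margin Grid parameters, defaults 1 A / 4 A.
#' @param em An [energy_model()].
#' @return List: `labels` (factor from [classify_pc1()]), `truth` (planted
#'   classes), `accuracy`, `pca`, `contributions` (per-probe PC1 shares),
#'   `tree` (NJ tree on PC1 distances), `fm` (the field matrix).
#' @export
classify_scaffold_set <- function(n_good = 7, n_poor = 7, seed = 1,
                                  probes = c("N1+", "DRY", "OH2"),
                                  jitter_sd = 0.15, charge_total = -3,
                                  n_ring = 12, ring_radius = 6,
                                  spacing = 1, margin = 4,
                                  em = energy_model()) {
  n <- n_good + n_poor
  sub_seeds <- .with_seed(seed, sample.int(1e6, n))
  cls <- rep(c("good", "poor"), c(n_good, n_poor))
  ids <- paste0(cls, rep(c(seq_len(n_good), seq_len(n_poor))))
  scaffolds <- lapply(seq_len(n), function(i) {
    simulate_scaffold(cls[i], n_ring = n_ring, ring_radius = ring_radius,
                      charge_total = charge_total, jitter_sd = jitter_sd,
                      seed = sub_seeds[i], id = ids[i])
  })
  names(scaffolds) <- ids

  ref_xyz <- coords(scaffolds[[1]])
  scaffolds <- lapply(scaffolds, function(s) {
    sp <- superpose(coords(s), ref_xyz)
    apply_superposition(s, sp)
  })
  grid <- make_grid(scaffolds[[1]], spacing = spacing, margin = margin)
  probe_list <- lapply(probes, probe_params)
  names(probe_list) <- probes
  fields <- lapply(scaffolds, function(s) {
    lapply(probe_list, function(p) compute_field(s, p, em, grid))
  })
  fm <- assemble_field_matrix(fields)
  pca <- run_pca(fm, reference = ids[1])
  labels <- classify_pc1(pca)
  truth <- factor(ifelse(cls == "good", "binder-like", "non-binder-like"),
                  levels = levels(labels))
  names(truth) <- ids
  list(labels = labels, truth = truth,
       accuracy = mean(labels == truth),
       pca = pca, contributions = block_contributions(pca),
       tree = nj_tree(pc1_distance(pca)), fm = fm)
}

#' Run the full synthetic profiling pipeline
#'
#' One seeded end-to-end run: builds the 32-peptide library and its
#' composition features, simulates one membrane per bromodomain from a
#' planted binding matrix and normalizes them back to scaled relative
#' intensities, calls binders and biclusters the heat map, runs the scaffold
#' field-PCA classification, computes the structure feature table, and writes
#' every artifact (TSV, Newick, OpenDX) plus a JSON manifest to `outdir`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param n_brd Number of simulated bromodomains/membranes, default 14.
#' @param rel_sd Membrane noise level, default 0.05.
#' @param binder_threshold Binder call threshold, default 0.2.
#' @param n_good,n_poor Scaffold class sizes for the classification stage.
#' @return Invisibly, a list with the in-memory results (`library`,
#'   `normalized`, `calls`, `heatmap`, `classification`, `features`,
#'   `manifest`).
#' @export
run_brd_pipeline <- function(outdir, seed = 1, n_brd = 14, rel_sd = 0.05,
                             binder_threshold = 0.2, n_good = 7, n_poor = 7) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(outdir, ...)

  lib <- build_library()
  write_peptide_library(lib, path("peptide_library.tsv"))
  comp <- composition_features(lib)
  utils::write.table(cbind(id = lib$id, comp), path("composition_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  n_pep <- nrow(lib)
  truth <- simulate_binding_matrix(n_brd = n_brd, n_pep = n_pep,
                                   noise_sd = 0, seed = seed)
  colnames(truth) <- lib$id
  membrane_seeds <- .with_seed(seed, sample.int(1e6, n_brd))
  norm <- matrix(NA_real_, n_brd, n_pep,
                 dimnames = list(rownames(truth), colnames(truth)))
  for (i in seq_len(n_brd)) {
    layout <- membrane_layout(lib$id, rows = 5, cols = 8,
                              subtype = (i - 1) %% 4 + 1)
    spots <- simulate_membrane(layout, theta = truth[i, ], rel_sd = rel_sd,
                               seed = membrane_seeds[i])
    norm[i, ] <- normalize_membrane(spots) / ws_factor(attr(spots, "subtype"))
  }
  utils::write.table(round(norm, 6), path("normalized_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  calls <- call_binders(norm, binder_threshold)
  utils::write.table(calls, path("binder_calls.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  freq <- binder_frequency(norm, binder_threshold)
  utils::write.table(data.frame(id = names(freq), frequency = freq),
                     path("binder_frequency.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hm <- cluster_heatmap(norm)
  utils::write.table(round(hm$matrix, 6), path("heatmap_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  cl <- classify_scaffold_set(n_good = n_good, n_poor = n_poor, seed = seed)
  utils::write.table(
    data.frame(structure_id = rownames(cl$pca$scores),
               pc1 = cl$pca$scores[, 1],
               label = as.character(cl$labels),
               truth = as.character(cl$truth)),
    path("pc1_classification.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(probe = names(cl$contributions),
               pc1_share = as.numeric(cl$contributions)),
    path("block_contributions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ape::write.tree(cl$tree, path("brd_tree.nwk"))
  masks <- loadings_map(cl$pca)
  write_mask_dx(masks[[1]], cl$pca$spec, path("pc1_mask_N1+.dx"))

  sub_seeds <- .with_seed(seed, sample.int(1e6, n_good + n_poor))
  scaffolds <- lapply(seq_len(n_good + n_poor), function(i) {
    simulate_scaffold(if (i <= n_good) "good" else "poor",
                      seed = sub_seeds[i],
                      id = names(cl$labels)[i])
  })
  names(scaffolds) <- names(cl$labels)
  feats <- feature_table(scaffolds, lapply(scaffolds, scaffold_annotation))
  utils::write.table(feats, path("feature_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = seed, n_brd = n_brd, n_peptides = n_pep, rel_sd = rel_sd,
    binder_threshold = binder_threshold, n_good = n_good, n_poor = n_poor,
    package_version = as.character(utils::packageVersion("bromoscope")),
    outputs = list.files(outdir)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(library = lib, normalized = norm, calls = calls,
                 heatmap = hm, classification = cl, features = feats,
                 manifest = manifest))
}
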