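#' Build a centred acetyl-lysine peptide
#'
#' Extracts a `window`-residue peptide around an acetylation site so that the
#' acetyl-lysine sits at the centre position. When fewer than `(window-1)/2`
#' residues precede the site (N-terminal sites such as H3K4 or H4K5), the
#' missing residues are supplied by the left-truncation of the linker `"GGSG"`
#' of exactly the missing length (`"GGSG"` for 4 missing, `"GGS"` for 3, ...).
#' Sites closer than `(window-1)/2` residues to the C-terminus are padded on
#' the right with `G` and flagged via `c_pad`. Peptides are marked as
#' N-terminally biotinylated, mirroring how they would be immobilised on a
#' streptavidin membrane.
#'
#' @param sequence Amino-acid string of the mature histone (residue 1 first).
#' @param histone Histone id used to label the peptide (e.g. `"H4"`).
#' @param position 1-based residue position of the acetyl-lysine (mature
#'   numbering).
#' @param window Odd peptide length, default 15.
#' @param acetylated Logical; `FALSE` produces a non-acetylated control
#'   peptide whose id lacks the `ac` suffix.
#' @param allow_substitution If `TRUE` and the residue at `position` is not
#'   lysine, a lysine is placed at the central position of the extracted
#'   context (the peptide is then flagged `substituted`); if `FALSE` (default)
#'   this is an error.
#' @return One-row data frame with columns `id`, `histone`, `position`,
#'   `sequence`, `kac_index`, `n_pad`, `c_pad`, `acetylated`, `biotinylated`,
#'   `substituted`.
#' @examples
#' h <- histone_sequences("human")
#' build_peptide(h[["H3"]], "H3", 4)   # GGSGARTKQTARKST
#' @export
build_peptide <- function(sequence, histone, position, window = 15,
                          acetylated = TRUE, allow_substitution = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (window %% 2L == 0L) {
    stop("`window` must be odd so the acetyl-lysine can sit at the centre")
  }
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("site position ", position, " outside the ", n, "-residue sequence")
  }
  res <- substr(sequence, position, position)
  substituted <- FALSE
  if (res != "K") {
    if (!allow_substitution) {
      stop("residue at ", histone, " position ", position, " is '", res,
           "', not lysine")
    }
    substituted <- TRUE
  }

  half <- (window - 1L) %/% 2L
  from <- position - half
  to <- position + half
  n_pad <- max(0L, 1L - from)
  c_pad <- max(0L, to - n)
  if (n_pad > 4L) {
    stop("site too close to the N-terminus: ", n_pad,
         " padding residues needed but the linker provides at most 4")
  }
  pad <- substr("GGSG", 1L, n_pad)     # left-truncation: 4 -> GGSG, 3 -> GGS
  core <- substr(sequence, max(1L, from), min(n, to))
  pep <- paste0(pad, core, strrep("G", c_pad))
  kac_index <- half + 1L
  if (substituted) {
    substr(pep, kac_index, kac_index) <- "K"
  }
  stopifnot(nchar(pep) == window,
            substr(pep, kac_index, kac_index) == "K")

  data.frame(
    id = paste0(histone, "K", position, if (acetylated) "ac" else ""),
    histone = histone, position = as.integer(position),
    sequence = pep, kac_index = kac_index,
    n_pad = n_pad, c_pad = c_pad,
    acetylated = acetylated, biotinylated = TRUE,
    substituted = substituted,
    stringsAsFactors = FALSE
  )
}

#' Build the acetyl-lysine peptide library
#'
#' Builds one acetylated peptide per site in `sites` (default: the packaged
#' table of 32 major acetylation sites on the four core histones), ordered by
#' (histone, position). Two packaged sites (H2AK21, H2BK118) are printed-list
#' positions that are not lysine in the canonical human sequences; for these
#' the builder places the acetyl-lysine at the listed position within the
#' canonical context and flags the peptide `substituted` (see the methods
#' vignette).
#'
#' @param sites Data frame with columns `histone`, `position`.
#' @param sequences Named character vector of histone sequences.
#' @param window Peptide length, default 15.
#' @param k56_control If `TRUE`, append a non-acetylated H3K56 control peptide
#'   (the K56' spot convention).
#' @param k56_species Sequence used for the K56/K56' pair when the control is
#'   enabled: `"human"` (default) or `"yeast"`.
#' @return Data frame of peptides, one row per peptide (see [build_peptide()]).
#' @export
build_library <- function(sites = acetyl_sites(),
                          sequences = histone_sequences("human"),
                          window = 15, k56_control = FALSE,
                          k56_species = c("human", "yeast")) {
  k56_species <- match.arg(k56_species)
  if (nrow(sites) == 0L) {
    return(build_peptide(strrep("K", 2L * window), "H3", window, window)[0, ])
  }
  key <- paste(sites$histone, sites$position)
  if (anyDuplicated(key)) {
    stop("duplicate acetylation site(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  missing_h <- setdiff(unique(sites$histone), names(sequences))
  if (length(missing_h)) {
    stop("no sequence for histone(s): ", paste(missing_h, collapse = ", "))
  }
  hist_order <- c("H3", "H4", "H2A", "H2B")
  o <- order(match(sites$histone, hist_order), sites$position)
  sites <- sites[o, , drop = FALSE]

  peps <- lapply(seq_len(nrow(sites)), function(i) {
    build_peptide(sequences[[sites$histone[i]]], sites$histone[i],
                  sites$position[i], window = window,
                  allow_substitution = TRUE)
  })
  lib <- do.call(rbind, peps)

  if (k56_control) {
    seq56 <- if (k56_species == "yeast") {
      histone_sequences("yeast")[["H3"]]
    } else {
      sequences[["H3"]]
    }
    ctrl <- build_peptide(seq56, "H3", 56, window = window, acetylated = FALSE)
    lib <- rbind(lib, ctrl)
  }
  rownames(lib) <- lib$id
  lib
}

#' Write a peptide library as TSV
#'
#' @param library Data frame from [build_library()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_peptide_library <- function(library, file) {
  utils::write.table(library, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

.aa_positive <- c("K", "R")
.aa_negative <- c("D", "E")
.aa_aromatic <- c("F", "Y", "W")
.aa_polar    <- c("S", "T", "N", "Q", "C", "H")  # polar non-charged; Y counted aromatic

#' Residue-composition features of peptides
#'
#' Whole-peptide counts of positively charged (K, R, the acetyl-lysine
#' included), negatively charged (D, E), polar non-charged (S, T, N, Q, C, H)
#' and aromatic (F, Y, W) residues, plus two local features around the
#' acetyl-lysine: the number of prolines at the Kac +/- 1 positions and
#' `has_basic_flank`, whether a Lys or Arg (other than the Kac itself) sits at
#' Kac +/- 1. These are the features that contrast binder and non-binder
#' histone sequences: binders are rich in basic residues flanking the Kac,
#' non-binders carry few basics and more prolines next to the Kac.
#'
#' @param peptides Data frame with columns `sequence` and `kac_index` (e.g.
#'   from [build_library()]), or a character vector of sequences (centre
#'   position then taken as the Kac).
#' @return Data frame with one row per peptide: `positive`, `negative`,
#'   `polar`, `aromatic`, `proline_adjacent`, `has_basic_flank`.
#' @export
composition_features <- function(peptides) {
  if (is.character(peptides)) {
    peptides <- data.frame(sequence = peptides,
                           kac_index = (nchar(peptides) + 1L) %/% 2L,
                           stringsAsFactors = FALSE)
  }
  feat <- lapply(seq_len(nrow(peptides)), function(i) {
    s <- strsplit(peptides$sequence[i], "")[[1]]
    k <- peptides$kac_index[i]
    flank <- s[intersect(c(k - 1L, k + 1L), seq_along(s))]
    data.frame(
      positive = sum(s %in% .aa_positive),
      negative = sum(s %in% .aa_negative),
      polar = sum(s %in% .aa_polar),
      aromatic = sum(s %in% .aa_aromatic),
      proline_adjacent = sum(flank == "P"),
      has_basic_flank = any(flank %in% .aa_positive)
    )
  })
  out <- do.call(rbind, feat)
  if (!is.null(peptides$id)) rownames(out) <- peptides$id
  out
}

#' Per-peptide binder frequency
#'
#' For each peptide (column of a normalized BRD x peptide matrix), the number
#' of bromodomains whose scaled relative intensity reaches `threshold` -- the
#' horizontal-bar statistic used to rank peptides by how many domains bind
#' them.
#'
#' @param m Numeric BRD x peptide matrix of scaled relative intensities.
#' @param threshold Non-negative binder call threshold (inclusive),
#'   default 0.2.
#' @return Named integer vector, one count per peptide.
#' @export
binder_frequency <- function(m, threshold = 0.2) {
  if (threshold < 0) stop("`threshold` must be non-negative")
  m <- as.matrix(m)
  counts <- colSums(m >= threshold)
  storage.mode(counts) <- "integer"
  counts
}
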