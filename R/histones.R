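#' Packaged canonical histone sequences
#'
#' Returns the mature (initiator-Met-removed) protein sequences of the four
#' core histones, read from the FASTA shipped with the package. Numbering of
#' acetylation sites (H3K4, H4K16, ...) is mature-chain numbering: the first
#' residue of the returned string is residue 1.
#'
#' @param species `"human"` (all four core histones) or `"yeast"` (H3 only,
#'   used for the K56/K56' control convention).
#' @return A named character vector of amino-acid strings, names are histone
#'   ids (`H3`, `H4`, `H2A`, `H2B`).
#' @export
histone_sequences <- function(species = c("human", "yeast")) {
  species <- match.arg(species)
  fa <- system.file("extdata", paste0("histones_", species, ".fasta"),
                    package = "bromoscope", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(fa)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), " "), `[`, "", 1L)
  seqs
}

#' Major histone acetylation sites
#'
#' The packaged table of major acetylation sites on the four core histones
#' (mature numbering): 10 on H3, 7 on H4, 6 on H2A and 9 on H2B, 32 in total.
#'
#' @return A data frame with columns `histone` and `position`, ordered by
#'   (histone, position) with histones in H3, H4, H2A, H2B order.
#' @export
acetyl_sites <- function() {
  f <- system.file("extdata", "acetyl_sites.tsv", package = "bromoscope",
                   mustWork = TRUE)
  sites <- utils::read.delim(f, stringsAsFactors = FALSE)
  sites$histone <- factor(sites$histone, levels = c("H3", "H4", "H2A", "H2B"))
  sites <- sites[order(sites$histone, sites$position), , drop = FALSE]
  sites$histone <- as.character(sites$histone)
  rownames(sites) <- NULL
  sites
}
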