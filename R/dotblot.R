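# Dot-blot quantification and normalization.
#
# A membrane carries one spot per peptide plus control spots: at least five
# EMPTY spots whose mean density is the background B, and GST spots at 20, 10
# and 5 ng of which the 5 ng spot calibrates the relative intensity
# RI = (Xi - B) / G. Membranes belong to one of four subtypes whose RI values
# are made comparable by fixed scaling factors Ws.

#' Per-subtype scaling factors Ws
#'
#' Fixed scaling applied to relative intensities so that membranes of the four
#' subtypes are comparable: Ws = 1.00, 0.95, 0.50, 0.20 for subtypes 1-4.
#'
#' @param subtype Integer vector with values in 1:4.
#' @return Numeric vector of scaling factors.
#' @export
ws_factor <- function(subtype) {
  ws <- c(1.00, 0.95, 0.50, 0.20)
  if (any(is.na(subtype)) || !all(subtype %in% 1:4)) {
    stop("membrane `subtype` must be an integer in 1:4")
  }
  ws[subtype]
}

#' Define a membrane layout
#'
#' Assigns peptides, EMPTY background spots and GST calibration spots to the
#' cells of a rows x cols membrane grid. Peptides fill the grid row-major from
#' the top-left; the GST spots (20, 10, 5 ng) occupy the first cells of the
#' last row, followed by the EMPTY spots; remaining cells are EMPTY too.
#'
#' @param peptide_ids Character vector of unique peptide ids.
#' @param rows,cols Grid dimensions.
#' @param n_empty Number of EMPTY spots, at least 5.
#' @param gst_ng Amounts (ng) of the GST calibration spots; must contain 5.
#' @param subtype Membrane subtype in 1:4.
#' @return Data frame of class `membrane_layout` with columns `row`, `col`,
#'   `id`, `type` (`peptide`/`EMPTY`/`GST`), `gst_ng`; attributes `rows`,
#'   `cols`, `subtype`.
#' @export
membrane_layout <- function(peptide_ids, rows, cols, n_empty = 5,
                            gst_ng = c(20, 10, 5), subtype = 1) {
  if (anyDuplicated(peptide_ids)) stop("peptide ids must be unique")
  if (n_empty < 5) stop("a membrane needs at least 5 EMPTY spots")
  if (!5 %in% gst_ng) stop("the GST series must include the 5 ng spot")
  ws_factor(subtype)
  n_cells <- rows * cols
  n_need <- length(peptide_ids) + n_empty + length(gst_ng)
  if (n_need > n_cells) {
    stop("layout needs ", n_need, " cells but the grid has ", n_cells)
  }
  last_row_start <- (rows - 1L) * cols
  if (length(peptide_ids) > last_row_start) {
    stop("peptides would spill into the last (control) row")
  }
  type <- rep("EMPTY", n_cells)
  id <- rep(NA_character_, n_cells)
  ng <- rep(NA_real_, n_cells)
  type[seq_along(peptide_ids)] <- "peptide"
  id[seq_along(peptide_ids)] <- peptide_ids
  gidx <- last_row_start + seq_along(gst_ng)
  type[gidx] <- "GST"
  ng[gidx] <- gst_ng
  out <- data.frame(
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows),
    id = id, type = type, gst_ng = ng,
    stringsAsFactors = FALSE
  )
  structure(out, rows = rows, cols = cols, subtype = as.integer(subtype),
            class = c("membrane_layout", "data.frame"))
}

#' Integrate spot densities from a grayscale membrane image
#'
#' Sums the pixel values within a circular window of `radius` pixels centred
#' on each grid cell of the layout. Cells are assumed to tile the image
#' uniformly (cell height = nrow(image)/rows, width = ncol(image)/cols).
#'
#' @param image Numeric matrix, pixel values >= 0.
#' @param layout A [membrane_layout()].
#' @param radius Integration radius in pixels; windows of neighbouring cells
#'   must not overlap.
#' @return A spot table: the layout data frame with a `density` column and the
#'   layout's `subtype` attribute carried over.
#' @export
integrate_spots <- function(image, layout, radius) {
  rows <- attr(layout, "rows"); cols <- attr(layout, "cols")
  ch <- nrow(image) / rows
  cw <- ncol(image) / cols
  if (2 * radius > min(ch, cw)) {
    stop("integration windows of radius ", radius,
         " px overlap neighbouring cells (pitch ", min(ch, cw), " px)")
  }
  yy <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  xx <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  dens <- vapply(seq_len(nrow(layout)), function(i) {
    cy <- (layout$row[i] - 0.5) * ch
    cx <- (layout$col[i] - 0.5) * cw
    sum(image[(yy - cy)^2 + (xx - cx)^2 <= radius^2])
  }, numeric(1))
  out <- as.data.frame(layout)
  out$density <- dens
  structure(out, subtype = attr(layout, "subtype"),
            class = c("spot_table", "data.frame"))
}

#' Background density of a membrane
#'
#' The background B is the arithmetic mean of the densities of 5 EMPTY spots;
#' when more than 5 exist, the first five in layout order are used.
#'
#' @param spots Spot table with columns `type` and `density`.
#' @return Numeric background density B.
#' @export
estimate_background <- function(spots) {
  empties <- spots$density[spots$type == "EMPTY"]
  if (length(empties) < 5) {
    stop("need at least 5 measured EMPTY spots, got ", length(empties))
  }
  mean(empties[1:5])
}

#' GST calibration density
#'
#' @param spots Spot table.
#' @param ng Which GST amount calibrates RI (default 5 ng).
#' @return Density G of the GST spot.
#' @export
gst_density <- function(spots, ng = 5) {
  g <- spots$density[spots$type == "GST" & !is.na(spots$gst_ng) &
                       spots$gst_ng == ng]
  if (length(g) != 1) stop("expected exactly one GST ", ng, " ng spot")
  g
}

#' Normalize a membrane to scaled relative intensities
#'
#' Converts raw spot densities to relative intensities RI = (Xi - B)/G, where
#' B is the EMPTY-spot background and G the density of the GST 5 ng spot, then
#' applies the membrane subtype's scaling factor: scaled RI = Ws * RI.
#' Negative values are retained so noise statistics stay unbiased.
#'
#' @param spots Spot table (carrying a `subtype` attribute), or raw densities
#'   if `B`, `G` and `subtype` are given explicitly.
#' @param B,G,subtype Optional explicit background, GST calibration density
#'   and subtype; by default derived from `spots`.
#' @return Named numeric vector of scaled RI values, one per peptide spot, in
#'   layout order.
#' @export
normalize_membrane <- function(spots, B = NULL, G = NULL, subtype = NULL) {
  if (is.null(B)) B <- estimate_background(spots)
  if (is.null(G)) G <- gst_density(spots)
  if (is.null(subtype)) subtype <- attr(spots, "subtype")
  if (is.null(subtype)) stop("membrane subtype unknown")
  if (!is.finite(G) || G <= 0) {
    stop("GST calibration density must be positive, got ", G)
  }
  keep <- spots$type == "peptide"
  ri <- (spots$density[keep] - B) / G
  out <- ws_factor(subtype) * ri
  names(out) <- spots$id[keep]
  out
}

#' Scaled relative intensity of raw densities
#'
#' Vectorised core of the normalization: `Ws(subtype) * (xi - B) / G`.
#'
#' @param xi Raw spot density or densities.
#' @param B Background density.
#' @param G GST (5 ng) calibration density, > 0.
#' @param subtype Membrane subtype in 1:4.
#' @return Scaled RI values.
#' @export
scale_ri <- function(xi, B, G, subtype) {
  if (!is.finite(G) || G <= 0) {
    stop("GST calibration density must be positive, got ", G)
  }
  ws_factor(subtype) * (xi - B) / G
}

#' Call binders from a normalized matrix
#'
#' A bromodomain is called a binder of a peptide when the scaled relative
#' intensity reaches `threshold` (inclusive). 0.2 is the value reported as the
#' least-preferred-binder end of the normalized scale.
#'
#' @param m BRD x peptide matrix of scaled RI values (finite).
#' @param threshold Call threshold, default 0.2.
#' @return Logical matrix of the same shape.
#' @export
call_binders <- function(m, threshold = 0.2) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("normalized matrix contains non-finite values")
  m >= threshold
}

#' Bicluster a BRD x peptide matrix for heat-map display
#'
#' Rows (bromodomains) and columns (peptides) are clustered independently by
#' average-linkage agglomerative clustering on Euclidean distances. Input rows
#' and columns are first ordered by label so the result is invariant to input
#' permutation, and ties merge deterministically.
#'
#' @param m Numeric matrix with row and column names, no missing values.
#' @return List of class `brd_heatmap`: `row_tree` and `col_tree` (`hclust`
#'   objects, or `NULL` for a single row/column) and `matrix`, the input
#'   reordered to the dendrogram leaf orders.
#' @export
cluster_heatmap <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("matrix contains missing/non-finite values")
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  tree1 <- function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  }
  rt <- tree1(m)
  ct <- tree1(t(m))
  ro <- if (is.null(rt)) 1L else rt$order
  co <- if (is.null(ct)) 1L else ct$order
  structure(list(row_tree = rt, col_tree = ct,
                 matrix = m[ro, co, drop = FALSE]),
            class = "brd_heatmap")
}
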