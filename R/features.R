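# Border-irregularity measures: the two-value vector (fractal dimension,
# convexity). Fractal dimension is estimated on the border image by box
# counting; convexity on the segmentation mask as hull perimeter over
# lesion perimeter.

#' Count covering boxes of side e
#'
#' Partitions the grid into an `e x e` lattice anchored at the image origin
#' and counts the cells containing at least one foreground pixel.
#'
#' @param border logical matrix (border pixels `TRUE`) or numeric matrix
#'   (positive = border).
#' @param e box side length in pixels (`>= 1`).
#' @return integer count `N(e)`.
#' @export
box_count <- function(border, e) {
  bw <- as_mask(border)
  if (e < 1) stopf("box side must be >= 1")
  idx <- which(bw)
  if (!length(idx)) stopf("border is empty")
  nr <- nrow(bw)
  rows <- ((idx - 1L) %% nr)        # 0-based
  cols <- ((idx - 1L) %/% nr)
  cells <- (rows %/% e) + (cols %/% e) * ((nr %/% e) + 2L)
  length(unique(cells))
}

#' Box-counting fractal dimension
#'
#' Least-squares slope of `log N(e)` against `log(1/e)` over a ladder of box
#' sizes; the default ladder is powers of 2 from 2 up to a quarter of the
#' image side. A straight line yields 1, space-filling structures approach
#' 2, and fractal borders (e.g. the Koch curve, log4/log3 ~ 1.262) fall in
#' between: the more irregular the border, the higher the dimension.
#'
#' @param border logical or numeric matrix of border pixels.
#' @param sizes box-side ladder (at least 3 sizes).
#' @return estimated dimension `D`.
#' @export
fractal_dimension <- function(border, sizes = NULL) {
  bw <- as_mask(border)
  if (!any(bw)) stopf("border is empty")
  if (is.null(sizes)) {
    top <- min(dim(bw)) / 4
    sizes <- 2^(seq_len(max(2, floor(log2(top)))))
    sizes <- sizes[sizes <= top]
  }
  if (length(sizes) < 3L) stopf("need at least 3 box sizes")
  N <- vapply(sizes, function(e) box_count(bw, e), 1L)
  if (any(N == 0L)) stopf("box count of zero")
  stats::coef(stats::lm(log(N) ~ I(log(1 / sizes))))[[2L]]
}

#' Convexity of a lesion mask
#'
#' Ratio of the perimeter of the convex hull of the lesion pixels (the
#' smallest convex polygon containing them) to the lesion boundary
#' perimeter. The boundary is the traced 8-connected contour with unit steps
#' for axial moves and sqrt(2) for diagonal moves; the hull perimeter is the
#' polygon arc length over the hull vertices. Convex shapes score 1 (an
#' axis-aligned rectangle exactly so); indentations lengthen the boundary
#' relative to its hull and push the value below 1. Note that for smooth
#' curves the digital contour length slightly overestimates the true arc
#' length, so even a discretised disk scores a few percent below 1.
#'
#' @param mask logical lesion mask (single connected component; if several
#'   are present the largest is used, with a warning).
#' @return convexity ratio.
#' @export
convexity <- function(mask) {
  bw <- as_mask(mask)
  if (!any(bw)) stopf("mask is empty")
  comps <- components(bw, connectivity = 4)
  if (length(comps) > 1L) {
    warning("mask has multiple components; using the largest", call. = FALSE)
    bw <- matrix(FALSE, nrow(bw), ncol(bw))
    bw[comps[[1L]]] <- TRUE
  }
  contour <- trace_contour(bw)
  if (nrow(contour) < 4L)
    stopf("mask is degenerate (fewer than 4 contour points)")
  perim <- contour_perimeter(contour)
  if (perim <= 0) stopf("mask is degenerate (zero perimeter)")
  pts <- unique(contour)
  hull <- grDevices::chull(pts[, 2L], pts[, 1L])   # x = col, y = row
  hp <- pts[hull, , drop = FALSE]
  hull_perim <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1L), , drop = FALSE])^2)))
  hull_perim / perim
}

#' Assemble the border-irregularity measure vector
#'
#' Routing follows the measurement pipeline: the fractal dimension is
#' computed on the border image (edge-filter output), the convexity on the
#' segmentation mask.
#'
#' @param mask logical lesion mask.
#' @param border logical or numeric border image derived from the same
#'   lesion.
#' @param id lesion identifier.
#' @param fd_sizes box-size ladder passed to [fractal_dimension()].
#' @return data frame with columns `id`, `fractal_dimension`, `convexity`.
#' @export
extract_features <- function(mask, border, id = "lesion", fd_sizes = NULL) {
  data.frame(id = as.character(id),
             fractal_dimension = fractal_dimension(border, fd_sizes),
             convexity = convexity(mask),
             stringsAsFactors = FALSE)
}

#' Compute features for a whole mask collection
#'
#' Runs the fuzzy edge filter on each mask and extracts the
#' (fractal dimension, convexity) vector.
#'
#' @param dataset result of [make_dataset()], or a list with `masks`,
#'   `ids` and optionally `labels`.
#' @param fd_sizes box-size ladder for the fractal dimension. The default
#'   `c(2, 4, 8, 16)` keeps every box well below the lesion diameter so the
#'   count probes border texture rather than lesion extent; boxes comparable
#'   to the lesion size only quantise its bounding box and add noise to the
#'   slope.
#' @return data frame with columns `id`, `fractal_dimension`, `convexity`
#'   and, when labels are present, `label`.
#' @export
pipeline_features <- function(dataset, fd_sizes = c(2, 4, 8, 16)) {
  n <- length(dataset$masks)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- dataset$masks[[i]]
    border <- suppressWarnings(fuzzedge_filter(mask)) > 0
    out[[i]] <- extract_features(mask, border, dataset$ids[i], fd_sizes)
  }
  res <- do.call(rbind, out)
  if (!is.null(dataset$labels)) res$label <- dataset$labels
  res
}
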