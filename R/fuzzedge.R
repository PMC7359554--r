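# Fuzzy border detection. The filter partitions the gray-level axis into
# Dark / Median / Bright fuzzy concepts built from the image histogram, runs
# a standard-deviation process over each 3x3 neighbourhood under each
# concept's membership function, and keeps the concept deviation nearest to
# a reference ("fuzzy estimator") deviation computed under an interval
# membership that spans the whole occupied gray range.

#' Build Dark / Median / Bright fuzzy concepts from an image histogram
#'
#' The gray axis `[0, L-1]` is divided into `N_f` bands:
#' `Dark_end = floor((L-1)/N_f)`, `Bright_begin = (N_f-1) * floor((L-1)/N_f)`,
#' with the Median band between them (widened by the optional overlaps).
#' `Dark_begin` / `Bright_end` snap to the first / last occupied gray level.
#' Each concept's membership function is the triangle with apex `m` at the
#' histogram mode inside its band and feet at the band ends (spreads
#' `alpha = m - begin`, `beta = end - m`). An empty band gets its midpoint as
#' centre, with a warning.
#'
#' @param image numeric matrix of gray levels in `[0, L-1]` (values in
#'   `[0, 1]` are rescaled to `[0, L-1]`).
#' @param N_f number of concepts (3).
#' @param overlaps numeric pair `(left_overlap, right_overlap)` widening the
#'   Median band; 0 by default.
#' @param L number of gray levels (256).
#' @return object of class `fuzzy_concepts`: a list of per-concept lists
#'   (`begin`, `end`, `m`, `alpha`, `beta`) for `Dark`, `Median`, `Bright`,
#'   plus `L` and `N_f`.
#' @export
create_concepts <- function(image, N_f = 3L, overlaps = c(0L, 0L), L = 256L) {
  g <- as_gray(image, L)
  if (!length(g)) stopf("image has no pixels")
  h <- tabulate(as.vector(g) + 1L, nbins = L)      # histogram over 0..L-1
  p <- h / sum(h)
  band <- (L - 1L) %/% N_f
  dark_end <- band
  bright_begin <- (N_f - 1L) * band
  occupied <- which(h > 0L) - 1L
  dark_begin <- if (any(occupied <= dark_end)) min(occupied[occupied <= dark_end]) else 0L
  bright_end <- if (any(occupied >= bright_begin)) max(occupied[occupied >= bright_begin]) else L - 1L
  med_begin <- dark_end - overlaps[1L]
  med_end <- bright_begin + overlaps[2L]
  concept <- function(name, begin, end) {
    idx <- seq.int(begin, end) + 1L
    if (sum(h[idx]) == 0L) {
      warning(sprintf("no pixels in the %s interval [%d, %d]; using its midpoint",
                      name, begin, end), call. = FALSE)
      m <- (begin + end) / 2
    } else {
      m <- (begin:end)[which.max(p[idx])]
    }
    list(begin = begin, end = end, m = m, alpha = m - begin, beta = end - m)
  }
  structure(list(
    Dark = concept("Dark", dark_begin, dark_end),
    Median = concept("Median", med_begin, med_end),
    Bright = concept("Bright", bright_begin, bright_end),
    L = as.integer(L), N_f = as.integer(N_f),
    range = c(dark_begin, bright_end)), class = "fuzzy_concepts")
}

# coerce an image to integer gray levels 0..L-1
as_gray <- function(image, L = 256L) {
  g <- as.matrix(image)
  storage.mode(g) <- "double"
  if (all(g >= 0 & g <= 1) && any(g %% 1 != 0)) g <- g * (L - 1L)
  if (is.logical(image)) g <- g * (L - 1L)
  g <- round(g)
  if (any(g < 0 | g > L - 1L)) stopf("gray levels must lie in [0, %d]", L - 1L)
  storage.mode(g) <- "integer"
  g
}

#' Triangular membership degree of a gray level in one concept
#'
#' 1 at the centre `m`, falling linearly to 0 at `m - alpha` and `m + beta`,
#' 0 outside. A degenerate spread collapses that side to a step at `m`.
#'
#' @param g gray level(s) in `[0, L-1]`.
#' @param concept one element of a [create_concepts()] set.
#' @return degrees in `[0, 1]`.
#' @export
concept_membership <- function(g, concept) {
  m <- concept$m; a <- concept$alpha; b <- concept$beta
  left <- if (a > 0) (g - (m - a)) / a else as.numeric(g >= m)
  right <- if (b > 0) ((m + b) - g) / b else as.numeric(g <= m)
  pmax(0, pmin(1, ifelse(g <= m, left, right)))
}

# population standard deviation over the 9 stacked neighbourhood planes
.stack_sd <- function(planes) {
  n <- length(planes)
  s <- Reduce(`+`, planes)
  s2 <- Reduce(`+`, lapply(planes, function(x) x * x))
  v <- s2 / n - (s / n)^2
  sqrt(pmax(v, 0))
}

#' Fuzzy edge filter
#'
#' For every pixel, three standard-deviation processes are run over its 3x3
#' neighbourhood, one per fuzzy concept, with each neighbour's value taken
#' through the concept's membership function (`value * membership`). A
#' fourth, reference deviation (the fuzzy estimator) uses the interval
#' membership function equal to 1 over the whole occupied gray range, i.e.
#' the plain neighbourhood standard deviation. The filter output is the
#' concept deviation nearest to the estimator (ties resolve Dark, Median,
#' Bright). Flat neighbourhoods give 0, so borders are exactly the pixels
#' with a non-zero response. Image edges are handled by replication padding.
#'
#' @param image grayscale matrix (see [create_concepts()]); a logical mask
#'   is treated as a 0/255 image.
#' @param concepts optional [create_concepts()] result; computed from the
#'   image when missing.
#' @return numeric matrix of edge responses (same size as `image`).
#' @export
fuzzedge_filter <- function(image, concepts = NULL) {
  g <- as_gray(image)
  if (nrow(g) < 3L || ncol(g) < 3L) stopf("image must be at least 3x3")
  if (is.null(concepts)) concepts <- create_concepts(g)
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- g
  pad[1L, ] <- pad[2L, ]; pad[nr + 2L, ] <- pad[nr + 1L, ]
  pad[, 1L] <- pad[, 2L]; pad[, nc + 2L] <- pad[, nc + 1L]
  shifts <- list()
  for (dr in 0:2) for (dc in 0:2)
    shifts[[length(shifts) + 1L]] <- pad[(1:nr) + dr, (1:nc) + dc]
  # membership lookup tables over gray levels 0..L-1
  levels <- 0:(concepts$L - 1L)
  ds <- vector("list", 3L)
  names(ds) <- c("Dark", "Median", "Bright")
  for (nm in names(ds)) {
    lut <- concept_membership(levels, concepts[[nm]])
    planes <- lapply(shifts, function(s) {
      matrix(lut[s + 1L] * as.numeric(s), nr, nc)
    })
    ds[[nm]] <- .stack_sd(planes)
  }
  est <- .stack_sd(lapply(shifts, function(s) matrix(as.numeric(s), nr, nc)))
  dd <- abs(ds$Dark - est); dm <- abs(ds$Median - est); db <- abs(ds$Bright - est)
  out <- ds$Dark
  better <- dm < dd
  out[better] <- ds$Median[better]
  best <- pmin(dd, dm)
  better <- db < best
  out[better] <- ds$Bright[better]
  out
}

#' Extract the dominant closed border contour
#'
#' Binarises the edge response (`> threshold`), keeps the largest
#' 8-connected component and traces its outer boundary clockwise starting
#' from the topmost-then-leftmost pixel, so the result is deterministic.
#'
#' @param border_image numeric edge-response matrix (or a logical border
#'   mask).
#' @param threshold binarisation threshold on the response (default 0).
#' @return integer matrix of ordered contour coordinates, columns `row` and
#'   `col`; the contour is closed (last point adjacent to the first).
#' @export
extract_border <- function(border_image, threshold = 0) {
  bw <- if (is.logical(border_image)) border_image else border_image > threshold
  if (!any(bw)) stopf("no border pixels found")
  comps <- components(bw, connectivity = 8)
  comp <- matrix(FALSE, nrow(bw), ncol(bw))
  comp[comps[[1L]]] <- TRUE
  if (length(comps[[1L]]) < 8L)
    stopf("largest border component has only %d pixels; no closed border",
          length(comps[[1L]]))
  contour <- trace_contour(comp)
  if (nrow(contour) < 8L) stopf("no closed border found")
  contour
}
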