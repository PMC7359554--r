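#' Shape specification for synthetic lesion masks
#'
#' Describes a single synthetic shape. Regular lesions are ellipse-like convex
#' regions; irregular lesions are star-convex regions whose radius is
#' perturbed by a sum of random-phase sinusoids, giving the indentations and
#' protrusions that characterise irregular lesion borders. `line`, `koch` and
#' `square` are analytic test shapes with known fractal dimension or
#' convexity.
#'
#' @param kind one of `"regular"`, `"irregular"`, `"line"`, `"koch"`,
#'   `"square"`.
#' @param image_side side of the square image, pixels.
#' @param base_radius mean lesion radius, pixels.
#' @param roughness unitless amplitude of the radial perturbation, `>= 0`;
#'   must be 0 for `kind = "regular"` and `< 1` for irregular shapes (at
#'   `roughness >= 1` the radius can reach zero).
#' @param harmonics number of sinusoidal frequency components in the radial
#'   perturbation (default 16).
#' @param seed integer seed; the same spec always yields the same mask.
#' @return an object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("regular", "irregular", "line", "koch", "square"),
                       image_side = 256L, base_radius = 64L,
                       roughness = 0, harmonics = 16L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "regular" && roughness != 0)
    stopf("regular shapes must have roughness = 0 (got %g)", roughness)
  if (roughness < 0) stopf("roughness must be >= 0")
  if (kind == "irregular") {
    if (roughness >= 1)
      stopf("roughness %g would allow a non-positive radius; need roughness < 1",
            roughness)
    if (image_side < 4L * base_radius)
      stopf("image_side must be >= 4 * base_radius for irregular shapes")
  }
  structure(list(kind = kind, image_side = as.integer(image_side),
                 base_radius = as.integer(base_radius),
                 roughness = roughness, harmonics = as.integer(harmonics),
                 seed = as.integer(seed)),
            class = "shape_spec")
}

#' Generate a binary lesion mask from a shape specification
#'
#' Regular masks are filled ellipses with a seeded aspect ratio and
#' orientation. Irregular masks are star-convex regions with radius
#' `r(theta) = base_radius * (1 + roughness * sum_k a_k sin(k theta + phi_k))`
#' over `harmonics` log-spaced integer frequencies from 2 up to roughly
#' three quarters of the base radius, so the boundary carries both coarse
#' lobes (which lower convexity) and fine serrations (which raise the
#' box-counting dimension). Amplitudes decay slowly (`k^-0.3`) and are
#' normalised so the total perturbation is bounded by `roughness`; phases
#' are seeded uniform. The returned mask is a single 4-connected component
#' that does not touch the image border.
#'
#' @param spec a [shape_spec()].
#' @return logical matrix (`TRUE` = lesion).
#' @export
make_mask <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  side <- spec$image_side
  if (spec$kind %in% c("line", "koch"))
    return(make_curve(spec$kind, level = 4L, image_side = side))
  if (spec$kind == "square") {
    m <- matrix(FALSE, side, side)
    half <- spec$base_radius
    lo <- side %/% 2L - half + 1L
    hi <- side %/% 2L + half
    m[lo:hi, lo:hi] <- TRUE
    return(m)
  }
  ctr <- (side + 1) / 2
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  dy <- rows - ctr; dx <- cols - ctr
  theta <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  mask <- with_seed(spec$seed, {
    if (spec$kind == "regular") {
      aspect <- stats::runif(1, 0.7, 1)
      phi <- stats::runif(1, 0, pi)
      # ellipse radius along direction theta, semi-axes a = base, b = aspect*a
      a <- spec$base_radius; b <- aspect * a
      th <- theta - phi
      rad <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    } else {
      kmax <- max(8, round(0.75 * spec$base_radius))
      k <- unique(round(exp(seq(log(2), log(kmax), length.out = spec$harmonics))))
      w <- k^(-0.3)
      amp <- w / sum(w)                       # sum |a_k| = 1 bounds the perturbation
      ph <- stats::runif(length(k), 0, 2 * pi)
      pert <- matrix(0, side, side)
      for (i in seq_along(k))
        pert <- pert + amp[i] * sin(k[i] * theta + ph[i])
      rad <- spec$base_radius * (1 + spec$roughness * pert)
    }
    rr <= rad
  })
  # star-convex rasterisation can leave stray 8-connected spurs; keep the
  # 4-connected component that contains the centre
  ci <- (round(ctr) - 1L) * side + round(ctr)
  if (!mask[ci]) mask[ci] <- TRUE
  mask <- flood_fill(mask, as.integer(ci), connectivity = 4)
  if (any(mask[1, ]) || any(mask[side, ]) || any(mask[, 1]) || any(mask[, side]))
    stopf("generated mask touches the image border; reduce base_radius or roughness")
  mask
}

#' Generate analytic test curves with known fractal dimension
#'
#' `line` draws a 1-pixel-thick horizontal segment spanning the image (its
#' box-counting dimension is 1). `koch` rasterises the Koch curve at the
#' given recursion level (analytic dimension log 4 / log 3 ~ 1.262).
#'
#' @param kind `"line"` or `"koch"`.
#' @param level Koch recursion level (`>= 1`); ignored for `line`.
#' @param image_side side of the square image, pixels.
#' @return logical matrix.
#' @export
make_curve <- function(kind = c("line", "koch"), level = 4L, image_side = 128L) {
  kind <- match.arg(kind)
  side <- as.integer(image_side)
  m <- matrix(FALSE, side, side)
  if (kind == "line") {
    m[side %/% 2L, ] <- TRUE
    return(m)
  }
  if (level < 1L) stopf("koch level must be >= 1")
  len <- side - 1
  if (len / 3^level < 1) stopf("koch level %d too deep for image_side %d", level, side)
  # complexify segments: each (p, q) becomes p-a-peak-b-q
  segs <- list(list(p = c(0, 0), q = c(len, 0)))
  for (l in seq_len(level)) {
    out <- vector("list", 4L * length(segs))
    j <- 0L
    for (s in segs) {
      d <- (s$q - s$p) / 3
      a <- s$p + d
      b <- s$p + 2 * d
      # peak: rotate d by -60 degrees (peak bulges upward, toward -y later)
      rot <- c(d[1] * cos(pi / 3) + d[2] * sin(pi / 3),
               -d[1] * sin(pi / 3) + d[2] * cos(pi / 3))
      peak <- a + rot
      out[[j + 1L]] <- list(p = s$p, q = a)
      out[[j + 2L]] <- list(p = a, q = peak)
      out[[j + 3L]] <- list(p = peak, q = b)
      out[[j + 4L]] <- list(p = b, q = s$q)
      j <- j + 4L
    }
    segs <- out
  }
  y_off <- round(side * 0.6)
  for (s in segs) {
    n <- max(2L, ceiling(2 * sqrt(sum((s$q - s$p)^2))))
    t <- seq(0, 1, length.out = n)
    xs <- round(s$p[1] + t * (s$q[1] - s$p[1])) + 1L
    ys <- y_off - round(s$p[2] + t * (s$q[2] - s$p[2]))
    keep <- xs >= 1L & xs <= side & ys >= 1L & ys <= side
    m[cbind(ys[keep], xs[keep])] <- TRUE
  }
  m
}

#' Generate a labelled collection of regular and irregular lesion masks
#'
#' Emulates a balanced study dataset: `n_regular` convex lesions labelled 1
#' and `n_irregular` perturbed lesions labelled 0. Per-mask seeds are derived
#' deterministically from `seed`.
#'
#' @param n_regular,n_irregular counts (`>= 1`).
#' @param roughness radial perturbation of the irregular class (default 0.4).
#' @param image_side,base_radius passed to [shape_spec()].
#' @param harmonics harmonic count for irregular masks.
#' @param seed integer master seed.
#' @return list with `masks` (list of logical matrices), `labels` (integer,
#'   regular = 1 / irregular = 0) and `ids` (character).
#' @export
make_dataset <- function(n_regular, n_irregular, roughness = 0.4,
                         image_side = 256L, base_radius = 64L,
                         harmonics = 16L, seed = 1L) {
  if (n_regular < 1L || n_irregular < 1L) stopf("counts must be >= 1")
  n <- n_regular + n_irregular
  kinds <- rep(c("regular", "irregular"), c(n_regular, n_irregular))
  seeds <- as.integer(seed) + 1000L * seq_len(n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- shape_spec(kinds[i], image_side = image_side,
                     base_radius = base_radius,
                     roughness = if (kinds[i] == "regular") 0 else roughness,
                     harmonics = harmonics, seed = seeds[i])
    masks[[i]] <- make_mask(sp)
  }
  list(masks = masks,
       labels = as.integer(kinds == "regular"),
       ids = sprintf("%s_%03d", ifelse(kinds == "regular", "r", "i"), seq_len(n)))
}

#' Augment a mask by 90-degree rotations and flips
#'
#' All transforms are isometries on the pixel grid, so foreground area is
#' preserved exactly. The original mask is always returned first.
#'
#' @param mask logical matrix.
#' @param ops character vector, subset of
#'   `c("rot90", "rot180", "rot270", "flip_h", "flip_v")`.
#' @return list of masks of length `length(ops) + 1`.
#' @export
augment <- function(mask, ops = c("rot90", "rot180", "rot270", "flip_h", "flip_v")) {
  mask <- as_mask(mask)
  if (!any(mask)) stopf("cannot augment an empty mask")
  ops <- unique(ops)
  bad <- setdiff(ops, c("rot90", "rot180", "rot270", "flip_h", "flip_v"))
  if (length(bad)) stopf("unknown augmentation op(s): %s", paste(bad, collapse = ", "))
  # quarter-turn clockwise of an image matrix: reverse rows, then transpose
  rot_cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  tf <- list(
    rot90  = rot_cw,
    rot180 = function(m) rot_cw(rot_cw(m)),
    rot270 = function(m) rot_cw(rot_cw(rot_cw(m))),
    flip_h = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
    flip_v = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  )
  c(list(mask), lapply(ops, function(o) tf[[o]](mask)))
}
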