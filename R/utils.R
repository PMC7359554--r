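# Internal helpers shared across modules: connected-component labelling,
# Moore-neighbour contour tracing and seed management. Masks are logical
# matrices in image convention: row 1 is the top scanline, columns run left
# to right.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' The global `.Random.seed` is restored afterwards so mask generation and
#' weight initialisation never perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  storage.mode(m) <- "double"
  m > 0
}

#' Vectorised breadth-first flood fill.
#'
#' @param mask logical matrix
#' @param start integer vector of linear indices to grow from
#' @param connectivity 4 or 8
#' @return logical matrix marking the component(s) reachable from `start`
#' @noRd
flood_fill <- function(mask, start, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  visited <- matrix(FALSE, nr, nc)
  frontier <- start[mask[start] & !visited[start]]
  visited[frontier] <- TRUE
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  while (length(frontier)) {
    r0 <- ((frontier - 1L) %% nr) + 1L
    c0 <- ((frontier - 1L) %/% nr) + 1L
    nxt <- integer(0)
    for (d in offs) {
      rr <- r0 + d[1L]; cc <- c0 + d[2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[mask[idx] & !visited[idx]]
      if (length(idx)) {
        visited[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  visited
}

#' Label connected components, returning a list of linear-index vectors
#' ordered by decreasing size.
#' @noRd
components <- function(mask, connectivity = 8) {
  remaining <- mask
  comps <- list()
  repeat {
    seed <- which(remaining)
    if (!length(seed)) break
    comp <- flood_fill(remaining, seed[1L], connectivity)
    comps[[length(comps) + 1L]] <- which(comp)
    remaining[comp] <- FALSE
  }
  comps[order(vapply(comps, length, 1L), decreasing = TRUE)]
}

# Moore neighbourhood in clockwise order for image coordinates (row grows
# downward): N, NE, E, SE, S, SW, W, NW.
.moore <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L,
                   1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)

#' Trace the outer boundary of a connected foreground region.
#'
#' Moore-neighbour tracing with Jacob's stopping criterion. The start pixel
#' is the topmost-then-leftmost foreground pixel and the walk is clockwise in
#' image coordinates, so results are deterministic.
#'
#' @param mask logical matrix holding a single connected component
#' @return integer matrix with columns `row`, `col`; closed contour, the
#'   last point is 8-adjacent to the first
#' @noRd
trace_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) stopf("cannot trace the contour of an empty mask")
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  r0 <- min(rows)
  c0 <- min(cols[rows == r0])
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  if (length(fg) == 1L) {
    return(matrix(c(r0, c0), ncol = 2L, dimnames = list(NULL, c("row", "col"))))
  }
  # One clockwise scan around `cur` starting just after the backtrack
  # direction `back` (0-based index into .moore). Returns the next contour
  # pixel and the backtrack direction seen from it, or NULL at a dead end.
  step_from <- function(cur, back) {
    for (k in 0:7) {
      j <- ((back + k) %% 8L) + 1L
      rr <- cur[1L] + .moore[j, 1L]
      cc <- cur[2L] + .moore[j, 2L]
      if (at(rr, cc)) {
        prev_bg <- ((back + k - 1L) %% 8L) + 1L   # last background cell scanned
        bg <- cur + .moore[prev_bg, ]
        d <- bg - c(rr, cc)
        nb <- which(.moore[, 1L] == d[1L] & .moore[, 2L] == d[2L]) - 1L
        return(list(nxt = c(rr, cc), back = nb))
      }
    }
    NULL
  }
  start <- c(r0, c0)
  # the start pixel's N and W neighbours are background by minimality,
  # so backtracking starts from the west
  s <- step_from(start, 7L)
  if (is.null(s)) {
    return(matrix(start, ncol = 2L, dimnames = list(NULL, c("row", "col"))))
  }
  second <- s$nxt
  path_r <- c(start[1L], second[1L])
  path_c <- c(start[2L], second[2L])
  cur <- second; back <- s$back
  limit <- 8L * nr * nc
  repeat {
    s <- step_from(cur, back)
    if (is.null(s)) break
    if (all(s$nxt == start)) {
      la <- step_from(start, s$back)
      if (!is.null(la) && all(la$nxt == second)) break  # contour closed
    }
    path_r <- c(path_r, s$nxt[1L]); path_c <- c(path_c, s$nxt[2L])
    cur <- s$nxt; back <- s$back
    if (length(path_r) > limit) stopf("contour tracing failed to close")
  }
  cbind(row = path_r, col = path_c)
}

#' Arc length of a closed pixel contour: unit steps for axial moves,
#' sqrt(2) for diagonal moves (last point wraps to the first).
#' @noRd
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  dr <- abs(nxt[, 1L] - contour[, 1L])
  dc <- abs(nxt[, 2L] - contour[, 2L])
  sum(sqrt(dr^2 + dc^2))
}

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
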