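# Translation-only registration and compositing. Each tile gets a single
# (x, y) position; no affine or elastic terms (elastic alignment of real
# sections is delegated to dedicated tools and out of scope here).

#' Measure the translation offset between two overlapping tiles
#'
#' Matches a central block of the nominal overlap region of `tile_b` against
#' `tile_a` over integer shifts within `search_radius` of the nominal
#' relative offset, maximizing normalized cross-correlation, with quadratic
#' subpixel refinement. The measured offset is the position of `tile_b`'s
#' origin relative to `tile_a`'s.
#'
#' @param tile_a,tile_b Numeric matrices.
#' @param nominal_offset Numeric `(dx, dy)`: nominal origin of `tile_b`
#'   relative to `tile_a` (px).
#' @param search_radius Maximum deviation from nominal searched (px).
#' @param max_block Cap on the matching block side (px), for speed.
#' @return An object of class `pair_offset`: list with `measured` `(dx, dy)`,
#'   `nominal`, `shift` (= measured - nominal), `confidence` (peak NCC, NA
#'   if the overlap was unusable), `ok` (overlap >= 64 px and non-constant).
#' @export
pair_offset <- function(tile_a, tile_b, nominal_offset, search_radius = 8,
                        max_block = 256) {
  dx <- nominal_offset[1]; dy <- nominal_offset[2]
  ha <- nrow(tile_a); wa <- ncol(tile_a)
  hb <- nrow(tile_b); wb <- ncol(tile_b)
  rdx <- round(dx); rdy <- round(dy)
  # overlap rectangle in a's frame (0-based, half-open)
  x0 <- max(0, rdx); x1 <- min(wa, rdx + wb)
  y0 <- max(0, rdy); y1 <- min(ha, rdy + hb)
  fail <- function() structure(list(
    measured = c(dx = NA_real_, dy = NA_real_),
    nominal = c(dx = dx, dy = dy), shift = c(dx = NA_real_, dy = NA_real_),
    confidence = NA_real_, ok = FALSE), class = "pair_offset")
  if (x1 - x0 < 64 || y1 - y0 < 64) return(fail())
  # shrink by the search margin, then take a centred block up to max_block
  bx0 <- x0 + search_radius; bx1 <- x1 - search_radius
  by0 <- y0 + search_radius; by1 <- y1 - search_radius
  if (bx1 - bx0 < 16 || by1 - by0 < 16) return(fail())
  if (bx1 - bx0 > max_block) {
    c0 <- (bx0 + bx1 - max_block) %/% 2; bx0 <- c0; bx1 <- c0 + max_block
  }
  if (by1 - by0 > max_block) {
    c0 <- (by0 + by1 - max_block) %/% 2; by0 <- c0; by1 <- c0 + max_block
  }
  # template from b (its pixels in b coords), search window from a
  tpl <- tile_b[(by0 - rdy + 1):(by1 - rdy), (bx0 - rdx + 1):(bx1 - rdx)]
  wy <- (by0 - search_radius + 1):(by1 + search_radius)
  wx <- (bx0 - search_radius + 1):(bx1 + search_radius)
  if (min(wy) < 1 || min(wx) < 1 || max(wy) > ha || max(wx) > wa)
    return(fail())
  if (stats::sd(tpl) == 0) return(fail())
  sc <- .ncc_search(tpl, tile_a[wy, wx], search_radius)
  if (all(is.na(sc))) return(fail())
  pk <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)
  if (nrow(pk) > 1L) {
    ctr <- search_radius + 1L
    d2 <- (pk[, 1] - ctr)^2 + (pk[, 2] - ctr)^2
    pk <- pk[which.min(d2), , drop = FALSE]
  }
  iy <- pk[1, 1]; ix <- pk[1, 2]
  sy <- iy - (search_radius + 1L) + .quad_refine(sc[, ix], iy)
  sx <- ix - (search_radius + 1L) + .quad_refine(sc[iy, ], ix)
  # template found at +s relative to nominal means b sits at nominal + s
  measured <- c(dx = unname(rdx + sx), dy = unname(rdy + sy))
  structure(list(
    measured = measured, nominal = c(dx = dx, dy = dy),
    shift = measured - c(dx, dy),
    confidence = sc[iy, ix], ok = TRUE
  ), class = "pair_offset")
}

#' Solve global tile positions from pairwise offsets
#'
#' Weighted linear least squares: minimizes
#' `sum w_k || (p_b - p_a) - measured_k ||^2` over tile positions `p`, with
#' the anchor tile fixed at its nominal position. Weights are the pair
#' confidences (clamped to be positive). The x and y axes decouple and are
#' solved independently via the normal equations.
#'
#' @param pairs Data frame with columns `a`, `b` (tile ids), `dx`, `dy`
#'   (measured offsets of b relative to a), and optionally `confidence`.
#' @param anchor Tile id to fix.
#' @param anchor_position Numeric `(x, y)` for the anchor (default `c(0,0)`).
#' @return An object of class `tile_positions`: data frame `positions` (id,
#'   x, y), `residuals` per pair (dx, dy), `rms_residual`.
#' @export
solve_positions <- function(pairs, anchor, anchor_position = c(0, 0)) {
  stopifnot(is.data.frame(pairs), all(c("a", "b", "dx", "dy") %in% names(pairs)))
  ids <- sort(unique(c(pairs$a, pairs$b)))
  if (!anchor %in% ids) {
    if (length(ids) == 0) ids <- anchor
    else stop("anchor tile not present in pair graph", call. = FALSE)
  }
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  # connectivity check
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(pairs))) {
    i <- idx[[pairs$a[k]]]; j <- idx[[pairs$b[k]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n)
  queue <- idx[[anchor]]; seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  if (!all(seen))
    stop("pair graph is disconnected; unreachable tiles: ",
         paste(ids[!seen], collapse = ", "), call. = FALSE)
  w <- if ("confidence" %in% names(pairs))
    pmax(pairs$confidence, 1e-3) else rep(1, nrow(pairs))
  # normal equations of the weighted graph Laplacian, anchor eliminated
  A <- matrix(0, n, n); bx <- rep(0, n); by <- rep(0, n)
  for (k in seq_len(nrow(pairs))) {
    i <- idx[[pairs$a[k]]]; j <- idx[[pairs$b[k]]]
    A[i, i] <- A[i, i] + w[k]; A[j, j] <- A[j, j] + w[k]
    A[i, j] <- A[i, j] - w[k]; A[j, i] <- A[j, i] - w[k]
    bx[i] <- bx[i] - w[k] * pairs$dx[k]; bx[j] <- bx[j] + w[k] * pairs$dx[k]
    by[i] <- by[i] - w[k] * pairs$dy[k]; by[j] <- by[j] + w[k] * pairs$dy[k]
  }
  a_i <- idx[[anchor]]
  free <- setdiff(seq_len(n), a_i)
  px <- py <- rep(0, n)
  px[a_i] <- anchor_position[1]; py[a_i] <- anchor_position[2]
  if (length(free)) {
    Af <- A[free, free, drop = FALSE]
    px[free] <- solve(Af, bx[free] - A[free, a_i] * px[a_i])
    py[free] <- solve(Af, by[free] - A[free, a_i] * py[a_i])
  }
  res <- data.frame(
    a = pairs$a, b = pairs$b,
    rx = (px[idx[pairs$b]] - px[idx[pairs$a]]) - pairs$dx,
    ry = (py[idx[pairs$b]] - py[idx[pairs$a]]) - pairs$dy
  )
  structure(list(
    positions = data.frame(id = ids, x = px, y = py, stringsAsFactors = FALSE),
    anchor = anchor,
    residuals = res,
    rms_residual = sqrt(mean(res$rx^2 + res$ry^2))
  ), class = "tile_positions")
}

#' Composite tiles into a stitched raster
#'
#' Renders tiles at their solved positions (rounded to the integer canvas)
#' with either linear feather blending over a ramp from each tile's border
#' or first-wins placement. Canvas size is the bounding box of the placed
#' tiles.
#'
#' @param tiles Named list of numeric matrices.
#' @param solution A [solve_positions()] result (ids must match tile names).
#' @param blend `"feather"` (default) or `"first"`.
#' @param feather_px Feather ramp width (px); defaults to 1/8 of the tile
#'   side.
#' @return List with `raster` (stitched matrix) and `origin` `(x, y)` of the
#'   canvas in solution coordinates.
#' @export
composite <- function(tiles, solution, blend = c("feather", "first"),
                      feather_px = NULL) {
  blend <- match.arg(blend)
  stopifnot(inherits(solution, "tile_positions"))
  pos <- solution$positions
  pos <- pos[pos$id %in% names(tiles), , drop = FALSE]
  if (nrow(pos) == 0) stop("no tiles to composite", call. = FALSE)
  xs <- round(pos$x); ys <- round(pos$y)
  sizes <- vapply(tiles[pos$id], dim, integer(2))
  x0 <- min(xs); y0 <- min(ys)
  W <- max(xs + sizes[2, ]) - x0
  H <- max(ys + sizes[1, ]) - y0
  num <- matrix(0, H, W)
  if (blend == "feather") {
    den <- matrix(0, H, W)
    for (k in seq_len(nrow(pos))) {
      tile <- tiles[[pos$id[k]]]
      th <- nrow(tile); tw <- ncol(tile)
      fp <- if (is.null(feather_px)) max(1L, min(th, tw) %/% 8L) else feather_px
      wy <- pmin(pmin(seq_len(th), th + 1 - seq_len(th)), fp) / fp
      wx <- pmin(pmin(seq_len(tw), tw + 1 - seq_len(tw)), fp) / fp
      wgt <- outer(wy, wx, pmin)
      ry <- (ys[k] - y0) + seq_len(th)
      rx <- (xs[k] - x0) + seq_len(tw)
      num[ry, rx] <- num[ry, rx] + tile * wgt
      den[ry, rx] <- den[ry, rx] + wgt
    }
    num <- num / pmax(den, .Machine$double.eps)
  } else {
    filled <- matrix(FALSE, H, W)
    for (k in seq_len(nrow(pos))) {
      tile <- tiles[[pos$id[k]]]
      ry <- (ys[k] - y0) + seq_len(nrow(tile))
      rx <- (xs[k] - x0) + seq_len(ncol(tile))
      sub <- !filled[ry, rx]
      block <- num[ry, rx]
      block[sub] <- tile[sub]
      num[ry, rx] <- block
      filled[ry, rx] <- TRUE
    }
  }
  list(raster = num, origin = c(x = x0, y = y0))
}

#' Measure all adjacent-tile offsets of an acquisition
#'
#' Enumerates tile pairs whose nominal footprints overlap by at least 64 px
#' in both dimensions and measures each offset with [pair_offset()].
#'
#' @param acq An [acquire_montage()] result.
#' @param search_radius Search radius passed to [pair_offset()] (should
#'   exceed the injected stage jitter).
#' @return Data frame with columns `a`, `b`, `dx`, `dy` (measured), `dx_nom`,
#'   `dy_nom`, `confidence`, `ok`.
#' @export
montage_pairs <- function(acq, search_radius = 8) {
  stopifnot(inherits(acq, "acquisition_result"))
  m <- acq$manifest
  T <- acq$plan$spec$tile_px
  out <- list()
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
    ddx <- m$nominal_x_px[j] - m$nominal_x_px[i]
    ddy <- m$nominal_y_px[j] - m$nominal_y_px[i]
    if (T - abs(ddx) < 64 || T - abs(ddy) < 64) next
    po <- pair_offset(acq$tiles[[m$name[i]]], acq$tiles[[m$name[j]]],
                      c(ddx, ddy), search_radius)
    out[[length(out) + 1L]] <- data.frame(
      a = m$name[i], b = m$name[j],
      dx = po$measured[["dx"]], dy = po$measured[["dy"]],
      dx_nom = ddx, dy_nom = ddy,
      confidence = po$confidence, ok = po$ok,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0)
    stop("no tile pairs overlap by >= 64 px; increase tile size or overlap",
         call. = FALSE)
  do.call(rbind, out)
}

#' Stitch a simulated acquisition end to end
#'
#' Measures adjacent-pair offsets, solves global positions anchored at the
#' centre subtile of the first (top-left) supertile — the undeflected,
#' best-quality tile — and composites the montage.
#'
#' @param acq An [acquire_montage()] result.
#' @param search_radius Passed to [montage_pairs()].
#' @param blend Passed to [composite()].
#' @return List with `solution` ([solve_positions()] result), `pairs`, and
#'   `mosaic` ([composite()] result).
#' @export
stitch_montage <- function(acq, search_radius = 8,
                           blend = c("feather", "first")) {
  m <- acq$manifest
  pairs <- montage_pairs(acq, search_radius)
  pairs <- pairs[pairs$ok, , drop = FALSE]
  ctr <- m$name[m$supertile == 1 & m$subtile_i == 0 & m$subtile_j == 0][1]
  anchor_pos <- c(m$nominal_x_px[m$name == ctr], m$nominal_y_px[m$name == ctr])
  sol <- solve_positions(pairs, ctr, anchor_pos)
  list(solution = sol, pairs = pairs,
       mosaic = composite(acq$tiles, sol, match.arg(blend)))
}
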