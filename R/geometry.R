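#' Supertile geometry specification
#'
#' Defines the subtile grid acquired by beam deflection at one stage position:
#' tile size, grid dimensions, and the overlap fraction between neighbouring
#' subtiles. Derived quantities (overlap in pixels, pitch, stitched extent)
#' follow the usual tiling arithmetic: with `n` tiles of side `T` and overlap
#' `v` pixels, the stitched extent per axis is `n*T - (n-1)*v`.
#'
#' @param tile_px Pixels per (square) camera tile side. Must be >= 1.
#' @param grid_rows,grid_cols Subtile grid dimensions, each >= 1.
#' @param intra_overlap_frac Fraction of a tile side shared by neighbouring
#'   subtiles, in `[0, 1)`. The pixel overlap is `round(frac * tile_px)`,
#'   so 15% of a 6000-px tile gives 900 px.
#' @return An object of class `supertile_spec`: a list with `tile_px`,
#'   `grid_rows`, `grid_cols`, `intra_overlap_frac`, `intra_overlap_px`,
#'   `pitch_px`, `extent_rows_px`, `extent_cols_px`.
#' @examples
#' spec <- make_supertile_spec(6000, 3, 3, 0.15)
#' spec$intra_overlap_px  # 900
#' spec$extent_rows_px    # 16200
#' @export
make_supertile_spec <- function(tile_px, grid_rows, grid_cols,
                                intra_overlap_frac = 0.15) {
  if (!is.numeric(tile_px) || length(tile_px) != 1L || tile_px < 1)
    stop("`tile_px` must be a single number >= 1", call. = FALSE)
  if (grid_rows < 1 || grid_cols < 1)
    stop("grid dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(intra_overlap_frac) || intra_overlap_frac < 0 ||
      intra_overlap_frac >= 1)
    stop("`intra_overlap_frac` must be in [0, 1)", call. = FALSE)
  tile_px <- as.integer(round(tile_px))
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  ov <- as.integer(round(intra_overlap_frac * tile_px))
  pitch <- tile_px - ov
  extent <- function(n) (n - 1L) * pitch + tile_px
  structure(list(
    tile_px = tile_px,
    grid_rows = grid_rows,
    grid_cols = grid_cols,
    intra_overlap_frac = intra_overlap_frac,
    intra_overlap_px = ov,
    pitch_px = pitch,
    extent_rows_px = extent(grid_rows),
    extent_cols_px = extent(grid_cols)
  ), class = "supertile_spec")
}

#' @export
print.supertile_spec <- function(x, ...) {
  cat(sprintf(
    "<supertile_spec> %dx%d subtiles of %d px, overlap %d px (%.0f%%)\n",
    x$grid_rows, x$grid_cols, x$tile_px, x$intra_overlap_px,
    100 * x$intra_overlap_frac))
  cat(sprintf("  pitch %d px, stitched extent %d x %d px\n",
              x$pitch_px, x$extent_rows_px, x$extent_cols_px))
  invisible(x)
}

#' Spiral deflection order over a subtile grid
#'
#' The acquisition sequence starts at the on-axis centre subtile (the tile
#' with the best image quality, acquired undeflected) and proceeds outward
#' ring by ring. Within each square (Chebyshev-radius) ring the order starts
#' at offset `(+1, 0)` relative to the centre and proceeds counter-clockwise;
#' this chirality is fixed by convention. Offsets are `(i, j)` with `i` the
#' column (east-positive) and `j` the row (north-positive) index. For
#' even-sized grids the centre is the tile at index `floor(dim / 2)` (0-based),
#' so rings clip asymmetrically at the grid edge.
#'
#' @param grid_rows,grid_cols Subtile grid dimensions, each >= 1.
#' @return An object of class `deflection_pattern`: a list with `order`, an
#'   integer matrix of `(i, j)` offsets (one row per subtile, `(0,0)` first),
#'   and `grid_rows`, `grid_cols`.
#' @examples
#' spiral_order(3, 3)$order
#' @export
spiral_order <- function(grid_rows, grid_cols) {
  if (grid_rows < 1 || grid_cols < 1)
    stop("grid dimensions must be >= 1", call. = FALSE)
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  cr <- grid_rows %/% 2L  # centre row index (0-based)
  cc <- grid_cols %/% 2L
  # i = column offset in [-cc, grid_cols-1-cc]; j = row offset likewise
  is <- seq.int(-cc, grid_cols - 1L - cc)
  js <- seq.int(-cr, grid_rows - 1L - cr)
  all_off <- expand.grid(i = is, j = js)
  ring <- pmax(abs(all_off$i), abs(all_off$j))
  ang <- atan2(all_off$j, all_off$i) %% (2 * pi)
  ord <- order(ring, ang)
  m <- as.matrix(all_off[ord, , drop = FALSE])
  dimnames(m) <- list(NULL, c("i", "j"))
  structure(list(order = m, grid_rows = grid_rows, grid_cols = grid_cols),
            class = "deflection_pattern")
}

#' Deflection offsets in pixels for a pattern
#'
#' @param pattern A `deflection_pattern`.
#' @param pitch_px Subtile centre-to-centre pitch in pixels.
#' @return Numeric matrix of `(x, y)` pixel offsets from the optic axis.
#' @export
deflection_offsets_px <- function(pattern, pitch_px) {
  pattern$order * pitch_px
}

#' Plan a section-scale montage of supertiles
#'
#' Computes the regular stage grid of supertiles needed to cover a
#' rectangular region of interest. The section extent in pixels is
#' `ceiling(size_nm / pixel_size_nm)`; the supertile stage step is the
#' supertile extent minus the inter-supertile overlap; the number of
#' supertiles per axis uses `ceiling`, so the montage always covers (and
#' typically overshoots) the requested region at the far edges.
#'
#' Coordinates are 0-based with origin at the ROI top-left; `x` indexes
#' columns and `y` rows; a tile occupies the half-open pixel interval
#' `[x, x + w)`.
#'
#' @param section_width_nm,section_height_nm Region of interest size in nm.
#' @param pixel_size_nm Pixel size in nm (e.g. 3 or 4).
#' @param spec A [make_supertile_spec()] object.
#' @param inter_overlap_px Overlap between neighbouring supertiles in pixels
#'   (default 600). Must be smaller than the supertile extent.
#' @return An object of class `montage_plan`: a list with the input
#'   parameters plus `section_width_px`, `section_height_px`, `step_x_px`,
#'   `step_y_px`, `n_rows`, `n_cols`, `n_supertiles`, `n_tiles`,
#'   `stage_positions` (data frame: row, col, x_px, y_px, x_nm, y_nm),
#'   `subtile_order` (spiral [spiral_order()] pattern), and
#'   `montage_extent_px` = `c(width, height)` of the stitched montage.
#' @examples
#' spec <- make_supertile_spec(6000, 3, 3, 0.15)
#' plan <- plan_montage(1e6, 1e6, 3.0, spec, 600)
#' plan$n_supertiles  # 484
#' plan$n_tiles       # 4356
#' @export
plan_montage <- function(section_width_nm, section_height_nm, pixel_size_nm,
                         spec, inter_overlap_px = 600L) {
  stopifnot(inherits(spec, "supertile_spec"))
  if (section_width_nm <= 0 || section_height_nm <= 0 || pixel_size_nm <= 0)
    stop("sizes and pixel size must be positive", call. = FALSE)
  ext_x <- spec$extent_cols_px
  ext_y <- spec$extent_rows_px
  if (inter_overlap_px >= min(ext_x, ext_y))
    stop("`inter_overlap_px` must be smaller than the supertile extent ",
         "(step would be <= 0)", call. = FALSE)
  inter_overlap_px <- as.integer(round(inter_overlap_px))
  sec_w <- as.integer(ceiling(section_width_nm / pixel_size_nm))
  sec_h <- as.integer(ceiling(section_height_nm / pixel_size_nm))
  step_x <- ext_x - inter_overlap_px
  step_y <- ext_y - inter_overlap_px
  n_cols <- max(1L, as.integer(ceiling((sec_w - ext_x) / step_x)) + 1L)
  n_rows <- max(1L, as.integer(ceiling((sec_h - ext_y) / step_y)) + 1L)
  # serpentine stage order: even rows left-to-right, odd rows right-to-left
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- unlist(lapply(seq_len(n_rows) - 1L, function(r) {
    cs <- seq_len(n_cols) - 1L
    if (r %% 2L == 1L) rev(cs) else cs
  }))
  pos <- data.frame(
    row = rows, col = cols,
    x_px = cols * step_x, y_px = rows * step_y
  )
  pos$x_nm <- pos$x_px * pixel_size_nm
  pos$y_nm <- pos$y_px * pixel_size_nm
  n_st <- n_rows * n_cols
  structure(list(
    pixel_size_nm = pixel_size_nm,
    section_width_px = sec_w,
    section_height_px = sec_h,
    spec = spec,
    inter_overlap_px = inter_overlap_px,
    step_x_px = step_x,
    step_y_px = step_y,
    n_rows = n_rows,
    n_cols = n_cols,
    n_supertiles = n_st,
    n_tiles = n_st * spec$grid_rows * spec$grid_cols,
    stage_positions = pos,
    subtile_order = spiral_order(spec$grid_rows, spec$grid_cols),
    montage_extent_px = c(
      width = (n_cols - 1L) * step_x + ext_x,
      height = (n_rows - 1L) * step_y + ext_y
    )
  ), class = "montage_plan")
}

#' @export
print.montage_plan <- function(x, ...) {
  cat(sprintf("<montage_plan> %.1f x %.1f um at %g nm/px\n",
              x$section_width_px * x$pixel_size_nm / 1e3,
              x$section_height_px * x$pixel_size_nm / 1e3, x$pixel_size_nm))
  cat(sprintf("  %d x %d supertiles = %d (%d tiles), step %d/%d px\n",
              x$n_rows, x$n_cols, x$n_supertiles, x$n_tiles,
              x$step_y_px, x$step_x_px))
  cat(sprintf("  montage extent %d x %d px\n",
              x$montage_extent_px[["width"]], x$montage_extent_px[["height"]]))
  invisible(x)
}

#' Unique (overlap-deduplicated) pixel count of a montage
#'
#' Overlap pixels are counted once: the stitched montage extent per axis is
#' `(n - 1) * step + supertile_extent`, and the unique count is the product
#' of the two extents.
#'
#' @param plan A [plan_montage()] object.
#' @return Number of unique pixels (numeric, may exceed 2^31).
#' @export
montage_unique_pixels <- function(plan) {
  stopifnot(inherits(plan, "montage_plan"))
  as.numeric(plan$montage_extent_px[["width"]]) *
    as.numeric(plan$montage_extent_px[["height"]])
}

#' Total acquired pixel count of a montage (overlaps included)
#'
#' @param plan A [plan_montage()] object.
#' @return `n_tiles * tile_px^2` (numeric).
#' @export
montage_total_pixels <- function(plan) {
  stopifnot(inherits(plan, "montage_plan"))
  as.numeric(plan$n_tiles) * as.numeric(plan$spec$tile_px)^2
}

# corner test: does tile centred at (i, j) * pitch fit entirely inside the
# circular beam boundary? All four corners must lie inside or on the circle.
.tile_fits <- function(i, j, radius_px, tile_px, pitch_px) {
  half <- tile_px / 2
  cx <- abs(i * pitch_px) + half
  cy <- abs(j * pitch_px) + half
  sqrt(cx^2 + cy^2) <= radius_px
}

#' Maximum rectangle of full subtiles inside the beam boundary
#'
#' Beam deflection is limited by a circular boundary within the microscope:
#' beyond a radius from the optic axis, tiles are obstructed or too dim.
#' A subtile grid is anchored with one tile centred on the axis; a tile
#' "fits" iff all four of its corners lie inside (or on) the circle. This
#' returns the contiguous axis-aligned rectangle of fitting tiles with the
#' largest count, ties broken toward the squarer shape (smaller
#' `|rows - cols|`, then fewer rows).
#'
#' @param boundary_radius_px Boundary circle radius in pixels (> 0).
#' @param tile_px Tile side in pixels.
#' @param pitch_px Subtile pitch in pixels.
#' @return List with `rows`, `cols`, `count`. `count` is 0 when even the
#'   centre tile does not fit.
#' @export
max_full_tiles_rect <- function(boundary_radius_px, tile_px, pitch_px) {
  if (boundary_radius_px <= 0) stop("radius must be > 0", call. = FALSE)
  if (!.tile_fits(0, 0, boundary_radius_px, tile_px, pitch_px))
    return(list(rows = 0L, cols = 0L, count = 0L))
  k <- as.integer(ceiling(boundary_radius_px / pitch_px)) + 1L
  idx <- seq.int(-k, k)
  fits <- outer(idx, idx, function(i, j)
    .tile_fits(i, j, boundary_radius_px, tile_px, pitch_px))
  best <- list(rows = 1L, cols = 1L, count = 1L)
  n <- length(idx)
  # brute force over all contiguous rectangles of the candidate grid
  for (r0 in seq_len(n)) for (r1 in r0:n) {
    # rows r0..r1 (j axis); find maximal column runs where all rows fit
    colok <- apply(fits[, r0:r1, drop = FALSE], 1L, all)
    if (!any(colok)) next
    runs <- rle(colok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    nr <- r1 - r0 + 1L
    for (q in which(runs$values)) {
      nc <- runs$lengths[q]
      cnt <- nr * nc
      better <- cnt > best$count ||
        (cnt == best$count &&
           abs(nr - nc) < abs(best$rows - best$cols))
      if (better) best <- list(rows = nr, cols = nc, count = cnt)
    }
  }
  best
}

#' Maximum cruciform set of full subtiles inside the beam boundary
#'
#' All grid tiles whose four corners lie inside the circular boundary. The
#' fitting set is symmetric and convex by row, giving the cruciform shapes
#' seen when packing the boundary as densely as possible.
#'
#' @inheritParams max_full_tiles_rect
#' @return List with `count` and `positions`, an integer matrix of fitting
#'   `(i, j)` grid indices.
#' @export
max_full_tiles_cruciform <- function(boundary_radius_px, tile_px, pitch_px) {
  if (boundary_radius_px <= 0) stop("radius must be > 0", call. = FALSE)
  k <- as.integer(ceiling(boundary_radius_px / pitch_px)) + 1L
  grid <- expand.grid(i = seq.int(-k, k), j = seq.int(-k, k))
  ok <- .tile_fits(grid$i, grid$j, boundary_radius_px, tile_px, pitch_px)
  pos <- as.matrix(grid[ok, , drop = FALSE])
  dimnames(pos) <- list(NULL, c("i", "j"))
  list(count = nrow(pos), positions = pos)
}

#' Serialize a montage plan to JSON
#'
#' @param plan A [plan_montage()] object.
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_plan_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "montage_plan"))
  obj <- list(
    pixel_size_nm = plan$pixel_size_nm,
    section_px = c(plan$section_width_px, plan$section_height_px),
    spec = unclass(plan$spec),
    inter_overlap_px = plan$inter_overlap_px,
    step_px = c(plan$step_x_px, plan$step_y_px),
    n_rows = plan$n_rows,
    n_cols = plan$n_cols,
    n_supertiles = plan$n_supertiles,
    n_tiles = plan$n_tiles,
    stage_positions = plan$stage_positions,
    subtile_order = plan$subtile_order$order,
    montage_extent_px = as.list(plan$montage_extent_px)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a montage plan from JSON
#'
#' @param path Path to a JSON file written by [write_plan_json()].
#' @return A `montage_plan` object.
#' @export
read_plan_json <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  spec <- make_supertile_spec(obj$spec$tile_px, obj$spec$grid_rows,
                              obj$spec$grid_cols, obj$spec$intra_overlap_frac)
  plan_montage(obj$section_px[1] * obj$pixel_size_nm,
               obj$section_px[2] * obj$pixel_size_nm,
               obj$pixel_size_nm, spec, obj$inter_overlap_px)
}
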