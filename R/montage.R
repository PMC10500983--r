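#' Electrode grid specification
#'
#' A `grid_spec` describes a rectangular lattice of surface electrodes:
#' `rows` x `cols` positions spaced by the interelectrode distance (IED)
#' `ied` mm, with an optional set of missing lattice positions (adhesive
#' grids typically omit one corner electrode per sub-grid). Rows run along
#' the muscle fiber (axial, x) direction, columns along the transverse (y)
#' direction. Electrode order is row-major over present electrodes.
#'
#' @param rows,cols Lattice dimensions (counts, >= 1).
#' @param ied Interelectrode distance, mm (> 0).
#' @param missing Integer matrix with columns `(row, col)` of 0-based
#'   lattice positions without an electrode, or `NULL`.
#' @param origin Numeric length-2, the `(x, y)` position in mm of lattice
#'   site `(0, 0)`. Defaults to centering the lattice on the origin, which
#'   places a simulated grid centered over the muscle in the transverse
#'   direction.
#' @return An object of class `grid_spec` with fields `rows`, `cols`,
#'   `ied`, `missing`, `origin`, plus derived `n` (electrode count) and
#'   `span` (covered extent, mm, `(rows-1)*ied` by `(cols-1)*ied`).
#' @examples
#' g <- grid_spec(13, 5, ied = 4, missing = rbind(c(0, 0)))
#' g$n  # 64
#' @export
grid_spec <- function(rows, cols, ied, missing = NULL, origin = NULL) {
  stopifnot(length(rows) == 1, length(cols) == 1, rows >= 1, cols >= 1)
  if (!is.numeric(ied) || length(ied) != 1 || ied <= 0)
    stop("'ied' must be a single positive number (mm)")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.null(missing)) {
    missing <- matrix(integer(0), ncol = 2)
  } else {
    missing <- matrix(as.integer(missing), ncol = 2)
    missing <- unique(missing)
    if (any(missing[, 1] < 0 | missing[, 1] >= rows |
            missing[, 2] < 0 | missing[, 2] >= cols))
      stop("missing positions must lie within the lattice")
  }
  colnames(missing) <- c("row", "col")
  if (is.null(origin))
    origin <- -c((rows - 1L), (cols - 1L)) * ied / 2
  stopifnot(length(origin) == 2)
  structure(list(
    rows = rows, cols = cols, ied = ied, missing = missing,
    origin = as.numeric(origin),
    n = rows * cols - nrow(missing),
    span = c((rows - 1L) * ied, (cols - 1L) * ied)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Electrode grid: %d x %d lattice, IED %g mm, %d electrodes (%d missing)\n",
    x$rows, x$cols, x$ied, x$n, nrow(x$missing)))
  cat(sprintf("  span %g x %g mm (%.1f cm^2 covered)\n",
              x$span[1], x$span[2], grid_area(x)))
  invisible(x)
}

#' Covered grid area in cm^2
#'
#' The rectangular extent spanned by the lattice,
#' `(rows - 1) * (cols - 1) * ied^2`, in cm^2.
#' @param grid A [grid_spec].
#' @return Area in cm^2.
#' @export
grid_area <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  (grid$rows - 1L) * (grid$cols - 1L) * grid$ied^2 / 100
}

#' Electrode positions of a grid
#'
#' @param grid A [grid_spec].
#' @return A data.frame with one row per present electrode, in electrode
#'   (row-major) order: `row`, `col` (0-based lattice indices), `x`, `y`
#'   (mm; x axial, y transverse).
#' @export
electrode_positions <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rc <- expand.grid(col = seq_len(grid$cols) - 1L,
                    row = seq_len(grid$rows) - 1L)[, c("row", "col")]
  if (nrow(grid$missing) > 0) {
    key <- rc$row * grid$cols + rc$col
    mkey <- grid$missing[, 1] * grid$cols + grid$missing[, 2]
    rc <- rc[!(key %in% mkey), , drop = FALSE]
  }
  data.frame(row = rc$row, col = rc$col,
             x = grid$origin[1] + rc$row * grid$ied,
             y = grid$origin[2] + rc$col * grid$ied,
             row.names = NULL)
}

#' @export
plot.grid_spec <- function(x, ...) {
  pos <- electrode_positions(x)
  plot(pos$x, pos$y, asp = 1, pch = 21, bg = "grey70",
       xlab = "axial x (mm)", ylab = "transverse y (mm)",
       main = sprintf("%d electrodes, IED %g mm", x$n, x$ied), ...)
  invisible(x)
}

#' The composite 256-electrode grid (4-mm IED)
#'
#' Four side-by-side 13 x 5 adhesive grids of 64 electrodes each (one
#' corner electrode missing per grid) form a 26 x 10 lattice at 4-mm IED:
#' 256 electrodes covering 10 x 3.6 cm. The corner assignment of the four
#' missing electrodes is the unique same-orientation placement for which
#' uniform decimation by 2/3/4 yields 64/35/20 electrodes and centered
#' 8x8 / 7x5 / 5x4 crops yield 63/34/19.
#'
#' @return A [grid_spec] with 256 electrodes.
#' @export
composite_grid <- function() {
  grid_spec(26, 10, ied = 4,
            missing = rbind(c(0, 0), c(0, 5), c(13, 0), c(13, 5)))
}

#' The ultradense 256-electrode grid (2-mm IED)
#'
#' A 26 x 10 lattice at 2-mm IED with a missing electrode in each lattice
#' corner: 256 electrodes covering 5 x 1.8 cm.
#'
#' @return A [grid_spec] with 256 electrodes.
#' @export
ultradense_grid <- function() {
  grid_spec(26, 10, ied = 2,
            missing = rbind(c(0, 0), c(0, 9), c(25, 0), c(25, 9)))
}

#' Down-sample a grid by discarding rows and columns
#'
#' Keeps lattice rows congruent to `phase[1]` and columns congruent to
#' `phase[2]` modulo `factor`, multiplying the IED by `factor`. Missing
#' positions that fall on the kept sub-lattice are inherited.
#'
#' @param grid A [grid_spec].
#' @param factor Integer decimation factor >= 1.
#' @param phase Integer length-2 `(row, col)` decimation phase, default
#'   `c(0, 0)`.
#' @return A [grid_spec].
#' @examples
#' decimate_grid(composite_grid(), 2)$n  # 64
#' @export
decimate_grid <- function(grid, factor, phase = c(0L, 0L)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be an integer >= 1")
  factor <- as.integer(factor)
  phase <- as.integer(phase) %% factor
  keep_r <- seq.int(phase[1], grid$rows - 1L, by = factor)
  keep_c <- seq.int(phase[2], grid$cols - 1L, by = factor)
  miss <- grid$missing
  keep <- miss[, 1] %in% keep_r & miss[, 2] %in% keep_c
  new_miss <- cbind((miss[keep, 1] - phase[1]) %/% factor,
                    (miss[keep, 2] - phase[2]) %/% factor)
  grid_spec(length(keep_r), length(keep_c), ied = grid$ied * factor,
            missing = if (nrow(new_miss)) new_miss else NULL,
            origin = grid$origin + phase * grid$ied)
}

#' Crop a grid to a centered window
#'
#' Discards peripheral electrodes, keeping a centered `keep_rows` x
#' `keep_cols` window (margins rounded down). Missing positions inside
#' the window are inherited.
#'
#' @param grid A [grid_spec].
#' @param keep_rows,keep_cols Window dimensions (<= grid dimensions).
#' @return A [grid_spec].
#' @examples
#' crop_center(composite_grid(), 8, 8)$n  # 63
#' @export
crop_center <- function(grid, keep_rows, keep_cols) {
  stopifnot(inherits(grid, "grid_spec"))
  keep_rows <- as.integer(keep_rows); keep_cols <- as.integer(keep_cols)
  if (keep_rows > grid$rows || keep_cols > grid$cols)
    stop("crop window larger than grid")
  r0 <- (grid$rows - keep_rows) %/% 2L
  c0 <- (grid$cols - keep_cols) %/% 2L
  miss <- grid$missing
  keep <- miss[, 1] >= r0 & miss[, 1] < r0 + keep_rows &
          miss[, 2] >= c0 & miss[, 2] < c0 + keep_cols
  new_miss <- cbind(miss[keep, 1] - r0, miss[keep, 2] - c0)
  grid_spec(keep_rows, keep_cols, ied = grid$ied,
            missing = if (nrow(new_miss)) new_miss else NULL,
            origin = grid$origin + c(r0, c0) * grid$ied)
}

#' Split a composite grid into its four quadrant sub-grids
#'
#' A composite montage assembled from 2 x 2 physical sub-grids (e.g., four
#' 13 x 5 grids of 64 electrodes) is split back into the four sub-grids.
#' Each returned [grid_spec] carries an attribute `channel_map`: the
#' indices of its electrodes within the parent's electrode order, so that
#' child channel k corresponds to parent channel `channel_map[k]`.
#'
#' @param grid A [grid_spec] with even `rows` and `cols`.
#' @return A list of four [grid_spec] objects (row-block major order).
#' @export
split_quadrants <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$rows %% 2L != 0L || grid$cols %% 2L != 0L)
    stop("grid is not a 2 x 2 composite of sub-grids")
  hr <- grid$rows %/% 2L; hc <- grid$cols %/% 2L
  parent <- electrode_positions(grid)
  pkey <- parent$row * grid$cols + parent$col
  quads <- list()
  for (qr in 0:1) for (qc in 0:1) {
    r0 <- qr * hr; c0 <- qc * hc
    miss <- grid$missing
    keep <- miss[, 1] >= r0 & miss[, 1] < r0 + hr &
            miss[, 2] >= c0 & miss[, 2] < c0 + hc
    new_miss <- cbind(miss[keep, 1] - r0, miss[keep, 2] - c0)
    g <- grid_spec(hr, hc, ied = grid$ied,
                   missing = if (nrow(new_miss)) new_miss else NULL,
                   origin = grid$origin + c(r0, c0) * grid$ied)
    cpos <- electrode_positions(g)
    ckey <- (cpos$row + r0) * grid$cols + (cpos$col + c0)
    attr(g, "channel_map") <- match(ckey, pkey)
    quads[[length(quads) + 1L]] <- g
  }
  quads
}

#' Build a simulated rectangular grid of given size and IED
#'
#' Constructs the lattice whose spans are closest to `length_cm` x
#' `width_cm` without exceeding them, at the given IED, centered on the
#' origin (i.e., centered over the muscle in the transverse direction).
#'
#' @param length_cm Axial extent, cm.
#' @param ied_mm Interelectrode distance, mm.
#' @param width_cm Transverse extent, cm (default 3.6).
#' @return A [grid_spec].
#' @examples
#' g <- simulated_grid(10, 4)    # 26 x 10, 36 cm^2
#' grid_area(g)
#' @export
simulated_grid <- function(length_cm, ied_mm, width_cm = 3.6) {
  stopifnot(length_cm > 0, width_cm > 0, ied_mm > 0)
  rows <- floor(length_cm * 10 / ied_mm) + 1L
  cols <- floor(width_cm * 10 / ied_mm) + 1L
  if (rows < 2L || cols < 2L)
    stop("'ied_mm' too large: fewer than 2 electrodes fit along an axis")
  grid_spec(rows, cols, ied = ied_mm)
}

# 1-D interpolation matrix mapping values at `nodes` to values at `targets`
# via natural cubic splines (linear when only 2-3 nodes). Interpolation is
# linear in the node values, so the map is a matrix.
interp_matrix_1d <- function(nodes, targets) {
  n <- length(nodes)
  M <- matrix(0, length(targets), n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    M[, i] <- if (n >= 4) {
      spline(nodes, e, xout = targets, method = "natural")$y
    } else {
      approx(nodes, e, xout = targets, rule = 2)$y
    }
  }
  M
}

#' Spatially interpolate multichannel EMG onto a denser grid
#'
#' Per-sample 2-D spline interpolation (tensor product of natural cubic
#' splines along the two lattice axes) of channel values recorded on
#' `from_grid` onto the electrode positions of `to_grid`. Values at source
#' electrode positions are preserved exactly. Missing source electrodes
#' are first imputed by spline interpolation along their lattice row.
#'
#' @param emg Numeric matrix `channels x samples` (channels in
#'   `from_grid` electrode order) or a [synthetic_emg] object.
#' @param from_grid,to_grid [grid_spec] objects; `to_grid` positions
#'   should lie within the span of `from_grid`.
#' @return A numeric matrix `to_grid$n x samples`.
#' @export
spatial_interpolate <- function(emg, from_grid, to_grid) {
  if (inherits(emg, "synthetic_emg")) emg <- emg$data
  stopifnot(is.matrix(emg), inherits(from_grid, "grid_spec"),
            inherits(to_grid, "grid_spec"))
  if (nrow(emg) != from_grid$n)
    stop("channel count does not match 'from_grid'")
  if (from_grid$n < 4L)
    stop("need at least 4 source electrodes")
  rx <- from_grid$origin[1] + (seq_len(from_grid$rows) - 1L) * from_grid$ied
  cy <- from_grid$origin[2] + (seq_len(from_grid$cols) - 1L) * from_grid$ied
  # scatter present channels onto the full lattice (full x samples)
  pos <- electrode_positions(from_grid)
  full <- matrix(0, from_grid$rows * from_grid$cols, ncol(emg))
  idx <- pos$row * from_grid$cols + pos$col + 1L
  full[idx, ] <- emg
  if (nrow(from_grid$missing) > 0) {
    for (k in seq_len(nrow(from_grid$missing))) {
      mr <- from_grid$missing[k, 1]; mc <- from_grid$missing[k, 2]
      have <- pos$row == mr
      w <- interp_matrix_1d(cy[pos$col[have] + 1L], cy[mc + 1L])
      full[mr * from_grid$cols + mc + 1L, ] <- w %*% emg[have, , drop = FALSE]
    }
  }
  tpos <- electrode_positions(to_grid)
  Mr <- interp_matrix_1d(rx, tpos$x)   # to_n x rows
  Mc <- interp_matrix_1d(cy, tpos$y)   # to_n x cols
  # tensor-product weights: out[e, ] = sum_{r,c} Mr[e,r] Mc[e,c] full[r*cols+c, ]
  W <- matrix(0, nrow(tpos), from_grid$rows * from_grid$cols)
  for (r in seq_len(from_grid$rows))
    W[, (r - 1L) * from_grid$cols + seq_len(from_grid$cols)] <-
      Mr[, r] * Mc
  W %*% full
}
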