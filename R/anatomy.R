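# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Layered cylindrical muscle geometry
#'
#' The muscle is a cylinder of radius `muscle_radius` mm with parallel
#' fibers along its axis, separated from the detection surface by a
#' subcutaneous fat layer and a skin layer. The outer (detection) surface
#' lies at radius `muscle_radius + fat_thickness + skin_thickness`.
#'
#' @param muscle_radius Muscle radius, mm (default 25.4).
#' @param fat_thickness Subcutaneous layer thickness, mm (default 5).
#' @param skin_thickness Skin layer thickness, mm (default 1).
#' @param fiber_length Fiber length, mm (default 60, the fascicle length
#'   scale of a muscle like the tibialis anterior); end-plates sit at the
#'   fiber midpoint with a small axial scatter (see [build_pool]).
#' @return An object of class `muscle_geometry`.
#' @export
muscle_geometry <- function(muscle_radius = 25.4, fat_thickness = 5,
                            skin_thickness = 1, fiber_length = 60) {
  stopifnot(muscle_radius > 0, fat_thickness > 0, skin_thickness > 0,
            fiber_length > 0)
  structure(list(muscle_radius = muscle_radius,
                 fat_thickness = fat_thickness,
                 skin_thickness = skin_thickness,
                 fiber_length = fiber_length,
                 outer_radius = muscle_radius + fat_thickness + skin_thickness),
            class = "muscle_geometry")
}

#' @export
print.muscle_geometry <- function(x, ...) {
  cat(sprintf(
    "Cylindrical muscle: radius %g mm + %g mm fat + %g mm skin (outer %g mm), fibers %g mm\n",
    x$muscle_radius, x$fat_thickness, x$skin_thickness, x$outer_radius,
    x$fiber_length))
  invisible(x)
}

#' Farthest-point sampling of motor-unit territory centers
#'
#' Places `count` territory centers in the muscle cross-section disc by
#' greedy farthest-point sampling over a dense seeded candidate set: the
#' first center is drawn uniformly; each subsequent center is the
#' candidate maximizing its minimum distance to all previously placed
#' centers. This yields a random yet even spatial distribution of
#' territories.
#'
#' @param count Number of centers (>= 1).
#' @param muscle_radius Disc radius, mm.
#' @param seed Integer RNG seed.
#' @param candidates Optional explicit candidate set, a numeric matrix
#'   `m x 2` (mm). By default, `50 * count` points drawn uniformly in the
#'   disc under `seed`.
#' @return Numeric matrix `count x 2` of center coordinates, mm.
#' @export
sample_motor_unit_centers <- function(count, muscle_radius = 25.4, seed = 1,
                                      candidates = NULL) {
  if (!is.numeric(count) || length(count) != 1 || count < 1)
    stop("'count' must be >= 1")
  stopifnot(muscle_radius > 0)
  count <- as.integer(count)
  with_seed(seed, {
    if (is.null(candidates)) {
      m <- 50L * count
      r <- muscle_radius * sqrt(runif(m))
      th <- runif(m, 0, 2 * pi)
      candidates <- cbind(r * cos(th), r * sin(th))
    } else {
      candidates <- as.matrix(candidates)
      stopifnot(ncol(candidates) == 2)
    }
    m <- nrow(candidates)
    if (m < count) stop("candidate set smaller than 'count'")
    chosen <- integer(count)
    chosen[1] <- sample.int(m, 1L)
    # squared min distance of each candidate to the chosen set
    mind <- (candidates[, 1] - candidates[chosen[1], 1])^2 +
            (candidates[, 2] - candidates[chosen[1], 2])^2
    if (count > 1L) for (i in 2:count) {
      chosen[i] <- which.max(mind)
      d2 <- (candidates[, 1] - candidates[chosen[i], 1])^2 +
            (candidates[, 2] - candidates[chosen[i], 2])^2
      mind <- pmin(mind, d2)
    }
    unname(candidates[chosen, , drop = FALSE])
  })
}

#' Rank-based exponential innervation numbers
#'
#' Assigns the number of muscle fibers innervated by each motor neuron
#' following an exponential distribution across the ranked pool:
#' `n_i = round(n_min * (n_max/n_min)^((i-1)/(count-1)))`, nondecreasing
#' from `n_min` (smallest unit) to `n_max` (largest unit).
#'
#' @param count Pool size (>= 2).
#' @param n_min,n_max Innervation number range (defaults 15 and 1500).
#' @return Integer vector of length `count`.
#' @examples
#' assign_innervation_numbers(200)[c(1, 200)]  # 15, 1500
#' @export
assign_innervation_numbers <- function(count, n_min = 15, n_max = 1500) {
  if (!is.numeric(count) || length(count) != 1 || count < 2)
    stop("'count' must be >= 2")
  stopifnot(n_min < n_max, n_min > 0)
  i <- seq_len(count)
  as.integer(round(n_min * (n_max / n_min)^((i - 1) / (count - 1))))
}

#' Generate an anatomical motor-unit pool
#'
#' Builds the full anatomical description of a motor-unit pool inside the
#' layered cylindrical muscle: territory centers by farthest-point
#' sampling, innervation numbers on the rank-based exponential law,
#' territory radii from the fiber density
#' (`r = sqrt(n / (pi * density))`, clipped to \[0.2, 9.8\] mm), and
#' individual fiber positions uniform within each territory disc
#' intersected with the muscle cross-section (territories may overhang
#' the boundary; overhanging fibers are resampled inside). Each unit's
#' fascicle bundle is centered at a unit-specific axial position
#' (uniform +/- `axial_scatter` mm, emulating innervation zones and
#' fascicle spans staggered along the muscle), and each fiber receives
#' an end-plate position at the fascicle midpoint plus a uniform
#' scatter of +/- `endplate_scatter` mm.
#'
#' @param geometry A [muscle_geometry].
#' @param count Number of motor units (default 200).
#' @param density Fiber density within a territory, fibers/mm^2
#'   (default 20).
#' @param n_min,n_max Innervation number range (defaults 15, 1500).
#' @param endplate_scatter Half-width of the uniform end-plate scatter,
#'   mm (default 5).
#' @param axial_scatter Half-width of the uniform per-unit axial
#'   territory-center scatter, mm (default 20).
#' @param seed Integer RNG seed; the pool is bit-reproducible given
#'   `(seed, config)`.
#' @return An object of class `mu_pool`: `geometry`, `seed`, `units` (a
#'   data.frame with `index`, `center_x`, `center_y`, `n_fibers`,
#'   `territory_radius`, `depth`, `axial_center`, sorted by `n_fibers`
#'   ascending) and `fibers` (a list of `n_fibers x 3` matrices: fiber
#'   cross-section position `u`, `w` in mm and end-plate axial offset
#'   `z0` in mm relative to the unit's `axial_center`).
#' @export
build_pool <- function(geometry = muscle_geometry(), count = 200,
                       density = 20, n_min = 15, n_max = 1500,
                       endplate_scatter = 5, axial_scatter = 20, seed = 1) {
  stopifnot(inherits(geometry, "muscle_geometry"), density > 0)
  centers <- sample_motor_unit_centers(count, geometry$muscle_radius,
                                       seed = seed)
  nfib <- assign_innervation_numbers(count, n_min, n_max)
  rad <- pmin(pmax(sqrt(nfib / (pi * density)), 0.2), 9.8)
  R <- geometry$muscle_radius
  fibers <- vector("list", count)
  axial_center <- numeric(count)
  with_seed(seed + 1L, {
    axial_center[] <- runif(count, -axial_scatter, axial_scatter)
    for (i in seq_len(count)) {
      got <- matrix(numeric(0), ncol = 2)
      while (nrow(got) < nfib[i]) {
        need <- nfib[i] - nrow(got)
        rr <- rad[i] * sqrt(runif(2L * need + 8L))
        th <- runif(2L * need + 8L, 0, 2 * pi)
        u <- centers[i, 1] + rr * cos(th)
        w <- centers[i, 2] + rr * sin(th)
        ok <- u^2 + w^2 <= R^2      # keep fibers inside the muscle disc
        got <- rbind(got, cbind(u[ok], w[ok]))
      }
      got <- got[seq_len(nfib[i]), , drop = FALSE]
      z0 <- runif(nfib[i], -endplate_scatter, endplate_scatter)
      fibers[[i]] <- cbind(u = got[, 1], w = got[, 2], z0 = z0)
    }
  })
  depth <- geometry$outer_radius - sqrt(rowSums(centers^2))
  structure(list(
    geometry = geometry, seed = seed, density = density,
    units = data.frame(index = seq_len(count),
                       center_x = centers[, 1], center_y = centers[, 2],
                       n_fibers = nfib, territory_radius = rad,
                       depth = depth, axial_center = axial_center),
    fibers = fibers
  ), class = "mu_pool")
}

#' @export
print.mu_pool <- function(x, ...) {
  cat(sprintf(
    "Motor-unit pool: %d units, %d-%d fibers, depths %.1f-%.1f mm (seed %d)\n",
    nrow(x$units), min(x$units$n_fibers), max(x$units$n_fibers),
    min(x$units$depth), max(x$units$depth), x$seed))
  invisible(x)
}

#' @export
plot.mu_pool <- function(x, ...) {
  th <- seq(0, 2 * pi, length.out = 181)
  R <- x$geometry$muscle_radius
  plot(R * cos(th), R * sin(th), type = "l", asp = 1,
       xlab = "u (mm)", ylab = "w (mm)", main = "Motor-unit territories", ...)
  lines(x$geometry$outer_radius * cos(th), x$geometry$outer_radius * sin(th),
        lty = 2)
  u <- x$units
  symbols(u$center_x, u$center_y, circles = u$territory_radius,
          inches = FALSE, add = TRUE, fg = "grey50")
  points(u$center_x, u$center_y, pch = 16, cex = 0.4)
  invisible(x)
}

#' Depth of a motor-unit territory below the skin surface
#'
#' Distance between the territory center and the outer skin surface:
#' `(muscle_radius + fat + skin) - radial distance of the center from the
#' cylinder axis`.
#'
#' @param unit Either a row of `pool$units` (with `center_x`, `center_y`)
#'   or a numeric length-2 center, mm.
#' @param geometry A [muscle_geometry].
#' @return Depth in mm.
#' @export
mu_depth <- function(unit, geometry) {
  stopifnot(inherits(geometry, "muscle_geometry"))
  ctr <- if (is.numeric(unit)) unit else c(unit$center_x, unit$center_y)
  r <- sqrt(sum(ctr^2))
  if (r > geometry$muscle_radius + 1e-9)
    stop("territory center lies outside the muscle cross-section")
  geometry$outer_radius - r
}
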