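#' Tissue electrical parameters for the volume conductor
#'
#' Parameters of the analytic line-source volume conductor: the muscle is
#' an anisotropic medium (conductivity higher along the fibers than
#' across them), and the subcutaneous fat and skin layers attenuate and
#' spatially low-pass the surface potential. The layers are modelled as
#' adding effective radial distance between source and electrode
#' (`attenuation x thickness`), which both reduces amplitude and smooths
#' the detected waveform with depth. Conduction velocity (CV) increases
#' with innervation number on a logarithmic law between `cv_min` and
#' `cv_max`.
#'
#' @param anisotropy_ratio Longitudinal/transverse muscle conductivity
#'   ratio (> 1 compresses axial distances), default 5.
#' @param fat_attenuation,skin_attenuation Dimensionless multipliers on
#'   the fat and skin thicknesses contributing effective radial
#'   source-electrode distance, default 0.5 (the layers blur less than
#'   their full geometric thickness because they are thin compared with
#'   the source-electrode distance).
#' @param distance_power Exponent of the inverse-distance weighting
#'   (default 4). The transmembrane current of a fiber is a balanced
#'   (quadrupole-like) source, and the low-conductivity fat and skin
#'   layers force its return currents close to the source, so the
#'   detected surface potential falls off much faster than a monopole
#'   field; the steep effective power both attenuates and spatially
#'   low-pass filters deep sources, as observed in surface EMG.
#' @param cv_min,cv_max Conduction-velocity range, m/s (defaults 3.5 and
#'   4.5; must lie within the physiological 2-6 m/s band).
#' @param amplitude_gain Overall output scale (arbitrary uV units),
#'   default 1.
#' @return An object of class `tissue_electrical`.
#' @export
tissue_electrical <- function(anisotropy_ratio = 5, fat_attenuation = 0.5,
                              skin_attenuation = 0.5, distance_power = 4,
                              cv_min = 3.5, cv_max = 4.5,
                              amplitude_gain = 1) {
  stopifnot(anisotropy_ratio > 0, fat_attenuation > 0, skin_attenuation > 0,
            distance_power > 0, amplitude_gain != 0)
  if (cv_min < 2 || cv_max > 6 || cv_min > cv_max)
    stop("conduction velocities must satisfy 2 <= cv_min <= cv_max <= 6 m/s")
  structure(list(anisotropy_ratio = anisotropy_ratio,
                 fat_attenuation = fat_attenuation,
                 skin_attenuation = skin_attenuation,
                 distance_power = distance_power,
                 cv_min = cv_min, cv_max = cv_max,
                 amplitude_gain = amplitude_gain),
            class = "tissue_electrical")
}

#' Conduction velocity from innervation number
#'
#' Logarithmic interpolation between `cv_min` and `cv_max` over the
#' innervation-number range: larger units have larger fibers and conduct
#' faster.
#'
#' @param n_fibers Innervation number(s).
#' @param tissue A [tissue_electrical].
#' @param n_min,n_max Innervation-number range anchoring the law.
#' @return Conduction velocity, m/s.
#' @export
conduction_velocity <- function(n_fibers, tissue = tissue_electrical(),
                                n_min = 15, n_max = 1500) {
  f <- (log(pmax(n_fibers, n_min)) - log(n_min)) / (log(n_max) - log(n_min))
  tissue$cv_min + (tissue$cv_max - tissue$cv_min) * pmin(f, 1)
}

#' Rosenfalck-form intracellular action potential
#'
#' Transmembrane potential of a depolarization zone as a function of the
#' axial coordinate z (mm) behind the wavefront:
#' `psi(z) = 96 z^3 exp(-z) - 90` mV for `z >= 0`, and -90 mV (resting)
#' for `z < 0`.
#'
#' @param z Axial coordinate(s), mm.
#' @return Potential, mV.
#' @examples
#' intracellular_ap(0)   # -90
#' intracellular_ap(3)   # 96*27*exp(-3) - 90
#' @export
intracellular_ap <- function(z) {
  ifelse(z >= 0, 96 * z^3 * exp(-z) - 90, -90)
}

# second spatial derivative of the intracellular action potential,
# proportional to the transmembrane current source density
psi_dd <- function(z) {
  out <- numeric(length(z))
  p <- z > 0
  zp <- z[p]
  out[p] <- 96 * exp(-zp) * (6 * zp - 6 * zp^2 + zp^3)
  dim(out) <- dim(z)
  out
}

# map electrode surface coordinates (x axial, y transverse arc length)
# to 3-D cross-section coordinates on the outer cylinder surface
electrode_xyz <- function(x, y, geometry) {
  th <- y / geometry$outer_radius
  cbind(x = x, ey = geometry$outer_radius * sin(th),
        ez = geometry$outer_radius * cos(th))
}

# Core forward engine. positions: matrix [nelec x 2] of (x, y) surface
# coordinates. Returns [n_units x nelec x nt] array of waveforms.
#
# For each fiber, two depolarization zones leave the end-plate at the
# fiber's CV toward both fiber ends; the transmembrane current is the
# second derivative of the intracellular potential, and the contribution
# to an electrode is the axial line sum weighted by the inverse
# anisotropy-scaled source-electrode distance. Truncating the line sum at
# the fiber ends (and the end-plate) produces the non-propagating
# generation and end-of-fiber components.
muap_engine <- function(pool, positions, fs = 2048, window_ms = 30,
                        tissue = tissue_electrical(), fiber_subsample = NULL,
                        dz = 1, seed = NULL) {
  geom <- pool$geometry
  nelec <- nrow(positions)
  nt <- max(0L, as.integer(round(window_ms * fs / 1000)))
  nu <- nrow(pool$units)
  out <- array(0, dim = c(nu, nelec, nt))
  if (nt == 0L || nelec == 0L) return(out)
  exyz <- electrode_xyz(positions[, 1], positions[, 2], geom)
  xk <- seq(-geom$fiber_length / 2, geom$fiber_length / 2, by = dz)
  nz <- length(xk)
  t_ms <- (seq_len(nt) - 1L) / fs * 1000
  ax <- if (is.null(pool$units$axial_center)) rep(0, nu)
        else pool$units$axial_center
  extra <- tissue$fat_attenuation * geom$fat_thickness +
           tissue$skin_attenuation * geom$skin_thickness
  cv <- conduction_velocity(pool$units$n_fibers, tissue)
  sub_idx <- lapply(seq_len(nu), function(i) seq_len(pool$units$n_fibers[i]))
  scale_f <- rep(1, nu)
  if (!is.null(fiber_subsample)) {
    with_seed(seed, {
      for (i in seq_len(nu)) {
        nf <- pool$units$n_fibers[i]
        if (nf > fiber_subsample) {
          sub_idx[[i]] <- sort(sample.int(nf, fiber_subsample))
          scale_f[i] <- nf / fiber_subsample
        }
      }
    })
  }
  for (i in seq_len(nu)) {
    fib <- pool$fibers[[i]][sub_idx[[i]], , drop = FALSE]
    nf <- nrow(fib)
    # anisotropy-scaled squared axial distances to this unit's fascicles
    DX2 <- outer(exyz[, 1] - ax[i], xk, "-")^2 / tissue$anisotropy_ratio
    # radial (transverse) source-electrode distances, constant per fiber
    rt <- sqrt(outer(exyz[, 2], fib[, 1], "-")^2 +
               outer(exyz[, 3], fib[, 2], "-")^2) + extra   # nelec x nf
    W <- array(0, dim = c(nelec, nz, nf))
    S <- array(0, dim = c(nz, nf, nt))
    pw <- tissue$distance_power
    for (f in seq_len(nf)) {
      d2 <- DX2 + rt[, f]^2
      W[, , f] <- if (pw == 4) 1 / (d2 * d2)
                  else if (pw == 2) 1 / d2
                  else if (pw == 1) 1 / sqrt(d2)
                  else d2^(-pw / 2)
      S[, f, ] <- psi_dd(outer(-abs(xk - fib[f, 3]), cv[i] * t_ms, "+"))
    }
    dim(W) <- c(nelec, nz * nf)
    dim(S) <- c(nz * nf, nt)
    out[i, , ] <- (W %*% S) * (dz * tissue$amplitude_gain * scale_f[i])
  }
  out
}

#' Surface potential of a single muscle fiber
#'
#' Waveform detected at one surface electrode from one fiber discharging
#' at time 0: two depolarization zones propagate from the end-plate
#' toward both fiber ends at the fiber's conduction velocity; the
#' electrode potential is the line-source sum of the transmembrane
#' current (second derivative of [intracellular_ap]) weighted by inverse
#' anisotropy-scaled distance, including the non-propagating end-plate
#' and end-of-fiber components.
#'
#' @param fiber Numeric length-3: cross-section position `(u, w)` mm and
#'   end-plate axial offset `z0` mm.
#' @param electrode Numeric length-2 surface point `(x, y)` mm (y is arc
#'   length around the cylinder from the grid center line).
#' @param cv Conduction velocity, m/s.
#' @param geometry A [muscle_geometry].
#' @param tissue A [tissue_electrical].
#' @param fs Sampling rate, Hz (>= 1024).
#' @param window_ms Waveform window, ms.
#' @param dz Axial discretization step, mm.
#' @return Numeric waveform of `round(window_ms * fs / 1000)` samples, uV.
#' @export
fiber_potential <- function(fiber, electrode, cv = 4,
                            geometry = muscle_geometry(),
                            tissue = tissue_electrical(),
                            fs = 2048, window_ms = 30, dz = 1) {
  if (fs < 1024) stop("'fs' must be >= 1024 Hz")
  stopifnot(length(fiber) == 3, length(electrode) == 2)
  fake_pool <- list(
    geometry = geometry,
    units = data.frame(n_fibers = 1L),
    fibers = list(matrix(fiber, nrow = 1))
  )
  tis <- tissue
  tis$cv_min <- tis$cv_max <- cv  # force the requested CV
  w <- muap_engine(fake_pool, matrix(electrode, nrow = 1), fs = fs,
                   window_ms = window_ms, tissue = tis, dz = dz)
  as.numeric(w[1, 1, ])
}

#' Compute multichannel surface MUAPs of a motor-unit pool
#'
#' Sums [fiber_potential]-type contributions of all fibers of each unit
#' at every electrode of the grid (electrodes treated as points;
#' optionally averaged over a 5-point 0.5-mm disc stencil). With
#' `fiber_subsample`, a seeded subsample of at most that many fibers per
#' unit is used and rescaled by `n_fibers / subsample`.
#'
#' @param pool A [build_pool] result.
#' @param grid A [grid_spec], centered over the muscle transversally.
#' @param fs Sampling rate, Hz (default 2048).
#' @param window_ms Waveform window, ms (default 30).
#' @param tissue A [tissue_electrical].
#' @param fiber_subsample Max fibers per unit, or `NULL` for all.
#' @param stencil If `TRUE`, average each electrode over a 5-point disc
#'   stencil of 0.5-mm radius instead of a point (default `FALSE`).
#' @param dz Axial discretization step, mm (default 1).
#' @param seed Seed for the fiber subsample.
#' @return An object of class `muap_set`: `waveforms` (array
#'   `units x electrodes x samples`, uV), `fs`, `window_ms`, `grid`,
#'   `depths` (mm per unit).
#' @export
compute_muaps <- function(pool, grid, fs = 2048, window_ms = 30,
                          tissue = tissue_electrical(),
                          fiber_subsample = NULL, stencil = FALSE,
                          dz = 1, seed = 1) {
  stopifnot(inherits(pool, "mu_pool"), inherits(grid, "grid_spec"))
  if (nrow(pool$units) == 0L || grid$n == 0L)
    stop("empty pool or grid")
  pos <- as.matrix(electrode_positions(grid)[, c("x", "y")])
  if (stencil) {
    st <- rbind(c(0, 0), c(0.5, 0), c(-0.5, 0), c(0, 0.5), c(0, -0.5))
    big <- pos[rep(seq_len(nrow(pos)), each = 5L), ] +
      st[rep(1:5, nrow(pos)), ]
    w <- muap_engine(pool, big, fs, window_ms, tissue, fiber_subsample,
                     dz, seed)
    nu <- dim(w)[1]; nt <- dim(w)[3]
    wav <- array(0, dim = c(nu, nrow(pos), nt))
    for (k in 1:5) wav <- wav + w[, seq(k, by = 5L, length.out = nrow(pos)),
                                  , drop = FALSE] / 5
  } else {
    wav <- muap_engine(pool, pos, fs, window_ms, tissue, fiber_subsample,
                       dz, seed)
  }
  structure(list(waveforms = wav, fs = fs, window_ms = window_ms,
                 grid = grid, depths = pool$units$depth),
            class = "muap_set")
}

#' @export
print.muap_set <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf(
    "MUAP set: %d units x %d electrodes x %d samples (%g Hz, %g ms)\n",
    d[1], d[2], d[3], x$fs, x$window_ms))
  invisible(x)
}

# select a channel subset of a muap_set (internal)
subset_muaps <- function(muaps, channels, grid = NULL) {
  muaps$waveforms <- muaps$waveforms[, channels, , drop = FALSE]
  if (!is.null(grid)) muaps$grid <- grid
  muaps
}
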