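#' Vertex nearest to a point
#' @param surface a [tri_surface()].
#' @param point 3-vector (mm).
#' @return vertex index (1-based).
#' @export
nearest_vertex <- function(surface, point) {
  which.min(colSums((t(surface$vertices) - point)^2))
}

# regular-grid triangulated rectangle [0,L] x [0,W] in the z = 0 plane,
# CCW orientation so normals point to +z; optional height field z = f(x, y)
.grid_sheet <- function(L, W, edge_length, zfun = NULL) {
  nx <- max(1L, round(L / edge_length))
  ny <- max(1L, round(W / edge_length))
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, W, length.out = ny + 1L)
  g <- expand.grid(x = xs, y = ys)
  z <- if (is.null(zfun)) 0 else zfun(g$x, g$y)
  v <- cbind(g$x, g$y, z)
  id <- function(i, j) i + (j - 1L) * (nx + 1L)          # i in 1..nx+1
  i <- rep(seq_len(nx), ny)
  j <- rep(seq_len(ny), each = nx)
  v00 <- id(i, j); v10 <- id(i + 1L, j)
  v01 <- id(i, j + 1L); v11 <- id(i + 1L, j + 1L)
  # alternate the cell diagonal in a checkerboard pattern so that the edge
  # graph offers both diagonal directions (worst-case geodesic
  # overestimation sec(pi/8) ~ 8% instead of 41%)
  even <- (i + j) %% 2L == 0L
  tr <- rbind(cbind(v00, v10, v11)[even, , drop = FALSE],
              cbind(v00, v11, v01)[even, , drop = FALSE],
              cbind(v00, v10, v01)[!even, , drop = FALSE],
              cbind(v10, v11, v01)[!even, , drop = FALSE])
  tri_surface(v, tr)
}

#' Surrogate surface specification
#'
#' Geometry parameters shared by the surrogate-surface generators.  The
#' planform footprint is \code{(l + 2 m) x 2 m} mm: the sheet extends
#' \code{m} beyond both ends of the electrode and \code{m} to both sides,
#' where \code{l} is the first-to-last contact span of the electrode.
#'
#' @param kind "flat", "sine" or "gyral".
#' @param l electrode span in mm (28 for 9 contacts at 3.5 mm pitch).
#' @param m margin in mm.
#' @param amplitude fold amplitude A in mm (sine/gyral).
#' @param wavelength fold wavelength in mm (gyral; the sine wavelength is
#'   always \code{l}).
#' @param standoff flat-sheet-to-electrode distance in mm.
#' @param edge_length target mesh edge length in mm.
#' @param n_contacts,pitch electrode layout.
#' @param seed integer seed (gyral only).
#' @return list of class \code{surrogate_spec}.
#' @export
surrogate_spec <- function(kind = c("flat", "sine", "gyral"),
                           l = 28, m = 15, amplitude = 7.89,
                           wavelength = 25, standoff = 1.47,
                           edge_length = 0.4, n_contacts = 9, pitch = 3.5,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(l > 0, m > 0, amplitude >= 0, standoff >= 0, edge_length > 0,
            wavelength > 0)
  if (edge_length > m) stop("edge_length must not exceed the margin m")
  structure(list(kind = kind, l = l, m = m, amplitude = amplitude,
                 wavelength = wavelength, standoff = standoff,
                 edge_length = edge_length, n_contacts = n_contacts,
                 pitch = pitch, seed = as.integer(seed)),
            class = "surrogate_spec")
}

# electrode along the x axis at mid-width, contacts spanning the central l
.surrogate_electrode <- function(spec, z) {
  make_electrode(n_contacts = spec$n_contacts, pitch = spec$pitch,
                 origin = c(spec$m, spec$m, z), direction = c(1, 0, 0))
}

#' Flat surrogate surface
#'
#' A flat rectangular sheet of dimensions \code{(l + 2m) x 2m} with the
#' depth electrode parallel to its long axis, offset from the plane by
#' \code{standoff} mm (default 1.47 mm).  With the default 9-contact
#' electrode the sheet is 58 x 30 mm with a total area of exactly
#' 1740 mm^2.
#'
#' @param spec a [surrogate_spec()] (kind is ignored).
#' @return list with elements \code{surface} and \code{electrode}.
#' @export
make_flat_surrogate <- function(spec = surrogate_spec("flat")) {
  s <- .grid_sheet(spec$l + 2 * spec$m, 2 * spec$m, spec$edge_length)
  list(surface = s, electrode = .surrogate_electrode(spec, spec$standoff))
}

#' Sinusoidal surrogate surface
#'
#' A folded sheet with height field \code{z = A sin(2 pi x / l)} over the
#' same planform footprint as the flat surrogate; the electrode runs along
#' the x axis at mid-width at \code{z = 0}, threading the folds.
#'
#' @param spec a [surrogate_spec()]; \code{amplitude} is A.
#' @return list with elements \code{surface} and \code{electrode}.
#' @export
make_sine_surrogate <- function(spec = surrogate_spec("sine")) {
  A <- spec$amplitude; l <- spec$l
  s <- .grid_sheet(spec$l + 2 * spec$m, 2 * spec$m, spec$edge_length,
                   zfun = function(x, y) A * sin(2 * pi * x / l))
  list(surface = s, electrode = .surrogate_electrode(spec, 0))
}

#' Gyral (band-limited random fold) surrogate surface
#'
#' A smooth random height field built as a sum of plane cosine waves with
#' wavenumber magnitudes jittered around \code{2 pi / wavelength} and
#' random propagation directions and phases, scaled so the field's standard
#' deviation equals \code{amplitude / sqrt(2)} (matching a single sine of
#' the same peak amplitude).  A seeded stand-in for a patient-specific
#' gyral patch: deterministic given \code{spec$seed}, same footprint and
#' electrode placement as the sine surrogate.
#'
#' @param spec a [surrogate_spec()].
#' @param n_waves number of cosine components.
#' @return list with elements \code{surface} and \code{electrode}.
#' @export
make_gyral_surrogate <- function(spec = surrogate_spec("gyral", amplitude = 4),
                                 n_waves = 24) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  k0 <- 2 * pi / spec$wavelength
  kmag <- k0 * exp(rnorm(n_waves, sd = 0.2))
  th <- stats::runif(n_waves, 0, 2 * pi)
  ph <- stats::runif(n_waves, 0, 2 * pi)
  amp <- spec$amplitude / sqrt(2) * sqrt(2 / n_waves)
  zfun <- function(x, y) {
    z <- 0
    for (w in seq_len(n_waves))
      z <- z + amp * cos(kmag[w] * (cos(th[w]) * x + sin(th[w]) * y) + ph[w])
    z
  }
  s <- .grid_sheet(spec$l + 2 * spec$m, 2 * spec$m, spec$edge_length, zfun)
  list(surface = s, electrode = .surrogate_electrode(spec, 0))
}

#' Build a surrogate surface by kind
#' @param spec a [surrogate_spec()].
#' @return list with elements \code{surface} and \code{electrode}.
#' @export
make_surrogate <- function(spec) {
  switch(spec$kind,
         flat = make_flat_surrogate(spec),
         sine = make_sine_surrogate(spec),
         gyral = make_gyral_surrogate(spec))
}

#' Per-vertex excitability map
#'
#' Assigns the epileptogenic-zone excitability \code{u0_ez} to all vertices
#' within geodesic distance \code{ez_diameter / 2} of \code{ez_center}, and
#' \code{u0_surround} elsewhere.  Without a center the map is uniformly at
#' the surround value.
#'
#' @param surface a [tri_surface()].
#' @param ez_center vertex index of the epileptogenic-zone center, or NULL.
#' @param ez_diameter EZ diameter in mm.
#' @param u0_ez,u0_surround excitability values.
#' @return object of class \code{excitability_map}: list with \code{u0}
#'   (per-vertex) and \code{ez_mask} (logical).
#' @export
make_excitability_map <- function(surface, ez_center = NULL, ez_diameter = 5,
                                  u0_ez = -1.8, u0_surround = -2.3) {
  n <- nrow(surface$vertices)
  u0 <- rep(u0_surround, n)
  mask <- rep(FALSE, n)
  if (!is.null(ez_center)) {
    stopifnot(ez_center >= 1, ez_center <= n)
    gf <- geodesic_distances(surface, ez_center)
    mask <- gf$distances <= ez_diameter / 2
    # a disc containing only the seed vertex is not a resolved EZ
    if (sum(mask) < 3)
      stop("unresolved epileptogenic zone: mesh too coarse for ez_diameter = ",
           ez_diameter, "; refine the mesh")
    u0[mask] <- u0_ez
  }
  structure(list(u0 = u0, ez_mask = mask), class = "excitability_map")
}
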