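#' Synthetic field ground truth
#'
#' Generates smooth spatial fields with known zone labels: a soil apparent
#' electrical conductivity (ECa) surface spanning the 5-20 mS/m class range
#' and a canopy-vigor surface whose NDVI transform spans 0.35-0.50. Each field
#' is a sum of random low-frequency cosine waves (wavelengths 60-250 m),
#' rescaled to its target range, so it is smooth, band-limited and
#' deterministic for a fixed seed. The true zone map is obtained by applying
#' the package's own three-class rules to the noiseless surfaces.
#'
#' Defaults give a 310 m x 300 m plot (9.3 ha) on a 10 m grid.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge, m.
#' @param eca_range,ndvi_range value spans of the two surfaces.
#' @param seed integer seed.
#' @return list of class `"field_truth"` with elements `eca_field`,
#'   `vigor_field` (both [raster_grid()], vigor in `[0, 1]`), `ndvi_field`
#'   (the NDVI transform of vigor) and `zone_truth` (labels 1/2/3, 0 =
#'   unclassified).
#' @export
gen_field_truth <- function(n_rows = 30, n_cols = 31, cell_size = 10,
                            eca_range = c(5, 20), ndvi_range = c(0.35, 0.50),
                            seed = 1L) {
  smooth_field <- function(sub) {
    with_seed(derive_seed(seed, sub), {
      g <- raster_grid(matrix(0, n_rows, n_cols), cell_size = cell_size)
      cc <- grid_coords(g)
      k <- 6L
      wl <- runif(k, 60, 250)
      ang <- runif(k, 0, pi)
      ph <- runif(k, 0, 2 * pi)
      amp <- runif(k, 0.5, 1)
      z <- numeric(length(cc$x))
      for (i in seq_len(k)) {
        z <- z + amp[i] * cos(2 * pi * (cc$x * cos(ang[i]) + cc$y * sin(ang[i])) / wl[i] + ph[i])
      }
      z <- (z - min(z)) / (max(z) - min(z))
      g$values[cbind(cc$row, cc$col)] <- z
      g
    })
  }
  eca <- smooth_field("eca")
  vigor <- smooth_field("vigor")
  eca$values <- eca_range[1] + diff(eca_range) * eca$values
  ndvi <- vigor
  ndvi$values <- ndvi_range[1] + diff(ndvi_range) * vigor$values

  eca_cl <- classify_layer(eca, breaks = c(10, 15))
  ndvi_cl <- classify_layer(ndvi, breaks = c(0.40, 0.45))
  zones <- combine_zones(eca_cl, ndvi_cl)
  structure(list(
    eca_field = eca, vigor_field = vigor, ndvi_field = ndvi,
    zone_truth = zones
  ), class = "field_truth")
}

#' Simulate an on-the-go ECa transect survey
#'
#' Samples the true ECa surface along parallel north-south transects, the way
#' a towed electromagnetic-induction sensor logs while driving the
#' inter-rows: transects `line_spacing` apart, one reading every
#' `sample_spacing` along the line (the distance covered per 1-s logging
#' interval at ~9 km/h is 2.5 m). `coverage` is the fraction of transect
#' lines actually driven (evenly thinned), for surveys that do not tile the
#' whole plot.
#'
#' @param truth a [gen_field_truth()] object.
#' @param line_spacing distance between transects, m.
#' @param sample_spacing along-line distance between readings, m.
#' @param noise_sd measurement noise, mS/m.
#' @param coverage fraction of lines driven, in `(0, 1]`.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`, `eca`, `depth_window`.
#' @export
gen_eca_survey <- function(truth, line_spacing = 4, sample_spacing = 2.5,
                           noise_sd = 0.5, coverage = 1, seed = 1L) {
  if (line_spacing <= 0 || sample_spacing <= 0) stop("spacings must be > 0")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  g <- truth$eca_field
  width <- g$n_cols * g$cell_size
  height <- g$n_rows * g$cell_size
  xs <- seq(g$origin_x + line_spacing / 2, g$origin_x + width - line_spacing / 2,
    by = line_spacing
  )
  if (coverage < 1) {
    keep <- unique(round(seq(1, length(xs), length.out = max(1, round(length(xs) * coverage)))))
    xs <- xs[keep]
  }
  ys <- seq(g$origin_y + sample_spacing / 2, g$origin_y + height - sample_spacing / 2,
    by = sample_spacing
  )
  pts <- expand.grid(y = ys, x = xs)[, c("x", "y")]
  val <- cell_at(g, pts$x, pts$y)
  ok <- !is.na(val)
  pts <- pts[ok, ]
  val <- val[ok]
  if (noise_sd > 0) {
    val <- val + with_seed(derive_seed(seed, "eca_survey"), rnorm(length(val), 0, noise_sd))
  }
  data.frame(
    x = pts$x, y = pts$y, eca = val,
    depth_window = "0-0.40m", stringsAsFactors = FALSE
  )
}

#' Emit a red/NIR reflectance pair consistent with a target NDVI
#'
#' Inverts the NDVI definition: for target index n, red = b(1 - n) and
#' NIR = b(1 + n) with brightness b = 0.3, so (NIR - R)/(NIR + R) recovers n
#' exactly. Optional noise is added to the target index before inversion.
#'
#' @param truth a [gen_field_truth()] object (uses its `ndvi_field`).
#' @param noise_sd NDVI-scale noise standard deviation.
#' @param seed integer seed.
#' @return list with `red` and `nir` [raster_grid()]s.
#' @export
gen_reflectance <- function(truth, noise_sd = 0, seed = 1L) {
  if (is.null(truth$ndvi_field)) stop("field truth lacks a vigor/NDVI surface")
  n <- truth$ndvi_field$values
  if (noise_sd > 0) {
    n <- n + with_seed(
      derive_seed(seed, "reflectance"),
      matrix(rnorm(length(n), 0, noise_sd), nrow(n))
    )
  }
  n <- pmin(pmax(n, -0.99), 0.99) # argument order preserves the matrix shape
  b <- 0.3
  red <- truth$ndvi_field
  nir <- truth$ndvi_field
  red$values <- b * (1 - n)
  nir$values <- b * (1 + n)
  list(red = red, nir = nir)
}
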