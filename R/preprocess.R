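#' Empirical-line reflectance calibration against a gray reference panel
#'
#' Per band, the gain is `panel_reflectance / mean(raw over the panel
#' region)`; the whole cube is multiplied by that gain and clipped to
#' [0, 1.2]. A cube whose panel region already reads the panel reflectance
#' is a fixed point, and the output is invariant to any positive rescaling
#' of the raw digital numbers.
#'
#' @param raw_cube HxWxB numeric array of raw sensor values.
#' @param panel_region logical HxW matrix (or integer pixel indices)
#'   selecting the reference panel pixels; must be nonempty.
#' @param panel_reflectance known panel reflectance, scalar or length-B
#'   vector with values in (0, 1].
#' @return HxWxB reflectance cube in [0, 1.2].
#' @export
calibrate_reflectance <- function(raw_cube, panel_region, panel_reflectance) {
  d <- dim(raw_cube)
  if (length(d) != 3) stop("raw_cube must be an HxWxB array")
  B <- d[3]
  if (is.logical(panel_region)) panel_region <- which(panel_region)
  if (length(panel_region) == 0) stop("panel_region is empty")
  pr <- rep_len(panel_reflectance, B)
  if (any(pr <= 0 | pr > 1)) stop("panel_reflectance must lie in (0, 1]")
  out <- raw_cube
  npix <- d[1] * d[2]
  flat <- matrix(raw_cube, npix, B)
  for (b in seq_len(B)) {
    pm <- mean(flat[panel_region, b])
    if (pm == 0) stop(sprintf("zero panel mean in band %d", b))
    flat[, b] <- flat[, b] * (pr[b] / pm)
  }
  array(pmin(pmax(flat, 0), 1.2), d)
}

#' Tile a scene into a non-overlapping grid of square tiles
#'
#' Row-major grid of `tile_size` x `tile_size` tiles with 0-based
#' provenance coordinates (origin top-left); partial border tiles are
#' dropped, so the tile count is `floor(H/tile_size) * floor(W/tile_size)`.
#'
#' @param scene a `weed_scene` (or any list with `rgb` and `mask`).
#' @param tile_size tile side in pixels (default 318).
#' @param scene_id identifier recorded in each tile's provenance.
#' @param keep_data keep pixel data in the tiles; `FALSE` yields a
#'   manifest-only tile set (provenance coordinates only), useful for
#'   split accounting at scale.
#' @return object of class `tile_set`: list with `tiles` (each
#'   `list(rgb, mask, scene_id, row, col)`) and `tile_size`.
#' @export
tile_scene <- function(scene, tile_size = 318, scene_id = "scene1",
                       keep_data = TRUE) {
  H <- nrow(scene$mask); W <- ncol(scene$mask)
  if (H < tile_size || W < tile_size) {
    stop(sprintf("scene %dx%d smaller than tile_size %d", H, W, tile_size))
  }
  nr <- H %/% tile_size; nc <- W %/% tile_size
  tiles <- vector("list", nr * nc)
  t <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * tile_size; c0 <- (j - 1L) * tile_size
      tl <- list(scene_id = scene_id, row = r0, col = c0)
      if (keep_data) {
        if (!is.null(scene$rgb)) {
          tl$rgb <- scene$rgb[r0 + seq_len(tile_size),
                              c0 + seq_len(tile_size), , drop = FALSE]
        }
        tl$mask <- scene$mask[r0 + seq_len(tile_size), c0 + seq_len(tile_size)]
      }
      tiles[[t]] <- tl
      t <- t + 1L
    }
  }
  structure(list(tiles = tiles, tile_size = as.integer(tile_size)),
            class = "tile_set")
}

#' Combine several tile sets
#' @param ... `tile_set` objects with equal `tile_size`.
#' @return one `tile_set`.
#' @export
combine_tilesets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "tile_set")) sets <- sets[[1]]
  ts <- unique(vapply(sets, function(s) s$tile_size, integer(1)))
  if (length(ts) != 1) stop("tile sizes differ")
  structure(list(tiles = do.call(c, lapply(sets, `[[`, "tiles")),
                 tile_size = ts), class = "tile_set")
}

#' Seeded train/validation split of a tile set
#'
#' Shuffles the tiles with the given seed and assigns the first
#' `floor(n * train_fraction)` to the training set; the split is disjoint
#' and exhaustive.
#'
#' @param tileset a `tile_set`.
#' @param train_fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `val` tile sets.
#' @export
split_tiles <- function(tileset, train_fraction = 0.7, seed = 1) {
  n <- length(tileset$tiles)
  if (n == 0) stop("empty tile set")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  ntr <- floor(n * train_fraction)
  mk <- function(idx) structure(list(tiles = tileset$tiles[idx],
                                     tile_size = tileset$tile_size),
                                class = "tile_set")
  list(train = mk(perm[seq_len(ntr)]),
       val = mk(perm[setdiff(seq_len(n), seq_len(ntr))]))
}

#' Reassemble tiles into their source-pixel positions
#'
#' Uses each tile's provenance (row, col) to rebuild the cropped region of
#' one source scene; tiling then stitching reconstructs that region exactly.
#'
#' @param tileset a `tile_set` whose tiles carry pixel data.
#' @param field "mask" or "rgb".
#' @return matrix (mask) or HxWx3 array (rgb) covering the tiled region.
#' @export
stitch_tiles <- function(tileset, field = c("mask", "rgb")) {
  field <- match.arg(field)
  if (length(tileset$tiles) == 0) stop("empty tile set")
  ts <- tileset$tile_size
  rows <- vapply(tileset$tiles, `[[`, numeric(1), "row")
  cols <- vapply(tileset$tiles, `[[`, numeric(1), "col")
  H <- max(rows) + ts; W <- max(cols) + ts
  out <- if (field == "mask") matrix(NA_integer_, H, W) else
    array(NA_integer_, c(H, W, 3))
  for (tl in tileset$tiles) {
    ri <- tl$row + seq_len(ts); ci <- tl$col + seq_len(ts)
    if (field == "mask") out[ri, ci] <- tl$mask else out[ri, ci, ] <- tl$rgb
  }
  out
}

#' Broadband vegetation index from two band rasters
#'
#' NDVI = (NIR - R) / (NIR + R); RVI = NIR / R;
#' SAVI = (1 + L) (NIR - R) / (NIR + R + L), with the soil factor
#' `params$L` (default 0.5). Pixels with a zero denominator are flagged
#' `NaN` and excluded from downstream means.
#'
#' @param nir_band,red_band numeric matrices of equal shape.
#' @param index_name "NDVI", "RVI" or "SAVI".
#' @param params list; `params$L` for SAVI.
#' @return object of class `index_map`: list(values, index_name, params).
#' @export
compute_index <- function(nir_band, red_band,
                          index_name = c("NDVI", "RVI", "SAVI"),
                          params = list()) {
  index_name <- match.arg(index_name)
  if (!identical(dim(nir_band), dim(red_band))) {
    stop("nir_band and red_band must have identical shape")
  }
  if (index_name == "SAVI" && is.null(params$L)) params$L <- 0.5
  values <- switch(index_name,
    NDVI = {
      den <- nir_band + red_band
      v <- (nir_band - red_band) / den
      v[den == 0] <- NaN
      v
    },
    RVI = {
      v <- nir_band / red_band
      v[red_band == 0] <- NaN
      v
    },
    SAVI = {
      den <- nir_band + red_band + params$L
      v <- (1 + params$L) * (nir_band - red_band) / den
      v[den == 0] <- NaN
      v
    })
  structure(list(values = values, index_name = index_name, params = params),
            class = "index_map")
}

#' Narrowband NDVI from two arbitrary cube wavelengths
#'
#' Forms NDVI from the grid bands nearest `lambda_a` (as NIR) and
#' `lambda_b` (as the red substitute); the resolved wavelengths are
#' recorded in the result's `params`.
#'
#' @param cube HxWxB reflectance array.
#' @param wavelengths_nm length-B wavelength grid.
#' @param lambda_a,lambda_b target wavelengths in nm, within the grid range.
#' @return an `index_map` with `params$lambda_a/lambda_b` (requested) and
#'   `params$resolved_a/resolved_b` (grid wavelengths used).
#' @export
narrowband_ndvi <- function(cube, wavelengths_nm, lambda_a, lambda_b) {
  lib <- list(wavelengths_nm = wavelengths_nm)
  ba <- nearest_band(lib, lambda_a)
  bb <- nearest_band(lib, lambda_b)
  a <- cube[, , ba]; b <- cube[, , bb]
  den <- a + b
  v <- (a - b) / den
  v[den == 0] <- NaN
  structure(list(values = v, index_name = "narrowband-NDVI",
                 params = list(lambda_a = lambda_a, lambda_b = lambda_b,
                               resolved_a = wavelengths_nm[ba],
                               resolved_b = wavelengths_nm[bb])),
            class = "index_map")
}
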