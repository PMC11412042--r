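#' Write a reflectance cube as an ENVI band-sequential file pair
#'
#' Emits an ASCII `.hdr` (with the wavelength list) and a float32
#' band-sequential binary alongside it.
#'
#' @param cube HxWxB numeric array.
#' @param wavelengths_nm length-B wavelengths.
#' @param path output path without extension; writes `path.hdr` and
#'   `path.bsq`.
#' @return invisibly, the two file paths.
#' @export
write_envi_cube <- function(cube, wavelengths_nm, path) {
  d <- dim(cube)
  if (length(d) != 3 || d[3] != length(wavelengths_nm)) {
    stop("cube must be HxWxB with one wavelength per band")
  }
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bsq", "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = { ",
                  paste(sprintf("%.4f", wavelengths_nm), collapse = ", "),
                  " }"))
  hdr_path <- paste0(path, ".hdr")
  bin_path <- paste0(path, ".bsq")
  writeLines(hdr, hdr_path)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  # BSQ: band-major, within band row-major (lines of samples)
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube[, , b])), con, size = 4, endian = "little")
  }
  invisible(c(hdr_path, bin_path))
}

#' Read an ENVI band-sequential cube written by [write_envi_cube()]
#'
#' @param path path without extension.
#' @return list with `cube` (HxWxB) and `wavelengths_nm`.
#' @export
read_envi_cube <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getval <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    as.integer(sub(".*= *", "", ln))
  }
  H <- getval("lines"); W <- getval("samples"); B <- getval("bands")
  wl_line <- grep("^wavelength *= *\\{", hdr, value = TRUE)[1]
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_line), ",")[[1]])
  con <- file(paste0(path, ".bsq"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = H * W * B, size = 4, endian = "little")
  cube <- array(0, c(H, W, B))
  for (b in seq_len(B)) {
    cube[, , b] <- t(matrix(vals[((b - 1) * H * W + 1):(b * H * W)], W, H))
  }
  list(cube = cube, wavelengths_nm = wl)
}

# label palette: 0 soil = black, 1 wheat = red, 2 weed = blue
mask_palette <- function() {
  matrix(c(0, 0, 0,   1, 0, 0,   0, 0, 1), nrow = 3, byrow = TRUE,
         dimnames = list(c("soil", "wheat", "weed"), c("r", "g", "b")))
}

#' Write a label mask as a palette PNG (black soil, red wheat, blue weed)
#' @param mask HxW integer matrix with labels 0/1/2.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  pal <- mask_palette()
  H <- nrow(mask); W <- ncol(mask)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[mask + 1L, ch], H)
  png::writePNG(img, path)
  invisible(path)
}

#' Read a palette mask PNG back into 0/1/2 labels
#' @param path PNG path.
#' @return HxW integer matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) return(matrix(0L, nrow(img), ncol(img)))
  pal <- mask_palette()
  H <- dim(img)[1]; W <- dim(img)[2]
  flat <- matrix(img[, , 1:3], H * W, 3)
  d <- vapply(seq_len(3), function(k) {
    rowSums(sweep(flat, 2, pal[k, ], `-`)^2)
  }, numeric(H * W))
  matrix(max.col(-d, ties.method = "first") - 1L, H, W)
}

#' Write an RGB scene image as PNG
#' @param rgb HxWx3 integer array (0-255).
#' @param path output path.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Write a tile manifest CSV (tile_id, scene_id, row, col, split)
#' @param splits list with `train` and `val` tile sets.
#' @param path output CSV path.
#' @export
write_tile_manifest <- function(splits, path) {
  rows <- list()
  for (nm in names(splits)) {
    for (tl in splits[[nm]]$tiles) {
      rows[[length(rows) + 1L]] <- data.frame(
        tile_id = sprintf("%s_r%d_c%d", tl$scene_id, tl$row, tl$col),
        scene_id = tl$scene_id, row = tl$row, col = tl$col, split = nm,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
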