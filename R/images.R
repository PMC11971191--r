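#' Grayscale image with physical pixel size
#'
#' Minimal container for a single-channel 16-bit image: an integer matrix of
#' intensities plus the edge length of one pixel in micrometres, which is
#' what converts pixel counts into the micrometre-squared particle areas the
#' size windows are defined on.
#'
#' @param intensities numeric/integer matrix of non-negative intensities
#'   (rows = image rows).
#' @param pixel_size_um micrometres per pixel edge, `> 0`.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(intensities, pixel_size_um) {
  if (!is.matrix(intensities) || length(intensities) == 0) {
    stop("`intensities` must be a non-empty matrix")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 0,
                    strict_lower = TRUE)
  storage.mode(intensities) <- "integer"
  structure(list(intensities = intensities,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> %d x %d px, %.4g um/px, intensity range [%d, %d]\n",
    nrow(x$intensities), ncol(x$intensities), x$pixel_size_um,
    min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$intensities)

#' Read and write 16-bit ASCII PGM images
#'
#' Plain-text (P2) portable graymap with maxval 65535 stands in for the
#' microscope's 16-bit grayscale export; the physical pixel size travels in
#' a JSON sidecar written next to the image (see [write_ground_truth()]).
#'
#' @param img an [image_grid()].
#' @param path file path (conventionally `.pgm`).
#' @param pixel_size_um pixel size to attach on read.
#' @return `write_pgm()` returns `path` invisibly; `read_pgm()` an
#'   [image_grid()].
#' @export
write_pgm <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  m <- img$intensities
  if (any(m > 65535L)) stop("intensities exceed 16-bit range")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "65535"), con,
             sep = "\n")
  # one image row per line keeps files diffable and parsing unambiguous
  writeLines(apply(m, 1L, paste, collapse = " "), con, sep = "\n")
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path, pixel_size_um = 1) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop("only ASCII (P2) PGM is supported")
  tokens <- scan(text = paste(txt[-1], collapse = "\n"), what = integer(),
                 quiet = TRUE)
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != w * h) stop("PGM pixel count does not match header")
  if (maxval > 65535) stop("maxval exceeds 16-bit range")
  image_grid(matrix(px, nrow = h, ncol = w, byrow = TRUE), pixel_size_um)
}

#' Ground-truth sidecar JSON
#'
#' Serializes a generator's ground truth (object classes, areas, centroids,
#' pixel size) next to the image it describes, so segmentation accuracy can
#' be audited on disk as well as in memory.
#'
#' @param ground_truth data frame with columns `class`, `area_um2`,
#'   `centroid_row`, `centroid_col` (as produced by
#'   [simulate_histology_image()]).
#' @param pixel_size_um pixel size of the image the truth refers to.
#' @param path output `.json` path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` a list with `objects` (data frame) and
#'   `pixel_size_um`.
#' @export
write_ground_truth <- function(ground_truth, pixel_size_um, path) {
  obj <- list(
    pixel_size_um = pixel_size_um,
    objects = ground_truth
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(objects = as.data.frame(x$objects),
       pixel_size_um = as.numeric(x$pixel_size_um))
}

# --- rasterization helpers -------------------------------------------------

# Pixels of an elliptical blob with EXACTLY n_px pixels: rank all pixels in a
# covering window by squared elliptical distance from the centre and keep the
# n_px closest (ties broken by row then column). Guarantees the pixelated
# area equals the requested pixel budget, so rasterization error is bounded
# by the rounding of area -> pixel count.
rasterize_blob <- function(center_row, center_col, n_px, axis_ratio = 1,
                           angle = 0) {
  stopifnot(n_px >= 1)
  # semi-axes in pixel units for the requested area: pi*a*b = n_px
  a <- sqrt(n_px * axis_ratio / pi)
  b <- a / axis_ratio
  r_max <- ceiling(a) + 2L
  off <- seq.int(-r_max, r_max)
  grid <- expand.grid(dr = off, dc = off)
  ca <- cos(angle); sa <- sin(angle)
  u <- (grid$dc * ca + grid$dr * sa) / a
  v <- (-grid$dc * sa + grid$dr * ca) / b
  d2 <- u * u + v * v
  ord <- order(d2, grid$dr, grid$dc)
  keep <- ord[seq_len(n_px)]
  cbind(row = center_row + grid$dr[keep], col = center_col + grid$dc[keep])
}

# Convert a requested physical area to a pixel budget clamped so the
# pixelated area stays inside [lower, upper] um^2.
area_to_pixels <- function(area_um2, pixel_size_um, lower, upper) {
  pa <- pixel_size_um^2
  n <- round(area_um2 / pa)
  n_min <- max(1L, ceiling(lower / pa - 1e-9))
  n_max <- max(n_min, floor(upper / pa + 1e-9))
  as.integer(min(max(n, n_min), n_max))
}

# Mark a Chebyshev-dilated neighbourhood of the given pixels in a logical
# mask (used to enforce minimum separation between placed objects).
mark_dilated <- function(mask, pixels, sep) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- expand.grid(dr = -sep:sep, dc = -sep:sep)
  for (k in seq_len(nrow(off))) {
    r <- pixels[, 1] + off$dr[k]
    c <- pixels[, 2] + off$dc[k]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}
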