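#' Size windows for particle classification
#'
#' Closed micrometre-squared area windows separating the two pathology
#' classes: small diffuse dot-like signal (default 1.5-3.5 um^2, the size
#' range of multimeric tau-PLA dots and small IHC-labelled structures) and
#' large perikaryal lesions (default 12.5-100 um^2, primarily tangles).
#' Boundaries are inclusive; a 12.5-um^2 particle is perikaryal.
#'
#' @param diffuse_um2 closed interval c(lower, upper) for the diffuse class.
#' @param perikaryal_um2 closed interval for the perikaryal class.
#' @return an object of class `size_windows`.
#' @export
size_windows <- function(diffuse_um2 = c(1.5, 3.5),
                         perikaryal_um2 = c(12.5, 100)) {
  stopifnot(length(diffuse_um2) == 2, length(perikaryal_um2) == 2,
            diffuse_um2[1] > 0, perikaryal_um2[1] > 0,
            diffuse_um2[1] <= diffuse_um2[2],
            perikaryal_um2[1] <= perikaryal_um2[2])
  if (diffuse_um2[2] >= perikaryal_um2[1] &&
      perikaryal_um2[2] >= diffuse_um2[1]) {
    if (max(diffuse_um2[1], perikaryal_um2[1]) <=
        min(diffuse_um2[2], perikaryal_um2[2])) {
      stop("diffuse and perikaryal windows must not overlap")
    }
  }
  structure(list(diffuse_um2 = diffuse_um2, perikaryal_um2 = perikaryal_um2),
            class = "size_windows")
}

#' Otsu threshold of an intensity matrix
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' intensity range. Intended for real scans whose manual threshold is
#' unknown; synthetic fixtures normally use an explicit threshold.
#'
#' @param intensities numeric matrix (or vector) of intensities.
#' @param n_bins histogram bins (default 256).
#' @return threshold on the intensity scale; foreground is strictly above.
#' @export
otsu_threshold <- function(intensities, n_bins = 256L) {
  x <- as.numeric(intensities)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("image is constant; Otsu thresholding is undefined - supply an ",
         "explicit threshold")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  if (!is.finite(between[k])) {
    stop("degenerate histogram; supply an explicit threshold")
  }
  breaks[k + 1L]
}

# Label connected components of a logical mask (8- or 4-connectivity) with
# a raster-scan union-find pass; returns an integer matrix of labels
# (0 = background).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(labels)
  parent <- seq_along(idx)
  lab_of <- integer(nr * nc)       # linear index -> provisional label id
  lab_of[idx] <- seq_along(idx)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  # neighbour offsets above/left of the scan position (column-major linear)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  for (k in seq_along(idx)) {
    r <- rows[k]; c <- cols[k]
    if (r > 1L && mask[r - 1L, c]) union(k, lab_of[idx[k] - 1L])
    if (c > 1L && mask[r, c - 1L]) union(k, lab_of[idx[k] - nr])
    if (connectivity == 8L) {
      if (r > 1L && c > 1L && mask[r - 1L, c - 1L]) {
        union(k, lab_of[idx[k] - nr - 1L])
      }
      if (r < nr && c > 1L && mask[r + 1L, c - 1L]) {
        union(k, lab_of[idx[k] - nr + 1L])
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels[idx] <- match(roots, sort(unique(roots)))
  labels
}

#' Segment particles from a thresholded image
#'
#' Foreground is every pixel strictly above the threshold; particles are its
#' 8-connected components (the behaviour of the usual particle-analysis
#' tools), with areas converted to um^2 through the pixel size.
#' Border-touching particles are kept.
#'
#' @param image an [image_grid()].
#' @param threshold numeric intensity, or `"otsu"` to derive one with
#'   [otsu_threshold()].
#' @param connectivity 8 (default) or 4.
#' @return data frame of class `particle_table`: `particle`, `pixel_count`,
#'   `area_um2`, `centroid_row`, `centroid_col`.
#' @export
segment_particles <- function(image, threshold, connectivity = 8L) {
  stopifnot(inherits(image, "image_grid"))
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(image$intensities)
  }
  assert_scalar_num(threshold, "threshold")
  mask <- image$intensities > threshold
  labels <- label_components(mask, connectivity)
  n <- max(labels)
  pa <- image$pixel_size_um^2
  if (n == 0L) {
    out <- data.frame(particle = integer(), pixel_count = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rows <- ((idx - 1L) %% nrow(labels)) + 1L
    cols <- ((idx - 1L) %/% nrow(labels)) + 1L
    cnt <- tabulate(lab, n)
    out <- data.frame(
      particle = seq_len(n),
      pixel_count = cnt,
      area_um2 = cnt * pa,
      centroid_row = as.numeric(tapply(rows, lab, mean)),
      centroid_col = as.numeric(tapply(cols, lab, mean))
    )
  }
  class(out) <- c("particle_table", class(out))
  out
}

#' Classify particles into diffuse / perikaryal / other
#'
#' @param particles a `particle_table` (from [segment_particles()]) or any
#'   data frame with an `area_um2` column.
#' @param windows a [size_windows()].
#' @return one-row data frame of class `particle_class_counts`:
#'   `diffuse_count`, `perikaryal_count`, `other_count`.
#' @export
classify_particles <- function(particles, windows = size_windows()) {
  stopifnot(inherits(windows, "size_windows"))
  a <- particles$area_um2
  diffuse <- a >= windows$diffuse_um2[1] & a <= windows$diffuse_um2[2]
  perik <- a >= windows$perikaryal_um2[1] & a <= windows$perikaryal_um2[2]
  out <- data.frame(
    diffuse_count = sum(diffuse),
    perikaryal_count = sum(perik),
    other_count = sum(!diffuse & !perik)
  )
  class(out) <- c("particle_class_counts", class(out))
  out
}

#' Mean class counts over a sample's images
#'
#' Three representative fields are captured per sample and region; the
#' sample's value is the arithmetic mean of its per-image counts.
#'
#' @param per_image_counts list of `particle_class_counts` rows (or a data
#'   frame with `diffuse_count`/`perikaryal_count`/`other_count` columns).
#' @return one-row data frame: `diffuse_mean`, `perikaryal_mean`,
#'   `other_mean`, `n_images`.
#' @export
sample_mean_counts <- function(per_image_counts) {
  if (is.data.frame(per_image_counts)) {
    df <- per_image_counts
  } else {
    if (length(per_image_counts) == 0) {
      stop("at least one image's counts are required")
    }
    df <- do.call(rbind, per_image_counts)
  }
  if (nrow(df) == 0) stop("at least one image's counts are required")
  data.frame(
    diffuse_mean = mean(df$diffuse_count),
    perikaryal_mean = mean(df$perikaryal_count),
    other_mean = mean(df$other_count),
    n_images = nrow(df)
  )
}

#' GFAP burden
#'
#' Percentage of a region of interest occupied by GFAP-immunostained
#' astrocyte signal: `100 * stain area / ROI area`.
#'
#' @param stain_area_um2 stained area within the ROI (um^2).
#' @param roi_area_um2 total ROI area (um^2), `> 0`.
#' @return burden in percent, in `[0, 100]`.
#' @examples
#' gfap_burden(25, 100)  # 25
#' @export
gfap_burden <- function(stain_area_um2, roi_area_um2) {
  if (any(roi_area_um2 <= 0)) stop("`roi_area_um2` must be > 0")
  if (any(stain_area_um2 < 0)) stop("`stain_area_um2` must be >= 0")
  if (any(stain_area_um2 > roi_area_um2)) {
    stop("stained area cannot exceed the ROI area")
  }
  100 * stain_area_um2 / roi_area_um2
}
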