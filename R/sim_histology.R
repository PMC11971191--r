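#' Specification of a synthetic histology field
#'
#' Describes one simulated microscope field: diffuse dot-like particles with
#' areas drawn uniformly from the diffuse window (1.5-3.5 um^2, the size of
#' the small multimeric tau-PLA signal) and large perikaryal blobs drawn
#' from the perikaryal window (12.5-100 um^2, tangle-sized lesions), placed
#' without overlap on a noisy background.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um micrometres per pixel edge (default 0.25, typical of
#'   a 40x scan).
#' @param n_diffuse,n_perikaryal object counts per class.
#' @param diffuse_um2,perikaryal_um2 closed area windows the two classes are
#'   drawn from.
#' @param foreground_intensity intensity of object pixels; must exceed
#'   `background_mean + 3 * background_sd`.
#' @param background_mean,background_sd background intensity model (noise is
#'   truncated at three SDs, so background never reaches the foreground).
#' @param min_separation_px minimum Chebyshev distance between pixels of
#'   different objects; `>= 2` guarantees objects cannot merge under
#'   8-connectivity.
#' @param max_attempts rejection-sampling attempts per object before the
#'   generator gives up with a density error.
#' @return an object of class `histology_spec`.
#' @export
histology_image_spec <- function(width_px = 512L, height_px = 512L,
                                 pixel_size_um = 0.25, n_diffuse = 30L,
                                 n_perikaryal = 5L,
                                 diffuse_um2 = c(1.5, 3.5),
                                 perikaryal_um2 = c(12.5, 100),
                                 foreground_intensity = 30000L,
                                 background_mean = 2000,
                                 background_sd = 300,
                                 min_separation_px = 2L,
                                 max_attempts = 500L) {
  stopifnot(width_px >= 8, height_px >= 8, n_diffuse >= 0, n_perikaryal >= 0,
            length(diffuse_um2) == 2, length(perikaryal_um2) == 2,
            diffuse_um2[1] > 0, perikaryal_um2[1] > 0,
            diffuse_um2[2] < perikaryal_um2[1] || n_diffuse == 0 ||
              n_perikaryal == 0)
  assert_scalar_num(pixel_size_um, "pixel_size_um", lower = 0,
                    strict_lower = TRUE)
  if (foreground_intensity <= background_mean + 3 * background_sd) {
    stop("foreground_intensity must exceed background_mean + 3*background_sd")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um, n_diffuse = as.integer(n_diffuse),
         n_perikaryal = as.integer(n_perikaryal),
         diffuse_um2 = diffuse_um2, perikaryal_um2 = perikaryal_um2,
         foreground_intensity = as.integer(foreground_intensity),
         background_mean = background_mean, background_sd = background_sd,
         min_separation_px = as.integer(min_separation_px),
         max_attempts = as.integer(max_attempts)),
    class = "histology_spec"
  )
}

#' Simulate a histology field with known particle ground truth
#'
#' Perikaryal blobs (ellipses with axis ratio in \[1, 2\]) are placed first,
#' then diffuse dots (disks), each rasterized to an exact pixel budget so
#' the pixelated area always equals the requested area to within one pixel
#' and stays inside its class window. Objects are rejected until they clear
#' every previously placed object by `min_separation_px`.
#'
#' @param spec a [histology_image_spec()].
#' @param seed integer seed; the image and its ground truth are a pure
#'   function of (`spec`, `seed`).
#' @return a list of class `sim_histology` with
#'   \describe{
#'     \item{image}{an [image_grid()], 16-bit intensities;}
#'     \item{ground_truth}{data frame: `class` ("diffuse"/"perikaryal"),
#'       `requested_area_um2`, `area_um2` (pixelated), `n_px`,
#'       `centroid_row`, `centroid_col`;}
#'     \item{spec, seed}{inputs echoed back.}
#'   }
#' @export
simulate_histology_image <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "histology_spec"))
  with_seed(seed, {
    nr <- spec$height_px; nc <- spec$width_px
    img <- matrix(
      pmin(65535, pmax(0, round(rnorm_trunc(nr * nc, spec$background_mean,
                                            spec$background_sd)))),
      nrow = nr, ncol = nc
    )
    blocked <- matrix(FALSE, nr, nc)
    pa <- spec$pixel_size_um^2
    # large objects first: easier packing
    plan <- rbind(
      if (spec$n_perikaryal > 0)
        data.frame(class = "perikaryal",
                   area = stats::runif(spec$n_perikaryal,
                                       spec$perikaryal_um2[1],
                                       spec$perikaryal_um2[2]),
                   lo = spec$perikaryal_um2[1], hi = spec$perikaryal_um2[2]),
      if (spec$n_diffuse > 0)
        data.frame(class = "diffuse",
                   area = stats::runif(spec$n_diffuse, spec$diffuse_um2[1],
                                       spec$diffuse_um2[2]),
                   lo = spec$diffuse_um2[1], hi = spec$diffuse_um2[2])
    )
    gt <- list()
    if (!is.null(plan)) {
      for (i in seq_len(nrow(plan))) {
        n_px <- area_to_pixels(plan$area[i], spec$pixel_size_um,
                               plan$lo[i], plan$hi[i])
        ratio <- if (plan$class[i] == "perikaryal") stats::runif(1, 1, 2) else 1
        angle <- if (ratio > 1) stats::runif(1, 0, pi) else 0
        margin <- ceiling(sqrt(n_px * ratio / pi)) + 3L
        placed <- FALSE
        for (att in seq_len(spec$max_attempts)) {
          cr <- sample.int(nr - 2L * margin, 1L) + margin
          cc <- sample.int(nc - 2L * margin, 1L) + margin
          px <- rasterize_blob(cr, cc, n_px, ratio, angle)
          if (!any(blocked[px])) {
            img[px] <- spec$foreground_intensity
            blocked <- mark_dilated(blocked, px, spec$min_separation_px)
            gt[[length(gt) + 1L]] <- data.frame(
              class = plan$class[i], requested_area_um2 = plan$area[i],
              area_um2 = n_px * pa, n_px = n_px,
              centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2])
            )
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf(
            paste0("could not place object %d of %d after %d attempts; ",
                   "field too dense for the requested object count"),
            i, nrow(plan), spec$max_attempts
          ))
        }
      }
    }
    structure(
      list(
        image = image_grid(img, spec$pixel_size_um),
        ground_truth = if (length(gt)) do.call(rbind, gt) else
          data.frame(class = character(), requested_area_um2 = numeric(),
                     area_um2 = numeric(), n_px = integer(),
                     centroid_row = numeric(), centroid_col = numeric()),
        spec = spec, seed = as.integer(seed)
      ),
      class = "sim_histology"
    )
  })
}
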