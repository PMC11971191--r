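#' Simulate a two-channel FRET biosensor cell field
#'
#' Channel 1 carries `n_cells` disk-shaped cells; channel 2 carries bright
#' puncta (intracellular inclusions) in exactly
#' `round(n_cells * inclusion_fraction)` of them, so the true
#' inclusion-bearing percentage is known by construction. Cells are placed
#' with a separation margin so segmentation cannot merge neighbours, and
#' each punctum lies strictly inside its cell's mask.
#'
#' @param n_cells number of cells, `>= 1`.
#' @param inclusion_fraction fraction of cells carrying inclusions, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param width_px,height_px field size in pixels.
#' @param cell_radius_px cell disk radius (pixels).
#' @param cell_intensity,punctum_intensity foreground intensities of the two
#'   channels.
#' @param background_mean,background_sd shared background model (truncated
#'   Gaussian noise).
#' @param puncta_per_cell c(min, max) puncta drawn per flagged cell.
#' @param punctum_n_px pixels per punctum (default 9, comfortably above the
#'   4-px scoring floor).
#' @param max_attempts placement attempts per cell before an overcrowding
#'   error.
#' @return a list of class `sim_fret` with
#'   \describe{
#'     \item{cells}{channel-1 [image_grid()];}
#'     \item{inclusions}{channel-2 [image_grid()];}
#'     \item{ground_truth}{data frame per cell: `cell_id`, `centroid_row`,
#'       `centroid_col`, `has_inclusion`;}
#'     \item{true_fraction}{`round(n_cells*inclusion_fraction)/n_cells`;}
#'     \item{seed}{the seed.}
#'   }
#' @export
simulate_fret_field <- function(n_cells, inclusion_fraction, seed = 1L,
                                width_px = 512L, height_px = 512L,
                                cell_radius_px = 7L,
                                cell_intensity = 20000L,
                                punctum_intensity = 40000L,
                                background_mean = 1000,
                                background_sd = 150,
                                puncta_per_cell = c(1L, 3L),
                                punctum_n_px = 9L,
                                max_attempts = 2000L) {
  stopifnot(n_cells >= 1, inclusion_fraction >= 0, inclusion_fraction <= 1)
  n_flagged <- round(n_cells * inclusion_fraction)
  with_seed(seed, {
    nr <- height_px; nc <- width_px
    bg <- function() matrix(
      pmin(65535, pmax(0, round(rnorm_trunc(nr * nc, background_mean,
                                            background_sd)))),
      nrow = nr, ncol = nc
    )
    ch1 <- bg(); ch2 <- bg()
    blocked <- matrix(FALSE, nr, nc)
    margin <- cell_radius_px + 3L
    centers <- matrix(NA_real_, n_cells, 2)
    masks <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        cr <- sample.int(nr - 2L * margin, 1L) + margin
        cc <- sample.int(nc - 2L * margin, 1L) + margin
        px <- rasterize_blob(cr, cc, round(pi * cell_radius_px^2))
        if (!any(blocked[px])) {
          ch1[px] <- cell_intensity
          blocked <- mark_dilated(blocked, px, 3L)
          centers[i, ] <- c(cr, cc)
          masks[[i]] <- px
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "could not place cell %d of %d: field overcrowded (radius %d px in %d x %d)",
          i, n_cells, cell_radius_px, width_px, height_px
        ))
      }
    }
    flagged <- rep(FALSE, n_cells)
    if (n_flagged > 0) flagged[sample.int(n_cells, n_flagged)] <- TRUE
    for (i in which(flagged)) {
      k <- sample(seq.int(puncta_per_cell[1], puncta_per_cell[2]), 1L)
      for (j in seq_len(k)) {
        # offset punctum centre within the cell so the punctum stays inside
        max_off <- max(0L, cell_radius_px - ceiling(sqrt(punctum_n_px / pi)) - 1L)
        dr <- sample.int(2L * max_off + 1L, 1L) - max_off - 1L
        dc <- sample.int(2L * max_off + 1L, 1L) - max_off - 1L
        px <- rasterize_blob(centers[i, 1] + dr, centers[i, 2] + dc,
                             punctum_n_px)
        ch2[px] <- punctum_intensity
      }
    }
    structure(
      list(
        cells = image_grid(ch1, 1),
        inclusions = image_grid(ch2, 1),
        ground_truth = data.frame(
          cell_id = seq_len(n_cells), centroid_row = centers[, 1],
          centroid_col = centers[, 2], has_inclusion = flagged
        ),
        true_fraction = n_flagged / n_cells,
        seed = as.integer(seed)
      ),
      class = "sim_fret"
    )
  })
}
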