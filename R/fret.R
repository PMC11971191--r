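#' Detect cells in the biosensor cell channel
#'
#' Thresholds the cell channel and keeps 8-connected components with at
#' least `min_cell_area` pixels as cells. Touching cells merge into one
#' component; the generator places cells with a separation margin so this
#' limitation does not bias synthetic benchmarks.
#'
#' @param cell_channel an [image_grid()] (channel 1).
#' @param threshold intensity threshold or `"otsu"`.
#' @param min_cell_area minimum pixel area of a cell component (default 20).
#' @return list with `labels` (integer matrix, 0 = background, one positive
#'   label per cell) and `cells` (data frame `cell`, `pixel_count`,
#'   `centroid_row`, `centroid_col`). Zero cells is a valid result.
#' @export
detect_cells <- function(cell_channel, threshold, min_cell_area = 20L) {
  stopifnot(inherits(cell_channel, "image_grid"))
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(cell_channel$intensities)
  }
  labels <- label_components(cell_channel$intensities > threshold, 8L)
  n <- max(labels)
  if (n > 0L) {
    cnt <- tabulate(labels[labels > 0L], n)
    keep <- which(cnt >= min_cell_area)
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    n <- length(keep)
  }
  if (n == 0L) {
    return(list(labels = labels,
                cells = data.frame(cell = integer(), pixel_count = integer(),
                                   centroid_row = numeric(),
                                   centroid_col = numeric())))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  list(
    labels = labels,
    cells = data.frame(
      cell = seq_len(n),
      pixel_count = tabulate(lab, n),
      centroid_row = as.numeric(tapply(rows, lab, mean)),
      centroid_col = as.numeric(tapply(cols, lab, mean))
    )
  )
}

#' Score cells for intracellular inclusions
#'
#' A cell is inclusion-positive when at least one connected bright region of
#' `min_punctum_px` or more pixels above `punctum_threshold` lies inside its
#' mask. Returns the percentage of inclusion-bearing cells — the cell-assay
#' seeding readout.
#'
#' @param cells result of [detect_cells()].
#' @param inclusion_channel an [image_grid()] (channel 2), same size as the
#'   cell channel.
#' @param punctum_threshold intensity threshold for puncta.
#' @param min_punctum_px minimum punctum size in pixels (default 4,
#'   suppressing single-pixel noise).
#' @return one-row data frame of class `inclusion_result`: `n_cells`,
#'   `n_with_inclusions`, `percent`. With zero cells `percent` is `NA` and
#'   a warning is raised.
#' @export
score_inclusions <- function(cells, inclusion_channel, punctum_threshold,
                             min_punctum_px = 4L) {
  stopifnot(inherits(inclusion_channel, "image_grid"))
  labels <- cells$labels
  if (!is.matrix(labels) ||
      !all(dim(labels) == dim(inclusion_channel$intensities))) {
    stop("cell labels and inclusion channel must have identical dimensions")
  }
  n_cells <- nrow(cells$cells)
  if (n_cells == 0L) {
    warning("no cells detected; inclusion percentage undefined")
    out <- data.frame(n_cells = 0L, n_with_inclusions = 0L,
                      percent = NA_real_)
    class(out) <- c("inclusion_result", class(out))
    return(out)
  }
  puncta <- label_components(
    inclusion_channel$intensities > punctum_threshold, 8L
  )
  pos <- logical(n_cells)
  np <- max(puncta)
  if (np > 0L) {
    sizes <- tabulate(puncta[puncta > 0L], np)
    idx <- which(puncta > 0L)
    ok <- sizes[puncta[idx]] >= min_punctum_px
    idx <- idx[ok]
    hosts <- unique(labels[idx])
    # a punctum straddling background and a cell still counts for the cell
    # pixels it covers
    hosts <- hosts[hosts > 0L]
    pos[hosts] <- TRUE
  }
  out <- data.frame(
    n_cells = n_cells,
    n_with_inclusions = sum(pos),
    percent = 100 * sum(pos) / n_cells
  )
  class(out) <- c("inclusion_result", class(out))
  out
}

#' Inclusion percentage of a whole field
#'
#' Convenience wrapper: detect cells in channel 1, score puncta in channel
#' 2, return the [score_inclusions()] result.
#'
#' @param field a `sim_fret` object or a list with `cells` and `inclusions`
#'   [image_grid()]s.
#' @param cell_threshold,punctum_threshold intensity thresholds; defaults
#'   suit the generator's intensity model.
#' @param min_cell_area,min_punctum_px size floors passed through.
#' @return an `inclusion_result` row.
#' @export
fret_field_percent <- function(field, cell_threshold = 10000,
                               punctum_threshold = 30000,
                               min_cell_area = 20L, min_punctum_px = 4L) {
  cells <- detect_cells(field$cells, cell_threshold, min_cell_area)
  score_inclusions(cells, field$inclusions, punctum_threshold,
                   min_punctum_px)
}
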