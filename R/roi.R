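#' Per-frame mean intensity of labelled ROIs
#'
#' Reproduces ImageJ Multi Measure on a label-mask segmentation: for each
#' frame and each nonzero label, the arithmetic mean (in double
#' precision) of the stack values over the pixels carrying that label.
#' Mask label 0 means unassigned; one label is designated the cell-free
#' background region and becomes the table's background column.
#'
#' @param stack T x Y x X numeric array of intensities.
#' @param mask Y x X integer label matrix matching the frame shape.
#' @param duration_s Recording duration in seconds.
#' @param background_label Label of the background region (default: the
#'   largest label present).
#' @return A [intensity_table()] with one `ROI<label>` column per cell
#'   label (ascending label order) and a `Background` column.
#' @export
#' @examples
#' st <- simulate_stack(n_cells = 2, image_shape = c(32, 32), cell_radius = 4)
#' tbl <- extract_mean_intensities(st$stack, st$mask, duration_s = 15,
#'                                 background_label = st$background_label)
extract_mean_intensities <- function(stack, mask, duration_s,
                                     background_label = NULL) {
  if (length(dim(stack)) != 3L) abort("`stack` must be a T x Y x X array.")
  if (!is.matrix(mask) || !identical(dim(stack)[2:3], dim(mask))) {
    abort(sprintf(
      "Mask shape (%s) does not match frame shape (%s).",
      paste(dim(mask), collapse = "x"), paste(dim(stack)[2:3], collapse = "x")
    ))
  }
  labels <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labels) < 2L) {
    abort("Need at least 2 labels (>= 1 cell plus a background region).")
  }
  background_label <- as.integer(background_label %||% max(labels))
  if (!background_label %in% labels) {
    abort(sprintf("Background label %d has zero pixels in the mask.",
                  background_label))
  }
  nt <- dim(stack)[1]
  flat <- matrix(as.numeric(stack), nrow = nt) # frames x pixels, mask order
  fm <- as.vector(mask)
  means <- lapply(labels, function(lab) {
    idx <- which(fm == lab)
    rowMeans(flat[, idx, drop = FALSE])
  })
  cells <- setdiff(labels, background_label)
  df <- setNames(
    c(means[match(cells, labels)], means[match(background_label, labels)]),
    c(paste0("ROI", cells), "Background")
  )
  intensity_table(as_tibble(df), duration_s = duration_s,
                  background = "Background")
}
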