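#' Measure per-object area and channel intensities
#'
#' For every labelled object, computes the pixel count (area), centroid,
#' and the integrated (sum) and mean intensity in each channel, measured on
#' the corrected, unsmoothed images. `integrated = mean * area` holds by
#' construction.
#'
#' @param labels integer label matrix (0 = background).
#' @param hoechst,sytox intensity matrices, same shape as `labels`.
#' @param metadata optional named list (e.g. `image_id`, `animal`,
#'   `treatment`, `replicate`) replicated onto every row.
#' @return data frame with one row per object, ordered by `object_id`;
#'   an empty mask yields a zero-row frame with the full set of columns.
#' @export
measure_objects <- function(labels, hoechst, sytox, metadata = NULL) {
  if (!all(dim(labels) == dim(hoechst)) || !all(dim(labels) == dim(sytox)))
    stop("labels and channel images must have identical shapes")
  nlab <- max(labels)
  empty <- data.frame(object_id = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      hoechst_integrated = numeric(0), hoechst_mean = numeric(0),
                      sytox_integrated = numeric(0), sytox_mean = numeric(0))
  tab <- if (nlab == 0L) empty else {
    idx <- which(labels > 0)
    lab <- labels[idx]
    # labels absent from the mask (possible in ground-truth masks where a
    # cell was fully overwritten) yield no row
    present <- sort(unique(lab))
    area <- tabulate(lab, nbins = nlab)[present]
    rows <- (idx - 1L) %% nrow(labels) + 1L
    cols <- (idx - 1L) %/% nrow(labels) + 1L
    sum_by <- function(x) as.vector(rowsum(x, lab, reorder = TRUE))
    hsum <- sum_by(hoechst[idx])
    ssum <- sum_by(sytox[idx])
    data.frame(object_id = present,
               area = area,
               centroid_row = sum_by(rows) / area,
               centroid_col = sum_by(cols) / area,
               hoechst_integrated = hsum,
               hoechst_mean = hsum / area,
               sytox_integrated = ssum,
               sytox_mean = ssum / area)
  }
  if (!is.null(metadata))
    for (nm in rev(names(metadata)))
      tab <- cbind(stats::setNames(
        data.frame(rep(metadata[[nm]], length.out = max(nrow(tab), 0)),
                   stringsAsFactors = FALSE), nm), tab)
  tab
}

#' Merge object measurements with image-level QC and metadata
#'
#' Inner join of the per-object table with the per-image QC verdict:
#' objects from images that failed focus QC are excluded; rows from passing
#' images survive unchanged. Optional image metadata is joined on
#' `image_id`.
#'
#' @param object_table data frame with an `image_id` column (e.g. from
#'   [measure_objects()]).
#' @param qc_table per-channel QC records (as from [qc_report()]) or any
#'   data frame with `image_id` and logical `passed`; an image passes only
#'   if all of its rows pass.
#' @param metadata optional data frame keyed by `image_id`.
#' @return filtered, joined data frame.
#' @export
merge_image_and_object_tables <- function(object_table, qc_table,
                                          metadata = NULL) {
  stopifnot("image_id" %in% names(object_table),
            all(c("image_id", "passed") %in% names(qc_table)))
  unknown <- setdiff(object_table$image_id, qc_table$image_id)
  if (length(unknown))
    stop("object rows reference image_id absent from QC table: ",
         paste(unknown, collapse = ", "))
  pass <- tapply(qc_table$passed, qc_table$image_id, all)
  keep_ids <- names(pass)[pass]
  out <- object_table[object_table$image_id %in% keep_ids, , drop = FALSE]
  if (!is.null(metadata)) {
    out <- merge(out, metadata, by = "image_id", sort = FALSE)
  }
  rownames(out) <- NULL
  out
}
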