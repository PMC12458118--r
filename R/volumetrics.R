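#' Per-class tissue volumes
#'
#' Volume per tissue class as voxel count times voxel volume (mm^3).
#'
#' @param labels a \code{tissue_labels} (or plain integer 3D array with
#'   codes 0 outside, 1 uninjured, 2 penumbra, 3 core).
#' @param voxel_size mm per axis; taken from \code{labels} when it is a
#'   \code{tissue_labels}.
#' @param subject_id,timepoint_h,group optional metadata carried into the
#'   output rows.
#' @return Data frame: one row per class (\code{uninjured}, \code{penumbra},
#'   \code{core}) with \code{n_voxels} and \code{volume_mm3}, plus any
#'   metadata columns.
#' @export
class_volumes <- function(labels, voxel_size = NULL, subject_id = NULL,
                          timepoint_h = NULL, group = NULL) {
  if (inherits(labels, "tissue_labels")) {
    voxel_size <- labels$voxel_size
    labels <- labels$labels
  }
  if (is.null(voxel_size)) stop("voxel_size required for a bare label array")
  codes <- unique(as.vector(labels))
  if (!all(codes %in% 0:3)) {
    stop("unknown label codes: ", paste(setdiff(codes, 0:3), collapse = ", "))
  }
  vox <- prod(voxel_size)
  n <- tabulate(labels[labels > 0L], nbins = 3L)
  out <- data.frame(class = c("uninjured", "penumbra", "core"),
                    n_voxels = n, volume_mm3 = n * vox)
  if (!is.null(subject_id)) out$subject <- subject_id
  if (!is.null(timepoint_h)) out$timepoint_h <- timepoint_h
  if (!is.null(group)) out$group <- group
  out
}

#' Hemisphere volumes and lost tissue
#'
#' Splits an in-brain mask at a sagittal midline column and computes the
#' volume of each hemisphere; tissue loss is the volume of the intact
#' (contralateral) hemisphere minus the injured (ipsilateral) one, clipped
#' at zero. A negative difference (ipsilateral swelling) yields zero loss
#' and sets the \code{swelling} flag. This lost-tissue class excludes core
#' and penumbra by construction: those voxels are still present in the
#' mask, so they never enter the difference.
#'
#' @param brain_mask logical 3D array.
#' @param midline_col last column of the contralateral side; must be
#'   strictly inside the grid.
#' @param voxel_size mm per axis.
#' @param ipsilateral_side \code{"right"} (columns above the midline;
#'   default) or \code{"left"}.
#' @return List: \code{ipsilateral_mm3}, \code{contralateral_mm3},
#'   \code{lost_mm3}, \code{swelling}.
#' @export
hemisphere_volumes <- function(brain_mask, midline_col, voxel_size,
                               ipsilateral_side = c("right", "left")) {
  ipsilateral_side <- match.arg(ipsilateral_side)
  stopifnot(length(dim(brain_mask)) == 3L)
  if (midline_col < 1L || midline_col >= dim(brain_mask)[2L]) {
    stop("midline_col must lie strictly inside the grid")
  }
  vox <- prod(voxel_size)
  cols <- slice.index(brain_mask, 2L)
  high <- sum(brain_mask & cols > midline_col) * vox
  low <- sum(brain_mask & cols <= midline_col) * vox
  ipsi <- if (ipsilateral_side == "right") high else low
  contra <- if (ipsilateral_side == "right") low else high
  list(ipsilateral_mm3 = ipsi, contralateral_mm3 = contra,
       lost_mm3 = max(0, contra - ipsi), swelling = ipsi > contra)
}

#' Long-format longitudinal volume table with group summaries
#'
#' Binds per-scan class volumes (and optional lost-tissue rows) into one
#' tidy long table — (subject, group, timepoint_h, class, volume_mm3) —
#' ready for external repeated-measures analysis, plus a per-group
#' mean +/- SD summary by timepoint and class.
#'
#' @param records data frame with columns \code{subject}, \code{group},
#'   \code{timepoint_h}, \code{class}, \code{volume_mm3} (e.g. rbind-ed
#'   [class_volumes()] outputs, optionally with \code{class = "lost"} rows
#'   from [hemisphere_volumes()]).
#' @return List of two data frames: \code{long} (sorted) and \code{summary}
#'   (\code{group}, \code{timepoint_h}, \code{class}, \code{n},
#'   \code{mean_mm3}, \code{sd_mm3}).
#' @export
longitudinal_table <- function(records) {
  need <- c("subject", "group", "timepoint_h", "class", "volume_mm3")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  key <- paste(records$subject, records$timepoint_h, records$class)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, timepoint, class) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  long <- records[order(records$group, records$subject,
                        records$timepoint_h, records$class),
                  need, drop = FALSE]
  rownames(long) <- NULL
  agg <- stats::aggregate(volume_mm3 ~ group + timepoint_h + class,
                          data = long,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  summary <- data.frame(group = agg$group, timepoint_h = agg$timepoint_h,
                        class = agg$class,
                        n = agg$volume_mm3[, "n"],
                        mean_mm3 = agg$volume_mm3[, "mean"],
                        sd_mm3 = agg$volume_mm3[, "sd"])
  summary <- summary[order(summary$group, summary$timepoint_h,
                           summary$class), , drop = FALSE]
  rownames(summary) <- NULL
  list(long = long, summary = summary)
}
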