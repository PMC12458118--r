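#' Segmentation parameters
#'
#' Tunable parameters of the hierarchical region-split segmentation. The
#' two physiological thresholds follow the edema-staging convention:
#' regions whose histogram mode exceeds \code{core_mode_threshold} (56 ms)
#' are ischemic core, other lesion regions penumbra, and any voxel with T2
#' below \code{uninjured_t2_threshold} (33 ms) is relabeled uninjured. Both
#' comparisons are strict.
#'
#' @param core_mode_threshold ms; a leaf is core when its mode is strictly
#'   greater than this.
#' @param uninjured_t2_threshold ms; a voxel is uninjured when its T2 is
#'   strictly less than this.
#' @param bin_width histogram bin width, ms.
#' @param smoothing_bandwidth Gaussian smoothing bandwidth, ms.
#' @param min_region_voxels smallest region allowed to result from a split.
#' @param max_depth recursion depth limit.
#' @param bimodality_min_prominence minimum peak prominence, as a fraction
#'   of the tallest smoothed bin, for a mode to count toward bimodality.
#' @return A \code{segmentation_params} list.
#' @export
segmentation_params <- function(core_mode_threshold = 56,
                                uninjured_t2_threshold = 33,
                                bin_width = 1,
                                smoothing_bandwidth = 2,
                                min_region_voxels = 30,
                                max_depth = 6,
                                bimodality_min_prominence = 0.05) {
  stopifnot(bin_width > 0, smoothing_bandwidth >= 0,
            min_region_voxels >= 1, max_depth >= 0,
            bimodality_min_prominence >= 0, bimodality_min_prominence <= 1)
  if (!(uninjured_t2_threshold > 0 &&
        uninjured_t2_threshold < core_mode_threshold)) {
    stop("need 0 < uninjured_t2_threshold < core_mode_threshold")
  }
  structure(list(core_mode_threshold = core_mode_threshold,
                 uninjured_t2_threshold = uninjured_t2_threshold,
                 bin_width = bin_width,
                 smoothing_bandwidth = smoothing_bandwidth,
                 min_region_voxels = as.integer(min_region_voxels),
                 max_depth = as.integer(max_depth),
                 bimodality_min_prominence = bimodality_min_prominence),
            class = "segmentation_params")
}

#' Build a (smoothed) T2 histogram
#'
#' Fixed-width bins covering the value range; smoothed counts by discrete
#' convolution with a Gaussian kernel (truncated at 4 bandwidths and
#' renormalized at the edges). Raw counts always sum to the number of
#' contributing voxels.
#'
#' @param t2_values T2 times, ms (at least one).
#' @param bin_width bin width, ms.
#' @param smoothing_bandwidth Gaussian kernel bandwidth, ms (0 = no
#'   smoothing; smoothed counts then equal raw counts).
#' @return A \code{t2_histogram}: \code{bin_edges} (length bins + 1),
#'   \code{mids}, \code{counts}, \code{smoothed}.
#' @export
build_histogram <- function(t2_values, bin_width = 1,
                            smoothing_bandwidth = 2) {
  t2_values <- t2_values[is.finite(t2_values)]
  if (!length(t2_values)) stop("no T2 values to histogram")
  stopifnot(bin_width > 0, smoothing_bandwidth >= 0)
  lo <- floor(min(t2_values) / bin_width) * bin_width
  hi <- ceiling(max(t2_values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  # left-closed bins, last bin closed on both sides
  counts <- tabulate(pmin(findInterval(t2_values, edges),
                          length(edges) - 1L),
                     nbins = length(edges) - 1L)
  smoothed <- gaussian_smooth_counts(counts, smoothing_bandwidth / bin_width)
  structure(list(bin_edges = edges,
                 mids = (edges[-1L] + edges[-length(edges)]) / 2,
                 counts = counts, smoothed = smoothed),
            class = "t2_histogram")
}

# discrete Gaussian smoothing; kernel renormalized at the boundaries
gaussian_smooth_counts <- function(counts, sd_bins) {
  if (sd_bins <= 0 || length(counts) < 2L) return(as.numeric(counts))
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  n <- length(counts)
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- vapply(seq_len(n), function(i) {
    sum(padded[i:(i + 2L * half)] * k)
  }, numeric(1))
  # renormalize: weight actually applied at each position
  wt <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sum(k[(lo - i + half + 1L):(hi - i + half + 1L)])
  }, numeric(1))
  sm / wt
}

# local maxima of a vector (plateaus collapse to their first index) with
# topographic prominence
find_peaks <- function(y) {
  n <- length(y)
  if (n < 1L) return(data.frame(index = integer(), prominence = numeric()))
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    # previous strictly different neighbour
    l <- i - 1L
    while (l >= 1L && y[l] == y[i]) l <- l - 1L
    r <- i + 1L
    # plateaus: only their first index counts
    if (i > 1L && y[i - 1L] == y[i]) next
    while (r <= n && y[r] == y[i]) r <- r + 1L
    left_ok <- l < 1L || y[l] < y[i]
    right_ok <- r > n || y[r] < y[i]
    is_peak[i] <- left_ok && right_ok && y[i] > 0
  }
  idx <- which(is_peak)
  prom <- vapply(idx, function(i) {
    # walk left/right to the nearest strictly higher bar; prominence is the
    # peak height above the higher of the two intervening minima; a side
    # with no higher bar contributes no base, so a global maximum keeps its
    # full height
    left_min <- y[i]
    j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) {
      left_min <- min(left_min, y[j]); j <- j - 1L
    }
    lbase <- if (j >= 1L) left_min else -Inf
    right_min <- y[i]
    j <- i + 1L
    while (j <= length(y) && y[j] <= y[i]) {
      right_min <- min(right_min, y[j]); j <- j + 1L
    }
    rbase <- if (j <= length(y)) right_min else -Inf
    base <- max(lbase, rbase)
    if (is.finite(base)) y[i] - base else y[i]
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Locate the valley between the two dominant histogram modes
#'
#' Identifies local maxima of the smoothed histogram, keeps those whose
#' topographic prominence is at least \code{min_prominence} of the tallest
#' smoothed bin, and takes the two most prominent. Returns the T2 (bin
#' midpoint) at the global minimum of the smoothed counts strictly between
#' them, ties broken toward lower T2. Returns \code{NULL} when fewer than
#' two qualifying modes exist — a unimodal region is a leaf, not an error.
#'
#' @param hist a \code{t2_histogram}.
#' @param min_prominence fraction of the tallest smoothed bin.
#' @return Valley T2 in ms, or \code{NULL}.
#' @export
find_valley <- function(hist, min_prominence = 0.05) {
  stopifnot(inherits(hist, "t2_histogram"))
  y <- hist$smoothed
  pk <- find_peaks(y)
  if (nrow(pk) < 2L) return(NULL)
  pk <- pk[pk$prominence >= min_prominence * max(y), , drop = FALSE]
  if (nrow(pk) < 2L) return(NULL)
  # two most prominent; prominence ties broken toward lower T2
  ord <- order(-pk$prominence, pk$index)
  two <- sort(pk$index[ord[1:2]])
  between <- (two[1L] + 1L):(two[2L] - 1L)
  if (!length(between) || two[2L] - two[1L] < 2L) return(NULL)
  vi <- between[which.min(y[between])]
  hist$mids[vi]
}

#' Mode (peak T2) of a histogram
#'
#' T2 bin midpoint at the maximum of the smoothed counts (ties toward lower
#' T2).
#' @param hist a \code{t2_histogram}.
#' @return T2 in ms.
#' @export
histogram_mode <- function(hist) {
  stopifnot(inherits(hist, "t2_histogram"))
  hist$mids[which.max(hist$smoothed)]
}

#' Recursive hierarchical region split
#'
#' The central segmentation procedure: build the region's T2 histogram,
#' find the valley between its two dominant modes, split the region into
#' \code{T2 <= valley} and \code{T2 > valley} sub-regions, and recurse.
#' Recursion stops when a region is unimodal (no qualifying valley), when a
#' split would produce a child smaller than \code{min_region_voxels}, or at
#' \code{max_depth}.
#'
#' @param t2_values per-voxel T2, ms; must all be finite (pre-filter to
#'   valid fits).
#' @param voxel_ids identifiers parallel to \code{t2_values} (e.g. linear
#'   voxel indices).
#' @param params a [segmentation_params()].
#' @param depth recursion depth of this node (internal).
#' @return A \code{region_node}: \code{voxel_ids}, \code{t2_values},
#'   \code{mode_t2}, \code{split_threshold} (\code{NULL} on leaves),
#'   \code{children} (list of 0 or 2 nodes), \code{depth}.
#' @export
hierarchical_split <- function(t2_values, voxel_ids = seq_along(t2_values),
                               params = segmentation_params(), depth = 0L) {
  if (!length(t2_values)) stop("empty region")
  if (any(!is.finite(t2_values))) {
    stop("region contains invalid-fit voxels; pre-filter to valid fits")
  }
  stopifnot(length(voxel_ids) == length(t2_values))
  h <- build_histogram(t2_values, params$bin_width,
                       params$smoothing_bandwidth)
  mode_t2 <- histogram_mode(h)
  node <- structure(list(voxel_ids = voxel_ids, t2_values = t2_values,
                         mode_t2 = mode_t2, split_threshold = NULL,
                         children = list(), depth = depth),
                    class = "region_node")
  if (depth >= params$max_depth) return(node)
  valley <- find_valley(h, params$bimodality_min_prominence)
  if (is.null(valley)) return(node)
  left <- t2_values <= valley
  if (sum(left) < params$min_region_voxels ||
      sum(!left) < params$min_region_voxels) {
    return(node)
  }
  node$split_threshold <- valley
  node$children <- list(
    hierarchical_split(t2_values[left], voxel_ids[left], params,
                       depth + 1L),
    hierarchical_split(t2_values[!left], voxel_ids[!left], params,
                       depth + 1L))
  node
}

region_leaves <- function(node) {
  if (!length(node$children)) return(list(node))
  c(region_leaves(node$children[[1L]]), region_leaves(node$children[[2L]]))
}

#' Classify the leaves of a region tree
#'
#' Every leaf is labeled ischemic core when its histogram mode is strictly
#' greater than \code{core_mode_threshold}, penumbra otherwise; then any
#' voxel whose own T2 is strictly below \code{uninjured_t2_threshold} is
#' relabeled uninjured, as a voxelwise override.
#'
#' @param tree root \code{region_node} from [hierarchical_split()].
#' @param params a [segmentation_params()].
#' @return Integer vector of labels (1 uninjured, 2 penumbra, 3 core) named
#'   by voxel id, in the order the voxels appear across the leaves.
#' @export
classify_leaves <- function(tree, params = segmentation_params()) {
  leaves <- region_leaves(tree)
  ids <- unlist(lapply(leaves, `[[`, "voxel_ids"))
  t2 <- unlist(lapply(leaves, `[[`, "t2_values"))
  lab <- unlist(lapply(leaves, function(lf) {
    cls <- if (lf$mode_t2 > params$core_mode_threshold) 3L else 2L
    rep(cls, length(lf$voxel_ids))
  }))
  lab[t2 < params$uninjured_t2_threshold] <- 1L
  names(lab) <- ids
  lab
}

#' Segment a masked T2 map into core and penumbra
#'
#' Composition of the full procedure on a parametric T2 map restricted to a
#' lesion (edema) region of interest: intersect the mask with valid fits,
#' run the hierarchical region split, classify the leaves, and emit a label
#' volume. The mask stands in for a manual edema outline and exists to keep
#' cerebrospinal fluid and skull-stripping errors out of the histogram.
#'
#' @param t2_map a \code{t2_map} from [fit_t2_map()].
#' @param lesion_mask logical 3D array on the same grid.
#' @param params a [segmentation_params()].
#' @return A \code{tissue_labels}: \code{labels} 3D integer array
#'   (0 outside, 1 uninjured, 2 penumbra, 3 core), \code{voxel_size},
#'   \code{tree} (the region tree, for inspection).
#' @export
segment_lesion <- function(t2_map, lesion_mask,
                           params = segmentation_params()) {
  stopifnot(inherits(t2_map, "t2_map"))
  if (!identical(dim(lesion_mask), dim(t2_map$t2))) {
    stop("lesion mask grid does not match the T2 map")
  }
  domain <- which(lesion_mask & t2_map$valid)
  if (!length(domain)) {
    stop("empty effective mask: no lesion voxels with a valid T2 fit")
  }
  tree <- hierarchical_split(t2_map$t2[domain], domain, params)
  lab <- classify_leaves(tree, params)
  labels <- array(0L, dim = dim(t2_map$t2))
  labels[as.integer(names(lab))] <- lab
  structure(list(labels = labels, voxel_size = t2_map$voxel_size,
                 tree = tree),
            class = "tissue_labels")
}

#' Print a region tree
#'
#' Indented dump: depth, voxel count, mode, split threshold.
#' @param x a \code{region_node}.
#' @param ... unused.
#' @export
print.region_node <- function(x, ...) {
  rec <- function(node) {
    split <- if (is.null(node$split_threshold)) "leaf" else {
      sprintf("split @ %.2f ms", node$split_threshold)
    }
    cat(sprintf("%s[depth %d] n=%d mode=%.2f ms %s\n",
                strrep("  ", node$depth), node$depth,
                length(node$voxel_ids), node$mode_t2, split))
    for (ch in node$children) rec(ch)
  }
  rec(x)
  invisible(x)
}
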