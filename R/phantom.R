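#' Specification of a synthetic multi-echo MRI phantom
#'
#' Describes a bilateral "brain" made of two ellipsoidal hemisphere halves,
#' with an ellipsoidal ischemic core and a surrounding penumbra shell placed
#' inside the ipsilateral hemisphere. Signal follows a mono-exponential echo
#' decay \eqn{S(TE) = S_0 \exp(-TE/T_2)} with a class-specific T2, and
#' magnitude images carry Rician noise. The defaults mirror a small-animal
#' multi-slice multi-echo acquisition: 0.12 x 0.12 mm in-plane voxels,
#' 0.5 mm slices, 10 echoes at TE = 10..100 ms.
#'
#' Class T2 means follow the convention used for neonatal edema staging:
#' uninjured tissue below 33 ms, penumbra intermediate, ischemic core above
#' 56 ms.
#'
#' @param grid_shape integer vector (rows, cols, slices). Rows run
#'   anterior-posterior, columns left-right (the midline splits columns),
#'   slices along the scanner axis.
#' @param voxel_size numeric length-3, mm per axis.
#' @param echo_times numeric vector of echo times in ms, strictly increasing.
#' @param midline_col last column index of the contralateral (left)
#'   hemisphere; columns greater than this are ipsilateral.
#' @param brain_semiaxes ellipsoid semi-axes of the whole brain, in voxels
#'   (rows, cols, slices), centred on the grid centre.
#' @param core_center,core_semiaxes centre (voxel coordinates) and semi-axes
#'   of the ischemic-core ellipsoid.
#' @param penumbra_semiaxes semi-axes of the outer lesion ellipsoid (same
#'   centre as the core); the penumbra is the shell between the two.
#' @param class_t2 named numeric: mean T2 (ms) for classes
#'   \code{uninjured}, \code{penumbra}, \code{core}.
#' @param class_t2_sd named numeric: within-class T2 standard deviation (ms).
#' @param s0 proton-density amplitude, arbitrary signal units.
#' @param noise_sigma Rician noise scale in signal units (0 = noiseless).
#' @param lost_fraction fraction in [0, 1] of ipsilateral non-lesion brain
#'   voxels removed (set to background) to emulate tissue loss; removal
#'   proceeds from the posterior-most rows forward (a wedge).
#' @param seed integer RNG seed.
#' @return An object of class \code{phantom_spec}.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 20L),
                         voxel_size = c(0.12, 0.12, 0.5),
                         echo_times = seq(10, 100, by = 10),
                         midline_col = NULL,
                         brain_semiaxes = NULL,
                         core_center = NULL,
                         core_semiaxes = NULL,
                         penumbra_semiaxes = NULL,
                         class_t2 = c(uninjured = 30, penumbra = 45, core = 70),
                         class_t2_sd = c(uninjured = 1.5, penumbra = 2.5, core = 3),
                         s0 = 1000,
                         noise_sigma = 20,
                         lost_fraction = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (length(echo_times) < 3L || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    stop("echo_times must be >= 3 strictly increasing positive values")
  }
  if (is.null(midline_col)) midline_col <- grid_shape[2L] %/% 2L
  midline_col <- as.integer(midline_col)
  if (midline_col < 1L || midline_col >= grid_shape[2L]) {
    stop("midline_col must lie strictly inside the column range")
  }
  # default geometry scales with the grid
  if (is.null(brain_semiaxes)) {
    brain_semiaxes <- c(0.42, 0.45, 0.46) * grid_shape
  }
  center <- (grid_shape + 1) / 2
  if (is.null(core_center)) {
    # centred in the ipsilateral hemisphere, inside the brain ellipsoid
    core_center <- c(center[1L], midline_col + 0.45 * brain_semiaxes[2L],
                     center[3L])
  }
  if (is.null(core_semiaxes)) core_semiaxes <- c(0.13, 0.10, 0.18) * grid_shape
  if (is.null(penumbra_semiaxes)) penumbra_semiaxes <- 1.55 * core_semiaxes
  need <- c("uninjured", "penumbra", "core")
  stopifnot(all(need %in% names(class_t2)), all(need %in% names(class_t2_sd)),
            all(class_t2 > 0), all(class_t2_sd >= 0))
  if (!(class_t2["uninjured"] < class_t2["penumbra"] &&
        class_t2["penumbra"] < class_t2["core"])) {
    stop("class_t2 must be ordered uninjured < penumbra < core")
  }
  if (any(penumbra_semiaxes < core_semiaxes)) {
    stop("penumbra_semiaxes must dominate core_semiaxes (core inside lesion)")
  }
  stopifnot(s0 > 0, noise_sigma >= 0,
            lost_fraction >= 0, lost_fraction <= 1)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 echo_times = as.numeric(echo_times),
                 midline_col = midline_col,
                 brain_semiaxes = as.numeric(brain_semiaxes),
                 core_center = as.numeric(core_center),
                 core_semiaxes = as.numeric(core_semiaxes),
                 penumbra_semiaxes = as.numeric(penumbra_semiaxes),
                 class_t2 = class_t2[need], class_t2_sd = class_t2_sd[need],
                 s0 = s0, noise_sigma = noise_sigma,
                 lost_fraction = lost_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinates inside an ellipsoid; returns a logical array
ellipsoid_mask <- function(grid_shape, center, semiaxes) {
  r <- (seq_len(grid_shape[1L]) - center[1L]) / semiaxes[1L]
  c_ <- (seq_len(grid_shape[2L]) - center[2L]) / semiaxes[2L]
  s <- (seq_len(grid_shape[3L]) - center[3L]) / semiaxes[3L]
  d2 <- outer(outer(r^2, c_^2, `+`), s^2, `+`)
  array(d2 <= 1, dim = grid_shape)
}

#' Render a synthetic multi-echo phantom
#'
#' Draws a per-voxel T2 from the owning class (truncated Gaussian, floor
#' 1 ms), renders the noiseless mono-exponential signal
#' \eqn{S_0 \exp(-TE/T_2)} at each echo, and applies Rician noise
#' \eqn{\sqrt{(S+n_1)^2 + n_2^2}} with independent Gaussian \eqn{n_1, n_2}
#' (the standard model for magnitude-reconstructed MRI). If
#' \code{lost_fraction > 0}, the posterior-most non-lesion ipsilateral rows
#' are removed (background signal) to emulate tissue loss.
#'
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components:
#' \describe{
#'   \item{volume}{a \code{multi_echo_volume}: 4D signal array
#'     (rows, cols, slices, echoes), \code{echo_times}, \code{voxel_size}.}
#'   \item{truth}{a \code{phantom_truth}: ground-truth \code{labels}
#'     (0 outside, 1 uninjured, 2 penumbra, 3 core), \code{t2} (generating
#'     per-voxel T2, ms), \code{true_volumes} (mm^3 per class),
#'     \code{true_lost} (mm^3), \code{brain_mask} (post-loss),
#'     \code{midline_col}.}
#'   \item{lesion_mask}{logical 3D array, core plus penumbra — the stand-in
#'     for a manually outlined edema region of interest.}
#' }
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  center <- (gs + 1) / 2
  brain <- ellipsoid_mask(gs, center, spec$brain_semiaxes)
  cols <- slice.index(brain, 2L)
  ipsi <- brain & cols > spec$midline_col
  contra <- brain & cols <= spec$midline_col
  core <- ellipsoid_mask(gs, spec$core_center, spec$core_semiaxes)
  lesion <- ellipsoid_mask(gs, spec$core_center, spec$penumbra_semiaxes)
  if (any(core & !lesion)) stop("core must lie inside the lesion ellipsoid")
  if (any(lesion & !ipsi)) {
    stop("lesion extends outside the ipsilateral hemisphere")
  }
  penumbra <- lesion & !core

  labels <- array(0L, dim = gs)
  labels[brain] <- 1L
  labels[penumbra] <- 2L
  labels[core] <- 3L

  set.seed(spec$seed)

  # tissue loss: drop a posterior wedge of non-lesion ipsilateral voxels
  lost_n <- 0L
  if (spec$lost_fraction > 0) {
    candidates <- which(ipsi & !lesion)
    n_remove <- round(spec$lost_fraction * length(candidates))
    if (n_remove > 0L) {
      rows <- slice.index(labels, 1L)[candidates]
      ord <- order(rows, decreasing = TRUE)  # posterior rows first
      removed <- candidates[ord[seq_len(n_remove)]]
      labels[removed] <- 0L
      brain[removed] <- FALSE
      lost_n <- n_remove
    }
  }

  # per-voxel T2, truncated at 1 ms so decay stays physical
  t2 <- array(NA_real_, dim = gs)
  for (cls in c(uninjured = 1L, penumbra = 2L, core = 3L)) {
    idx <- which(labels == cls)
    if (!length(idx)) next
    nm <- names(spec$class_t2)[cls]
    draw <- stats::rnorm(length(idx), spec$class_t2[[nm]],
                         spec$class_t2_sd[[nm]])
    t2[idx] <- pmax(draw, 1)
  }

  ne <- length(spec$echo_times)
  signal <- array(0, dim = c(gs, ne))
  inb <- which(labels > 0L)
  for (e in seq_len(ne)) {
    plane <- array(0, dim = gs)
    plane[inb] <- spec$s0 * exp(-spec$echo_times[e] / t2[inb])
    signal[, , , e] <- plane
  }
  if (spec$noise_sigma > 0) {
    n1 <- array(stats::rnorm(length(signal), 0, spec$noise_sigma),
                dim = dim(signal))
    n2 <- array(stats::rnorm(length(signal), 0, spec$noise_sigma),
                dim = dim(signal))
    signal <- sqrt((signal + n1)^2 + n2^2)
  }

  vox_mm3 <- prod(spec$voxel_size)
  counts <- tabulate(labels[labels > 0L], nbins = 3L)
  true_volumes <- c(uninjured = counts[1L], penumbra = counts[2L],
                    core = counts[3L]) * vox_mm3

  volume <- structure(list(signal = signal, echo_times = spec$echo_times,
                           voxel_size = spec$voxel_size),
                      class = "multi_echo_volume")
  truth <- structure(list(labels = labels, t2 = t2,
                          true_volumes = true_volumes,
                          true_lost = lost_n * vox_mm3,
                          brain_mask = brain,
                          midline_col = spec$midline_col),
                     class = "phantom_truth")
  list(volume = volume, truth = truth, lesion_mask = penumbra | core)
}
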