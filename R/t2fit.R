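#' Construct a multi-echo volume
#'
#' @param signal 4D non-negative array (rows, cols, slices, echoes).
#' @param echo_times echo times in ms, one per echo, strictly increasing.
#' @param voxel_size mm per axis, length 3.
#' @return A \code{multi_echo_volume}.
#' @export
multi_echo_volume <- function(signal, echo_times, voxel_size) {
  stopifnot(length(dim(signal)) == 4L, length(voxel_size) == 3L)
  if (length(echo_times) != dim(signal)[4L]) {
    stop("echo count must match the 4th axis of the signal array")
  }
  if (length(echo_times) < 3L || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    stop("echo_times must be >= 3 strictly increasing positive values")
  }
  structure(list(signal = signal, echo_times = as.numeric(echo_times),
                 voxel_size = as.numeric(voxel_size)),
            class = "multi_echo_volume")
}

# loglinear OLS of ln(S) on TE; returns list(s0, t2, r2, valid)
# signal: matrix voxels x echoes (all rows), te: echo times
loglinear_fit_matrix <- function(signal, te) {
  nv <- nrow(signal)
  s0 <- t2 <- r2 <- rep(NA_real_, nv)
  valid <- rep(FALSE, nv)
  ok <- rowSums(signal <= 0 | !is.finite(signal)) == 0L
  if (any(ok)) {
    y <- log(signal[ok, , drop = FALSE])
    tec <- te - mean(te)
    sxx <- sum(tec^2)
    slope <- as.vector(y %*% tec) / sxx
    intercept <- rowMeans(y) - slope * mean(te)
    fitted <- outer(slope, te) + intercept
    ss_res <- rowSums((y - fitted)^2)
    ss_tot <- rowSums((y - rowMeans(y))^2)
    r2ok <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
    good <- slope < 0
    idx <- which(ok)[good]
    s0[idx] <- exp(intercept[good])
    t2[idx] <- -1 / slope[good]
    r2[idx] <- r2ok[good]
    valid[idx] <- TRUE
  }
  list(s0 = s0, t2 = t2, r2 = r2, valid = valid)
}

# variable projection: for rate r, optimal S0 = sum(S e)/sum(e^2),
# SSE(r) = sum(S^2) - (sum(S e))^2 / sum(e^2), e = exp(-r TE)
varpro_sse <- function(r, s, te) {
  e <- exp(-r * te)
  sum(s^2) - sum(s * e)^2 / sum(e * e)
}

nonlinear_fit_voxel <- function(s, te, t2_init) {
  r0 <- 1 / t2_init
  opt <- stats::optimize(varpro_sse, s = s, te = te,
                         lower = r0 / 5, upper = r0 * 5, tol = 1e-10)
  r <- opt$minimum
  e <- exp(-r * te)
  s0 <- sum(s * e) / sum(e * e)
  ss_tot <- sum((s - mean(s))^2)
  r2 <- if (ss_tot > 0) 1 - opt$objective / ss_tot else NA_real_
  c(s0 = s0, t2 = 1 / r, r2 = r2)
}

#' Fit a mono-exponential decay to one voxel
#'
#' Model \eqn{S(TE) = S_0 \exp(-TE/T_2)}. The \code{loglinear} method is
#' ordinary least squares of \eqn{\ln S} on TE (requires all intensities
#' positive); the \code{nonlinear} method minimizes the untransformed
#' residual sum of squares by variable projection (the amplitude is profiled
#' out in closed form and the decay rate optimized in one dimension),
#' initialized from the loglinear solution. A non-positive decay-rate
#' estimate or an unusable signal yields \code{valid = FALSE} — data, not an
#' error, so one bad voxel cannot abort a map.
#'
#' @param signal per-echo intensities.
#' @param echo_times ms, strictly increasing, length >= 3.
#' @param method \code{"nonlinear"} (default) or \code{"loglinear"}.
#' @return List: \code{s0}, \code{t2} (ms), \code{r2} (coefficient of
#'   determination; on the log scale for loglinear, signal scale for
#'   nonlinear), \code{valid}.
#' @export
fit_t2_voxel <- function(signal, echo_times,
                         method = c("nonlinear", "loglinear")) {
  method <- match.arg(method)
  if (length(echo_times) < 3L) stop("at least 3 echoes required")
  if (length(signal) != length(echo_times)) {
    stop("signal and echo_times lengths differ")
  }
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop("echo_times must be strictly increasing and positive")
  }
  ll <- loglinear_fit_matrix(matrix(signal, nrow = 1L), echo_times)
  if (method == "loglinear" || !ll$valid[1L]) {
    return(list(s0 = ll$s0[1L], t2 = ll$t2[1L], r2 = ll$r2[1L],
                valid = ll$valid[1L]))
  }
  nl <- nonlinear_fit_voxel(signal, echo_times, ll$t2[1L])
  list(s0 = unname(nl["s0"]), t2 = unname(nl["t2"]),
       r2 = unname(nl["r2"]), valid = is.finite(nl["t2"]) && nl["t2"] > 0)
}

#' Fit a voxelwise T2 parametric map
#'
#' Applies [fit_t2_voxel()] across a multi-echo volume, optionally
#' restricted to a brain mask. Voxels outside the mask (or with degenerate
#' signal) are marked invalid. Deterministic for fixed input.
#'
#' @param vol a \code{multi_echo_volume}.
#' @param brain_mask optional logical 3D array on the same grid.
#' @param method passed to [fit_t2_voxel()].
#' @param omit_first_echo drop the first echo before fitting (a common
#'   multi-echo practice when the first echo carries stimulated-echo
#'   contamination); off by default.
#' @return A \code{t2_map}: 3D arrays \code{t2} (ms), \code{s0}, \code{r2},
#'   \code{valid}, plus \code{voxel_size}.
#' @export
fit_t2_map <- function(vol, brain_mask = NULL,
                       method = c("nonlinear", "loglinear"),
                       omit_first_echo = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "multi_echo_volume"))
  gs <- dim(vol$signal)[1:3]
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), as.integer(gs)) &&
        !identical(dim(brain_mask), gs)) {
      stop("brain_mask grid does not match the volume")
    }
    idx <- which(brain_mask)
  } else {
    idx <- seq_len(prod(gs))
  }
  te <- vol$echo_times
  keep <- if (omit_first_echo) -1L else seq_along(te)
  te <- te[keep]
  if (length(te) < 3L) stop("fewer than 3 echoes after omitting the first")

  t2 <- s0 <- r2 <- array(NA_real_, dim = gs)
  valid <- array(FALSE, dim = gs)
  if (length(idx)) {
    nvox <- prod(gs)
    sig <- matrix(vol$signal, nrow = nvox)[idx, keep, drop = FALSE]
    ll <- loglinear_fit_matrix(sig, te)
    if (method == "nonlinear") {
      ok <- which(ll$valid)
      for (j in ok) {
        nl <- nonlinear_fit_voxel(sig[j, ], te, ll$t2[j])
        if (is.finite(nl["t2"]) && nl["t2"] > 0) {
          ll$s0[j] <- nl["s0"]; ll$t2[j] <- nl["t2"]; ll$r2[j] <- nl["r2"]
        } else {
          ll$valid[j] <- FALSE
          ll$s0[j] <- ll$t2[j] <- ll$r2[j] <- NA_real_
        }
      }
    }
    t2[idx] <- ll$t2; s0[idx] <- ll$s0; r2[idx] <- ll$r2
    valid[idx] <- ll$valid
  }
  structure(list(t2 = t2, s0 = s0, r2 = r2, valid = valid,
                 voxel_size = vol$voxel_size),
            class = "t2_map")
}
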