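# Independent brute-force oracles. These deliberately re-derive results
# with plain loops and exhaustive scans; they never call the package's own
# code paths for the quantity they check.

# --- exhaustive grid-search least-squares T2 oracle ---------------------
# For each row of `signal` (one voxel), scan a fine T2 grid; at each grid
# point the best amplitude for S(TE) = S0 exp(-TE/T2) follows from the
# normal equation, so the SSE minimum over the grid is exact to the step.
oracle_t2_grid <- function(signal, te, t2_grid = seq(20, 120, by = 0.02)) {
  E <- exp(-outer(te, 1 / t2_grid))
  E2 <- colSums(E^2)
  n <- nrow(signal)
  best <- numeric(n)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1000))
  for (ix in chunks) {
    C <- signal[ix, , drop = FALSE] %*% E
    score <- C^2 / rep(E2, each = length(ix))  # maximize = minimize SSE
    best[ix] <- t2_grid[max.col(score, ties.method = "first")]
  }
  best
}

# --- brute-force recursive region-split oracle --------------------------
# Loop-based histogram with left-closed fixed-width bins (last bin closed).
oracle_histogram <- function(values, bin_width) {
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (v in values) {
    b <- nb
    for (j in seq_len(nb)) {
      if (v >= edges[j] && v < edges[j + 1L]) { b <- j; break }
    }
    counts[b] <- counts[b] + 1L
  }
  list(edges = edges, mids = (edges[-1L] + edges[-(nb + 1L)]) / 2,
       counts = counts)
}

oracle_smooth <- function(counts, sd_bins) {
  if (sd_bins <= 0) return(as.numeric(counts))
  n <- length(counts)
  if (n < 2L) return(as.numeric(counts))
  half <- max(1L, ceiling(4 * sd_bins))
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in (-half):half) {
      k <- exp(-j^2 / (2 * sd_bins^2))
      if (i + j >= 1L && i + j <= n) {
        num <- num + k * counts[i + j]
        den <- den + k
      }
    }
    out[i] <- num / den
  }
  out
}

# exhaustive local-maximum scan; plateaus count once, at their first bin
oracle_peaks <- function(y) {
  n <- length(y)
  peaks <- integer(0)
  for (i in seq_len(n)) {
    if (y[i] <= 0) next
    if (i > 1L && y[i - 1L] == y[i]) next
    l <- i - 1L
    while (l >= 1L && y[l] == y[i]) l <- l - 1L
    r <- i + 1L
    while (r <= n && y[r] == y[i]) r <- r + 1L
    if ((l < 1L || y[l] < y[i]) && (r > n || y[r] < y[i])) {
      peaks <- c(peaks, i)
    }
  }
  peaks
}

oracle_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { left_min <- min(left_min, y[j]); j <- j - 1L }
  lbase <- if (j >= 1L) left_min else -Inf
  right_min <- y[i]; j <- i + 1L
  while (j <= n && y[j] <= y[i]) { right_min <- min(right_min, y[j]); j <- j + 1L }
  rbase <- if (j <= n) right_min else -Inf
  base <- max(lbase, rbase)
  if (is.finite(base)) y[i] - base else y[i]
}

# valley between the two most prominent qualifying modes, or NULL
oracle_valley <- function(values, params) {
  h <- oracle_histogram(values, params$bin_width)
  sm <- oracle_smooth(h$counts,
                      params$smoothing_bandwidth / params$bin_width)
  pk <- oracle_peaks(sm)
  if (length(pk) < 2L) return(NULL)
  prom <- vapply(pk, function(i) oracle_prominence(sm, i), numeric(1))
  keep <- prom >= params$bimodality_min_prominence * max(sm)
  pk <- pk[keep]; prom <- prom[keep]
  if (length(pk) < 2L) return(NULL)
  ord <- order(-prom, pk)
  two <- sort(pk[ord[1:2]])
  if (two[2L] - two[1L] < 2L) return(NULL)
  between <- (two[1L] + 1L):(two[2L] - 1L)
  best <- between[1L]
  for (b in between) if (sm[b] < sm[best]) best <- b
  h$mids[best]
}

oracle_mode <- function(values, params) {
  h <- oracle_histogram(values, params$bin_width)
  sm <- oracle_smooth(h$counts,
                      params$smoothing_bandwidth / params$bin_width)
  h$mids[which.max(sm)]
}

# hand-rolled recursion of the stated rules; returns per-voxel labels
# (1 uninjured, 2 penumbra, 3 core) named by id
oracle_segment <- function(values, ids, params, depth = 0L) {
  classify <- function() {
    cls <- if (oracle_mode(values, params) > params$core_mode_threshold) {
      3L
    } else {
      2L
    }
    lab <- rep(cls, length(values))
    names(lab) <- ids
    lab
  }
  if (depth >= params$max_depth) return(classify())
  valley <- oracle_valley(values, params)
  if (is.null(valley)) return(classify())
  left <- values <= valley
  if (sum(left) < params$min_region_voxels ||
      sum(!left) < params$min_region_voxels) {
    return(classify())
  }
  c(oracle_segment(values[left], ids[left], params, depth + 1L),
    oracle_segment(values[!left], ids[!left], params, depth + 1L))
}

oracle_segment_with_override <- function(values, ids, params) {
  lab <- oracle_segment(values, ids, params)
  lab <- lab[match(ids, names(lab))]
  lab[values < params$uninjured_t2_threshold] <- 1L
  lab
}

# --- misc ----------------------------------------------------------------
# trivial trapezoid sum, written out longhand
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  }
  s
}

# small fast phantom spec shared across tests
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(40L, 40L, 8L), ...)
}
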