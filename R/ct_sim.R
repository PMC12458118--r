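#' Simulate a qPCR Ct table
#'
#' Generates threshold-cycle (Ct) values for one target and one housekeeping
#' gene across experimental groups. Each sample's housekeeping Ct is drawn
#' around \code{base_ct}; the target Ct sits \code{base_dct} cycles above it
#' plus the group's imposed shift, so a shift of +1 cycle halves the
#' expected expression fold change (fold \code{2^-shift}).
#'
#' @param n_per_group samples per group (>= 1).
#' @param group_effects named numeric: imposed target-gene delta-Ct shift
#'   (cycles) per group; the reference group is conventionally 0.
#' @param seed integer RNG seed.
#' @param target_gene,housekeeping_gene gene labels.
#' @param base_ct mean housekeeping Ct, cycles.
#' @param base_dct baseline target minus housekeeping Ct, cycles.
#' @param noise_sd Gaussian Ct noise, cycles (applied independently per
#'   well).
#' @return Data frame with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{ct} — two rows (target, housekeeping) per sample.
#' @export
make_ct_table <- function(n_per_group, group_effects, seed = 1L,
                          target_gene = "Gria2",
                          housekeeping_gene = "Gapdh",
                          base_ct = 18, base_dct = 5, noise_sd = 0.15) {
  stopifnot(n_per_group >= 1, length(group_effects) >= 1,
            !is.null(names(group_effects)), noise_sd >= 0)
  set.seed(seed)
  rows <- lapply(names(group_effects), function(g) {
    ids <- sprintf("%s_%02d", g, seq_len(n_per_group))
    hk <- base_ct + stats::rnorm(n_per_group, 0, noise_sd)
    tg <- hk + base_dct + group_effects[[g]] +
      stats::rnorm(n_per_group, 0, noise_sd)
    data.frame(sample_id = rep(ids, 2L),
               group = g,
               gene = rep(c(target_gene, housekeeping_gene),
                          each = n_per_group),
               ct = c(tg, hk))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
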