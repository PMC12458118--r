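#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-sample fold changes of a target gene normalized to a
#' housekeeping gene and a reference group:
#' \deqn{\Delta Ct = Ct_{target} - Ct_{housekeeping},\quad
#'       \Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{ref},\quad
#'       fold = 2^{-\Delta\Delta Ct}.}
#' Technical replicates (multiple wells per sample and gene) are averaged on
#' the Ct scale before the subtraction. Samples missing either gene are
#' skipped with a warning rather than aborting the batch.
#'
#' @param records data frame with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{ct}.
#' @param target_gene,housekeeping_gene gene labels present in
#'   \code{records$gene}.
#' @param reference_group group label whose mean delta-Ct anchors the fold
#'   scale; must be non-empty.
#' @return Data frame with one row per usable sample: \code{sample_id},
#'   \code{group}, \code{gene}, \code{delta_ct}, \code{delta_delta_ct},
#'   \code{fold}, \code{reference_group}. The geometric mean fold of the
#'   reference group is exactly 1.
#' @export
delta_delta_ct <- function(records, target_gene, housekeeping_gene,
                           reference_group) {
  need <- c("sample_id", "group", "gene", "ct")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (!any(records$gene == target_gene)) {
    stop("target gene '", target_gene, "' absent from records")
  }
  if (!any(records$gene == housekeeping_gene)) {
    stop("housekeeping gene '", housekeeping_gene, "' absent from records")
  }
  # average technical replicates on the Ct scale
  mean_ct <- function(gene) {
    sub <- records[records$gene == gene, , drop = FALSE]
    stats::aggregate(ct ~ sample_id + group, data = sub, FUN = mean)
  }
  tg <- mean_ct(target_gene)
  hk <- mean_ct(housekeeping_gene)
  m <- merge(tg, hk, by = c("sample_id", "group"),
             suffixes = c("_target", "_hk"), all.x = TRUE)
  missing_hk <- is.na(m$ct_hk)
  if (any(missing_hk)) {
    warning(sum(missing_hk), " sample(s) skipped: missing housekeeping Ct (",
            paste(m$sample_id[missing_hk], collapse = ", "), ")")
    m <- m[!missing_hk, , drop = FALSE]
  }
  ref <- m$group == reference_group
  if (!any(ref)) stop("reference group '", reference_group, "' is empty")
  m$delta_ct <- m$ct_target - m$ct_hk
  ref_mean <- mean(m$delta_ct[ref])
  m$delta_delta_ct <- m$delta_ct - ref_mean
  out <- data.frame(sample_id = m$sample_id, group = m$group,
                    gene = target_gene,
                    delta_ct = m$delta_ct,
                    delta_delta_ct = m$delta_delta_ct,
                    fold = 2^(-m$delta_delta_ct),
                    reference_group = reference_group)
  out[order(out$group, out$sample_id), , drop = FALSE]
}

#' Per-group fold-change summary
#'
#' Fold changes are log-scale quantities, so groups are summarized by
#' geometric means (with the log2-scale SD alongside).
#'
#' @param folds output of [delta_delta_ct()].
#' @return Data frame: \code{group}, \code{n}, \code{geo_mean_fold},
#'   \code{log2_sd}.
#' @export
fold_change_summary <- function(folds) {
  stopifnot(all(c("group", "fold") %in% names(folds)))
  groups <- split(folds$fold, folds$group)
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             geo_mean_fold = vapply(groups, function(f) 2^mean(log2(f)),
                                    numeric(1)),
             log2_sd = vapply(groups, function(f) stats::sd(log2(f)),
                              numeric(1)),
             row.names = NULL)
}
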