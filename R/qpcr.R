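#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample_id`, `target`, `Ct` and optionally
#'   `plate_id`.
#' @return Data frame of Ct records; technical replicates (repeated
#'   (sample, target) rows) are kept and averaged downstream.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "target", "Ct")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("Ct table missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$Ct <- as.numeric(tab$Ct)
  tab
}

#' Relative quantity by the 2^-dCt method
#'
#' Quantifies a target amplicon relative to the total-bacteria reference
#' amplified on the same plate: `2^-(Ct_target - Ct_total)`, assuming
#' perfect doubling per cycle. Technical replicates should be averaged on
#' the Ct scale beforehand ([delta_ct_quantities()] does this).
#'
#' @param ct_target,ct_total Ct values (vectorised).
#' @return Relative quantity; 1 at equal Ct, and
#'   `log2(relative_quantity) == -(ct_target - ct_total)` exactly.
#' @export
relative_quantity <- function(ct_target, ct_total) {
  if (anyNA(ct_target) || anyNA(ct_total)) {
    stop("missing Ct value", call. = FALSE)
  }
  2^-(ct_target - ct_total)
}

#' Per-sample relative quantities from a Ct table
#'
#' Averages technical replicates on the Ct scale, then computes
#' `2^-dCt` of every non-reference target against `total_bacteria` for
#' the same sample.
#'
#' @param ct Data frame as from [read_ct_table()].
#' @param reference Reference target name (default `"total_bacteria"`).
#' @return Data frame `sample_id`, `target`, `delta_ct`,
#'   `relative_quantity`.
#' @export
delta_ct_quantities <- function(ct, reference = "total_bacteria") {
  stopifnot(all(c("sample_id", "target", "Ct") %in% names(ct)))
  mean_ct <- stats::aggregate(Ct ~ sample_id + target, data = ct, FUN = mean)
  ref <- mean_ct[mean_ct$target == reference, c("sample_id", "Ct")]
  tgt <- mean_ct[mean_ct$target != reference, , drop = FALSE]
  idx <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("no %s reference for sample(s): %s", reference,
                 paste(unique(tgt$sample_id[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  dct <- tgt$Ct - ref$Ct[idx]
  out <- data.frame(sample_id = tgt$sample_id, target = tgt$target,
                    delta_ct = dct,
                    relative_quantity = relative_quantity(tgt$Ct,
                                                          ref$Ct[idx]),
                    stringsAsFactors = FALSE)
  out[order(out$target, out$sample_id), , drop = FALSE]
}

#' Two-group comparison of relative quantities
#'
#' Classic equal-variance Student's t-test, two-sided, as used for
#' sorted-vs-unsorted comparisons. If both groups are degenerate (zero
#' variance) with equal means the statistic is undefined and p = 1 is
#' returned flagged.
#'
#' @param quantities Numeric vector of relative quantities.
#' @param groups Two-level factor or character vector.
#' @return One-row data frame: `comparison`, `method`, `statistic`,
#'   `p_value`, `adj_p_value`, `n_a`, `n_b`, `degenerate`.
#' @export
compare_fractions <- function(quantities, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(quantities) == length(groups))
  n <- table(groups)
  if (any(n < 2)) stop("both groups need >= 2 values", call. = FALSE)
  a <- quantities[groups == levels(groups)[1]]
  b <- quantities[groups == levels(groups)[2]]
  comparison <- paste(levels(groups), collapse = "_vs_")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(group_test_result(comparison, "t_test", 0, 1, n_pairs = 1,
                               n_a = n[[1]], n_b = n[[2]],
                               degenerate = TRUE))
    }
    return(group_test_result(comparison, "t_test",
                             sign(mean(b) - mean(a)) * Inf, 0, n_pairs = 1,
                             n_a = n[[1]], n_b = n[[2]], degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, var.equal = TRUE)
  group_test_result(comparison, "t_test", unname(tt$statistic), tt$p.value,
                    n_pairs = 1, n_a = n[[1]], n_b = n[[2]])
}
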