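#' Classify mutant-dependence of phasiRNA accumulation
#'
#' Compares replicated wild-type and mutant counts per feature. Counts are
#' RPM-normalized by the supplied library sizes; the fold change is the
#' wild-type over mutant mean RPM. Significance comes from a two-sided
#' exact binomial test on the pooled raw counts of each feature against the
#' library-size expectation (p0 = pooled WT library size / pooled total), a
#' deliberately simple stand-in for a count-model differential test, with
#' Benjamini-Hochberg FDR control. Externally computed per-feature p-values
#' (e.g. from a negative-binomial model) can be supplied via `p_values` and
#' are then used unchanged before the FDR step. A feature is dependent iff
#' `fold_change >= fold` and `fdr <= fdr_max`.
#'
#' @param counts_wt,counts_mut Numeric matrices (features x replicates) with
#'   matching row names; at least 2 replicates per condition.
#' @param lib_wt,lib_mut Library sizes (total mapped clean-read counts) per
#'   replicate; all must be > 0.
#' @param fold Fold-change threshold (wild-type / mutant).
#' @param fdr_max FDR threshold.
#' @param p_values Optional externally computed p-values (named or in row
#'   order).
#' @return `data.frame(feature, mean_rpm_wt, mean_rpm_mut, fold_change,
#'   p_value, fdr, dependent)`. Features with zero counts in both conditions
#'   are skipped (count in the `"skipped"` attribute).
#' @export
classify_dependence <- function(counts_wt, counts_mut, lib_wt, lib_mut,
                                fold = 2, fdr_max = 0.05, p_values = NULL) {
  counts_wt <- as.matrix(counts_wt)
  counts_mut <- as.matrix(counts_mut)
  if (nrow(counts_wt) != nrow(counts_mut))
    stop("feature sets of the two conditions differ")
  if (ncol(counts_wt) < 2L || ncol(counts_mut) < 2L)
    stop("at least 2 replicates per condition are required")
  if (length(lib_wt) != ncol(counts_wt) || length(lib_mut) != ncol(counts_mut))
    stop("one library size per replicate is required")
  if (any(c(lib_wt, lib_mut) <= 0)) stop("library sizes must be positive")
  features <- rownames(counts_wt)
  if (is.null(features)) features <- sprintf("feature%d", seq_len(nrow(counts_wt)))

  keep <- rowSums(counts_wt) + rowSums(counts_mut) > 0
  skipped <- sum(!keep)
  counts_wt <- counts_wt[keep, , drop = FALSE]
  counts_mut <- counts_mut[keep, , drop = FALSE]
  features <- features[keep]

  rpm_wt <- sweep(counts_wt, 2L, lib_wt, "/") * 1e6
  rpm_mut <- sweep(counts_mut, 2L, lib_mut, "/") * 1e6
  mean_wt <- rowMeans(rpm_wt)
  mean_mut <- rowMeans(rpm_mut)
  fc <- ifelse(mean_mut > 0, mean_wt / mean_mut, Inf)

  if (is.null(p_values)) {
    p0 <- sum(lib_wt) / (sum(lib_wt) + sum(lib_mut))
    x <- round(rowSums(counts_wt))
    n <- round(rowSums(counts_wt) + rowSums(counts_mut))
    pv <- vapply(seq_along(x), function(i) {
      if (n[i] == 0) return(1)
      binom.test(x[i], n[i], p = p0)$p.value
    }, numeric(1))
  } else {
    pv <- if (!is.null(names(p_values))) unname(p_values[features])
      else p_values[keep]
    if (length(pv) != length(features) || anyNA(pv))
      stop("p_values must cover every retained feature")
  }
  fdr <- p.adjust(pv, method = "BH")
  out <- data.frame(feature = features, mean_rpm_wt = mean_wt,
                    mean_rpm_mut = mean_mut, fold_change = fc, p_value = pv,
                    fdr = fdr, dependent = fc >= fold & fdr <= fdr_max,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Threshold gating on an expression matrix
#'
#' The same fold + FDR gate applied to a user-supplied expression matrix and
#' precomputed p-values (e.g. target mRNA differential expression); no count
#' model is fit here.
#'
#' @param mean_a,mean_b Per-feature condition means (numerator /
#'   denominator of the fold change).
#' @param p_values Per-feature p-values (BH-adjusted internally).
#' @param fold,fdr_max Thresholds.
#' @return Logical vector: passes the gate.
#' @export
threshold_gate <- function(mean_a, mean_b, p_values, fold = 1.5,
                           fdr_max = 0.05) {
  fc <- ifelse(mean_b > 0, mean_a / mean_b, Inf)
  fc >= fold & p.adjust(p_values, method = "BH") <= fdr_max
}
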