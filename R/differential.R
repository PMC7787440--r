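# Cohort-style differential statistics on function (or route) tables:
# within-sample rank transform, per-condition geometric means of ranks,
# per-feature Wilcoxon rank-sum tests and log2 fold changes of group mean
# relative abundances.

# accept either a design data.frame (sample_id, condition) or a named vector
design_vector <- function(design) {
  if (is.data.frame(design))
    return(stats::setNames(as.character(design$condition), design$sample_id))
  if (!is.null(names(design))) return(stats::setNames(as.character(design),
                                                      names(design)))
  stop("design must be a data.frame or a named vector", call. = FALSE)
}

split_groups <- function(m, design, case = NULL) {
  dv <- design_vector(design)
  samples <- intersect(colnames(m), names(dv))
  if (!length(samples)) stop("no design entry matches the table's samples",
                             call. = FALSE)
  dv <- dv[samples]
  labels <- sort(unique(dv))
  if (length(labels) != 2)
    stop("exactly two conditions required, got: ",
         paste(labels, collapse = ", "), call. = FALSE)
  case <- case %||% labels[1]
  if (!case %in% labels) stop("unknown case label: ", case, call. = FALSE)
  control <- setdiff(labels, case)
  list(case = case, control = control,
       case_samples = samples[dv == case],
       control_samples = samples[dv == control])
}

#' Rank-transform a table within each sample
#'
#' Replaces every sample column by the ranks of its values (average ranks
#' for ties, rank 1 = smallest), making downstream summaries invariant to
#' any strictly monotone within-sample transform.
#'
#' @param m feature x sample matrix with at least 2 features.
#' @return matrix of ranks in `[1, n_features]`.
#' @export
rank_transform <- function(m) {
  check_abundance_matrix(m, "table")
  if (nrow(m) < 2) stop("need at least two features to rank", call. = FALSE)
  out <- apply(m, 2, rank)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-feature, per-condition geometric means
#'
#' @param m feature x sample matrix of positive values (typically ranks
#'   from [rank_transform()]).
#' @param design two-condition design (data.frame or named vector).
#' @return feature x condition matrix of geometric means
#'   `exp(mean(log(x)))`.
#' @export
group_geometric_mean <- function(m, design) {
  dv <- design_vector(design)
  samples <- intersect(colnames(m), names(dv))
  if (any(m[, samples] <= 0))
    stop("geometric means require strictly positive values", call. = FALSE)
  groups <- sort(unique(dv[samples]))
  out <- vapply(groups, function(g) {
    cols <- samples[dv[samples] == g]
    exp(rowMeans(log(m[, cols, drop = FALSE])))
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), groups))
  out
}

# two-sided Wilcoxon rank-sum p for one feature; exact enumeration (via
# stats::wilcox.test) when both groups are small and tie-free, else normal
# approximation with tie and continuity correction
wilcoxon_one <- function(x, y, exact_max = 12) {
  n1 <- length(x)
  if (length(unique(c(x, y))) == 1L)
    return(list(W = n1 * (n1 + 1) / 2 + n1 * length(y) / 2, p = 1,
                constant = TRUE))
  ties <- any(duplicated(c(x, y)))
  ex <- !ties && n1 <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = ex,
                                            correct = TRUE))
  # report W as the rank sum of group 1, not the Mann-Whitney U
  list(W = unname(wt$statistic) + n1 * (n1 + 1) / 2,
       p = wt$p.value, constant = FALSE)
}

#' Per-feature Wilcoxon rank-sum test between two conditions
#'
#' The two-sided p-value is computed by exact enumeration when both groups
#' have at most 12 samples and the feature has no ties, and by the normal
#' approximation with tie and continuity correction otherwise. Constant
#' features are reported with p = 1 and flagged. Each feature is tested
#' independently.
#'
#' @param m feature x sample matrix.
#' @param design two-condition design (data.frame or named vector).
#' @param case condition treated as group 1 (defaults to the alphabetically
#'   first label); `W` is the rank sum of this group.
#' @return data.frame with columns `feature`, `W`, `p.value`, `constant`,
#'   `n_case`, `n_control`.
#' @export
wilcoxon_test <- function(m, design, case = NULL) {
  check_abundance_matrix(m, "table")
  g <- split_groups(m, design, case)
  if (!length(g$case_samples) || !length(g$control_samples))
    stop("both conditions need at least one sample", call. = FALSE)
  res <- lapply(rownames(m), function(f) {
    r <- wilcoxon_one(m[f, g$case_samples], m[f, g$control_samples])
    data.frame(feature = f, W = r$W, p.value = r$p, constant = r$constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$n_case <- length(g$case_samples)
  out$n_control <- length(g$control_samples)
  attr(out, "case") <- g$case
  attr(out, "control") <- g$control
  rownames(out) <- NULL
  out
}

#' Per-feature log2 fold change of group mean relative abundances
#'
#' log2 of the ratio of group arithmetic means, with a pseudocount (default
#' half the smallest nonzero value of the table) added to both means so the
#' result stays finite. Positive values mean higher abundance in the case
#' group.
#'
#' @param m feature x sample matrix on the relative scale.
#' @param design two-condition design.
#' @param case condition used as the numerator group.
#' @param pseudocount override for the default pseudocount.
#' @return data.frame with `feature`, `mean_case`, `mean_control`, `log2fc`
#'   (`NA` and flagged when both means are zero and no pseudocount exists).
#' @export
log2_foldchange <- function(m, design, case = NULL, pseudocount = NULL) {
  check_abundance_matrix(m, "table")
  g <- split_groups(m, design, case)
  pc <- pseudocount %||% {
    nz <- m[m > 0]
    if (length(nz)) min(nz) / 2 else 0
  }
  mc <- rowMeans(m[, g$case_samples, drop = FALSE])
  mh <- rowMeans(m[, g$control_samples, drop = FALSE])
  lfc <- log2((mc + pc) / (mh + pc))
  undefined <- (mc + pc) == 0 & (mh + pc) == 0
  lfc[undefined] <- NA_real_
  data.frame(feature = rownames(m), mean_case = mc, mean_control = mh,
             log2fc = lfc, undefined = undefined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Full differential-abundance analysis of a function table
#'
#' Convenience pipeline: within-sample rank transform, per-condition
#' geometric means of ranks, per-feature Wilcoxon rank-sum tests and log2
#' fold changes of relative abundances, optionally BH-adjusted.
#'
#' @param ft function x sample matrix (raw or relative).
#' @param design two-condition design.
#' @param case case label (numerator group).
#' @param fdr add a BH-adjusted `q.value` column.
#' @return data.frame sorted by p-value.
#' @export
diff_analysis <- function(ft, design, case = NULL, fdr = FALSE) {
  rel <- relative_abundance(ft)
  rk <- rank_transform(ft)
  gm <- group_geometric_mean(rk, design)
  wt <- wilcoxon_test(ft, design, case)
  lfc <- log2_foldchange(rel, design, case)
  case_lab <- attr(wt, "case")
  ctrl_lab <- attr(wt, "control")
  out <- data.frame(wt[c("feature", "W", "p.value", "constant")],
                    gm_rank_case = gm[wt$feature, case_lab],
                    gm_rank_control = gm[wt$feature, ctrl_lab],
                    log2fc = lfc$log2fc[match(wt$feature, lfc$feature)],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (fdr) out$q.value <- adjust_fdr(out$p.value)
  attr(out, "case") <- case_lab
  attr(out, "control") <- ctrl_lab
  out[order(out$p.value), ]
}
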