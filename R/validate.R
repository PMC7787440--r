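# Agreement between predicted and reference function profiles: per-sample
# Spearman correlation over the zero-filled union of function ids, plus a
# permutation (ASV-label shuffling) + bootstrap (samples drawn with
# replacement) null distribution and a Welch t-test against it.

#' Per-sample Spearman correlation between two function tables
#'
#' For every sample shared between the tables, computes the Spearman rank
#' correlation over the union of function ids present in either table,
#' filling absences with 0 (so false presences and false absences are
#' penalized symmetrically) and averaging ranks for ties. Each column is
#' scaled to relative abundance first; Spearman is invariant to this, it is
#' applied for numeric hygiene only.
#'
#' @param pred,ref function x sample matrices in the same namespace.
#' @return object of class `scc_result`: list with `scc` (named numeric,
#'   `NA` = undefined), `n_functions` (union size), `fill`
#'   (`"union_zero_fill"`) and `n_undefined`.
#' @export
spearman_per_sample <- function(pred, ref) {
  check_abundance_matrix(pred, "predicted table")
  check_abundance_matrix(ref, "reference table")
  ns_p <- attr(pred, "namespace", exact = TRUE)
  ns_r <- attr(ref, "namespace", exact = TRUE)
  if (!is.null(ns_p) && !is.null(ns_r) && ns_p != ns_r)
    stop("tables are in different namespaces (", ns_p, " vs ", ns_r, ")",
         call. = FALSE)
  samples <- intersect(colnames(pred), colnames(ref))
  if (!length(samples)) stop("no shared sample id", call. = FALSE)
  fids <- sort(union(rownames(pred), rownames(ref)))
  expand <- function(m) {
    out <- matrix(0, length(fids), length(samples),
                  dimnames = list(fids, samples))
    common <- intersect(rownames(m), fids)
    out[common, ] <- m[common, samples, drop = FALSE]
    cs <- colSums(out)
    cs[cs == 0] <- 1
    sweep(out, 2, cs, "/")
  }
  p <- expand(pred)
  r <- expand(ref)
  scc <- vapply(samples, function(s) {
    x <- p[, s]
    y <- r[, s]
    if (length(fids) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  structure(list(scc = scc, n_functions = length(fids),
                 fill = "union_zero_fill",
                 n_undefined = sum(is.na(scc))),
            class = "scc_result")
}

#' @export
print.scc_result <- function(x, ...) {
  ok <- x$scc[!is.na(x$scc)]
  cat("scc_result:", length(x$scc), "sample(s),", x$n_functions,
      "functions in union; mean SCC =",
      if (length(ok)) format(mean(ok), digits = 4) else "undefined", "\n")
  invisible(x)
}

#' Shuffle ASV identities in an ASV table
#'
#' Reassigns ASV ids (and hence their taxonomy) to abundance rows by a
#' uniform random permutation. The multiset of row vectors, and therefore
#' every per-sample total, is unchanged.
#'
#' @param asv ASV x sample matrix.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return matrix with permuted row ids.
#' @export
permute_asv_labels <- function(asv, seed) {
  check_abundance_matrix(asv, "ASV table")
  out <- asv
  rownames(out) <- with_seed(seed, sample(rownames(asv)))
  out
}

#' Permutation + bootstrap null distribution of per-sample SCC
#'
#' For each of `n_permutations` label-shuffled datasets, draws
#' `n_bootstrap` samples with replacement from the sample set, runs the
#' aggregate -> copy-number-normalize -> predict pipeline, computes the
#' per-sample Spearman correlation against the reference profile, and pools
#' all coefficients. Per-permutation child seeds are derived from the root
#' seed so individual permutations are independently reproducible.
#'
#' @param asv ASV x sample matrix.
#' @param taxonomy named taxon-label vector (see [read_taxonomy()]).
#' @param copy_numbers input for [normalize_copy_number()], or `NULL` to
#'   skip normalization.
#' @param network a `metgems_network`.
#' @param ref reference function x sample matrix.
#' @param n_permutations,n_bootstrap null-size parameters (the validation
#'   procedure used 100 and 200).
#' @param seed root integer seed.
#' @return object of class `null_scc`: list with `null` (pooled
#'   coefficients), `n_permutations`, `n_bootstrap`, `seed`, `n_dropped`
#'   (undefined coefficients excluded).
#' @export
build_null <- function(asv, taxonomy, copy_numbers, network, ref,
                       n_permutations = 100, n_bootstrap = 200, seed = 1) {
  check_abundance_matrix(asv, "ASV table")
  samples <- colnames(asv)
  pooled <- vector("list", n_permutations)
  dropped <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- permute_asv_labels(asv, seed + i)
    idx <- with_seed(seed + 500000L + i,
                     sample(length(samples), n_bootstrap, replace = TRUE))
    boot <- perm[, idx, drop = FALSE]
    boot_ids <- sprintf("%s_b%03d", samples[idx], seq_len(n_bootstrap))
    colnames(boot) <- boot_ids
    res <- tryCatch({
      taxa <- suppressWarnings(aggregate_asvs(boot, taxonomy))
      if (!is.null(copy_numbers))
        taxa <- normalize_copy_number(taxa, copy_numbers)
      pred <- predict_functions(taxa, network)
      ref_b <- ref[, samples[idx], drop = FALSE]
      colnames(ref_b) <- boot_ids
      spearman_per_sample(pred, ref_b)
    }, error = function(e)
      stop("permutation ", i, ": ", conditionMessage(e), call. = FALSE))
    dropped <- dropped + res$n_undefined
    pooled[[i]] <- res$scc[!is.na(res$scc)]
  }
  structure(list(null = unname(unlist(pooled)),
                 n_permutations = n_permutations,
                 n_bootstrap = n_bootstrap, seed = seed,
                 n_dropped = dropped),
            class = "null_scc")
}

#' @export
print.null_scc <- function(x, ...) {
  cat("null_scc:", length(x$null), "coefficients from", x$n_permutations,
      "permutation(s) x", x$n_bootstrap, "bootstrap draw(s); mean =",
      format(mean(x$null), digits = 4), "\n")
  invisible(x)
}

#' Welch t-test of real SCCs against the null distribution
#'
#' Two-sample t-test with unequal variances between the defined per-sample
#' coefficients of `real` and the pooled null coefficients.
#'
#' @param real an `scc_result` from [spearman_per_sample()].
#' @param null a `null_scc` from [build_null()].
#' @return list with `statistic`, `p.value`, `mean_real`, `mean_null`,
#'   `df`.
#' @export
compare_to_null <- function(real, null) {
  stopifnot(inherits(real, "scc_result"), inherits(null, "null_scc"))
  x <- real$scc[!is.na(real$scc)]
  y <- null$null[is.finite(null$null)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two defined coefficients", call. = FALSE)
  t <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(t$statistic), p.value = t$p.value,
       mean_real = mean(x), mean_null = mean(y),
       df = unname(t$parameter))
}
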