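# ASV table -> taxon table -> function table. All three stages are plain
# numeric matrices (features x samples); bookkeeping (normalisation state,
# namespace, scale, mapping reports) travels as attributes and is read back
# with mapping_report().

#' Retrieve the mapping/prediction report attached to a table
#' @param x a table produced by [aggregate_asvs()], [predict_functions()] or
#'   [relative_abundance()].
#' @return a list, or `NULL` when no report is attached.
#' @export
mapping_report <- function(x) attr(x, "report", exact = TRUE)

#' Aggregate an ASV-by-sample table to taxon groups
#'
#' Sums the counts of all ASVs assigned to the same taxon label. Unassigned
#' ASVs (`NA` label) are excluded from the result but tallied in the report,
#' which also gives the fraction of reads retained per sample.
#'
#' @param asv numeric matrix, ASVs x samples.
#' @param taxonomy named character vector asv id -> taxon label
#'   (`NA` = unassigned), e.g. from [read_taxonomy()].
#' @return taxon x sample matrix with attributes `normalized = FALSE` and
#'   `report` (`n_asvs`, `n_assigned`, `n_taxa`, `unassigned_asvs`,
#'   `retained_fraction`).
#' @export
aggregate_asvs <- function(asv, taxonomy) {
  check_abundance_matrix(asv, "ASV table")
  lab <- taxonomy[rownames(asv)]
  lab[!is.na(lab) & tolower(lab) == "unassigned"] <- NA
  assigned <- !is.na(lab)
  if (!any(assigned))
    warning("no ASV carries a taxonomy assignment; result is empty",
            call. = FALSE)
  sub <- asv[assigned, , drop = FALSE]
  m <- if (nrow(sub)) rowsum(sub, group = lab[assigned]) else
    matrix(0, 0, ncol(asv), dimnames = list(character(0), colnames(asv)))
  if (nrow(m) > 1) m <- m[order(rownames(m)), , drop = FALSE]
  total <- colSums(asv)
  kept <- colSums(sub)
  retained <- ifelse(total > 0, kept / total, NA_real_)
  if (any(kept == 0))
    warning("sample(s) with no assigned reads: ",
            paste(colnames(asv)[kept == 0], collapse = ", "), call. = FALSE)
  attr(m, "normalized") <- FALSE
  attr(m, "report") <- list(
    n_asvs = nrow(asv), n_assigned = sum(assigned),
    n_taxa = nrow(m),
    unassigned_asvs = rownames(asv)[!assigned],
    retained_fraction = stats::setNames(retained, colnames(asv)))
  m
}

#' Median 16S copy number per taxon
#'
#' @param copy_numbers data.frame with columns `taxon` and `copy_number`
#'   (one genome per row), e.g. from [read_copy_numbers()], or an already
#'   reduced named numeric vector which is returned as-is.
#' @return named numeric vector taxon -> median copy number.
#' @export
taxon_copy_numbers <- function(copy_numbers) {
  if (is.numeric(copy_numbers) && !is.null(names(copy_numbers)))
    return(copy_numbers)
  stopifnot(is.data.frame(copy_numbers))
  med <- tapply(copy_numbers$copy_number, copy_numbers$taxon, stats::median)
  stats::setNames(as.numeric(med), names(med))
}

#' Normalize a taxon table by 16S rRNA gene copy number
#'
#' Divides every taxon row by the median 16S copy number of the genomes
#' pooled at that taxon, approximating organismal abundance. Taxa without
#' copy-number data are divided by `default` (1, i.e. left unchanged) and
#' listed in the report rather than dropped.
#'
#' @param taxa taxon x sample matrix from [aggregate_asvs()].
#' @param copy_numbers input accepted by [taxon_copy_numbers()].
#' @param default divisor for taxa without copy-number data.
#' @return normalized taxon x sample matrix (`normalized = TRUE`).
#' @export
normalize_copy_number <- function(taxa, copy_numbers, default = 1) {
  check_abundance_matrix(taxa, "taxon table")
  if (isTRUE(attr(taxa, "normalized")))
    stop("taxon table is already copy-number normalized", call. = FALSE)
  cn <- taxon_copy_numbers(copy_numbers)
  if (any(!is.finite(cn) | cn <= 0))
    stop("non-positive median copy number", call. = FALSE)
  if (!is.finite(default) || default <= 0)
    stop("default copy number must be positive", call. = FALSE)
  div <- cn[rownames(taxa)]
  missing <- rownames(taxa)[is.na(div)]
  div[is.na(div)] <- default
  out <- taxa / as.numeric(div)
  attr(out, "normalized") <- TRUE
  rep0 <- attr(taxa, "report")
  attr(out, "report") <- c(rep0, list(taxa_without_copy_number = missing))
  out
}

#' Predict function abundances from taxon abundances
#'
#' Linear mixture: the abundance of function f in sample s is the sum over
#' taxa of (taxon abundance in s) x (network entry for that taxon and f),
#' restricted to taxa present in both the table and the network. Taxa
#' absent from the network are listed in the report.
#'
#' @param taxa taxon x sample matrix (normalized or not).
#' @param network a `metgems_network` (see [build_network()]).
#' @return function x sample matrix with attributes `namespace`,
#'   `scale = "raw"` and `report` (`unmapped_taxa`, `n_taxa_mapped`).
#' @export
predict_functions <- function(taxa, network) {
  check_abundance_matrix(taxa, "taxon table")
  stopifnot(inherits(network, "metgems_network"))
  shared <- intersect(rownames(taxa), rownames(network$matrix))
  if (!length(shared))
    stop("no taxon label shared between table (e.g. '",
         rownames(taxa)[1] %||% "<none>", "') and network (e.g. '",
         rownames(network$matrix)[1] %||% "<none>", "')", call. = FALSE)
  unmapped <- setdiff(rownames(taxa), shared)
  out <- t(network$matrix[shared, , drop = FALSE]) %*%
    taxa[shared, , drop = FALSE]
  attr(out, "namespace") <- network$namespace
  attr(out, "scale") <- "raw"
  attr(out, "report") <- list(unmapped_taxa = unmapped,
                              n_taxa_mapped = length(shared),
                              n_taxa_total = nrow(taxa))
  out
}

#' Predict with species-level resolution where available
#'
#' ASVs whose species label appears in the species network are predicted
#' through it; the remainder fall back to the genus network. The two
#' function tables are summed over the union of function ids.
#'
#' @param asv ASV x sample matrix.
#' @param taxonomy_genus,taxonomy_species named label vectors at each rank.
#' @param net_genus,net_species the two reference networks.
#' @param cn_genus,cn_species optional copy-number inputs per rank.
#' @return function x sample matrix (raw scale).
#' @export
predict_functions2 <- function(asv, taxonomy_genus, taxonomy_species,
                               net_genus, net_species,
                               cn_genus = NULL, cn_species = NULL) {
  sp <- taxonomy_species[rownames(asv)]
  use_sp <- !is.na(sp) & sp %in% rownames(net_species$matrix)
  pieces <- list()
  if (any(use_sp)) {
    t_sp <- aggregate_asvs(asv[use_sp, , drop = FALSE], taxonomy_species)
    if (!is.null(cn_species)) t_sp <- normalize_copy_number(t_sp, cn_species)
    pieces$species <- predict_functions(t_sp, net_species)
  }
  if (any(!use_sp)) {
    t_g <- suppressWarnings(
      aggregate_asvs(asv[!use_sp, , drop = FALSE], taxonomy_genus))
    if (nrow(t_g)) {
      if (!is.null(cn_genus)) t_g <- normalize_copy_number(t_g, cn_genus)
      pieces$genus <- predict_functions(t_g, net_genus)
    }
  }
  if (!length(pieces)) stop("no ASV could be mapped at either rank",
                            call. = FALSE)
  fids <- sort(unique(unlist(lapply(pieces, rownames))))
  out <- matrix(0, length(fids), ncol(asv),
                dimnames = list(fids, colnames(asv)))
  for (p in pieces) out[rownames(p), ] <- out[rownames(p), ] + p
  attr(out, "namespace") <- net_genus$namespace
  attr(out, "scale") <- "raw"
  out
}

#' Scale a function table to per-sample relative abundance
#'
#' Divides every sample column by its sum. All-zero columns are left as
#' zeros and flagged in the report. Idempotent.
#'
#' @param ft function x sample matrix.
#' @return matrix with `scale = "relative"`; columns sum to 1 (or 0).
#' @export
relative_abundance <- function(ft) {
  check_abundance_matrix(ft, "function table")
  sums <- colSums(ft)
  zero <- sums == 0
  sums[zero] <- 1
  out <- sweep(ft, 2, sums, "/")
  for (a in c("namespace", "report"))
    attr(out, a) <- attr(ft, a, exact = TRUE)
  attr(out, "scale") <- "relative"
  if (any(zero))
    attr(out, "report") <- c(attr(out, "report"),
                             list(all_zero_samples = colnames(ft)[zero]))
  out
}

#' Summarize a KO table by functional category
#'
#' @param ft KO x sample matrix.
#' @param category_map named character vector KO id -> category label;
#'   functions without an entry are pooled under `"Unclassified"`.
#' @return list with `table` (category x sample sums) and `n_functions`
#'   (KO ids per category).
#' @export
summarize_by_category <- function(ft, category_map) {
  check_abundance_matrix(ft, "function table")
  ns <- attr(ft, "namespace", exact = TRUE)
  if (!is.null(ns) && ns != "KO")
    stop("category summaries are defined for the KO namespace", call. = FALSE)
  cat <- category_map[rownames(ft)]
  cat[is.na(cat)] <- "Unclassified"
  tab <- rowsum(ft, group = as.character(cat))
  tab <- tab[order(rownames(tab)), , drop = FALSE]
  n <- table(as.character(cat))
  list(table = tab,
       n_functions = stats::setNames(as.integer(n), names(n)))
}
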