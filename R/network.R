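# Taxon-by-function reference matrices ("networks"). Four modes:
#   pan         sum (or mean, the default) of member-genome counts
#   core        1 iff the function is present in every member genome
#   pan_weight  pan computed on taxon-weighted counts
#   core_weight core computed on unweighted presence (weights recorded only)
# Rows are taxon labels at the chosen rank, columns are KO ids or EC numbers.

new_network <- function(matrix, mode, rank, namespace, genomes_per_taxon,
                        aggregation = NULL) {
  structure(list(matrix = matrix, mode = mode, rank = rank,
                 namespace = namespace, aggregation = aggregation,
                 genomes_per_taxon = genomes_per_taxon),
            class = "metgems_network")
}

#' @export
print.metgems_network <- function(x, ...) {
  cat("metgems_network:", x$mode, "/", x$rank, "/", x$namespace, "-",
      nrow(x$matrix), "taxa x", ncol(x$matrix), "functions\n")
  invisible(x)
}

# shared front half of pan/core: resolve rank labels, drop genomes without
# one, subset the function table to the namespace
prepare_rank <- function(gems, rank, namespace) {
  labels <- as.character(gems$meta[[rank]])
  ok <- !is.na(labels) & nzchar(labels)
  if (!all(ok))
    warning(sum(!ok), " genome(s) lack a ", rank, " label and were excluded",
            call. = FALSE)
  if (!any(ok))
    stop("no genome carries a ", rank, " label", call. = FALSE)
  meta <- gems$meta[ok, ]
  labels <- labels[ok]
  gpt <- table(labels)
  gpt <- stats::setNames(as.integer(gpt), names(gpt))
  f <- gems$functions[gems$functions$namespace == namespace &
                      gems$functions$genome_id %in% meta$genome_id, ]
  f$taxon <- stats::setNames(labels, meta$genome_id)[f$genome_id]
  list(meta = meta, functions = f, genomes_per_taxon = gpt)
}

#' Build a pan-function reference network
#'
#' Aggregates member-genome function counts per taxon, either as a plain sum
#' or (the default) divided by the number of genomes in the taxon so that
#' heavily sequenced genera do not dominate in proportion to sequencing
#' effort.
#'
#' @param gems a [gem_collection()] (possibly weighted via [apply_weights()]).
#' @param rank `"genus"` or `"species"`.
#' @param namespace `"KO"` or `"EC"`.
#' @param aggregation `"mean"` (default) or `"sum"`.
#' @return a `metgems_network` with mode `pan` (or `pan_weight` when the
#'   collection is weighted).
#' @export
build_pan <- function(gems, rank = c("genus", "species"),
                      namespace = c("KO", "EC"),
                      aggregation = c("mean", "sum")) {
  stopifnot(inherits(gems, "gem_collection"))
  rank <- match.arg(rank)
  namespace <- match.arg(namespace)
  aggregation <- match.arg(aggregation)
  p <- prepare_rank(gems, rank, namespace)
  f <- p$functions
  taxa <- names(p$genomes_per_taxon)
  fids <- sort(unique(f$function_id))
  m <- matrix(0, nrow = length(taxa), ncol = length(fids),
              dimnames = list(taxa, fids))
  if (nrow(f)) {
    agg <- tapply(f$count, list(f$taxon, f$function_id), sum, default = 0)
    m[rownames(agg), colnames(agg)] <- agg
  }
  if (aggregation == "mean")
    m <- m / p$genomes_per_taxon[rownames(m)]
  new_network(m, mode = if (gems$weighted) "pan_weight" else "pan",
              rank = rank, namespace = namespace,
              genomes_per_taxon = p$genomes_per_taxon,
              aggregation = aggregation)
}

#' Build a core-function reference network
#'
#' Entry (taxon, function) is 1 iff the function is present (count > 0) in
#' every member genome of the taxon, else 0 — the intersection of member
#' presence sets. Presence is always evaluated on unweighted counts, so the
#' core network of a weighted collection equals the unweighted core (only
#' the mode label differs).
#'
#' @inheritParams build_pan
#' @return a `metgems_network` with 0/1 entries, mode `core` or
#'   `core_weight`.
#' @export
build_core <- function(gems, rank = c("genus", "species"),
                       namespace = c("KO", "EC")) {
  stopifnot(inherits(gems, "gem_collection"))
  rank <- match.arg(rank)
  namespace <- match.arg(namespace)
  p <- prepare_rank(gems, rank, namespace)
  f <- p$functions
  present <- f$presence_count %||% f$count
  f <- f[present > 0, ]
  taxa <- names(p$genomes_per_taxon)
  fids <- sort(unique(f$function_id))
  m <- matrix(0, nrow = length(taxa), ncol = length(fids),
              dimnames = list(taxa, fids))
  if (nrow(f)) {
    npresent <- tapply(f$genome_id, list(f$taxon, f$function_id),
                       function(x) length(unique(x)), default = 0L)
    hit <- matrix(0L, nrow = length(taxa), ncol = length(fids),
                  dimnames = list(taxa, fids))
    hit[rownames(npresent), colnames(npresent)] <- npresent
    m[] <- as.numeric(hit == p$genomes_per_taxon[rownames(m)])
  }
  new_network(m, mode = if (gems$weighted) "core_weight" else "core",
              rank = rank, namespace = namespace,
              genomes_per_taxon = p$genomes_per_taxon)
}

#' Build a reference network under one of the four computational modes
#'
#' Convenience dispatcher: `pan_weight`/`core_weight` require `weights`,
#' which are applied via [apply_weights()] before aggregation.
#'
#' @inheritParams build_pan
#' @param mode one of `"pan"`, `"core"`, `"pan_weight"`, `"core_weight"`.
#' @param weights named numeric genome weights (weighted modes only).
#' @return a `metgems_network`.
#' @export
build_network <- function(gems, mode = c("pan", "core", "pan_weight",
                                         "core_weight"),
                          rank = c("genus", "species"),
                          namespace = c("KO", "EC"), weights = NULL,
                          aggregation = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (mode %in% c("pan_weight", "core_weight")) {
    if (is.null(weights))
      stop("mode '", mode, "' needs a weight table", call. = FALSE)
    gems <- apply_weights(gems, weights)
  }
  if (mode %in% c("pan", "pan_weight"))
    build_pan(gems, rank, namespace, aggregation)
  else
    build_core(gems, rank, namespace)
}

#' Number of functions covered by a network
#'
#' Counts distinct function ids whose entry is positive in at least one
#' taxon (the per-mode coverage tallies of a reference collection).
#'
#' @param network a `metgems_network`.
#' @return non-negative integer.
#' @export
coverage <- function(network) {
  stopifnot(inherits(network, "metgems_network"))
  m <- network$matrix
  if (!length(m)) return(0L)
  sum(apply(m > 0, 2, any))
}
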