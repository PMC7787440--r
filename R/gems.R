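# A genome collection holds one function profile per genome: its taxonomy
# (class/genus/species), its KO and EC counts and, when known, its 16S rRNA
# gene copy number. This is the raw material the taxon-level reference
# networks are aggregated from.

#' Construct a genome function-profile collection
#'
#' @param meta data.frame with columns `genome_id`, `class`, `genus`,
#'   `species` and optionally `copy_number_16s` (positive, `NA` allowed).
#' @param functions long data.frame with columns `genome_id`, `function_id`,
#'   `namespace` (`"KO"`/`"EC"`) and `count` (finite, non-negative).
#' @param weighted internal flag set by [apply_weights()].
#' @return object of class `gem_collection`.
#' @export
gem_collection <- function(meta, functions, weighted = FALSE) {
  need <- c("genome_id", "class", "genus", "species")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta$genome_id <- as.character(meta$genome_id)
  if (anyDuplicated(meta$genome_id))
    stop("duplicate genome_id: ",
         meta$genome_id[duplicated(meta$genome_id)][1], call. = FALSE)
  if (!nrow(meta)) stop("empty genome collection", call. = FALSE)
  if (is.null(meta$copy_number_16s)) meta$copy_number_16s <- NA_real_
  cn <- meta$copy_number_16s
  if (any(!is.na(cn) & (!is.finite(cn) | cn <= 0)))
    stop("16S copy numbers must be positive", call. = FALSE)

  fneed <- c("genome_id", "function_id", "namespace", "count")
  miss <- setdiff(fneed, names(functions))
  if (length(miss))
    stop("function table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  functions$genome_id <- as.character(functions$genome_id)
  unknown <- setdiff(functions$genome_id, meta$genome_id)
  if (length(unknown))
    stop("function rows for unknown genome: ", unknown[1], call. = FALSE)
  if (!all(functions$namespace %in% c("KO", "EC")))
    stop("namespace must be 'KO' or 'EC'", call. = FALSE)
  if (any(!is.finite(functions$count) | functions$count < 0))
    stop("function counts must be finite and non-negative", call. = FALSE)
  if (anyDuplicated(functions[c("genome_id", "function_id")]))
    stop("duplicate (genome_id, function_id) pair", call. = FALSE)

  structure(list(meta = meta[c(need, "copy_number_16s")],
                 functions = functions[fneed],
                 weighted = isTRUE(weighted)),
            class = "gem_collection")
}

#' @export
print.gem_collection <- function(x, ...) {
  cat("gem_collection:", nrow(x$meta), "genomes,",
      sum(x$functions$namespace == "KO"), "KO entries,",
      sum(x$functions$namespace == "EC"), "EC entries",
      if (x$weighted) "(taxon-weighted)" else "", "\n")
  invisible(x)
}

#' Load genome function annotations from TSV
#'
#' Two dialects are auto-detected from the header. The long dialect has
#' columns `genome_id, class, genus, species, copy_number_16s, function_id,
#' count` with one (genome, function) pair per row; the wide dialect has one
#' row per genome and one column per function id (`K00001`, `1.1.1.1`, ...).
#' Function ids are normalized with [normalize_function_ids()]; tokens
#' matching neither the KO (`K` + 5 digits) nor the EC (`a.b.c.d`, trailing
#' `-` allowed) syntax are dropped with a warning naming their lines.
#'
#' @param path TSV file of genome annotations.
#' @return a [gem_collection()].
#' @export
load_gem_metadata <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, comment.char = "")
  need <- c("genome_id", "class", "genus", "species")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  if ("function_id" %in% names(d)) {
    if (!"count" %in% names(d))
      stop("missing mandatory column(s): count", call. = FALSE)
    meta <- unique(d[c(need, intersect("copy_number_16s", names(d)))])
    if (anyDuplicated(meta$genome_id))
      stop("conflicting metadata rows for genome_id: ",
           meta$genome_id[duplicated(meta$genome_id)][1], call. = FALSE)
    fid <- normalize_function_ids(d$function_id)
    empty <- !nzchar(fid)
    if (any(empty))
      warning("empty function cell on line(s) ",
              paste(which(empty) + 1L, collapse = ", "), call. = FALSE)
    ns <- function_namespace(fid)
    bad <- !empty & is.na(ns)
    if (any(bad))
      warning("malformed function id(s) on line(s) ",
              paste(which(bad) + 1L, collapse = ", "), ": ",
              paste(unique(fid[bad]), collapse = ", "), call. = FALSE)
    keep <- !empty & !bad
    fun <- data.frame(genome_id = d$genome_id[keep],
                      function_id = fid[keep],
                      namespace = ns[keep],
                      count = as.numeric(d$count[keep]),
                      stringsAsFactors = FALSE)
  } else {
    # wide dialect: every non-metadata column is a candidate function id
    meta_cols <- c(need, "copy_number_16s")
    fun_cols <- setdiff(names(d), meta_cols)
    norm <- normalize_function_ids(fun_cols)
    ns <- function_namespace(norm)
    if (any(is.na(ns)))
      warning("malformed function column(s) ignored: ",
              paste(fun_cols[is.na(ns)], collapse = ", "), call. = FALSE)
    keep <- !is.na(ns)
    fun_cols <- fun_cols[keep]
    norm <- norm[keep]
    ns <- ns[keep]
    meta <- d[intersect(meta_cols, names(d))]
    if (anyDuplicated(d$genome_id))
      stop("duplicate genome_id: ",
           d$genome_id[duplicated(d$genome_id)][1], call. = FALSE)
    counts <- as.matrix(d[fun_cols])
    mode(counts) <- "numeric"
    nz <- which(counts > 0, arr.ind = TRUE)
    fun <- data.frame(genome_id = d$genome_id[nz[, 1]],
                      function_id = norm[nz[, 2]],
                      namespace = ns[nz[, 2]],
                      count = counts[nz],
                      stringsAsFactors = FALSE)
  }
  if (!is.null(meta$copy_number_16s))
    meta$copy_number_16s <- as.numeric(meta$copy_number_16s)
  gem_collection(meta, fun)
}

#' Apply per-genome taxonomic weights to a collection
#'
#' Multiplies every function count by its genome's weight (pan-weight
#' semantics). The unweighted counts are retained so that core-type
#' matrices keep being computed from unweighted presence, which is what
#' makes the core and core-weight networks coincide.
#'
#' @param gems a [gem_collection()].
#' @param weights named numeric vector genome id -> non-negative weight;
#'   genomes without a weight default to 1 with a warning.
#' @return a weighted `gem_collection`.
#' @export
apply_weights <- function(gems, weights) {
  stopifnot(inherits(gems, "gem_collection"))
  if (any(!is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  if (!any(weights > 0)) stop("at least one weight must be positive",
                              call. = FALSE)
  missing <- setdiff(gems$meta$genome_id, names(weights))
  if (length(missing)) {
    warning(length(missing), " genome(s) without a weight; defaulting to 1",
            call. = FALSE)
    weights[missing] <- 1
  }
  f <- gems$functions
  if (is.null(f$presence_count)) f$presence_count <- f$count
  f$count <- f$count * unname(weights[f$genome_id])
  out <- gems
  out$functions <- f
  out$weighted <- TRUE
  out$weights <- weights[gems$meta$genome_id]
  out
}

#' Per-genome KO/EC count summaries and their correlation
#'
#' Counts, for every genome, the distinct KO ids and EC numbers present
#' (count > 0), summarizes mean and SD per taxonomic group, and reports the
#' Pearson correlation between the two per-genome count vectors.
#'
#' @param gems a [gem_collection()].
#' @param group_rank grouping rank for the summaries (default `"class"`).
#' @return list with `summary` (data.frame: group, n_genomes, ko_mean,
#'   ko_sd, ec_mean, ec_sd), `pcc` (Pearson coefficient, `NA` when a count
#'   vector has zero variance) and `pcc_defined`.
#' @export
function_count_correlation <- function(gems, group_rank = "class") {
  stopifnot(inherits(gems, "gem_collection"))
  if (nrow(gems$meta) < 2)
    stop("need at least two genomes", call. = FALSE)
  f <- gems$functions[gems$functions$count > 0, ]
  count_of <- function(ns) {
    sub <- f[f$namespace == ns, ]
    n <- tapply(sub$function_id, sub$genome_id,
                function(x) length(unique(x)))
    out <- stats::setNames(rep(0L, nrow(gems$meta)), gems$meta$genome_id)
    out[names(n)] <- as.integer(n)
    out
  }
  n_ko <- count_of("KO")
  n_ec <- count_of("EC")
  grp <- gems$meta[[group_rank]]
  if (is.null(grp)) stop("unknown rank: ", group_rank, call. = FALSE)
  summary <- do.call(rbind, lapply(split(seq_along(grp), grp), function(i) {
    data.frame(group = grp[i][1], n_genomes = length(i),
               ko_mean = mean(n_ko[i]), ko_sd = stats::sd(n_ko[i]),
               ec_mean = mean(n_ec[i]), ec_sd = stats::sd(n_ec[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  defined <- stats::sd(n_ko) > 0 && stats::sd(n_ec) > 0
  pcc <- if (defined) stats::cor(n_ko, n_ec) else NA_real_
  list(summary = summary, pcc = pcc, pcc_defined = defined,
       ko_per_genome = n_ko, ec_per_genome = n_ec)
}
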