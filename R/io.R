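# Tab-separated table dialect shared by every command: first column holds
# row ids (header cell may be "#ASV_ID"-style), remaining columns are
# numeric, values written with 7 significant digits, "# key=value" comment
# lines carry metadata. BIOM TSV exports ("# Constructed from biom file")
# are tolerated on read, never written.

#' Read a labelled numeric matrix from TSV
#'
#' @param path file path.
#' @return numeric matrix with row/column names; `# key=value` metadata
#'   lines are attached as attribute `"metgems_meta"` (named character).
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)

  # comment/metadata lines start with '#' and contain no tab; a '#'-prefixed
  # line WITH tabs is the (QIIME-style) header
  is_meta <- startsWith(lines, "#") & !grepl("\t", lines, fixed = TRUE)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  offsets <- which(!is_meta)  # original line numbers for diagnostics
  if (!length(body)) stop("no header row in ", path, call. = FALSE)

  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol <- length(header) - 1L
  sample_ids <- header[-1]

  n <- length(fields) - 1L
  if (n == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol,
                dimnames = list(character(0), sample_ids))
  } else {
    rows <- fields[-1]
    lens <- lengths(rows)
    if (any(lens != ncol + 1L)) {
      bad <- offsets[-1][which(lens != ncol + 1L)[1]]
      stop("ragged row at line ", bad, " of ", path, call. = FALSE)
    }
    row_ids <- vapply(rows, `[[`, character(1), 1L)
    if (anyDuplicated(row_ids)) {
      stop("duplicate row id '", row_ids[duplicated(row_ids)][1], "' in ",
           path, call. = FALSE)
    }
    vals <- suppressWarnings(
      vapply(rows, function(r) as.numeric(r[-1]), numeric(ncol)))
    # vapply gives a length-n vector when ncol == 1, else an ncol x n matrix
    vals <- matrix(vals, nrow = ncol, ncol = n)
    if (anyNA(vals)) {
      bad_row <- which(colSums(is.na(vals)) > 0)[1]
      stop("non-numeric cell at line ", offsets[-1][bad_row], " of ", path,
           call. = FALSE)
    }
    m <- matrix(t(vals), nrow = n, ncol = ncol,
                dimnames = list(row_ids, sample_ids))
  }
  kv <- parse_meta_lines(meta_lines)
  if (length(kv)) attr(m, "metgems_meta") <- kv
  m
}

parse_meta_lines <- function(meta_lines) {
  out <- character(0)
  for (l in meta_lines) {
    l <- sub("^#\\s*", "", l)
    toks <- strsplit(l, "\\s+")[[1]]
    toks <- toks[grepl("=", toks, fixed = TRUE)]
    for (t in toks) {
      kv <- strsplit(t, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) out[kv[1]] <- kv[2]
    }
  }
  out
}

#' Write a labelled numeric matrix as TSV
#'
#' Values are written with 7 significant digits, so a write/read round trip
#' reproduces values to a relative error below 5e-7.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_label header cell for the id column.
#' @param meta optional named character vector written as `# key=value`.
#' @export
write_table_tsv <- function(m, path, id_label = "#ID", meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", paste(names(meta), meta, sep = "=",
                                  collapse = " ")), con)
  }
  writeLines(paste(c(id_label, colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    body <- apply(m, 1, function(r) paste(sprintf("%.7g", r), collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a taxon-by-function reference network with its metadata sidecar
#' @param net a `metgems_network`.
#' @param path output path.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "metgems_network"))
  gpt <- paste(names(net$genomes_per_taxon), net$genomes_per_taxon,
               sep = ":", collapse = ",")
  meta <- c(mode = net$mode, rank = net$rank, namespace = net$namespace,
            aggregation = net$aggregation %||% "NA",
            n_genomes = as.character(sum(net$genomes_per_taxon)),
            genomes_per_taxon = gpt)
  write_table_tsv(net$matrix, path, id_label = "#taxon", meta = meta)
}

#' Read a reference network written by [write_network_tsv()]
#' @param path file path.
#' @return a `metgems_network`.
#' @export
read_network_tsv <- function(path) {
  m <- read_table_tsv(path)
  kv <- attr(m, "metgems_meta")
  if (is.null(kv) || is.na(kv["mode"]))
    stop("network file lacks '# mode=...' metadata: ", path, call. = FALSE)
  attr(m, "metgems_meta") <- NULL
  gpt <- integer(0)
  if (!is.na(kv["genomes_per_taxon"])) {
    pairs <- strsplit(strsplit(kv[["genomes_per_taxon"]], ",")[[1]], ":")
    gpt <- stats::setNames(vapply(pairs, function(p) as.integer(p[2]),
                                  integer(1)),
                           vapply(pairs, `[[`, character(1), 1))
  }
  new_network(m, mode = kv[["mode"]], rank = kv[["rank"]],
              namespace = kv[["namespace"]],
              aggregation = if (is.na(kv["aggregation"])) NULL
                            else kv[["aggregation"]],
              genomes_per_taxon = gpt)
}

#' Read an ASV-to-taxonomy mapping
#'
#' Accepts a two-column TSV `asv_id<TAB>lineage`, where the lineage is either
#' a plain taxon label or a QIIME2/Greengenes-style string
#' (`k__...;p__...;c__...;o__...;f__...;g__...;s__...`). The label at `rank`
#' is extracted by prefix; an empty field yields `NA` (unassigned).
#'
#' @param path file path.
#' @param rank `"genus"` or `"species"`.
#' @return named character vector asv id -> taxon label (`NA` = unassigned).
#' @export
read_taxonomy <- function(path, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  # tolerate a QIIME "Feature ID<TAB>Taxon" header
  if (length(lines)) {
    first <- tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1])
    if (first %in% c("feature id", "feature_id", "featureid", "asv_id",
                     "asv id", "otu id", "otu_id"))
      lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  lineages <- vapply(fields, function(f)
    if (length(f) >= 2) f[2] else "", character(1))
  if (anyDuplicated(ids))
    stop("duplicate ASV id in taxonomy file: ", ids[duplicated(ids)][1],
         call. = FALSE)
  stats::setNames(vapply(lineages, parse_lineage_rank, character(1),
                         rank = rank, USE.NAMES = FALSE), ids)
}

parse_lineage_rank <- function(lineage, rank) {
  lineage <- trimws(lineage)
  if (!nzchar(lineage) || tolower(lineage) == "unassigned")
    return(NA_character_)
  if (!grepl("__", lineage, fixed = TRUE)) return(lineage)  # plain label
  grab <- function(prefix) {
    m <- regmatches(lineage,
                    regexpr(paste0("(^|;)\\s*", prefix, "__[^;]*"), lineage))
    if (!length(m)) return("")
    trimws(sub(paste0("^(;)?\\s*", prefix, "__"), "", m))
  }
  g <- grab("g")
  if (rank == "genus") return(if (nzchar(g)) g else NA_character_)
  s <- grab("s")
  if (!nzchar(s)) return(NA_character_)
  # Greengenes species fields usually hold the epithet only
  if (nzchar(g) && !startsWith(s, g)) paste(g, s) else s
}

#' Read a sample design table
#'
#' TSV with header `sample_id<TAB>condition[<TAB>stratum]`.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `condition` and optionally
#'   `stratum`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, comment.char = "")
  names(d)[1:2] <- c("sample_id", "condition")
  if (ncol(d) >= 3) names(d)[3] <- "stratum"
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample id in design table", call. = FALSE)
  d
}

#' Read per-genome 16S copy numbers grouped by taxon
#'
#' TSV with header `taxon<TAB>copy_number`, one genome per row; the
#' per-taxon value used downstream is the median over rows.
#'
#' @param path file path.
#' @return data.frame with columns `taxon`, `copy_number`.
#' @export
read_copy_numbers <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, comment.char = "")
  names(d)[1:2] <- c("taxon", "copy_number")
  d$copy_number <- as.numeric(d$copy_number)
  if (anyNA(d$copy_number) || any(d$copy_number <= 0))
    stop("copy numbers must be positive", call. = FALSE)
  d
}

#' Read a per-genome taxonomic weight table (`genome_id<TAB>weight`)
#' @param path file path.
#' @return named numeric vector.
#' @export
read_weights <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, comment.char = "")
  w <- as.numeric(d[[2]])
  if (anyNA(w)) stop("non-numeric weight in ", path, call. = FALSE)
  stats::setNames(w, d[[1]])
}

#' Read a route catalog (MinPath-style mapping file)
#'
#' Two tab-separated columns `route_id<TAB>ec_number`, one pair per line,
#' no header required.
#'
#' @param path file path.
#' @return named list route id -> character vector of EC numbers.
#' @export
read_route_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2))
    stop("route catalog rows need 2 columns", call. = FALSE)
  rid <- vapply(fields, `[[`, character(1), 1L)
  ec <- normalize_function_ids(vapply(fields, `[[`, character(1), 2L))
  bad <- !is_ec_id(ec)
  if (any(bad))
    stop("malformed EC number '", ec[bad][1], "' in route catalog",
         call. = FALSE)
  cat <- split(ec, rid)
  lapply(cat, unique)
}
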