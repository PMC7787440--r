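#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the previous RNG
#' state so that seeded helpers never disturb the caller's random stream.
#'
#' @param seed integer seed passed to [set.seed()].
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# -- function-id hygiene -------------------------------------------------

#' Normalize function identifiers
#'
#' Trims whitespace and strips an `EC:`/`ec:` prefix. Partial EC numbers
#' with a trailing `-` are kept verbatim.
#'
#' @param ids character vector of KO or EC identifiers.
#' @return normalized character vector.
#' @export
normalize_function_ids <- function(ids) {
  ids <- trimws(as.character(ids))
  sub("^[Ee][Cc][: ]\\s*", "", ids)
}

is_ko_id <- function(ids) grepl("^K[0-9]{5}$", ids)
is_ec_id <- function(ids) grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$", ids)

#' @noRd
function_namespace <- function(ids) {
  ns <- rep(NA_character_, length(ids))
  ns[is_ko_id(ids)] <- "KO"
  ns[is_ec_id(ids)] <- "EC"
  ns
}

# -- matrix hygiene ------------------------------------------------------

check_abundance_matrix <- function(m, what = "table") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have row and column names", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop(what, " has duplicated row ids", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop(what, " has duplicated column ids", call. = FALSE)
  if (any(!is.finite(m)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (any(m < 0))
    stop(what, " contains negative values", call. = FALSE)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
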