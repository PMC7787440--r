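# Metabolic-route inference: per sample, pick the minimum set of routes
# (set cover) whose EC members jointly explain every observed EC, then score
# each selected route by the harmonic mean of its member EC abundances.

#' Select a minimal set of routes covering the observed EC numbers
#'
#' Finds a minimum-cardinality subset of catalog routes that jointly contain
#' every observed EC appearing in at least one route; ECs in no route are
#' reported as uncoverable. Routes whose (observed-restricted) EC set is
#' contained in another route's are pruned first. When the pruned candidate
#' count is at most `exact_limit` the solution is provably minimal
#' (enumeration by increasing cover size); otherwise a greedy
#' largest-marginal-cover heuristic is used and flagged. Ties are broken by
#' the lexicographically smallest sorted route-id tuple, so identical inputs
#' always yield identical selections.
#'
#' @param observed_ecs character vector of EC numbers with positive
#'   abundance in one sample.
#' @param catalog named list route id -> character vector of EC numbers
#'   (see [read_route_catalog()]).
#' @param exact_limit candidate-route count up to which the exact search is
#'   used (default 20).
#' @return object of class `route_selection`: list with `selected`,
#'   `covered`, `uncoverable`, `method` (`"exact"`, `"greedy"` or `"none"`)
#'   and `provably_minimal`.
#' @export
select_minimal_routes <- function(observed_ecs, catalog, exact_limit = 20) {
  if (!length(catalog)) stop("empty route catalog", call. = FALSE)
  observed <- unique(normalize_function_ids(observed_ecs))
  all_ecs <- unique(unlist(catalog, use.names = FALSE))
  covered <- intersect(observed, all_ecs)
  uncoverable <- setdiff(observed, all_ecs)
  empty <- function(method) structure(
    list(selected = character(0), covered = covered,
         uncoverable = uncoverable, method = method,
         provably_minimal = TRUE), class = "route_selection")
  if (!length(covered)) return(empty("none"))

  cand <- lapply(catalog, intersect, covered)
  cand <- cand[lengths(cand) > 0]
  cand <- cand[order(names(cand))]

  # dominance pruning: drop routes contained in another candidate; among
  # routes with identical coverage keep the smallest id
  n <- length(cand)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (all(cand[[i]] %in% cand[[j]])) {
        if (length(cand[[i]]) < length(cand[[j]]) || j < i) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  cand <- cand[keep]
  ids <- names(cand)
  inc <- vapply(cand, function(s) covered %in% s,
                logical(length(covered)))
  inc <- matrix(inc, nrow = length(covered), ncol = length(ids),
                dimnames = list(covered, ids))

  if (length(ids) <= exact_limit) {
    sel <- cover_exact(inc)
    method <- "exact"
    minimal <- TRUE
  } else {
    message("more than ", exact_limit, " candidate routes; using greedy ",
            "cover (selection may be non-optimal)")
    sel <- cover_greedy(inc)
    method <- "greedy"
    minimal <- FALSE
  }
  structure(list(selected = sort(sel), covered = covered,
                 uncoverable = uncoverable, method = method,
                 provably_minimal = minimal),
            class = "route_selection")
}

# exact minimum cover by enumerating route combinations of increasing size;
# `inc` is the EC x route incidence matrix with lexicographically sorted
# column ids, so the first hit is the lexicographically smallest cover
cover_exact <- function(inc) {
  ids <- colnames(inc)
  for (k in seq_along(ids)) {
    combos <- utils::combn(seq_along(ids), k, simplify = FALSE)
    for (cb in combos) {
      if (all(rowSums(inc[, cb, drop = FALSE]) > 0))
        return(ids[cb])
    }
  }
  stop("internal error: candidates do not cover their own union")
}

cover_greedy <- function(inc) {
  ids <- colnames(inc)
  unmet <- rep(TRUE, nrow(inc))
  sel <- character(0)
  while (any(unmet)) {
    gain <- colSums(inc[unmet, , drop = FALSE])
    best <- which(gain == max(gain))[1]  # ids sorted -> lexicographic tie-break
    sel <- c(sel, ids[best])
    unmet <- unmet & !inc[, best]
  }
  sel
}

#' @export
print.route_selection <- function(x, ...) {
  cat("route_selection:", length(x$selected), "route(s) [", x$method, "],",
      length(x$covered), "EC(s) covered,", length(x$uncoverable),
      "uncoverable\n")
  invisible(x)
}

#' Harmonic-mean route abundances
#'
#' For each selected route in each sample, the abundance is the harmonic
#' mean n / sum(1/x_i) over the route's member ECs present in the table.
#' Any member EC with abundance 0 forces the route abundance to 0 (the
#' harmonic-mean limit): a route whose required step is absent is scored as
#' absent. Unselected routes get 0.
#'
#' @param ec_table EC x sample matrix.
#' @param selections a single `route_selection` applied to every sample, or
#'   a named list of selections keyed by sample id.
#' @param catalog route catalog list.
#' @return route x sample abundance matrix.
#' @export
route_abundance <- function(ec_table, selections, catalog) {
  check_abundance_matrix(ec_table, "EC table")
  ns <- attr(ec_table, "namespace", exact = TRUE)
  if (!is.null(ns) && ns != "EC")
    stop("route abundance requires an EC-namespace table", call. = FALSE)
  samples <- colnames(ec_table)
  if (inherits(selections, "route_selection"))
    selections <- stats::setNames(rep(list(selections), length(samples)),
                                  samples)
  routes <- sort(unique(unlist(lapply(selections, `[[`, "selected"))))
  out <- matrix(0, length(routes), length(samples),
                dimnames = list(routes, samples))
  for (s in samples) {
    sel <- selections[[s]]
    if (is.null(sel)) next
    for (r in sel$selected) {
      members <- intersect(catalog[[r]], rownames(ec_table))
      if (!length(members)) {
        warning("route ", r, " has no member EC in the table", call. = FALSE)
        next
      }
      x <- ec_table[members, s]
      out[r, s] <- if (any(x == 0)) 0 else length(x) / sum(1 / x)
    }
  }
  out
}

#' Per-sample minimal-route selection plus abundances
#'
#' Convenience wrapper: for every sample, the observed ECs are those with
#' positive abundance in that sample; a minimal cover is selected and scored
#' by [route_abundance()].
#'
#' @inheritParams route_abundance
#' @inheritParams select_minimal_routes
#' @return list with `abundance` (route x sample matrix) and `selections`
#'   (per-sample `route_selection` list).
#' @export
infer_routes <- function(ec_table, catalog, exact_limit = 20) {
  check_abundance_matrix(ec_table, "EC table")
  selections <- lapply(stats::setNames(colnames(ec_table),
                                       colnames(ec_table)), function(s) {
    observed <- rownames(ec_table)[ec_table[, s] > 0]
    select_minimal_routes(observed, catalog, exact_limit)
  })
  list(abundance = route_abundance(ec_table, selections, catalog),
       selections = selections)
}

#' Differential route abundance between two conditions
#'
#' Delegates to [wilcoxon_test()] per route and orders the result by
#' p-value.
#'
#' @param route_table route x sample matrix.
#' @param design data.frame from [read_design()] or named condition vector.
#' @param case condition label treated as the case group (defaults to the
#'   alphabetically first label).
#' @return data.frame of per-route statistics sorted by p-value.
#' @export
compare_routes <- function(route_table, design, case = NULL) {
  res <- wilcoxon_test(route_table, design, case = case)
  res[order(res$p.value), ]
}
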