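# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, full enumeration) and never share code
# with the implementation they check.

# -- fixture builders ----------------------------------------------------

# small hand-rolled genome collection: n_genomes random genomes spread over
# n_taxa genera, integer counts in 0..max_count over a shared function pool
random_gems <- function(n_genomes = 10, n_taxa = 3, n_functions = 25,
                        namespace = "KO", max_count = 3, seed = 1,
                        p_present = 0.5) {
  with_seed(seed, {
    fids <- if (namespace == "KO") sprintf("K%05d", seq_len(n_functions))
            else sprintf("%d.%d.%d.%d", 1 + seq_len(n_functions) %% 5,
                         1 + seq_len(n_functions) %% 7,
                         1 + seq_len(n_functions) %% 3,
                         seq_len(n_functions))
    genera <- sprintf("g%02d", sample(n_taxa, n_genomes, replace = TRUE))
    meta <- data.frame(genome_id = sprintf("G%03d", seq_len(n_genomes)),
                       class = "c1", genus = genera,
                       species = sprintf("g sp%d", seq_len(n_genomes)),
                       copy_number_16s = sample(1:5, n_genomes, TRUE),
                       stringsAsFactors = FALSE)
    fun <- do.call(rbind, lapply(seq_len(n_genomes), function(i) {
      present <- fids[stats::runif(n_functions) < p_present]
      if (!length(present)) return(NULL)
      data.frame(genome_id = meta$genome_id[i], function_id = present,
                 namespace = namespace,
                 count = sample(seq_len(max_count), length(present), TRUE),
                 stringsAsFactors = FALSE)
    }))
    gem_collection(meta, fun)
  })
}

# dense genome x function count matrix view of a collection (one namespace)
gems_count_matrix <- function(gems, namespace) {
  f <- gems$functions[gems$functions$namespace == namespace, ]
  fids <- sort(unique(f$function_id))
  m <- matrix(0, nrow(gems$meta), length(fids),
              dimnames = list(gems$meta$genome_id, fids))
  for (i in seq_len(nrow(f)))
    m[f$genome_id[i], f$function_id[i]] <- f$count[i]
  m
}

rand_matrix <- function(nr, nc, seed, rpref = "f", cpref = "s",
                        fun = function(n) round(stats::runif(n, 0, 10), 3)) {
  with_seed(seed,
    matrix(fun(nr * nc), nr, nc,
           dimnames = list(paste0(rpref, seq_len(nr)),
                           paste0(cpref, seq_len(nc)))))
}

# -- oracles -------------------------------------------------------------

# pan aggregation by explicit per-genus loop-and-sum
oracle_pan <- function(gems, namespace, aggregation = "mean",
                       weights = NULL) {
  cm <- gems_count_matrix(gems, namespace)
  if (!is.null(weights)) cm <- cm * weights[rownames(cm)]
  genera <- gems$meta$genus
  out <- matrix(0, length(unique(genera)), ncol(cm),
                dimnames = list(sort(unique(genera)), colnames(cm)))
  for (g in rownames(out)) {
    members <- gems$meta$genome_id[genera == g]
    for (f in colnames(out)) {
      s <- 0
      for (gm in members) s <- s + cm[gm, f]
      out[g, f] <- if (aggregation == "mean") s / length(members) else s
    }
  }
  out
}

# core as an explicit set intersection of per-genome presence sets
oracle_core <- function(gems, namespace) {
  cm <- gems_count_matrix(gems, namespace)
  genera <- gems$meta$genus
  out <- matrix(0, length(unique(genera)), ncol(cm),
                dimnames = list(sort(unique(genera)), colnames(cm)))
  for (g in rownames(out)) {
    members <- gems$meta$genome_id[genera == g]
    common <- colnames(cm)
    for (gm in members)
      common <- intersect(common, colnames(cm)[cm[gm, ] > 0])
    out[g, common] <- 1
  }
  out
}

# function prediction by triple loop over (function, sample, taxon)
oracle_predict <- function(taxa, net_matrix) {
  shared <- intersect(rownames(taxa), rownames(net_matrix))
  out <- matrix(0, ncol(net_matrix), ncol(taxa),
                dimnames = list(colnames(net_matrix), colnames(taxa)))
  for (f in colnames(net_matrix))
    for (s in colnames(taxa))
      for (tg in shared)
        out[f, s] <- out[f, s] + taxa[tg, s] * net_matrix[tg, f]
  out
}

# Spearman as rank-then-Pearson from the textbook formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# minimum set cover size by enumeration of all 2^n route subsets
# (bit masks over the observed ECs keep full enumeration cheap)
oracle_min_cover_size <- function(observed, catalog) {
  observed <- intersect(observed, unique(unlist(catalog)))
  if (!length(observed)) return(0L)
  stopifnot(length(observed) <= 30, length(catalog) <= 16)
  route_mask <- vapply(catalog, function(s)
    as.integer(sum(2^(match(intersect(s, observed), observed) - 1))),
    integer(1))
  target <- as.integer(2^length(observed) - 1)
  best <- Inf
  n <- length(catalog)
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, as.integer(2^(seq_len(n) - 1))) > 0L)
    if (length(sel) >= best) next
    cov <- Reduce(bitwOr, route_mask[sel], 0L)
    if (cov == target) best <- length(sel)
  }
  as.integer(best)
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))  # enumeration assumes no ties
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1, simplify = FALSE)
  ws <- vapply(combos, function(i) sum(r[i]), numeric(1))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Welch two-sample t statistic and p from the closed-form formulas
oracle_welch <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# tiny deterministic prediction fixture shared by several tests
toy_network <- function(m, mode = "pan", rank = "genus", namespace = "KO",
                        gpt = NULL) {
  gpt <- gpt %||% stats::setNames(rep(1L, nrow(m)), rownames(m))
  metgems:::new_network(m, mode = mode, rank = rank, namespace = namespace,
                        genomes_per_taxon = gpt, aggregation = "mean")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
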