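# Synthetic-data generator with known ground truth. The stated world: a
# community of n_taxa genera, each with a fixed core function set shared by
# all its genomes plus per-genome accessory functions; taxon abundances are
# Dirichlet-distributed per sample, reads are split across each taxon's
# ASVs and sampled multinomially at a fixed depth; a reference profile is
# the true function mixture under multiplicative log-normal noise.

#' Parameters of the synthetic world
#'
#' @param n_taxa number of genera.
#' @param genomes_per_taxon genomes per genus.
#' @param n_functions size of the KO pool (the EC pool is half as large).
#' @param core_fraction fraction of the pool forming each taxon's core set.
#' @param accessory_presence_prob per-genome presence probability of
#'   non-core functions.
#' @param copy_number_range integer range of per-genome 16S copy numbers.
#' @param n_asvs_per_taxon ASVs per genus.
#' @param n_samples number of community samples.
#' @param sequencing_depth reads per sample (multinomial total).
#' @param abundance_dirichlet_alpha Dirichlet concentration of taxon
#'   proportions.
#' @param reference_noise_sd SD of the log-normal noise on the reference
#'   profile.
#' @param seed root seed; all generators derive their streams from it.
#' @return validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_taxa = 10, genomes_per_taxon = 3,
                       n_functions = 200, core_fraction = 0.3,
                       accessory_presence_prob = 0.3,
                       copy_number_range = c(1L, 7L),
                       n_asvs_per_taxon = 3, n_samples = 10,
                       sequencing_depth = 50000,
                       abundance_dirichlet_alpha = 1,
                       reference_noise_sd = 0.5, seed = 42) {
  spec <- list(n_taxa = n_taxa, genomes_per_taxon = genomes_per_taxon,
               n_functions = n_functions, core_fraction = core_fraction,
               accessory_presence_prob = accessory_presence_prob,
               copy_number_range = as.integer(copy_number_range),
               n_asvs_per_taxon = n_asvs_per_taxon, n_samples = n_samples,
               sequencing_depth = sequencing_depth,
               abundance_dirichlet_alpha = abundance_dirichlet_alpha,
               reference_noise_sd = reference_noise_sd, seed = seed)
  counts <- c("n_taxa", "genomes_per_taxon", "n_functions",
              "n_asvs_per_taxon", "n_samples", "sequencing_depth")
  for (p in counts)
    if (spec[[p]] < 1) stop(p, " must be positive", call. = FALSE)
  for (p in c("core_fraction", "accessory_presence_prob"))
    if (spec[[p]] < 0 || spec[[p]] > 1)
      stop(p, " must lie in [0, 1]", call. = FALSE)
  if (spec$reference_noise_sd < 0)
    stop("reference_noise_sd must be >= 0", call. = FALSE)
  if (length(spec$copy_number_range) != 2 ||
      spec$copy_number_range[1] < 1 ||
      diff(spec$copy_number_range) < 0)
    stop("invalid copy_number_range", call. = FALSE)
  structure(spec, class = "synth_spec")
}

synth_ec_ids <- function(n) {
  i <- seq_len(n) - 1L
  sprintf("%d.%d.%d.%d", 1L + i %% 6L, 1L + (i %/% 6L) %% 8L,
          1L + (i %/% 48L) %% 8L, 1L + i %/% 384L)
}

#' Generate a genome collection with per-taxon core/accessory structure
#'
#' Each genus receives a core function set (size `core_fraction` x pool
#' size, drawn per genus) present in all of its genomes; every other pool
#' function is present in a genome independently with
#' `accessory_presence_prob`. Present functions get small integer counts;
#' 16S copy numbers are uniform integers in `copy_number_range`.
#' Per-genome taxonomic weights (gamma-distributed) are generated alongside.
#'
#' @param spec a [synth_spec()].
#' @return list with `gems` (a [gem_collection()]), `weights` (named
#'   numeric), `ko_pool`, `ec_pool`.
#' @export
make_genomes <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ko_pool <- sprintf("K%05d", seq_len(spec$n_functions))
  ec_pool <- synth_ec_ids(max(4L, ceiling(spec$n_functions / 2)))
  genera <- sprintf("g_%02d", seq_len(spec$n_taxa))
  classes <- sprintf("c_%d", 1L + (seq_len(spec$n_taxa) - 1L) %% 3L)
  with_seed(spec$seed, {
    meta <- list()
    fun <- list()
    for (t in seq_len(spec$n_taxa)) {
      core <- list(
        KO = sample(ko_pool, round(spec$core_fraction * length(ko_pool))),
        EC = sample(ec_pool, round(spec$core_fraction * length(ec_pool))))
      pools <- list(KO = ko_pool, EC = ec_pool)
      for (k in seq_len(spec$genomes_per_taxon)) {
        gid <- sprintf("%s_gm%d", genera[t], k)
        meta[[gid]] <- data.frame(
          genome_id = gid, class = classes[t], genus = genera[t],
          species = sprintf("%s sp%d", genera[t], k),
          copy_number_16s = sample(seq(spec$copy_number_range[1],
                                       spec$copy_number_range[2]), 1),
          stringsAsFactors = FALSE)
        for (ns in c("KO", "EC")) {
          acc_pool <- setdiff(pools[[ns]], core[[ns]])
          acc <- acc_pool[stats::runif(length(acc_pool)) <
                            spec$accessory_presence_prob]
          ids <- c(core[[ns]], acc)
          if (!length(ids)) next
          fun[[paste(gid, ns)]] <- data.frame(
            genome_id = gid, function_id = ids, namespace = ns,
            count = sample(1:3, length(ids), replace = TRUE,
                           prob = c(0.7, 0.2, 0.1)),
            stringsAsFactors = FALSE)
        }
      }
    }
    gems <- gem_collection(do.call(rbind, meta), do.call(rbind, fun))
    weights <- stats::setNames(
      round(stats::rgamma(nrow(gems$meta), shape = 2, rate = 2), 4) + 1e-3,
      gems$meta$genome_id)
    list(gems = gems, weights = weights,
         ko_pool = ko_pool, ec_pool = ec_pool)
  })
}

#' Generate a community: ASV table, taxonomy and ground truth
#'
#' Per sample, taxon proportions are Dirichlet(`alpha`); each taxon's reads
#' are split across its ASVs by a fixed Dirichlet(1) weight vector and the
#' sample's counts are one multinomial draw at `sequencing_depth`. The ASV
#' taxonomy map is exact (noise-free). The ground-truth function profile is
#' the exact pan-mean mixture of genome profiles at the *realized* taxon
#' counts, i.e. what an ideal predictor would reconstruct from the
#' sequenced table.
#'
#' @param spec a [synth_spec()].
#' @param genomes output of [make_genomes()] under the same spec.
#' @return list with `asv` (ASV x sample counts), `taxonomy` (named genus
#'   labels), `truth` (list: `taxon_props` intended proportions,
#'   `taxon_counts` realized counts, `function_profile` list of KO and EC
#'   matrices, `spec`).
#' @export
make_community <- function(spec, genomes) {
  stopifnot(inherits(spec, "synth_spec"))
  genera <- sprintf("g_%02d", seq_len(spec$n_taxa))
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  nets <- list(KO = build_pan(genomes$gems, "genus", "KO", "mean"),
               EC = build_pan(genomes$gems, "genus", "EC", "mean"))
  with_seed(spec$seed + 1L, {
    props <- matrix(vapply(samples, function(s) {
      x <- stats::rgamma(spec$n_taxa, shape = spec$abundance_dirichlet_alpha)
      x / sum(x)
    }, numeric(spec$n_taxa)),
    nrow = spec$n_taxa, dimnames = list(genera, samples))
    asv_w <- matrix(vapply(genera, function(g) {
      x <- stats::rgamma(spec$n_asvs_per_taxon, shape = 1)
      x / sum(x)
    }, numeric(spec$n_asvs_per_taxon)),
    nrow = spec$n_asvs_per_taxon, ncol = spec$n_taxa)
    asv_ids <- sprintf("asv_%04d", seq_len(spec$n_taxa *
                                             spec$n_asvs_per_taxon))
    taxonomy <- stats::setNames(rep(genera, each = spec$n_asvs_per_taxon),
                                asv_ids)
    asv_probs <- matrix(0, length(asv_ids), length(samples),
                        dimnames = list(asv_ids, samples))
    # asv_w is n_asvs x n_taxa (one column per genus); the taxon-major
    # column flattening matches the asv_ids ordering above
    for (j in seq_along(samples))
      asv_probs[, j] <- as.numeric(sweep(asv_w, 2, props[, j], "*"))
    asv <- matrix(vapply(seq_along(samples), function(j)
      as.numeric(stats::rmultinom(1, spec$sequencing_depth, asv_probs[, j])),
      numeric(length(asv_ids))),
      nrow = length(asv_ids), dimnames = list(asv_ids, samples))

    taxon_counts <- rowsum(asv, taxonomy[asv_ids])
    taxon_counts <- taxon_counts[genera, , drop = FALSE]
    profile <- lapply(nets, function(net)
      t(net$matrix[genera, , drop = FALSE]) %*% taxon_counts)
    list(asv = asv, taxonomy = taxonomy,
         truth = list(taxon_props = props, taxon_counts = taxon_counts,
                      function_profile = profile, spec = spec))
  })
}

#' Reference function profile: ground truth under log-normal noise
#'
#' Multiplies the true function profile elementwise by
#' `exp(N(0, noise_sd^2))` and renormalizes every sample column to sum 1.
#' With `noise_sd = 0` the exact (renormalized) truth is returned.
#'
#' @param truth `truth` element of [make_community()] output.
#' @param noise_sd log-scale noise SD; defaults to the spec's value.
#' @param namespace `"KO"` or `"EC"`.
#' @param seed defaults to `spec$seed + 2`.
#' @return function x sample matrix, columns summing to 1.
#' @export
make_reference_profile <- function(truth, noise_sd = NULL,
                                   namespace = c("KO", "EC"), seed = NULL) {
  namespace <- match.arg(namespace)
  noise_sd <- noise_sd %||% truth$spec$reference_noise_sd
  seed <- seed %||% (truth$spec$seed + 2L)
  m <- truth$function_profile[[namespace]]
  if (noise_sd > 0)
    m <- m * with_seed(seed, matrix(exp(stats::rnorm(length(m),
                                                     sd = noise_sd)),
                                    nrow(m), ncol(m)))
  cs <- colSums(m)
  cs[cs == 0] <- 1
  out <- sweep(m, 2, cs, "/")
  attr(out, "namespace") <- namespace
  attr(out, "scale") <- "relative"
  out
}

#' Generate a route catalog with a planted unique minimum cover
#'
#' Builds `planted_size` disjoint routes whose union is the designated
#' observed EC set, plus decoy routes, and verifies by exhaustive
#' enumeration that the planted subset is the unique minimum cover of the
#' observed set. Retries with fresh draws until the verification passes.
#'
#' @param n_routes total routes in the catalog (kept small enough for
#'   brute-force verification).
#' @param ec_pool character vector of EC numbers to draw from.
#' @param size_range integer range of route sizes.
#' @param seed integer seed.
#' @param planted_size size of the planted cover.
#' @return list with `catalog` (named list), `observed` (EC set whose
#'   unique minimum cover is planted) and `planted` (sorted route ids).
#' @export
make_route_catalog <- function(n_routes = 8, ec_pool, size_range = c(2, 4),
                               seed = 1, planted_size = 2) {
  stopifnot(n_routes >= planted_size, n_routes <= 16,
            length(ec_pool) >= planted_size * size_range[2])
  with_seed(seed, {
    for (attempt in 1:200) {
      sizes <- sample(seq(size_range[1], size_range[2]), planted_size,
                      replace = TRUE)
      picked <- sample(ec_pool, sum(sizes))
      planted_sets <- split(picked, rep(seq_len(planted_size), times = sizes))
      observed <- sort(picked)
      decoys <- lapply(seq_len(n_routes - planted_size), function(i) {
        sz <- sample(seq(size_range[1], size_range[2]), 1)
        sample(ec_pool, sz)
      })
      sets <- c(unname(planted_sets), decoys)
      ids <- sprintf("R%02d", seq_len(n_routes))
      perm <- sample(n_routes)  # catalog[[i]] <- sets[[perm[i]]]
      catalog <- stats::setNames(sets[perm], ids)
      planted_ids <- sort(ids[perm %in% seq_len(planted_size)])
      if (unique_minimum_cover(observed, catalog, planted_ids))
        return(list(catalog = catalog, observed = observed,
                    planted = planted_ids))
    }
    stop("failed to plant a unique minimum cover; enlarge ec_pool",
         call. = FALSE)
  })
}

# brute force: TRUE iff `planted` is the one and only cover of `observed`
# of size <= length(planted)
unique_minimum_cover <- function(observed, catalog, planted) {
  ids <- names(catalog)
  k <- length(planted)
  hits <- list()
  for (size in seq_len(k)) {
    for (cb in utils::combn(ids, size, simplify = FALSE)) {
      if (all(observed %in% unlist(catalog[cb], use.names = FALSE)))
        hits[[length(hits) + 1L]] <- sort(cb)
    }
  }
  length(hits) == 1L && identical(hits[[1]], planted)
}
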