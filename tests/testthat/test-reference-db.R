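# Taxon-by-function reference network construction (pan / core / weighted)

write_long_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "genome_id\tclass\tgenus\tspecies\tcopy_number_16s\tfunction_id\tcount"
  writeLines(c(header, rows), path)
  path
}

test_that("load_gem_metadata parses the long dialect and flags bad input", {
  path <- write_long_tsv(c(
    "G1\tc1\tgA\tgA sp1\t4\tK00001\t2",
    "G1\tc1\tgA\tgA sp1\t4\tK00002\t1",
    "G2\tc1\tgB\tgB sp1\t2\tK00001\t3"))
  gems <- load_gem_metadata(path)
  expect_equal(nrow(gems$meta), 2)
  f1 <- gems$functions[gems$functions$genome_id == "G1", ]
  expect_setequal(f1$function_id, c("K00001", "K00002"))
  expect_equal(f1$count[f1$function_id == "K00001"], 2)
  expect_equal(gems$functions$count[gems$functions$genome_id == "G2"], 3)

  # empty function cell -> warning, genome still present with no counts
  p2 <- write_long_tsv(c("G1\tc1\tgA\tgA sp1\t4\tK00001\t2",
                         "G2\tc1\tgB\tgB sp1\t2\t\t0"))
  expect_warning(g2 <- load_gem_metadata(p2), "empty function cell")
  expect_true("G2" %in% g2$meta$genome_id)
  expect_false("G2" %in% g2$functions$genome_id)

  # malformed function token -> warning naming the line
  p3 <- write_long_tsv(c("G1\tc1\tgA\tgA sp1\t4\tK1\t2",
                         "G1\tc1\tgA\tgA sp1\t4\tK00002\t1"))
  expect_warning(g3 <- load_gem_metadata(p3), "malformed function id")
  expect_equal(g3$functions$function_id, "K00002")

  # EC: prefix stripped, partial EC numbers kept
  p4 <- write_long_tsv(c("G1\tc1\tgA\tgA sp1\t4\tEC: 1.2.3.4\t1",
                         "G1\tc1\tgA\tgA sp1\t4\t1.2.3.-\t1"))
  g4 <- load_gem_metadata(p4)
  expect_setequal(g4$functions$function_id, c("1.2.3.4", "1.2.3.-"))
  expect_true(all(g4$functions$namespace == "EC"))

  # missing mandatory column named in the error
  p5 <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tclass\tspecies", "G1\tc1\ts1"), p5)
  expect_error(load_gem_metadata(p5), "genus")
})

test_that("load_gem_metadata parses the wide dialect and rejects duplicates", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tclass\tgenus\tspecies\tK00001\tK00002",
               "G1\tc1\tgA\ts1\t2\t0",
               "G2\tc1\tgA\ts2\t1\t3"), p)
  gems <- load_gem_metadata(p)
  expect_equal(sum(gems$functions$genome_id == "G1"), 1)  # zero cells dropped
  expect_equal(gems$functions$count[gems$functions$genome_id == "G2" &
                                    gems$functions$function_id == "K00002"], 3)
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tclass\tgenus\tspecies\tK00001",
               "G1\tc1\tgA\ts1\t2",
               "G1\tc1\tgA\ts1\t1"), p2)
  expect_error(load_gem_metadata(p2), "duplicate genome_id")
})

two_genome_gems <- function(counts2 = c(K00001 = 0)) {
  meta <- data.frame(genome_id = c("G1", "G2"), class = "c1", genus = "gA",
                     species = c("s1", "s2"), stringsAsFactors = FALSE)
  fun <- rbind(
    data.frame(genome_id = "G1", function_id = "K00001", namespace = "KO",
               count = 2, stringsAsFactors = FALSE),
    data.frame(genome_id = "G2", function_id = names(counts2),
               namespace = "KO", count = unname(counts2),
               stringsAsFactors = FALSE))
  gem_collection(meta, fun)
}

test_that("build_pan matches the by-hand examples and the loop oracle", {
  gems <- two_genome_gems(c(K00001 = 0))
  pan_mean <- build_pan(gems, "genus", "KO", "mean")
  pan_sum <- build_pan(gems, "genus", "KO", "sum")
  expect_equal(pan_mean$matrix["gA", "K00001"], 1.0)
  expect_equal(pan_sum$matrix["gA", "K00001"], 2.0)
  expect_equal(pan_mean$mode, "pan")

  # single-genome taxon: entries equal the genome's counts either way
  solo <- gem_collection(
    data.frame(genome_id = "G1", class = "c1", genus = "gA", species = "s",
               stringsAsFactors = FALSE),
    data.frame(genome_id = "G1", function_id = c("K00001", "K00002"),
               namespace = "KO", count = c(3, 1), stringsAsFactors = FALSE))
  expect_equal(build_pan(solo, "genus", "KO", "mean")$matrix["gA", ],
               build_pan(solo, "genus", "KO", "sum")$matrix["gA", ])

  for (seed in 1:5) {
    gems <- random_gems(n_genomes = 10, n_taxa = 3, n_functions = 25,
                        seed = seed)
    for (agg in c("mean", "sum")) {
      got <- build_pan(gems, "genus", "KO", agg)$matrix
      want <- oracle_pan(gems, "KO", agg)
      expect_equal(got[rownames(want), colnames(want), drop = FALSE], want,
                   tolerance = 1e-12)
    }
  }
})

test_that("build_core is the member-presence intersection", {
  meta <- data.frame(genome_id = c("G1", "G2"), class = "c1", genus = "gA",
                     species = c("s1", "s2"), stringsAsFactors = FALSE)
  fun <- data.frame(genome_id = c("G1", "G1", "G2"),
                    function_id = c("K00001", "K00002", "K00001"),
                    namespace = "KO", count = c(2, 1, 1),
                    stringsAsFactors = FALSE)
  core <- build_core(gem_collection(meta, fun), "genus", "KO")
  expect_equal(core$matrix["gA", "K00001"], 1)
  expect_equal(core$matrix["gA", "K00002"], 0)
  expect_true(all(core$matrix %in% c(0, 1)))

  for (seed in 1:5) {
    gems <- random_gems(n_genomes = 5, n_taxa = 1, n_functions = 20,
                        seed = seed)
    got <- build_core(gems, "genus", "KO")$matrix
    want <- oracle_core(gems, "KO")
    expect_equal(got[rownames(want), colnames(want), drop = FALSE], want)
  }
})

test_that("core is invariant to positive count rescaling and genome order", {
  gems <- random_gems(seed = 7)
  scaled <- gems
  scaled$functions$count <- scaled$functions$count * 0.013
  expect_equal(build_core(scaled, "genus", "KO")$matrix,
               build_core(gems, "genus", "KO")$matrix)

  perm <- with_seed(3, sample(nrow(gems$meta)))
  shuffled <- gem_collection(gems$meta[perm, ], gems$functions)
  for (build in list(build_pan, build_core)) {
    a <- build(gems, "genus", "KO")$matrix
    b <- build(shuffled, "genus", "KO")$matrix
    expect_equal(b[rownames(a), colnames(a), drop = FALSE], a)
  }
})

test_that("genomes without the requested rank are excluded with a warning", {
  gems <- random_gems(seed = 2)
  gems$meta$genus[1] <- NA
  expect_warning(net <- build_pan(gems, "genus", "KO"), "excluded")
  expect_false(gems$meta$genome_id[1] %in% names(net$genomes_per_taxon))
  gems$meta$genus[] <- NA
  expect_error(suppressWarnings(build_pan(gems, "genus", "KO")),
               "no genome")
})

test_that("apply_weights scales counts; weight 1 is the identity", {
  gems <- random_gems(seed = 4)
  ones <- setNames(rep(1, nrow(gems$meta)), gems$meta$genome_id)
  expect_equal(apply_weights(gems, ones)$functions$count,
               gems$functions$count)

  w <- setNames(rep(1, nrow(gems$meta)), gems$meta$genome_id)
  w["G001"] <- 0.5
  g1 <- gems$functions$genome_id == "G001"
  weighted <- apply_weights(gems, w)
  expect_equal(weighted$functions$count[g1],
               gems$functions$count[g1] * 0.5)
  expect_error(apply_weights(gems, setNames(-1, "G001")), "negative")
  expect_warning(apply_weights(gems, c(G001 = 2)), "without a weight")

  # weighted pan equals the weighted loop-and-sum oracle
  for (seed in 1:3) {
    gems <- random_gems(seed = seed)
    w <- with_seed(seed + 100,
                   setNames(round(runif(nrow(gems$meta), 0.1, 2), 3),
                            gems$meta$genome_id))
    got <- build_pan(apply_weights(gems, w), "genus", "KO")$matrix
    want <- oracle_pan(gems, "KO", "mean", weights = w)
    expect_equal(got[rownames(want), colnames(want), drop = FALSE], want,
                 tolerance = 1e-12)
  }
})

test_that("core_weight equals core computed from unweighted presence", {
  gems <- random_gems(seed = 9)
  w <- with_seed(10, setNames(runif(nrow(gems$meta), 0, 2),
                              gems$meta$genome_id))
  w[1] <- 0  # zero weight must not delete presence
  cw <- build_core(apply_weights(gems, w), "genus", "KO")
  core <- build_core(gems, "genus", "KO")
  expect_equal(cw$matrix, core$matrix)
  expect_equal(cw$mode, "core_weight")
})

test_that("coverage counts functions present in at least one taxon", {
  gems <- random_gems(seed = 5)
  net <- build_pan(gems, "genus", "KO")
  # columnwise any-nonzero scan oracle
  scan <- 0L
  for (j in seq_len(ncol(net$matrix)))
    if (any(net$matrix[, j] > 0)) scan <- scan + 1L
  expect_identical(coverage(net), scan)

  empty <- gem_collection(gems$meta,
                          gems$functions[0, ])
  expect_identical(coverage(build_pan(empty, "genus", "KO")), 0L)

  # core never covers more than pan, with or without weights
  for (seed in 1:10) {
    gems <- random_gems(n_genomes = 8, n_taxa = 2, seed = seed)
    expect_lte(coverage(build_core(gems, "genus", "KO")),
               coverage(build_pan(gems, "genus", "KO")))
  }
})

test_that("core presence implies pan(mean) >= 1 on integer counts", {
  gems <- random_gems(seed = 12)
  pan <- build_pan(gems, "genus", "KO", "mean")$matrix
  core <- build_core(gems, "genus", "KO")$matrix
  idx <- core == 1
  expect_true(all(pan[rownames(core), colnames(core), drop = FALSE][idx] >= 1))
})

test_that("function_count_correlation reports per-group stats and PCC", {
  # genomes whose EC count is exactly half their KO count -> PCC 1
  meta <- data.frame(genome_id = sprintf("G%d", 1:4), class = "c1",
                     genus = "g", species = sprintf("s%d", 1:4),
                     stringsAsFactors = FALSE)
  fun <- do.call(rbind, lapply(1:4, function(i) {
    ko <- sprintf("K%05d", seq_len(2 * i))
    ec <- sprintf("%d.1.1.%d", i, seq_len(i))
    rbind(data.frame(genome_id = meta$genome_id[i], function_id = ko,
                     namespace = "KO", count = 1, stringsAsFactors = FALSE),
          data.frame(genome_id = meta$genome_id[i], function_id = ec,
                     namespace = "EC", count = 1, stringsAsFactors = FALSE))
  }))
  res <- function_count_correlation(gem_collection(meta, fun))
  expect_equal(res$pcc, 1.0)
  expect_equal(res$summary$ko_mean, mean(c(2, 4, 6, 8)))

  # two genomes: |PCC| = 1 or undefined
  two <- gem_collection(meta[1:2, ], fun[fun$genome_id %in% c("G1", "G2"), ])
  r2 <- function_count_correlation(two)
  expect_true(!r2$pcc_defined || abs(abs(r2$pcc) - 1) < 1e-12)

  # zero-variance vector -> explicitly undefined, not silently NaN
  same <- gem_collection(meta[1:2, ], do.call(rbind, lapply(1:2, function(i)
    data.frame(genome_id = meta$genome_id[i],
               function_id = c("K00001", "1.1.1.1"),
               namespace = c("KO", "EC"), count = 1,
               stringsAsFactors = FALSE))))
  rs <- function_count_correlation(same)
  expect_false(rs$pcc_defined)
  expect_true(is.na(rs$pcc))

  # 50 simulated genomes against the direct-formula oracle
  gems <- random_gems(n_genomes = 50, n_taxa = 5, n_functions = 40,
                      seed = 21)
  ec <- random_gems(n_genomes = 50, n_taxa = 5, n_functions = 30,
                    namespace = "EC", seed = 22)
  both <- gem_collection(gems$meta, rbind(gems$functions, ec$functions))
  res <- function_count_correlation(both)
  # textbook formula, written out
  x <- res$ko_per_genome; y <- res$ec_per_genome
  pcc <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pcc, pcc, tolerance = 1e-12)
})
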