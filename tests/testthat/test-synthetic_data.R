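or_spec <- function(seed = 1L, n_copies = 3L) {
  genome_sim_spec(seed = seed, n_contigs = 2L, contig_length_bp = 40000L,
                  genes = gene_family_spec("or", n_copies = n_copies,
                                           n_exons = 3L,
                                           exon_len_aa = c(90L, 120L)))
}

test_that("generators are pure functions of spec and seed", {
  s1 <- simulate_genome_with_families(or_spec(seed = 5))
  s2 <- simulate_genome_with_families(or_spec(seed = 5))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(
    s1$genome, simulate_genome_with_families(or_spec(seed = 6))$genome))

  expect_identical(emit_truth_hsps(s1$truth, seed = 9),
                   emit_truth_hsps(s1$truth, seed = 9))

  t1 <- simulate_expansion_tree(c("a", "b"), background_leaves = 10, seed = 3)
  t2 <- simulate_expansion_tree(c("a", "b"), background_leaves = 10, seed = 3)
  expect_identical(t1$newick, t2$newick)

  r1 <- simulate_rad_matrix(rad_sim_spec(seed = 4, n_loci = 200))
  r2 <- simulate_rad_matrix(rad_sim_spec(seed = 4, n_loci = 200))
  expect_identical(r1$matrix$counts, r2$matrix$counts)
})

test_that("implant truth is self-consistent with extraction and translation", {
  sim <- simulate_genome_with_families(or_spec(seed = 11))
  expect_length(sim$truth, 3L)
  for (i in seq_along(sim$truth)) {
    m <- extract_and_translate(sim$models[[i]], sim$genome)
    expect_identical(m$protein, sim$truth[[i]]$protein)
    expect_length(m$flags, 0L)
  }
  # truth GFF3 carries one exon line per implanted exon
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$models, gff)
  gr <- rtracklayer::import(gff)
  expect_equal(sum(gr$type == "exon"), 9L)

  empty <- simulate_genome_with_families(
    genome_sim_spec(seed = 1, n_contigs = 1, contig_length_bp = 5000))
  expect_length(empty$truth, 0L)
})

test_that("infeasible placement fails with advice rather than overlapping genes", {
  tight <- genome_sim_spec(seed = 2, n_contigs = 1, contig_length_bp = 3000,
                           genes = gene_family_spec("or", n_copies = 4))
  expect_error(simulate_genome_with_families(tight), "contig_length_bp")
})

run_pipeline <- function(sim, hsps, cfg = chaining_config()) {
  kept <- select_best_per_locus(hsps, cfg)
  models <- chain_hsps(kept, cfg)
  models <- lapply(models, extract_and_translate, genome = sim$genome)
  filter_models(models, cfg)
}

test_that("noise-free hit tables chain back to the exact implanted genes", {
  sim <- simulate_genome_with_families(or_spec(seed = 13, n_copies = 5))
  models <- run_pipeline(sim, emit_truth_hsps(sim$truth, seed = 1))
  expect_length(models, 5L)
  key <- function(ex) paste(sort(paste(ex$start, ex$end)), collapse = ";")
  expect_setequal(vapply(models, function(m) key(m$exons), character(1)),
                  vapply(sim$truth, function(g) key(g$exons), character(1)))
})

test_that("spurious hits below the e-value gate never change recovery", {
  sim <- simulate_genome_with_families(or_spec(seed = 17, n_copies = 4))
  clean <- run_pipeline(sim, emit_truth_hsps(sim$truth, seed = 2))
  noisy <- run_pipeline(sim, emit_truth_hsps(sim$truth, spurious_rate = 3,
                                             seed = 2))
  expect_equal(length(noisy), length(clean))
  expect_setequal(vapply(noisy, `[[`, character(1), "protein"),
                  vapply(sim$truth, `[[`, character(1), "protein"))
})

test_that("split HSPs stay chainable: span and protein match truth", {
  sim <- simulate_genome_with_families(or_spec(seed = 19, n_copies = 4))
  models <- run_pipeline(sim, emit_truth_hsps(sim$truth, split_prob = 1,
                                              seed = 3))
  expect_length(models, 4L)
  span <- function(ex) c(min(ex$start), max(ex$end))
  expect_setequal(vapply(models, function(m) paste(span(m$exons), collapse = "-"),
                         character(1)),
                  vapply(sim$truth, function(g) paste(span(g$exons), collapse = "-"),
                         character(1)))
  expect_setequal(vapply(models, `[[`, character(1), "protein"),
                  vapply(sim$truth, `[[`, character(1), "protein"))
})

test_that("introns above the chaining bound split genes (negative control)", {
  spec <- genome_sim_spec(seed = 23, n_contigs = 1, contig_length_bp = 60000,
                          genes = gene_family_spec(
                            "big", n_copies = 1, n_exons = 2,
                            exon_len_aa = c(150L, 160L),
                            intron_len_bp = c(11000L, 12000L)))
  sim <- simulate_genome_with_families(spec)
  kept <- select_best_per_locus(emit_truth_hsps(sim$truth, seed = 4))
  models <- chain_hsps(kept)
  expect_length(models, 2L)  # the >10 kb intron prevents joining
})

test_that("planted expansions are recovered; sub-threshold plants are not", {
  sim <- simulate_expansion_tree(
    c("goby", "stickleback", "tilapia", "zebrafish"),
    plant = list(list(species = "goby", clade_size = 7)),
    background_leaves = 24, seed = 29)
  cl <- find_maximal_monospecific_clades(sim$tree, sim$map)
  expect_equal(sum(cl$size), length(sim$tree$tip.label))
  calls <- call_expansions(cl, 5)
  holding <- vapply(calls$leaves,
                    function(l) all(sim$truth[[1]]$leaves %in% l), logical(1))
  expect_equal(sum(holding), 1L)
  expect_gte(calls$size[holding], 7L)

  sub <- simulate_expansion_tree(
    c("goby", "stickleback", "tilapia", "zebrafish"),
    plant = list(list(species = "goby", clade_size = 4)),
    background_leaves = 24, seed = 31)
  subcalls <- call_expansions(
    find_maximal_monospecific_clades(sub$tree, sub$map), 5)
  contains_plant <- vapply(subcalls$leaves,
                           function(l) any(sub$truth[[1]]$leaves %in% l),
                           logical(1))
  expect_false(any(contains_plant))
})

test_that("background clades in unplanted trees match the brute-force scan", {
  sim <- simulate_expansion_tree(c("a", "b", "c"), plant = list(),
                                 background_leaves = 30, seed = 37)
  cl <- find_maximal_monospecific_clades(sim$tree, sim$map)
  expect_identical(clade_keys(cl), oracle_clade_keys(sim$tree, sim$map))
})

test_that("RAD simulation plants recoverable sex-linked loci", {
  sim <- simulate_rad_matrix(rad_sim_spec(seed = 41, n_loci = 1000,
                                          n_sex_linked = 3, dropout_rate = 0))
  calls <- call_sex_specific_loci(sim$matrix)
  expect_setequal(calls$locus, sim$truth)
  expect_true(all(calls$sex == "male"))

  none <- simulate_rad_matrix(rad_sim_spec(seed = 43, n_loci = 500,
                                           n_sex_linked = 0, dropout_rate = 0))
  expect_equal(interpret_sex_system(
    nrow(call_sex_specific_loci(none$matrix))), "none_detected")
})

test_that("background dropout never erodes planted sex-linked calls", {
  heavy <- simulate_rad_matrix(rad_sim_spec(seed = 47, n_loci = 300,
                                            n_sex_linked = 4,
                                            dropout_rate = 0.9,
                                            linked_sex = "female"))
  calls <- call_sex_specific_loci(heavy$matrix)
  expect_true(all(heavy$truth %in% calls$locus))
  expect_true(all(calls$sex[calls$locus %in% heavy$truth] == "female"))
})

test_that("counts matrices round-trip through the TSV writer", {
  sim <- simulate_rad_matrix(rad_sim_spec(seed = 53, n_loci = 50,
                                          n_males = 4, n_females = 4,
                                          n_sex_linked = 1, dropout_rate = 0))
  counts <- withr::local_tempfile(fileext = ".tsv")
  sexf <- withr::local_tempfile(fileext = ".tsv")
  write_counts_matrix(sim$matrix, counts, sexf)
  back <- read_counts_matrix(counts, sexf)
  expect_equal(back$counts, sim$matrix$counts)
  expect_equal(back$sex, sim$matrix$sex)
})
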