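cfg <- chaining_config()

test_that("select_best_per_locus keeps the best hit per overlapping locus", {
  h <- hsp_table(query_id = c("q1", "q2"), subject_id = "ctg1",
                 aln_len = c(100, 100), q_start = c(1, 1), q_end = c(100, 100),
                 s_start = c(101, 301), s_end = c(400, 600),
                 evalue = 1e-60, bit_score = c(200, 150))
  kept <- select_best_per_locus(h, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$bit_score, 200)

  disjoint <- hsp_table(query_id = c("q1", "q2"), subject_id = "ctg1",
                        aln_len = 100, q_start = 1, q_end = 100,
                        s_start = c(101, 2001), s_end = c(400, 2300),
                        evalue = 1e-60, bit_score = c(200, 150))
  expect_equal(nrow(select_best_per_locus(disjoint, cfg)), 2L)
})

test_that("no surviving pair overlaps, on random inputs (brute-force check)", {
  withr::local_seed(41)
  for (rep in 1:25) {
    kept <- select_best_per_locus(random_hsp_set(12), cfg)
    if (nrow(kept) < 2) next
    for (i in seq_len(nrow(kept) - 1)) {
      for (j in (i + 1):nrow(kept)) {
        same <- kept$contig[i] == kept$contig[j]
        overlap <- kept$start[i] < kept$end[j] & kept$start[j] < kept$end[i]
        expect_false(same && overlap)
      }
    }
  }
})

test_that("ties resolve by evalue then query id, over all input orders", {
  base <- data.frame(
    query_id = c("qa", "qb", "qc"), subject_id = "ctg1",
    pct_identity = 90, aln_len = 100, q_start = 1, q_end = 100,
    s_start = c(101, 151, 201), s_end = c(400, 450, 500),
    evalue = c(1e-60, 1e-70, 1e-70), bit_score = 200,
    stringsAsFactors = FALSE)
  for (perm in list(1:3, c(2, 1, 3), c(3, 1, 2), c(3, 2, 1), c(2, 3, 1), c(1, 3, 2))) {
    kept <- select_best_per_locus(as_hsp_table(base[perm, ]), cfg)
    # equal bit scores: lower evalue wins, then smaller query id -> qb
    expect_equal(kept$query_id, "qb")
  }
})

test_that("select_best_per_locus drops hits above the e-value gate and is idempotent", {
  withr::local_seed(43)
  h <- random_hsp_set(12)
  h$evalue[1] <- 1e-10  # above the 1e-50 gate
  kept <- select_best_per_locus(h, cfg)
  expect_false(any(kept$evalue > cfg$max_evalue))
  expect_equal(select_best_per_locus(kept, cfg), kept)
})

test_that("chain_hsps joins compatible consecutive hits into one model", {
  h <- hsp_table(query_id = "q1", subject_id = "ctg1", aln_len = c(100, 86),
                 q_start = c(1, 95), q_end = c(100, 180),
                 s_start = c(5001, 9001), s_end = c(5300, 9258),
                 evalue = 1e-60, bit_score = c(200, 180))
  models <- chain_hsps(h, cfg)
  expect_length(models, 1L)
  expect_equal(nrow(models[[1]]$exons), 2L)  # overlap 6 aa, gap 3700 bp

  # same pair but with a 10,001 bp gap: two single-exon models
  h2 <- h
  h2$s_start[2] <- 5300 + 10001 + 1
  h2$s_end[2] <- h2$s_start[2] + 257
  h2 <- as_hsp_table(h2[, !names(h2) %in% c("contig", "strand", "start", "end")])
  expect_length(chain_hsps(h2, cfg), 2L)
})

test_that("chaining respects the 15 aa overlap and 10 kb gap boundaries", {
  mk <- function(q2_start, s2_start) {
    hsp_table(query_id = "q1", subject_id = "ctg1", aln_len = 100,
              q_start = c(1, q2_start), q_end = c(100, q2_start + 99),
              s_start = c(5001, s2_start), s_end = c(5300, s2_start + 299),
              evalue = 1e-60, bit_score = 200)
  }
  n_models <- function(h) length(chain_hsps(h, cfg))
  # overlap = 100 - q2_start + 1
  expect_equal(n_models(mk(86, 9001)), 1L)   # overlap 15: joined
  expect_equal(n_models(mk(85, 9001)), 2L)   # overlap 16: not joined
  # gap = s2_start - 1 - 5300
  expect_equal(n_models(mk(101, 5300 + 9999 + 1)), 1L)   # gap 9999 < 10 kb
  expect_equal(n_models(mk(101, 5300 + 10000 + 1)), 2L)  # gap 10000: excluded
  expect_equal(n_models(mk(101, 5300 + 10001 + 1)), 2L)  # gap 10001
})

test_that("chaining matches the exhaustive run-partition oracle", {
  withr::local_seed(47)
  for (rep in 1:30) {
    kept <- select_best_per_locus(random_hsp_set(10), cfg)
    expect_identical(model_keys(chain_hsps(kept, cfg)),
                     oracle_chain_keys(kept, cfg))
  }
})

test_that("every deduplicated HSP lands in exactly one model", {
  withr::local_seed(53)
  for (rep in 1:20) {
    kept <- select_best_per_locus(random_hsp_set(12), cfg)
    models <- chain_hsps(kept, cfg)
    n_assigned <- sum(vapply(models, function(m) nrow(m$source_hsps),
                             integer(1)))
    expect_equal(n_assigned, nrow(kept))
    # and output invariants hold
    for (m in models) {
      expect_silent(validate_gene_model(m))
      src <- m$source_hsps
      if (nrow(src) > 1) {
        for (i in seq_len(nrow(src) - 1)) {
          overlap <- src$q_end[i] - src$q_start[i + 1] + 1
          expect_lte(overlap, cfg$max_query_overlap_aa)
          gap <- if (m$strand == "+") src$start[i + 1] - src$end[i]
                 else src$start[i] - src$end[i + 1]
          expect_lt(gap, cfg$max_genomic_gap_bp)
        }
      }
    }
  }
})

test_that("extract_and_translate produces the ORF protein on both strands", {
  genome <- seq_set("ctg1", paste0("AAAA", "ATGGCCTAA", "AAAA"), alphabet = "dna")
  m <- gene_model("g", "ctg1", "+", data.frame(start = 4L, end = 13L))
  m <- extract_and_translate(m, genome)
  expect_equal(m$protein, "MA")
  expect_equal(m$flags, character(0))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGGCCTAA")))
  genome2 <- seq_set("ctg1", paste0("AAAA", rc, "AAAA"), alphabet = "dna")
  m2 <- gene_model("g", "ctg1", "-", data.frame(start = 4L, end = 13L))
  m2 <- extract_and_translate(m2, genome2)
  expect_equal(m2$protein, "MA")

  genome3 <- seq_set("ctg1", "ATGTAAGCCGCC", alphabet = "dna")
  m3 <- gene_model("g", "ctg1", "+", data.frame(start = 0L, end = 12L))
  m3 <- extract_and_translate(m3, genome3)
  expect_true("internal_stop" %in% m3$flags)
})

test_that("extract_and_translate validates contigs and bounds", {
  genome <- seq_set("ctg1", "ATGGCCTAA", alphabet = "dna")
  m <- gene_model("g", "ctgX", "+", data.frame(start = 0L, end = 9L))
  expect_error(extract_and_translate(m, genome), "ctgX not found")
  m2 <- gene_model("g", "ctg1", "+", data.frame(start = 0L, end = 50L))
  expect_error(extract_and_translate(m2, genome), "beyond end of contig")
})

test_that("filter_models applies the 250 aa threshold inclusively", {
  mk <- function(len) {
    m <- gene_model("g", "ctg1", "+", data.frame(start = 0L, end = 3L))
    m$protein <- strrep("A", len)
    m
  }
  expect_length(filter_models(list(mk(249)), cfg), 0L)
  expect_length(filter_models(list(mk(250)), cfg), 1L)
  expect_length(filter_models(list(), cfg), 0L)
  expect_error(filter_models(list(gene_model("g", "c", "+",
                                             data.frame(start = 0L, end = 3L))),
                             cfg),
               "extract_and_translate")
})

test_that("filter_orthologs applies inclusive coverage/identity and strict e-value", {
  mk <- function(q_end, ident, ev) {
    hsp_table(query_id = "q", subject_id = "c", pct_identity = ident,
              aln_len = q_end, q_start = 1, q_end = q_end,
              s_start = 1, s_end = q_end * 3, evalue = ev, bit_score = 100)
  }
  lens <- c(q = 100)
  expect_equal(nrow(filter_orthologs(mk(70, 40.0, 1e-21), lens)), 1L)  # exactly at both bounds
  expect_equal(nrow(filter_orthologs(mk(69, 40.0, 1e-21), lens)), 0L)  # coverage 0.69
  expect_equal(nrow(filter_orthologs(mk(70, 39.9, 1e-21), lens)), 0L)  # identity below
  expect_equal(nrow(filter_orthologs(mk(70, 40.0, 1e-20), lens)), 0L)  # e-value not strict-below
  expect_error(filter_orthologs(mk(70, 40.0, 1e-21), c(other = 10)),
               "no query length for q")
})
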