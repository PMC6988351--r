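# Seeded simulators producing inputs with the statistical structure the
# analysis modules assume: genomes with implanted multi-exon gene-family
# members (plus matching translated-homology hit tables), phylogenies with
# planted same-species expansions, and RAD count matrices with optional
# sex-linked loci. Every generator is a pure function of its spec and seed,
# and each carries a machine-readable truth object so recovery is testable.

#' Specification of one implanted gene family
#'
#' @param family Family label.
#' @param n_copies Number of gene copies to implant.
#' @param n_exons Exons per gene.
#' @param exon_len_aa Length-2 integer range: coding length per exon, in
#'   amino acids (exons are codon-aligned so hit tables carry clean protein
#'   coordinates).
#' @param intron_len_bp Length-2 integer range for intron sizes; the default
#'   (200-2000 bp) sits safely below the 10 kb chaining bound. Pass a range
#'   above 10000 to simulate gene-splitting introns (the negative case).
#' @param strand `"random"`, `"+"` or `"-"`.
#' @return A list of class `gene_family_spec`.
#' @export
gene_family_spec <- function(family = "fam1", n_copies = 1L, n_exons = 3L,
                             exon_len_aa = c(60L, 120L),
                             intron_len_bp = c(200L, 2000L),
                             strand = "random") {
  stopifnot(n_copies >= 1, n_exons >= 1,
            length(exon_len_aa) == 2L, all(exon_len_aa > 0),
            length(intron_len_bp) == 2L, all(intron_len_bp > 0),
            strand %in% c("random", "+", "-"))
  structure(list(family = family, n_copies = as.integer(n_copies),
                 n_exons = as.integer(n_exons),
                 exon_len_aa = as.integer(exon_len_aa),
                 intron_len_bp = as.integer(intron_len_bp), strand = strand),
            class = "gene_family_spec")
}

#' Genome simulation spec
#'
#' @param seed Integer seed; the output is a pure function of the spec.
#' @param n_contigs,contig_length_bp Background contig layout.
#' @param gc_fraction Background GC content (default 0.416, a typical
#'   teleost genome-wide value).
#' @param genes List of [gene_family_spec()]s to implant.
#' @return A list of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(seed = 1L, n_contigs = 2L,
                            contig_length_bp = 100000L, gc_fraction = 0.416,
                            genes = list()) {
  stopifnot(n_contigs >= 1, contig_length_bp > 0,
            gc_fraction > 0, gc_fraction < 1)
  if (inherits(genes, "gene_family_spec")) genes <- list(genes)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length_bp = as.integer(contig_length_bp),
                 gc_fraction = gc_fraction, genes = genes),
            class = "genome_sim_spec")
}

.coding_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.stop_codons <- function() c("TAA", "TAG", "TGA")

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a genome with implanted multi-exon gene-family members
#'
#' Generates random background contigs at the requested GC content and
#' implants each gene as an ATG-initiated open reading frame split across
#' codon-aligned exons by introns, on the requested strand. Exon intervals
#' in the truth are CDS spans in the GFF3 sense (the stop codon belongs to
#' the last exon). Deterministic for a fixed spec.
#'
#' @param spec A [genome_sim_spec()].
#' @return List with `genome` (sequence frame, see [read_fasta()]), `truth`
#'   (list of implanted genes: `gene_id`, `family`, `contig`, `strand`,
#'   `exons` in transcription order, `exon_aa`, `protein`) and `models`
#'   (the truth as `gene_model` objects, e.g. for [write_gff3()]).
#' @export
simulate_genome_with_families <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  withr::with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    pr <- c((1 - spec$gc_fraction) / 2, spec$gc_fraction / 2,
            spec$gc_fraction / 2, (1 - spec$gc_fraction) / 2)
    contig_ids <- sprintf("ctg%03d", seq_len(spec$n_contigs))
    chars <- lapply(seq_len(spec$n_contigs), function(i) {
      sample(bases, spec$contig_length_bp, replace = TRUE, prob = pr)
    })
    names(chars) <- contig_ids
    margin <- 500L
    cursor <- stats::setNames(rep(margin, spec$n_contigs), contig_ids)
    coding <- .coding_codons()
    coding <- coding[coding != "ATG"]
    code <- Biostrings::GENETIC_CODE

    truth <- list()
    copy_no <- 0L
    for (fam in spec$genes) {
      for (cp in seq_len(fam$n_copies)) {
        copy_no <- copy_no + 1L
        n_ex <- fam$n_exons
        exon_aa <- sample(seq(fam$exon_len_aa[1L], fam$exon_len_aa[2L]),
                          n_ex, replace = TRUE)
        introns <- if (n_ex > 1L) {
          sample(seq(fam$intron_len_bp[1L], fam$intron_len_bp[2L]),
                 n_ex - 1L, replace = TRUE)
        } else integer(0)
        total_aa <- sum(exon_aa)
        gene_codons <- c("ATG", sample(coding, total_aa - 1L, replace = TRUE))
        protein <- paste(code[gene_codons], collapse = "")
        stop_codon <- sample(.stop_codons(), 1L)
        exon_bp <- 3L * exon_aa
        exon_bp[n_ex] <- exon_bp[n_ex] + 3L  # stop codon in last exon
        cds <- paste0(paste(gene_codons, collapse = ""), stop_codon)
        # forward-orientation gene sequence: exons interleaved with introns
        exon_seqs <- character(n_ex)
        off <- 0L
        for (j in seq_len(n_ex)) {
          exon_seqs[j] <- substr(cds, off + 1L, off + exon_bp[j])
          off <- off + exon_bp[j]
        }
        intron_seqs <- vapply(introns, function(L) {
          paste(sample(bases, L, replace = TRUE, prob = pr), collapse = "")
        }, character(1))
        pieces <- character(0)
        for (j in seq_len(n_ex)) {
          pieces <- c(pieces, exon_seqs[j],
                      if (j < n_ex) intron_seqs[j] else NULL)
        }
        gene_seq <- paste(pieces, collapse = "")
        gene_len <- nchar(gene_seq)
        strand <- if (fam$strand == "random") sample(c("+", "-"), 1L) else fam$strand

        # first contig with room, leaving a margin on both sides
        placed <- FALSE
        for (ci in contig_ids) {
          g0 <- unname(cursor[ci])
          if (g0 + gene_len + margin <= spec$contig_length_bp) {
            cursor[ci] <- g0 + gene_len + 1500L
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("cannot place gene ", copy_no,
               ": increase contig_length_bp or n_contigs, or implant fewer genes")
        }
        impl <- if (strand == "+") gene_seq else .revcomp(gene_seq)
        chars[[ci]][(g0 + 1L):(g0 + gene_len)] <-
          strsplit(impl, "", fixed = TRUE)[[1L]]

        # exon offsets within the forward-orientation gene
        offs <- cumsum(c(0L, (exon_bp + c(introns, 0L))[-n_ex]))
        if (strand == "+") {
          starts <- g0 + offs
          ends <- starts + exon_bp
        } else {
          ends <- g0 + gene_len - offs
          starts <- ends - exon_bp
        }
        truth[[copy_no]] <- list(
          gene_id = sprintf("%s_g%03d", fam$family, copy_no),
          family = fam$family, contig = ci, strand = strand,
          exons = data.frame(start = starts, end = ends),
          exon_aa = exon_aa, protein = protein)
      }
    }
    genome <- seq_set(contig_ids,
                      vapply(chars, paste, character(1), collapse = ""),
                      alphabet = "dna")
    models <- lapply(truth, function(g) {
      gene_model(model_id = g$gene_id, contig = g$contig, strand = g$strand,
                 exons = g$exons, query_id = g$gene_id, protein = g$protein)
    })
    attr(truth, "contig_lengths") <-
      stats::setNames(rep(spec$contig_length_bp, spec$n_contigs), contig_ids)
    list(genome = genome, truth = truth, models = models)
  })
}

#' Emit a translated-homology hit table from implant truth
#'
#' Produces one HSP per implanted exon, with the implanted protein as its
#' own query (protein coordinates follow exon phase; subject coordinates
#' span the CDS exon). With probability `split_prob` an exon's HSP is split
#' into two still-chainable pieces sharing at most 15 query residues.
#' Spurious background HSPs are added at rate `spurious_rate` per true HSP,
#' with bit scores strictly below true scores and e-values above the default
#' chaining gate, emulating the score separation that a hard e-value
#' threshold exploits.
#'
#' @param truth Truth list from [simulate_genome_with_families()].
#' @param split_prob Per-exon probability of splitting the exon's HSP.
#' @param spurious_rate Expected spurious HSPs per true HSP.
#' @param score_jitter Half-width of uniform jitter added to true bit
#'   scores.
#' @param seed Integer seed.
#' @return An HSP data frame ([as_hsp_table()]).
#' @export
emit_truth_hsps <- function(truth, split_prob = 0, spurious_rate = 0,
                            score_jitter = 0, seed = 1L) {
  rows <- list()
  add <- function(qid, ctg, qs, qe, ss, se, ev, bit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = qid, subject_id = ctg, pct_identity = 100,
      aln_len = qe - qs + 1L, q_start = qs, q_end = qe,
      s_start = ss, s_end = se, evalue = ev, bit_score = bit,
      stringsAsFactors = FALSE)
  }
  withr::with_seed(seed, {
    n_true <- 0L
    for (g in truth) {
      aa <- g$exon_aa
      qoff <- cumsum(c(0L, aa[-length(aa)]))
      for (j in seq_along(aa)) {
        n_true <- n_true + 1L
        ex <- g$exons[j, ]
        qs <- qoff[j] + 1L; qe <- qoff[j] + aa[j]
        jit <- function() if (score_jitter > 0) stats::runif(1, -score_jitter, score_jitter) else 0
        ev <- 10^-(120 + stats::runif(1, 0, 60))
        split <- split_prob > 0 && aa[j] >= 40L &&
          stats::runif(1) < split_prob
        if (!split) {
          if (g$strand == "+") {
            add(g$gene_id, g$contig, qs, qe, ex$start + 1L, ex$end,
                ev, 2 * aa[j] + jit())
          } else {
            add(g$gene_id, g$contig, qs, qe, ex$end, ex$start + 1L,
                ev, 2 * aa[j] + jit())
          }
        } else {
          cutc <- sample(15L:(aa[j] - 16L), 1L)
          o <- min(sample(0L:15L, 1L), aa[j] - cutc)
          cut_bp <- 3L * cutc
          if (g$strand == "+") {
            add(g$gene_id, g$contig, qs, qs + cutc + o - 1L,
                ex$start + 1L, ex$start + cut_bp,
                ev, 2 * (cutc + o) + jit())
            add(g$gene_id, g$contig, qs + cutc, qe,
                ex$start + cut_bp + 1L, ex$end,
                ev, 2 * (aa[j] - cutc) + jit())
          } else {
            add(g$gene_id, g$contig, qs, qs + cutc + o - 1L,
                ex$end, ex$end - cut_bp + 1L,
                ev, 2 * (cutc + o) + jit())
            add(g$gene_id, g$contig, qs + cutc, qe,
                ex$end - cut_bp, ex$start + 1L,
                ev, 2 * (aa[j] - cutc) + jit())
          }
        }
      }
    }
    if (spurious_rate > 0 && n_true > 0L) {
      clens <- attr(truth, "contig_lengths")
      n_spur <- stats::rpois(1L, spurious_rate * n_true)
      for (k in seq_len(n_spur)) {
        ctg <- sample(names(clens), 1L)
        len_aa <- sample(20:60, 1L)
        pos <- sample.int(max(1L, clens[[ctg]] - 3L * len_aa), 1L)
        minus <- stats::runif(1) < 0.5
        ss <- if (minus) pos + 3L * len_aa - 1L else pos
        se <- if (minus) pos else pos + 3L * len_aa - 1L
        add(sprintf("spurious_q%03d", k), ctg, 1L, len_aa, ss, se,
            10^-stats::runif(1, 1, 5), stats::runif(1, 20, 40))
      }
    }
  })
  if (length(rows) == 0L) {
    return(hsp_table(character(0), character(0), numeric(0), integer(0),
                     integer(0), integer(0), integer(0), integer(0),
                     numeric(0), numeric(0)))
  }
  as_hsp_table(do.call(rbind, rows))
}

.single_tip_phylo <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                 Nnode = 1L, edge.length = 0.1), class = "phylo")
}

#' Simulate a gene tree with planted same-species expansions
#'
#' Draws a random background gene tree with species assigned uniformly to
#' leaves, then grafts each planted clade as a monospecific subtree onto the
#' edge above a random background leaf (so planted clades stay monophyletic
#' by construction). Branch lengths are positive throughout.
#'
#' @param species Character vector of species tokens for background leaves.
#' @param plant List of `list(species =, clade_size =)` entries to implant.
#' @param background_leaves Number of background leaves (>= 2).
#' @param seed Integer seed.
#' @return List with `tree` ([ape::phylo]), `newick` (canonical string),
#'   `map` ([species_map()]) and `truth` (list of planted leaf sets).
#' @export
simulate_expansion_tree <- function(species, plant = list(),
                                    background_leaves = 20L, seed = 1L) {
  stopifnot(background_leaves >= 2L, length(species) >= 1L)
  withr::with_seed(seed, {
    tr <- ape::rtree(background_leaves)
    sp_assign <- sample(species, background_leaves, replace = TRUE)
    tr$tip.label <- sprintf("bg%03d_%s", seq_len(background_leaves), sp_assign)
    leaf_to_species <- stats::setNames(sp_assign, tr$tip.label)
    truth <- list()
    for (k in seq_along(plant)) {
      sp <- plant[[k]]$species
      size <- plant[[k]]$clade_size
      stopifnot(size >= 1L)
      labels <- sprintf("%s_exp%d_g%d", sp, k, seq_len(size))
      sub <- if (size == 1L) {
        .single_tip_phylo(labels)
      } else {
        s <- ape::rtree(size)
        s$tip.label <- labels
        s
      }
      sub$root.edge <- 0.1
      bg_tips <- grep("^bg", tr$tip.label)
      w <- sample(bg_tips, 1L)
      elen <- tr$edge.length[tr$edge[, 2L] == w]
      tr <- ape::bind.tree(tr, sub, where = w, position = elen / 2)
      leaf_to_species[labels] <- sp
      truth[[k]] <- list(species = sp, leaves = labels)
    }
    list(tree = tr, newick = serialize_newick(tr),
         map = species_map(leaf_to_species[tr$tip.label]), truth = truth)
  })
}

#' RAD matrix simulation spec
#'
#' Defaults emulate the design of a RAD-tag sex screen in a ~1 Gb fish
#' genome: 47 males and 45 females passing the read filter and ~21,877
#' callable loci, with mean per-sample totals comfortably above the 150,000
#' read threshold.
#'
#' @param seed Integer seed.
#' @param n_males,n_females Sample counts.
#' @param n_loci Number of RAD loci.
#' @param mean_reads_per_sample Expected total reads per sample.
#' @param dropout_rate Per-(locus, sample) probability that a background
#'   locus drops out (default 0.05, a typical RAD allele-dropout scale).
#' @param n_sex_linked Number of strictly sex-linked loci to plant.
#' @param linked_sex Which sex carries the planted loci.
#' @return A list of class `rad_sim_spec`.
#' @export
rad_sim_spec <- function(seed = 1L, n_males = 47L, n_females = 45L,
                         n_loci = 21877L, mean_reads_per_sample = 300000L,
                         dropout_rate = 0.05, n_sex_linked = 0L,
                         linked_sex = c("male", "female")) {
  linked_sex <- match.arg(linked_sex)
  stopifnot(n_males >= 1, n_females >= 1, n_loci >= 1,
            n_sex_linked <= n_loci, dropout_rate >= 0, dropout_rate < 1)
  structure(list(seed = as.integer(seed), n_males = as.integer(n_males),
                 n_females = as.integer(n_females), n_loci = as.integer(n_loci),
                 mean_reads_per_sample = as.integer(mean_reads_per_sample),
                 dropout_rate = dropout_rate,
                 n_sex_linked = as.integer(n_sex_linked),
                 linked_sex = linked_sex),
            class = "rad_sim_spec")
}

#' Simulate a RAD locus-by-sample count matrix with optional sex-linked loci
#'
#' Background loci are present in every sample (Poisson counts shifted by 1)
#' with independent dropout at `dropout_rate`. Planted sex-linked loci carry
#' reads only in samples of `linked_sex` (never subject to dropout) and are
#' structurally zero in the other sex. Deterministic per seed.
#'
#' @param spec A [rad_sim_spec()].
#' @return List with `matrix` (a [presence_matrix()]) and `truth` (character
#'   vector of planted locus names).
#' @export
simulate_rad_matrix <- function(spec) {
  stopifnot(inherits(spec, "rad_sim_spec"))
  withr::with_seed(spec$seed, {
    samples <- c(sprintf("M%03d", seq_len(spec$n_males)),
                 sprintf("F%03d", seq_len(spec$n_females)))
    sex <- stats::setNames(rep(c("male", "female"),
                               c(spec$n_males, spec$n_females)), samples)
    loci <- sprintf("locus_%05d", seq_len(spec$n_loci))
    lambda <- spec$mean_reads_per_sample / spec$n_loci
    counts <- matrix(stats::rpois(spec$n_loci * length(samples), lambda) + 1L,
                     nrow = spec$n_loci, ncol = length(samples),
                     dimnames = list(loci, samples))
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(counts)) < spec$dropout_rate,
                     nrow = nrow(counts))
      counts[drop] <- 0L
    }
    truth <- character(0)
    if (spec$n_sex_linked > 0L) {
      linked <- sort(sample.int(spec$n_loci, spec$n_sex_linked))
      truth <- loci[linked]
      carrier <- names(sex)[sex == spec$linked_sex]
      other <- setdiff(samples, carrier)
      counts[linked, other] <- 0L
      counts[linked, carrier] <-
        stats::rpois(length(linked) * length(carrier), lambda) + 1L
    }
    list(matrix = presence_matrix(counts, sex), truth = truth)
  })
}

#' Write a presence matrix to dense TSV files
#'
#' @param m A [presence_matrix()].
#' @param counts_path,sex_path Output paths (counts TSV with locus ids in
#'   the first column; two-column sample/sex TSV).
#' @return Invisibly, `counts_path`.
#' @export
write_counts_matrix <- function(m, counts_path, sex_path) {
  df <- data.frame(locus = rownames(m$counts), m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(m$sex), sex = unname(m$sex)),
                     sex_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(counts_path)
}
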