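# Turning translated-homology (tblastn) hit tables into multi-exon gene
# models: e-value gating, best-hit-per-locus deduplication, exon chaining,
# longest-ORF translation, and protein-length filtering. This generalizes a
# genome-wide olfactory-receptor mining procedure; the same machinery serves
# any protein family searched against a genome.

#' Chaining configuration
#'
#' Thresholds controlling HSP deduplication and exon chaining.
#'
#' @param max_evalue HSPs with e-value above this are discarded before
#'   deduplication (default `1e-50`).
#' @param max_query_overlap_aa Maximum shared query (protein) positions
#'   between consecutive chained HSPs, inclusive (default 15 aa).
#' @param max_genomic_gap_bp Genomic distance between adjacent exons must be
#'   strictly smaller than this (default 10000 bp, i.e. "< 10 kb").
#' @param min_protein_len_aa Models translating to fewer residues than this
#'   are removed by [filter_models()] (default 250 aa).
#' @return A list of class `chaining_config`.
#' @export
chaining_config <- function(max_evalue = 1e-50, max_query_overlap_aa = 15L,
                            max_genomic_gap_bp = 10000L,
                            min_protein_len_aa = 250L) {
  stopifnot(max_evalue > 0, max_query_overlap_aa > 0,
            max_genomic_gap_bp > 0, min_protein_len_aa > 0)
  structure(list(max_evalue = max_evalue,
                 max_query_overlap_aa = as.integer(max_query_overlap_aa),
                 max_genomic_gap_bp = as.integer(max_genomic_gap_bp),
                 min_protein_len_aa = as.integer(min_protein_len_aa)),
            class = "chaining_config")
}

#' Homolog acceptance filter
#'
#' Coverage/identity/e-value acceptance thresholds used when screening BLAST
#' hits for confident homologs (e.g. osmoregulatory gene families). Coverage
#' and identity bounds are inclusive; the e-value bound is strict.
#'
#' @param min_query_coverage Minimum fraction of the query covered
#'   (default 0.70, inclusive).
#' @param min_identity Minimum fractional sequence identity (default 0.40,
#'   inclusive).
#' @param max_evalue Hits must have e-value strictly below this
#'   (default 1e-20).
#' @return A list of class `homolog_filter`.
#' @export
homolog_filter <- function(min_query_coverage = 0.70, min_identity = 0.40,
                           max_evalue = 1e-20) {
  stopifnot(min_query_coverage > 0, min_query_coverage <= 1,
            min_identity > 0, min_identity <= 1, max_evalue > 0)
  structure(list(min_query_coverage = min_query_coverage,
                 min_identity = min_identity, max_evalue = max_evalue),
            class = "homolog_filter")
}

# Deterministic hit ordering used for all greedy resolutions and tie-breaks.
.hsp_priority_order <- function(h) {
  order(-h$bit_score, h$evalue, h$query_id, h$start)
}

#' Keep the best hit per genomic locus
#'
#' Applies the e-value gate, then resolves every set of HSPs whose genomic
#' subject intervals overlap (same contig, either strand) down to the single
#' highest-bit-score HSP, greedily from highest to lowest score. Ties break
#' by lower e-value, then lexicographically smaller query id, then genomic
#' start.
#'
#' @param hsps An HSP data frame ([read_hsp_table()] / [hsp_table()]).
#' @param cfg A [chaining_config()].
#' @return The surviving HSPs, sorted by contig then genomic start.
#' @export
select_best_per_locus <- function(hsps, cfg = chaining_config()) {
  h <- hsps[hsps$evalue <= cfg$max_evalue, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  h <- h[.hsp_priority_order(h), , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    prior <- which(keep & h$contig == h$contig[i])
    clash <- any(h$start[prior] < h$end[i] & h$start[i] < h$end[prior])
    keep[i] <- !clash
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a gene model
#'
#' A gene model is an ordered set of exons on one strand of one contig, in
#' transcription order (ascending genomic position on `+`, descending on
#' `-`), optionally carrying its coding sequence, translated protein and
#' quality flags.
#'
#' @param model_id Unique model identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with 0-based half-open `start`/`end` columns, in
#'   transcription order.
#' @param query_id Query protein that seeded the model.
#' @param source_hsps Optional HSP rows the model was chained from.
#' @param cds,protein Optional coding and protein sequence strings.
#' @param flags Character vector drawn from
#'   `c("internal_stop", "no_start", "no_stop", "short")`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(model_id, contig, strand, exons, query_id = NA_character_,
                       source_hsps = NULL, cds = NULL, protein = NULL,
                       flags = character()) {
  m <- structure(list(model_id = model_id, contig = contig, strand = strand,
                      exons = as.data.frame(exons), query_id = query_id,
                      source_hsps = source_hsps, cds = cds, protein = protein,
                      flags = flags),
                 class = "gene_model")
  validate_gene_model(m)
  m
}

#' Validate gene-model invariants
#'
#' Checks exon sanity: at least one exon, `start < end`, pairwise-disjoint
#' intervals, and transcription-order sorting consistent with the strand.
#'
#' @param m A `gene_model`.
#' @return Invisibly, `m`; errors on violation.
#' @export
validate_gene_model <- function(m) {
  ex <- m$exons
  if (is.null(ex) || nrow(ex) == 0L) stop("model ", m$model_id, " has no exons")
  if (any(ex$start >= ex$end)) stop("model ", m$model_id, " has an empty exon")
  if (!m$strand %in% c("+", "-")) stop("model ", m$model_id, " has invalid strand")
  g <- ex[order(ex$start), , drop = FALSE]
  if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])) {
    stop("model ", m$model_id, " has overlapping exons")
  }
  expect <- if (m$strand == "+") order(ex$start) else order(-ex$start)
  if (!identical(expect, seq_len(nrow(ex)))) {
    stop("model ", m$model_id, " exons not in transcription order")
  }
  invisible(m)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s:%s %d exon(s), query %s\n", x$model_id,
              x$contig, x$strand, nrow(x$exons), x$query_id))
  if (!is.null(x$protein)) {
    cat(sprintf("  protein: %d aa%s\n", nchar(x$protein),
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' Chain deduplicated HSPs into multi-exon gene models
#'
#' Within each (contig, strand, query) group, HSPs sorted into transcription
#' order are joined into one model whenever, for each consecutive pair, (i)
#' query coordinates advance (`next q_start > previous q_start`) with an
#' overlap of at most `max_query_overlap_aa` shared residues (computed
#' inclusively as `prev_q_end - next_q_start + 1`), and (ii) the genomic gap
#' between adjacent subject intervals is non-negative and strictly smaller
#' than `max_genomic_gap_bp`. Each maximal joinable run becomes one model;
#' singleton HSPs become single-exon models.
#'
#' @param hsps HSPs already deduplicated with [select_best_per_locus()].
#' @param cfg A [chaining_config()].
#' @return List of `gene_model` objects, sorted by contig then genomic start.
#' @export
chain_hsps <- function(hsps, cfg = chaining_config()) {
  if (nrow(hsps) == 0L) return(list())
  groups <- split(seq_len(nrow(hsps)),
                  paste(hsps$contig, hsps$strand, hsps$query_id, sep = "\r"))
  models <- list()
  for (idx in groups) {
    g <- hsps[idx, , drop = FALSE]
    # transcription order: ascending genomic position on +, descending on -
    g <- g[order(if (g$strand[1L] == "+") g$start else -g$start), , drop = FALSE]
    run_start <- 1L
    runs <- list()
    if (nrow(g) > 1L) {
      for (i in seq_len(nrow(g) - 1L)) {
        prev <- g[i, ]; nxt <- g[i + 1L, ]
        overlap <- prev$q_end - nxt$q_start + 1L
        gap <- if (prev$strand == "+") nxt$start - prev$end else prev$start - nxt$end
        joinable <- nxt$q_start > prev$q_start &&
          overlap <= cfg$max_query_overlap_aa &&
          gap >= 0L && gap < cfg$max_genomic_gap_bp
        if (!joinable) {
          runs[[length(runs) + 1L]] <- run_start:i
          run_start <- i + 1L
        }
      }
    }
    runs[[length(runs) + 1L]] <- run_start:nrow(g)
    for (r in runs) {
      gg <- g[r, , drop = FALSE]
      models[[length(models) + 1L]] <- gene_model(
        model_id = "pending", contig = gg$contig[1L], strand = gg$strand[1L],
        exons = data.frame(start = gg$start, end = gg$end),
        query_id = gg$query_id[1L], source_hsps = gg)
    }
  }
  span_start <- vapply(models, function(m) min(m$exons$start), numeric(1))
  contigs <- vapply(models, function(m) m$contig, character(1))
  models <- models[order(contigs, span_start)]
  for (i in seq_along(models)) {
    m <- models[[i]]
    models[[i]]$model_id <- sprintf("%s.%s.m%03d", m$query_id, m$contig, i)
  }
  models
}

.codon_table <- function() Biostrings::GENETIC_CODE

# Translate a DNA string in frame 0, truncated to whole codons.
.translate_frame0 <- function(dna) {
  n <- 3L * (nchar(dna) %/% 3L)
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

#' Extract the coding sequence of a model and translate it
#'
#' Concatenates the exon subsequences in transcription order
#' (reverse-complemented for minus-strand models) into the CDS, then predicts
#' the protein as the longest ATG-initiated open reading frame across the
#' three forward frames of the CDS (standing in for an external ORF caller).
#' If no ATG exists, the longest stop-free stretch of the frame-0 translation
#' is used and the model is flagged `no_start`. Flags: `internal_stop` if the
#' frame-0 translation of the full CDS contains a stop before its last codon;
#' `no_stop` if the chosen reading frame runs off the end of the CDS without
#' a stop codon.
#'
#' @param model A `gene_model`.
#' @param genome Sequence data frame of contigs ([read_fasta()], dna).
#' @return The model with `cds`, `protein` and `flags` populated.
#' @export
extract_and_translate <- function(model, genome) {
  validate_gene_model(model)
  row <- match(model$contig, genome$id)
  if (is.na(row)) stop("contig ", model$contig, " not found in genome")
  contig_seq <- genome$residues[row]
  if (any(model$exons$end > nchar(contig_seq))) {
    stop("exon beyond end of contig ", model$contig)
  }
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  pieces <- substring(contig_seq, ex$start + 1L, ex$end)
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }

  flags <- character()
  aa0 <- .translate_frame0(cds)
  if (nchar(aa0) > 1L && grepl("*", substr(aa0, 1L, nchar(aa0) - 1L), fixed = TRUE)) {
    flags <- c(flags, "internal_stop")
  }

  best <- NULL  # list(protein, stopped)
  for (frame in 0:2) {
    aa <- .translate_frame0(substr(cds, frame + 1L, nchar(cds)))
    if (!nzchar(aa)) next
    m <- gregexpr("M[^*]*", aa)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      stopped <- (m[k] + lens[k] - 1L) < nchar(aa) &&
        substr(aa, m[k] + lens[k], m[k] + lens[k]) == "*"
      if (is.null(best) || lens[k] > nchar(best$protein)) {
        best <- list(protein = substr(aa, m[k], m[k] + lens[k] - 1L),
                     stopped = stopped)
      }
    }
  }
  if (is.null(best)) {
    segs <- strsplit(aa0, "*", fixed = TRUE)[[1L]]
    if (length(segs) == 0L) segs <- ""
    pick <- which.max(nchar(segs))
    stopped <- pick < length(segs) || endsWith(aa0, "*")
    best <- list(protein = segs[pick], stopped = stopped)
    flags <- c(flags, "no_start")
  }
  if (!best$stopped) flags <- c(flags, "no_stop")

  model$cds <- cds
  model$protein <- best$protein
  model$flags <- unique(flags)
  model
}

#' Remove models whose predicted protein is too short
#'
#' Drops models translating to fewer than `min_protein_len_aa` residues
#' (249 aa is removed, 250 aa is retained under the default). Order of the
#' retained models is preserved.
#'
#' @param models List of translated `gene_model`s.
#' @param cfg A [chaining_config()].
#' @return The retained models.
#' @export
filter_models <- function(models, cfg = chaining_config()) {
  if (length(models) == 0L) return(models)
  lens <- vapply(models, function(m) {
    if (is.null(m$protein)) {
      stop("model ", m$model_id,
           " has no protein; run extract_and_translate() first")
    }
    nchar(m$protein)
  }, numeric(1))
  models[lens >= cfg$min_protein_len_aa]
}

#' Filter HSPs to confident homologs
#'
#' Retains hits covering at least `min_query_coverage` of the query
#' (inclusive), with fractional identity at least `min_identity` (inclusive)
#' and e-value strictly below `max_evalue`.
#'
#' @param hsps An HSP data frame.
#' @param query_lengths Named numeric vector, query id to query length in aa.
#' @param flt A [homolog_filter()].
#' @return The retained HSP rows.
#' @export
filter_orthologs <- function(hsps, query_lengths, flt = homolog_filter()) {
  if (nrow(hsps) == 0L) return(hsps)
  qlen <- query_lengths[hsps$query_id]
  if (anyNA(qlen)) {
    stop("no query length for ",
         paste(unique(hsps$query_id[is.na(qlen)]), collapse = ", "))
  }
  coverage <- (hsps$q_end - hsps$q_start + 1) / qlen
  keep <- coverage >= flt$min_query_coverage &
    hsps$pct_identity / 100 >= flt$min_identity &
    hsps$evalue < flt$max_evalue
  out <- hsps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize gene models as a report table
#'
#' @param models List of `gene_model`s.
#' @return Data frame with model id, contig, strand, exon count, protein
#'   length and flags.
#' @export
model_report <- function(models) {
  data.frame(
    model_id = vapply(models, `[[`, character(1), "model_id"),
    contig = vapply(models, `[[`, character(1), "contig"),
    strand = vapply(models, `[[`, character(1), "strand"),
    n_exons = vapply(models, function(m) nrow(m$exons), integer(1)),
    protein_len = vapply(models, function(m)
      if (is.null(m$protein)) NA_integer_ else nchar(m$protein), integer(1)),
    flags = vapply(models, function(m) paste(m$flags, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
}
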