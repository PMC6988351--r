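# Readers/writers for the standard formats the toolkit touches.
#
# Internal coordinate convention: genomic intervals are 0-based, half-open,
# always on the forward strand, with a separate strand flag. Format boundaries
# (BLAST outfmt 6, GFF3: 1-based inclusive) convert at I/O time only.

.alphabet_chars <- list(
  dna     = c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y",
              "B", "J", "O", "U", "X", "Z", "*")
)

#' Read a FASTA file into a sequence table
#'
#' Parses FASTA (wrapped lines allowed) into a data frame with one row per
#' record. The first whitespace-delimited token of each header is the record
#' id; the remainder is kept as the description. Residues are upper-cased and
#' validated against the declared alphabet (IUPAC ambiguity codes permitted).
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"dna"` or `"protein"`.
#' @return A data frame with columns `id`, `description`, `residues` and an
#'   attribute `alphabet`; input order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT", ">b some gene", "TTTT"), fa)
#' read_fasta(fa, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences found in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(id))) stop("empty sequence id in ", path)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L) stop("duplicate id ", paste(dup, collapse = ", "))
  residues <- toupper(as.character(set))
  if (any(!nzchar(residues))) {
    stop("empty sequence for id ", paste(id[!nzchar(residues)], collapse = ", "))
  }
  allowed <- .alphabet_chars[[alphabet]]
  for (i in seq_along(residues)) {
    chars <- unique(strsplit(residues[[i]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("sequence ", id[[i]], " contains characters invalid for alphabet '",
           alphabet, "': ", paste(bad, collapse = ", "))
    }
  }
  seq_set(id, residues, description, alphabet)
}

#' Build a sequence table in memory
#'
#' @param id Character vector of unique record ids.
#' @param residues Character vector of sequences (same length as `id`).
#' @param description Optional descriptions.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A sequence data frame as returned by [read_fasta()].
#' @export
seq_set <- function(id, residues, description = "", alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(id) == length(residues))
  out <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(id)),
                    residues = toupper(as.character(residues)),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a sequence table to FASTA
#'
#' @param seqs A sequence data frame ([read_fasta()] / [seq_set()]).
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  headers <- ifelse(nzchar(seqs$description),
                    paste(seqs$id, seqs$description), seqs$id)
  set <- Biostrings::BStringSet(stats::setNames(seqs$residues, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the 12-column tab-separated BLAST format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`); lines starting with `#` are skipped. Subject
#' coordinates with `sstart > send` encode a minus-strand hit; hits are
#' normalized at parse time to forward-strand 0-based half-open intervals
#' (`start`, `end`) plus a `strand` flag, as produced by tblastn searches of
#' protein queries against a genome. `mismatch` and `gapopen` are parsed for
#' validation but not retained.
#'
#' @param path Path to the tab-separated hit table.
#' @return An HSP data frame; see [as_hsp_table()] for columns.
#' @export
read_hsp_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(as_hsp_table(data.frame(query_id = character(), subject_id = character(),
                                   pct_identity = numeric(), aln_len = integer(),
                                   q_start = integer(), q_end = integer(),
                                   s_start = integer(), s_end = integer(),
                                   evalue = numeric(), bit_score = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("expected 12 columns at line ", lineno[i], " (found ", nf[i], ")")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num_cols <- 3:12
  for (j in num_cols) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric value '", m[i, j], "' in column ", j,
           " at line ", lineno[i])
    }
  }
  as_hsp_table(data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = as.numeric(m[, 3L]), aln_len = as.integer(m[, 4L]),
    q_start = as.integer(m[, 7L]), q_end = as.integer(m[, 8L]),
    s_start = as.integer(m[, 9L]), s_end = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bit_score = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE))
}

#' Validate an HSP data frame and derive strand and forward-strand coordinates
#'
#' @param df Data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_len`, `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bit_score`
#'   (1-based inclusive coordinates; `s_start > s_end` means minus strand).
#' @return The data frame with added columns `contig` (= `subject_id`),
#'   `strand` (`+`/`-`) and `start`/`end` (0-based half-open, forward strand).
#' @export
as_hsp_table <- function(df) {
  required <- c("query_id", "subject_id", "pct_identity", "aln_len",
                "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("HSP table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(df$q_start > df$q_end)) stop("HSP with q_start > q_end")
    if (any(df$evalue < 0)) stop("negative e-value in HSP table")
    if (any(df$bit_score < 0)) stop("negative bit score in HSP table")
  }
  df$contig <- df$subject_id
  df$strand <- ifelse(df$s_start <= df$s_end, "+", "-")
  df$start <- pmin(df$s_start, df$s_end) - 1L
  df$end <- pmax(df$s_start, df$s_end)
  class(df) <- c("hsp_table", "data.frame")
  df
}

#' Construct an HSP table from vectors
#'
#' Convenience constructor mirroring the outfmt-6 column order, mainly for
#' simulations and tests.
#'
#' @inheritParams as_hsp_table
#' @param query_id,subject_id,pct_identity,aln_len,q_start,q_end,s_start,s_end,evalue,bit_score
#'   Parallel vectors, one element per HSP.
#' @return An HSP data frame (see [as_hsp_table()]).
#' @export
hsp_table <- function(query_id, subject_id, pct_identity = 100, aln_len,
                      q_start, q_end, s_start, s_end,
                      evalue = 1e-100, bit_score) {
  as_hsp_table(data.frame(
    query_id = query_id, subject_id = subject_id,
    pct_identity = pct_identity, aln_len = as.integer(aln_len),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    evalue = evalue, bit_score = bit_score,
    stringsAsFactors = FALSE))
}

#' Write gene models to GFF3
#'
#' Emits one `gene` + one `mRNA` + one `exon` line per exon for each model,
#' linked by `ID`/`Parent` attributes, sorted by contig and then genomic
#' start. Internal 0-based half-open coordinates are converted to the
#' 1-based inclusive GFF3 convention on output.
#'
#' @param models List of gene models (see [gene_model()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(is.list(models))
  if (length(models) == 0L) {
    rtracklayer::export(GenomicRanges::GRanges(), path, format = "gff3")
    return(invisible(path))
  }
  for (m in models) validate_gene_model(m)
  span_start <- vapply(models, function(m) min(m$exons$start), numeric(1))
  contigs <- vapply(models, function(m) m$contig, character(1))
  models <- models[order(contigs, span_start)]

  seqn <- character(0); starts <- integer(0); ends <- integer(0)
  strands <- character(0); types <- character(0)
  ids <- character(0); parents <- character(0)
  for (m in models) {
    gs <- min(m$exons$start) + 1L
    ge <- max(m$exons$end)
    mid <- m$model_id
    seqn <- c(seqn, m$contig, m$contig)
    starts <- c(starts, gs, gs); ends <- c(ends, ge, ge)
    strands <- c(strands, m$strand, m$strand)
    types <- c(types, "gene", "mRNA")
    ids <- c(ids, mid, paste0(mid, ".mRNA"))
    parents <- c(parents, NA_character_, mid)
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    for (k in seq_len(nrow(ex))) {
      seqn <- c(seqn, m$contig)
      starts <- c(starts, ex$start[k] + 1L); ends <- c(ends, ex$end[k])
      strands <- c(strands, m$strand)
      types <- c(types, "exon")
      ids <- c(ids, paste0(mid, ".exon", k))
      parents <- c(parents, paste0(mid, ".mRNA"))
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands)
  S4Vectors::mcols(gr)$type <- types
  S4Vectors::mcols(gr)$ID <- ids
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(parents), "", parents)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Parse a Newick tree string
#'
#' Thin wrapper over [ape::read.tree()] with explicit pre-validation so that
#' malformed input fails with a character offset rather than an opaque error.
#'
#' @param text A Newick string (must end with `;`).
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed '(' at end of input")
  if (!grepl(";", text, fixed = TRUE)) stop("Newick string lacks terminating ';'")
  bad <- regexpr("(,\\s*[,;)])|(\\(\\s*,)", text)
  if (bad > 0L) stop("dangling comma at character ", as.integer(bad))
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("failed to parse Newick string")
  tr
}

# Smallest descendant leaf name of each node; used to order children
# deterministically during serialization.
.min_leaf_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  minleaf <- character(ntip + nnode)
  minleaf[seq_len(ntip)] <- tree$tip.label
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    parent <- po[i, 1L]; child <- po[i, 2L]
    if (minleaf[parent] == "" || minleaf[child] < minleaf[parent]) {
      minleaf[parent] <- minleaf[child]
    }
  }
  minleaf
}

#' Serialize a tree to canonical Newick
#'
#' Children of every node are ordered by their smallest descendant leaf name,
#' so isomorphic trees serialize identically (deterministic round-trips).
#' Branch lengths and internal node labels are preserved when present.
#'
#' @param tree An [ape::phylo] tree.
#' @return A single Newick string.
#' @export
serialize_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  minleaf <- .min_leaf_below(tree)
  has_len <- !is.null(tree$edge.length)
  node_lab <- tree$node.label

  fmt_len <- function(edge_i) {
    if (!has_len) return("")
    paste0(":", format(tree$edge.length[edge_i], digits = 10, trim = TRUE,
                       scientific = FALSE))
  }
  recurse <- function(node, edge_i) {
    if (node <= ntip) {
      return(paste0(tree$tip.label[node], fmt_len(edge_i)))
    }
    kid_edges <- children[[as.character(node)]]
    kid_nodes <- tree$edge[kid_edges, 2L]
    ord <- order(minleaf[kid_nodes])
    inner <- vapply(ord, function(j) recurse(kid_nodes[j], kid_edges[j]),
                    character(1))
    lab <- if (!is.null(node_lab)) {
      l <- node_lab[node - ntip]
      if (is.na(l)) "" else l
    } else ""
    paste0("(", paste(inner, collapse = ","), ")", lab, fmt_len(edge_i))
  }
  paste0(recurse(root, NA_integer_), ";")
}

#' Construct a RAD locus-by-sample presence matrix
#'
#' @param counts Integer matrix, loci in rows (unique rownames), samples in
#'   columns (colnames).
#' @param sex Named character vector mapping sample name to `"male"`,
#'   `"female"` or `"unknown"`; samples absent from `sex` are labelled
#'   `unknown` with a warning.
#' @return A `presence_matrix` object: list with elements `counts` and `sex`.
#' @export
presence_matrix <- function(counts, sex) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts matrix must have locus rownames and sample colnames")
  }
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup) > 0L) stop("duplicate locus id ", paste(dup, collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "integer"
  sex <- .normalize_sex(sex)
  missing <- setdiff(colnames(counts), names(sex))
  if (length(missing) > 0L) {
    warning("no sex label for sample(s) ", paste(missing, collapse = ", "),
            "; set to 'unknown'")
    sex <- c(sex, stats::setNames(rep("unknown", length(missing)), missing))
  }
  sex <- sex[colnames(counts)]
  structure(list(counts = counts, sex = sex), class = "presence_matrix")
}

.normalize_sex <- function(sex) {
  v <- tolower(trimws(as.character(sex)))
  v[v %in% c("m", "male")] <- "male"
  v[v %in% c("f", "female")] <- "female"
  v[!v %in% c("male", "female")] <- "unknown"
  stats::setNames(v, names(sex))
}

#' Read a RAD counts matrix plus per-sample sex labels
#'
#' Accepts either a dense TSV (locus ids in the first column, sample ids in
#' the header) or a long-format triple file with header
#' `locus<TAB>sample<TAB>count`, auto-detected from the header (Stacks
#' matches-table exports come in both shapes). The sex file is two-column
#' TSV `sample<TAB>sex` (an optional header row is detected and skipped).
#'
#' @param path Path to the counts TSV.
#' @param sex_path Path to the sample-sex TSV.
#' @return A [presence_matrix()].
#' @export
read_counts_matrix <- function(path, sex_path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) == 3L &&
      all(tolower(trimws(header)) == c("locus", "sample", "count"))) {
    long <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                              check.names = FALSE)
    if (any(is.na(long$count)) || any(long$count < 0)) {
      stop("counts must be non-negative")
    }
    loci <- unique(long$locus); samples <- unique(long$sample)
    counts <- matrix(0L, length(loci), length(samples),
                     dimnames = list(loci, samples))
    counts[cbind(match(long$locus, loci), match(long$sample, samples))] <-
      as.integer(long$count)
  } else {
    dense <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                               check.names = FALSE)
    loci <- as.character(dense[[1L]])
    dup <- unique(loci[duplicated(loci)])
    if (length(dup) > 0L) stop("duplicate locus id ", paste(dup, collapse = ", "))
    counts <- as.matrix(dense[, -1L, drop = FALSE])
    if (!is.numeric(counts)) stop("non-numeric counts in ", path)
    if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
    rownames(counts) <- loci
  }
  sx <- utils::read.delim(sex_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(sx) > 0L &&
      !tolower(trimws(sx[1L, 2L])) %in% c("male", "female", "unknown", "m", "f")) {
    sx <- sx[-1L, , drop = FALSE]  # header row
  }
  sex <- stats::setNames(as.character(sx[[2L]]), as.character(sx[[1L]]))
  presence_matrix(counts, sex)
}
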