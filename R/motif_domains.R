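# PROSITE-style motif scanning and the classifiers built on it:
# cytochrome P450 completeness calls, NLR-C Walker-A group assignment,
# best-domain (7tm1/7tm4) assignment, and the PYD-CARD (ASC) screen.
#
# The matcher is a direct backtracking interpreter over parsed pattern
# elements rather than a regex translation, so tests can cross-check it
# against an independent regular-expression oracle.

#' Parse a PROSITE-syntax pattern
#'
#' Supported syntax: elements separated by `-`; `x` wildcard; `[ABC]`
#' alternatives; `{ABC}` exclusions; `e(n)` / `e(n,m)` repetition on any
#' element; `<` (N-terminal) and `>` (C-terminal) anchors; an optional
#' trailing `.`. As an extension beyond strict PROSITE (needed for published
#' Walker A motif tables), an element may be a parenthesized alternation of
#' residue strings, `(AB/CD)`.
#'
#' @param pattern Pattern string, e.g. `"F-x-x-G-x-x-x-C-x-G"`.
#' @param name Motif name to report in hits (defaults to the pattern itself).
#' @return An object of class `prosite_pattern`.
#' @export
prosite_pattern <- function(pattern, name = pattern) {
  p <- trimws(pattern)
  p <- sub("\\.$", "", p)
  anchor_start <- startsWith(p, "<")
  if (anchor_start) p <- substring(p, 2L)
  anchor_end <- endsWith(p, ">")
  if (anchor_end) p <- substring(p, 1L, nchar(p) - 1L)
  if (!nzchar(p)) stop("empty pattern '", pattern, "'")
  toks <- strsplit(p, "-", fixed = TRUE)[[1L]]
  elements <- lapply(toks, .parse_prosite_element, full = pattern)
  structure(list(name = name, pattern = pattern,
                 anchor_start = anchor_start, anchor_end = anchor_end,
                 elements = elements),
            class = "prosite_pattern")
}

.parse_prosite_element <- function(tok, full) {
  if (!nzchar(tok)) stop("cannot parse pattern element '' in '", full, "'")
  min_rep <- 1L; max_rep <- 1L
  rep_m <- regmatches(tok, regexec("^(.*)\\((\\d+)(,(\\d+))?\\)$", tok))[[1L]]
  base <- tok
  if (length(rep_m) > 0L) {
    base <- rep_m[2L]
    min_rep <- as.integer(rep_m[3L])
    max_rep <- if (nzchar(rep_m[5L])) as.integer(rep_m[5L]) else min_rep
    if (max_rep < min_rep) stop("cannot parse pattern element '", tok, "'")
  }
  el <- if (base %in% c("x", "X")) {
    list(type = "any")
  } else if (grepl("^\\[[A-Za-z]+\\]$", base)) {
    list(type = "class",
         chars = strsplit(toupper(substr(base, 2L, nchar(base) - 1L)), "")[[1L]])
  } else if (grepl("^\\{[A-Za-z]+\\}$", base)) {
    list(type = "not",
         chars = strsplit(toupper(substr(base, 2L, nchar(base) - 1L)), "")[[1L]])
  } else if (grepl("^[A-Za-z]$", base)) {
    list(type = "literal", chars = toupper(base))
  } else if (grepl("^\\([A-Za-z]+(/[A-Za-z]+)+\\)$", base)) {
    list(type = "alt",
         alts = toupper(strsplit(substr(base, 2L, nchar(base) - 1L), "/",
                                 fixed = TRUE)[[1L]]))
  } else {
    stop("cannot parse pattern element '", tok, "' in '", full, "'")
  }
  el$min_rep <- min_rep
  el$max_rep <- max_rep
  el
}

# Try to match elements k.. starting at position pos (1-based) of chars;
# returns the end position + 1 of the first (greedy) match, or NA.
.match_from <- function(chars, pos, elements, k, anchor_end) {
  n <- length(chars)
  if (k > length(elements)) {
    if (anchor_end && pos != n + 1L) return(NA_integer_)
    return(pos)
  }
  e <- elements[[k]]
  if (e$type == "alt") {
    # repetition on alternations applies to the whole alternation
    .match_alt <- function(pos, reps_left) {
      if (reps_left == 0L) return(pos)
      for (a in e$alts) {
        la <- nchar(a)
        if (pos + la - 1L <= n &&
            paste(chars[pos:(pos + la - 1L)], collapse = "") == a) {
          res <- .match_alt(pos + la, reps_left - 1L)
          if (!is.na(res)) return(res)
        }
      }
      NA_integer_
    }
    for (r in seq(e$max_rep, e$min_rep)) {
      after <- .match_alt(pos, r)
      if (!is.na(after)) {
        res <- .match_from(chars, after, elements, k + 1L, anchor_end)
        if (!is.na(res)) return(res)
      }
    }
    return(NA_integer_)
  }
  ok_char <- function(ch) {
    switch(e$type,
           any = TRUE,
           literal = ch == e$chars,
           class = ch %in% e$chars,
           not = !(ch %in% e$chars))
  }
  for (r in seq(e$max_rep, e$min_rep)) {
    if (pos + r - 1L > n) next
    window_ok <- r == 0L ||
      all(vapply(chars[pos:(pos + r - 1L)], ok_char, logical(1)))
    if (window_ok) {
      res <- .match_from(chars, pos + r, elements, k + 1L, anchor_end)
      if (!is.na(res)) return(res)
    }
  }
  NA_integer_
}

#' Scan a protein for PROSITE-style motifs
#'
#' Reports, for each pattern, all non-overlapping leftmost matches with
#' greedy repetition semantics (the behaviour of ScanProsite and of a greedy
#' regular-expression engine). Anchors restrict matches to the sequence
#' termini. Coordinates are 0-based half-open.
#'
#' @param protein A single-row sequence data frame, or a plain character
#'   string (optionally named with the protein id).
#' @param patterns List of [prosite_pattern()]s (a single pattern is
#'   accepted).
#' @return Data frame with columns `motif_name`, `protein_id`, `start`,
#'   `end`, `matched_text`; zero rows when nothing matches.
#' @export
scan_motifs <- function(protein, patterns) {
  pr <- .as_protein(protein)
  if (inherits(patterns, "prosite_pattern")) patterns <- list(patterns)
  chars <- strsplit(pr$residues, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- list()
  for (pat in patterns) {
    stopifnot(inherits(pat, "prosite_pattern"))
    pos <- 1L
    while (pos <= n) {
      if (pat$anchor_start && pos > 1L) break
      end <- .match_from(chars, pos, pat$elements, 1L, pat$anchor_end)
      if (!is.na(end) && end > pos) {
        out[[length(out) + 1L]] <- data.frame(
          motif_name = pat$name, protein_id = pr$id,
          start = pos - 1L, end = end - 1L,
          matched_text = substr(pr$residues, pos, end - 1L),
          stringsAsFactors = FALSE)
        pos <- end
      } else {
        pos <- pos + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif_name = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.as_protein <- function(protein) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    return(list(id = protein$id[1L], residues = toupper(protein$residues[1L])))
  }
  stopifnot(is.character(protein), length(protein) == 1L)
  id <- if (!is.null(names(protein))) names(protein) else "query"
  list(id = id, residues = toupper(unname(protein)))
}

#' Default CYP motif patterns
#'
#' Surrogate consensus patterns for the four conserved cytochrome P450
#' motifs (I-helix, K-helix, meander coil, heme-binding loop). The published
#' analysis used ScanProsite with unspecified accessions, so these defaults
#' follow the widely used consensus shapes (e.g. the FxxGxxxCxG heme loop)
#' and are meant to be overridden with curated patterns where available.
#'
#' @return Named list of [prosite_pattern()]s with names `I-helix`,
#'   `K-helix`, `meander`, `heme-loop`.
#' @export
cyp_motif_patterns <- function() {
  list(
    `I-helix` = prosite_pattern("[AG]-G-x-[DE]-T", name = "I-helix"),
    `K-helix` = prosite_pattern("E-x-x-R", name = "K-helix"),
    meander = prosite_pattern("P-x-R", name = "meander"),
    `heme-loop` = prosite_pattern("F-x-x-G-x-x-x-C-x-G", name = "heme-loop"))
}

#' CYP completeness call rules
#'
#' @param required_motifs Motif names that must all be present for a gene to
#'   escape the `fragment` class.
#' @param full_length_aa Nominal full-length CYP protein size (~500 aa).
#' @param tolerance_aa Band around `full_length_aa` still counted as full
#'   length (default 50, i.e. 450-550 aa).
#' @param core_region_aa Size of the motif-bearing core region (~120 aa);
#'   informational.
#' @param require_start,require_stop Whether `complete` requires an initial
#'   methionine / a stop codon.
#' @return A list of class `cyp_call_rules`.
#' @export
cyp_call_rules <- function(required_motifs = c("I-helix", "K-helix",
                                               "meander", "heme-loop"),
                           full_length_aa = 500L, tolerance_aa = 50L,
                           core_region_aa = 120L,
                           require_start = TRUE, require_stop = TRUE) {
  stopifnot(core_region_aa < full_length_aa)
  structure(list(required_motifs = required_motifs,
                 full_length_aa = as.integer(full_length_aa),
                 tolerance_aa = as.integer(tolerance_aa),
                 core_region_aa = as.integer(core_region_aa),
                 require_start = require_start, require_stop = require_stop),
            class = "cyp_call_rules")
}

#' Classify a cytochrome P450 gene as complete, partial or fragment
#'
#' A gene missing any required motif is a `fragment`. With all motifs
#' present, it is `complete` when its length falls within
#' `full_length_aa` +/- `tolerance_aa`, it starts with methionine (if
#' required), its translation terminated at a stop codon (if required), and
#' it matches the family profile HMM; otherwise it is `partial` (the intact
#' motif-bearing core region at clearly less than full length). Profile-HMM
#' scanning itself is out of scope: `has_hmm_match` is supplied by the
#' caller.
#'
#' @param protein Protein sequence (string or single-row sequence frame).
#' @param hits Motif hits for this protein from [scan_motifs()].
#' @param rules A [cyp_call_rules()].
#' @param has_hmm_match Logical: did the protein match the CYP profile HMM?
#' @param has_stop Logical: did the gene model terminate at a stop codon?
#' @return One of `"complete"`, `"partial"`, `"fragment"`.
#' @export
classify_cyp <- function(protein, hits, rules = cyp_call_rules(),
                         has_hmm_match = TRUE, has_stop = TRUE) {
  pr <- .as_protein(protein)
  present <- rules$required_motifs %in% hits$motif_name
  if (!all(present)) return("fragment")
  len <- nchar(pr$residues)
  full_length <- abs(len - rules$full_length_aa) <= rules$tolerance_aa
  start_ok <- !rules$require_start || startsWith(pr$residues, "M")
  stop_ok <- !rules$require_stop || isTRUE(has_stop)
  if (full_length && start_ok && stop_ok && isTRUE(has_hmm_match)) "complete"
  else "partial"
}

#' Pick the highest-scoring domain annotation
#'
#' Returns the name of the maximum-score domain for a protein (e.g. deciding
#' between the 7tm1 and 7tm4 transmembrane families for an olfactory
#' receptor). Ties break by earlier domain start, then name.
#'
#' @param ann Data frame of domain annotations for one protein with columns
#'   `name`, `start`, `end`, `score`.
#' @return The winning domain name.
#' @export
assign_best_domain <- function(ann) {
  if (is.null(ann) || nrow(ann) == 0L) stop("empty domain list")
  ann[order(-ann$score, ann$start, ann$name), ][1L, "name"]
}

#' Read a domain-annotation TSV
#'
#' Expected columns (tab-separated, with header):
#' `protein_id`, `name`, `start`, `end`, `score` — the tabular shape emitted
#' by standard domain scanners. Rows are sorted by protein and domain start.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotations.
#' @export
read_domain_tsv <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("protein_id", "name", "start", "end", "score")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) {
    stop("domain table lacks columns: ", paste(missing, collapse = ", "))
  }
  d[order(d$protein_id, d$start), , drop = FALSE]
}

#' NLR-C group specifications
#'
#' The six fish NLR-C groups, each defined by a highly conserved Walker A
#' motif within the NACHT domain together with whether group members may
#' carry an N-terminal PYD and/or a C-terminal B30.2 domain. Patterns use
#' the extended notation of [prosite_pattern()]: `x` is any residue and
#' `(A/B)` alternation covers variable positions (including multi-residue
#' variants). Groups 1-4 are the zebrafish groups; groups 5 and 6 are the
#' goby-specific groups.
#'
#' @return List of six specs: `group_id`, `walker_a` (pattern string),
#'   `pattern` (compiled), `pyd_allowed`, `b30_2_allowed`.
#' @export
nlr_group_specs <- function() {
  tab <- list(
    list(1L, "GIAGVGKTL(I/M)PVVKNT(T/R)RA", TRUE, TRUE),
    list(2L, "GVAGIGKSLSAVIKTSKRA", TRUE, TRUE),
    list(3L, "GIAGIGKTL(IP/TA)AV(R/S)NC(RK/TR/RR)A", FALSE, TRUE),
    list(4L, "GVAGIGKTLPV(I/V)xxxx(A/V)x", FALSE, FALSE),
    list(5L, "xGVAG(V/I)GKT(L/M)PV(V/I)KASxK(A/V)", TRUE, TRUE),
    list(6L, "xGVAGVGKTL(I/V)P(A/V)VRNCRKA", FALSE, FALSE))
  lapply(tab, function(row) {
    # published Walker A tables write runs of residues without separators;
    # insert '-' between syntactic units before parsing
    units <- regmatches(row[[2L]],
                        gregexpr("\\([A-Za-z/]+\\)|[A-Za-z]", row[[2L]]))[[1L]]
    list(group_id = row[[1L]], walker_a = row[[2L]],
         pattern = prosite_pattern(paste(units, collapse = "-"),
                                   name = paste0("walkerA_g", row[[1L]])),
         pyd_allowed = row[[3L]], b30_2_allowed = row[[4L]])
  })
}

#' Assign an NLR-C protein to a group from its Walker A motif
#'
#' Matches the Walker A region against all six group motifs and checks
#' domain-architecture consistency: a PYD or B30.2 domain present on the
#' protein disqualifies groups whose members never carry that domain
#' (absence of a domain is always consistent). A unique surviving group is
#' returned; zero or multiple consistent groups yield `"unassigned"` (with a
#' warning in the ambiguous case).
#'
#' @param walker_a_region Protein substring containing the Walker A motif.
#' @param has_pyd,has_b30_2 Logical domain-presence flags for the protein.
#' @param specs Group specifications ([nlr_group_specs()]).
#' @return Integer group id (1-6) or the string `"unassigned"`.
#' @export
classify_nlr_group <- function(walker_a_region, has_pyd, has_b30_2,
                               specs = nlr_group_specs()) {
  region <- .as_protein(walker_a_region)$residues
  if (!nzchar(region)) stop("empty Walker A region")
  consistent <- vapply(specs, function(sp) {
    hit <- nrow(scan_motifs(region, sp$pattern)) > 0L
    hit && (!has_pyd || sp$pyd_allowed) && (!has_b30_2 || sp$b30_2_allowed)
  }, logical(1))
  n <- sum(consistent)
  if (n == 1L) return(specs[[which(consistent)]]$group_id)
  if (n > 1L) {
    warning("Walker A region consistent with groups ",
            paste(vapply(specs[consistent], `[[`, integer(1), "group_id"),
                  collapse = ", "), "; returning 'unassigned'")
  }
  "unassigned"
}

#' Find PYD-followed-by-adjacent-CARD (ASC) domain architectures
#'
#' Screens domain annotations for proteins in which a PYD domain is
#' immediately followed by a CARD domain with no other annotated domain in
#' between - the architecture of the inflammasome adaptor ASC (PYCARD).
#' Adjacency is positional (no intervening annotated domain), with an
#' optional maximum residue gap.
#'
#' @param ann Domain-annotation data frame (`protein_id`, `name`, `start`,
#'   `end`, `score`) covering one or more proteins.
#' @param max_gap_aa Optional maximum gap in residues between the PYD end
#'   and the CARD start (default unlimited).
#' @return Data frame of candidates: `protein_id`, `pyd_start`, `pyd_end`,
#'   `card_start`, `card_end`.
#' @export
find_pyd_card_architectures <- function(ann, max_gap_aa = Inf) {
  empty <- data.frame(protein_id = character(), pyd_start = integer(),
                      pyd_end = integer(), card_start = integer(),
                      card_end = integer(), stringsAsFactors = FALSE)
  if (is.null(ann) || nrow(ann) == 0L) return(empty)
  out <- list()
  for (pid in unique(ann$protein_id)) {
    d <- ann[ann$protein_id == pid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2L) next
    for (i in seq_len(nrow(d) - 1L)) {
      if (d$name[i] == "PYD" && d$name[i + 1L] == "CARD" &&
          d$start[i] < d$start[i + 1L] &&
          (d$start[i + 1L] - d$end[i]) <= max_gap_aa) {
        out[[length(out) + 1L]] <- data.frame(
          protein_id = pid, pyd_start = d$start[i], pyd_end = d$end[i],
          card_start = d$start[i + 1L], card_end = d$end[i + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
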