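# Independent oracles and random-input generators shared across tests.
# Each oracle takes a different computational route from the implementation
# it checks (regex engine vs backtracking matcher; exhaustive partition /
# clade enumeration vs the package's greedy / postorder algorithms).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ---- PROSITE oracle: translate the pattern to a PCRE regex and scan with
# gregexpr; returns 0-based half-open hit coordinates.

prosite_to_regex <- function(pattern) {
  p <- trimws(sub("\\.$", "", pattern))
  anchor_start <- startsWith(p, "<")
  if (anchor_start) p <- substring(p, 2)
  anchor_end <- endsWith(p, ">")
  if (anchor_end) p <- substring(p, 1, nchar(p) - 1)
  toks <- strsplit(p, "-", fixed = TRUE)[[1]]
  rx <- vapply(toks, function(tok) {
    rep_m <- regmatches(tok, regexec("^(.*)\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    base <- tok
    suffix <- ""
    if (length(rep_m) > 0) {
      base <- rep_m[2]
      suffix <- if (nzchar(rep_m[5])) {
        sprintf("{%s,%s}", rep_m[3], rep_m[5])
      } else {
        sprintf("{%s}", rep_m[3])
      }
    }
    core <- if (base %in% c("x", "X")) {
      "."
    } else if (grepl("^\\[", base)) {
      base
    } else if (grepl("^\\{", base)) {
      paste0("[^", substr(base, 2, nchar(base) - 1), "]")
    } else {
      base
    }
    paste0(core, suffix)
  }, character(1))
  paste0(if (anchor_start) "^" else "", paste(rx, collapse = ""),
         if (anchor_end) "$" else "")
}

regex_scan <- function(pattern, sequence) {
  rx <- prosite_to_regex(pattern)
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Random PROSITE pattern over standard syntax (no alternation extension),
# with an embeddable witness string so positive cases are frequent.
random_prosite_pattern <- function() {
  n <- sample(3:7, 1)
  toks <- character(n)
  witness <- character(n)
  for (i in seq_len(n)) {
    type <- sample(c("literal", "any", "class", "not"), 1,
                   prob = c(0.45, 0.25, 0.2, 0.1))
    if (type == "literal") {
      ch <- sample(AA20, 1)
      base <- ch
      pick <- ch
    } else if (type == "any") {
      base <- "x"
      pick <- sample(AA20, 1)
    } else if (type == "class") {
      cls <- sample(AA20, sample(2:4, 1))
      base <- paste0("[", paste(cls, collapse = ""), "]")
      pick <- sample(cls, 1)
    } else {
      cls <- sample(AA20, sample(1:3, 1))
      base <- paste0("{", paste(cls, collapse = ""), "}")
      pick <- sample(setdiff(AA20, cls), 1)
    }
    reps <- 1L
    if (runif(1) < 0.3) {
      if (runif(1) < 0.5) {
        reps <- sample(1:3, 1)
        base <- sprintf("%s(%d)", base, reps)
      } else {
        lo <- sample(1:2, 1); hi <- lo + sample(1:2, 1)
        reps <- sample(lo:hi, 1)
        base <- sprintf("%s(%d,%d)", base, lo, hi)
      }
    }
    toks[i] <- base
    witness[i] <- paste(rep(pick, reps), collapse = "")
  }
  pat <- paste(toks, collapse = "-")
  anchor <- sample(c("none", "start", "end"), 1, prob = c(0.8, 0.1, 0.1))
  if (anchor == "start") pat <- paste0("<", pat)
  if (anchor == "end") pat <- paste0(pat, ">")
  list(pattern = pat, witness = paste(witness, collapse = ""),
       anchor = anchor)
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# ---- Chaining oracle: enumerate all contiguous partitions of each sorted
# (contig, strand, query) group into runs whose adjacent pairs satisfy the
# two chaining rules, and keep the partition that greedily maximizes run
# lengths from the transcription start.

oracle_chain_keys <- function(hsps, cfg) {
  if (nrow(hsps) == 0) return(character())
  keys <- character()
  groups <- split(seq_len(nrow(hsps)),
                  paste(hsps$contig, hsps$strand, hsps$query_id, sep = "\r"))
  for (idx in groups) {
    g <- hsps[idx, , drop = FALSE]
    g <- g[order(if (g$strand[1] == "+") g$start else -g$start), , drop = FALSE]
    n <- nrow(g)
    pair_ok <- function(i) {
      prev <- g[i, ]; nxt <- g[i + 1, ]
      overlap <- prev$q_end - nxt$q_start + 1
      gap <- if (prev$strand == "+") nxt$start - prev$end else prev$start - nxt$end
      nxt$q_start > prev$q_start && overlap <= cfg$max_query_overlap_aa &&
        gap >= 0 && gap < cfg$max_genomic_gap_bp
    }
    best <- NULL
    if (n == 1) {
      best <- list(1L)
    } else {
      # bit b of mask set = cut between position b and b+1
      for (mask in 0:(2^(n - 1) - 1)) {
        cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
        bounds <- c(0, cuts, n)
        runs <- lapply(seq_len(length(bounds) - 1),
                       function(k) (bounds[k] + 1):bounds[k + 1])
        valid <- all(vapply(runs, function(r) {
          length(r) == 1 || all(vapply(r[-length(r)], pair_ok, logical(1)))
        }, logical(1)))
        if (!valid) next
        if (is.null(best)) {
          best <- runs
        } else {
          # greedy from 5': lexicographically longer runs win
          a <- lengths(runs); b <- lengths(best)
          len <- min(length(a), length(b))
          cmp <- 0
          for (k in seq_len(len)) {
            if (a[k] != b[k]) { cmp <- sign(a[k] - b[k]); break }
          }
          if (cmp > 0) best <- runs
        }
      }
    }
    for (r in best) {
      gg <- g[r, , drop = FALSE]
      keys <- c(keys, paste(gg$contig[1], gg$strand[1], gg$query_id[1],
                            paste(sort(gg$start), collapse = ","),
                            paste(sort(gg$end), collapse = ","), sep = "|"))
    }
  }
  sort(keys)
}

model_keys <- function(models) {
  sort(vapply(models, function(m) {
    paste(m$contig, m$strand, m$query_id,
          paste(sort(m$exons$start), collapse = ","),
          paste(sort(m$exons$end), collapse = ","), sep = "|")
  }, character(1)))
}

# Random already-plausible HSP set for chaining tests (deduplicated via
# select_best_per_locus before use, as the chaining contract requires).
random_hsp_set <- function(n_max = 12) {
  n <- sample(2:n_max, 1)
  contig <- sample(c("c1", "c2"), n, replace = TRUE)
  strand_minus <- runif(n) < 0.4
  query <- sample(c("qA", "qB"), n, replace = TRUE)
  q_start <- sample(1:250, n, replace = TRUE)
  q_len <- sample(20:120, n, replace = TRUE)
  s_pos <- sample(1:40000, n, replace = TRUE)
  s_len <- q_len * 3
  s_start <- ifelse(strand_minus, s_pos + s_len - 1, s_pos)
  s_end <- ifelse(strand_minus, s_pos, s_pos + s_len - 1)
  hsp_table(query_id = query, subject_id = contig,
            pct_identity = round(runif(n, 40, 100), 1), aln_len = q_len,
            q_start = q_start, q_end = q_start + q_len - 1,
            s_start = s_start, s_end = s_end,
            evalue = 10^-runif(n, 40, 120),
            bit_score = round(runif(n, 80, 400), 1))
}

# ---- Clade oracle: brute-force scan of every clade (tip or internal node)
# for monospecificity and maximality, via phangorn::Descendants.

oracle_clade_keys <- function(tree, map) {
  groups <- map$leaf_to_species[tree$tip.label]
  if (!is.null(map$equivalence)) {
    grp <- map$equivalence[groups]
    groups <- ifelse(is.na(grp), groups, grp)
  }
  ntip <- length(tree$tip.label)
  nodes <- seq_len(ntip + tree$Nnode)
  tipsets <- phangorn::Descendants(tree, nodes, type = "tips")
  mono <- vapply(tipsets, function(t) length(unique(groups[t])) == 1,
                 logical(1))
  parent <- rep(NA_integer_, length(nodes))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  maximal <- logical(length(nodes))
  maximal[is.na(parent)] <- mono[is.na(parent)]
  has_p <- !is.na(parent)
  maximal[has_p] <- mono[has_p] & !mono[parent[has_p]]
  sort(vapply(which(maximal), function(nd) {
    paste(sort(tree$tip.label[tipsets[[nd]]]), collapse = ",")
  }, character(1)))
}

clade_keys <- function(clades) {
  sort(vapply(clades$leaves, function(l) paste(sort(l), collapse = ","),
              character(1)))
}

random_species_tree <- function(max_leaves = 64, n_species = 4) {
  n <- sample(4:max_leaves, 1)
  tr <- ape::rtree(n)
  sp <- sample(paste0("sp", seq_len(n_species)), n, replace = TRUE)
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  list(tree = tr, map = species_map(stats::setNames(sp, tr$tip.label)))
}
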