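# Lineage-specific gene-family expansion detection on species-labelled
# phylogenies: maximal monophyletic same-species clades of at least a
# threshold size (default 5 gene copies) are called expansions.

#' Build a species map for tree leaves
#'
#' @param leaf_to_species Named character vector mapping leaf name to
#'   species token.
#' @param equivalence Optional named character vector mapping species token
#'   to a group token; species sharing a group are treated as one lineage in
#'   monospecificity checks (defaults to the identity).
#' @return A list of class `species_map`.
#' @export
species_map <- function(leaf_to_species, equivalence = NULL) {
  stopifnot(!is.null(names(leaf_to_species)))
  structure(list(leaf_to_species = leaf_to_species,
                 equivalence = equivalence),
            class = "species_map")
}

#' Read a two-column leaf-to-species TSV
#'
#' @param path TSV with leaf name in column 1, species in column 2 (no
#'   header).
#' @return A [species_map()].
#' @export
read_species_map <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  species_map(stats::setNames(as.character(d[[2L]]), as.character(d[[1L]])))
}

#' Merge species into shared expansion groups
#'
#' Species merged into one group count together in monospecificity checks.
#' The motivating case is allowing genes from a closely related sister
#' species with a poorer assembly (e.g. a second mudskipper) to be absorbed
#' into the focal species' lineage-specific expansion clades.
#'
#' @param map A [species_map()].
#' @param merges Named character vector: species token -> group token.
#' @return The updated map.
#' @export
apply_species_equivalence <- function(map, merges) {
  stopifnot(inherits(map, "species_map"), !is.null(names(merges)))
  known <- unique(unname(map$leaf_to_species))
  unknown <- setdiff(names(merges), known)
  if (length(unknown) > 0L) {
    stop("merge references unknown species: ", paste(unknown, collapse = ", "))
  }
  eq <- map$equivalence
  if (is.null(eq)) eq <- stats::setNames(known, known)
  eq[names(merges)] <- unname(merges)
  if (length(unique(eq[known])) == 1L && length(known) > 1L) {
    warning("all species merged into one group; every clade is monospecific")
  }
  map$equivalence <- eq
  map
}

.leaf_groups <- function(tree, map) {
  sp <- map$leaf_to_species[tree$tip.label]
  if (anyNA(sp)) {
    stop("no species mapping for leaf ",
         paste(tree$tip.label[is.na(sp)], collapse = ", "))
  }
  if (!is.null(map$equivalence)) {
    grp <- map$equivalence[sp]
    sp <- ifelse(is.na(grp), sp, grp)
  }
  unname(sp)
}

# Root an input tree if needed: midpoint when branch lengths are available,
# otherwise keep the basal polytomy as root and warn.
.ensure_rooted <- function(tree) {
  if (ape::is.rooted(tree)) return(tree)
  if (!is.null(tree$edge.length)) return(phangorn::midpoint(tree))
  warning("unrooted tree without branch lengths; rooting at the basal polytomy")
  tree
}

#' Find maximal monospecific clades
#'
#' Returns every clade (internal node or single leaf) whose descendant
#' leaves all belong to one species group and whose parent clade does not
#' - i.e. the coarsest monospecific partition of the leaf set. Singleton
#' clades are included, so the returned clades always partition the leaves.
#' Unrooted trees are midpoint-rooted first (branch lengths required).
#'
#' @param tree An [ape::phylo] tree ([parse_newick()]).
#' @param map A [species_map()] resolving every leaf.
#' @return Data frame with columns `node`, `species_group`, `size` and a
#'   list-column `leaves`.
#' @export
find_maximal_monospecific_clades <- function(tree, map) {
  tree <- .ensure_rooted(tree)
  groups <- .leaf_groups(tree, map)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  # single species group of each node's leaf set, NA when mixed
  node_group <- c(groups, rep(NA_character_, nnode))
  mixed <- c(rep(FALSE, ntip), rep(FALSE, nnode))
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    parent <- po[i, 1L]; child <- po[i, 2L]
    if (mixed[child]) {
      mixed[parent] <- TRUE
    } else if (is.na(node_group[parent]) && !mixed[parent]) {
      node_group[parent] <- node_group[child]
    } else if (!mixed[parent] && node_group[parent] != node_group[child]) {
      mixed[parent] <- TRUE
    }
  }
  node_group[mixed] <- NA_character_
  parent_of <- rep(NA_integer_, total)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  mono <- !is.na(node_group)
  maximal <- mono & (is.na(parent_of) | !mono[ifelse(is.na(parent_of), 1L,
                                                     parent_of)])
  nodes <- which(maximal)
  leaves <- lapply(nodes, function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else tree$tip.label[.tips_below(tree, nd)]
  })
  out <- data.frame(node = nodes,
                    species_group = node_group[nodes],
                    size = lengths(leaves),
                    stringsAsFactors = FALSE)
  out$leaves <- leaves
  out[order(-out$size, out$species_group, out$node), , drop = FALSE]
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  sort(unlist(lapply(kids, .tips_below, tree = tree)))
}

#' Call lineage-specific expansions
#'
#' Retains maximal monospecific clades with at least `min_size` gene copies
#' (leaves). With the default `min_size = 5`, a monophyletic group of five
#' or more genes of the same species (group) is an expansion; size-4 clades
#' are not called.
#'
#' @param clades Output of [find_maximal_monospecific_clades()].
#' @param min_size Minimum clade size (>= 2; default 5).
#' @return The qualifying rows, sorted by size (descending) then species
#'   group.
#' @export
call_expansions <- function(clades, min_size = 5L) {
  if (min_size < 2L) stop("min_size must be at least 2: an expansion needs multiple gene copies")
  out <- clades[clades$size >= min_size, , drop = FALSE]
  out[order(-out$size, out$species_group), , drop = FALSE]
}
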