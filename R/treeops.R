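## Low-level tree surgery and split utilities used by search, consensus,
## placement and regrafting.  Trees are ape "phylo" objects; topology-only
## trees (no edge lengths) are the common case in parsimony work.

new_phylo <- function(edge, tip.label, Nnode) {
  phy <- list(edge = edge, tip.label = tip.label, Nnode = as.integer(Nnode))
  class(phy) <- "phylo"
  phy
}

# Insert a new tip by bisecting edge `edge_index`.
attach_tip <- function(phy, edge_index, label) {
  E <- phy$edge
  ntip <- length(phy$tip.label)
  E[E > ntip] <- E[E > ntip] + 1L
  newtip <- ntip + 1L
  newnode <- ntip + 1L + phy$Nnode + 1L
  child <- E[edge_index, 2]
  E[edge_index, 2] <- newnode
  E <- rbind(E, c(newnode, child), c(newnode, newtip))
  out <- new_phylo(E, c(phy$tip.label, label), phy$Nnode + 1L)
  out
}

# Attach a whole subtree `sub` (rooted phylo; may be a single tip given as
# a label string) by bisecting edge `edge_index` of `phy`.
attach_clade <- function(phy, edge_index, sub) {
  if (is.character(sub)) return(attach_tip(phy, edge_index, sub))
  if (length(sub$tip.label) == 1) return(attach_tip(phy, edge_index,
                                                    sub$tip.label))
  n1 <- length(phy$tip.label); m1 <- phy$Nnode
  n2 <- length(sub$tip.label); m2 <- sub$Nnode
  # new numbering: phy tips 1..n1, sub tips n1+1..n1+n2, phy internals
  # shifted by +n2 (root stays at n1+n2+1), joint attachment node next,
  # sub internals after that.
  E1 <- phy$edge
  E1[E1 > n1] <- E1[E1 > n1] + n2
  joint <- n1 + n2 + m1 + 1L
  E2 <- sub$edge
  E2[sub$edge <= n2] <- sub$edge[sub$edge <= n2] + n1
  E2[sub$edge > n2] <- sub$edge[sub$edge > n2] + n1 + m1 + 1L
  sub_root <- n2 + 1L + n1 + m1 + 1L
  child <- E1[edge_index, 2]
  E1[edge_index, 2] <- joint
  E <- rbind(E1, c(joint, child), c(joint, sub_root), E2)
  new_phylo(E, c(phy$tip.label, sub$tip.label), m1 + m2 + 1L)
}

# Remove the clade below `node` (a node or tip id); returns
# list(pruned = phylo, sub = phylo or tip label).  The degree-2 node left
# behind is collapsed.
detach_clade <- function(phy, node) {
  ntip <- length(phy$tip.label)
  clade_tips <- if (node <= ntip) phy$tip.label[node]
                else ape::extract.clade(phy, node)$tip.label
  if (length(clade_tips) >= ntip - 1)
    stop_glasstree("cannot detach a clade leaving fewer than 2 leaves")
  sub <- if (length(clade_tips) == 1) clade_tips
         else ape::extract.clade(phy, node)
  pruned <- ape::drop.tip(phy, clade_tips, collapse.singles = TRUE)
  list(pruned = pruned, sub = sub)
}

## ---- splits -------------------------------------------------------------

# Unrooted splits (bipartitions) as canonical strings: the side NOT
# containing the reference taxon, written as sorted labels joined by "|".
# Only non-trivial splits (2 <= side size <= n-2) are returned.
tree_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  bp <- ape::prop.part(phy)
  labs <- attr(bp, "labels")
  out <- character(0)
  for (cl in bp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= ntip - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# signature identifying an unrooted topology
tree_signature <- function(phy) {
  paste(sort(tree_splits(phy)), collapse = ";")
}

same_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) &&
    identical(tree_signature(a), tree_signature(b))
}

# Canonical Newick of the unrooted topology: root at the alphabetically
# first taxon and sort clades by their own canonical string.
canonical_newick <- function(phy) {
  ref <- sort(phy$tip.label)[1]
  phy2 <- tryCatch(ape::root(phy, outgroup = ref, resolve.root = TRUE),
                   error = function(e) phy)
  phy2$edge.length <- NULL
  kids <- split(phy2$edge[, 2], phy2$edge[, 1])
  ntip <- length(phy2$tip.label)
  rec <- function(v) {
    if (v <= ntip) return(phy2$tip.label[v])
    parts <- sort(vapply(kids[[as.character(v)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}

# Build a rooted phylo from a set of clades (as label vectors) plus the
# full label set; clades must be compatible (nested or disjoint).
tree_from_clades <- function(clades, labels) {
  rec <- function(set, clades) {
    inner <- clades[vapply(clades, function(cl)
      length(cl) < length(set) && all(cl %in% set), logical(1))]
    maximal <- inner[vapply(seq_along(inner), function(i)
      !any(vapply(seq_along(inner), function(j)
        j != i && all(inner[[i]] %in% inner[[j]]), logical(1))),
      logical(1))]
    used <- unlist(maximal)
    singles <- setdiff(set, used)
    ch <- c(lapply(maximal, function(cl) rec(cl, inner)),
            as.list(sort(singles)))
    ch <- ch[order(vapply(ch, identity, character(1)))]
    paste0("(", paste(unlist(ch), collapse = ","), ")")
  }
  txt <- paste0(rec(sort(labels), clades), ";")
  ape::read.tree(text = txt)
}

## ---- rearrangement moves ------------------------------------------------

# All trees one NNI away (internal-edge sibling swaps).
nni_neighbours <- function(phy) {
  ntip <- length(phy$tip.label)
  E <- phy$edge
  out <- list()
  internal <- which(E[, 2] > ntip)
  for (e in internal) {
    p <- E[e, 1]; v <- E[e, 2]
    sibs <- E[E[, 1] == p & E[, 2] != v, 2]
    vkids <- E[E[, 1] == v, 2]
    if (length(sibs) != 1 || length(vkids) < 2) next
    for (gk in vkids) {
      E2 <- E
      E2[E[, 1] == p & E[, 2] == sibs, 2] <- gk
      E2[E[, 1] == v & E[, 2] == gk, 2] <- sibs
      out[[length(out) + 1L]] <- new_phylo(E2, phy$tip.label, phy$Nnode)
    }
  }
  out
}

# Candidate (prune-node, pruned object) pairs for SPR/TBR.
spr_candidates <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(phy$edge[, 2], integer(0)) # all non-root nodes
  nodes[vapply(nodes, function(v) {
    tips <- if (v <= ntip) 1 else length(ape::extract.clade(phy, v)$tip.label)
    tips <= ntip - 2
  }, logical(1))]
}

# All rootings of an unrooted version of `sub` (for TBR reconnection).
subtree_rerootings <- function(sub) {
  if (is.character(sub) || length(sub$tip.label) <= 2) return(list(sub))
  un <- ape::unroot(sub)
  out <- list()
  seen <- character(0)
  for (e in seq_len(nrow(un$edge))) {
    child <- un$edge[e, 2]
    ntip <- length(un$tip.label)
    tips_below <- if (child <= ntip) un$tip.label[child]
                  else ape::extract.clade(un, child)$tip.label
    if (length(tips_below) == ntip) next
    r <- tryCatch(ape::root(un, outgroup = tips_below, resolve.root = TRUE),
                  error = function(err) NULL)
    if (is.null(r)) next
    key <- canonical_rooted_key(r)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- r
  }
  if (length(out) == 0) list(sub) else out
}

canonical_rooted_key <- function(phy) {
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  ntip <- length(phy$tip.label)
  rec <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    paste0("(", paste(sort(vapply(kids[[as.character(v)]], rec,
                                  character(1))), collapse = ","), ")")
  }
  rec(ntip + 1L)
}
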