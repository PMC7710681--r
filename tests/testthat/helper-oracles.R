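# Independent oracles: brute-force parsimony by exhaustive assignment
# enumeration, exhaustive rooted-binary-tree enumeration, and a cached run
# of the exact search on the packaged matrix.

# Minimum changes for every character by enumerating all internal-node
# state assignments (plus the implicit state-0 ancestor above the root).
# Missing leaves contribute no cost. Exponential in the node count; for
# small trees only.
oracle_length <- function(tree, matrix, per_character = FALSE) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1L
  tipstate <- matrix$cells[, match(tr$tip.label, matrix$taxa), drop = FALSE]
  nchar <- nrow(tipstate)
  best <- rep(Inf, nchar)
  for (code in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(code)[seq_len(nnode)])
    state_of <- function(v) internal[v - ntip]
    for (k in seq_len(nchar)) {
      cost <- state_of(root)            # stem change if root derived
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        sc <- if (ch <= ntip) tipstate[k, ch] else state_of(ch)
        if (is.na(sc)) next
        cost <- cost + (state_of(p) != sc)
      }
      if (cost < best[k]) best[k] <- cost
    }
  }
  best <- as.integer(best)
  if (per_character) best else sum(best)
}

# All rooted binary topologies over the given labels, as Newick strings,
# by sequential insertion on every edge (stem included).
all_rooted_trees <- function(labels) {
  stopifnot(length(labels) >= 2)
  trees <- list(list(labels[1], labels[2]))
  insert_everywhere <- function(node, leaf) {
    out <- list(list(node, leaf))       # above this node
    if (!is.character(node)) {
      for (l in insert_everywhere(node[[1]], leaf)) {
        out <- c(out, list(list(l, node[[2]])))
      }
      for (r in insert_everywhere(node[[2]], leaf)) {
        out <- c(out, list(list(node[[1]], r)))
      }
    }
    out
  }
  for (lab in labels[-(1:2)]) {
    trees <- unlist(lapply(trees, insert_everywhere, leaf = lab),
                    recursive = FALSE)
  }
  to_newick <- function(node) {
    if (is.character(node)) return(node)
    paste0("(", to_newick(node[[1]]), ",", to_newick(node[[2]]), ")")
  }
  vapply(trees, function(t) paste0(to_newick(t), ";"), character(1))
}

# Fitch parsimony via phangorn as a second, external oracle: the stem-model
# length on a rooted binary tree equals unrooted Fitch length after
# attaching an all-plesiomorphic outgroup leaf above the root.
phangorn_length <- function(tree, matrix) {
  skip_if_not_installed("phangorn")
  nwk <- format_tree(tree)
  aug <- parse_tree(paste0("(", sub(";$", "", nwk), ",OUTGROUP__);"))
  dat <- cbind(matrix$cells, `OUTGROUP__` = 0L)   # chars x (taxa + outgroup)
  dat <- ifelse(is.na(dat), "?", as.character(dat))
  dat <- t(dat)                                   # taxa as rows, as phyDat wants
  rownames(dat) <- c(matrix$taxa, "OUTGROUP__")
  phy <- phangorn::phyDat(dat, type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  as.integer(phangorn::parsimony(aug, phy, method = "fitch"))
}

# An isomorphic copy of a tree with every internal node's children reversed.
mirror_tree <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  to_newick <- function(v) {
    if (v <= ntip) return(tr$tip.label[v])
    kids <- rev(children[[as.character(v)]])
    paste0("(", paste(vapply(kids, to_newick, character(1)), collapse = ","), ")")
  }
  parse_tree(paste0(to_newick(ntip + 1L), ";"))
}

# Canonical string form of a clade set, for set comparisons in tests.
clade_key <- function(sets) {
  vapply(sets, paste, character(1), collapse = "\r")
}

# Cached fixture computations shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

fixture_resolved <- function() {
  if (is.null(.fixture_cache$resolved)) {
    .fixture_cache$resolved <- apply_polarity_policy(laophontodes_matrix())
  }
  .fixture_cache$resolved
}

fixture_search <- function() {
  if (is.null(.fixture_cache$search)) {
    .fixture_cache$search <- branch_and_bound(fixture_resolved(),
                                              time_budget = 600)
  }
  .fixture_cache$search
}
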