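# Root-constrained two-state parsimony on rooted trees with polytomies.
#
# Model: an implicit all-plesiomorphic ancestor sits above the root, joined
# to it by a stem edge on which a 0->1 change may occur. Per character the
# length is min(cost(root = 0), cost(root = 1) + 1), where cost() is the
# exact minimum-change dynamic programme over arbitrary-arity nodes (hard
# polytomies; Hartigan semantics). Missing leaves are unconstrained. A
# character derived in every taxon therefore costs a single origin -- on the
# stem -- rather than one origin per root child.

BIG <- 1e9

# DP tables; rows = nodes (tips first, ape numbering), cols = characters.
parsimony_dp <- function(tree, matrix) {
  check_leaves(tree, matrix)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  nchar <- nrow(matrix$cells)
  tipstate <- matrix$cells[, match(tr$tip.label, matrix$taxa), drop = FALSE]

  cost0 <- matrix(0, nrow = ntip + nnode, ncol = nchar)
  cost1 <- matrix(0, nrow = ntip + nnode, ncol = nchar)
  for (j in seq_len(ntip)) {
    s <- tipstate[, j]
    cost0[j, ] <- ifelse(is.na(s) | s == 0L, 0, BIG)
    cost1[j, ] <- ifelse(is.na(s) | s == 1L, 0, BIG)
  }
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    cost0[p, ] <- cost0[p, ] + pmin(cost0[ch, ], cost1[ch, ] + 1)
    cost1[p, ] <- cost1[p, ] + pmin(cost1[ch, ], cost0[ch, ] + 1)
  }
  list(tree = tr, cost0 = cost0, cost1 = cost1, root = ntip + 1L,
       ntip = ntip, nchar = nchar)
}

#' Parsimony length of a matrix on a cladogram
#'
#' Minimum total number of state changes the characters require on the
#' tree, summed over characters. Exact for arbitrary node arity (hard
#' polytomies), with the all-plesiomorphic ancestor above the root: a
#' character may change 0 to 1 on the stem edge, so an all-derived
#' character costs one step, matching its reading as an autapomorphy of the
#' whole group. Missing cells are unconstrained.
#'
#' @param tree Rooted `phylo`; leaf set must equal the matrix taxon set.
#' @param matrix A `resolved_matrix` (see [apply_polarity_policy()]).
#' @param per_character If `TRUE`, return the integer vector of
#'   per-character steps instead of their sum.
#' @return Integer number of steps (or vector if `per_character`).
#' @export
#' @examples
#' r <- apply_polarity_policy(laophontodes_matrix())
#' parsimony_length(reference_cladogram(), r)
parsimony_length <- function(tree, matrix, per_character = FALSE) {
  dp <- parsimony_dp(tree, matrix)
  len <- pmin(dp$cost0[dp$root, ], dp$cost1[dp$root, ] + 1)
  len <- as.integer(len)
  if (per_character) {
    names(len) <- matrix$characters$id
    len
  } else {
    sum(len)
  }
}

#' Ancestral reconstruction: placing origins and reversals on edges
#'
#' Computes, for every character, a most-parsimonious assignment of states
#' to internal nodes and reads off the edges on which the derived state
#' arises (origins, 0 to 1) or is lost again (reversals, 1 to 0). Ties are
#' broken by the placement policy: `"delay-changes"` (default) keeps the
#' parental state where possible, pushing changes towards the leaves and
#' preferring independent convergent origins over origin-plus-reversal --
#' secondary re-development of a lost structure being possible but
#' improbable; `"accelerate-changes"` prefers the earliest possible origin,
#' accepting reversals below it.
#'
#' @inheritParams parsimony_length
#' @param placement `"delay-changes"` or `"accelerate-changes"`.
#' @return A list of class `reconstruction_set`; one element per character,
#'   each a list with `char_id`, `origin_edges` and `reversal_edges` (lists
#'   of leaf sets subtended by the edge; the whole taxon set denotes the
#'   stem edge), `origin_count`, and `steps`.
#' @export
#' @examples
#' r <- apply_polarity_policy(laophontodes_matrix())
#' rec <- reconstruct(reference_cladogram(), r)
#' rec[[17]]$origin_count   # body-somite extension arises twice
reconstruct <- function(tree, matrix,
                        placement = c("delay-changes", "accelerate-changes")) {
  placement <- match.arg(placement)
  dp <- parsimony_dp(tree, matrix)
  tr <- dp$tree
  nnodes <- nrow(dp$cost0)
  nchar <- dp$nchar
  c0r <- dp$cost0[dp$root, ]; c1r <- dp$cost1[dp$root, ]

  state <- matrix(NA_integer_, nrow = nnodes, ncol = nchar)
  state[dp$root, ] <- if (placement == "delay-changes") {
    ifelse(c1r + 1 < c0r, 1L, 0L)
  } else {
    ifelse(c1r + 1 <= c0r, 1L, 0L)
  }
  # preorder = reverse postorder edge sweep
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sp <- state[p, ]
    keep <- ifelse(sp == 0L, dp$cost0[ch, ], dp$cost1[ch, ])
    move <- ifelse(sp == 0L, dp$cost1[ch, ], dp$cost0[ch, ]) + 1
    state[ch, ] <- if (placement == "delay-changes") {
      ifelse(move < keep, 1L - sp, sp)
    } else {
      ifelse(keep < move, sp, 1L - sp)
    }
  }

  # leaf sets under each node, for naming edges by their subtended clade
  leafsets <- vector("list", nnodes)
  for (j in seq_len(dp$ntip)) leafsets[[j]] <- tr$tip.label[j]
  for (e in seq_len(nrow(tr$edge))) {   # postorder: children ready first
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    leafsets[[p]] <- c(leafsets[[p]], leafsets[[ch]])
  }
  leafsets <- lapply(leafsets, sort)

  out <- vector("list", nchar)
  for (k in seq_len(nchar)) {
    origins <- list(); reversals <- list()
    if (state[dp$root, k] == 1L) origins <- list(leafsets[[dp$root]])
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (state[p, k] == 0L && state[ch, k] == 1L) {
        origins <- c(origins, list(leafsets[[ch]]))
      } else if (state[p, k] == 1L && state[ch, k] == 0L) {
        reversals <- c(reversals, list(leafsets[[ch]]))
      }
    }
    out[[k]] <- list(char_id = matrix$characters$id[k],
                     origin_edges = origins, reversal_edges = reversals,
                     origin_count = length(origins),
                     steps = length(origins) + length(reversals))
  }
  names(out) <- matrix$characters$id
  structure(out, class = "reconstruction_set", placement = placement)
}

#' @export
print.reconstruction_set <- function(x, ...) {
  oc <- vapply(x, `[[`, 1L, "origin_count")
  cat(sprintf("Character reconstruction (%s): %d characters, %d steps total\n",
              attr(x, "placement"), length(x),
              sum(vapply(x, `[[`, 1L, "steps"))))
  multi <- names(oc)[oc > 1]
  if (length(multi)) {
    cat("  characters with >1 origin (convergences):",
        paste(multi, collapse = ", "), "\n")
  } else {
    cat("  no character requires more than one origin\n")
  }
  invisible(x)
}

#' Characters requiring more than one origin on a tree
#'
#' A character whose derived state must arise independently more than once
#' on the tree is convergent (homoplastic) with respect to that topology.
#'
#' @inheritParams parsimony_length
#' @return Sorted integer vector of character ids with more than one origin
#'   under the delay-changes reconstruction.
#' @export
#' @examples
#' r <- apply_polarity_policy(laophontodes_matrix())
#' convergent_characters(reference_cladogram(), r)
convergent_characters <- function(tree, matrix) {
  rec <- reconstruct(tree, matrix, placement = "delay-changes")
  ids <- vapply(rec, `[[`, 1L, "char_id")
  sort(unname(ids[vapply(rec, `[[`, 1L, "origin_count") > 1]))
}

char_min_steps <- function(matrix) {
  # one origin suffices on some tree for any character with >= 1 derived cell
  as.integer(rowSums(matrix$cells == 1L, na.rm = TRUE) > 0)
}

char_max_steps <- function(matrix) {
  # the star tree maximises steps: min(k, m0 + 1) per character
  k <- rowSums(matrix$cells == 1L, na.rm = TRUE)
  m0 <- rowSums(matrix$cells == 0L, na.rm = TRUE)
  as.integer(ifelse(k == 0, 0L, pmin(k, m0 + 1)))
}

#' Homoplasy indices
#'
#' `consistency_index()`: the ratio of the minimum conceivable step count
#' (one origin per character present) to the steps required on the given
#' tree; 1 means no homoplasy. `retention_index()`: the fraction of
#' potential synapomorphy retained as synapomorphy, `(g - s) / (g - m)`
#' with `s` the observed steps, `m` the minimum, and `g` the maximum (the
#' star-tree step count), summed over characters.
#'
#' @inheritParams parsimony_length
#' @return A single ratio in `[0, 1]`, or `NA` with attribute
#'   `undefined = TRUE` when the denominator is zero (e.g. a matrix without
#'   derived states).
#' @export
#' @examples
#' r <- apply_polarity_policy(laophontodes_matrix())
#' consistency_index(reference_cladogram(), r)
consistency_index <- function(tree, matrix) {
  s <- sum(parsimony_length(tree, matrix, per_character = TRUE))
  m <- sum(char_min_steps(matrix))
  if (s == 0) return(structure(NA_real_, undefined = TRUE))
  m / s
}

#' @rdname consistency_index
#' @export
retention_index <- function(tree, matrix) {
  s <- sum(parsimony_length(tree, matrix, per_character = TRUE))
  m <- sum(char_min_steps(matrix))
  g <- sum(char_max_steps(matrix))
  if (g == m) return(structure(NA_real_, undefined = TRUE))
  (g - s) / (g - m)
}
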