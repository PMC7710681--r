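#' Parse and format rooted cladograms
#'
#' Thin, validating wrappers around the Newick reader/writer of \pkg{ape}.
#' Trees are plain `phylo` objects; polytomies are allowed and kept; branch
#' lengths are ignored. The root is read as the hypothetical ancestor
#' carrying the plesiomorphic state of every character.
#'
#' @param newick A Newick string (terminating `;` optional).
#' @return `parse_tree()`: a `phylo`; `format_tree()`: a Newick string.
#' @export
#' @examples
#' tr <- parse_tree("(A,(B,C));")
#' format_tree(tr)
parse_tree <- function(newick) {
  if (!grepl(";\\s*$", newick)) newick <- paste0(newick, ";")
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = newick)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string: ", substr(newick, 1, 60), call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' @rdname parse_tree
#' @param tree A `phylo` object.
#' @export
format_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- NULL
  tree$node.label <- NULL
  ape::write.tree(tree)
}

#' Nontrivial clades of a rooted tree
#'
#' The label sets of all internal nodes other than the root: clades with at
#' least 2 and fewer than all leaves. Polytomies contribute only the clades
#' they actually contain.
#'
#' @param tree A rooted `phylo`.
#' @return List of sorted character vectors, one per nontrivial clade.
#' @export
clade_sets <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- lapply(parts, function(i) sort(labs[i]))
  out[vapply(out, length, 1L) < length(labs)]
}

clade_key <- function(sets) vapply(sets, paste, character(1), collapse = "\r")

#' Robinson-Foulds distance between rooted trees
#'
#' Rooted variant: the size of the symmetric difference of the two trees'
#' nontrivial clade sets (see [clade_sets()]).
#'
#' @param a,b Rooted `phylo` objects over the same leaf set.
#' @return Non-negative integer.
#' @export
#' @examples
#' rf_distance(parse_tree("(A,(B,C));"), parse_tree("((A,B),C);"))
rf_distance <- function(a, b) {
  stopifnot(inherits(a, "phylo"), inherits(b, "phylo"))
  if (!setequal(a$tip.label, b$tip.label)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(a$tip.label, b$tip.label),
                 setdiff(b$tip.label, a$tip.label)), collapse = ", "),
         call. = FALSE)
  }
  ka <- clade_key(clade_sets(a))
  kb <- clade_key(clade_sets(b))
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Build the minimal rooted tree displaying a set of clades
#'
#' Given pairwise compatible clades (each a subset of `taxa`, sizes 2 to
#' `length(taxa) - 1`), returns the unique minimal rooted tree whose
#' nontrivial clades are exactly the given ones; taxa contained in no clade
#' attach at the root polytomy.
#'
#' @param clades List of character vectors.
#' @param taxa Character vector of all leaf labels.
#' @return A `phylo`.
#' @export
#' @examples
#' tree_from_clades(list(c("A", "B"), c("A", "B", "C")), c("A", "B", "C", "D"))
tree_from_clades <- function(clades, taxa) {
  taxa <- as.character(taxa)
  clades <- unique(lapply(clades, function(s) sort(as.character(s))))
  for (s in clades) {
    if (!all(s %in% taxa)) stop("clade contains unknown taxa", call. = FALSE)
    if (length(s) < 2 || length(s) >= length(taxa)) {
      stop("clades must have >= 2 and < all taxa", call. = FALSE)
    }
  }
  n <- length(clades)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!characters_compatible(clades[[i]], clades[[j]])) {
        stop("incompatible clade pair: {",
             paste(clades[[i]], collapse = ","), "} vs {",
             paste(clades[[j]], collapse = ","), "}", call. = FALSE)
      }
    }
  }
  build <- function(set, avail) {
    inside <- avail[vapply(avail, function(s) all(s %in% set) && length(s) < length(set), TRUE)]
    if (length(inside) == 0) {
      maximal <- list()
    } else {
      maximal <- inside[vapply(seq_along(inside), function(i) {
        !any(vapply(seq_along(inside), function(j) {
          i != j && all(inside[[i]] %in% inside[[j]]) &&
            length(inside[[j]]) > length(inside[[i]])
        }, TRUE))
      }, TRUE)]
      maximal <- unique(maximal)
    }
    covered <- unlist(maximal)
    singles <- setdiff(set, covered)
    parts <- c(vapply(maximal, function(s) build(s, inside), character(1)), singles)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- if (length(taxa) == 1) paste0("(", taxa, ")") else build(taxa, clades)
  parse_tree(paste0(nwk, ";"))
}

#' Strict consensus of rooted trees
#'
#' The tree containing exactly the nontrivial clades present in every input
#' tree.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`) sharing one
#'   leaf set.
#' @return A `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) stop("no trees given", call. = FALSE)
  taxa <- sort(trees[[1]]$tip.label)
  keys <- lapply(trees, function(tr) {
    if (!identical(sort(tr$tip.label), taxa)) {
      stop("trees do not share one leaf set", call. = FALSE)
    }
    clade_key(clade_sets(tr))
  })
  shared <- Reduce(intersect, keys)
  tree_from_clades(lapply(strsplit(shared, "\r"), identity), taxa)
}

#' The published Laophontodes cladogram
#'
#' The reference topology of the genus-level analysis: *L. whitsoni*,
#' *L. macclintocki* and *L. sabinegeorgeae* attach at the root (their
#' mutual relationships are unresolved), a nine-species clade is supported
#' by the chirocer male antennule and the loss of the outer seta on the
#' female P4 endopod, and progressively nested clades of 8, 6, 4, 3, and 2
#' species follow; *L. spongiosus* and *L. gertraudae* sit in an unresolved
#' trichotomy with the four-species clade.
#'
#' @param variant `"polytomy"` (default): the three early species in a root
#'   polytomy, reflecting that their relationships are unresolved;
#'   `"ladder"`: the alternative reading with *L. whitsoni* branching first.
#' @return A rooted `phylo` with 12 leaves.
#' @export
#' @examples
#' reference_cladogram()
reference_cladogram <- function(variant = c("polytomy", "ladder")) {
  variant <- match.arg(variant)
  core <- paste0("(monsmaris,((mourois,typicus),(spongiosus,gertraudae,",
                 "(georgei,(volkerlehmanskii,(sarsi,scottorum))))))")
  nwk <- if (variant == "polytomy") {
    paste0("(whitsoni,macclintocki,sabinegeorgeae,", core, ");")
  } else {
    paste0("(whitsoni,(macclintocki,sabinegeorgeae,", core, "));")
  }
  parse_tree(nwk)
}

# leaf-set / taxon-set agreement check shared by the parsimony operations
check_leaves <- function(tree, matrix) {
  a <- setdiff(tree$tip.label, matrix$taxa)
  b <- setdiff(matrix$taxa, tree$tip.label)
  if (length(a) + length(b) > 0) {
    stop("tree leaves and matrix taxa differ; only in tree: {",
         paste(a, collapse = ", "), "}, only in matrix: {",
         paste(b, collapse = ", "), "}", call. = FALSE)
  }
  invisible(TRUE)
}
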