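# Seeded simulator of binary polarity-coded characters on random rooted
# trees, with convergence modelled as a second independent origin (never a
# reversal) and optional missing/uncertainty codes -- the structure of a
# small morphological matrix: binary polarity, rare convergence, sparse
# missing data.

#' Simulation configuration
#'
#' Defaults emulate the packaged 12-species, 39-character analysis: about
#' one character in ten carries a second convergent origin (4 of 38
#' informative characters there), and roughly half a percent of cells are
#' missing or uncertain (3 uncertain + 2 missing of 468 cells there).
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param n_chars Number of characters (>= 1).
#' @param homoplasy_fraction Probability that a character receives a second,
#'   independent origin, in `[0, 1]`.
#' @param missing_rate Per-cell probability of `?`, in `[0, 1]`.
#' @param uncertainty_rate Per-cell probability of downgrading `1` to `1?`
#'   or `0` to `0?`, in `[0, 1]`.
#' @param seed Integer seed; identical configurations give identical output.
#' @param coverage `"random"`: every origin edge drawn uniformly;
#'   `"clades"`: the first characters are assigned one per internal
#'   non-root edge (one clean synapomorphy per true clade), the remainder
#'   drawn at random.
#' @param include_stem If `TRUE`, the stem edge is a candidate origin, so
#'   all-derived characters can arise; off by default.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 12, n_chars = 39,
                              homoplasy_fraction = 4 / 39,
                              missing_rate = 0.005, uncertainty_rate = 0.005,
                              seed = 1, coverage = c("random", "clades"),
                              include_stem = FALSE) {
  coverage <- match.arg(coverage)
  stopifnot(n_taxa >= 3, n_chars >= 1,
            homoplasy_fraction >= 0, homoplasy_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            uncertainty_rate >= 0, uncertainty_rate <= 1)
  structure(list(n_taxa = as.integer(n_taxa), n_chars = as.integer(n_chars),
                 homoplasy_fraction = homoplasy_fraction,
                 missing_rate = missing_rate,
                 uncertainty_rate = uncertainty_rate,
                 seed = as.integer(seed), coverage = coverage,
                 include_stem = include_stem),
            class = "simulation_config")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample a random rooted binary tree
#'
#' Sequential uniform leaf addition: starting from two leaves, each further
#' leaf attaches on an edge chosen uniformly at random (the stem above the
#' root included). Deterministic per seed.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Integer seed.
#' @param labels Optional leaf labels (default `t1 ... tn`).
#' @return A rooted binary `phylo`.
#' @export
#' @examples
#' format_tree(sample_tree(5, seed = 42))
sample_tree <- function(n_taxa, seed, labels = NULL) {
  if (n_taxa < 3) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  with_seed(seed, {
    # node arrays as in the C search: leaves 1..n, internals n+1..
    parent <- integer(2 * n_taxa); left <- integer(2 * n_taxa)
    right <- integer(2 * n_taxa)
    root <- n_taxa + 1L
    left[root] <- 1L; right[root] <- 2L
    parent[1:2] <- root
    nodes <- c(1L, 2L, root)
    for (k in 3:n_taxa) {
      v <- n_taxa + k - 1L
      c0 <- nodes[sample.int(length(nodes), 1)]
      if (c0 == root) {
        left[v] <- root; right[v] <- k
        parent[root] <- v; parent[k] <- v
        root <- v
      } else {
        p <- parent[c0]
        if (left[p] == c0) left[p] <- v else right[p] <- v
        parent[v] <- p; left[v] <- c0; right[v] <- k
        parent[c0] <- v; parent[k] <- v
      }
      nodes <- c(nodes, k, v)
    }
    to_newick <- function(v) {
      if (v <= n_taxa) return(labels[v])
      paste0("(", to_newick(left[v]), ",", to_newick(right[v]), ")")
    }
    parse_tree(paste0(to_newick(root), ";"))
  })
}

tip_descendants <- function(tree) {
  # list: for each node, the tip labels below it (postorder fill)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  sets <- vector("list", ntip + tr$Nnode)
  for (j in seq_len(ntip)) sets[[j]] <- tr$tip.label[j]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  list(tree = tr, sets = lapply(sets, sort))
}

#' Evolve a polarity-coded matrix on a tree
#'
#' Each character picks one edge of the tree as the origin of its derived
#' state: every leaf below that edge is scored 1, all others 0. With
#' probability `homoplasy_fraction` a second, independent origin is added
#' on an edge neither ancestral nor descendant to (nor sibling of) the
#' first, so the two derived patches are disjoint and remain separately
#' reconstructible; if no such edge exists the character is regenerated
#' (with a message). Missing (`?`) and uncertainty (`1?`/`0?`) codes are
#' then applied cell-wise at their configured rates. The generating truth
#' is recorded alongside the matrix.
#'
#' @param tree A rooted binary `phylo`.
#' @param config A [simulation_config()].
#' @return List with `matrix` (a [character_matrix]) and `truth` (list:
#'   `true_tree`, `true_origins` -- per character the list of origin leaf
#'   sets -- and `convergent_ids`).
#' @export
#' @examples
#' tr <- sample_tree(8, seed = 3)
#' sim <- evolve_matrix(tr, simulation_config(n_taxa = 8, n_chars = 12, seed = 3))
evolve_matrix <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "simulation_config"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("tree must be rooted and binary", call. = FALSE)
  }
  td <- tip_descendants(tree)
  tr <- td$tree; sets <- td$sets
  taxa <- tr$tip.label
  ntip <- length(taxa)
  root <- ntip + 1L
  nedges <- nrow(tr$edge)
  edge_child <- tr$edge[, 2]

  # ancestor/descendant test via leaf sets (disjoint = neither)
  related <- function(i, j) {
    a <- sets[[edge_child[i]]]; b <- sets[[edge_child[j]]]
    any(a %in% b)
  }
  siblings <- function(i, j) tr$edge[i, 1] == tr$edge[j, 1]

  with_seed(config$seed + 1L, {
    nch <- config$n_chars
    cells <- matrix("0", nrow = nch, ncol = ntip,
                    dimnames = list(seq_len(nch), taxa))
    true_origins <- vector("list", nch)
    convergent <- integer(0)

    internal_nonroot <- which(edge_child > ntip)
    fixed <- if (config$coverage == "clades") {
      internal_nonroot[seq_len(min(length(internal_nonroot), nch))]
    } else {
      integer(0)
    }

    for (k in seq_len(nch)) {
      if (k <= length(fixed)) {
        e1 <- fixed[k]
        origins <- list(sets[[edge_child[e1]]])
      } else {
        attempts <- 0
        repeat {
          attempts <- attempts + 1
          pool <- if (config$include_stem) c(0L, seq_len(nedges)) else seq_len(nedges)
          e1 <- pool[sample.int(length(pool), 1)]
          two <- stats::runif(1) < config$homoplasy_fraction
          if (!two) {
            origins <- list(if (e1 == 0L) sort(taxa) else sets[[edge_child[e1]]])
            break
          }
          if (e1 == 0L) {         # everything descends from the stem
            if (attempts >= 100) stop("cannot place a second origin")
            next
          }
          valid <- Filter(function(j) {
            j != e1 && !related(e1, j) && !siblings(e1, j)
          }, seq_len(nedges))
          if (length(valid) == 0) {
            if (attempts >= 100) stop("cannot place a second origin")
            message("character ", k, ": no disjoint edge for a second origin; regenerated")
            next
          }
          e2 <- valid[sample.int(length(valid), 1)]
          origins <- list(sets[[edge_child[e1]]], sets[[edge_child[e2]]])
          convergent <- c(convergent, k)
          break
        }
      }
      true_origins[[k]] <- origins
      cells[k, unlist(origins)] <- "1"
    }

    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(length(cells)) < config$missing_rate,
                     nrow = nch)
      cells[drop] <- "?"
    }
    if (config$uncertainty_rate > 0) {
      unc <- matrix(stats::runif(length(cells)) < config$uncertainty_rate,
                    nrow = nch)
      cells[unc & cells == "1"] <- "1?"
      cells[unc & cells == "0"] <- "0?"
    }

    m <- character_matrix(
      taxa = taxa,
      characters = data.frame(
        id = seq_len(nch),
        description = paste0("simulated character ", seq_len(nch), " (derived)"),
        plesiomorphic_description = "ancestral"),
      cells = cells)
    list(matrix = m,
         truth = list(true_tree = tr,
                      true_origins = stats::setNames(true_origins, seq_len(nch)),
                      convergent_ids = sort(convergent)))
  })
}

#' Generate a tree and matrix in one call
#'
#' @param config A [simulation_config()].
#' @return As [evolve_matrix()], the tree drawn by [sample_tree()] with the
#'   same seed.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- sample_tree(config$n_taxa, config$seed)
  evolve_matrix(tree, config)
}

#' Tree-recovery experiment
#'
#' For each replicate: simulate a dataset, run the exact search, and
#' compare the strict consensus of the optimal trees against the generating
#' tree. Reports per-replicate Robinson-Foulds distance and the optimal
#' length next to the true number of origins.
#'
#' @param config A [simulation_config()] (replicate `i` uses `seed + i`).
#' @param replicates Number of replicates.
#' @param time_budget Per-replicate search budget in seconds.
#' @return A data frame (class `recovery_experiment`) with columns
#'   `replicate`, `rf`, `best_length`, `true_length`, `exhausted`, and a
#'   `summary` attribute holding mean/min/max of `rf` and `best_length`.
#' @export
#' @examples
#' cfg <- simulation_config(n_taxa = 6, n_chars = 8, homoplasy_fraction = 0, seed = 5)
#' recovery_experiment(cfg, replicates = 3)
recovery_experiment <- function(config, replicates = 20, time_budget = 30) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_taxa > 12) {
    stop("recovery experiments use the exact search; keep n_taxa <= 12",
         call. = FALSE)
  }
  rows <- lapply(seq_len(replicates), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    ds <- simulate_dataset(cfg)
    res <- branch_and_bound(apply_polarity_policy(ds$matrix),
                            time_budget = time_budget)
    cons <- strict_consensus(res$best_trees)
    data.frame(replicate = i,
               rf = rf_distance(cons, ds$truth$true_tree),
               best_length = res$best_length,
               true_length = sum(lengths(ds$truth$true_origins)),
               exhausted = res$exhausted)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    metric = c("rf", "best_length"),
    mean = c(mean(out$rf), mean(out$best_length)),
    min = c(min(out$rf), min(out$best_length)),
    max = c(max(out$rf), max(out$best_length)))
  class(out) <- c("recovery_experiment", "data.frame")
  out
}
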