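#' Exact branch-and-bound search for most-parsimonious trees
#'
#' Finds the minimum parsimony length over all rooted binary topologies on
#' the matrix taxa (stem-edge root semantics as in [parsimony_length()]),
#' and collects all length-optimal trees up to a cap. Taxa are added in
#' order of decreasing derived-cell count; the initial upper bound is the
#' length of the cladogram built by [hennigian_analysis()] unless supplied.
#' The search is exact (`exhausted = TRUE`) when it covers the whole space
#' within the time budget; otherwise the incumbent result is returned with
#' `exhausted = FALSE`.
#'
#' @param matrix A `resolved_matrix`.
#' @param time_budget Wall-clock budget in seconds (default 60).
#' @param constraint Optional backbone `phylo`: only trees displaying every
#'   clade of the backbone are considered. Required above 15 taxa, where an
#'   unconstrained exact search is refused.
#' @param upper_bound Optional starting upper bound on tree length.
#' @param max_trees Cap on the number of co-optimal trees retained
#'   (default 10000); beyond it only the tie count grows.
#' @return A list of class `search_result`: `best_length`, `best_trees`
#'   (a `multiPhylo`), `nodes_examined`, `exhausted`, `tie_count`.
#' @export
#' @examples
#' cfg <- simulation_config(n_taxa = 6, n_chars = 10, seed = 7)
#' ds <- simulate_dataset(cfg)
#' branch_and_bound(apply_polarity_policy(ds$matrix))
branch_and_bound <- function(matrix, time_budget = 60, constraint = NULL,
                             upper_bound = NULL, max_trees = 10000) {
  stopifnot(inherits(matrix, "resolved_matrix"))
  n <- length(matrix$taxa)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  if (n > 15 && is.null(constraint)) {
    stop("exact search over ", n, " taxa is not feasible; supply a backbone ",
         "constraint tree (argument 'constraint') to restrict the space, or ",
         "reduce the taxon set", call. = FALSE)
  }
  ord <- order(-colSums(matrix$cells == 1L, na.rm = TRUE))
  taxa <- matrix$taxa[ord]
  states <- matrix$cells[, ord, drop = FALSE]

  if (is.null(upper_bound)) {
    upper_bound <- tryCatch({
      parsimony_length(hennigian_analysis(matrix)$tree, matrix)
    }, error = function(e) NULL)
    if (is.null(upper_bound)) {
      star <- parse_tree(paste0("(", paste(matrix$taxa, collapse = ","), ");"))
      upper_bound <- parsimony_length(star, matrix)
    }
  }

  masks <- integer(0)
  if (!is.null(constraint)) {
    check_leaves(constraint, matrix)
    masks <- vapply(clade_sets(constraint), function(s) {
      sum(bitwShiftL(1L, match(s, taxa) - 1L))
    }, 1L)
  }

  res <- .bnb_search(states, taxa, as.numeric(upper_bound),
                     as.numeric(time_budget), as.integer(masks),
                     as.integer(max_trees))
  if (length(res$trees) == 0 && res$exhausted) {
    # a user-supplied upper bound below the true optimum: redo unbounded
    res <- .bnb_search(states, taxa, sum(char_max_steps(matrix)) + 1,
                       as.numeric(time_budget), as.integer(masks),
                       as.integer(max_trees))
  }
  trees <- if (length(res$trees)) {
    ape::read.tree(text = paste(res$trees, collapse = "\n"))
  } else {
    NULL
  }
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  structure(list(best_length = as.integer(res$best_length),
                 best_trees = trees,
                 nodes_examined = res$nodes_examined,
                 exhausted = res$exhausted,
                 tie_count = res$tie_count),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Parsimony search: best length %d, %g co-optimal tree(s)%s, %g insertions examined, %s\n",
              x$best_length, x$tie_count,
              if (x$tie_count > length(x$best_trees))
                sprintf(" (%d kept)", length(x$best_trees)) else "",
              x$nodes_examined,
              if (x$exhausted) "search exhausted (exact)" else
                "time budget expired (incumbent only)"))
  invisible(x)
}
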