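#' Pairwise compatibility of two derived taxon sets
#'
#' Two binary rooted characters can both be single-origin synapomorphies on
#' one tree exactly when their derived taxon sets nest or are disjoint.
#' Overlap without nesting is character conflict: one of the two must be
#' convergent.
#'
#' @param setA,setB Character vectors of taxon labels.
#' @return `TRUE` if compatible.
#' @export
#' @examples
#' characters_compatible(c("A", "B"), c("A", "B", "C"))  # nested
#' characters_compatible(c("A", "B"), c("B", "C"))       # conflict
characters_compatible <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  all(a %in% b) || all(b %in% a) || !any(a %in% b)
}

#' Group taxa by shared derived character states
#'
#' The first step of Hennigian argumentation: each distinct derived taxon
#' set of size two or more becomes a clade hypothesis, supported by every
#' character sharing that set. Characters derived in a single taxon are
#' routed to that taxon's autapomorphy list; characters derived in every
#' taxon diagnose the whole group (clade-level autapomorphies); characters
#' derived nowhere are uninformative.
#'
#' Characters with missing cells are handled as in the source analyses:
#' under `missing_support = "observed"` (default) such a character supports
#' an existing hypothesis whose taxa lie between its observed derived set
#' and that set plus the missing taxa -- a species of unknown state does
#' not break an otherwise supported group -- and otherwise founds a
#' hypothesis on the observed set alone. `"strict"` demotes characters
#' with missing cells to unplaced.
#'
#' @param matrix A `resolved_matrix`.
#' @param missing_support `"observed"` or `"strict"`.
#' @return A list of class `synapomorphy_groups`: `hypotheses` (each with
#'   `taxa`, `chars`, `status`), `conflicts` (data frame of conflicting
#'   hypothesis pairs), `autapomorphies` (named list taxon -> char ids),
#'   `monophylum_chars`, `unplaced`.
#' @export
#' @examples
#' g <- group_by_synapomorphy(apply_polarity_policy(laophontodes_matrix()))
#' lengths(lapply(g$hypotheses, `[[`, "taxa"))
group_by_synapomorphy <- function(matrix,
                                  missing_support = c("observed", "strict")) {
  stopifnot(inherits(matrix, "resolved_matrix"))
  missing_support <- match.arg(missing_support)
  ids <- matrix$characters$id
  all_taxa <- matrix$taxa
  obs <- lapply(ids, function(i) sort(derived_taxon_set(matrix, i)))
  mis <- lapply(ids, function(i) sort(missing_taxon_set(matrix, i)))
  has_missing <- lengths(mis) > 0

  autapomorphies <- list()
  monophylum <- integer(0)
  unplaced <- integer(0)
  hypotheses <- list()
  hyp_key <- character(0)

  route_simple <- function(k) {
    # returns TRUE if the character was consumed by a non-hypothesis route
    d <- obs[[k]]
    if (length(d) == 0) { unplaced <<- c(unplaced, ids[k]); return(TRUE) }
    if (length(d) == 1) {
      autapomorphies[[d]] <<- c(autapomorphies[[d]], ids[k]); return(TRUE)
    }
    if (length(d) == length(all_taxa)) {
      monophylum <<- c(monophylum, ids[k]); return(TRUE)
    }
    FALSE
  }

  # pass 1: characters fully observed found hypotheses keyed by derived set
  for (k in seq_along(ids)) {
    if (has_missing[k]) next
    if (route_simple(k)) next
    key <- paste(obs[[k]], collapse = "\r")
    j <- match(key, hyp_key)
    if (is.na(j)) {
      hypotheses[[length(hypotheses) + 1]] <-
        list(taxa = obs[[k]], chars = ids[k], status = "candidate")
      hyp_key <- c(hyp_key, key)
    } else {
      hypotheses[[j]]$chars <- c(hypotheses[[j]]$chars, ids[k])
    }
  }
  # pass 2: characters with missing cells
  for (k in seq_along(ids)) {
    if (!has_missing[k]) next
    if (missing_support == "strict") { unplaced <- c(unplaced, ids[k]); next }
    if (route_simple(k)) next
    d <- obs[[k]]; reach <- c(d, mis[[k]])
    cand <- which(vapply(hypotheses, function(h) {
      all(d %in% h$taxa) && all(h$taxa %in% reach)
    }, TRUE))
    if (length(cand) > 0) {
      # prefer the best-supported host, then the tightest one
      j <- cand[order(-vapply(hypotheses[cand], function(h) length(h$chars), 1L),
                      vapply(hypotheses[cand], function(h) length(h$taxa), 1L))][1]
      hypotheses[[j]]$chars <- c(hypotheses[[j]]$chars, ids[k])
    } else {
      key <- paste(d, collapse = "\r")
      j <- match(key, hyp_key)
      if (is.na(j)) {
        hypotheses[[length(hypotheses) + 1]] <-
          list(taxa = d, chars = ids[k], status = "candidate")
        hyp_key <- c(hyp_key, key)
      } else {
        hypotheses[[j]]$chars <- c(hypotheses[[j]]$chars, ids[k])
      }
    }
  }

  conflicts <- data.frame(a = integer(0), b = integer(0))
  nh <- length(hypotheses)
  if (nh > 1) {
    for (i in seq_len(nh - 1)) for (j in (i + 1):nh) {
      if (!characters_compatible(hypotheses[[i]]$taxa, hypotheses[[j]]$taxa)) {
        conflicts <- rbind(conflicts, data.frame(a = i, b = j))
      }
    }
  }
  structure(list(hypotheses = hypotheses, conflicts = conflicts,
                 autapomorphies = autapomorphies,
                 monophylum_chars = sort(monophylum),
                 unplaced = sort(unplaced), taxa = all_taxa),
            class = "synapomorphy_groups")
}

#' @export
print.synapomorphy_groups <- function(x, ...) {
  cat(sprintf("Synapomorphy grouping: %d clade hypotheses, %d conflicting pairs\n",
              length(x$hypotheses), nrow(x$conflicts)))
  for (h in x$hypotheses) {
    cat(sprintf("  %2d taxa <- chars {%s}\n", length(h$taxa),
                paste(h$chars, collapse = ", ")))
  }
  invisible(x)
}

# Exact maximum-weight pairwise-compatible subset of hypotheses, solved per
# connected component of the conflict graph. Weight = number of supporting
# characters. Ties are broken by preferring the subset whose supporting
# character ids, sorted, are lexicographically smallest -- i.e. the lowest
# character ids win, which encodes the source analysis's preference for the
# chirocer-antennule grouping over the equally weighted setal losses.
select_compatible <- function(hypotheses, conflicts) {
  nh <- length(hypotheses)
  if (nh == 0) return(integer(0))
  adj <- vector("list", nh)
  for (r in seq_len(nrow(conflicts))) {
    a <- conflicts$a[r]; b <- conflicts$b[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(nh); cc <- 0
  for (s in seq_len(nh)) {
    if (comp[s] != 0) next
    cc <- cc + 1; queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0) next
      comp[v] <- cc
      queue <- c(queue, adj[[v]])
    }
  }
  w <- vapply(hypotheses, function(h) length(h$chars), 1L)
  chars_of <- function(sel) sort(unlist(lapply(hypotheses[sel], `[[`, "chars")))
  better <- function(sel_a, sel_b) {
    # is selection a better than b?
    wa <- sum(w[sel_a]); wb <- sum(w[sel_b])
    if (wa != wb) return(wa > wb)
    ca <- chars_of(sel_a); cb <- chars_of(sel_b)
    len <- min(length(ca), length(cb))
    if (len > 0) {
      d <- which(ca[seq_len(len)] != cb[seq_len(len)])
      if (length(d)) return(ca[d[1]] < cb[d[1]])
    }
    length(ca) > length(cb)
  }
  chosen <- integer(0)
  for (c0 in seq_len(cc)) {
    members <- which(comp == c0)
    best <- integer(0)
    search <- function(idx, sel) {
      if (idx > length(members)) {
        if (length(best) == 0 || better(sel, best)) best <<- sel
        return(invisible())
      }
      v <- members[idx]
      if (sum(w[c(sel, members[idx:length(members)])]) < sum(w[best])) {
        return(invisible())   # cannot beat incumbent even taking everything
      }
      if (!any(adj[[v]] %in% sel)) search(idx + 1, c(sel, v))
      search(idx + 1, sel)
    }
    search(1, integer(0))
    chosen <- c(chosen, best)
  }
  sort(chosen)
}

#' Arbitrate character conflicts by parsimony
#'
#' Resolves the conflicts found by [group_by_synapomorphy()]: the accepted
#' clade set is a maximum-weight pairwise-compatible subset of the
#' hypotheses (weight = number of supporting characters, ties broken in
#' favour of the lowest character ids), so that as few characters as
#' possible must be explained as convergences. Characters of rejected
#' hypotheses become convergences; their independent origins are read off a
#' reconstruction on the cladogram built from the accepted clades.
#'
#' @param groups A `synapomorphy_groups` object.
#' @param matrix The `resolved_matrix` the groups were derived from.
#' @return A list of class `argumentation_report`: `accepted` (clade
#'   hypotheses with supporting chars, outermost first), `autapomorphies`,
#'   `convergences` (char id -> list of origin leaf sets), `conflicts`
#'   (with resolution notes), `monophylum_chars`, `unplaced`, `tree`.
#' @export
#' @examples
#' r <- apply_polarity_policy(laophontodes_matrix())
#' rep <- arbitrate(group_by_synapomorphy(r), r)
#' names(rep$convergences)
arbitrate <- function(groups, matrix) {
  stopifnot(inherits(groups, "synapomorphy_groups"),
            inherits(matrix, "resolved_matrix"))
  keep <- select_compatible(groups$hypotheses, groups$conflicts)
  accepted <- groups$hypotheses[keep]
  rejected <- groups$hypotheses[setdiff(seq_along(groups$hypotheses), keep)]
  accepted <- lapply(accepted, function(h) { h$status <- "accepted"; h })
  order_by_size <- order(-vapply(accepted, function(h) length(h$taxa), 1L))
  accepted <- accepted[order_by_size]

  tree <- tree_from_clades(lapply(accepted, `[[`, "taxa"), groups$taxa)
  conv_ids <- sort(unlist(lapply(rejected, `[[`, "chars")))
  convergences <- list()
  if (length(conv_ids) > 0) {
    rec <- reconstruct(tree, matrix, placement = "delay-changes")
    all_ids <- vapply(rec, `[[`, 1L, "char_id")
    for (id in conv_ids) {
      convergences[[as.character(id)]] <- rec[[match(id, all_ids)]]$origin_edges
    }
  }
  notes <- character(0)
  if (nrow(groups$conflicts) > 0) {
    notes <- vapply(seq_len(nrow(groups$conflicts)), function(r) {
      i <- groups$conflicts$a[r]; j <- groups$conflicts$b[r]
      wini <- i %in% keep
      winner <- if (wini) i else if (j %in% keep) j else NA
      hi <- groups$hypotheses[[i]]; hj <- groups$hypotheses[[j]]
      if (is.na(winner)) {
        sprintf("chars {%s} vs {%s}: both rejected",
                paste(hi$chars, collapse = ","), paste(hj$chars, collapse = ","))
      } else {
        win <- groups$hypotheses[[winner]]
        lose <- if (wini) hj else hi
        sprintf("chars {%s} vs {%s}: kept {%s}; chars {%s} convergent",
                paste(hi$chars, collapse = ","), paste(hj$chars, collapse = ","),
                paste(win$chars, collapse = ","), paste(lose$chars, collapse = ","))
      }
    }, character(1))
  }
  conflicts <- groups$conflicts
  if (nrow(conflicts) > 0) conflicts$resolution <- notes

  structure(list(accepted = accepted, autapomorphies = groups$autapomorphies,
                 convergences = convergences, conflicts = conflicts,
                 monophylum_chars = groups$monophylum_chars,
                 unplaced = groups$unplaced, taxa = groups$taxa, tree = tree),
            class = "argumentation_report")
}

#' @export
print.argumentation_report <- function(x, ...) {
  cat("Hennigian argumentation report\n")
  if (length(x$monophylum_chars)) {
    cat("  whole-group (clade-level) autapomorphies: chars",
        paste(x$monophylum_chars, collapse = ", "), "\n")
  }
  cat(sprintf("  accepted clades (%d):\n", length(x$accepted)))
  for (h in x$accepted) {
    cat(sprintf("    %2d taxa {%s} <- chars {%s}\n", length(h$taxa),
                paste(h$taxa, collapse = ", "),
                paste(h$chars, collapse = ", ")))
  }
  cat("  convergent characters:",
      if (length(x$convergences)) paste(names(x$convergences), collapse = ", ")
      else "none", "\n")
  ntaxa_aut <- sum(lengths(x$autapomorphies))
  cat(sprintf("  autapomorphies: %d characters across %d taxa\n",
              ntaxa_aut, length(x$autapomorphies)))
  invisible(x)
}

#' Build the cladogram implied by an argumentation report
#'
#' The unique minimal rooted tree whose nontrivial clades are exactly the
#' accepted clades of the report; taxa supported into no clade attach at
#' the root polytomy.
#'
#' @param report An `argumentation_report` from [arbitrate()].
#' @param taxa Optional taxon ordering (defaults to the report's taxa).
#' @return A `phylo`.
#' @export
build_cladogram <- function(report, taxa = NULL) {
  stopifnot(inherits(report, "argumentation_report"))
  if (is.null(taxa)) taxa <- report$taxa
  tree_from_clades(lapply(report$accepted, `[[`, "taxa"), taxa)
}

#' One-call argumentation pipeline
#'
#' Runs [apply_polarity_policy()] (if needed), [group_by_synapomorphy()],
#' [arbitrate()] and [build_cladogram()] in sequence.
#'
#' @param matrix A [character_matrix] or `resolved_matrix`.
#' @param policy Polarity policy if `matrix` is unresolved.
#' @param missing_support Passed to [group_by_synapomorphy()].
#' @return List with `report` (the `argumentation_report`) and `tree`.
#' @export
#' @examples
#' res <- hennigian_analysis(laophontodes_matrix())
#' format_tree(res$tree)
hennigian_analysis <- function(matrix, policy = "as-argued",
                               missing_support = "observed") {
  if (inherits(matrix, "character_matrix")) {
    matrix <- apply_polarity_policy(matrix, policy)
  }
  groups <- group_by_synapomorphy(matrix, missing_support)
  report <- arbitrate(groups, matrix)
  list(report = report, tree = report$tree, matrix = matrix)
}
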