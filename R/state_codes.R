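#' Polarity state codes
#'
#' Cell values of a polarity-coded morphological matrix. Six codes are
#' recognised, serialized exactly as they appear in published character
#' tables:
#'
#' * `"0"`  -- plesiomorphic (ancestral) state
#' * `"1"`  -- apomorphic (derived) state
#' * `"?"`  -- no information available
#' * `"1?"` -- apomorphic, but the observation is uncertain
#' * `"0?"` -- plesiomorphic, but the observation is uncertain
#' * `"0*"` -- plesiomorphic, with the apomorphic state also present as
#'   intraspecific variability
#'
#' @return Character vector of the six serialized codes.
#' @export
#' @examples
#' state_codes()
state_codes <- function() {
  c(PLESIOMORPHIC = "0", APOMORPHIC = "1", MISSING = "?",
    APOMORPHIC_UNCERTAIN = "1?", PLESIOMORPHIC_UNCERTAIN = "0?",
    PLESIOMORPHIC_VARIABLE = "0*")
}

is_state_code <- function(x) x %in% state_codes()

#' Reduce uncertainty codes to plain binary states
#'
#' Maps a polarity-coded matrix onto the three-valued alphabet \{0, 1,
#' missing\} used by all downstream parsimony and grouping operations.
#'
#' Two policies are offered. `"as-argued"` follows the argued polarity of
#' each uncertain observation: `1?` is scored derived, `0?` plesiomorphic,
#' and `0*` plesiomorphic -- the variable appearance of the derived state
#' within a species is read as an intraspecific deviation, not as evidence
#' that the species belongs to the derived group. `"conservative"` demotes
#' all four non-plain codes (`?`, `1?`, `0?`, `0*`) to missing, for
#' sensitivity analysis.
#'
#' @param matrix A [character_matrix].
#' @param policy `"as-argued"` (default) or `"conservative"`.
#' @return A `resolved_matrix`: list with `taxa`, `characters`, and `cells`,
#'   an integer matrix (characters x taxa) over \{0, 1, `NA`\}, plus the
#'   applied `policy` name.
#' @export
#' @examples
#' m <- laophontodes_matrix()
#' r <- apply_polarity_policy(m)
#' r$cells[3, "whitsoni"]   # 0* scored plesiomorphic
apply_polarity_policy <- function(matrix, policy = c("as-argued", "conservative")) {
  stopifnot(inherits(matrix, "character_matrix"))
  policy <- match.arg(policy)
  map <- if (policy == "as-argued") {
    c("0" = 0L, "1" = 1L, "?" = NA_integer_, "1?" = 1L, "0?" = 0L, "0*" = 0L)
  } else {
    c("0" = 0L, "1" = 1L, "?" = NA_integer_,
      "1?" = NA_integer_, "0?" = NA_integer_, "0*" = NA_integer_)
  }
  cells <- matrix(map[matrix$cells], nrow = nrow(matrix$cells),
                  dimnames = dimnames(matrix$cells))
  structure(
    list(taxa = matrix$taxa, characters = matrix$characters,
         cells = cells, policy = policy),
    class = "resolved_matrix")
}

#' @export
print.resolved_matrix <- function(x, ...) {
  cat(sprintf("Resolved character matrix (policy '%s'): %d characters x %d taxa, %d missing cells\n",
              x$policy, nrow(x$cells), ncol(x$cells), sum(is.na(x$cells))))
  invisible(x)
}

#' Taxa carrying the derived state of a character
#'
#' Reads the derived (apomorphic) taxon set of one character off a resolved
#' matrix. Missing cells are excluded: a taxon scored `?` is neither inside
#' nor outside the set.
#'
#' @param matrix A `resolved_matrix` from [apply_polarity_policy()].
#' @param char_id Integer character id (1-based, as in the matrix).
#' @return Character vector of taxon labels whose cell equals 1.
#' @export
#' @examples
#' r <- apply_polarity_policy(laophontodes_matrix())
#' derived_taxon_set(r, 8)   # the six species sharing the loss on P2exp-3
derived_taxon_set <- function(matrix, char_id) {
  stopifnot(inherits(matrix, "resolved_matrix"))
  i <- match(char_id, matrix$characters$id)
  if (is.na(i)) {
    stop("unknown character id: ", char_id, call. = FALSE)
  }
  row <- matrix$cells[i, ]
  matrix$taxa[!is.na(row) & row == 1L]
}

#' Taxa with a missing cell for a character
#' @noRd
missing_taxon_set <- function(matrix, char_id) {
  i <- match(char_id, matrix$characters$id)
  if (is.na(i)) stop("unknown character id: ", char_id, call. = FALSE)
  matrix$taxa[is.na(matrix$cells[i, ])]
}
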