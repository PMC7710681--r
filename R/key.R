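#' Construct a dichotomous identification key
#'
#' A key is a numbered set of couplets; each couplet offers two contrasting
#' leads, and each lead points either to another couplet or to a terminal
#' taxon. Lead order follows the printed convention: the first lead is the
#' un-dashed line.
#'
#' @param couplets A list, one element per couplet, each a list with
#'   integer `id` and two leads `a` and `b`; a lead is a list with `text`
#'   and either `goto` (a couplet id) or `taxon` (a label).
#' @param start Id of the starting couplet (default: the first).
#' @return An object of class `dichotomous_key`.
#' @export
#' @examples
#' k <- dichotomous_key(list(
#'   list(id = 1,
#'        a = list(text = "seta present", taxon = "A"),
#'        b = list(text = "seta absent", taxon = "B"))))
#' validate_key(k)
dichotomous_key <- function(couplets, start = NULL) {
  ids <- vapply(couplets, function(cp) as.integer(cp$id), 1L)
  if (anyDuplicated(ids)) stop("duplicate couplet ids", call. = FALSE)
  couplets <- lapply(couplets, function(cp) {
    for (side in c("a", "b")) {
      lead <- cp[[side]]
      if (is.null(lead$text) || (is.null(lead$goto) && is.null(lead$taxon))) {
        stop("couplet ", cp$id, " lead ", side,
             " needs text and a goto/taxon target", call. = FALSE)
      }
      if (!is.null(lead$goto)) lead$goto <- as.integer(lead$goto)
      cp[[side]] <- lead
    }
    cp$id <- as.integer(cp$id)
    cp
  })
  names(couplets) <- ids
  structure(list(couplets = couplets,
                 start = as.integer(if (is.null(start)) ids[1] else start)),
            class = "dichotomous_key")
}

key_taxa <- function(key) {
  unlist(lapply(key$couplets, function(cp) {
    c(cp$a$taxon, cp$b$taxon)
  }), use.names = FALSE)
}

#' @export
print.dichotomous_key <- function(x, ...) {
  cat(sprintf("Dichotomous key: %d couplets, %d terminal taxa (start at %d)\n",
              length(x$couplets), length(key_taxa(x)), x$start))
  invisible(x)
}

#' The published key to Laophontodes species
#'
#' Packaged transcription of the diagnostic key to the twelve species
#' analysed in the genus study: couplets 1--11, lead texts verbatim from the
#' printed key (which also uses characters absent from the character
#' matrix, such as the shape of the anal-operculum spinules).
#'
#' @return A [dichotomous_key()] over the epithet labels of
#'   [laophontodes_taxa()].
#' @export
#' @examples
#' identify_taxon(laophontodes_key(), c("b"))
laophontodes_key <- function() {
  read_key(system.file("extdata", "laophontodes_key.yaml", package = "hennig",
                       mustWork = TRUE))
}

#' Read and write keys as YAML
#'
#' @param path File path.
#' @return `read_key()`: a `dichotomous_key`; `write_key()`: `path`,
#'   invisibly.
#' @export
read_key <- function(path) {
  y <- yaml::read_yaml(path)
  dichotomous_key(y$couplets, start = y$start)
}

#' @rdname read_key
#' @param key A `dichotomous_key`.
#' @export
write_key <- function(key, path) {
  stopifnot(inherits(key, "dichotomous_key"))
  yaml::write_yaml(list(start = key$start, couplets = unname(key$couplets)),
                   path)
  invisible(path)
}

#' Validate a dichotomous key
#'
#' Checks the structural invariants: every couplet has two leads with
#' resolvable targets, every couplet is reachable from the start, no
#' couplet can reach itself (the key is acyclic), every non-start couplet
#' is entered by exactly one lead, and every taxon terminates exactly one
#' lead. Problems are report rows, not errors.
#'
#' @param key A `dichotomous_key`.
#' @return Data frame with columns `check`, `couplet`, `detail`; zero rows
#'   means the key is valid.
#' @export
#' @examples
#' nrow(validate_key(laophontodes_key()))  # 0
validate_key <- function(key) {
  stopifnot(inherits(key, "dichotomous_key"))
  v <- data.frame(check = character(0), couplet = integer(0),
                  detail = character(0))
  note <- function(check, couplet, detail) {
    v <<- rbind(v, data.frame(check = check, couplet = couplet, detail = detail))
  }
  ids <- as.integer(names(key$couplets))
  if (!key$start %in% ids) {
    note("start", key$start, "start couplet does not exist")
    return(v)
  }
  entered <- integer(0)
  for (cp in key$couplets) {
    for (side in c("a", "b")) {
      g <- cp[[side]]$goto
      if (!is.null(g)) {
        if (!g %in% ids) {
          note("dangling-target", cp$id,
               sprintf("lead %s points to missing couplet %d", side, g))
        } else {
          entered <- c(entered, g)
        }
      }
    }
  }
  dup <- unique(entered[duplicated(entered)])
  for (d in dup) note("multiple-entry", d, "couplet is the target of more than one lead")
  if (key$start %in% entered) {
    note("start-entered", key$start, "start couplet is the target of a lead")
  }
  # reachability and cycles from start
  seen <- integer(0); stack <- key$start
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur %in% seen || !cur %in% ids) next
    seen <- c(seen, cur)
    cp <- key$couplets[[as.character(cur)]]
    stack <- c(stack, unlist(c(cp$a$goto, cp$b$goto)))
  }
  for (u in setdiff(ids, seen)) note("unreachable", u, "couplet cannot be reached from start")
  # cycle check: DFS colouring
  state <- stats::setNames(rep(0L, length(ids)), ids)
  cyc <- FALSE
  visit <- function(id) {
    if (state[as.character(id)] == 1L) { cyc <<- TRUE; return(invisible()) }
    if (state[as.character(id)] == 2L) return(invisible())
    state[as.character(id)] <<- 1L
    cp <- key$couplets[[as.character(id)]]
    for (g in c(cp$a$goto, cp$b$goto)) if (!is.null(g) && g %in% ids) visit(g)
    state[as.character(id)] <<- 2L
  }
  visit(key$start)
  if (cyc) note("cycle", NA_integer_, "a couplet is reachable from itself")
  taxa <- key_taxa(key)
  for (t in unique(taxa[duplicated(taxa)])) {
    note("duplicate-terminal", NA_integer_,
         sprintf("taxon '%s' terminates more than one lead", t))
  }
  v
}

#' Traverse a key with a sequence of choices
#'
#' Follows leads from the start couplet: choice `"a"` takes the first lead,
#' `"b"` the second. Stops at a terminal taxon or when the choices run out.
#'
#' @param key A `dichotomous_key`.
#' @param choices Character vector over `c("a", "b")` (may be empty).
#' @return List with `taxon` (label, or `NA` if not yet resolved),
#'   `pending` (next couplet id, or `NA` once resolved), and `path` (the
#'   couplet ids visited).
#' @export
#' @examples
#' identify_taxon(laophontodes_key(), c("a", "b", "b", "b", "b", "b"))$taxon
identify_taxon <- function(key, choices = character(0)) {
  stopifnot(inherits(key, "dichotomous_key"))
  choices <- as.character(choices)
  if (!all(choices %in% c("a", "b"))) {
    stop("choices must be 'a' or 'b'", call. = FALSE)
  }
  cur <- key$start
  path <- integer(0)
  for (i in seq_along(choices)) {
    if (is.na(cur)) {
      stop(sprintf("trailing input: %d choice(s) left after reaching a taxon",
                   length(choices) - i + 1L), call. = FALSE)
    }
    cp <- key$couplets[[as.character(cur)]]
    path <- c(path, cur)
    lead <- cp[[choices[i]]]
    if (!is.null(lead$taxon)) {
      cur <- NA_integer_
      taxon <- lead$taxon
    } else {
      cur <- lead$goto
      taxon <- NA_character_
    }
  }
  if (length(choices) == 0 || !is.na(cur)) {
    return(list(taxon = NA_character_, pending = cur, path = path))
  }
  list(taxon = taxon, pending = NA_integer_, path = path)
}

#' Generate a dichotomous key from a character matrix
#'
#' Greedy construction: at each step the character whose derived taxon set
#' splits the remaining taxa most evenly is chosen (ties go to the lowest
#' character id); the derived lead comes first. Characters with a missing
#' cell among the remaining taxa are skipped at that step, since a lead
#' must decide every remaining taxon. Fails with the offending pair if two
#' taxa cannot be separated by any character.
#'
#' @param matrix A `resolved_matrix`.
#' @param descriptions Optional data frame (like `matrix$characters`) used
#'   for the lead texts.
#' @return A `dichotomous_key` identifying every taxon of the matrix.
#' @export
#' @examples
#' k <- generate_key(apply_polarity_policy(laophontodes_matrix()))
#' nrow(validate_key(k))
generate_key <- function(matrix, descriptions = NULL) {
  stopifnot(inherits(matrix, "resolved_matrix"))
  if (is.null(descriptions)) descriptions <- matrix$characters
  ids <- matrix$characters$id
  couplets <- list()
  next_id <- 0L

  build <- function(taxa) {
    # returns a lead target: list(goto=) or list(taxon=)
    if (length(taxa) == 1) return(list(taxon = taxa))
    best <- NULL; best_bal <- -1L
    for (k in seq_along(ids)) {
      row <- matrix$cells[k, taxa]
      if (anyNA(row)) next
      n1 <- sum(row == 1L)
      if (n1 == 0 || n1 == length(taxa)) next
      bal <- min(n1, length(taxa) - n1)
      if (bal > best_bal) { best_bal <- bal; best <- k }
    }
    if (is.null(best)) {
      stop("indistinguishable taxa: no character separates {",
           paste(taxa[1:2], collapse = ", "), "}", call. = FALSE)
    }
    next_id <<- next_id + 1L
    my_id <- next_id
    row <- matrix$cells[best, taxa]
    der <- taxa[row == 1L]; ple <- taxa[row == 0L]
    d <- descriptions[descriptions$id == ids[best], , drop = FALSE]
    ptxt <- if (nzchar(d$plesiomorphic_description)) {
      d$plesiomorphic_description
    } else {
      paste("not:", d$description)
    }
    # placeholder now, fill after recursion so couplet numbering is preorder
    couplets[[as.character(my_id)]] <<- list(id = my_id)
    lead_a <- c(list(text = d$description), build(der))
    lead_b <- c(list(text = ptxt), build(ple))
    couplets[[as.character(my_id)]] <<- list(id = my_id, a = lead_a, b = lead_b)
    list(goto = my_id)
  }
  build(sort(matrix$taxa))
  dichotomous_key(unname(couplets), start = 1L)
}

#' Render a key as plain text
#'
#' @param key A `dichotomous_key`.
#' @return Character vector of lines in the printed two-line-per-couplet
#'   layout.
#' @export
render_key <- function(key) {
  stopifnot(inherits(key, "dichotomous_key"))
  unlist(lapply(key$couplets, function(cp) {
    tgt <- function(lead) {
      if (!is.null(lead$taxon)) lead$taxon else sprintf("-> %d", lead$goto)
    }
    c(sprintf("%-3d %s\t%s", cp$id, cp$a$text, tgt(cp$a)),
      sprintf("-   %s\t%s", cp$b$text, tgt(cp$b)))
  }), use.names = FALSE)
}
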