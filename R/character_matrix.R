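#' Construct a polarity-coded character matrix
#'
#' The central container of the package: an ordered list of taxa, an ordered
#' list of character definitions (each stating the apomorphic condition and,
#' in brackets in published tables, the plesiomorphic one), and a grid of
#' polarity codes (see [state_codes()]). Cells flagged in the source as
#' supposed convergences are carried as annotations.
#'
#' @param taxa Character vector of unique taxon labels (columns).
#' @param characters Data frame with columns `id` (integer, unique),
#'   `description` (apomorphic condition, non-empty), and optionally
#'   `plesiomorphic_description` and `source_anchor`.
#' @param cells Character matrix, `nrow(characters)` x `length(taxa)`, cells
#'   drawn from [state_codes()].
#' @param convergences Optional data frame with columns `char_id`, `taxon`:
#'   apomorphic cells flagged as convergent in the source.
#' @return An object of class `character_matrix`.
#' @export
#' @examples
#' character_matrix(
#'   taxa = c("A", "B"),
#'   characters = data.frame(id = 1L, description = "seta lost [present]"),
#'   cells = matrix(c("0", "1"), nrow = 1)
#' )
character_matrix <- function(taxa, characters, cells, convergences = NULL) {
  taxa <- as.character(taxa)
  if (length(taxa) == 0) stop("matrix must contain at least one taxon", call. = FALSE)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  characters <- as.data.frame(characters)
  if (!all(c("id", "description") %in% names(characters))) {
    stop("characters must have columns 'id' and 'description'", call. = FALSE)
  }
  characters$id <- as.integer(characters$id)
  if (anyDuplicated(characters$id)) stop("duplicate character ids", call. = FALSE)
  if (any(!nzchar(characters$description))) {
    stop("character descriptions must be non-empty", call. = FALSE)
  }
  if (is.null(characters$plesiomorphic_description)) {
    split <- split_description(characters$description)
    characters$description <- split$apomorphic
    characters$plesiomorphic_description <- split$plesiomorphic
  }
  if (is.null(characters$source_anchor)) characters$source_anchor <- ""
  cells <- as.matrix(cells)
  mode(cells) <- "character"
  if (nrow(cells) != nrow(characters) || ncol(cells) != length(taxa)) {
    stop(sprintf("cell grid is %d x %d but %d characters and %d taxa were given",
                 nrow(cells), ncol(cells), nrow(characters), length(taxa)),
         call. = FALSE)
  }
  bad <- which(matrix(!is_state_code(cells), nrow = nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid state token '%s' at character %d, taxon '%s'",
                 cells[bad[1, 1], bad[1, 2]], characters$id[bad[1, 1]],
                 taxa[bad[1, 2]]), call. = FALSE)
  }
  dimnames(cells) <- list(as.character(characters$id), taxa)
  if (is.null(convergences)) {
    convergences <- data.frame(char_id = integer(), taxon = character())
  }
  convergences <- as.data.frame(convergences)
  if (nrow(convergences) > 0) {
    convergences$char_id <- as.integer(convergences$char_id)
    convergences$taxon <- as.character(convergences$taxon)
    for (k in seq_len(nrow(convergences))) {
      i <- match(convergences$char_id[k], characters$id)
      j <- match(convergences$taxon[k], taxa)
      if (is.na(i) || is.na(j)) {
        stop("convergence annotation refers to unknown character or taxon",
             call. = FALSE)
      }
      if (!cells[i, j] %in% c("1", "1?")) {
        stop(sprintf("convergence annotation (%d, %s) does not mark an apomorphic cell",
                     convergences$char_id[k], convergences$taxon[k]), call. = FALSE)
      }
    }
  }
  structure(list(taxa = taxa, characters = characters, cells = cells,
                 convergences = convergences),
            class = "character_matrix")
}

# "apomorphic text [plesiomorphic text]" -> two columns
split_description <- function(x) {
  m <- regmatches(x, regexpr("\\[[^][]*\\]$", x))
  has <- grepl("\\[[^][]*\\]$", x)
  plesio <- character(length(x))
  plesio[has] <- sub("^\\[", "", sub("\\]$", "", regmatches(x, regexpr("\\[[^][]*\\]$", x))))
  apo <- trimws(sub("\\[[^][]*\\]$", "", x))
  list(apomorphic = ifelse(nzchar(apo), apo, x), plesiomorphic = plesio)
}

joint_description <- function(characters) {
  p <- characters$plesiomorphic_description
  ifelse(nzchar(p), paste0(characters$description, " [", p, "]"),
         characters$description)
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Polarity-coded character matrix: %d characters x %d taxa\n",
              nrow(x$cells), ncol(x$cells)))
  tab <- table(factor(x$cells, levels = state_codes()))
  cat("  cells: ", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  if (nrow(x$convergences) > 0) {
    cat(sprintf("  %d cell(s) annotated as supposed convergences\n",
                nrow(x$convergences)))
  }
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

#' The Laophontodes character matrix
#'
#' Packaged transcription of the published 39-character, 12-species
#' polarity-coded matrix for the benthic copepod genus *Laophontodes*
#' (Ancorabolidae, Laophontodinae). Character 1 is derived in all twelve
#' species and diagnoses the larger monophylum the genus belongs to;
#' characters 2--14 group progressively smaller species sets; characters
#' 15--39 are putative autapomorphies of single species. Cells use the codes
#' of [state_codes()], including `?` (no information), `1?`/`0?` (uncertain
#' observations of character 2), and `0*` (intraspecific variability in
#' *L. whitsoni*). The three cells printed in bold in the source --
#' characters 4 and 5 for *L. macclintocki* and character 17 for
#' *L. spongiosus* -- are carried as convergence annotations.
#'
#' @return A [character_matrix] with 39 characters and 12 taxa, taxa labelled
#'   by bare species epithets (see [laophontodes_taxa()] for full names).
#' @export
#' @examples
#' m <- laophontodes_matrix()
#' dim(m)
laophontodes_matrix <- function() {
  path <- system.file("extdata", "laophontodes_matrix.csv", package = "hennig",
                      mustWork = TRUE)
  load_matrix(path, dialect = "csv")
}

#' Full species names for the Laophontodes fixture
#'
#' @return Named character vector mapping the epithet labels used throughout
#'   the package to full species names.
#' @export
laophontodes_taxa <- function() {
  c(sarsi            = "Laophontodes sarsi George, 2018",
    scottorum        = "Laophontodes scottorum George, 2018",
    volkerlehmanskii = "Laophontodes volkerlehmanskii sp. nov.",
    georgei          = "Laophontodes georgei Lee & Huys, 2019",
    gertraudae       = "Laophontodes gertraudae George, 2018",
    spongiosus       = "Laophontodes spongiosus Schizas & Shirley, 1994",
    mourois          = "Laophontodes mourois Arroyo, George, Benito & Maldonado, 2003",
    typicus          = "Laophontodes typicus T. Scott, 1894",
    monsmaris        = "Laophontodes monsmaris George, 2018",
    macclintocki     = "Laophontodes macclintocki Schizas & Shirley, 1994",
    sabinegeorgeae   = "Laophontodes sabinegeorgeae George, 2018",
    whitsoni         = "Laophontodes whitsoni T. Scott, 1912")
}

#' Sensitivity fixture: the dorsal-ripples character
#'
#' A candidate 40th character (fine longitudinal dorsal ripples on the
#' P2--P4-bearing somites) observed in five species but unknown in several
#' others; it was excluded from the main analysis because treating it as a
#' synapomorphy would demote characters 2--14 to convergences, which is less
#' parsimonious. Returned as a one-row matrix fragment for sensitivity
#' experiments; not part of [laophontodes_matrix()].
#'
#' @return A [character_matrix] with this single character over the 12 taxa.
#' @export
laophontodes_ripples_character <- function() {
  taxa <- names(laophontodes_taxa())
  cells <- matrix("?", nrow = 1, ncol = length(taxa),
                  dimnames = list("40", taxa))
  cells[1, c("whitsoni", "sabinegeorgeae", "typicus", "mourois", "scottorum")] <- "1"
  cells[1, c("gertraudae", "monsmaris", "volkerlehmanskii")] <- "0"
  character_matrix(
    taxa = taxa,
    characters = data.frame(
      id = 40L,
      description = "Pedigerous somites P2-P4 with fine longitudinal dorsal ripples",
      plesiomorphic_description = "somites smooth dorsally"),
    cells = cells)
}
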