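#' Read a polarity-coded character matrix
#'
#' Supported dialects:
#' * `"csv"` / `"tsv"`: one row per character; first column the character id,
#'   second the description (with the plesiomorphic state in trailing square
#'   brackets), remaining columns one per taxon, named in the header. A
#'   sidecar file `<path>.meta`, if present, lists convergence-annotated
#'   cells as `char_id,taxon` pairs.
#' * `"nexus"`: a DATA block (`DATATYPE=STANDARD SYMBOLS="01" MISSING=?`)
#'   plus an optional private POLARITY block carrying the uncertainty codes
#'   `1?`/`0?`/`0*`, character descriptions, and convergence annotations,
#'   as written by [write_nexus()].
#'
#' @param path Path to the matrix file.
#' @param dialect One of `"csv"`, `"tsv"`, `"nexus"`. Defaults from the file
#'   extension.
#' @param taxa_as_rows For csv/tsv: set `TRUE` if the file is transposed
#'   (taxa as rows, characters as columns).
#' @return A [character_matrix].
#' @export
#' @examples
#' path <- system.file("extdata", "laophontodes_matrix.csv", package = "hennig")
#' m <- load_matrix(path)
load_matrix <- function(path, dialect = NULL, taxa_as_rows = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      csv = "csv", tsv = "tsv", txt = "tsv",
                      nex = "nexus", nexus = "nexus",
                      stop("cannot infer dialect from extension of ", path,
                           call. = FALSE))
  }
  dialect <- match.arg(dialect, c("csv", "tsv", "nexus"))
  if (dialect == "nexus") return(read_nexus_matrix(path))

  sep <- if (dialect == "csv") "," else "\t"
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2) {
    stop("parse error in ", path, ": need a header line and at least one data row",
         call. = FALSE)
  }
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("dimension error in %s: line %d has %d fields, header has %d",
                 path, bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (taxa_as_rows) {
    # first column = taxon label, remaining columns = character ids
    if (ncol(df) < 2) {
      stop("parse error in ", path, ": transposed layout needs a taxon column ",
           "and at least one character column", call. = FALSE)
    }
    taxa <- df[[1]]
    ids <- suppressWarnings(as.integer(names(df)[-1]))
    if (anyNA(ids)) {
      stop("malformed header in ", path,
           ": character columns must be named by integer ids", call. = FALSE)
    }
    cells <- t(as.matrix(df[, -1, drop = FALSE]))
    chars <- data.frame(id = ids, description = paste("character", ids))
  } else {
    if (ncol(df) < 3 || !identical(tolower(names(df)[1:2]), c("id", "description"))) {
      stop("malformed header in ", path,
           " (line 1): expected columns 'id', 'description', then one column per taxon",
           call. = FALSE)
    }
    ids <- suppressWarnings(as.integer(df$id))
    if (anyNA(ids)) {
      bad <- which(is.na(ids))[1]
      stop(sprintf("parse error in %s (line %d): character id '%s' is not an integer",
                   path, bad + 1L, df$id[bad]), call. = FALSE)
    }
    taxa <- names(df)[-(1:2)]
    cells <- as.matrix(df[, -(1:2), drop = FALSE])
    chars <- data.frame(id = ids, description = df$description)
  }
  cells[] <- trimws(cells)
  convergences <- NULL
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    convergences <- utils::read.csv(meta, colClasses = c("integer", "character"))
    names(convergences) <- c("char_id", "taxon")
  }
  character_matrix(taxa = taxa, characters = chars, cells = cells,
                   convergences = convergences)
}

#' Write a character matrix as CSV or TSV
#'
#' Inverse of [load_matrix()] for the delimited dialects. Convergence
#' annotations, which the tabular layout cannot carry, go to a sidecar
#' `<path>.meta` file that [load_matrix()] picks up automatically.
#'
#' @param matrix A [character_matrix].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(matrix, "character_matrix"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(id = matrix$characters$id,
                   description = joint_description(matrix$characters),
                   matrix$cells, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = 2L)
  meta <- paste0(path, ".meta")
  if (nrow(matrix$convergences) > 0) {
    utils::write.csv(matrix$convergences, meta, row.names = FALSE, quote = FALSE)
  } else if (file.exists(meta)) {
    unlink(meta)
  }
  invisible(path)
}

nexus_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

#' Write a character matrix as NEXUS
#'
#' Emits a standard-datatype DATA block (`SYMBOLS="01" MISSING=?`) readable
#' by any NEXUS consumer, followed by a private POLARITY block that records
#' what standard NEXUS cannot: the uncertainty/variability codes `1?`, `0?`,
#' `0*` (the matrix body carries their base symbol), the character
#' descriptions with polarity brackets, and convergence annotations. A
#' matrix written here and reloaded with [load_matrix()] round-trips
#' cell-for-cell.
#'
#' @param matrix A [character_matrix] with at least one taxon.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_nexus <- function(matrix, path) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(matrix$taxa) == 0) stop("matrix has no taxa", call. = FALSE)
  base <- c("0" = "0", "1" = "1", "?" = "?", "1?" = "1", "0?" = "0", "0*" = "0")
  body <- matrix(base[matrix$cells], nrow = nrow(matrix$cells))
  rows <- vapply(seq_along(matrix$taxa), function(j) {
    paste0("    ", matrix$taxa[j], "  ", paste(body[, j], collapse = ""))
  }, character(1))
  special <- which(matrix(matrix$cells %in% c("1?", "0?", "0*"),
                          nrow = nrow(matrix$cells)), arr.ind = TRUE)
  codes <- character(0)
  if (nrow(special) > 0) {
    codes <- sprintf("  CODE %d %s %s;",
                     matrix$characters$id[special[, 1]],
                     matrix$taxa[special[, 2]],
                     matrix$cells[special])
  }
  chardefs <- sprintf("  CHARDEF %d %s %s;",
                      matrix$characters$id,
                      nexus_quote(matrix$characters$description),
                      nexus_quote(matrix$characters$plesiomorphic_description))
  conv <- character(0)
  if (nrow(matrix$convergences) > 0) {
    conv <- sprintf("  CONVERGENT %d %s;",
                    matrix$convergences$char_id, matrix$convergences$taxon)
  }
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
            length(matrix$taxa), nrow(matrix$cells)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX",
    rows,
    "  ;",
    "END;",
    "BEGIN POLARITY;",
    chardefs,
    codes,
    conv,
    "END;")
  ok <- tryCatch({ suppressWarnings(writeLines(lines, path)); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

# Parse the DATA block with ape and the POLARITY block by hand.
read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dat <- ape::read.nexus.data(path)   # list: taxon -> character vector of symbols
  taxa <- names(dat)
  nchar <- length(dat[[1]])
  cells <- matrix(NA_character_, nrow = nchar, ncol = length(taxa))
  for (j in seq_along(taxa)) cells[, j] <- toupper(dat[[j]])
  cells[cells == "N" | cells == "-"] <- "?"
  ok <- cells %in% c("0", "1", "?")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid state token '%s' in NEXUS matrix of %s",
                 cells[bad], path), call. = FALSE)
  }

  ids <- seq_len(nchar)
  chars <- data.frame(id = ids, description = paste("character", ids),
                      plesiomorphic_description = "")
  convergences <- NULL

  block <- grep("^\\s*BEGIN\\s+POLARITY\\s*;", lines, ignore.case = TRUE)
  if (length(block) == 1) {
    endl <- grep("^\\s*END\\s*;", lines, ignore.case = TRUE)
    endl <- endl[endl > block][1]
    inner <- lines[(block + 1):(endl - 1)]
    for (ln in inner) {
      ln <- trimws(sub(";\\s*$", "", ln))
      if (grepl("^CHARDEF ", ln)) {
        m <- regmatches(ln, regexec("^CHARDEF (\\d+) '((?:[^']|'')*)' '((?:[^']|'')*)'$", ln))[[1]]
        if (length(m) == 4) {
          i <- as.integer(m[2])
          chars$description[i] <- gsub("''", "'", m[3])
          chars$plesiomorphic_description[i] <- gsub("''", "'", m[4])
        }
      } else if (grepl("^CODE ", ln)) {
        m <- strsplit(ln, "\\s+")[[1]]
        i <- as.integer(m[2]); j <- match(m[3], taxa)
        cells[i, j] <- m[4]
      } else if (grepl("^CONVERGENT ", ln)) {
        m <- strsplit(ln, "\\s+")[[1]]
        convergences <- rbind(convergences,
                              data.frame(char_id = as.integer(m[2]), taxon = m[3]))
      }
    }
  }
  character_matrix(taxa = taxa, characters = chars, cells = cells,
                   convergences = convergences)
}
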