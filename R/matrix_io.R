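# Discrete morphological character matrices with missing ("?") and
# inapplicable ("-") cells. Internally cells are stored as an integer
# matrix: states 0..9 as themselves, MISSING as NA, INAPPLICABLE as -1.

INAPPLICABLE <- -1L

#' Construct a discrete character matrix
#'
#' A `character_matrix` holds a taxa-by-characters block of discrete
#' morphological scores. Each cell is an integer state in 0..9, `NA`
#' (missing, unknown: the "?" of a NEXUS file) or `-1` (inapplicable:
#' the "-" gap symbol, meaning the character cannot logically be scored
#' for that taxon). Characters may belong to named, possibly
#' overlapping partitions (e.g. "sporophyte", "gametophyte") used to
#' build trait-subset morphospaces.
#'
#' @param cells Integer matrix, rows = taxa, columns = characters, with
#'   row and column names. Values must be in 0..9, `NA` or `-1`.
#' @param partitions Named list of character-id vectors; members must
#'   be column names of `cells`. Partitions may overlap.
#' @param ordered Logical vector, one per character; all characters are
#'   treated as unordered by default and ordered characters are not
#'   used by any distance here (kept for provenance only).
#' @return An object of class `character_matrix` with elements `cells`,
#'   `partitions` and `ordered`.
#' @export
character_matrix <- function(cells, partitions = list(), ordered = NULL) {
  if (!is.matrix(cells)) cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (is.null(rownames(cells))) stop("cells must have taxon row names")
  if (is.null(colnames(cells))) {
    colnames(cells) <- paste0("c", seq_len(ncol(cells)))
  }
  if (anyDuplicated(rownames(cells))) {
    stop("duplicated taxon labels: ",
         paste(unique(rownames(cells)[duplicated(rownames(cells))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(cells))) stop("duplicated character ids")
  vals <- cells[!is.na(cells)]
  bad <- vals[vals != INAPPLICABLE & (vals < 0L | vals > 9L)]
  if (length(bad)) {
    stop("cell states must be 0..9, NA (missing) or -1 (inapplicable); saw ",
         paste(unique(bad), collapse = ", "))
  }
  if (is.null(ordered)) ordered <- rep(FALSE, ncol(cells))
  stopifnot(length(ordered) == ncol(cells))
  if (length(partitions)) {
    if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
      stop("partitions must be named")
    for (nm in names(partitions)) {
      unknown <- setdiff(partitions[[nm]], colnames(cells))
      if (length(unknown)) {
        stop("partition '", nm, "' names unknown characters: ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  structure(list(cells = cells, partitions = partitions,
                 ordered = as.logical(ordered)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix:", nrow(x$cells), "taxa x", ncol(x$cells),
      "characters\n")
  cat("  missing:", sum(is.na(x$cells)),
      " inapplicable:", sum(x$cells == INAPPLICABLE, na.rm = TRUE), "\n")
  if (length(x$partitions))
    cat("  partitions:", paste(names(x$partitions), collapse = ", "), "\n")
  invisible(x)
}

#' Taxa and character accessors
#' @param m A `character_matrix` or `presence_matrix`.
#' @return Character vector of taxon labels / character ids.
#' @export
taxa <- function(m) rownames(m$cells)

#' @rdname taxa
#' @export
characters <- function(m) colnames(m$cells)

# Map one cell token to the internal integer code. Polymorphic or
# ambiguous tokens ("{01}", "(01)", "0/1", "0&1") collapse to missing.
.parse_cell <- function(tok) {
  tok <- trimws(tok)
  if (tok %in% c("?", "", "NA")) return(NA_integer_)
  if (tok == "-") return(INAPPLICABLE)
  if (grepl("^[0-9]$", tok)) return(as.integer(tok))
  if (grepl("^[{(].*[})]$", tok) || grepl("[/&]", tok)) return(NA_integer_)
  stop("unrecognised cell symbol '", tok, "'", call. = FALSE)
}

.parse_cells <- function(chr_mat, what = "matrix") {
  poly <- grepl("^[{(].*[})]$", chr_mat) | grepl("[/&]", chr_mat)
  n_poly <- sum(poly)
  out <- matrix(NA_integer_, nrow(chr_mat), ncol(chr_mat),
                dimnames = dimnames(chr_mat))
  for (j in seq_len(ncol(chr_mat))) {
    col <- chr_mat[, j]
    parsed <- vapply(col, function(tok) {
      tryCatch(.parse_cell(tok), error = function(e) {
        stop("character '", colnames(chr_mat)[j], "': ",
             conditionMessage(e), call. = FALSE)
      })
    }, integer(1))
    out[, j] <- parsed
  }
  if (n_poly > 0) {
    warning(n_poly, " polymorphic/ambiguous cell(s) recoded as missing",
            call. = FALSE)
  }
  out
}

#' Read a character matrix from CSV or NEXUS
#'
#' The CSV dialect is: header row of character ids, first column the
#' taxon label, cells one of `0`..`9`, `?` (missing) and `-`
#' (inapplicable). NEXUS `DATA`/`CHARACTERS` blocks are read with the
#' standard `MISSING=?` and `GAP=-` conventions. Polymorphic cells
#' (e.g. `{01}`) are recoded as missing with a warning, since unordered
#' Mk machinery downstream has no polymorphism concept.
#'
#' @param path File path.
#' @param format `"csv"` or `"nexus"`; guessed from the extension when
#'   omitted.
#' @param partitions Optional named list of character-id vectors
#'   attached to the result (neither format carries partitions).
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, format = c("auto", "csv", "nexus"),
                                  partitions = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "csv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, ",", fixed = TRUE)
    header <- trimws(fields[[1]])
    char_ids <- header[-1]
    body <- fields[-1]
    lens <- lengths(body)
    if (any(lens != length(header))) {
      bad <- which(lens != length(header))[1]
      stop("row for taxon '", trimws(body[[bad]][1]), "' has ",
           lens[bad] - 1L, " cells, expected ", length(char_ids))
    }
    tax <- vapply(body, function(f) trimws(f[1]), character(1))
    cells <- t(vapply(body, function(f) trimws(f[-1]),
                      character(length(char_ids))))
    if (length(char_ids) == 1L) cells <- matrix(cells, ncol = 1L)
    dimnames(cells) <- list(tax, char_ids)
  } else {
    raw <- ape::read.nexus.data(path)
    lens <- lengths(raw)
    if (length(unique(lens)) > 1L) {
      bad <- names(raw)[lens != max(lens)][1]
      stop("row for taxon '", bad, "' has ", lens[[bad]],
           " cells, expected ", max(lens))
    }
    cells <- do.call(rbind, lapply(raw, as.character))
    rownames(cells) <- names(raw)
    colnames(cells) <- paste0("c", seq_len(ncol(cells)))
  }
  character_matrix(.parse_cells(cells), partitions = partitions)
}

.cell_symbols <- function(cells) {
  sym <- matrix("?", nrow(cells), ncol(cells), dimnames = dimnames(cells))
  sym[!is.na(cells) & cells == INAPPLICABLE] <- "-"
  coded <- !is.na(cells) & cells != INAPPLICABLE
  sym[coded] <- as.character(cells[coded])
  sym
}

#' Write a character matrix to CSV or NEXUS
#'
#' @param m A [character_matrix()].
#' @param path Output file path.
#' @param format `"csv"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(m, path, format = c("csv", "nexus")) {
  format <- match.arg(format)
  sym <- .cell_symbols(m$cells)
  if (format == "csv") {
    header <- paste(c("taxon", colnames(sym)), collapse = ",")
    rows <- vapply(seq_len(nrow(sym)), function(i) {
      paste(c(rownames(sym)[i], sym[i, ]), collapse = ",")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    states <- sort(unique(m$cells[!is.na(m$cells) & m$cells != INAPPLICABLE]))
    symbols <- paste(states, collapse = "")
    if (!nzchar(symbols)) symbols <- "01"
    rows <- vapply(seq_len(nrow(sym)), function(i) {
      paste0(gsub("[^A-Za-z0-9_.]", "_", rownames(sym)[i]), "  ",
             paste(sym[i, ], collapse = ""))
    }, character(1))
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      paste0("DIMENSIONS NTAX=", nrow(sym), " NCHAR=", ncol(sym), ";"),
      paste0("FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"",
             symbols, "\";"),
      "MATRIX", rows, ";", "END;"), path)
  }
  invisible(path)
}

#' Restrict a matrix to a subset of characters
#'
#' Column order is preserved and partitions are intersected with the
#' retained set (empty partitions are dropped). Used to build the
#' trait-category morphospaces (sporophyte-only, gametophyte-only, ...).
#'
#' @param m A [character_matrix()].
#' @param keep Character ids to retain (non-empty subset of
#'   `characters(m)`).
#' @return A [character_matrix()] with `length(keep)` columns.
#' @export
subset_characters <- function(m, keep) {
  stopifnot(inherits(m, "character_matrix"))
  if (length(keep) == 0L) stop("keep must be non-empty")
  unknown <- setdiff(keep, characters(m))
  if (length(unknown)) {
    stop("unknown character id(s): ", paste(unknown, collapse = ", "))
  }
  sel <- characters(m)[characters(m) %in% keep]
  parts <- lapply(m$partitions, intersect, sel)
  parts <- parts[lengths(parts) > 0]
  character_matrix(m$cells[, sel, drop = FALSE], partitions = parts,
                  ordered = m$ordered[match(sel, characters(m))])
}

#' Recode a multistate matrix to presence/absence
#'
#' Each retained character becomes binary: 1 = trait present, 0 =
#' absent. Inapplicable cells map to absent (an organ that cannot exist
#' is not present); missing cells stay missing. Characters whose
#' recode entry is the string `"drop"` are removed.
#'
#' @param m A [character_matrix()].
#' @param recode_table Named list, one entry per character to keep or
#'   drop. Each entry is either `"drop"` or a named numeric vector
#'   mapping every observed state of that character to 0 or 1, e.g.
#'   `c("0" = 0, "1" = 1, "2" = 1)`. Characters absent from the table
#'   are passed through unchanged and must already be binary.
#' @return A `presence_matrix`: list with a `cells` integer matrix of
#'   0/1/NA in the same taxon order.
#' @export
recode_presence <- function(m, recode_table = list()) {
  stopifnot(inherits(m, "character_matrix"))
  keep <- characters(m)
  drop <- names(recode_table)[vapply(recode_table, identical, logical(1),
                                     "drop")]
  keep <- setdiff(keep, drop)
  out <- matrix(NA_integer_, nrow(m$cells), length(keep),
                dimnames = list(taxa(m), keep))
  for (ch in keep) {
    col <- m$cells[, ch]
    val <- col
    val[!is.na(col) & col == INAPPLICABLE] <- 0L
    map <- recode_table[[ch]]
    coded <- !is.na(col) & col != INAPPLICABLE
    if (!is.null(map)) {
      hit <- match(as.character(col[coded]), names(map))
      if (anyNA(hit)) {
        missing_state <- as.character(col[coded])[is.na(hit)][1]
        stop("character '", ch, "': state ", missing_state,
             " has no recode entry")
      }
      val[coded] <- as.integer(map[hit])
    } else if (any(col[coded] > 1L)) {
      stop("character '", ch, "' is multistate (states ",
           paste(sort(unique(col[coded])), collapse = ","),
           ") and has no recode entry")
    }
    out[, ch] <- val
  }
  if (!all(out[!is.na(out)] %in% c(0L, 1L))) {
    stop("recode table must map states to 0 or 1")
  }
  structure(list(cells = out), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$cells), "taxa x", ncol(x$cells),
      "characters (", sum(is.na(x$cells)), "missing )\n")
  invisible(x)
}

#' Proportion of characters applicable to a taxon
#'
#' A coarse complexity proxy: the fraction of a taxon's characters that
#' can logically be scored (i.e. are not inapplicable). Missing cells
#' are excluded from the denominator by default so that poorly known
#' taxa are not penalised for ignorance on top of inapplicability; set
#' `include_missing = TRUE` to count them as applicable-unknown in the
#' denominator.
#'
#' @param m A [character_matrix()].
#' @param taxon Taxon label.
#' @param include_missing Count missing cells in the denominator?
#' @return A fraction in \[0, 1\] (0 when no cell is scored).
#' @export
applicable_proportion <- function(m, taxon, include_missing = FALSE) {
  stopifnot(inherits(m, "character_matrix"))
  if (!taxon %in% taxa(m)) stop("taxon '", taxon, "' not in matrix")
  row <- m$cells[taxon, ]
  applicable <- sum(!is.na(row) & row != INAPPLICABLE)
  denom <- if (include_missing) length(row) else sum(!is.na(row))
  if (denom == 0L) return(0)
  applicable / denom
}
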