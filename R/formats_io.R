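#' @title Tabular input/output for the transient-helix pipeline
#' @description Readers and writers for the small set of plain-text formats
#'   the pipeline touches: chemical-shift tables (TSV or a minimal NMR-STAR
#'   v3 assigned-chemical-shift loop), generic long tables (decays,
#'   sensorgrams, isotherms, tracks), and TSV/JSON result files. All readers
#'   validate strictly; malformed rows are errors, not warnings.
#' @name formats_io
NULL

#' Construct and validate a chemical-shift table
#'
#' A shift table holds one row per (residue, nucleus) observed backbone
#' chemical shift. Nuclei are \code{H} (amide proton), \code{N} (amide
#' nitrogen), \code{C} (carbonyl), \code{CA} and \code{CB}.
#'
#' @param residue_number integer vector of residue numbers (construct
#'   numbering, taken verbatim).
#' @param residue_type one-letter amino-acid codes.
#' @param nucleus character vector, subset of \code{c("H","N","C","CA","CB")}.
#' @param shift observed shifts in ppm.
#' @return A data.frame of class \code{"shift_table"} sorted by
#'   (nucleus, residue_number).
#' @export
shift_table <- function(residue_number, residue_type, nucleus, shift) {
  x <- data.frame(
    residue_number = as.integer(residue_number),
    residue_type   = toupper(as.character(residue_type)),
    nucleus        = as.character(nucleus),
    shift          = as.numeric(shift),
    stringsAsFactors = FALSE
  )
  bad <- !x$nucleus %in% .NUCLEI
  if (any(bad)) {
    x <- x[!bad, , drop = FALSE]
    message(sprintf("skipped %d entr%s with unknown nucleus",
                    sum(bad), if (sum(bad) == 1) "y" else "ies"))
  }
  if (any(!is.finite(x$shift)))
    stop("non-finite chemical shifts present")
  key <- paste(x$residue_number, x$nucleus)
  if (anyDuplicated(key))
    stop("duplicate (residue, nucleus) assignments: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(x$residue_type == "G" & x$nucleus == "CB"))
    stop("glycine cannot carry a CB shift (residues ",
         paste(x$residue_number[x$residue_type == "G" & x$nucleus == "CB"],
               collapse = ", "), ")")
  x <- x[order(x$nucleus, x$residue_number), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("shift_table", "data.frame")
  x
}

#' Read a chemical-shift table
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} for a tab-separated table with columns
#'   \code{residue_number}, \code{residue_type}, \code{nucleus},
#'   \code{shift} (header required, \code{#} comments allowed), or
#'   \code{"nmrstar"} for a file containing exactly one NMR-STAR v3
#'   \code{_Atom_chem_shift} loop (columns \code{Comp_index_ID},
#'   \code{Comp_ID}, \code{Atom_ID}, \code{Val}).
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, dialect = c("tsv", "nmrstar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    x <- .read_delim_strict(path, sep = "\t",
                            required = c("residue_number", "residue_type",
                                         "nucleus", "shift"),
                            numeric_cols = c("residue_number", "shift"))
    shift_table(x$residue_number, x$residue_type, x$nucleus, x$shift)
  } else {
    .read_nmrstar_shifts(path)
  }
}

# minimal NMR-STAR v3 reader: one _Atom_chem_shift loop only
.read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  shift_loop <- NULL
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, sub("^\\s*", "", sub("\\s*$", "", lines[i])))
      i <- i + 1L
    }
    if (any(grepl("^_Atom_chem_shift\\.", tags))) {
      if (!is.null(shift_loop))
        stop("file contains more than one _Atom_chem_shift loop")
      shift_loop <- list(tags = tags, body_start = i)
    }
  }
  if (is.null(shift_loop))
    stop("no _Atom_chem_shift loop found in ", path)
  tags <- sub("^_Atom_chem_shift\\.", "", shift_loop$tags)
  need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
  if (!all(need %in% tags))
    stop("_Atom_chem_shift loop lacks required columns: ",
         paste(setdiff(need, tags), collapse = ", "))
  rows <- list()
  i <- shift_loop$body_start
  while (i <= length(lines)) {
    ln <- sub("^\\s+", "", sub("\\s+$", "", lines[i]))
    if (ln == "" ) { i <- i + 1L; next }
    if (grepl("^(stop_|loop_|save_)", ln)) break
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) != length(tags))
      stop(sprintf("malformed NMR-STAR data row at line %d: expected %d fields, got %d",
                   i, length(tags), length(fields)))
    rows[[length(rows) + 1L]] <- fields
    i <- i + 1L
  }
  if (!length(rows)) stop("empty _Atom_chem_shift loop in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  comp3 <- toupper(m[, "Comp_ID"])
  one <- .three_to_one(comp3)
  if (anyNA(one))
    stop("unknown residue type(s) in NMR-STAR loop: ",
         paste(unique(comp3[is.na(one)]), collapse = ", "))
  val <- suppressWarnings(as.numeric(m[, "Val"]))
  if (anyNA(val)) stop("non-numeric shift value in NMR-STAR loop")
  shift_table(as.integer(m[, "Comp_index_ID"]), one, m[, "Atom_ID"], val)
}

.three_to_one <- function(x) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- unname(map[x])
  out[nchar(x) == 1 & x %in% map] <- x[nchar(x) == 1 & x %in% map]
  out
}

.read_delim_strict <- function(path, sep, required, numeric_cols) {
  x <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", blank.lines.skip = TRUE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    if (anyNA(v) && !all(is.na(x[[cc]])))
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   cc, which(is.na(v))[1]))
    x[[cc]] <- v
  }
  x
}

#' Read a generic long-format series table
#'
#' A long table carries one or more series of (x, y) points keyed by a
#' series identifier: relaxation decays (residue, time, intensity),
#' sensorgrams (concentration, time, response), isotherms, and the like.
#'
#' @param path path to a delimited file with a header row.
#' @param schema character vector of length 3 (or 4, with a weight column)
#'   naming, in order, the columns holding the series key, x and y (and
#'   optionally weight).
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @param replicates if \code{FALSE} (default), duplicated (series, x)
#'   pairs are an error.
#' @return A data.frame of class \code{"long_table"} with canonical columns
#'   \code{series_key}, \code{x}, \code{y} (and \code{weight}), sorted by
#'   (series_key, x).
#' @export
read_long_table <- function(path, schema, dialect = c("tsv", "csv"),
                            replicates = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(length(schema) %in% c(3L, 4L))
  sep <- if (dialect == "tsv") "\t" else ","
  x <- .read_delim_strict(path, sep, required = schema,
                          numeric_cols = schema[-1])
  out <- data.frame(series_key = as.character(x[[schema[1]]]),
                    x = x[[schema[2]]], y = x[[schema[3]]],
                    stringsAsFactors = FALSE)
  if (length(schema) == 4L) out$weight <- x[[schema[4]]]
  if (any(!is.finite(out$x))) stop("non-finite x values present")
  if (!replicates && anyDuplicated(paste(out$series_key, out$x)))
    stop("duplicated (series, x) pairs under a no-replicate schema")
  out <- out[order(out$series_key, out$x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("long_table", "data.frame")
  out
}

#' Write a keyed result set to TSV or JSON
#'
#' Numeric values are serialized with full precision: a round trip through
#' [read_long_table()] (TSV) or \code{jsonlite::fromJSON} reproduces values
#' to at least 12 significant digits.
#'
#' @param records a data.frame (TSV) or named list / data.frame (JSON).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param allow_na permit NA values (default \code{FALSE}).
#' @return \code{invisible(path)}.
#' @export
write_results <- function(records, path, format = c("tsv", "json"),
                          allow_na = FALSE) {
  format <- match.arg(format)
  if (!allow_na) {
    vals <- if (is.data.frame(records)) unlist(records, use.names = FALSE)
            else unlist(records, use.names = FALSE)
    if (anyNA(vals)) stop("NA values present; pass allow_na = TRUE to permit")
  }
  if (format == "tsv") {
    stopifnot(is.data.frame(records))
    if (nrow(records) == 0L) warning("writing header-only file (no records)")
    rec <- records
    for (cc in names(rec))
      if (is.numeric(rec[[cc]])) rec[[cc]] <- formatC(rec[[cc]], digits = 15,
                                                      format = "g")
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Residue coverage report for a shift table
#'
#' Partitions the residues of a sequence into assigned (at least one shift
#' observed), unassigned, and prolines, as done when reporting assignment
#' completeness of a disordered construct.
#'
#' @param table a [shift_table()].
#' @param sequence one-letter amino-acid string.
#' @param offset integer such that sequence position 1 corresponds to
#'   residue number \code{offset} (construct-absolute numbering).
#' @return A list with \code{assigned} (count of assigned non-proline
#'   residues), \code{assigned_residues}, \code{unassigned} (residue
#'   numbers of unassigned non-prolines), \code{prolines} (residue
#'   numbers), \code{n_nonproline}.
#' @export
validate_residue_coverage <- function(table, sequence, offset = 1L) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  res_nums <- seq_along(seq_chars) + as.integer(offset) - 1L
  in_range <- table$residue_number %in% res_nums
  tb <- table[in_range, , drop = FALSE]
  seq_type <- seq_chars[match(tb$residue_number, res_nums)]
  mism <- tb$residue_type != seq_type
  if (any(mism))
    stop("residue-type mismatch between table and sequence at position(s): ",
         paste(unique(tb$residue_number[mism]), collapse = ", "))
  pro <- res_nums[seq_chars == "P"]
  nonpro <- res_nums[seq_chars != "P"]
  assigned <- intersect(nonpro, unique(tb$residue_number))
  list(assigned = length(assigned),
       assigned_residues = sort(assigned),
       unassigned = sort(setdiff(nonpro, assigned)),
       prolines = pro,
       n_nonproline = length(nonpro))
}
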