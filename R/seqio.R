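#' @keywords internal
"_PACKAGE"

# The 20 canonical one-letter residue codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a peptide
#'
#' A peptide is a named amino-acid sequence over the 20 canonical one-letter
#' residue codes. Sequences are upper-cased on construction; ambiguity codes
#' (B, Z, X, J, U, O) and anything else outside the canonical alphabet are
#' rejected rather than silently scored. Positions are 1-based and inclusive
#' throughout the package, with the initiator methionine at position 1.
#'
#' @param id single character identifier.
#' @param seq single character string of residues (case-insensitive).
#' @return An object of class `peptide`: a list with elements `id` and `seq`.
#' @examples
#' p <- peptide("synTP", "MALRSSLRQLLRSATATASA")
#' nchar_peptide(p)
#' @export
peptide <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("peptide '", id, "': empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA20)
  if (length(bad)) {
    stop("peptide '", id, "': invalid residue '", chars[bad[1L]],
         "' at position ", bad[1L],
         " (only the 20 canonical residues are accepted)", call. = FALSE)
  }
  structure(list(id = id, seq = seq), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d aa)\n%s\n", x$id, nchar(x$seq), x$seq))
  invisible(x)
}

#' Peptide length in residues
#' @param p a `peptide`.
#' @return integer length.
#' @export
nchar_peptide <- function(p) nchar(p$seq)

#' Residues of a peptide as a character vector
#' @param p a `peptide`.
#' @return character vector, one element per position (position 1 = Met end).
#' @export
residues <- function(p) strsplit(p$seq, "", fixed = TRUE)[[1L]]

as_peptide_list <- function(x) {
  if (inherits(x, "peptide")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "peptide")))
  x
}

#' Read peptides from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that validates every
#' record against the canonical 20-letter alphabet. Record order is
#' preserved; the id of each peptide is the first whitespace-delimited token
#' of its header. Lowercase input is folded to uppercase.
#'
#' @param path path to a FASTA file.
#' @return list of [peptide()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  mapply(peptide, ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write peptides to a FASTA file
#'
#' @param peptides a `peptide` or list of peptides.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  peptides <- as_peptide_list(peptides)
  seqs <- vapply(peptides, function(p) p$seq, character(1))
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- vapply(peptides, function(p) p$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the whitespace-separated NCBI matrix text format (header row of
#' residue labels, `#` comment lines). Columns and rows outside the canonical
#' 20-letter alphabet (B, Z, X, `*`) are parsed but dropped with a message.
#' The resulting 20x20 matrix must be symmetric and complete, otherwise
#' parsing fails.
#'
#' The BLOSUM30 matrix used for N-terminal screening ships with the package:
#' `system.file("extdata", "BLOSUM30", package = "presqkit")`.
#'
#' @param path path to the matrix file.
#' @param name matrix name; defaults to the file's basename.
#' @return a `substitution_matrix`: an integer matrix with residue dimnames
#'   and attributes `name`.
#' @export
read_matrix <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- lapply(body, function(x) {
    v <- suppressWarnings(as.integer(x[-1L]))
    if (anyNA(v)) stop("non-integer score in matrix file: ", path, call. = FALSE)
    v
  })
  if (any(lengths(vals) != length(header)))
    stop("ragged matrix rows in: ", path, call. = FALSE)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rows, header)
  extra <- union(setdiff(rows, AA20), setdiff(header, AA20))
  if (length(extra))
    message("read_matrix: dropping non-canonical columns/rows: ",
            paste(extra, collapse = ", "))
  missing <- union(setdiff(AA20, rows), setdiff(AA20, header))
  if (length(missing))
    stop("matrix is missing residues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- m[AA20, AA20]
  if (!isTRUE(all.equal(m, t(m))))
    stop("asymmetric substitution matrix in: ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  structure(m, name = name, class = c("substitution_matrix", class(m)))
}

#' The shipped BLOSUM30 substitution matrix
#' @return a `substitution_matrix` (see [read_matrix()]).
#' @export
blosum30 <- function() {
  suppressMessages(
    read_matrix(system.file("extdata", "BLOSUM30", package = "presqkit"),
                name = "BLOSUM30"))
}

#' Read a presequence annotation table
#'
#' Tab-separated with a header row and `#` comments. Expected columns:
#' `protein_id`, `organelle` (one of `mito`, `chloro`, `other`), `tp_end`
#' (1-based inclusive end of the targeting peptide; 0 means none),
#' `helix_segments` (semicolon-separated `start-end` pairs, 1-based
#' inclusive, may be empty), `helix_class` (`single_alpha`, `multi_alpha`,
#' `beta`, `mixed`, `none`). Extra columns (e.g. predictor scores) pass
#' through untouched. Segments must lie within `1..tp_end`, be sorted and
#' non-overlapping.
#'
#' @param path path to the TSV.
#' @return a data.frame with a parsed `helix_segments` list-column of
#'   two-column matrices (`start`, `end`).
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "organelle", "tp_end", "helix_segments", "helix_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_org <- setdiff(unique(df$organelle), c("mito", "chloro", "other"))
  if (length(bad_org))
    stop("unknown organelle label(s): ", paste(bad_org, collapse = ", "),
         call. = FALSE)
  df$helix_segments <- lapply(seq_len(nrow(df)), function(i) {
    seg <- parse_segments(df$helix_segments[i])
    validate_segments(seg, df$tp_end[i], df$protein_id[i])
    seg
  })
  df
}

parse_segments <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)))
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1L]]
  se <- t(vapply(strsplit(parts, "-", fixed = TRUE), function(x) {
    v <- as.integer(x)
    if (length(v) != 2L || anyNA(v)) stop("bad helix segment: ", paste(x, collapse = "-"),
                                          call. = FALSE)
    v
  }, integer(2)))
  colnames(se) <- c("start", "end")
  se
}

validate_segments <- function(seg, tp_end, id) {
  if (nrow(seg) == 0L) return(invisible(TRUE))
  if (any(seg[, "start"] < 1L) || any(seg[, "end"] > tp_end) ||
      any(seg[, "start"] > seg[, "end"]))
    stop("protein '", id, "': helix segments must lie within 1..tp_end",
         call. = FALSE)
  if (is.unsorted(seg[, "start"], strictly = TRUE) ||
      any(seg[-1L, "start"] <= seg[-nrow(seg), "end"]))
    stop("protein '", id, "': helix segments must be sorted and non-overlapping",
         call. = FALSE)
  invisible(TRUE)
}

format_segments <- function(seg) {
  if (nrow(seg) == 0L) return("")
  paste(sprintf("%d-%d", seg[, "start"], seg[, "end"]), collapse = ";")
}

#' Read a pairwise-alignment overhang table
#'
#' Tab-separated, header row, `#` comments; columns `query_id`, `homolog_id`,
#' `query_aln_start` (1-based earliest aligned query position; 1 means the
#' homolog aligns from the very N-terminus).
#'
#' @param path path to the TSV.
#' @return data.frame with the three columns.
#' @export
read_overhangs <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("query_id", "homolog_id", "query_aln_start")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("overhang table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$query_aln_start < 1L))
    stop("query_aln_start must be >= 1", call. = FALSE)
  df
}

#' Write a data.frame as TSV
#'
#' The package's table dialect: tab-separated, header row, no quoting, no
#' row names. List-columns of helix segments are serialized as
#' `start-end;start-end`.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  if (!is.null(df$helix_segments) && is.list(df$helix_segments))
    df$helix_segments <- vapply(df$helix_segments, format_segments, character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
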