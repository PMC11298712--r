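# Presequence dataset construction: delineate targeting-peptide (TP) regions
# from N-terminal alignment overhangs, apply the 10-150 aa length filter,
# select single-alpha-helix TPs, summarize lengths.

#' Delineate a targeting peptide from homolog overhang starts
#'
#' A presequence is the N-terminal region of a precursor that its mature-part
#' homologs do not align to. Given the earliest aligned query position for
#' each homolog of one query protein, the TP end is
#' `aggregate(starts) - 1`; `tp_end = 0` means no presequence (the
#' N-terminus is conserved). The default median aggregation is robust to a
#' spurious full-length hit; for an even number of homologs a half-integer
#' median is floored (the conservative, shorter presequence).
#'
#' @param starts integer vector of 1-based earliest aligned query positions,
#'   one per homolog.
#' @param aggregation `"median"` (default), `"min"` or `"max"`.
#' @return integer `tp_end` (0 = no presequence).
#' @export
delineate_tp <- function(starts, aggregation = c("median", "min", "max")) {
  aggregation <- match.arg(aggregation)
  if (length(starts) == 0L) stop("no overhang rows for query", call. = FALSE)
  if (any(starts < 1L)) stop("aligned start positions must be >= 1", call. = FALSE)
  agg <- switch(aggregation,
                median = stats::median(starts),
                min = min(starts),
                max = max(starts))
  as.integer(floor(agg)) - 1L
}

#' Delineate every query in an overhang table
#'
#' @param overhangs data.frame as from [read_overhangs()].
#' @param aggregation passed to [delineate_tp()].
#' @return data.frame with `protein_id`, `tp_end`, `n_homologs`,
#'   `has_presequence`.
#' @export
delineate_all <- function(overhangs, aggregation = "median") {
  sp <- split(overhangs$query_aln_start, overhangs$query_id)
  tp_end <- vapply(sp, delineate_tp, integer(1), aggregation = aggregation)
  out <- data.frame(protein_id = names(sp),
                    tp_end = unname(tp_end),
                    n_homologs = unname(lengths(sp)),
                    has_presequence = unname(tp_end) > 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the presequence length filter
#'
#' Keeps records whose TP length lies in the inclusive band
#' `[min_len, max_len]` (default 10..150 residues); anything shorter or
#' longer is omitted. The partition is exhaustive.
#'
#' @param records data.frame with a `tp_length` column.
#' @param min_len,max_len inclusive bounds.
#' @return list with data.frames `kept` and `omitted`.
#' @export
apply_length_filter <- function(records, min_len = 10L, max_len = 150L) {
  stopifnot("tp_length" %in% names(records))
  keep <- records$tp_length >= min_len & records$tp_length <= max_len
  list(kept = records[keep, , drop = FALSE],
       omitted = records[!keep, , drop = FALSE])
}

#' Select single-alpha-helix presequence peptides
#'
#' Extracts the helix-segment subsequence of every record whose TP contains
#' exactly one annotated alpha-helix (`helix_class == "single_alpha"`), with
#' segment length below `max_len` residues (strictly, by default).
#'
#' @param records data.frame with `protein_id`, `helix_class`, a
#'   `helix_segments` list-column (see [read_annotations()]) and `tp_seq`
#'   (character TP sequence).
#' @param max_len length cutoff in residues.
#' @param strict_less if TRUE (default), keep segments with
#'   `length < max_len`; if FALSE, `length <= max_len`.
#' @return list of [peptide()]s (the helix subsequences).
#' @export
select_single_helices <- function(records, max_len = 25L, strict_less = TRUE) {
  stopifnot(all(c("protein_id", "helix_class", "helix_segments", "tp_seq")
                %in% names(records)))
  out <- list()
  for (i in seq_len(nrow(records))) {
    if (!identical(records$helix_class[i], "single_alpha")) next
    seg <- records$helix_segments[[i]]
    if (nrow(seg) != 1L) next
    # an annotated segment that runs past the (possibly re-delineated) TP
    # cannot be extracted in full; skip it
    if (seg[1, "end"] > nchar(records$tp_seq[i])) next
    len <- seg[1, "end"] - seg[1, "start"] + 1L
    ok <- if (strict_less) len < max_len else len <= max_len
    if (!ok) next
    sub <- substr(records$tp_seq[i], seg[1, "start"], seg[1, "end"])
    out[[length(out) + 1L]] <- peptide(records$protein_id[i], sub)
  }
  out
}

#' Summary statistics of TP lengths
#'
#' Mean and sample standard deviation (n - 1 denominator) of `tp_length`.
#' A single record yields sd 0 with a message.
#'
#' @param records data.frame with `tp_length`, or a numeric vector of lengths.
#' @return list with `n`, `mean`, `sd`.
#' @export
summarize_lengths <- function(records) {
  x <- if (is.data.frame(records)) records$tp_length else records
  if (length(x) == 0L) stop("no records to summarize", call. = FALSE)
  s <- if (length(x) == 1L) {
    message("summarize_lengths: single record, reporting sd = 0")
    0
  } else stats::sd(x)
  list(n = length(x), mean = mean(x), sd = s)
}

#' Build presequence records from a proteome and annotations
#'
#' Joins a proteome FASTA with an annotation table into enriched records:
#' TP subsequence, TP length, and the 10-150 aa filter flag.
#'
#' @param proteome list of peptides (full-length ORFs).
#' @param annotations data.frame from [read_annotations()].
#' @return data.frame of records (one per annotated protein with
#'   `tp_end >= 1`), with columns `protein_id`, `organelle`, `tp_seq`,
#'   `tp_length`, `helix_class`, `helix_segments`, `passed_filter`.
#' @export
build_records <- function(proteome, annotations) {
  seqs <- vapply(proteome, function(p) p$seq, character(1))
  names(seqs) <- vapply(proteome, function(p) p$id, character(1))
  ann <- annotations[annotations$tp_end >= 1L, , drop = FALSE]
  miss <- setdiff(ann$protein_id, names(seqs))
  if (length(miss))
    stop("annotated proteins absent from proteome: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  tp_seq <- substr(seqs[ann$protein_id], 1L, ann$tp_end)
  out <- data.frame(protein_id = ann$protein_id,
                    organelle = ann$organelle,
                    tp_seq = unname(tp_seq),
                    tp_length = nchar(tp_seq),
                    helix_class = ann$helix_class,
                    stringsAsFactors = FALSE)
  out$helix_segments <- ann$helix_segments
  out$passed_filter <- out$tp_length >= 10L & out$tp_length <= 150L
  rownames(out) <- NULL
  out
}
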