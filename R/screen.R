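# Ungapped substitution-matrix screening of proteome N-termini against a
# query peptide (the BLOSUM30 synTP screen).

#' Ungapped substitution-matrix score of two equal-length peptides
#'
#' Sum over aligned positions of the matrix score of the residue pair; no
#' gaps, no shifts.
#'
#' @param a,b [peptide()]s of equal length.
#' @param m a `substitution_matrix` (see [read_matrix()], [blosum30()]).
#' @return integer score in matrix units.
#' @export
ungapped_score <- function(a, b, m = blosum30()) {
  ra <- residues(a)
  rb <- residues(b)
  if (length(ra) != length(rb))
    stop("ungapped_score: peptides must have equal length (",
         length(ra), " vs ", length(rb), ")", call. = FALSE)
  sum(m[cbind(ra, rb)])
}

#' Screen a proteome's N-termini against a query peptide
#'
#' Scores the first `k` residues of every ORF against the query with
#' [ungapped_score()] and ranks ORFs by descending score. ORFs shorter than
#' `k` are skipped (a message reports how many); ranking is dense (equal
#' scores share a rank, ranks contiguous from 1) with a deterministic
#' secondary order by `orf_id`.
#'
#' @param proteome list of [peptide()]s (full-length ORFs).
#' @param query a [peptide()] of length `k`.
#' @param k N-terminal window length (default 24; window anchored at
#'   position 1, initiator Met included).
#' @param m a `substitution_matrix`.
#' @return data.frame with `orf_id`, `nterm_seq`, `score`, `rank`, sorted by
#'   descending score then `orf_id`.
#' @export
screen_proteome <- function(proteome, query, k = 24L, m = blosum30()) {
  proteome <- as_peptide_list(proteome)
  if (nchar_peptide(query) != k)
    stop("query length (", nchar_peptide(query), ") must equal k (", k, ")",
         call. = FALSE)
  lens <- vapply(proteome, nchar_peptide, integer(1))
  short <- sum(lens < k)
  if (short > 0L)
    message("screen_proteome: skipped ", short, " ORF(s) shorter than ", k,
            " residues")
  keep <- proteome[lens >= k]
  if (length(keep) == 0L) stop("no ORF of length >= k to screen", call. = FALSE)
  nterm <- vapply(keep, function(p) substr(p$seq, 1L, k), character(1))
  ids <- vapply(keep, function(p) p$id, character(1))
  qres <- residues(query)
  scores <- vapply(nterm, function(s) {
    sum(m[cbind(strsplit(s, "", fixed = TRUE)[[1L]], qres)])
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-scores, ids)
  out <- data.frame(orf_id = ids[ord],
                    nterm_seq = nterm[ord],
                    score = as.integer(scores[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- match(out$score, unique(out$score))  # dense rank, descending
  rownames(out) <- NULL
  out
}
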