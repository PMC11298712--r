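# Rule-based mitochondrial-targeting classifier. The rule encodes the
# experimentally derived requirements for a functional presequence in an
# organism whose TOM complex authenticates precursors through TOM22 alone:
#   (i)  at least `min_basic` basic residue(s) (R or K by default) within the
#        N-terminal window, outside the flanking positions {1, 2};
#   (ii) at most `max_acidic` acidic residue(s) (D or E) anywhere in the
#        window (default 0: a single remaining glutamate is enough to keep a
#        reporter cytosolic).
# Histidine is not counted basic by default: only R and K are demonstrated
# carriers of targeting activity.

#' Classifier parameters
#'
#' @param window N-terminal window length in residues (default 24).
#' @param min_basic minimum number of basic residues at non-flank window
#'   positions (default 1).
#' @param flank_excluded_positions window positions whose basic residues do
#'   not count toward `min_basic` (default `c(1, 2)`: position 1 is the
#'   initiator Met; a basic residue at position 2 does not support
#'   targeting).
#' @param max_acidic maximum number of acidic residues tolerated in the
#'   window (default 0).
#' @param basic_residues,acidic_residues residue sets counted by each clause.
#' @return a `rule_params` list.
#' @export
rule_params <- function(window = 24L, min_basic = 1L,
                        flank_excluded_positions = c(1L, 2L),
                        max_acidic = 0L,
                        basic_residues = c("R", "K"),
                        acidic_residues = c("D", "E")) {
  stopifnot(window >= 1L, min_basic >= 0L, max_acidic >= 0L)
  structure(list(window = as.integer(window),
                 min_basic = as.integer(min_basic),
                 flank_excluded_positions = as.integer(flank_excluded_positions),
                 max_acidic = as.integer(max_acidic),
                 basic_residues = toupper(basic_residues),
                 acidic_residues = toupper(acidic_residues)),
            class = "rule_params")
}

# Positions 3-5 (between the excluded flank and the first position shown to
# support targeting) were not probed experimentally; basic residues there are
# counted, and the call notes it.
UNTESTED_BASIC_POSITIONS <- 3:5

#' Predict mitochondrial targeting of a peptide
#'
#' Applies the two-clause rule of [rule_params()] to the N-terminal window
#' of a peptide. A peptide shorter than the window is evaluated over its
#' available length with a warning.
#'
#' @param p a [peptide()].
#' @param params a `rule_params` object.
#' @return a `localization_call`: list with `call` (`"mitochondrion"` or
#'   `"cytosol"`), `n_basic_nonflank`, `n_acidic`, and `reasons` (character
#'   vector recording the outcome of each clause).
#' @export
predict_targeting <- function(p, params = rule_params()) {
  res <- residues(p)
  if (length(res) < params$window)
    warning("peptide '", p$id, "' is shorter than the ", params$window,
            "-residue window; evaluating over ", length(res), " residues",
            call. = FALSE)
  win <- seq_len(min(params$window, length(res)))
  nonflank <- setdiff(win, params$flank_excluded_positions)
  n_basic <- sum(res[nonflank] %in% params$basic_residues)
  n_acidic <- sum(res[win] %in% params$acidic_residues)
  basic_ok <- n_basic >= params$min_basic
  acidic_ok <- n_acidic <= params$max_acidic
  reasons <- c(
    sprintf("basic clause %s: %d basic residue(s) at non-flank window positions (need >= %d)",
            if (basic_ok) "passed" else "failed", n_basic, params$min_basic),
    sprintf("acidic clause %s: %d acidic residue(s) in window (allow <= %d)",
            if (acidic_ok) "passed" else "failed", n_acidic, params$max_acidic))
  untested <- intersect(which(res %in% params$basic_residues),
                        intersect(nonflank, UNTESTED_BASIC_POSITIONS))
  if (length(untested))
    reasons <- c(reasons,
                 paste0("note: basic residue(s) at experimentally untested position(s) ",
                        paste(untested, collapse = ", "), " counted as supporting"))
  structure(list(call = if (basic_ok && acidic_ok) "mitochondrion" else "cytosol",
                 n_basic_nonflank = n_basic,
                 n_acidic = n_acidic,
                 reasons = reasons),
            class = "localization_call")
}

#' @export
print.localization_call <- function(x, ...) {
  cat("<localization_call>", x$call, "\n")
  for (r in x$reasons) cat(" -", r, "\n")
  invisible(x)
}

# Apply the rule clauses directly to a feature vector (used for
# figure-only constructs encoded as features instead of sequences).
predict_from_features <- function(window, basic_positions, n_acidic, params) {
  bp <- basic_positions[basic_positions <= min(window, params$window)]
  bp <- setdiff(bp, params$flank_excluded_positions)
  basic_ok <- length(bp) >= params$min_basic
  acidic_ok <- n_acidic <= params$max_acidic
  if (basic_ok && acidic_ok) "mitochondrion" else "cytosol"
}

parse_positions <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(integer(0))
  as.integer(strsplit(trimws(s), ",", fixed = TRUE)[[1L]])
}

#' Evaluate the classifier against a construct truth table
#'
#' Runs the rule classifier over a table of reporter constructs with known
#' localization outcomes and reports the agreement fraction and any
#' disagreements. Constructs may be given as sequences (`seq` column) or as
#' feature vectors (`window`, `basic_positions` as a comma-separated list,
#' `n_acidic`); the shipped fixture uses feature vectors because the full
#' construct sequences are not machine-readable.
#'
#' @param fixture data.frame with columns `label`, `observed`
#'   (`mitochondrion`/`cytosol`) and either `seq` or the feature columns.
#' @param params a `rule_params` object.
#' @return list with `accuracy`, `n`, and a per-construct `report`
#'   data.frame (`label`, `predicted`, `observed`, `agree`).
#' @export
evaluate_truth_table <- function(fixture, params = rule_params()) {
  if (nrow(fixture) == 0L) stop("empty truth table", call. = FALSE)
  predicted <- vapply(seq_len(nrow(fixture)), function(i) {
    row <- fixture[i, ]
    if (!is.null(row$seq) && !is.na(row$seq) && nzchar(row$seq)) {
      predict_targeting(peptide(row$label, row$seq), params)$call
    } else {
      predict_from_features(row$window, parse_positions(row$basic_positions),
                            row$n_acidic, params)
    }
  }, character(1))
  report <- data.frame(label = fixture$label,
                       predicted = predicted,
                       observed = fixture$observed,
                       agree = predicted == fixture$observed,
                       stringsAsFactors = FALSE)
  list(accuracy = mean(report$agree), n = nrow(report), report = report)
}

#' The shipped construct truth table
#'
#' Loads the 16-row fixture of reporter constructs with experimentally
#' observed localization (see [generate_truth_table()] for its provenance
#' and the enumeration of folded rows).
#'
#' @return data.frame.
#' @export
truth_table <- function() {
  utils::read.delim(system.file("extdata", "truth_table.tsv",
                                package = "presqkit"),
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(basic_positions = "character"))
}
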