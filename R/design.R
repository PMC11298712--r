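# Consensus-based synthetic presequence design and systematic variant
# generation: arginine-count series, lysine swap, arginine scanning, point
# mutants. All operations are substitution-only: no indels, output length
# always equals input length.

#' Consensus peptide design from aligned helices
#'
#' Builds a designed peptide by taking the modal residue at each of the
#' first `length` positions over a set of left-anchored helices (position p
#' is voted on by the helices of length >= p). Ties are resolved by the
#' configured rule and flagged so the design is auditable.
#'
#' @param helices list of peptides, anchored at position 1.
#' @param length design length in residues (default 24).
#' @param tie_break `"overall_freq"` (default: prefer the residue more
#'   frequent over all positions of the input set, then alphabetical) or
#'   `"alpha"` (alphabetical).
#' @return a `consensus_result`: list with `peptide` (the designed
#'   [peptide()]), and a `positions` data.frame (`position`, `residue`,
#'   `freq`, `tie`).
#' @export
consensus_design <- function(helices, length = 24L,
                             tie_break = c("overall_freq", "alpha")) {
  tie_break <- match.arg(tie_break)
  helices <- as_peptide_list(helices)
  fm <- frequency_matrix(helices, length = length)
  if (any(fm$coverage == 0L))
    stop("no input helix covers position ",
         which(fm$coverage == 0L)[1L], call. = FALSE)
  overall <- colSums(fm$counts)
  pick <- function(i) {
    cnt <- fm$counts[i, ]
    top <- names(cnt)[cnt == max(cnt)]
    tie <- length(top) > 1L
    if (tie && tie_break == "overall_freq") {
      top <- top[order(-overall[top], top)]
    } else {
      top <- sort(top)
    }
    list(residue = top[1L], freq = fm$freqs[i, top[1L]], tie = tie)
  }
  picks <- lapply(seq_len(length), pick)
  pos <- data.frame(position = seq_len(length),
                    residue = vapply(picks, `[[`, character(1), "residue"),
                    freq = vapply(picks, `[[`, numeric(1), "freq"),
                    tie = vapply(picks, `[[`, logical(1), "tie"))
  structure(list(peptide = peptide("consensus", paste(pos$residue, collapse = "")),
                 positions = pos),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s  (%d ties)\n", x$peptide$seq,
              sum(x$positions$tie)))
  invisible(x)
}

substitute_positions <- function(p, positions, new_residues, id = p$id) {
  res <- residues(p)
  if (any(positions < 1L | positions > length(res)))
    stop("substitution position out of range for '", p$id, "'", call. = FALSE)
  if (anyDuplicated(positions))
    stop("duplicate substitution positions", call. = FALSE)
  res[positions] <- new_residues
  peptide(id, paste(res, collapse = ""))
}

#' Charge-adjust a consensus design by explicit substitutions
#'
#' Applies `(position, residue)` substitutions to a consensus design — the
#' step that brings the designed peptide's net charge down toward the
#' endogenous mean by replacing surplus arginines (e.g. one with leucine,
#' one with serine). A warning is raised if a substituted position does not
#' currently hold arginine.
#'
#' @param consensus a `consensus_result` or a [peptide()].
#' @param substitutions data.frame/list with `position` and `residue`
#'   vectors; empty for the identity.
#' @param id id of the resulting peptide.
#' @return the substituted [peptide()].
#' @export
charge_adjust <- function(consensus, substitutions, id = "synTP") {
  p <- if (inherits(consensus, "consensus_result")) consensus$peptide else consensus
  pos <- as.integer(substitutions$position)
  new <- as.character(substitutions$residue)
  if (length(pos) == 0L) return(peptide(id, p$seq))
  if (any(pos < 1L | pos > nchar_peptide(p)))
    stop("charge_adjust: substitution position out of range", call. = FALSE)
  cur <- residues(p)[pos]
  if (any(cur != "R"))
    warning("charge_adjust: position(s) ",
            paste(pos[cur != "R"], collapse = ", "),
            " do not hold arginine", call. = FALSE)
  substitute_positions(p, pos, toupper(new), id = id)
}

#' Suggest charge-adjusting substitutions
#'
#' Greedy helper: replaces arginines one at a time (each with the given
#' replacement residues, in order) until the peptide's net charge is as
#' close as possible to `target_charge`. Arginines are considered in
#' position order.
#'
#' @param p a [peptide()].
#' @param target_charge target net charge in e (default 2.80, the endogenous
#'   single-helix mean at pH 7).
#' @param replacements residues used for successive replacements, recycled.
#' @param pka,pH,include_termini passed to [net_charge()].
#' @return data.frame with `position`, `residue` — ready for
#'   [charge_adjust()] (possibly zero rows).
#' @export
suggest_charge_adjust <- function(p, target_charge = 2.80,
                                  replacements = c("L", "S"),
                                  pka = pka_set("protcalc"), pH = 7,
                                  include_termini = TRUE) {
  rpos <- which(residues(p) == "R")
  best <- data.frame(position = integer(0), residue = character(0))
  best_err <- abs(net_charge(p, pka, pH, include_termini) - target_charge)
  cur <- p
  subs <- best
  for (k in seq_along(rpos)) {
    repl <- replacements[(k - 1L) %% length(replacements) + 1L]
    cur <- substitute_positions(cur, rpos[k], repl)
    subs <- rbind(subs, data.frame(position = rpos[k], residue = repl))
    err <- abs(net_charge(cur, pka, pH, include_termini) - target_charge)
    if (err < best_err) {
      best_err <- err
      best <- subs
    }
  }
  best
}

variant <- function(label, base, positions, residues_new) {
  list(label = label,
       base = base,
       substitutions = data.frame(position = as.integer(positions),
                                  residue = as.character(residues_new)),
       peptide = if (length(positions))
         substitute_positions(base, as.integer(positions),
                              as.character(residues_new), id = label)
       else peptide(label, base$seq))
}

#' Arginine-count variant series
#'
#' From a base peptide with n arginines, emits the series with arginines
#' progressively replaced down to zero, plus an all-R-to-K swap:
#' labels `<id>_3R`, `<id>_2R`, ... `<id>_0R`, `<id>_3K` for a 3-arginine
#' base. Arginines are removed in ascending position order by default, each
#' replaced by the next residue of `replacements` (recycled).
#'
#' @param base a [peptide()] containing at least one arginine.
#' @param replacements neutral replacement residues, used in removal order.
#' @param remove_order `"ascending"` (default) or `"descending"` position
#'   order of arginine removal.
#' @return list of variant specs, each a list with `label`, `base`,
#'   `substitutions` and the realized `peptide`.
#' @export
arg_series <- function(base, replacements = c("L", "S"),
                       remove_order = c("ascending", "descending")) {
  remove_order <- match.arg(remove_order)
  rpos <- which(residues(base) == "R")
  if (length(rpos) == 0L)
    stop("arg_series: base peptide contains no arginine", call. = FALSE)
  if (remove_order == "descending") rpos <- rev(rpos)
  n <- length(rpos)
  out <- vector("list", n + 2L)
  for (k in 0:n) {
    lab <- sprintf("%s_%dR", base$id, n - k)
    pos <- rpos[seq_len(k)]
    repl <- replacements[((seq_len(k) - 1L) %% length(replacements)) + 1L]
    out[[k + 1L]] <- variant(lab, base, pos, repl)
  }
  out[[n + 2L]] <- variant(sprintf("%s_%dK", base$id, n), base,
                           sort(rpos), rep("K", n))
  out
}

#' Arginine scanning
#'
#' Places a single arginine at each listed position of an arginine-free base
#' peptide, one variant per position (labels `<id>_R<pos>`).
#'
#' @param base0R a [peptide()] containing no arginine.
#' @param positions 1-based positions to scan (default the canonical
#'   +2/+6/+8/+9/+12/+13/+15/+21 set).
#' @return list of variant specs (see [arg_series()]).
#' @export
arg_scan <- function(base0R, positions = c(2L, 6L, 8L, 9L, 12L, 13L, 15L, 21L)) {
  if (any(residues(base0R) == "R"))
    stop("arg_scan: base peptide must contain no arginine", call. = FALSE)
  if (anyDuplicated(positions))
    stop("arg_scan: duplicate positions", call. = FALSE)
  lapply(as.integer(positions), function(pos)
    variant(sprintf("%s_R%d", base0R$id, pos), base0R, pos, "R"))
}

#' Point mutants
#'
#' Generates single mutants and, optionally, every combination of the listed
#' mutations, with standard labels (`E2A`, `E18A`, `E2A/E18A`, ...). Each
#' mutation's `from` residue must match the base sequence.
#'
#' @param base a [peptide()].
#' @param muts data.frame with `position`, `from`, `to`.
#' @param combos if TRUE, also emit all higher-order combinations.
#' @return list of variant specs (see [arg_series()]).
#' @export
point_mutants <- function(base, muts, combos = TRUE) {
  pos <- as.integer(muts$position)
  from <- toupper(as.character(muts$from))
  to <- toupper(as.character(muts$to))
  cur <- residues(base)[pos]
  if (any(cur != from))
    stop("point_mutants: base residue mismatch at position(s) ",
         paste(pos[cur != from], collapse = ", "), call. = FALSE)
  sizes <- if (combos) seq_along(pos) else 1L
  out <- list()
  for (k in sizes) {
    for (idx in utils::combn(seq_along(pos), k, simplify = FALSE)) {
      lab <- paste(sprintf("%s%d%s", from[idx], pos[idx], to[idx]),
                   collapse = "/")
      out[[length(out) + 1L]] <- variant(lab, base, pos[idx], to[idx])
    }
  }
  out
}
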