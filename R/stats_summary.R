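# Dataset-level summaries: composition reports, physicochemical aggregates,
# and N-terminal-domain charge for receptor comparisons.

#' Composition report for a peptide set
#'
#' Pooled-residue class fractions plus the 20-residue frequency vector for a
#' named peptide set — the numbers behind a composition bar chart.
#'
#' @param peptides a `peptide` or list of peptides.
#' @param scheme residue class scheme (see [default_class_scheme()]).
#' @param name set label.
#' @return a `composition_report`: list with `name`, `n_sequences`,
#'   `n_residues`, `class_fractions` (length 4), `residue_freqs` (length 20,
#'   sums to 1).
#' @export
composition_report <- function(peptides, scheme = default_class_scheme(),
                               name = "peptide set") {
  peptides <- as_peptide_list(peptides)
  if (length(peptides) == 0L) stop("empty peptide set", call. = FALSE)
  res <- unlist(lapply(peptides, residues), use.names = FALSE)
  freqs <- as.numeric(table(factor(res, levels = AA20))) / length(res)
  names(freqs) <- AA20
  structure(list(name = name,
                 n_sequences = length(peptides),
                 n_residues = length(res),
                 class_fractions = class_composition(peptides, scheme),
                 residue_freqs = freqs),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %s: %d sequences, %d residues\n",
              x$name, x$n_sequences, x$n_residues))
  print(round(100 * x$class_fractions, 1))
  invisible(x)
}

#' Physicochemical aggregates over a peptide set
#'
#' Computes a [physchem_profile()] per peptide, then the mean and sample
#' standard deviation (n - 1) of net charge, mean hydrophobicity and
#' hydrophobic moment.
#'
#' @inheritParams physchem_profile
#' @param peptides list of peptides.
#' @return list with `n`, `profiles` (per-peptide data.frame), and `summary`
#'   (data.frame with `property`, `mean`, `sd`).
#' @export
physchem_aggregate <- function(peptides, pka = pka_set("protcalc"), pH = 7,
                               include_termini = TRUE,
                               scale = fauchere_pliska(), delta_deg = 100,
                               window = NULL, scheme = default_class_scheme()) {
  peptides <- as_peptide_list(peptides)
  if (length(peptides) == 0L) stop("empty peptide set", call. = FALSE)
  profiles <- do.call(rbind, lapply(peptides, physchem_profile,
                                    pka = pka, pH = pH,
                                    include_termini = include_termini,
                                    scale = scale, delta_deg = delta_deg,
                                    window = window, scheme = scheme))
  props <- c("net_charge", "mean_hydrophobicity", "hydrophobic_moment")
  summ <- data.frame(
    property = props,
    mean = vapply(props, function(p) mean(profiles[[p]]), numeric(1)),
    sd = vapply(props, function(p)
      if (nrow(profiles) > 1L) stats::sd(profiles[[p]]) else 0, numeric(1)))
  rownames(summ) <- NULL
  list(n = length(peptides), profiles = profiles, summary = summ)
}

#' Reproduce dataset-level summaries from a curated presequence directory
#'
#' Convenience entry point over a directory holding a curated presequence
#' dataset in the package's formats: `presequences.tsv` (TSV with
#' `protein_id`, `organelle`, `tp_length`) and `helices.fasta` (the
#' single-alpha-helix peptides, < 25 aa). Applies the 10-150 aa length
#' filter, then computes per-organelle length statistics, the helix-set
#' composition report and physicochemical aggregates — the full
#' dataset-level summary in one call.
#'
#' @param dir directory containing the two files.
#' @param pka,pH see [net_charge()].
#' @return list with `lengths` (per-organelle [summarize_lengths()]
#'   results), `n_helices`, `composition` (helix-set
#'   [composition_report()]), and `physchem` ([physchem_aggregate()]
#'   summary).
#' @export
dataset_summary <- function(dir, pka = pka_set("protcalc"), pH = 7) {
  pre_path <- file.path(dir, "presequences.tsv")
  hel_path <- file.path(dir, "helices.fasta")
  for (f in c(pre_path, hel_path))
    if (!file.exists(f)) stop("missing dataset file: ", f, call. = FALSE)
  pre <- utils::read.delim(pre_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  kept <- apply_length_filter(pre)$kept
  lengths <- lapply(split(kept, kept$organelle), summarize_lengths)
  helices <- read_fasta(hel_path)
  helices <- Filter(function(p) nchar_peptide(p) < 25L, helices)
  list(lengths = lengths,
       n_helices = length(helices),
       composition = composition_report(helices, name = "single helices"),
       physchem = physchem_aggregate(helices, pka = pka, pH = pH))
}

#' Net charge of an N-terminal domain
#'
#' Charge at `pH` of residues `1..domain_end` of a protein, with the free
#' N-terminal amine included and the C-terminal carboxylate excluded (the
#' chain continues past the truncation point in the intact protein). Used
#' for comparing the cytosol-facing N-terminal domains of presequence
#' receptors. Set `include_cterm = TRUE` to treat the domain as a free
#' peptide instead.
#'
#' @param p a [peptide()] (the full protein).
#' @param domain_end 1-based inclusive end of the domain.
#' @param pka,pH see [net_charge()].
#' @param include_cterm include the C-terminal carboxylate (default FALSE).
#' @return net charge in e.
#' @export
domain_charge <- function(p, domain_end, pka = pka_set("protcalc"), pH = 7,
                          include_cterm = FALSE) {
  if (domain_end < 1L || domain_end > nchar_peptide(p))
    stop("domain_end out of range for '", p$id, "'", call. = FALSE)
  dom <- peptide(paste0(p$id, "_1-", domain_end),
                 substr(p$seq, 1L, domain_end))
  net_charge(dom, pka = pka, pH = pH,
             include_termini = TRUE, include_cterm = include_cterm)
}
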