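# Peptide physicochemistry: class composition, Henderson-Hasselbalch net
# charge, mean hydrophobicity, hydrophobic moment, helical wheel, positional
# frequency matrices.

#' Default residue class scheme
#'
#' Standard textbook grouping of the 20 residues into four chemical classes:
#' basic \{K, R, H\}, acidic \{D, E\}, polar uncharged \{S, T, N, Q, C, Y\},
#' nonpolar \{G, A, V, L, I, P, F, M, W\}. Every residue belongs to exactly
#' one class.
#'
#' @return named character vector mapping residue to class.
#' @export
default_class_scheme <- function() {
  c(K = "basic", R = "basic", H = "basic",
    D = "acidic", E = "acidic",
    S = "polar_uncharged", T = "polar_uncharged", N = "polar_uncharged",
    Q = "polar_uncharged", C = "polar_uncharged", Y = "polar_uncharged",
    G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
    I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
    W = "nonpolar")
}

RESIDUE_CLASSES <- c("basic", "acidic", "polar_uncharged", "nonpolar")

check_scheme <- function(scheme) {
  if (!setequal(names(scheme), AA20) || anyDuplicated(names(scheme)))
    stop("class scheme must cover the 20 residues exactly once", call. = FALSE)
  invisible(scheme)
}

#' Fauchere-Pliska hydrophobicity scale
#'
#' The octanol/water partition scale of Fauchere & Pliska, the scale used by
#' the HELIQUEST helix analysis server. Dimensionless H units.
#'
#' @return named numeric vector over the 20 residues.
#' @export
fauchere_pliska <- function() {
  c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
    Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
    L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
    S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)
}

check_scale <- function(scale) {
  if (!all(AA20 %in% names(scale)))
    stop("hydrophobicity scale must define all 20 residues", call. = FALSE)
  invisible(scale)
}

#' Ionizable-group pKa presets
#'
#' Two shipped sets. `"protcalc"` (the default) approximates the Protein
#' Calculator v3.4 values: N-terminus 8.0, C-terminus 3.1, K 10.0, R 12.0,
#' H 6.5, D 4.4, E 4.4, C 8.5, Y 10.0. `"emboss"` carries the EMBOSS
#' defaults: N-terminus 8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9,
#' E 4.1, C 8.5, Y 10.1.
#'
#' @param name `"protcalc"` or `"emboss"`.
#' @return named numeric vector with elements K, R, H, D, E, C, Y, Nterm,
#'   Cterm.
#' @export
pka_set <- function(name = c("protcalc", "emboss")) {
  name <- match.arg(name)
  set <- switch(name,
    protcalc = c(K = 10.0, R = 12.0, H = 6.5, D = 4.4, E = 4.4,
                 C = 8.5, Y = 10.0, Nterm = 8.0, Cterm = 3.1),
    emboss   = c(K = 10.8, R = 12.5, H = 6.5, D = 3.9, E = 4.1,
                 C = 8.5, Y = 10.1, Nterm = 8.6, Cterm = 3.6))
  structure(set, name = name)
}

check_pka <- function(pka) {
  need <- c("K", "R", "H", "D", "E", "C", "Y", "Nterm", "Cterm")
  if (!all(need %in% names(pka)))
    stop("pKa set must define ", paste(need, collapse = ", "), call. = FALSE)
  if (any(pka <= 0) || any(pka >= 14))
    stop("pKa values must lie in (0, 14)", call. = FALSE)
  invisible(pka)
}

#' Class composition of a peptide set
#'
#' Fractions of basic / acidic / polar uncharged / nonpolar residues over the
#' pooled residues of all input peptides.
#'
#' @param peptides a `peptide` or list of peptides.
#' @param scheme residue class scheme (see [default_class_scheme()]).
#' @return named numeric vector of the four class fractions, summing to 1.
#' @export
class_composition <- function(peptides, scheme = default_class_scheme()) {
  check_scheme(scheme)
  peptides <- as_peptide_list(peptides)
  if (length(peptides) == 0L) stop("empty peptide set", call. = FALSE)
  res <- unlist(lapply(peptides, residues), use.names = FALSE)
  cls <- factor(scheme[res], levels = RESIDUE_CLASSES)
  frac <- as.numeric(table(cls)) / length(res)
  names(frac) <- RESIDUE_CLASSES
  frac
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: each positive group
#' (N-terminus if included, K, R, H) contributes
#' \eqn{+1/(1+10^{pH-pKa})}; each negative group (C-terminus if included,
#' D, E, C, Y) contributes \eqn{-1/(1+10^{pKa-pH})}.
#'
#' @param p a `peptide`.
#' @param pka a pKa set (see [pka_set()]).
#' @param pH solution pH, in (0, 14).
#' @param include_termini include the free terminal amine/carboxylate
#'   (default TRUE). For internal truncations use [domain_charge()].
#' @param include_cterm override for the C-terminal carboxylate only;
#'   defaults to `include_termini`.
#' @return net charge in elementary charge units (e).
#' @export
net_charge <- function(p, pka = pka_set("protcalc"), pH = 7,
                       include_termini = TRUE,
                       include_cterm = include_termini) {
  check_pka(pka)
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)", call. = FALSE)
  res <- residues(p)
  n <- table(factor(res, levels = AA20))
  pos <- sum(vapply(c("K", "R", "H"), function(a)
    n[[a]] / (1 + 10^(pH - pka[[a]])), numeric(1)))
  neg <- sum(vapply(c("D", "E", "C", "Y"), function(a)
    n[[a]] / (1 + 10^(pka[[a]] - pH)), numeric(1)))
  q <- pos - neg
  if (include_termini) q <- q + 1 / (1 + 10^(pH - pka[["Nterm"]]))
  if (include_cterm)   q <- q - 1 / (1 + 10^(pka[["Cterm"]] - pH))
  q
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of per-residue hydrophobicity values.
#'
#' @param p a `peptide`.
#' @param scale hydrophobicity scale (default [fauchere_pliska()]).
#' @return mean hydrophobicity H.
#' @export
mean_hydrophobicity <- function(p, scale = fauchere_pliska()) {
  check_scale(scale)
  mean(scale[residues(p)])
}

#' Hydrophobic moment
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed at
#' `delta_deg` angular increments around an ideal helix, normalized by
#' peptide length (the mean-vector convention):
#' \deqn{\mu H = \frac{1}{N}\sqrt{\left(\sum_i H_i\cos\delta(i-1)\right)^2 +
#'  \left(\sum_i H_i\sin\delta(i-1)\right)^2}}
#'
#' With `window` set, the maximum moment over all windows of that length is
#' returned instead (HELIQUEST-style windowed scan; windows longer than the
#' peptide fall back to the full length).
#'
#' @param p a `peptide`.
#' @param scale hydrophobicity scale.
#' @param delta_deg angular step per residue in degrees (100 for an ideal
#'   alpha-helix).
#' @param window optional window length (e.g. 18); NULL computes over the
#'   full peptide.
#' @return hydrophobic moment (>= 0), in the scale's H units.
#' @export
hydrophobic_moment <- function(p, scale = fauchere_pliska(), delta_deg = 100,
                               window = NULL) {
  check_scale(scale)
  h <- unname(scale[residues(p)])
  if (is.null(window) || window >= length(h)) return(moment_of(h, delta_deg))
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  starts <- seq_len(length(h) - window + 1L)
  max(vapply(starts, function(s) moment_of(h[s:(s + window - 1L)], delta_deg),
             numeric(1)))
}

moment_of <- function(h, delta_deg) {
  ang <- (seq_along(h) - 1) * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

#' Helical-wheel projection
#'
#' Places residue i at angle `(i - 1) * delta_deg mod 360` on an ideal
#' helical wheel.
#'
#' @param p a `peptide`.
#' @param delta_deg angular step per residue in degrees.
#' @return data.frame with `position`, `residue`, `angle_deg`.
#' @export
helical_wheel <- function(p, delta_deg = 100) {
  res <- residues(p)
  data.frame(position = seq_along(res),
             residue = res,
             angle_deg = ((seq_along(res) - 1) * delta_deg) %% 360)
}

#' Per-position residue frequency matrix
#'
#' Counts residue occurrences at each of the first `length` positions over a
#' set of left-anchored peptides (all aligned at position 1). Position p is
#' counted over the sequences of length >= p ("coverage"); frequencies are
#' normalized by coverage. This is the data behind a sequence logo and the
#' source for consensus design.
#'
#' @param peptides list of peptides, anchored at position 1.
#' @param length number of positions; defaults to the longest input.
#' @return a `frequency_matrix`: list with `counts` and `freqs`
#'   (length x 20 matrices) and `coverage` (integer vector).
#' @export
frequency_matrix <- function(peptides, length = NULL) {
  peptides <- as_peptide_list(peptides)
  if (base::length(peptides) == 0L) stop("empty peptide set", call. = FALSE)
  lens <- vapply(peptides, nchar_peptide, integer(1))
  if (is.null(length)) length <- max(lens)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  counts <- matrix(0L, nrow = length, ncol = 20, dimnames = list(NULL, AA20))
  for (p in peptides) {
    res <- residues(p)
    k <- min(base::length(res), length)
    for (i in seq_len(k)) counts[i, res[i]] <- counts[i, res[i]] + 1L
  }
  coverage <- vapply(seq_len(length), function(i) sum(lens >= i), integer(1))
  freqs <- counts / ifelse(coverage > 0L, coverage, NA_integer_)
  structure(list(counts = counts, freqs = freqs, coverage = coverage),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d positions, coverage %d..%d\n",
              nrow(x$counts), min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Export a frequency matrix as TSV
#'
#' One row per position: `position`, `coverage`, then the 20 residue
#' frequencies — directly consumable by logo-plotting tools.
#'
#' @param fm a `frequency_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(fm, path) {
  df <- data.frame(position = seq_len(nrow(fm$freqs)), coverage = fm$coverage)
  df <- cbind(df, as.data.frame(fm$freqs))
  write_tsv(df, path)
}

#' Full physicochemical profile of a peptide
#'
#' Length, net charge at `pH`, mean hydrophobicity, hydrophobic moment, and
#' the four class fractions, in one row.
#'
#' @inheritParams net_charge
#' @inheritParams hydrophobic_moment
#' @param scheme residue class scheme.
#' @return one-row data.frame (`id`, `length`, `net_charge`,
#'   `mean_hydrophobicity`, `hydrophobic_moment`, `frac_basic`, `frac_acidic`,
#'   `frac_polar_uncharged`, `frac_nonpolar`).
#' @export
physchem_profile <- function(p, pka = pka_set("protcalc"), pH = 7,
                             include_termini = TRUE,
                             scale = fauchere_pliska(), delta_deg = 100,
                             window = NULL, scheme = default_class_scheme()) {
  cc <- class_composition(p, scheme)
  data.frame(id = p$id,
             length = nchar_peptide(p),
             net_charge = net_charge(p, pka, pH, include_termini),
             mean_hydrophobicity = mean_hydrophobicity(p, scale),
             hydrophobic_moment = hydrophobic_moment(p, scale, delta_deg, window),
             frac_basic = cc[["basic"]],
             frac_acidic = cc[["acidic"]],
             frac_polar_uncharged = cc[["polar_uncharged"]],
             frac_nonpolar = cc[["nonpolar"]])
}
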