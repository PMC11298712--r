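# Synthetic-data generator: proteomes with planted targeting peptides,
# homolog-overhang tables, and the construct truth-table fixture. Every
# stage of the pipeline can run on this output without external downloads.

# Run code under a temporary RNG state seeded from `seed`, restoring any
# pre-existing state afterwards (one documented stream, no global leakage).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Spread class-level fractions uniformly over the residues of each class.
class_profile_to_freqs <- function(class_fracs, scheme = default_class_scheme()) {
  check_scheme(scheme)
  stopifnot(setequal(names(class_fracs), RESIDUE_CLASSES))
  class_fracs <- class_fracs / sum(class_fracs)
  freqs <- vapply(AA20, function(a) {
    cls <- scheme[[a]]
    class_fracs[[cls]] / sum(scheme == cls)
  }, numeric(1))
  freqs
}

#' Specification of a synthetic proteome
#'
#' Defaults emulate a minimal single-exon genome: 4803 single-exon ORFs; background
#' residue composition with class fractions 11.2% basic / 14.0% acidic /
#' 22.2% polar uncharged / 52.5% nonpolar (spread uniformly within classes);
#' mitochondrial TP lengths Normal(59.3, 23.4) and chloroplast TP lengths
#' Normal(78.4, 17.3), truncated to 10..150 by redraw; planted TP/helix
#' residues drawn from the presequence-helix class profile 17.3% / 3.6% /
#' 26.2% / 52.9%. 14% of ORFs carry a TP, split evenly between the two
#' organelles (roughly the 336/349 putative organellar proteins of a
#' 4803-ORF genome).
#'
#' @param n_orfs number of ORFs.
#' @param orf_meanlog,orf_sdlog log-normal parameters of mature-region
#'   length.
#' @param background_freqs 20-residue background frequency vector (sums
#'   to 1); defaults to the all-ORF class profile spread within classes.
#' @param helix_freqs 20-residue frequency vector for planted TP/helix
#'   residues; defaults to the presequence-helix class profile spread within
#'   classes.
#' @param tp_fraction fraction of ORFs carrying a TP (mito and chloro
#'   together).
#' @param mito_mean,mito_sd,chloro_mean,chloro_sd TP length distributions.
#' @param tp_len_range inclusive truncation bounds for TP lengths.
#' @return a `proteome_spec` list.
#' @export
proteome_spec <- function(n_orfs = 4803L,
                          orf_meanlog = log(350), orf_sdlog = 0.5,
                          background_freqs = class_profile_to_freqs(
                            c(basic = 0.112, acidic = 0.140,
                              polar_uncharged = 0.222, nonpolar = 0.525)),
                          helix_freqs = class_profile_to_freqs(
                            c(basic = 0.173, acidic = 0.036,
                              polar_uncharged = 0.262, nonpolar = 0.529)),
                          tp_fraction = 0.14,
                          mito_mean = 59.3, mito_sd = 23.4,
                          chloro_mean = 78.4, chloro_sd = 17.3,
                          tp_len_range = c(10L, 150L)) {
  stopifnot(n_orfs >= 1L, tp_fraction >= 0, tp_fraction <= 1,
            abs(sum(background_freqs) - 1) < 1e-9,
            abs(sum(helix_freqs) - 1) < 1e-9,
            all(names(background_freqs) == AA20),
            all(names(helix_freqs) == AA20))
  structure(list(n_orfs = as.integer(n_orfs),
                 orf_meanlog = orf_meanlog, orf_sdlog = orf_sdlog,
                 background_freqs = background_freqs,
                 helix_freqs = helix_freqs,
                 tp_fraction = tp_fraction,
                 mito_mean = mito_mean, mito_sd = mito_sd,
                 chloro_mean = chloro_mean, chloro_sd = chloro_sd,
                 tp_len_range = as.integer(tp_len_range)),
            class = "proteome_spec")
}

# Mean and sd of a Normal(mu, sigma) truncated to [a, b].
truncated_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  lam <- (stats::dnorm(al) - stats::dnorm(be)) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z -
                    lam^2)
  c(mean = m, sd = sqrt(v))
}

# Parent Normal(mu, sigma) whose [a, b]-truncation has the target mean/sd.
# The published length statistics are post-filter moments, so planted
# lengths must match them after truncation, not before.
truncated_normal_parent <- function(target_mean, target_sd, range) {
  obj <- function(par) {
    mo <- truncated_moments(par[1L], exp(par[2L]), range[1L], range[2L])
    (mo[["mean"]] - target_mean)^2 + (mo[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1L], sd = exp(fit$par[2L]))
}

rtrunc_norm_int <- function(n, mean, sd, range) {
  parent <- truncated_normal_parent(mean, sd, range)
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(stats::rnorm(n, parent[["mean"]], parent[["sd"]])))
    out <- c(out, x[x >= range[1L] & x <= range[2L]])
  }
  out[seq_len(n)]
}

draw_residues <- function(n, freqs) {
  if (n <= 0L) return(character(0))
  sample(AA20, n, replace = TRUE, prob = freqs)
}

#' Generate a synthetic proteome with planted targeting peptides
#'
#' Every ORF starts with methionine. A `tp_fraction` of ORFs (split evenly
#' mito/chloro) carries a planted TP: residues 2..tp_end drawn from the
#' helix profile, with a single annotated alpha-helix segment of 10-24
#' residues inside the TP and at least one basic residue (R/K) guaranteed at
#' a non-flank position (>= 3) within that segment. The mature region and
#' TP-free ORFs are drawn from the background profile. Deterministic given
#' `seed`.
#'
#' @param spec a [proteome_spec()].
#' @param seed integer seed (mandatory).
#' @return list with `proteome` (list of [peptide()]s) and `annotations`
#'   (ground-truth data.frame: `protein_id`, `organelle`, `tp_end`,
#'   `helix_segments` list-column, `helix_class`).
#' @export
generate_proteome <- function(spec = proteome_spec(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed(seed, {
    n <- spec$n_orfs
    n_tp <- round(spec$tp_fraction * n)
    n_mito <- floor(n_tp / 2)
    n_chloro <- n_tp - n_mito
    organelle <- rep("other", n)
    if (n_tp > 0L)
      organelle[sample.int(n, n_tp)] <- rep(c("mito", "chloro"),
                                            c(n_mito, n_chloro))
    tp_end <- integer(n)
    is_m <- organelle == "mito"
    is_c <- organelle == "chloro"
    tp_end[is_m] <- rtrunc_norm_int(sum(is_m), spec$mito_mean, spec$mito_sd,
                                    spec$tp_len_range)
    tp_end[is_c] <- rtrunc_norm_int(sum(is_c), spec$chloro_mean, spec$chloro_sd,
                                    spec$tp_len_range)
    mature_len <- pmax(30L, as.integer(round(
      stats::rlnorm(n, spec$orf_meanlog, spec$orf_sdlog))))
    ids <- sprintf("ORF%05d", seq_len(n))
    proteome <- vector("list", n)
    segs <- vector("list", n)
    for (i in seq_len(n)) {
      if (tp_end[i] > 0L) {
        tp <- c("M", draw_residues(tp_end[i] - 1L, spec$helix_freqs))
        hl <- sample(10:24, 1L)
        hl <- min(hl, tp_end[i] - 1L)
        hstarts <- 2:(tp_end[i] - hl + 1L)
        hstart <- if (length(hstarts) == 1L) hstarts else sample(hstarts, 1L)
        hend <- hstart + hl - 1L
        basic_ok <- seq.int(max(hstart, 3L), hend)
        if (!any(tp[basic_ok] %in% c("R", "K")))
          tp[sample(basic_ok, 1L)] <- sample(c("R", "K"), 1L)
        segs[[i]] <- matrix(c(hstart, hend), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
        body <- draw_residues(mature_len[i], spec$background_freqs)
        proteome[[i]] <- peptide(ids[i], paste(c(tp, body), collapse = ""))
      } else {
        segs[[i]] <- matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
        body <- draw_residues(mature_len[i] - 1L, spec$background_freqs)
        proteome[[i]] <- peptide(ids[i], paste(c("M", body), collapse = ""))
      }
    }
    ann <- data.frame(protein_id = ids,
                      organelle = organelle,
                      tp_end = tp_end,
                      helix_class = ifelse(tp_end > 0L, "single_alpha", "none"),
                      stringsAsFactors = FALSE)
    ann$helix_segments <- segs
    list(proteome = proteome, annotations = ann)
  })
}

#' Generate planted helix peptides
#'
#' Draws `n` alpha-helix-like peptides from the presequence-helix residue
#' profile, with lengths uniform over `len_range`. Used for
#' parameter-recovery checks and as consensus-design input.
#'
#' @param n number of helices.
#' @param seed integer seed (mandatory).
#' @param helix_freqs 20-residue frequency vector.
#' @param len_range inclusive length range.
#' @return list of [peptide()]s.
#' @export
generate_helices <- function(n, seed,
                             helix_freqs = proteome_spec()$helix_freqs,
                             len_range = c(10L, 24L)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  with_seed(seed, {
    lens <- sample(seq.int(len_range[1L], len_range[2L]), n, replace = TRUE)
    lapply(seq_len(n), function(i)
      peptide(sprintf("helix%05d", i),
              paste(draw_residues(lens[i], helix_freqs), collapse = "")))
  })
}

#' Generate a homolog-overhang table from ground truth
#'
#' Emulates the overhang structure of a homology search against mature-part
#' homologs: for each annotated protein, `n_homologs` rows with
#' `query_aln_start = tp_end + 1 + round(Normal(0, noise_sd))`, floored
#' at 1. A `full_length_hit_rate` fraction of rows instead starts at 1
#' (spurious full-length hits against a presequence-bearing homolog).
#'
#' @param truth annotation data.frame with `protein_id` and `tp_end`.
#' @param n_homologs homologs per protein.
#' @param noise_sd sd of boundary noise in residues.
#' @param full_length_hit_rate probability a row is a spurious start-at-1
#'   hit.
#' @param seed integer seed (mandatory).
#' @return data.frame with `query_id`, `homolog_id`, `query_aln_start`.
#' @export
generate_overhangs <- function(truth, n_homologs = 5L, noise_sd = 0,
                               full_length_hit_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(c("protein_id", "tp_end") %in% names(truth)),
            n_homologs >= 1L, full_length_hit_rate >= 0,
            full_length_hit_rate <= 1)
  with_seed(seed, {
    nrow_out <- nrow(truth) * n_homologs
    query_id <- rep(truth$protein_id, each = n_homologs)
    tp_end <- rep(truth$tp_end, each = n_homologs)
    starts <- pmax(1L, tp_end + 1L +
                     as.integer(round(stats::rnorm(nrow_out, 0, noise_sd))))
    spurious <- stats::runif(nrow_out) < full_length_hit_rate
    starts[spurious] <- 1L
    data.frame(query_id = query_id,
               homolog_id = paste0(query_id, "_hom",
                                   rep(seq_len(n_homologs), nrow(truth))),
               query_aln_start = starts,
               stringsAsFactors = FALSE)
  })
}

#' The construct truth-table fixture
#'
#' Returns (and optionally writes) the 16-row table of fluorescent-reporter
#' constructs with experimentally observed localization, encoded as feature
#' vectors (window length, non-flank basic positions, acidic count) because
#' the full construct sequences are not machine-readable. Enumeration:
#' the AAT 1-33 helix; the synthetic-presequence arginine series 3R/2R/0R
#' and the 3K lysine swap; the eight single-arginine scan constructs
#' (the R13 row is also the series' 1R construct); FMNL 1-24 wild type; the
#' FMNL single-glutamate mutant (E2A; E18A has the identical feature vector
#' and outcome, folded into this row); and the FMNL E2A/E18A double mutant
#' (RPSA 1-24 shares this feature signature and outcome, folded). Basic
#' positions of AAT and multi-arginine constructs are representative
#' non-flank stand-ins; only the counts enter the classifier.
#'
#' @param path optional output TSV path.
#' @return data.frame with `label`, `window`, `basic_positions`,
#'   `n_acidic`, `observed`; written to `path` if given.
#' @export
generate_truth_table <- function(path = NULL) {
  tt <- data.frame(
    label = c("AAT_1-33",
              "synTP_3R", "synTP_2R", "synTP_0R", "synTP_3K",
              "synTP_1R_R2", "synTP_1R_R6", "synTP_1R_R8", "synTP_1R_R9",
              "synTP_1R_R12", "synTP_1R_R13", "synTP_1R_R15", "synTP_1R_R21",
              "FMNL_1-24", "FMNL_E2A", "FMNL_E2A/E18A"),
    window = c(33L, rep(24L, 15L)),
    basic_positions = c("5,12",
                        "6,9,13", "9,13", "", "6,9,13",
                        "2", "6", "8", "9", "12", "13", "15", "21",
                        "9", "9", "9"),
    n_acidic = c(0L, 0L, 0L, 0L, 0L,
                 rep(0L, 8L),
                 2L, 1L, 0L),
    observed = c("mitochondrion",
                 "mitochondrion", "mitochondrion", "cytosol", "mitochondrion",
                 "cytosol", "mitochondrion", "mitochondrion", "mitochondrion",
                 "mitochondrion", "mitochondrion", "mitochondrion",
                 "mitochondrion",
                 "cytosol", "cytosol", "mitochondrion"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(c(
      "# Reporter-construct truth table (feature-vector encoding).",
      "# 16 rows: AAT 1-33; synTP 3R/2R/0R/3K; eight 1R scan constructs",
      "#   (the R13 row doubles as the arginine series' 1R member);",
      "#   FMNL 1-24 wt; FMNL E2A (E18A folded: identical features/outcome);",
      "#   FMNL E2A/E18A (RPSA 1-24 folded: identical signature/outcome).",
      "# basic_positions for AAT / multi-R rows are representative non-flank",
      "#   stand-ins (synthetic); the classifier consumes only the counts."),
      con)
    utils::write.table(tt, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  tt
}
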