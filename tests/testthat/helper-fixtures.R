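# Shared test fixtures, built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len, id = "rp") {
  peptide(id, paste(sample(AA20, len, replace = TRUE), collapse = ""))
}

# Independent brute-force hydrophobic moment: explicit 2-D vector summation,
# residue by residue, no shared code with the package implementation.
brute_moment <- function(seq, scale = fauchere_pliska(), delta_deg = 100) {
  chars <- strsplit(seq, "")[[1]]
  x <- 0
  y <- 0
  for (i in seq_along(chars)) {
    h <- scale[[chars[i]]]
    theta <- (i - 1) * delta_deg * pi / 180
    x <- x + h * cos(theta)
    y <- y + h * sin(theta)
  }
  sqrt(x^2 + y^2) / length(chars)
}

# Independent nested-loop ungapped scorer + dense ranker for tiny proteomes.
brute_screen <- function(proteome, query_seq, k, m) {
  rows <- list()
  for (p in proteome) {
    if (nchar(p$seq) < k) next
    s <- 0L
    for (i in seq_len(k))
      s <- s + m[substr(p$seq, i, i), substr(query_seq, i, i)]
    rows[[length(rows) + 1]] <- data.frame(orf_id = p$id, score = s)
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, df$orf_id), ]
  df$rank <- cumsum(!duplicated(df$score))
  rownames(df) <- NULL
  df
}

# A small curated record table with helix annotations, built in code.
toy_records <- function() {
  seg <- function(s, e) matrix(c(s, e), ncol = 2,
                               dimnames = list(NULL, c("start", "end")))
  two_seg <- rbind(seg(2, 10), seg(15, 24))
  df <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4", "p5"),
    organelle = c("mito", "mito", "mito", "mito", "chloro"),
    tp_seq = c("MALRSSLRQLLRSATATASAVRLLK",       # single helix 2-21 (20 aa)
               "MAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",  # single helix 2-26 (25 aa)
               "MKLSTATRVVASTLLRSAGAVSTRALAA",    # two helices
               "MRSTALLKQV",                      # single short helix 2-9
               "MAVVSTLRSQATLLRSA"),
    helix_class = c("single_alpha", "single_alpha", "multi_alpha",
                    "single_alpha", "none"),
    stringsAsFactors = FALSE)
  df$helix_segments <- list(seg(2, 21), seg(2, 26), two_seg, seg(2, 9),
                            matrix(integer(0), ncol = 2,
                                   dimnames = list(NULL, c("start", "end"))))
  df$tp_length <- nchar(df$tp_seq)
  df
}
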