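test_that("class composition matches hand classification and normalizes", {
  expect_equal(class_composition(peptide("x", "KRH")),
               c(basic = 1, acidic = 0, polar_uncharged = 0, nonpolar = 0))
  # M,A,L nonpolar; S,T polar uncharged; K basic
  expect_equal(class_composition(peptide("x", "MASTKL")),
               c(basic = 1 / 6, acidic = 0, polar_uncharged = 2 / 6,
                 nonpolar = 3 / 6))
  expect_error(class_composition(list()), "empty")

  set.seed(5)
  for (i in 1:20) {
    peps <- lapply(1:3, function(j) random_peptide(sample(4:30, 1)))
    cc <- class_composition(peps)
    expect_equal(sum(cc), 1)
    # pooling is count-weighted: duplicating the whole set changes nothing
    expect_equal(class_composition(c(peps, peps)), cc)
  }
})

test_that("net charge follows Henderson-Hasselbalch and decreases with pH", {
  expect_equal(net_charge(peptide("g", "GGG"), include_termini = FALSE), 0)
  # hand computation with the EMBOSS pKa triple (Nterm 8.6, K 10.8, Cterm 3.6)
  q <- 1 / (1 + 10^(7 - 8.6)) + 1 / (1 + 10^(7 - 10.8)) - 1 / (1 + 10^(3.6 - 7))
  expect_equal(net_charge(peptide("k", "K"), pka_set("emboss"), pH = 7), q)
  expect_equal(round(q, 3), 0.976)

  expect_error(net_charge(peptide("k", "K"), pH = 15), "pH")

  set.seed(6)
  for (i in 1:10) {
    p <- random_peptide(sample(3:40, 1))
    qs <- vapply(seq(1, 13, by = 0.5), function(ph) net_charge(p, pH = ph),
                 numeric(1))
    expect_true(all(diff(qs) <= 1e-12))
  }
})

test_that("mean hydrophobicity is the order-free per-residue mean", {
  sc <- fauchere_pliska()
  for (r in c("A", "W", "D"))
    expect_equal(mean_hydrophobicity(peptide("h", strrep(r, 7))), sc[[r]])
  expect_equal(mean_hydrophobicity(peptide("ag", "AG")), 0.155)
  set.seed(7)
  p <- random_peptide(25)
  shuf <- peptide("s", paste(sample(residues(p)), collapse = ""))
  expect_equal(mean_hydrophobicity(shuf), mean_hydrophobicity(p))
})

test_that("hydrophobic moment matches closed-form degenerate cases", {
  # 18 residues at 100 deg/residue span all multiples of 20 deg and cancel
  expect_equal(hydrophobic_moment(peptide("a", strrep("L", 18))), 0)
  expect_equal(hydrophobic_moment(peptide("a", "W")),
               abs(fauchere_pliska()[["W"]]))
  expect_gte(hydrophobic_moment(random_peptide(12)), 0)
})

test_that("hydrophobic moment equals brute-force 2-D vector summation", {
  set.seed(8)
  for (i in 1:300) {
    p <- random_peptide(sample(1:8, 1))
    expect_equal(hydrophobic_moment(p), brute_moment(p$seq), tolerance = 1e-12)
  }
})

test_that("hydrophobic moment is invariant under a uniform phase offset", {
  phase_moment <- function(seq, k, delta_deg = 100) {
    sc <- fauchere_pliska()
    h <- sc[strsplit(seq, "")[[1]]]
    ang <- (seq_along(h) - 1 + k) * delta_deg * pi / 180
    sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
  }
  set.seed(9)
  for (i in 1:20) {
    p <- random_peptide(sample(2:24, 1))
    mu <- hydrophobic_moment(p)
    for (k in c(-3, 1, 7))
      expect_equal(phase_moment(p$seq, k), mu, tolerance = 1e-12)
  }
})

test_that("windowed moment is the maximum over sliding windows", {
  set.seed(10)
  p <- random_peptide(30)
  manual <- max(vapply(1:13, function(s)
    brute_moment(substr(p$seq, s, s + 17)), numeric(1)))
  expect_equal(hydrophobic_moment(p, window = 18), manual, tolerance = 1e-12)
  # window longer than peptide falls back to full length
  expect_equal(hydrophobic_moment(p, window = 40), hydrophobic_moment(p))
})

test_that("helical wheel places residue i at (i-1)*delta mod 360", {
  w <- helical_wheel(peptide("w", strrep("A", 19)))
  expect_equal(w$angle_deg[1], 0)
  expect_equal(w$angle_deg[2], 100)
  expect_equal(w$angle_deg[19], 0)  # 5 full turns
  expect_equal(helical_wheel(peptide("w", "AAA"), delta_deg = 120)$angle_deg,
               c(0, 120, 240))
})

test_that("frequency matrix counts by coverage and normalizes per position", {
  fm <- frequency_matrix(list(peptide("a", "AR"), peptide("b", "AR"),
                              peptide("c", "AR")))
  expect_equal(unname(fm$freqs[1, "A"]), 1)
  expect_equal(unname(fm$freqs[2, "R"]), 1)

  fm2 <- frequency_matrix(list(peptide("a", "AR"), peptide("b", "RA")))
  expect_equal(fm2$freqs[1, c("A", "R")], c(A = 0.5, R = 0.5))
  expect_equal(fm2$freqs[2, c("A", "R")], c(A = 0.5, R = 0.5))

  # ragged set: coverage at position p = number of sequences of length >= p
  fm3 <- frequency_matrix(list(peptide("a", "ARK"), peptide("b", "A")))
  expect_equal(fm3$coverage, c(2L, 1L, 1L))
  rs <- rowSums(fm3$freqs)
  expect_equal(rs[fm3$coverage > 0], rep(1, 3), ignore_attr = TRUE)
  expect_error(frequency_matrix(list()), "empty")
})

test_that("physchem profile assembles a consistent row", {
  pr <- physchem_profile(peptide("x", "MALRSSLRQLLRSATATASAVRLL"))
  expect_equal(pr$length, 24)
  frac <- pr$frac_basic + pr$frac_acidic + pr$frac_polar_uncharged +
    pr$frac_nonpolar
  expect_equal(frac, 1)
  expect_gte(pr$hydrophobic_moment, 0)
})
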