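test_that("consensus takes the modal residue per position", {
  same <- lapply(1:4, function(i) peptide(paste0("h", i), "MALRS"))
  expect_equal(consensus_design(same, length = 5)$peptide$seq, "MALRS")

  cr <- consensus_design(list(peptide("a", "AR"), peptide("b", "AK"),
                              peptide("c", "AR")), length = 2)
  expect_equal(cr$peptide$seq, "AR")
  expect_false(any(cr$positions$tie))
  expect_error(consensus_design(list(peptide("a", "AR")), length = 5),
               "position 3")
})

test_that("consensus ties are flagged and broken by overall frequency then alphabet", {
  # position 2: R vs K tie; R is overall more frequent in the set (pos 1)
  cr <- consensus_design(list(peptide("a", "RR"), peptide("b", "RK")),
                         length = 2)
  expect_true(cr$positions$tie[2])
  expect_equal(cr$peptide$seq, "RR")
  # alphabetical fallback when overall counts tie too
  cr2 <- consensus_design(list(peptide("a", "KR"), peptide("b", "RK")),
                          length = 2, tie_break = "alpha")
  expect_equal(cr2$peptide$seq, "KK")
})

test_that("consensus is invariant to input order", {
  set.seed(12)
  hel <- generate_helices(25, seed = 31)
  a <- consensus_design(hel, length = 10)
  b <- consensus_design(rev(hel), length = 10)
  expect_equal(a$peptide$seq, b$peptide$seq)
})

test_that("charge adjustment applies explicit substitutions", {
  base <- peptide("cons", "MRRLRSATAR")
  expect_equal(charge_adjust(base, data.frame(position = integer(0),
                                              residue = character(0)))$seq,
               base$seq)
  adj <- charge_adjust(base, data.frame(position = c(2, 5),
                                        residue = c("L", "S")))
  expect_equal(adj$seq, "MLRLSSATAR")
  expect_equal(sum(residues(adj) == "R"), 2)
  expect_warning(charge_adjust(base, data.frame(position = 1, residue = "A")),
                 "do not hold arginine")
  expect_error(charge_adjust(base, data.frame(position = 99, residue = "A")),
               "out of range")
})

test_that("suggested substitutions move the net charge toward the target", {
  p <- peptide("p", "MRRLRSATARLL")  # 4 arginines, charge ~ +4
  subs <- suggest_charge_adjust(p, target_charge = 2)
  adj <- charge_adjust(p, subs)
  expect_lt(abs(net_charge(adj) - 2), abs(net_charge(p) - 2))
  expect_equal(sum(residues(adj) == "R"), 4 - nrow(subs))
})

test_that("arginine series descends to zero and adds the lysine swap", {
  base <- peptide("synTP", "MALRSSLRQLLRSATATASAVSTL")  # 3 R, no K
  vs <- arg_series(base)
  expect_length(vs, 5)
  rc <- vapply(vs, function(v) sum(residues(v$peptide) == "R"), integer(1))
  expect_equal(rc, c(3L, 2L, 1L, 0L, 0L))
  expect_equal(vapply(vs, `[[`, "", "label"),
               c("synTP_3R", "synTP_2R", "synTP_1R", "synTP_0R", "synTP_3K"))
  kswap <- vs[[5]]$peptide
  expect_equal(sum(residues(kswap) == "K"), 3)
  expect_true(all(vapply(vs, function(v) nchar_peptide(v$peptide),
                         integer(1)) == nchar_peptide(base)))
  expect_error(arg_series(peptide("x", "MALSS")), "no arginine")
})

test_that("arginine scan plants exactly one R per listed position", {
  base0 <- peptide("synTP_0R", "MALKSSLKQLLKSATATASAVSTL")
  vs <- arg_scan(base0)
  expect_length(vs, 8)
  for (v in vs) expect_equal(sum(residues(v$peptide) == "R"), 1)
  seqs <- vapply(vs, function(v) v$peptide$seq, character(1))
  expect_equal(anyDuplicated(seqs), 0L)
  expect_equal(vs[[1]]$label, "synTP_0R_R2")
  expect_equal(substr(vs[[1]]$peptide$seq, 2, 2), "R")
  expect_length(arg_scan(base0, integer(0)), 0)
  expect_error(arg_scan(peptide("x", "MRL")), "no arginine")
  expect_error(arg_scan(base0, c(2, 2)), "duplicate")
})

test_that("point mutants cover singles and combinations with matched labels", {
  base <- peptide("FMNL", "MEATKVLSWQAVDLAKSEAFSTLA")  # E2, E18
  muts <- data.frame(position = c(2, 18), from = "E", to = "A")
  vs <- point_mutants(base, muts, combos = TRUE)
  expect_equal(vapply(vs, `[[`, "", "label"), c("E2A", "E18A", "E2A/E18A"))
  expect_equal(vs[[3]]$peptide$seq, gsub("E", "A", base$seq))
  expect_length(point_mutants(base, muts, combos = FALSE), 2)
  bad <- data.frame(position = 3, from = "E", to = "A")
  expect_error(point_mutants(base, bad), "mismatch")
})
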