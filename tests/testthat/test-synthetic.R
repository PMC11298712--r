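test_that("proteome generation is deterministic given the seed", {
  a <- generate_proteome(proteome_spec(n_orfs = 60), seed = 101)
  b <- generate_proteome(proteome_spec(n_orfs = 60), seed = 101)
  expect_identical(lapply(a$proteome, `[[`, "seq"),
                   lapply(b$proteome, `[[`, "seq"))
  expect_identical(a$annotations$tp_end, b$annotations$tp_end)
  c <- generate_proteome(proteome_spec(n_orfs = 60), seed = 102)
  expect_false(identical(lapply(a$proteome, `[[`, "seq"),
                         lapply(c$proteome, `[[`, "seq")))
  expect_error(generate_proteome(proteome_spec(n_orfs = 5)), "seed")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_proteome(proteome_spec(n_orfs = 10), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("generated ORFs start with Met; planted TPs respect the ground truth", {
  gp <- generate_proteome(proteome_spec(n_orfs = 150), seed = 103)
  expect_true(all(vapply(gp$proteome, function(p) substr(p$seq, 1, 1),
                         "") == "M"))
  ann <- gp$annotations
  with_tp <- ann[ann$tp_end > 0, ]
  expect_true(all(with_tp$tp_end >= 10 & with_tp$tp_end <= 150))
  expect_true(all(with_tp$helix_class == "single_alpha"))
  seqs <- vapply(gp$proteome, `[[`, "", "seq")
  names(seqs) <- vapply(gp$proteome, `[[`, "", "id")
  for (i in seq_len(nrow(with_tp))) {
    seg <- with_tp$helix_segments[[i]]
    expect_true(seg[1, "start"] >= 2 && seg[1, "end"] <= with_tp$tp_end[i])
    # at least one basic residue at a non-flank position inside the helix
    helix <- substr(seqs[with_tp$protein_id[i]],
                    max(seg[1, "start"], 3), seg[1, "end"])
    expect_true(grepl("[RK]", helix))
  }
})

test_that("tp_fraction 0 yields a pure background proteome", {
  gp <- generate_proteome(proteome_spec(n_orfs = 40, tp_fraction = 0),
                          seed = 104)
  expect_true(all(gp$annotations$tp_end == 0))
  expect_true(all(gp$annotations$organelle == "other"))
})

test_that("planted mitochondrial TP lengths recover the target mean at n=2000", {
  gp <- generate_proteome(proteome_spec(n_orfs = 4000, tp_fraction = 1),
                          seed = 105)
  mito <- gp$annotations[gp$annotations$organelle == "mito", ]
  expect_equal(nrow(mito), 2000)
  s <- summarize_lengths(mito$tp_end)
  se <- s$sd / sqrt(s$n)
  expect_lt(abs(s$mean - 59.3), 2 * se)
})

test_that("planted helices recover the class composition within 1 point", {
  hel <- generate_helices(10000, seed = 106)
  cc <- class_composition(hel)
  target <- c(basic = 0.173, acidic = 0.036,
              polar_uncharged = 0.262, nonpolar = 0.529)
  expect_true(all(abs(cc - target[names(cc)]) < 0.01))
})

test_that("noiseless overhangs reproduce every TP boundary exactly", {
  gp <- generate_proteome(proteome_spec(n_orfs = 120), seed = 107)
  ov <- generate_overhangs(gp$annotations, n_homologs = 3, noise_sd = 0,
                           full_length_hit_rate = 0, seed = 108)
  res <- delineate_all(ov, aggregation = "median")
  merged <- merge(res, gp$annotations, by = "protein_id")
  expect_equal(merged$tp_end.x, merged$tp_end.y)
})

test_that("median delineation absorbs spurious full-length hits; min does not", {
  gp <- generate_proteome(proteome_spec(n_orfs = 250, tp_fraction = 1),
                          seed = 109)
  ov <- generate_overhangs(gp$annotations, n_homologs = 5, noise_sd = 0,
                           full_length_hit_rate = 0.3, seed = 110)
  truth <- gp$annotations$tp_end[match(unique(ov$query_id),
                                       gp$annotations$protein_id)]
  med <- delineate_all(ov, "median")
  mn <- delineate_all(ov, "min")
  med_rate <- mean(med$tp_end[match(unique(ov$query_id), med$protein_id)]
                   == truth)
  min_rate <- mean(mn$tp_end[match(unique(ov$query_id), mn$protein_id)]
                   == truth)
  expect_gt(med_rate, 0.7)
  expect_lt(min_rate, 0.4)
  expect_gt(med_rate, min_rate)
})

test_that("noisy overhang delineation recovers boundaries within the noise scale", {
  gp <- generate_proteome(proteome_spec(n_orfs = 200, tp_fraction = 1),
                          seed = 111)
  noise_sd <- 2
  ov <- generate_overhangs(gp$annotations, n_homologs = 7,
                           noise_sd = noise_sd, full_length_hit_rate = 0,
                           seed = 112)
  res <- delineate_all(ov, "median")
  merged <- merge(res, gp$annotations, by = "protein_id")
  within <- mean(abs(merged$tp_end.x - merged$tp_end.y) <= noise_sd)
  expect_gte(within, 0.95)
})

test_that("single-homolog tables give single-row groups", {
  ann <- data.frame(protein_id = c("p1", "p2"), tp_end = c(30L, 0L))
  ov <- generate_overhangs(ann, n_homologs = 1, seed = 113)
  expect_equal(nrow(ov), 2)
  expect_equal(ov$query_aln_start, c(31L, 1L))
})

test_that("the full pipeline runs end-to-end from one seed", {
  t0 <- Sys.time()
  gp <- generate_proteome(proteome_spec(n_orfs = 400), seed = 114)
  ov <- generate_overhangs(gp$annotations, n_homologs = 5, noise_sd = 1,
                           full_length_hit_rate = 0.1, seed = 115)
  bounds <- delineate_all(ov, "median")
  ann <- gp$annotations
  ann$tp_end <- bounds$tp_end[match(ann$protein_id, bounds$protein_id)]
  ann <- ann[ann$tp_end > 0, ]
  recs <- build_records(gp$proteome, ann)
  kept <- apply_length_filter(recs)$kept
  helices <- select_single_helices(kept)
  cons <- consensus_design(helices, length = 24)
  syn <- charge_adjust(cons, suggest_charge_adjust(cons$peptide))
  prof <- physchem_profile(syn)
  hits <- suppressMessages(screen_proteome(gp$proteome, syn))
  call <- predict_targeting(syn)
  expect_equal(nchar_peptide(syn), 24)
  expect_equal(nrow(prof), 1)
  expect_gt(nrow(hits), 0)
  expect_true(call$call %in% c("mitochondrion", "cytosol"))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})
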