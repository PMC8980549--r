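panel <- clcc1_panel()
core <- find_shared_core(panel$carriers, panel$map)
founder <- infer_founder(panel$carriers, panel$map, core)
partition <- partition_blocks(panel$carriers, panel$map, founder)

test_that("shared core on the packaged panel is the 9-marker autozygous run", {
  expect_equal(core$n_markers, 9)
  expect_equal(core$rsid_from, "rs10857972")
  expect_equal(core$rsid_to, "rs570812")
  # maximality: widening one marker either side breaks unanimity
  widen <- function(j) {
    a <- unique(panel$carriers[, j]); length(a[!is.na(a)]) > 1
  }
  expect_true(widen(core$from - 1))
  expect_true(widen(core$to + 1))
})

test_that("shared core degenerate cases", {
  map <- toy_map(5)
  all_same <- toy_carriers(list("ACGTA", "ACGTA", "-CGT-"), map)
  expect_equal(unlist(find_shared_core(all_same, map)[c("from", "to")]),
               c(from = 1, to = 5))
  # both flanking markers discordant: core is the focal site alone
  disc <- toy_carriers(list("AAGTA", "ACGCA"), map)
  cr <- find_shared_core(disc, map)
  expect_equal(c(cr$from, cr$to, cr$n_markers), c(3, 3, 1))
})

test_that("founder inference matches the published ancestral haplotype", {
  i <- match("rs17014495", panel$map$rsid)
  expect_equal(founder$alleles[i], "C")
  expect_equal(founder$support[i], 12)
  # support is full over the core and non-increasing outward on each side
  fi <- focal_index(panel$map)
  expect_true(all(founder$support[core$from:core$to] == 18))
  expect_true(all(diff(founder$support[fi:1]) <= 0))
  expect_true(all(diff(founder$support[fi:length(founder$support)]) <= 0))
  # the founder never contradicts the intact carrier family
  keep <- !is.na(panel$carriers["61224-a", ])
  expect_equal(founder$alleles[keep], unname(panel$carriers["61224-a", keep]))
})

test_that("founder inference is exact on unanimous and planted data", {
  map <- toy_map(5)
  hap <- c("A", "C", "G", "T", "A")
  same <- toy_carriers(list("ACGTA", "ACGTA", "ACGTA", "ACGTA"), map)
  f <- infer_founder(same, map)
  expect_equal(f$alleles, hap)
  expect_true(all(f$support == 4))

  # three families, planted founder ACGTA, one recombination each
  planted <- toy_carriers(list("TTGTA", "TTGTA", "ACGCC", "ACGCC",
                               "ACGTA", "ACGTA"), map)
  f2 <- infer_founder(planted, map)
  expect_equal(f2$alleles, hap)
  # recovered founder attains the brute-force minimum recombination count
  expect_equal(observed_events(planted, map, f2),
               brute_force_min_events(planted, map))
})

test_that("inferred founder minimises recombination events on random toys", {
  set.seed(11)
  map <- toy_map(4, focal = 2)
  for (rep in 1:20) {
    hap <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
    rows <- lapply(1:3, function(i) {
      x <- hap
      side <- sample(c("l", "r", "none"), 1)
      if (side == "l") x[1] <- sample(setdiff(c("A", "C", "G", "T"), x[1]), 1)
      if (side == "r") x[3:4] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
      x[2] <- hap[2]
      paste(x, collapse = "")
    })
    cm <- toy_carriers(rep(rows, each = 2), map)
    f <- infer_founder(cm, map)
    expect_equal(observed_events(cm, map, f), brute_force_min_events(cm, map))
  }
})

test_that("block partition reproduces the published 10-block layout", {
  b <- partition$blocks
  expect_equal(nrow(b), 10)
  expect_equal(b$label,
               c("rs12403629", "rs345292", "rs17020437", "rs12034547",
                 "rs1333130", "CLCC1-MUTATION", "rs587727", "rs17014495",
                 "rs12239350", "rs11102121"))
  expect_equal(b$n_markers, c(10, 13, 6, 8, 24, 9, 2, 17, 4, 2))
  expect_equal(sort(partition$tail_markers),
               sort(c("rs11102065", "rs752653894", "rs61787370",
                      "rs1030926216")))
  # blocks are disjoint and contiguous in position order
  expect_true(all(b$from[-1] > b$to[-nrow(b)]))
})

test_that("scan layout assigns every marker with boundaries at divergences", {
  ps <- partition_blocks(panel$carriers, panel$map, founder, layout = "scan")
  expect_length(ps$tail_markers, 0)
  expect_equal(sum(ps$blocks$n_markers), nrow(panel$map))
  # the published layout differs only at the distal right arm
  expect_equal(ps$blocks$n_markers[1:8], partition$blocks$n_markers[1:8])
})

test_that("single founder-identical chromosome yields one full-map block", {
  map <- toy_map(5)
  cm <- toy_carriers(list(X = "ACGTA"), map)
  f <- infer_founder(cm, map)
  pb <- partition_blocks(cm, map, f)
  expect_equal(nrow(pb$blocks), 1)
  expect_equal(pb$blocks$n_markers, 5)
  expect_equal(pb$blocks$side, "focal")
})

test_that("recombination fractions recompute from positions at 1 cM/Mb", {
  th <- block_theta(partition, panel$map)
  expect_equal(round(unname(th[c("rs12403629", "rs345292", "rs17020437",
                                 "rs12034547", "rs1333130", "CLCC1-MUTATION",
                                 "rs587727", "rs17014495", "rs12239350",
                                 "rs11102121")]), 5),
               c(0.01242, 0.01068, 0.01009, 0.00858, 0.00130, 0,
                 0.00192, 0.00221, 0.00828, 0.01522))
})

test_that("sharing counts match the published table and are monotone", {
  s <- sharing_counts(partition)
  expect_equal(unname(s), c(4, 6, 8, 10, 14, 18, 16, 12, 6, 2))
  foc <- which(partition$blocks$side == "focal")
  expect_equal(unname(s[foc]), nrow(panel$carriers))
  expect_true(all(diff(s[foc:1]) <= 0))
  expect_true(all(diff(s[foc:length(s)]) <= 0))
})

test_that("family derivations: at most two events, published counts and groups", {
  ev <- derive_family_events(panel$carriers, panel$map, founder, partition)
  fam <- ev$families
  expect_true(all(fam$n_events <= 2))
  expect_equal(fam$n_events[fam$family == "61224"], 0)
  expect_equal(fam$n_events[fam$family == "61244"], 1)
  grp <- split(fam$family, fam$group)
  grp <- lapply(grp, sort)
  expect_setequal(grp, list(c("61030", "61334"), c("61031", "61328"),
                            c("FAM2", "FAM3")))
  expect_equal(fam$level, fam$n_events)
  expect_length(ev$data_errors, 0)
})

test_that("a family not carrying the risk allele at the focal site errors", {
  map <- toy_map(3, focal = 2)
  al <- rbind(c("A", "C", "G"), c("A", "C", "G"),
              c("A", "T", "G"), c("A", "T", "G"))
  rownames(al) <- c("F1-a", "F1-b", "F2-a", "F2-b")
  expect_error(carrier_matrix(al, map), "disagree at the focal site")
})

test_that("segment lengths follow the midpoint and censoring conventions", {
  seg <- segment_lengths(panel$carriers, panel$map, founder)
  s61224 <- seg[seg$chromosome == "61224-a", ]
  expect_true(s61224$left_censored && s61224$right_censored)
  # censored lengths run to the outermost genotyped markers
  fi <- focal_index(panel$map)
  expect_equal(s61224$left_morgans,
               (panel$map$pos[fi] - panel$map$pos[1]) * 1e-8)
  expect_equal(s61224$right_morgans,
               (panel$map$pos[nrow(panel$map)] - panel$map$pos[fi]) * 1e-8)
  # FAM3 genotypes stop before the map end on the right: censoring respects it
  sF3 <- seg[seg$chromosome == "FAM3-a", ]
  expect_false(sF3$right_censored)  # FAM3 diverges within the map

  # midpoint convention on a toy: divergence at both flanking markers
  map <- toy_map(3, focal = 2)
  cm <- toy_carriers(list(X1 = "TCG", X2 = "ACT"), map)
  f <- infer_founder(cm, map)
  # founder = ACG (plurality with lexicographic tie-break), both chromosomes
  # diverge at a flanking marker; midpoint = half the 0.001 M inter-marker gap
  sg <- segment_lengths(cm, map, f)
  expect_equal(sg$left_morgans[1], 0.0005)
  expect_equal(sg$right_morgans[2], 0.0005)

  # last-match / first-mismatch conventions bracket the midpoint
  lm <- segment_lengths(cm, map, f, censoring = "last-match")
  fm <- segment_lengths(cm, map, f, censoring = "first-mismatch")
  expect_equal(lm$left_morgans[1], 0)
  expect_equal(fm$left_morgans[1], 0.001)
})
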