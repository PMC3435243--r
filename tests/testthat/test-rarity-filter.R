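test_that("uniqueness keeps at 50% or less and removes strictly above", {
  aff <- mk_cnv("A1", 1, 100001, 200000, 3)          # length 100 kb
  kept49 <- unique_to_affected(
    aff, mk_cnv("U1", 1, 151001, 300000, 3), aff[0, ])     # 49% overlap
  expect_equal(nrow(kept49$kept), 1L)
  kept50 <- unique_to_affected(
    aff, mk_cnv("U1", 1, 150001, 300000, 3), aff[0, ])     # exactly 50%
  expect_equal(nrow(kept50$kept), 1L)
  gone51 <- unique_to_affected(
    aff, aff[0, ], mk_cnv("C1", 1, 149001, 300000, 3))     # 51% control
  expect_equal(nrow(gone51$kept), 0L)
  expect_equal(gone51$traces$stage[!gone51$traces$kept], "control_cohort")
})

test_that("uniqueness comparisons are state-stratified", {
  aff <- mk_cnv("A1", 1, 100001, 200000, 3)                 # gain
  opp <- mk_cnv("C1", 1, 100001, 200000, 1, state = "loss") # 100% but loss
  r <- unique_to_affected(aff, aff[0, ], opp)
  expect_equal(nrow(r$kept), 1L)
})

test_that("sex-chromosomal uniqueness uses any-overlap semantics", {
  aff <- mk_cnv("A1", "X", 100001, 200000, 3)
  cmp <- mk_cnv("U1", "X", 199001, 350000, 3)   # tiny overlap
  expect_equal(nrow(unique_sex_chromosomal(aff, cmp)), 0L)
  cmp2 <- mk_cnv("U1", "X", 300001, 400000, 3)  # disjoint
  expect_equal(nrow(unique_sex_chromosomal(aff, cmp2)), 1L)
  expect_error(unique_sex_chromosomal(mk_cnv("A1", 1, 1, 1e5, 3), cmp),
               "X/Y")
})

test_that("segdup removal uses union coverage, not per-record overlap", {
  cnv <- mk_cnv("A1", 1, 1, 1000, 3)
  segdup <- mk_track(1, c(1, 201), c(300, 600))   # union covers 600/1000
  # oracle by base enumeration
  covered <- length(unique(c(1:300, 201:600)))
  expect_equal(covered / 1000, 0.6)
  r <- filter_segdup(cnv, segdup)
  expect_equal(nrow(r$kept), 0L)
  expect_equal(r$traces$overlap, 0.6)
  # a single 49% record keeps the CNV
  r2 <- filter_segdup(cnv, mk_track(1, 1, 490))
  expect_equal(nrow(r2$kept), 1L)
  r3 <- filter_segdup(cnv, mk_track(9, 1, 490))
  expect_equal(nrow(r3$kept), 1L)
})

test_that("known-variant removal is inclusive at 50%", {
  cnv <- mk_cnv("A1", 2, 1001, 2000, 3)
  expect_equal(nrow(filter_common(cnv, mk_track(2, 1001, 1500))$kept), 0L)
  expect_equal(nrow(filter_common(cnv, mk_track(2, 1001, 1499))$kept), 1L)
  expect_equal(nrow(filter_common(cnv, mk_track(2, 1, 2)[0, ])$kept), 1L)
})

test_that("family stage removes unaffected-relative mirrors and groups events", {
  ped <- mk_nuclear_ped(pheno = c(P1 = "affected", P2 = "unaffected",
                                  S1 = "affected", S2 = "unaffected"))
  # S1's CNV mirrored at 80% in unaffected sib S2 -> removed
  cnv_s1 <- mk_cnv("S1", 3, 100001, 200000, 3)
  mirror <- mk_cnv("S2", 3, 120001, 220000, 3)
  r <- family_consistency_filter(cnv_s1, ped, rbind(cnv_s1, mirror))
  expect_equal(nrow(r$kept), 0L)
  # mirrored at 60% in affected father -> both kept, one event id
  cnv_p1 <- mk_cnv("P1", 3, 100001, 200000, 3)
  cnv_s1b <- mk_cnv("S1", 3, 140001, 240000, 3)  # reciprocal 0.6
  both <- rbind(cnv_p1, cnv_s1b)
  r2 <- family_consistency_filter(both, ped, both)
  expect_equal(nrow(r2$kept), 2L)
  expect_length(unique(r2$kept$event_id), 1L)
  # singleton CNV keeps its own event
  single <- mk_cnv("S1", 9, 1e6, 1.1e6, 1, state = "loss")
  r3 <- family_consistency_filter(single, ped, single)
  expect_equal(nrow(r3$kept), 1L)
  expect_false(is.na(r3$kept$event_id))
})

test_that("the full chain attributes every removal to exactly one stage", {
  ped <- mk_nuclear_ped(pheno = c(P1 = "affected", P2 = "unaffected",
                                  S1 = "affected", S2 = "unaffected"))
  segdup <- mk_track(8, 1e6, 2e6)
  known <- mk_track(11, 5e6, 5.1e6)
  aff <- mk_cnvs(
    mk_cnv("S1", 5, 1e6, 1.2e6, 3),              # survives everything
    mk_cnv("S1", 6, 1e6, 1.2e6, 3),              # mirrored in unaffecteds
    mk_cnv("S1", 8, 1.2e6, 1.5e6, 3),            # inside segdup
    mk_cnv("S1", 11, 5e6, 5.09e6, 3),            # on a known variant
    mk_cnv("P1", 7, 1e6 + 1, 1.2e6, 1, state = "loss"))  # 50% mirror in S2
  unaff <- mk_cnvs(
    mk_cnv("U9", 6, 1e6, 1.19e6, 3, family_id = "F9"),
    # overlaps P1's loss by exactly 50% of it: passes the strictly-greater
    # uniqueness rule but is removed by the inclusive family rule
    mk_cnv("S2", 7, 1.1e6 + 1, 1.4e6, 1, state = "loss"))
  ctrl <- mk_cnv("C1", 12, 1e6, 1.1e6, 3, family_id = "C1")
  res <- run_filter_chain(aff, unaff, ctrl, segdup, known, ped)
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$kept$chrom, "5")
  # stage accounting: kept + removed = input; one removing stage per CNV
  expect_equal(sum(res$stage_counts$removed) + nrow(res$kept), nrow(aff))
  removed <- res$traces[!res$traces$kept, ]
  expect_false(anyDuplicated(removed$cnv_id) > 0)
  expect_equal(sort(res$stage_counts$removed),
               sort(c(1L, 0L, 1L, 1L, 1L)))
})

test_that("segdup and common stages commute", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 12
    starts <- sample(seq(1e5, 8e6, by = 1e4), n)
    cnvs <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_cnv(sprintf("S%d", i), sample(1:4, 1), starts[i],
             starts[i] + sample(5:30, 1) * 1e4, 3)))
    sd_starts <- sample(seq(1e5, 8e6, by = 1e4), 3)
    segdup <- mk_track(sample(1:4, 3, replace = TRUE), sd_starts,
                       sd_starts + 4e5)
    kn_starts <- sample(seq(1e5, 8e6, by = 1e4), 3)
    known <- mk_track(sample(1:4, 3, replace = TRUE), kn_starts,
                      kn_starts + 3e5)
    k1 <- filter_common(filter_segdup(cnvs, segdup)$kept, known)$kept
    k2 <- filter_segdup(filter_common(cnvs, known)$kept, segdup)$kept
    expect_equal(sort(k1$cnv_id), sort(k2$cnv_id))
  }
})

test_that("enlarging a comparison set never enlarges the kept set", {
  set.seed(24)
  aff <- do.call(rbind, lapply(1:10, function(i) {
    s <- sample(seq(1e5, 5e6, by = 1e4), 1)
    mk_cnv(sprintf("A%d", i), sample(1:3, 1), s, s + 2e5, 3)
  }))
  base_cmp <- do.call(rbind, lapply(1:5, function(i) {
    s <- sample(seq(1e5, 5e6, by = 1e4), 1)
    mk_cnv(sprintf("U%d", i), sample(1:3, 1), s, s + 2e5, 3)
  }))
  extra <- do.call(rbind, lapply(1:5, function(i) {
    s <- sample(seq(1e5, 5e6, by = 1e4), 1)
    mk_cnv(sprintf("U%d", i + 5), sample(1:3, 1), s, s + 2e5, 3)
  }))
  k_small <- unique_to_affected(aff, base_cmp, aff[0, ])$kept
  k_big <- unique_to_affected(aff, rbind(base_cmp, extra), aff[0, ])$kept
  expect_true(all(k_big$cnv_id %in% k_small$cnv_id))
})
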