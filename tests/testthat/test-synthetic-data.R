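# Scaled-down configuration shared by the generator tests.
small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_families = 12, n_common_cnps = 15,
                   n_segdup_regions = 4, n_artifact_events = 3,
                   n_planted_causal = 2, n_controls = 30, n_genes = 60,
                   fp_rate = 0.5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is fully deterministic under a fixed seed", {
  s1 <- simulate_cohort(small_cfg(seed = 99))
  s2 <- simulate_cohort(small_cfg(seed = 99))
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  expect_identical(s1$truth$individual_cnvs, s2$truth$individual_cnvs)
  expect_identical(s1$calls$cohort_a, s2$calls$cohort_a)
  expect_identical(s1$evidence$sage, s2$evidence$sage)
  s3 <- simulate_cohort(small_cfg(seed = 100))
  expect_false(identical(s1$calls$cohort_a, s3$calls$cohort_a))
})

test_that("pedigree structure is valid and sized as the branching predicts", {
  cfg <- sim_config(seed = 5)
  ped <- simulate_pedigrees(cfg)
  expect_s3_class(ped, "cnv_pedigree")  # as_pedigree validates loops/parents
  # expectation per family from the branching process:
  # 2 founders + E[children] + marry_prob * E[children] * (1 + spouse +
  # E[grandchildren per couple]) with E[children] = 1 + mean_children
  ec <- 1 + cfg$mean_children
  expected <- cfg$n_families *
    (2 + ec + cfg$marry_prob * ec * (2 + ec))
  expect_gt(nrow(ped), 0.8 * expected)
  expect_lt(nrow(ped), 1.2 * expected)
  # minimal structure: one family, two generations
  mini <- simulate_pedigrees(sim_config(seed = 2, n_families = 1,
                                        generations = 2))
  expect_true(all(mini$family_id == "F001"))
  expect_equal(sum(is.na(mini$father_id)), 2L)  # just the founder couple
  expect_error(sim_config(seed = 1, n_families = 0), "at least one")
})

test_that("every simulated call is attributable to exactly one truth source", {
  sim <- simulate_cohort(small_cfg(seed = 7))
  ind <- sim$truth$individual_cnvs
  expect_true(all(ind$origin %in%
                    c("cnp", "causal", "denovo_background", "artifact")))
  expect_false(anyNA(ind$origin))
  # planted causal carriers are all affected under full penetrance
  carriers <- sim$truth$causal_carriers
  ph <- sim$pedigree$phenotype[match(carriers,
                                     sim$pedigree$individual_id)]
  expect_true(all(ph == "affected"))
})

test_that("CNP transmission follows Mendelian expectation", {
  sim <- simulate_cohort(sim_config(seed = 21, n_families = 40,
                                    n_common_cnps = 20, n_controls = 10,
                                    n_planted_causal = 0,
                                    n_artifact_events = 0, fp_rate = 0))
  ind <- sim$truth$individual_cnvs
  ped <- sim$pedigree
  cnp <- sim$tracks$cnp_loci
  founders <- ped$individual_id[is.na(ped$father_id)]
  # founder carrier rate per locus should match 1 - (1 - f)^2
  cnp_calls <- ind[ind$origin == "cnp", ]
  obs <- vapply(seq_len(nrow(cnp)), function(j) {
    mean(founders %in%
           cnp_calls$sample_id[cnp_calls$event_id == cnp$name[j]])
  }, numeric(1))
  expected <- 1 - (1 - cnp$freq)^2
  # aggregate over loci: tight agreement in the mean
  expect_lt(abs(mean(obs) - mean(expected)), 0.04)
  # per-sample call load is near the configured target scale
  mean_calls <- nrow(ind) / nrow(ped)
  expect_gt(mean_calls, 3)   # 20 CNPs at f ~ 0.175 -> ~6 calls/sample
  expect_lt(mean_calls, 10)
})

test_that("de novo event count follows the configured binomial", {
  cfg <- sim_config(seed = 31, n_families = 60, n_common_cnps = 5,
                    n_planted_causal = 0, n_artifact_events = 0,
                    fp_rate = 0, n_controls = 5,
                    de_novo_probability = 0.05)
  ped <- simulate_pedigrees(cfg)
  g <- simulate_genome_and_cnvs(cfg, ped)
  n_off <- sum(!is.na(ped$father_id))
  n_dn <- sum(g$truth$events$type == "de_novo_background")
  ci <- qbinom(c(0.005, 0.995), n_off, cfg$de_novo_probability)
  expect_gte(n_dn, ci[1])
  expect_lte(n_dn, ci[2])
})

test_that("caller outputs respect the jitter and dropout model", {
  # zero jitter, zero dropout: both callers reproduce the truth exactly
  cfg0 <- small_cfg(seed = 41, jitter = 0, fp_rate = 0)
  sim0 <- simulate_cohort(cfg0)
  ind <- sim0$truth$individual_cnvs
  a <- sim0$calls$cohort_a
  expect_equal(nrow(a), nrow(ind))
  expect_equal(sort(a$start), sort(ind$start))
  merged <- merge_cohort(sim0$calls$cohort_a, sim0$calls$cohort_b,
                         min_size = 1, min_probes = 1)
  expect_equal(nrow(merged), nrow(ind))

  # jitter 0.2: merged envelopes still overlap the truth >= 50%
  cfg2 <- small_cfg(seed = 42, jitter = 0.2, fp_rate = 0)
  sim2 <- simulate_cohort(cfg2)
  m2 <- merge_cohort(sim2$calls$cohort_a, sim2$calls$cohort_b,
                     min_size = 1, min_probes = 1)
  ind2 <- sim2$truth$individual_cnvs
  ok <- vapply(seq_len(nrow(m2)), function(j) {
    cand <- ind2[ind2$sample_id == m2$sample_id[j] &
                   ind2$chrom == m2$chrom[j], , drop = FALSE]
    any(cnvfam:::intersect_length(m2$start[j], m2$end[j], cand$start,
                                  cand$end) /
          (cand$end - cand$start + 1) >= 0.5)
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  # total dropout of one caller leaves nothing to merge
  cfg1 <- small_cfg(seed = 43, fn_rate = 1, fp_rate = 0)
  sim1 <- simulate_cohort(cfg1)
  expect_equal(nrow(sim1$calls$cohort_a), 0L)

  # without segdup hotspots the two callers' false positives are placed
  # independently and essentially never co-localize: an FP-only run merges
  # to (almost) nothing — coincidental >= 50% overlaps of two uniform
  # placements survive at a rate far below the FP rate itself
  cfgf <- small_cfg(seed = 44, fn_rate = 1, fp_rate = 2,
                    n_segdup_regions = 0, n_artifact_events = 0)
  simf <- simulate_cohort(cfgf)
  mf <- merge_cohort(simf$calls$cohort_a, simf$calls$cohort_b)
  expect_lte(nrow(mf), 0.02 * nrow(simf$calls$cohort_a))
})

test_that("evidence tables separate causal from background genes", {
  sim <- simulate_cohort(small_cfg(seed = 51, evidence_fold = 8,
                                   evidence_score_shift = 4))
  genes <- sim$tracks$genes
  causal <- genes$name[genes$causal]
  folds <- sage_fold_table(sim$evidence$sage)
  expect_true(all(folds$sage_fold[folds$gene %in% causal] >= 3))
  fp <- fuse_rankings(sim$evidence$scores, n_null = 2000, seed = 1)
  expect_true(all(fp$fusion_p[fp$gene %in% causal] < 0.05))
  prof <- build_evidence_profiles(genes$name, fp, folds,
                                  sim$evidence$flags)
  expect_true(all(prof$candidate[prof$gene %in% causal]))
  # background candidate rate stays near the analytic expectation of the
  # 2-of-3 rule under independent evidences (loose bound)
  bg_rate <- mean(prof$candidate[!(prof$gene %in% causal)])
  expect_lt(bg_rate, 0.15)
})
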