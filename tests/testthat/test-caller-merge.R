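test_that("overlap_fraction matches a base-enumeration oracle", {
  a <- list(chrom = "1", start = 100, end = 199)
  expect_equal(overlap_fraction(a, a), 1.0)
  expect_equal(overlap_fraction(a, a, "reciprocal"), 1.0)

  a <- list(chrom = "8", start = 1, end = 100000)
  b <- list(chrom = "8", start = 50001, end = 150000)
  # oracle: enumerate covered bases on a 1:1000 scaled copy
  ov <- enumerate_overlap(1, 100000, 50001, 150000, scale = 1000) * 1000
  expect_equal(overlap_fraction(a, b), ov / 100000)
  expect_equal(overlap_fraction(a, b), 0.5)

  expect_equal(overlap_fraction(list(chrom = "8", start = 1, end = 10),
                                list(chrom = "9", start = 1, end = 10)), 0)
})

test_that("overlap_fraction agrees with random enumeration and is bounded", {
  set.seed(11)
  for (i in 1:50) {
    s1 <- sample(1:50, 1); e1 <- s1 + sample(0:50, 1)
    s2 <- sample(1:50, 1); e2 <- s2 + sample(0:50, 1)
    a <- list(chrom = "3", start = s1, end = e1)
    b <- list(chrom = "3", start = s2, end = e2)
    ov <- enumerate_overlap(s1, e1, s2, e2)
    expect_equal(overlap_fraction(a, b), ov / (e1 - s1 + 1))
    expect_equal(overlap_fraction(a, b, "reciprocal"),
                 min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
    expect_lte(overlap_fraction(a, b, "reciprocal"),
               overlap_fraction(a, b))
  }
})

test_that("CNP normal state is the rounded population mean", {
  r <- canary_normal_state(c(a = 2, b = 2, c = 2, d = 3))
  expect_equal(r$normal_state, 2L)  # mean 2.25 rounds to 2
  expect_equal(unname(r$deltas["d"]), "gain")
  expect_equal(unname(r$deltas["a"]), "normal")

  # a population whose normal state is not two
  r3 <- canary_normal_state(c(a = 3, b = 3, c = 3))
  expect_equal(r3$normal_state, 3L)
  expect_true(all(r3$deltas == "normal"))

  # documented tie rule: halves round away from zero
  r2 <- canary_normal_state(c(a = 2, b = 3))
  expect_equal(r2$normal_state, 3L)
  expect_equal(unname(r2$deltas["a"]), "loss")

  expect_error(canary_normal_state(integer(0)), "no individuals")
})

test_that("rare-CNV states use the fixed reference, sex-specific on X/Y", {
  expect_equal(rare_cnv_delta(0), "loss")
  expect_equal(rare_cnv_delta(3), "gain")
  expect_equal(rare_cnv_delta(2), "normal")
  expect_equal(rare_cnv_delta(2, "X", "male"), "gain")
  expect_equal(rare_cnv_delta(1, "X", "female"), "loss")
  expect_equal(rare_cnv_delta(1, "Y", "male"), "normal")
  expect_equal(rare_cnv_delta(1, "Y", "female"), "gain")
  expect_true(is.na(rare_cnv_delta(1, "X", "unknown")))
  expect_error(rare_cnv_delta(-1), "negative")
})

test_that("two-caller merge keeps outer boundaries above the overlap gate", {
  a <- mk_cnv("S1", 1, 100001, 200000, 3, n_probes = 8)
  b <- mk_cnv("S1", 1, 150001, 260000, 3, caller = "B")
  m <- merge_two_callers(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100001)   # outer envelope
  expect_equal(m$end, 260000)
  expect_equal(m$overlap, 0.5)    # fraction of the caller-A segment
  expect_equal(m$n_probes, 10L)   # max of the sources

  # below the 50% gate: no merge
  b2 <- mk_cnv("S1", 1, 180001, 400000, 3, caller = "B")
  expect_equal(nrow(merge_two_callers(a, b2)), 0L)

  # a call without a counterpart in the other caller is never emitted
  expect_equal(nrow(merge_two_callers(a, mk_cnv("S1", 2, 1, 50000, 3))), 0L)

  # opposite states never merge
  b3 <- mk_cnv("S1", 1, 100001, 200000, 1, caller = "B", state = "loss")
  expect_equal(nrow(merge_two_callers(a, b3)), 0L)
})

test_that("size, probe and confidence gates drop consensus calls", {
  a <- mk_cnv("S1", 1, 100001, 110000, 3)        # 10 kb: too short
  b <- mk_cnv("S1", 1, 100001, 110000, 3, caller = "B")
  expect_equal(nrow(merge_two_callers(a, b)), 0L)
  expect_equal(nrow(merge_two_callers(a, b, min_size = 10000)), 1L)

  a2 <- mk_cnv("S1", 1, 100001, 200000, 3, n_probes = 4)
  b2 <- mk_cnv("S1", 1, 100001, 200000, 3, n_probes = 4, caller = "B")
  expect_equal(nrow(merge_two_callers(a2, b2)), 0L)  # < 5 probes

  b3 <- mk_cnv("S1", 1, 100001, 200000, 3, caller = "B", confidence = 9.9)
  a3 <- mk_cnv("S1", 1, 100001, 200000, 3)
  expect_equal(nrow(merge_two_callers(a3, b3)), 0L)  # B below conf 10
})

test_that("merge rejects mixed-sample input", {
  expect_error(
    merge_two_callers(mk_cnv("S1", 1, 1, 50000, 3),
                      mk_cnv("S2", 1, 1, 50000, 3, caller = "B")),
    "single sample")
})

test_that("merged envelopes contain both sources; count is bounded", {
  set.seed(7)
  for (rep in 1:20) {
    n_a <- sample(1:6, 1); n_b <- sample(1:6, 1)
    mk_rand <- function(n, caller) {
      s <- sample(seq(1, 5e5, by = 1e4), n)
      do.call(rbind, lapply(s, function(x)
        mk_cnv("S1", 2, x, x + sample(2:8, 1) * 1e4, 3, caller = caller)))
    }
    a <- mk_rand(n_a, "A"); b <- mk_rand(n_b, "B")
    m <- merge_two_callers(a, b, min_size = 1, min_probes = 1)
    expect_lte(nrow(m), min(n_a, n_b))
    for (j in seq_len(nrow(m))) {
      # the envelope must contain at least one A and one B source interval
      contains <- function(df) any(df$start >= m$start[j] &
                                     df$end <= m$end[j])
      expect_true(contains(a) && contains(b))
    }
  }
})

test_that("greedy matching attains the exhaustive optimum on small sets", {
  # the greedy one-to-one matching should match an exhaustive search over
  # all matchings on nearly all random instances
  set.seed(21)
  n_agree <- 0; n_inst <- 40
  for (rep in seq_len(n_inst)) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    mk_rand <- function(n, caller) do.call(rbind, lapply(seq_len(n),
      function(i) {
        s <- sample(seq(1, 3e5, by = 5e3), 1)
        mk_cnv("S1", 2, s, s + sample(c(4, 6, 8, 12), 1) * 1e4, 3,
               caller = caller)
      }))
    a <- mk_rand(n_a, "A"); b <- mk_rand(n_b, "B")
    fm <- outer(seq_len(n_a), seq_len(n_b), Vectorize(function(i, j) {
      overlap_fraction(a[i, ], b[j, ])
    }))
    best <- exhaustive_best_matching(fm, 0.5)
    m <- merge_two_callers(a, b, min_size = 1, min_probes = 1)
    greedy_tot <- sum(m$overlap)
    if (isTRUE(all.equal(greedy_tot, best)) || greedy_tot >= best - 1e-9) {
      n_agree <- n_agree + 1
    }
  }
  expect_gte(n_agree / n_inst, 0.95)
})
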