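seg_core <- function(seq, id = "x") segment_trna(seq, id = id)

test_that("identical sequences give single-letter columns at full count", {
  p <- build_profile(replicate(10, seg_core(ancestral_core()),
                               simplify = FALSE))
  expect_equal(p$n_sequences, 10L)
  expect_true(all(colSums(p$counts) == 10L))
  expect_true(all(apply(p$counts[1:4, ], 2, max) == 10L))
  expect_equal(sum(p$counts["-", ]), 0L)
})

test_that("a D-loop deletion shows up as gaps confined to DMH columns", {
  core <- ancestral_core()
  del3 <- paste0(substr(core, 1, 11), substr(core, 15, 75))
  p <- build_profile(list(seg_core(core), seg_core(del3)))
  gaps <- which(p$counts["-", ] > 0)
  expect_length(gaps, 3L)
  expect_true(all(gaps >= 8 & gaps <= 24))
  # per-position counts still partition the set
  expect_true(all(colSums(p$counts) == 2L))
})

test_that("profile columns always sum to the number of sequences", {
  s <- generate_trna_set(n = 100, substitution_rate = 0.1, seed = 31)
  segs <- suppressWarnings(segment_set(s$sequences))
  p <- build_profile(segs)
  expect_true(all(colSums(p$counts) == length(segs)))
})

test_that("information content matches closed forms and stays in [0, 2]", {
  core <- ancestral_core()
  # invariant columns: 2 bits
  ip1 <- information_content(build_profile(list(seg_core(core))))
  expect_true(all(ip1$bits == 2))
  # a 50/50 column: 1 bit; a uniform column: 0 bits (V-loop position 49)
  flip <- function(base) paste0(substr(core, 1, 48), base,
                                substr(core, 50, 75))
  p2 <- build_profile(lapply(c("A", "C"), function(b) seg_core(flip(b))))
  expect_equal(information_content(p2)$bits[49], 1)
  p4 <- build_profile(lapply(c("A", "C", "G", "T"),
                             function(b) seg_core(flip(b))))
  expect_equal(information_content(p4)$bits[49], 0)
  expect_true(all(information_content(p4)$bits >= 0 &
                    information_content(p4)$bits <= 2))
})

test_that("the small-sample correction only lowers bits, floored at 0", {
  s <- generate_trna_set(n = 20, substitution_rate = 0.1, seed = 8)
  p <- build_profile(suppressWarnings(segment_set(s$sequences)))
  raw <- information_content(p)$bits
  cor <- information_content(p, correction = TRUE)$bits
  expect_true(all(cor <= raw + 1e-12))
  expect_true(all(cor >= 0))
})

test_that("mean information decreases with the substitution rate", {
  mean_bits <- vapply(c(0, 0.05, 0.2), function(rate) {
    s <- generate_trna_set(n = 200, substitution_rate = rate,
                           d_deletion_probability = 0,
                           v_insertion_probability = 0, seed = 13)
    segs <- suppressWarnings(segment_set(s$sequences))
    mean(information_content(build_profile(segs))$bits)
  }, numeric(1))
  expect_equal(mean_bits[1], 2)
  expect_true(all(diff(mean_bits) < 0))
})

test_that("consensus calling honours the threshold and gap columns", {
  core <- ancestral_core()
  p1 <- build_profile(replicate(3, seg_core(core), simplify = FALSE))
  expect_equal(consensus(p1, 1), core)
  # 60/40 split at position 49 (3 C vs 2 A)
  flip <- function(base) paste0(substr(core, 1, 48), base,
                                substr(core, 50, 75))
  p <- build_profile(lapply(c("C", "C", "C", "A", "A"),
                            function(b) seg_core(flip(b))))
  expect_equal(substr(consensus(p, 0.5), 49, 49), "C")
  expect_equal(substr(consensus(p, 0.7), 49, 49), "N")
  expect_error(consensus(p, 0.2), "threshold")
  # a column that is all gaps reports '-'
  del3 <- paste0(substr(core, 1, 11), substr(core, 15, 75))
  pd <- build_profile(list(seg_core(del3)))
  expect_equal(substr(consensus(pd, 0.5), 22, 22), "-")
})

test_that("segment similarity reproduces the ancestral relic identities", {
  p <- build_profile(list(seg_core(ancestral_core())))
  # D relic GACCG vs acceptor stem 3-7 GGCCG
  dv <- segment_similarity(p, "DREM", 3:7)
  expect_equal(dv$matches, 4L)
  expect_equal(dv$denominator, 5L)
  # V relic TGGTC vs acceptor stem 69-73 CGGCC
  vv <- segment_similarity(p, "VLOOP", 69:73)
  expect_equal(vv$matches, 3L)
  # ancestral Ac vs T microhelices: 12 of the 14 defined positions
  ac <- seq_identity("CCGGGCTXXXAACCCGG", anc[["t_microhelix"]])
  expect_equal(ac$matches, 12L)
  expect_equal(ac$denominator, 14L)
  expect_error(segment_similarity(p, "DREM", 3:8), "equal length")
  expect_error(segment_similarity(p, "NOPE", 3:7), "unknown segment")
})
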