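test_that("minihelix construction enforces component lengths", {
  mh <- build_minihelix("TAGTCTAGCCTGGACTA", "GCGGCCG", "CGGCCGC")
  expect_equal(as.character(mh), "GCGGCCGTAGTCTAGCCTGGACTACGGCCGC")
  expect_equal(nchar(as.character(mh)), 31L)
  expect_equal(mh$micro$anticodon, "GCC")
  expect_error(microhelix(substr("TAGTCTAGCCTGGACTA", 1, 16)), "17 nt")
  expect_error(build_minihelix("TAGTCTAGCCTGGACTA", "GCGGCC", "CGGCCGC"),
               "acc5")
  expect_error(build_minihelix("TAGTCTAGCCTGGACTA", "GCGGCCG", "GGCCGC"),
               "acc3")
})

test_that("CCA attachment yields the 20-nt adaptor and 34-nt minihelix", {
  expect_equal(nchar(attach_cca(anc[["d_microhelix"]])), 20L)
  long <- attach_cca(build_minihelix(anc[["d_microhelix"]],
                                     anc[["acc5"]], anc[["acc3"]]))
  expect_equal(nchar(long), 34L)
  expect_equal(substr(long, 32, 34), "CCA")
  expect_error(attach_cca(""), "17-nt microhelix or 31-nt")
  expect_error(attach_cca("ACGT"), "17-nt microhelix or 31-nt")
})

test_that("ligation of the ancestral minihelices reproduces the model core", {
  mhs <- ancestral_minihelices()
  res <- ligate_and_delete(mhs[[1]], mhs[[2]], mhs[[3]])
  expect_equal(nchar(res$precursor), 93L)
  expect_equal(nchar(res$core), 75L)
  expect_equal(res$segment_map[["DREM"]], "GGCCG")   # acc5 positions 3-7
  expect_equal(res$segment_map[["VLOOP"]], "CGGCC")  # acc3 positions 1-5
  expect_equal(unname(nchar(res$segment_map)), c(7L, 17L, 5L, 17L, 5L, 17L, 7L))
})

test_that("the ligation plan controls and validates the retained windows", {
  mhs <- ancestral_minihelices()
  alt <- ligation_plan(junction1 = 8:12, junction2 = 3:7)
  res <- ligate_and_delete(mhs[[1]], mhs[[2]], mhs[[3]], plan = alt)
  expect_equal(nchar(res$core), 75L)
  # junction1 window 8-12 = downstream acc5 positions 1-5
  expect_equal(res$segment_map[["DREM"]], substr(anc[["acc5"]], 1, 5))
  expect_error(ligation_plan(junction1 = 11:15), "within the 14-nt")
  expect_error(ligation_plan(junction1 = c(1, 3, 5, 7, 9)), "contiguous")
  expect_error(ligation_plan(junction1 = 1:4), "5 contiguous")
})

test_that("ligate-then-segment is the identity on the seven segments", {
  set.seed(101)
  for (i in 1:100) {
    mhs <- random_minihelix_triple()
    res <- ligate_and_delete(mhs[[1]], mhs[[2]], mhs[[3]])
    expect_equal(nchar(res$precursor), 93L)
    expect_equal(nchar(res$core), 75L)
    expect_equal(nchar(res$segment_map[["DREM"]]), 5L)
    expect_equal(nchar(res$segment_map[["VLOOP"]]), 5L)
    st <- segment_trna(res$core)
    expect_identical(st$segments, res$segment_map)
    expect_equal(st$d_status, "intact")
    expect_equal(st$v_status, "simple")
  }
})

test_that("snapback replication appends exact reverse complements", {
  mhs <- ancestral_minihelices()
  p1 <- snapback_replicate(mhs[[1]], 1)
  expect_equal(nchar(p1$product), 62L)
  expect_equal(substr(p1$product, 32, 62),
               reverse_complement(substr(p1$product, 1, 31)))
  p3 <- snapback_replicate(mhs[[1]], 3)
  expect_equal(nchar(p3$product), 124L)  # 31 x 4
  # template/copy relation holds at every round
  for (r in 1:3) {
    expect_equal(p3$units[r + 1], reverse_complement(p3$units[r]))
  }
  # involution: copying a copy restores the template
  expect_equal(reverse_complement(reverse_complement(p3$units[1])),
               p3$units[1])
  expect_error(snapback_replicate(mhs[[1]], 0), "rounds")
  expect_error(snapback_replicate("ACGT", 1), "31-nt")
})

test_that("replication with a seeded error rate is reproducible", {
  mhs <- ancestral_minihelices()
  a <- snapback_replicate(mhs[[2]], 4, error_rate = 0.1, seed = 11)
  b <- snapback_replicate(mhs[[2]], 4, error_rate = 0.1, seed = 11)
  expect_identical(a$product, b$product)
  expect_false(identical(a$product,
                         snapback_replicate(mhs[[2]], 4)$product))
})

test_that("minihelix excision decomposes concatemers and rejects cores", {
  mhs <- ancestral_minihelices()
  res <- ligate_and_delete(mhs[[1]], mhs[[2]], mhs[[3]])
  units <- excise_minihelices(res$precursor)
  expect_length(units, 3L)
  expect_equal(paste(units, collapse = ""), res$precursor)
  expect_equal(units[1], as.character(mhs[[1]]))
  expect_length(excise_minihelices(snapback_replicate(mhs[[1]], 1)), 2L)
  expect_error(excise_minihelices(res$core), "not decomposable")
})
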