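test_that("the coordinate scheme partitions 1-75 and its arithmetic holds", {
  sch <- segment_scheme()
  expect_equal(sch$start[1], 1L)
  expect_equal(sch$end[nrow(sch)], 75L)
  expect_true(all(sch$start[-1] == sch$end[-nrow(sch)] + 1L))
  expect_equal(sum(sch$length), 75L)
  k <- core_constants()
  expect_equal(unname(3L * k["minihelix_len"] - 2L * k["deletion_len"]),
               unname(k["core_len"]))
  expect_equal(unname(k["junction_len"] - k["deletion_len"]),
               unname(k["remnant_len"]))
  expect_equal(unname(k["microhelix_len"]), 5L + 7L + 5L)
  expect_equal(unname(k["microhelix_len"] + k["junction_len"]),
               unname(k["minihelix_len"]))
})

test_that("normalization maps modified-base codes to parent bases", {
  expect_equal(as.character(normalize_sequence("GCGGAUUUA")), "GCGGATTTA")
  expect_equal(as.character(normalize_sequence("P")), "T")  # pseudouridine
  expect_equal(as.character(normalize_sequence("5")), "C")  # 5-methyl-C
  expect_equal(as.character(normalize_sequence("1")), "A")
  expect_equal(as.character(normalize_sequence("Y")), "A")
  expect_equal(nchar(normalize_sequence("acgu")), 4L)
})

test_that("normalization handles gaps, ambiguity and unknown symbols", {
  x <- normalize_sequence("AC-G U")
  expect_equal(as.character(x), "ACGT")
  expect_equal(attr(x, "gap_positions"), 3L)
  # O is ambiguous: rejected strictly, N leniently
  expect_error(normalize_sequence("ACO"), "position 3")
  expect_equal(as.character(normalize_sequence("ACO", strict = FALSE)),
               "ACN")
  expect_error(normalize_sequence("AC!G"), "unknown symbol '!' at position 3")
  expect_error(normalize_sequence(""), "empty")
})

test_that("the ancestral core segments exactly onto the scheme", {
  st <- segment_trna(ancestral_core(), id = "anc")
  expect_equal(
    unname(st$segments),
    unname(anc[c("acc5", "d_microhelix", "d_relic", "ac_microhelix",
                 "v_relic", "t_microhelix", "acc3")]))
  expect_equal(st$d_region_length, 22L)
  expect_equal(st$d_status, "intact")
  expect_equal(st$v_region_length, 5L)
  expect_equal(st$v_status, "simple")
})

test_that("D-loop deletions and V-loop insertions are detected and measured", {
  core <- ancestral_core()
  # remove 3 nt from within DMH (positions 12-14)
  del3 <- paste0(substr(core, 1, 11), substr(core, 15, 75))
  st <- segment_trna(del3)
  expect_equal(st$d_region_length, 19L)
  expect_equal(st$d_status, "deleted")
  expect_equal(st$v_status, "simple")
  # insert 2 nt into the V loop (after position 49)
  ins2 <- paste0(substr(core, 1, 49), "AA", substr(core, 50, 75))
  st2 <- segment_trna(ins2)
  expect_equal(st2$v_region_length, 7L)
  expect_equal(st2$v_status, "inserted")
  expect_equal(st2$d_status, "intact")
  expect_equal(nchar(st2$v_insertion), 2L)
})

test_that("segmentation is invariant to a 3'-CCA suffix", {
  core <- ancestral_core()
  a <- segment_trna(core)
  b <- segment_trna(paste0(core, "CCA"))
  expect_false(a$cca_stripped)
  expect_true(b$cca_stripped)
  expect_identical(a$segments, b$segments)
  expect_identical(a$d_status, b$d_status)
})

test_that("segmentation rejects model violations with diagnostics", {
  expect_error(segment_trna(strrep("ACGT", 30)), "outside the modelable")
  expect_error(segment_trna(substr(ancestral_core(), 1, 50)),
               "outside the modelable")
  # poly-A interior: no 17-nt stem-loop anywhere
  polyA <- paste0("GCGGCCG", strrep("A", 61), "CGGCCGC")
  expect_error(segment_trna(polyA), "stem-loop")
  # D region longer than 22 nt is a model violation, not a truncation
  wide <- paste0(substr(ancestral_core(), 1, 24), "AAAA",
                 substr(ancestral_core(), 25, 75))
  expect_error(segment_trna(wide), "exceeds the model maximum")
})

test_that("a dot-bracket structure line guides segmentation", {
  core <- ancestral_core()
  db <- paste0(
    "(((((((",                      # AS5
    "(((((.......)))))",           # DMH hairpin
    ".....",                        # DREM
    "(((((.......)))))",           # ACMH hairpin
    ".....",                        # VLOOP
    "(((((.......)))))",           # TMH hairpin
    ")))))))")
  expect_equal(nchar(db), 75L)
  st <- segment_trna(core, structure = db)
  expect_equal(st$segments[["ACMH"]], unname(anc["ac_microhelix"]))
  expect_error(segment_trna(core, structure = substr(db, 1, 40)),
               "structure length")
  expect_error(segment_trna(core, structure = paste0(substr(db, 1, 74), "(")),
               "unbalanced")
})

test_that("classify_set partitions and counts a mixed set", {
  core <- ancestral_core()
  one <- classify_set(list(segment_trna(core)))
  expect_equal(one$intact, 1L)
  expect_equal(one$n, 1L)

  del <- paste0(substr(core, 1, 11), substr(core, 15, 75))
  mix <- c(replicate(10, segment_trna(core), simplify = FALSE),
           replicate(10, segment_trna(del), simplify = FALSE))
  cs <- classify_set(mix)
  expect_equal(cs$intact, 10L)
  expect_equal(cs$deleted, 10L)
  expect_equal(sum(cs$table), cs$n)
  expect_equal(cs$intact_fraction, 0.5)
  expect_error(classify_set(list()), "empty")
})

test_that("segment_set skips and reports unsegmentable records", {
  seqs <- c(good = ancestral_core(), bad = strrep("A", 75))
  expect_warning(res <- segment_set(seqs), "1 of 2")
  expect_equal(names(res), "good")
  expect_match(attr(res, "failures")[["bad"]], "stem-loop")
  expect_error(segment_set(seqs, on_error = "stop"), "record 'bad'")
})
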