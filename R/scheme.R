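#' The 75-nt core coordinate scheme
#'
#' The conserved tRNA core is modelled as 75 nt partitioned into seven
#' segments: two 7-nt acceptor stems (`AS5`, `AS3`), three 17-nt
#' microhelices (`DMH`, `ACMH`, `TMH`; each a 5-nt stem, 7-nt loop, 5-nt
#' stem), and two 5-nt acceptor-stem relics (`DREM`, the 3'-most 5 nt of
#' the D region, and `VLOOP`, the simple variable loop). Coordinates are
#' 1-based inclusive throughout the package.
#'
#' @return A data frame with columns `segment`, `start`, `end`, `length`,
#'   one row per segment in 5' to 3' order.
#' @examples
#' segment_scheme()
#' @export
segment_scheme <- function() {
  data.frame(
    segment = c("AS5", "DMH", "DREM", "ACMH", "VLOOP", "TMH", "AS3"),
    start   = c(1L, 8L, 25L, 30L, 47L, 52L, 69L),
    end     = c(7L, 24L, 29L, 46L, 51L, 68L, 75L),
    length  = c(7L, 17L, 5L, 17L, 5L, 17L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Derived length constants of the three-minihelix model
#'
#' The arithmetic of the model: three 31-nt minihelices (each a 17-nt
#' microhelix flanked by a 2 x 7-nt acceptor stem) are ligated into a
#' 93-nt precursor; two symmetrical 9-nt deletions within the joined
#' 14-nt acceptor-stem junctions leave two 5-nt relics and the 75-nt core.
#'
#' @return Named integer vector of the model's fixed lengths.
#' @examples
#' core_constants()[["core_len"]]  # 75
#' @export
core_constants <- function() {
  c(
    acceptor_len   = 7L,
    stem_len       = 5L,
    loop_len       = 7L,
    microhelix_len = 17L,  # 5 + 7 + 5
    minihelix_len  = 31L,  # 17 + 14
    junction_len   = 14L,  # 7 + 7 joined acceptor stems
    deletion_len   = 9L,
    remnant_len    = 5L,   # 14 - 9
    d_region_len   = 22L,  # DMH + DREM
    core_len       = 75L,  # 3*31 - 2*9
    precursor_len  = 93L   # 3*31
  )
}

# Anticodon core coordinates: ACMH loop positions 3-5 (35-41 is the loop).
ANTICODON_CORE_POS <- 37:39

#' Ancestral sequence set used throughout the model
#'
#' Reconstructed ancestral sequences for the core's building blocks: the
#' acceptor stems (`AS5` = GCGGCCG, `AS3` = CGGCCGC), the acceptor-stem
#' relics (`DREM` = GACCG at 25-29, `VLOOP` = TGGTC at 47-51), and the
#' three 17-nt microhelices: the D-loop ancestor TAGTCTAGCCTGGACTA (GCC
#' anticodon, glycine), the anticodon-loop placeholder CCGGGCTTGTAACCCGG
#' (TGT; the true ancestral anticodon is unknowable), and the T-loop
#' ancestor CCGGGTTCAAATCCCGG (CAA, leucine).
#'
#' @return Named character vector of ancestral sequences.
#' @examples
#' ancestral_sequences()[["d_microhelix"]]
#' @export
ancestral_sequences <- function() {
  c(
    acc5          = "GCGGCCG",
    acc3          = "CGGCCGC",
    d_relic       = "GACCG",
    v_relic       = "TGGTC",
    d_microhelix  = "TAGTCTAGCCTGGACTA",
    ac_microhelix = "CCGGGCTTGTAACCCGG",
    t_microhelix  = "CCGGGTTCAAATCCCGG"
  )
}

#' The assembled 75-nt ancestral core
#'
#' Concatenates the ancestral segments in scheme order:
#' AS5 + DMH + DREM + ACMH + VLOOP + TMH + AS3. Note the relic segments
#' here are the reconstructed ancestral relics (GACCG, TGGTC); a core
#' produced by [ligate_and_delete()] from identical acceptor stems
#' instead carries the stem-derived remnants (GGCCG, CGGCC).
#'
#' @return A 75-character string.
#' @examples
#' nchar(ancestral_core())  # 75
#' @export
ancestral_core <- function() {
  a <- ancestral_sequences()
  paste0(a[["acc5"]], a[["d_microhelix"]], a[["d_relic"]],
         a[["ac_microhelix"]], a[["v_relic"]], a[["t_microhelix"]],
         a[["acc3"]])
}

# Split a 75-nt core string into the seven named segments.
split_core <- function(core) {
  stopifnot(nchar(core) == 75L)
  sch <- segment_scheme()
  segs <- substring(core, sch$start, sch$end)
  names(segs) <- sch$segment
  segs
}
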