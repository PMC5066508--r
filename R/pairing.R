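# Base-pair classification for one antiparallel position pair.
classify_pair <- function(x, y) {
  wc <- c(A = "T", T = "A", G = "C", C = "G")
  if (x %in% names(wc) && identical(unname(wc[x]), y)) return("WC")
  if ((x == "G" && y == "T") || (x == "T" && y == "G")) return("wobble")
  "mismatch"
}

#' Count antiparallel base pairs between two sequences
#'
#' Scores position i of `a` against position n+1-i of `b` (the
#' antiparallel register used when two strands of equal length form a
#' duplex). Watson-Crick pairs are A:T, T:A, G:C, C:G; the wobble pair is
#' G:T / T:G. The strict count is WC only; the permissive count adds
#' wobble pairs.
#'
#' @param a,b Character scalars of equal length over A/C/G/T (strict) —
#'   `U` is accepted and read as `T`.
#' @param allow_wobble Logical; if `TRUE` the report's headline `count`
#'   is the permissive count, otherwise the strict count. Both counts are
#'   always returned.
#' @param strict Logical; reject non-ACGT symbols (default). In lenient
#'   mode positions involving other symbols classify as `mismatch`.
#' @return A `pairing_report`: list with `classification` (per position
#'   of `a`: WC/wobble/mismatch), `n`, `strict_count`, `permissive_count`,
#'   `count` and `allow_wobble`.
#' @examples
#' antiparallel_pair_count("GACCG", "TGGTC")$strict_count           # 4
#' antiparallel_pair_count("GACCG", "TGGTC", TRUE)$permissive_count # 5
#' @export
antiparallel_pair_count <- function(a, b, allow_wobble = FALSE,
                                    strict = TRUE) {
  a <- chartr("U", "T", toupper(as.character(a)))
  b <- chartr("U", "T", toupper(as.character(b)))
  if (nchar(a) != nchar(b)) {
    stop(sprintf("sequences must have equal length (%d vs %d)",
                 nchar(a), nchar(b)))
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (strict && !all(c(av, bv) %in% c("A", "C", "G", "T"))) {
    bad <- setdiff(unique(c(av, bv)), c("A", "C", "G", "T"))
    stop("non-ACGT symbol(s) in strict mode: ", paste(bad, collapse = ", "))
  }
  n <- length(av)
  cls <- vapply(seq_len(n), function(i) classify_pair(av[i], bv[n + 1L - i]),
                character(1))
  strict_count <- sum(cls == "WC")
  permissive_count <- strict_count + sum(cls == "wobble")
  structure(list(
    a = a, b = b, n = n,
    classification = cls,
    strict_count = strict_count,
    permissive_count = permissive_count,
    count = if (allow_wobble) permissive_count else strict_count,
    allow_wobble = allow_wobble
  ), class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  cat("<pairing_report> ", x$a, " vs ", x$b, " (antiparallel)\n", sep = "")
  cat("  WC: ", x$strict_count, "/", x$n,
      "; +wobble: ", x$permissive_count, "/", x$n, "\n", sep = "")
  cat("  per-position: ", paste(x$classification, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# Stem score used for arm location: WC = 1, wobble = 0.5.
stem_score <- function(stem5, stem3) {
  r <- antiparallel_pair_count(stem5, stem3, strict = FALSE)
  r$strict_count + 0.5 * (r$permissive_count - r$strict_count)
}

#' Fold a 17-nt sequence as a microhelix
#'
#' Applies the fixed 5-7-5 partition (5-nt stem, 7-nt loop, 5-nt stem),
#' counts antiparallel pairs between the two stem strands, and extracts
#' the anticodon from loop positions 3-5.
#'
#' @param seq Character scalar, exactly 17 nt.
#' @param allow_wobble Count G:T wobble pairs as paired (default strict
#'   Watson-Crick only).
#' @return A `microhelix_fold`: list with `stem5`, `loop_seq`, `stem3`,
#'   `stem_pairs` (0-5), `anticodon` (3 nt), and `decoded_amino_acid`.
#' @examples
#' fold_microhelix("TAGTCTAGCCTGGACTA")  # 5/5 stem, GCC -> glycine
#' @export
fold_microhelix <- function(seq, allow_wobble = FALSE) {
  seq <- chartr("U", "T", toupper(as.character(seq)))
  if (nchar(seq) != 17L) {
    stop(sprintf("microhelix must be exactly 17 nt (got %d)", nchar(seq)))
  }
  stem5 <- substr(seq, 1, 5)
  loop  <- substr(seq, 6, 12)
  stem3 <- substr(seq, 13, 17)
  rep_ <- antiparallel_pair_count(stem5, stem3, allow_wobble = allow_wobble,
                                  strict = FALSE)
  anticodon <- substr(loop, 3, 5)
  structure(list(
    seq = seq, stem5 = stem5, loop_seq = loop, stem3 = stem3,
    stem_pairs = rep_$count,
    anticodon = anticodon,
    decoded_amino_acid = decode_anticodon(anticodon),
    allow_wobble = allow_wobble
  ), class = "microhelix_fold")
}

#' @export
print.microhelix_fold <- function(x, ...) {
  cat("<microhelix_fold> ", x$stem5, "-", x$loop_seq, "-", x$stem3, "\n",
      sep = "")
  cat("  stem pairs: ", x$stem_pairs, "/5",
      if (x$allow_wobble) " (wobble allowed)" else " (strict WC)",
      "\n", sep = "")
  cat("  anticodon: ", x$anticodon, " -> ", x$decoded_amino_acid, "\n",
      sep = "")
  invisible(x)
}

# one-letter -> full amino-acid name
AA_NAMES <- c(
  A = "alanine", R = "arginine", N = "asparagine", D = "aspartate",
  C = "cysteine", Q = "glutamine", E = "glutamate", G = "glycine",
  H = "histidine", I = "isoleucine", L = "leucine", K = "lysine",
  M = "methionine", F = "phenylalanine", P = "proline", S = "serine",
  T = "threonine", W = "tryptophan", Y = "tyrosine", V = "valine",
  "*" = "stop"
)

#' Decode an anticodon to its amino acid
#'
#' The codon read by an anticodon is its reverse complement (both written
#' 5' to 3'); translation uses the standard genetic code.
#'
#' @param anticodon Character scalar, 3 letters over A/C/G/T (U accepted).
#' @return The amino-acid name (lower case), `"stop"` for a stop codon,
#'   or `"unknown"` if the anticodon contains ambiguity letters.
#' @examples
#' decode_anticodon("GCC")  # glycine
#' decode_anticodon("CAA")  # leucine
#' @export
decode_anticodon <- function(anticodon) {
  anticodon <- chartr("U", "T", toupper(as.character(anticodon)))
  if (nchar(anticodon) != 3L) stop("anticodon must be 3 nt")
  if (grepl("[^ACGT]", anticodon)) return("unknown")
  codon <- reverse_complement(anticodon)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  unname(AA_NAMES[aa])
}
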