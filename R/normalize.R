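#' Normalize a tRNA sequence to the A/C/G/T alphabet
#'
#' Database tRNA sequences carry one-letter codes for modified
#' nucleosides. Normalization maps each residue to the canonical DNA-style
#' base of its parent nucleoside: `U` to `T`, `5` (5-methyl-cytosine) to
#' `C`, `P` (pseudouridine) to `T`, `1` and `Y` (adenosine derivatives) to
#' `A`. `O` (a uracil or guanosine derivative) is genuinely ambiguous and
#' is kept as the ambiguity marker `N`, which strict mode rejects.
#' Whitespace and gap characters (`-`, `.`) are removed and their
#' positions (in the cleaned raw string) recorded.
#'
#' @param raw Character scalar, the sequence as read (case-insensitive).
#' @param strict Logical; if `TRUE` (default) any symbol outside the
#'   normalization table, and any symbol mapping to `N`, is an error
#'   naming the offending character and position. If `FALSE`, unknown
#'   symbols and ambiguity codes become `N`.
#' @return A `nuc_sequence`: a character scalar of A/C/G/T (and `N` in
#'   lenient mode) with attributes `raw` (the input) and `gap_positions`.
#' @examples
#' normalize_sequence("GCGGAUUUA")  # U -> T
#' normalize_sequence("P")          # pseudouridine -> T
#' @export
normalize_sequence <- function(raw, strict = TRUE) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("empty sequence")
  chars <- strsplit(toupper(raw), "", fixed = TRUE)[[1]]
  chars <- chars[!grepl("[[:space:]]", chars)]
  gap <- chars %in% c("-", ".")
  gap_positions <- which(gap)
  chars <- chars[!gap]
  if (length(chars) == 0L) stop("sequence contains only gaps/whitespace")

  map <- c(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    "5" = "C",  # 5-methyl-cytosine
    P = "T",    # pseudouridine
    "1" = "A",  # 1-methyl-adenosine
    Y = "A",    # wyosine-type adenosine derivative
    O = "N",    # uracil-or-guanosine derivative: ambiguous
    N = "N", X = "N",
    # remaining IUPAC ambiguity codes
    R = "N", S = "N", W = "N", K = "N", M = "N",
    B = "N", D = "N", H = "N", V = "N"
  )
  known <- chars %in% names(map)
  if (!all(known)) {
    i <- which(!known)[1]
    stop(sprintf("unknown symbol '%s' at position %d", chars[i], i))
  }
  out <- unname(map[chars])
  if (strict && any(out == "N")) {
    i <- which(out == "N")[1]
    stop(sprintf(
      "ambiguous symbol '%s' at position %d (strict normalization)",
      chars[i], i))
  }
  structure(paste(out, collapse = ""),
            raw = raw, gap_positions = gap_positions,
            class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat("<nuc_sequence> ", unclass(x), " (", nchar(x), " nt)\n", sep = "")
  invisible(x)
}

#' @export
as.character.nuc_sequence <- function(x, ...) {
  as.vector(unclass(x), "character")
}

#' Reverse complement of a DNA-alphabet sequence
#'
#' @param x Character scalar over A/C/G/T/N.
#' @return Character scalar, the reverse complement.
#' @examples
#' reverse_complement("GACCG")  # "CGGTC"
#' @export
reverse_complement <- function(x) {
  x <- toupper(as.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Convert to output alphabet for display/FASTA export.
to_alphabet <- function(x, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "rna") chartr("T", "U", x) else x
}
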