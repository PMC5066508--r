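#' Segment a tRNA onto the 75-nt core coordinate scheme
#'
#' Maps a (normalized) tRNA sequence onto the seven-segment model: the
#' outermost 7 nt on each side are the acceptor stem halves (`AS5`,
#' `AS3`); the 17 nt immediately 5' of `AS3` are the T microhelix
#' (`TMH`, invariably adjacent to the acceptor stem); the anticodon
#' microhelix (`ACMH`) is located as the best-folding 17-nt stem-loop in
#' the interior; the D region is everything between `AS5` and `ACMH`
#' (its 3'-most 5 nt are the `DREM` relic, the rest is `DMH`); the V
#' region lies between `ACMH` and `TMH` (simple at 5 nt, otherwise
#' annotated as inserted or deleted).
#'
#' Without a structure line, `ACMH` is found by a greedy fold: every
#' admissible 17-nt window is scored as a 5-7-5 stem-loop (Watson-Crick
#' pair = 1, wobble = 0.5); the best-scoring window wins, ties resolved
#' by V-region length closest to the model's simple 5 nt, then by
#' smaller start. With a dot-bracket structure, hairpins whose outermost
#' stem pair encloses 15 nt are used as candidate microhelices instead.
#'
#' @param seq Sequence: a `nuc_sequence` from [normalize_sequence()] or a
#'   raw character string (normalized internally, strict mode).
#' @param structure Optional dot-bracket string of the same length as the
#'   input sequence (before CCA stripping), Vienna dialect.
#' @param id Record identifier carried into the result.
#' @param strip_cca Strip a 3'-terminal CCA (or partial CA/A, when doing
#'   so improves the terminal 7-bp acceptor pairing) before segmentation.
#' @param min_stem_score Minimum 5-7-5 stem score (WC = 1, wobble = 0.5)
#'   for a window to count as a microhelix; below it segmentation fails.
#' @return A `segmented_trna`: list with `id`, `segments` (named character
#'   vector over the seven segment names), `v_insertion` (nt in excess of
#'   the 5-nt V loop), `d_region_length`, `v_region_length`, `d_status`
#'   (`intact`/`deleted`), `v_status` (`simple`/`inserted`/`deleted`),
#'   `cca_stripped`, and `sequence` (the normalized, CCA-stripped input).
#' @examples
#' st <- segment_trna(ancestral_core())
#' st$d_status  # "intact"
#' @export
segment_trna <- function(seq, structure = NULL, id = "trna",
                         strip_cca = TRUE, min_stem_score = 3) {
  if (!inherits(seq, "nuc_sequence")) seq <- normalize_sequence(seq)
  s <- as.character(seq)

  cca <- 0L
  if (strip_cca) {
    cca <- cca_suffix_length(s)
    if (cca > 0L) {
      s <- substr(s, 1L, nchar(s) - cca)
      if (!is.null(structure)) {
        structure <- substr(structure, 1L, nchar(structure) - cca)
      }
    }
  }
  n <- nchar(s)
  if (n < 55L || n > 100L) {
    stop(sprintf(
      "sequence length %d outside the modelable window [55, 100] after CCA stripping",
      n))
  }
  if (!is.null(structure)) check_dotbracket(structure, n)

  as5 <- substr(s, 1L, 7L)
  as3 <- substr(s, n - 6L, n)
  tmh_start <- n - 23L
  tmh <- substr(s, tmh_start, n - 7L)
  if (stem_score(substr(tmh, 1, 5), substr(tmh, 13, 17)) < min_stem_score) {
    stop(sprintf(
      "cannot locate T arm: 17-nt window %d-%d does not fold as a stem-loop (score < %s)",
      tmh_start, n - 7L, format(min_stem_score)))
  }

  ac_start <- locate_acmh(s, tmh_start, structure, min_stem_score)
  acmh <- substr(s, ac_start, ac_start + 16L)

  d_len <- ac_start - 8L
  if (d_len > 22L) {
    stop(sprintf(
      "D region of %d nt exceeds the model maximum of 22 (model violation)",
      d_len))
  }
  d_region <- substr(s, 8L, ac_start - 1L)
  drem <- if (d_len >= 5L) substr(d_region, d_len - 4L, d_len) else d_region
  dmh  <- if (d_len >= 5L) substr(d_region, 1L, d_len - 5L) else ""

  v_start <- ac_start + 17L
  v_len <- tmh_start - v_start
  v_region <- if (v_len > 0L) substr(s, v_start, tmh_start - 1L) else ""
  vloop <- substr(v_region, 1L, min(5L, v_len))
  v_insertion <- if (v_len > 5L) substr(v_region, 6L, v_len) else ""

  segments <- c(AS5 = as5, DMH = dmh, DREM = drem, ACMH = acmh,
                VLOOP = vloop, TMH = tmh, AS3 = as3)

  structure(list(
    id = id,
    segments = segments,
    v_insertion = v_insertion,
    d_region_length = d_len,
    v_region_length = v_len,
    d_status = if (d_len == 22L) "intact" else "deleted",
    v_status = if (v_len == 5L) "simple" else if (v_len > 5L) "inserted"
               else "deleted",
    cca_stripped = cca > 0L,
    sequence = s
  ), class = "segmented_trna")
}

# Length of the 3'-CCA (or partial CA/A) suffix to strip: the suffix is
# a post-transcriptional addition only if removing it leaves the
# outermost 7+7 positions pairing at least as well (a core whose
# acceptor stem genuinely ends in CCA must not lose real sequence).
cca_suffix_length <- function(s) {
  n <- nchar(s)
  score_at <- function(k) {
    m <- n - k
    if (m < 55L) return(-Inf)
    stem_score(substr(s, 1L, 7L), substr(s, m - 6L, m))
  }
  if (substr(s, n - 2L, n) == "CCA" && score_at(3L) >= score_at(0L)) {
    return(3L)
  }
  for (suf in c("CA", "A")) {
    k <- nchar(suf)
    if (substr(s, n - k + 1L, n) == suf && score_at(k) > score_at(0L)) {
      return(k)
    }
  }
  0L
}

# Find the ACMH start: best 5-7-5 stem score; ties -> V length closest
# to 5; then smallest start. Candidate windows must leave D <= 22 and a
# non-negative V region.
locate_acmh <- function(s, tmh_start, structure, min_stem_score) {
  starts <- seq.int(8L, tmh_start - 17L)
  if (length(starts) == 0L) stop("no admissible anticodon-arm window")

  if (!is.null(structure)) {
    pt <- pair_table(structure)
    hp <- which(pt == seq_along(pt) + 16L)
    hp <- hp[hp %in% starts]
    if (length(hp) > 0L) starts <- hp
  }

  score <- vapply(starts, function(a) {
    stem_score(substr(s, a, a + 4L), substr(s, a + 12L, a + 16L))
  }, numeric(1))
  if (max(score) < min_stem_score) {
    stop(sprintf(
      "cannot locate anticodon arm: no 17-nt window folds as a stem-loop (best score %s < %s)",
      format(max(score)), format(min_stem_score)))
  }
  # layout score: stem pairing minus a mild penalty for V regions away
  # from the model's simple 5 nt (the D microhelix also folds 5/5 in
  # intact cores, so raw stem score alone cannot discriminate)
  vlen <- tmh_start - (starts + 17L)
  combined <- score - 0.1 * abs(vlen - 5L)
  combined[score < min_stem_score] <- -Inf
  best <- max(combined)
  cand <- starts[combined == best]
  cand[1L]
}

# Dot-bracket -> pair table (0 = unpaired); errors on unbalanced input.
pair_table <- function(db) {
  v <- strsplit(db, "", fixed = TRUE)[[1]]
  pt <- integer(length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] %in% c("(", "<", "[", "{")) {
      stack <- c(stack, i)
    } else if (v[i] %in% c(")", ">", "]", "}")) {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure")
  pt
}

check_dotbracket <- function(db, n) {
  if (nchar(db) != n) {
    stop(sprintf("structure length %d does not match sequence length %d",
                 nchar(db), n))
  }
  invisible(pair_table(db))
}

#' @export
print.segmented_trna <- function(x, ...) {
  cat("<segmented_trna> ", x$id, " (", nchar(x$sequence), " nt",
      if (x$cca_stripped) ", CCA stripped" else "", ")\n", sep = "")
  sch <- segment_scheme()
  for (seg in sch$segment) {
    cat(sprintf("  %-5s %s\n", seg, x$segments[[seg]]))
  }
  if (nzchar(x$v_insertion)) cat("  V insertion: ", x$v_insertion, "\n",
                                 sep = "")
  cat("  D region: ", x$d_region_length, " nt (", x$d_status,
      "); V region: ", x$v_region_length, " nt (", x$v_status, ")\n",
      sep = "")
  invisible(x)
}

#' Tabulate D-loop and V-loop status over a set of segmented tRNAs
#'
#' @param trnas List of `segmented_trna` objects.
#' @return A `trna_class_summary`: list with `table` (d_status x
#'   v_status counts), `n`, `intact` and `deleted` counts, and
#'   `intact_fraction`.
#' @examples
#' cores <- replicate(3, segment_trna(ancestral_core()), simplify = FALSE)
#' classify_set(cores)$intact  # 3
#' @export
classify_set <- function(trnas) {
  if (length(trnas) == 0L) stop("empty tRNA set")
  stopifnot(all(vapply(trnas, inherits, logical(1), "segmented_trna")))
  d <- factor(vapply(trnas, `[[`, character(1), "d_status"),
              levels = c("intact", "deleted"))
  v <- factor(vapply(trnas, `[[`, character(1), "v_status"),
              levels = c("simple", "inserted", "deleted"))
  tab <- table(d_status = d, v_status = v)
  structure(list(
    table = tab,
    n = length(trnas),
    intact = sum(d == "intact"),
    deleted = sum(d == "deleted"),
    intact_fraction = mean(d == "intact")
  ), class = "trna_class_summary")
}

#' @export
print.trna_class_summary <- function(x, ...) {
  cat("<trna_class_summary> n = ", x$n, "\n", sep = "")
  print(x$table)
  cat(sprintf("intact D loop: %d/%d (%.1f%%)\n", x$intact, x$n,
              100 * x$intact_fraction))
  invisible(x)
}

#' Per-segment table for one or more segmented tRNAs
#'
#' @param trnas A `segmented_trna` or list of them.
#' @return Data frame with columns `id`, `segment`, `start`, `end`,
#'   `subsequence`, `d_status`, `v_status` (model coordinates; segments
#'   shortened by deletions keep their model range with the observed
#'   subsequence).
#' @export
segmentation_table <- function(trnas) {
  if (inherits(trnas, "segmented_trna")) trnas <- list(trnas)
  sch <- segment_scheme()
  do.call(rbind, lapply(trnas, function(x) {
    data.frame(
      id = x$id, segment = sch$segment, start = sch$start, end = sch$end,
      subsequence = unname(x$segments[sch$segment]),
      d_status = x$d_status, v_status = x$v_status,
      stringsAsFactors = FALSE
    )
  }))
}
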