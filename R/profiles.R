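PROFILE_LETTERS <- c("A", "C", "G", "T", "-")

#' Build a per-position frequency profile on core coordinates
#'
#' Places each segmented tRNA onto the 75 core columns and counts letters
#' per column. D-region deletions appear as gaps within `DMH` (observed
#' D-microhelix residues are left-aligned in columns 8-24, so gaps sit
#' 3', adjacent to the relic — the true deletion site is unrecoverable
#' from sequence alone); short V regions leave gaps in `VLOOP` columns
#' and V-loop insertions are excluded from core columns entirely.
#' Ambiguity letters (`N`, lenient normalization) are excluded from
#' composition and counted with the gaps.
#'
#' @param trnas List of `segmented_trna` objects on the same scheme.
#' @return A `frequency_profile`: list with `counts` (5 x 75 matrix over
#'   A/C/G/T/`-`) and `n_sequences`.
#' @examples
#' p <- build_profile(list(segment_trna(ancestral_core())))
#' p$counts[, 1]
#' @export
build_profile <- function(trnas) {
  if (length(trnas) == 0L) stop("empty tRNA set")
  stopifnot(all(vapply(trnas, inherits, logical(1), "segmented_trna")))
  sch <- segment_scheme()
  counts <- matrix(0L, nrow = 5L, ncol = 75L,
                   dimnames = list(PROFILE_LETTERS, NULL))
  for (x in trnas) {
    row <- rep("-", 75L)
    for (k in seq_len(nrow(sch))) {
      seg <- sch$segment[k]
      sub <- x$segments[[seg]]
      if (!nzchar(sub)) next
      v <- strsplit(sub, "", fixed = TRUE)[[1]]
      if (seg == "DREM") {
        # 3'-most relic: right-align at column 29
        pos <- seq.int(sch$end[k] - length(v) + 1L, sch$end[k])
      } else {
        pos <- seq.int(sch$start[k], sch$start[k] + length(v) - 1L)
      }
      row[pos] <- v
    }
    row[!row %in% c("A", "C", "G", "T")] <- "-"
    idx <- cbind(match(row, PROFILE_LETTERS), seq_len(75L))
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(counts = counts, n_sequences = length(trnas)),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("<frequency_profile> ", x$n_sequences,
      " sequences x 75 core positions\n", sep = "")
  cat("consensus (>= 50%): ", consensus(x, 0.5), "\n", sep = "")
  invisible(x)
}

# Per-column letter frequencies over non-gap observations (4 x 75).
profile_freqs <- function(p) {
  cnt <- p$counts[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(cnt)
  f <- sweep(cnt, 2, pmax(tot, 1L), "/")
  f[, tot == 0L] <- NA_real_
  f
}

#' Shannon information content per core position
#'
#' Computes the sequence-logo information measure per column:
#' `bits = 2 - H`, with `H = -sum f log2 f` over the non-gap base
#' frequencies. An optional small-sample correction
#' `e(n) = 3 / (2 ln(2) n)` (n = non-gap observations in the column) is
#' subtracted and the result floored at 0. All-gap columns have no
#' defined content and are reported as `NA`.
#'
#' @param p A [build_profile()] result.
#' @param correction Apply the small-sample correction (default off).
#' @return An `information_profile`: list with `bits` (length 75),
#'   `heights` (4 x 75 letter heights, frequency x bits), `gap_fraction`,
#'   and `correction`.
#' @examples
#' ip <- information_content(build_profile(list(segment_trna(ancestral_core()))))
#' range(ip$bits)  # 2 2 for a single sequence, no correction
#' @export
information_content <- function(p, correction = FALSE) {
  stopifnot(inherits(p, "frequency_profile"), p$n_sequences >= 1L)
  f <- profile_freqs(p)
  nongap <- colSums(p$counts[c("A", "C", "G", "T"), , drop = FALSE])
  H <- apply(f, 2, function(col) {
    if (anyNA(col)) return(NA_real_)
    nz <- col[col > 0]
    -sum(nz * log2(nz))
  })
  bits <- 2 - H
  if (correction) {
    e_n <- ifelse(nongap > 0, 3 / (2 * log(2) * nongap), NA_real_)
    bits <- pmax(bits - e_n, 0)
  }
  heights <- sweep(f, 2, bits, "*")
  structure(list(bits = bits, heights = heights,
                 gap_fraction = p$counts["-", ] / p$n_sequences,
                 correction = correction),
            class = "information_profile")
}

#' @export
print.information_profile <- function(x, ...) {
  ok <- !is.na(x$bits)
  cat("<information_profile> 75 positions",
      if (x$correction) " (small-sample corrected)", "\n", sep = "")
  cat(sprintf("  mean %.3f bits, range [%.3f, %.3f]; %d undefined\n",
              mean(x$bits[ok]), min(x$bits[ok]), max(x$bits[ok]),
              sum(!ok)))
  invisible(x)
}

#' Sequence-logo style plot of an information profile
#'
#' Stacked per-position letter heights (frequency x bits), base
#' graphics. Segment boundaries of the 75-nt scheme are marked.
#'
#' @param x An `information_profile`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.information_profile <- function(x, ...) {
  h <- x$heights
  h[is.na(h)] <- 0
  cols <- c(A = "forestgreen", C = "steelblue", G = "goldenrod",
            T = "firebrick")
  graphics::plot(NA, xlim = c(0.5, 75.5), ylim = c(0, 2),
                 xlab = "core position", ylab = "bits", ...)
  for (j in seq_len(75L)) {
    ord <- order(h[, j])
    y0 <- 0
    for (i in ord) {
      if (h[i, j] <= 0) next
      graphics::rect(j - 0.45, y0, j + 0.45, y0 + h[i, j],
                     col = cols[rownames(h)[i]], border = NA)
      y0 <- y0 + h[i, j]
    }
  }
  sch <- segment_scheme()
  graphics::abline(v = sch$start[-1] - 0.5, lty = 3, col = "grey40")
  graphics::mtext(sch$segment, side = 3, line = 0,
                  at = (sch$start + sch$end) / 2, cex = 0.7)
  invisible(x)
}

#' Consensus sequence of a frequency profile
#'
#' @param p A `frequency_profile`.
#' @param threshold Minimum frequency (over non-gap observations) for a
#'   majority call; positions below it are `N`. Must be in (0.25, 1].
#' @return A 75-character string; all-gap columns are `-`.
#' @examples
#' consensus(build_profile(list(segment_trna(ancestral_core()))), 0.9)
#' @export
consensus <- function(p, threshold = 0.5) {
  stopifnot(inherits(p, "frequency_profile"))
  if (threshold <= 0.25 || threshold > 1) {
    stop("threshold must be in (0.25, 1]")
  }
  f <- profile_freqs(p)
  letters4 <- rownames(f)
  out <- vapply(seq_len(ncol(f)), function(j) {
    col <- f[, j]
    if (anyNA(col)) return("-")
    i <- which.max(col)  # ties: first of A,C,G,T
    if (col[i] >= threshold) letters4[i] else "N"
  }, character(1))
  paste(out, collapse = "")
}

#' Position-wise identity between two sequences
#'
#' Parallel (same-direction) comparison; positions where either sequence
#' has an ambiguity or gap symbol (`N`, `X`, `-`) are excluded from the
#' denominator.
#'
#' @param a,b Equal-length character scalars.
#' @return List with `matches`, `denominator`, and `identity`
#'   (`matches / denominator`; `NaN` when nothing is comparable).
#' @examples
#' seq_identity("GACCG", "GGCCG")$matches  # 4
#' @export
seq_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) {
    stop(sprintf("ranges must have equal length (%d vs %d)",
                 nchar(a), nchar(b)))
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- !(av %in% c("N", "X", "-")) & !(bv %in% c("N", "X", "-"))
  list(matches = sum(av[ok] == bv[ok]),
       denominator = sum(ok),
       identity = sum(av[ok] == bv[ok]) / sum(ok))
}

#' Consensus identity between two segments of a profile
#'
#' Compares the consensus letters of two equal-length core ranges in
#' parallel alignment; `N` and all-gap positions drop out of the
#' denominator (which is reported).
#'
#' @param p A `frequency_profile`, or a character scalar treated as a
#'   ready-made consensus on core coordinates.
#' @param segA,segB Segment name from [segment_scheme()] (e.g. `"DREM"`)
#'   or an integer range of core positions (e.g. `3:7`).
#' @param threshold Consensus threshold when `p` is a profile.
#' @return As [seq_identity()].
#' @examples
#' p <- build_profile(list(segment_trna(ancestral_core())))
#' segment_similarity(p, "DREM", 3:7)$matches  # GACCG vs GGCCG: 4
#' @export
segment_similarity <- function(p, segA, segB, threshold = 0.5) {
  cons <- if (is.character(p)) toupper(p) else consensus(p, threshold)
  resolve <- function(seg) {
    if (is.character(seg) && length(seg) == 1L) {
      sch <- segment_scheme()
      k <- match(seg, sch$segment)
      if (is.na(k)) stop("unknown segment name: ", seg)
      seq.int(sch$start[k], sch$end[k])
    } else {
      as.integer(seg)
    }
  }
  ra <- resolve(segA); rb <- resolve(segB)
  if (length(ra) != length(rb)) stop("ranges must have equal length")
  seq_identity(paste(strsplit(cons, "")[[1]][ra], collapse = ""),
               paste(strsplit(cons, "")[[1]][rb], collapse = ""))
}

#' Export a profile as a position-by-letter table
#'
#' @param p A `frequency_profile`.
#' @param correction Passed to [information_content()].
#' @return Data frame: `position`, counts `A`/`C`/`G`/`T`/`gap`, `bits`.
#' @export
profile_table <- function(p, correction = FALSE) {
  ip <- information_content(p, correction = correction)
  cnt <- t(p$counts)
  colnames(cnt) <- c("A", "C", "G", "T", "gap")
  data.frame(position = seq_len(75L), cnt, bits = ip$bits,
             stringsAsFactors = FALSE, check.names = FALSE)
}
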