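#' Construct a 17-nt microhelix
#'
#' A microhelix is a 5-nt stem, 7-nt loop, 5-nt stem; the anticodon
#' occupies loop positions 3-5.
#'
#' @param stem5,loop,stem3 Components of 5, 7 and 5 nt respectively; or
#'   pass a single 17-nt string as `stem5` with the others missing.
#' @return A `microhelix` object.
#' @examples
#' microhelix("TAGTCTAGCCTGGACTA")$anticodon  # "GCC"
#' @export
microhelix <- function(stem5, loop, stem3) {
  if (missing(loop) && missing(stem3)) {
    s <- chartr("U", "T", toupper(as.character(stem5)))
    if (nchar(s) != 17L) {
      stop(sprintf("microhelix must be 17 nt (got %d)", nchar(s)))
    }
    stem5 <- substr(s, 1, 5); loop <- substr(s, 6, 12)
    stem3 <- substr(s, 13, 17)
  }
  stem5 <- toupper(as.character(stem5))
  loop  <- toupper(as.character(loop))
  stem3 <- toupper(as.character(stem3))
  if (nchar(stem5) != 5L) stop("stem5 must be 5 nt")
  if (nchar(loop) != 7L)  stop("loop must be 7 nt")
  if (nchar(stem3) != 5L) stop("stem3 must be 5 nt")
  structure(list(stem5 = stem5, loop = loop, stem3 = stem3,
                 anticodon = substr(loop, 3, 5)),
            class = "microhelix")
}

#' @export
as.character.microhelix <- function(x, ...) {
  paste0(x$stem5, x$loop, x$stem3)
}

#' @export
print.microhelix <- function(x, ...) {
  cat("<microhelix> ", x$stem5, "-", x$loop, "-", x$stem3,
      " (anticodon ", x$anticodon, ")\n", sep = "")
  invisible(x)
}

#' Build a 31-nt minihelix from a microhelix and an acceptor stem
#'
#' A minihelix is a 17-nt microhelix flanked by a 14-nt (2 x 7-nt)
#' acceptor stem: `acc5 + microhelix + acc3`, 31 nt in all.
#'
#' @param micro A [microhelix()] (or 17-nt string).
#' @param acc5,acc3 The 7-nt acceptor stem halves.
#' @return A `minihelix` object.
#' @examples
#' mh <- build_minihelix("TAGTCTAGCCTGGACTA", "GCGGCCG", "CGGCCGC")
#' as.character(mh)  # 31 nt
#' @export
build_minihelix <- function(micro, acc5, acc3) {
  if (!inherits(micro, "microhelix")) micro <- microhelix(micro)
  acc5 <- toupper(as.character(acc5))
  acc3 <- toupper(as.character(acc3))
  if (nchar(acc5) != 7L) stop("acc5 must be 7 nt")
  if (nchar(acc3) != 7L) stop("acc3 must be 7 nt")
  structure(list(acc5 = acc5, micro = micro, acc3 = acc3),
            class = "minihelix")
}

#' @export
as.character.minihelix <- function(x, ...) {
  paste0(x$acc5, as.character(x$micro), x$acc3)
}

#' @export
print.minihelix <- function(x, ...) {
  cat("<minihelix> ", x$acc5, "-[", as.character(x$micro), "]-", x$acc3,
      " (31 nt, anticodon ", x$micro$anticodon, ")\n", sep = "")
  invisible(x)
}

#' Attach a 3'-CCA to a microhelix or minihelix
#'
#' A 17-nt microhelix with CCA is a 20-nt translation adaptor lacking an
#' acceptor stem; a 31-nt minihelix with CCA is 34 nt.
#'
#' @param x A `microhelix`, `minihelix`, or a string of 17 or 31 nt.
#' @return Character scalar ending in `CCA`, length 20 or 34.
#' @examples
#' nchar(attach_cca("TAGTCTAGCCTGGACTA"))  # 20
#' @export
attach_cca <- function(x) {
  s <- as.character(x)
  if (!nchar(s) %in% c(17L, 31L)) {
    stop(sprintf("expected a 17-nt microhelix or 31-nt minihelix (got %d nt)",
                 nchar(s)))
  }
  paste0(s, "CCA")
}

#' Ligation plan: which 9 of each 14-nt junction are deleted
#'
#' Ligating three minihelices joins two acceptor stems at each of the two
#' junctions (7 + 7 = 14 nt); a symmetrical 9-nt deletion leaves a 5-nt
#' remnant. The retained window is given per junction as positions within
#' the 14-nt junction (1-14, 5' to 3'). The default encodes the model's
#' alignments: junction 1 retains positions 10-14 (positions 3-7 of the
#' downstream acceptor stem, the future D-loop relic at 25-29); junction
#' 2 retains positions 1-5 (positions 1-5 of the upstream 3' acceptor
#' stem, the future V loop at 47-51).
#'
#' @param junction1,junction2 Integer vectors of 5 contiguous positions
#'   in 1..14.
#' @return A `ligation_plan` object.
#' @export
ligation_plan <- function(junction1 = 10:14, junction2 = 1:5) {
  check_window <- function(w, nm) {
    w <- as.integer(w)
    if (length(w) != 5L || any(diff(w) != 1L) || w[1] < 1L || w[5] > 14L) {
      stop(nm, " must be 5 contiguous positions within the 14-nt junction")
    }
    w
  }
  structure(list(junction1 = check_window(junction1, "junction1"),
                 junction2 = check_window(junction2, "junction2")),
            class = "ligation_plan")
}

#' @export
print.ligation_plan <- function(x, ...) {
  cat("<ligation_plan> junction 1 retains ", x$junction1[1], "-",
      x$junction1[5], "/14; junction 2 retains ", x$junction2[1], "-",
      x$junction2[5], "/14 (9-nt deletions)\n", sep = "")
  invisible(x)
}

#' Ligate three minihelices and apply the two symmetrical 9-nt deletions
#'
#' The generative step of the model: three 31-nt minihelices are ligated
#' into a 93-nt precursor; within each 14-nt acceptor-stem junction a
#' 9-nt deletion leaves a 5-nt remnant, yielding the 75-nt core
#' (93 - 18 = 75).
#'
#' @param mh1,mh2,mh3 `minihelix` objects (5' to 3': future D, anticodon
#'   and T arms).
#' @param plan A [ligation_plan()]; the default encodes the model's
#'   retained windows.
#' @return A `clover_core`: list with `precursor` (93 nt), `core`
#'   (75 nt), and `segment_map` (named 7/17/5/17/5/17/7 segments).
#' @examples
#' a <- ancestral_sequences()
#' mhs <- lapply(a[c("d_microhelix", "ac_microhelix", "t_microhelix")],
#'               build_minihelix, acc5 = a[["acc5"]], acc3 = a[["acc3"]])
#' nchar(ligate_and_delete(mhs[[1]], mhs[[2]], mhs[[3]])$core)  # 75
#' @export
ligate_and_delete <- function(mh1, mh2, mh3, plan = ligation_plan()) {
  for (mh in list(mh1, mh2, mh3)) {
    if (!inherits(mh, "minihelix")) stop("inputs must be minihelix objects")
  }
  if (!inherits(plan, "ligation_plan")) stop("plan must be a ligation_plan")
  precursor <- paste0(as.character(mh1), as.character(mh2),
                      as.character(mh3))
  stopifnot(nchar(precursor) == 93L)

  keep_window <- function(junction14, keep) {
    paste(strsplit(junction14, "", fixed = TRUE)[[1]][keep], collapse = "")
  }
  j1 <- paste0(mh1$acc3, mh2$acc5)  # junction 1: 14 nt
  j2 <- paste0(mh2$acc3, mh3$acc5)  # junction 2: 14 nt
  drem  <- keep_window(j1, plan$junction1)
  vloop <- keep_window(j2, plan$junction2)

  segment_map <- c(
    AS5   = mh1$acc5,
    DMH   = as.character(mh1$micro),
    DREM  = drem,
    ACMH  = as.character(mh2$micro),
    VLOOP = vloop,
    TMH   = as.character(mh3$micro),
    AS3   = mh3$acc3
  )
  core <- paste(segment_map, collapse = "")
  stopifnot(nchar(core) == 75L)
  structure(list(precursor = precursor, core = core,
                 segment_map = segment_map, plan = plan),
            class = "clover_core")
}

#' @export
print.clover_core <- function(x, ...) {
  cat("<clover_core> 93-nt precursor -> 75-nt core\n")
  for (nm in names(x$segment_map)) {
    cat(sprintf("  %-5s %s\n", nm, x$segment_map[[nm]]))
  }
  invisible(x)
}

#' Snapback replication of a minihelix
#'
#' Models minihelix replication by 3'-ligation of a complementary
#' minihelix primer followed by templated extension: each round appends
#' one 31-nt unit that is the exact reverse complement of the previous
#' unit, so the product of round r is a 31 x (r + 1) nt concatemer of
#' alternating minihelix and complement. Optionally a per-base
#' substitution rate introduces seeded copying errors.
#'
#' @param mh A `minihelix` or 31-nt string.
#' @param rounds Number of replication rounds (>= 1).
#' @param error_rate Per-base substitution probability during copying
#'   (default 0: deterministic templated copying).
#' @param seed Optional integer seed for the error process.
#' @return A `snapback_product`: list with `product` (the concatemer),
#'   `units` (each 31-nt unit), and `rounds`.
#' @examples
#' p <- snapback_replicate(build_minihelix("TAGTCTAGCCTGGACTA",
#'                                         "GCGGCCG", "CGGCCGC"), 1)
#' nchar(p$product)  # 62
#' @export
snapback_replicate <- function(mh, rounds, error_rate = 0, seed = NULL) {
  s <- chartr("U", "T", toupper(as.character(mh)))
  if (nchar(s) != 31L) stop("template must be a 31-nt minihelix")
  if (rounds < 1L) stop("rounds must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  units <- character(rounds + 1L)
  units[1] <- s
  for (r in seq_len(rounds)) {
    copy <- reverse_complement(units[r])
    if (error_rate > 0) {
      v <- strsplit(copy, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(v)) < error_rate)
      for (i in hit) {
        v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
      }
      copy <- paste(v, collapse = "")
    }
    units[r + 1L] <- copy
  }
  structure(list(product = paste(units, collapse = ""), units = units,
                 rounds = rounds, error_rate = error_rate),
            class = "snapback_product")
}

#' @export
print.snapback_product <- function(x, ...) {
  cat("<snapback_product> ", x$rounds, " round(s), ",
      nchar(x$product), " nt (", length(x$units), " x 31)\n", sep = "")
  invisible(x)
}

#' Excise 31-nt minihelix units from a concatemer
#'
#' @param concatemer Character scalar whose length is a multiple of 31,
#'   or a `snapback_product`.
#' @return Character vector of 31-nt units whose concatenation restores
#'   the input.
#' @examples
#' length(excise_minihelices(strrep("GCGGCCGTAGTCTAGCCTGGACTACGGCCGC", 3)))
#' @export
excise_minihelices <- function(concatemer) {
  if (inherits(concatemer, "snapback_product")) {
    concatemer <- concatemer$product
  }
  s <- toupper(as.character(concatemer))
  n <- nchar(s)
  if (n == 0L || n %% 31L != 0L) {
    stop(sprintf("length %d is not decomposable into 31-nt minihelices", n))
  }
  starts <- seq.int(1L, n, by = 31L)
  substring(s, starts, starts + 30L)
}
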