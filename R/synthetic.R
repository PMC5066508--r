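#' Generate an archaeal-like synthetic tRNA set with known truth
#'
#' Draws i.i.d. records from the 75-nt ancestral core under a simple
#' evolutionary model: per-position substitutions at a fixed rate
#' (sparing the anticodon by default — each anticodon is its own
#' lineage), a D-loop deletion of variable length confined to the D
#' microhelix (columns 8-24), and a V-loop insertion. The intact-D
#' fraction therefore has expectation `1 - d_deletion_probability`.
#' Output is fully determined by the seed (Mersenne-Twister).
#'
#' @param n Number of records.
#' @param ancestral 75-nt core to mutate (default [ancestral_core()]).
#' @param substitution_rate Per-position substitution probability.
#' @param d_deletion_probability Probability a record carries a D-loop
#'   deletion (default 0.8, the archaeal survey's ~20% intact fraction).
#' @param d_deletion_lengths Integer vector (support 1..14) from which a
#'   deletion length is drawn uniformly, or a named probability vector.
#' @param v_insertion_probability Probability of a V-loop insertion.
#' @param v_insertion_lengths As `d_deletion_lengths`, for insertions.
#' @param protect_anticodon Spare core positions 37-39 from substitution
#'   (default TRUE).
#' @param seed Integer seed; same config + seed reproduces the set
#'   byte-identically.
#' @return A `synthetic_trna_set`: list with `sequences` (named
#'   character), `truth` (data frame: `id`, `intact`,
#'   `d_deletion_length`, `v_insertion_length`,
#'   `substituted_positions`), and `config`.
#' @examples
#' s <- generate_trna_set(n = 5, seed = 1)
#' s$truth$intact
#' @export
generate_trna_set <- function(n = 500,
                              ancestral = ancestral_core(),
                              substitution_rate = 0.05,
                              d_deletion_probability = 0.8,
                              d_deletion_lengths = 1:9,
                              v_insertion_probability = 0.2,
                              v_insertion_lengths = 1:4,
                              protect_anticodon = TRUE,
                              seed = NULL) {
  stopifnot(n >= 1L, nchar(ancestral) == 75L,
            substitution_rate >= 0, substitution_rate <= 1,
            d_deletion_probability >= 0, d_deletion_probability <= 1,
            v_insertion_probability >= 0, v_insertion_probability <= 1,
            all(d_deletion_lengths %in% 1:14))
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  bases <- c("A", "C", "G", "T")
  anc <- strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]

  draw_len <- function(lens) {
    if (!is.null(names(lens))) {
      as.integer(sample(names(lens), 1L, prob = lens))
    } else {
      lens[sample.int(length(lens), 1L)]
    }
  }

  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    v <- anc
    # substitutions on core coordinates
    subst_ok <- seq_len(75L)
    if (protect_anticodon) subst_ok <- setdiff(subst_ok, ANTICODON_CORE_POS)
    hit <- subst_ok[stats::runif(length(subst_ok)) < substitution_rate]
    for (p in hit) v[p] <- sample(setdiff(bases, v[p]), 1L)

    # D-loop deletion, confined to DMH (8-24)
    d_len <- 0L
    if (stats::runif(1) < d_deletion_probability) {
      d_len <- draw_len(d_deletion_lengths)
      start <- 8L + sample.int(17L - d_len + 1L, 1L) - 1L
      v <- v[-(start:(start + d_len - 1L))]
    }

    # V-loop insertion: random bases inserted within the V loop
    ins_len <- 0L
    if (stats::runif(1) < v_insertion_probability) {
      ins_len <- draw_len(v_insertion_lengths)
      ins <- sample(bases, ins_len, replace = TRUE)
      # V loop occupies 47-51 pre-deletion; locate it post-deletion
      at <- 51L - d_len
      v <- append(v, ins, after = at)
    }

    seqs[i] <- paste(v, collapse = "")
    truth[[i]] <- data.frame(
      id = sprintf("synth_%04d", i),
      intact = d_len == 0L,
      d_deletion_length = d_len,
      v_insertion_length = ins_len,
      substituted_positions = paste(hit, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  names(seqs) <- truth$id
  structure(list(sequences = seqs, truth = truth,
                 config = list(n = n, ancestral = ancestral,
                               substitution_rate = substitution_rate,
                               d_deletion_probability = d_deletion_probability,
                               d_deletion_lengths = d_deletion_lengths,
                               v_insertion_probability = v_insertion_probability,
                               v_insertion_lengths = v_insertion_lengths,
                               protect_anticodon = protect_anticodon,
                               seed = seed)),
            class = "synthetic_trna_set")
}

#' @export
print.synthetic_trna_set <- function(x, ...) {
  cat("<synthetic_trna_set> n = ", length(x$sequences),
      ", intact ", sum(x$truth$intact), "/", nrow(x$truth),
      " (seed ", if (is.null(x$config$seed)) "none" else x$config$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Generate idealized hairpin backbone coordinates
#'
#' Builds a deterministic stem-loop backbone trace: two antiparallel
#' A-form-like helical strands (given rise and twist per residue) closed
#' by a loop arc, with six backbone atoms per residue (P, O5', C5',
#' C4', C3', O3') and optional per-coordinate Gaussian noise. Intended
#' as a ground-truth fixture for superposition: two noise-free copies
#' superpose at RMSD 0.
#'
#' @param n_residues Number of residues (>= 4; 17 gives the canonical
#'   5-7-5 stem-loop).
#' @param rise Helical rise per residue, Angstrom (default 2.8).
#' @param twist Helical twist per residue, degrees (default 32.7).
#' @param noise Gaussian noise standard deviation per coordinate,
#'   Angstrom.
#' @param seed Integer seed for the noise.
#' @param file Optional path; if given, a PDB file is written there.
#' @return A `backbone_selection` (invisibly when `file` is given).
#' @examples
#' h <- generate_hairpin_coords(17)
#' nrow(h)  # 17 * 6 = 102 points
#' @export
generate_hairpin_coords <- function(n_residues = 17, rise = 2.8,
                                    twist = 32.7, noise = 0,
                                    seed = NULL, file = NULL) {
  if (n_residues < 4L) stop("n_residues must be >= 4")
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  stem_n <- max(1L, (n_residues - 7L) %/% 2L)
  loop_n <- n_residues - 2L * stem_n
  radius <- 9.4
  tw <- twist * pi / 180

  centers <- matrix(NA_real_, n_residues, 3)
  angles <- numeric(n_residues)
  # strand A: ascending helix
  for (i in seq_len(stem_n)) {
    th <- (i - 1) * tw
    centers[i, ] <- c(radius * cos(th), radius * sin(th), (i - 1) * rise)
    angles[i] <- th
  }
  z_top <- (stem_n - 1) * rise
  # loop: arc over the top, shrinking radius
  for (j in seq_len(loop_n)) {
    th <- (stem_n - 1) * tw + j * tw
    frac <- j / (loop_n + 1)
    r <- radius * (0.55 + 0.45 * cos(pi * frac))
    centers[stem_n + j, ] <- c(r * cos(th), r * sin(th),
                               z_top + 5 * sin(pi * frac) + rise * frac)
    angles[stem_n + j] <- th
  }
  # strand B: descending, offset around the axis from its pair
  for (k in seq_len(stem_n)) {
    pair <- stem_n - k + 1L          # paired strand-A residue
    th <- (pair - 1) * tw + 2.4      # ~140 degree strand separation
    centers[stem_n + loop_n + k, ] <-
      c(radius * cos(th), radius * sin(th), (pair - 1) * rise + 1.2)
    angles[stem_n + loop_n + k] <- th
  }

  atom_names <- BACKBONE_ATOM_SETS$backbone6
  offsets <- rbind(
    P     = c(0.0,  0.0, 0.0),
    `O5'` = c(0.9,  0.5, 0.4),
    `C5'` = c(1.6,  1.0, 0.8),
    `C4'` = c(2.3,  0.8, 1.3),
    `C3'` = c(2.7, -0.2, 1.7),
    `O3'` = c(3.1, -0.6, 2.4)
  )
  rows <- vector("list", n_residues * 6L)
  k <- 0L
  for (i in seq_len(n_residues)) {
    th <- angles[i]
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                  3, 3)
    for (a in atom_names) {
      k <- k + 1L
      xyz <- centers[i, ] + as.numeric(rot %*% offsets[a, ])
      if (noise > 0) xyz <- xyz + stats::rnorm(3, sd = noise)
      rows[[k]] <- data.frame(resno = i, elety = a, x = xyz[1],
                              y = xyz[2], z = xyz[3],
                              stringsAsFactors = FALSE)
    }
  }
  sel <- do.call(rbind, rows)
  sel <- structure(sel, missing_atoms = character(0), chain = "A",
                   range = c(1L, n_residues),
                   class = c("backbone_selection", "data.frame"))
  if (!is.null(file)) {
    write_backbone_pdb(sel, file)
    return(invisible(sel))
  }
  sel
}

#' Write a backbone selection as a PDB file
#'
#' Minimal single-chain PDB writer for synthetic backbone fixtures
#' (residue name `A`, chain `A`, occupancy 1.00).
#'
#' @param sel A `backbone_selection`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_backbone_pdb <- function(sel, file) {
  name4 <- vapply(sel$elety, function(a) {
    if (nchar(a) < 4L) sprintf(" %-3s", a) else a
  }, character(1))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(sel)), name4, "A", "A", sel$resno,
    sel$x, sel$y, sel$z, 1.0, 0.0)
  writeLines(c(lines, "END"), file)
  invisible(file)
}
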