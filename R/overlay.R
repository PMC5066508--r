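BACKBONE_ATOM_SETS <- list(
  backbone6 = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
  p = "P"
)

resolve_atom_set <- function(atoms) {
  if (length(atoms) == 1L && atoms %in% names(BACKBONE_ATOM_SETS)) {
    BACKBONE_ATOM_SETS[[atoms]]
  } else if (length(atoms) == 1L && atoms == "heavy") {
    NULL  # all non-hydrogen atoms, order as in file
  } else {
    atoms
  }
}

#' Read an ordered backbone selection from a PDB file
#'
#' Extracts atomic coordinates for a contiguous residue range of one
#' chain, restricted to a named backbone atom set, ordered by residue
#' then by the atom-set order. Alternate locations resolve to the
#' highest-occupancy copy. The default 6-atom ribose-phosphate backbone
#' (P, O5', C5', C4', C3', O3') gives 6 points per residue.
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param chain Chain identifier.
#' @param resno Integer vector of residue numbers (contiguous range).
#' @param atoms `"backbone6"` (default), `"p"`, `"heavy"`, or a character
#'   vector of atom names.
#' @return A `backbone_selection`: data frame with columns `resno`,
#'   `elety`, `x`, `y`, `z`; attribute `missing_atoms` lists requested
#'   atoms absent from the file.
#' @export
read_backbone <- function(pdb, chain = "A", resno, atoms = "backbone6") {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- pdb$atom
  atom_set <- resolve_atom_set(atoms)
  resno <- as.integer(resno)

  sel <- at$chain %in% chain & at$resno %in% resno & at$type == "ATOM"
  if (!is.null(atom_set)) sel <- sel & at$elety %in% atom_set
  else sel <- sel & !grepl("^H", trimws(at$elety))
  at <- at[sel, , drop = FALSE]

  present <- unique(at$resno)
  missing_res <- setdiff(resno, present)
  if (length(missing_res) > 0L) {
    stop("residues missing from chain ", chain, ": ",
         paste(missing_res, collapse = ", "))
  }

  # altloc: keep highest occupancy per (resno, elety)
  if (any(!at$alt %in% c("", NA))) {
    key <- paste(at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  rows <- list()
  missing_atoms <- character(0)
  for (r in resno) {
    sub <- at[at$resno == r, , drop = FALSE]
    order_names <- if (is.null(atom_set)) unique(sub$elety) else atom_set
    for (a in order_names) {
      i <- which(sub$elety == a)
      if (length(i) == 0L) {
        missing_atoms <- c(missing_atoms, paste0(r, ":", a))
        next
      }
      rows[[length(rows) + 1L]] <- sub[i[1L], c("resno", "elety",
                                                "x", "y", "z")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, missing_atoms = missing_atoms,
            chain = chain, range = range(resno),
            class = c("backbone_selection", "data.frame"))
}

#' @export
print.backbone_selection <- function(x, ...) {
  rng <- attr(x, "range")
  cat("<backbone_selection> chain ", attr(x, "chain"), ", residues ",
      rng[1], "-", rng[2], ": ", nrow(x), " atoms\n", sep = "")
  miss <- attr(x, "missing_atoms")
  if (length(miss) > 0L) {
    cat("  missing: ", paste(miss, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

selection_coords <- function(x) {
  if (inherits(x, "backbone_selection")) {
    as.matrix(x[, c("x", "y", "z")])
  } else {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 3L)
    m
  }
}

#' Optimal rigid superposition of two ordered point sets (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `P`
#' onto `Q` under ordinal correspondence (i-th point to i-th point),
#' computed by singular value decomposition of the cross-covariance of
#' the centred sets, with the determinant sign corrected so the rotation
#' is always proper (no reflection).
#'
#' @param P,Q `backbone_selection` objects or n x 3 coordinate matrices
#'   with equal point counts (selections must also agree in atom-name
#'   sequence).
#' @return A `superposition_result`: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3), `rmsd` (Angstrom),
#'   `n_atoms`, and `transformed` (P after the fit).
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(P, P)$rmsd  # 0
#' @export
kabsch_superpose <- function(P, Q) {
  if (inherits(P, "backbone_selection") &&
      inherits(Q, "backbone_selection")) {
    if (!identical(as.character(P$elety), as.character(Q$elety))) {
      stop("atom-name sequences of the two selections differ")
    }
  }
  p <- selection_coords(P)
  q <- selection_coords(Q)
  if (nrow(p) != nrow(q)) {
    stop(sprintf("point counts differ (%d vs %d)", nrow(p), nrow(q)))
  }
  n <- nrow(p)
  if (n < 3L) stop("at least 3 points are required")

  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)

  H <- crossprod(pc, qc)  # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    warning("degenerate (collinear) point set; rotation not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((transformed - qc)^2)))
  translation <- as.numeric(cq - R %*% cp)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_atoms = n,
                 transformed = sweep(transformed, 2, cq, "+")),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> %d atoms, RMSD %.4f Angstrom\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Superpose the anticodon arm onto the T arm of one structure
#'
#' Reads two 17-residue stem-loop backbone selections from the same
#' structure and computes their optimal rigid superposition with
#' stem-on-stem, loop-on-loop ordinal correspondence. Residues whose
#' default atoms are incomplete are dropped pairwise from both
#' selections (reported via a message).
#'
#' @param pdb Path to a PDB file or a `bio3d` `pdb` object.
#' @param ac_range,t_range Integer vectors of 17 residue numbers
#'   (anticodon and T stem-loops; on the 75-nt scheme these are 30-46
#'   and 52-68, but deposited structures usually need explicit ranges).
#' @param chain Chain identifier.
#' @param atoms Atom set as in [read_backbone()].
#' @return A `superposition_result`.
#' @export
overlay_ac_vs_t <- function(pdb, ac_range, t_range, chain = "A",
                            atoms = "backbone6") {
  if (length(ac_range) != 17L || length(t_range) != 17L) {
    stop("both ranges must span exactly 17 residues")
  }
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  a <- read_backbone(pdb, chain, ac_range, atoms)
  b <- read_backbone(pdb, chain, t_range, atoms)

  # pairwise-complete on (ordinal residue, atom name)
  key <- function(x, rng) {
    paste(match(x$resno, rng), x$elety)
  }
  ka <- key(a, ac_range); kb <- key(b, t_range)
  common <- intersect(ka, kb)
  if (length(common) < length(ka) || length(common) < length(kb)) {
    message("dropping ", (length(ka) - length(common)) +
              (length(kb) - length(common)),
            " unmatched atoms (pairwise-complete selection)")
  }
  kabsch_superpose(a[ka %in% common, , drop = FALSE],
                   b[kb %in% common, , drop = FALSE])
}
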