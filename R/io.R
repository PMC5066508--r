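#' Read tRNA sequences from FASTA
#'
#' Plain multi-record FASTA; sequences may carry modified-nucleotide
#' codes, so records are read without alphabet validation (normalize
#' with [normalize_sequence()] or via [segment_set()]).
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of raw sequences.
#' @export
read_trna_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read sequences with interleaved dot-bracket structures
#'
#' Vienna-style records: a `>id` header, one sequence line, then one
#' dot-bracket line (optionally carrying a free-energy annotation, which
#' is dropped). This interleaved dialect is not valid plain FASTA, hence
#' the dedicated reader.
#'
#' @param file Path.
#' @return List with `sequences` and `structures`, both named character
#'   vectors.
#' @export
read_vienna <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers in ", file)
  seqs <- structure(character(0), names = character(0))
  strs <- structure(character(0), names = character(0))
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[hdr[k]]))
    body <- lines[seq.int(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    first_tok <- sub("\\s.*$", "", body)
    is_struct <- nzchar(first_tok) & !grepl("[A-Za-z0-9]", first_tok)
    struct <- body[is_struct]
    seq <- paste(gsub("\\s", "", body[!is_struct]), collapse = "")
    seqs[id] <- seq
    strs[id] <- if (length(struct) > 0L) {
      sub("\\s.*$", "", struct[1])
    } else NA_character_
  }
  list(sequences = seqs, structures = strs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param file Output path.
#' @param alphabet `"dna"` (default) or `"rna"` (T written as U).
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file, alphabet = "dna") {
  seqs <- vapply(seqs, to_alphabet, character(1), alphabet = alphabet)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  invisible(file)
}

#' Normalize and segment a set of sequences
#'
#' Pipeline convenience: normalizes each raw sequence and segments it
#' onto the 75-nt scheme. Records that cannot be segmented are either an
#' error (`on_error = "stop"`) or collected and reported (`"skip"`,
#' the default for surveys: failures are listed, never silent).
#'
#' @param seqs Named character vector of raw sequences, or a path to a
#'   FASTA file.
#' @param structures Optional named character vector of dot-bracket
#'   strings (ids matching `seqs`).
#' @param strict Strict normalization (see [normalize_sequence()]).
#' @param on_error `"skip"` or `"stop"`.
#' @param ... Passed to [segment_trna()].
#' @return List of `segmented_trna`; attribute `failures` is a named
#'   character vector of error messages for skipped records.
#' @export
segment_set <- function(seqs, structures = NULL, strict = TRUE,
                        on_error = c("skip", "stop"), ...) {
  on_error <- match.arg(on_error)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    seqs <- read_trna_fasta(seqs)
  }
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
  }
  out <- list()
  failures <- character(0)
  for (id in names(seqs)) {
    st <- if (!is.null(structures) && id %in% names(structures) &&
              !is.na(structures[[id]])) structures[[id]] else NULL
    res <- tryCatch(
      segment_trna(normalize_sequence(seqs[[id]], strict = strict),
                   structure = st, id = id, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") {
        stop("record '", id, "': ", conditionMessage(res))
      }
      failures[id] <- conditionMessage(res)
    } else {
      out[[id]] <- res
    }
  }
  if (length(failures) > 0L) {
    warning(length(failures), " of ", length(seqs),
            " records could not be segmented (see attr 'failures')")
  }
  attr(out, "failures") <- failures
  out
}

#' JSON segmentation report
#'
#' @param trnas A `segmented_trna` or list of them.
#' @param file Optional path; if given, JSON is written there.
#' @return JSON string (invisibly when `file` is given).
#' @export
segmentation_json <- function(trnas, file = NULL) {
  if (inherits(trnas, "segmented_trna")) trnas <- list(trnas)
  payload <- lapply(trnas, function(x) {
    list(id = x$id,
         segments = as.list(x$segments),
         v_insertion = x$v_insertion,
         d_region_length = x$d_region_length,
         v_region_length = x$v_region_length,
         d_status = x$d_status, v_status = x$v_status,
         cca_stripped = x$cca_stripped)
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
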