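#' The canonical RVD-base code
#'
#' One TALE repeat reads one base; the repeat-variable diresidue (RVD)
#' determines which. The canonical code used throughout the package is
#' HD -> C, NN -> G, NI -> A, NG -> T (NN also binds A, more weakly; the
#' preference matrix carries that nuance, the code here is the one-to-one
#' design mapping).
#'
#' @format Named character vector mapping base to RVD.
#' @export
RVD_CODE <- c(C = "HD", G = "NN", A = "NI", T = "NG")

# inverse map, RVD -> preferred base
RVD_PREFERRED_BASE <- setNames(names(RVD_CODE), RVD_CODE)

#' Validate an EBE sequence
#'
#' An effector-binding element (EBE) is the DNA sequence bound by a TALE:
#' by default a 19-mer over {A,C,G,T} whose first base is the invariant
#' T0 thymine. Positions are numbered 1-based with T0 at position 1.
#'
#' @param sequence Character scalar, the candidate EBE. Case is
#'   normalized to upper.
#' @param length Required length (default 19). Design-grade elements are
#'   at least 12 bases ([generation_config()] enforces that floor); short
#'   explicit lengths are accepted here for toy constructions.
#' @return The validated, uppercased sequence with class `"ebe"` and a
#'   `length` attribute.
#' @details Each failure mode signals a distinct condition class:
#'   `orthotale_error_length`, `orthotale_error_alphabet`,
#'   `orthotale_error_t0`.
#' @examples
#' validate_ebe("TCCCCGCATAGCTGAACAT")
#' @export
validate_ebe <- function(sequence, length = 19L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    ot_stop("input", "`sequence` must be a single non-empty string")
  }
  if (length < 2L) {
    ot_stop("config", "EBE length must be >= 2")
  }
  s <- toupper(sequence)
  if (nchar(s) != length) {
    ot_stop("length", sprintf("EBE must be %d bases long, got %d",
                              length, nchar(s)))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), DNA_BASES)
  if (length(bad) > 0L) {
    ot_stop("alphabet", sprintf("EBE contains non-ACGT character(s): %s",
                                paste(bad, collapse = ", ")))
  }
  if (chars[1L] != "T") {
    ot_stop("t0", sprintf(
      "EBE must start with the invariant T0 thymine, got '%s'", chars[1L]))
  }
  structure(s, length = nchar(s), class = "ebe")
}

#' @export
print.ebe <- function(x, ...) {
  cat(sprintf("<EBE %d-mer> %s\n", attr(x, "length"), unclass(x)))
  invisible(x)
}

# coerce an ebe/character to a plain uppercase string without revalidating
as_ebe_string <- function(ebe) {
  if (inherits(ebe, "ebe")) return(unclass(ebe)[1L])
  toupper(as.character(ebe)[1L])
}

#' Translate an EBE into its TALE repeat (RVD) array
#'
#' Applies the canonical code (C->HD, G->NN, A->NI, T->NG) to bases 2..L
#' of the EBE. T0 is not represented: it is coordinated by the degenerate
#' N-terminal repeats, not by a canonical repeat, so a 19-mer EBE yields
#' an 18-repeat array.
#'
#' @param ebe An `"ebe"` object or a string (validated with the default
#'   length of `nchar(ebe)` if plain).
#' @return Character vector of RVD codes with class `"rvd_array"`.
#' @examples
#' ebe_to_rvds(validate_ebe("TCCCCGCATAGCTGAACAT"))
#' @export
ebe_to_rvds <- function(ebe) {
  if (!inherits(ebe, "ebe")) ebe <- validate_ebe(ebe, length = nchar(ebe))
  chars <- strsplit(as_ebe_string(ebe), "", fixed = TRUE)[[1L]]
  structure(unname(RVD_CODE[chars[-1L]]), class = "rvd_array")
}

#' Reverse-translate an RVD array into the EBE it targets
#'
#' Prepends T0 and maps each RVD to its preferred base (NN -> G).
#'
#' @param rvds Character vector of RVD codes (`"rvd_array"` or plain).
#' @return An `"ebe"` object of length `length(rvds) + 1`.
#' @export
rvds_to_ebe <- function(rvds) {
  rvds <- as.character(rvds)
  unknown <- setdiff(unique(rvds), names(RVD_PREFERRED_BASE))
  if (length(unknown) > 0L) {
    ot_stop("rvd", sprintf("unknown RVD code(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  seq <- paste0("T", paste(RVD_PREFERRED_BASE[rvds], collapse = ""))
  validate_ebe(seq, length = nchar(seq))
}

#' @method format rvd_array
#' @export
format.rvd_array <- function(x, ...) paste(unclass(x), collapse = "-")

#' @export
print.rvd_array <- function(x, ...) {
  cat(sprintf("<RVD array, %d repeats> %s\n", length(unclass(x)), format(x)))
  invisible(x)
}

#' Mismatch profile between an EBE and an equal-length site
#'
#' Positions are 1-based over the full element with T0 at position 1 —
#' the coordinate system used by the position factor [position_factor()].
#'
#' @param ebe An `"ebe"` object or plain string.
#' @param site DNA string of the same length (uppercased internally).
#' @return List with class `"mismatch_profile"`: `positions` (sorted
#'   integer vector) and `count`.
#' @examples
#' mismatch_profile("TCCCCGCATAGCTGAACAT", "ACCCCGCATAGCTGGACAA")
#' @export
mismatch_profile <- function(ebe, site) {
  a <- as_ebe_string(ebe)
  b <- toupper(as.character(site)[1L])
  if (nchar(a) != nchar(b)) {
    ot_stop("length", sprintf(
      "site length (%d) does not match EBE length (%d)", nchar(b), nchar(a)))
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  pos <- which(ca != cb)
  structure(list(positions = as.integer(pos), count = length(pos)),
            class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat(sprintf("<mismatch profile> %d mismatch(es) at {%s}\n", x$count,
              paste(x$positions, collapse = ",")))
  invisible(x)
}

#' Read EBEs from FASTA or bare text
#'
#' Accepts a FASTA file (via Biostrings) or a plain file with one
#' sequence per line.
#'
#' @param path File path.
#' @param length Expected EBE length.
#' @return List of `"ebe"` objects, named when the FASTA carries names.
#' @export
read_ebes <- function(path, length = 19L) {
  if (!file.exists(path)) ot_stop("io", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    set <- Biostrings::readDNAStringSet(path)
    seqs <- setNames(as.character(set), names(set))
  } else {
    lines <- readLines(path)
    seqs <- trimws(lines[nzchar(trimws(lines))])
  }
  lapply(seqs, validate_ebe, length = length)
}

#' Write EBEs as multi-record FASTA
#'
#' @param ebes List/vector of EBEs (or plain strings).
#' @param path Output path.
#' @param ids Record identifiers (default `ebe_1`, `ebe_2`, ...).
#' @return `path`, invisibly.
#' @export
write_ebes <- function(ebes, path, ids = NULL) {
  seqs <- vapply(ebes, as_ebe_string, character(1L))
  if (is.null(ids)) ids <- sprintf("ebe_%d", seq_along(seqs))
  set <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
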