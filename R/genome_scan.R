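#' Read a genome into a DNAStringSet
#'
#' Accepts a FASTA path, a `DNAStringSet`, or a named character vector.
#' Sequences are uppercased (soft-masked lowercase bases are treated as
#' ordinary bases; any N disqualifies the windows that contain it from
#' matching downstream).
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @return Named uppercase character vector, one element per contig.
#' @export
read_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    set <- Biostrings::readDNAStringSet(genome)
    g <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  } else if (methods::is(genome, "DNAStringSet")) {
    g <- setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    g <- genome
  } else if (is.character(genome) && length(genome) == 1L) {
    ot_stop("io", sprintf("genome FASTA not found: %s", genome))
  } else {
    ot_stop("input", "genome must be a FASTA path, DNAStringSet, or named character vector")
  }
  toupper(g)
}

# reverse complement of a plain character string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

strand_set <- function(strands) {
  strands <- match.arg(strands, c("both", "+", "-"))
  if (strands == "both") c("+", "-") else strands
}

# near-equal contiguous blocks covering 1..L, for the pigeonhole filter
seed_blocks <- function(L, k) {
  k <- min(k, L)
  sizes <- rep(L %/% k, k)
  if (L %% k > 0L) sizes[seq_len(L %% k)] <- sizes[seq_len(L %% k)] + 1L
  ends <- cumsum(sizes)
  data.frame(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

# candidate window starts in one contig for one oriented pattern, by the
# pigeonhole principle: a window with <= max_mismatch mismatches must
# match at least one of max_mismatch+1 disjoint seed blocks exactly.
pigeonhole_candidates <- function(pattern, subject_dna, max_mismatch) {
  L <- nchar(pattern)
  n <- length(subject_dna)
  if (n < L) return(integer(0L))
  if (max_mismatch >= L) return(seq_len(n - L + 1L))
  blocks <- seed_blocks(L, max_mismatch + 1L)
  starts <- integer(0L)
  for (i in seq_len(nrow(blocks))) {
    seed <- substr(pattern, blocks$start[i], blocks$end[i])
    m <- Biostrings::matchPattern(seed, subject_dna, max.mismatch = 0,
                                  fixed = TRUE)
    starts <- c(starts, BiocGenerics::start(m) - blocks$start[i] + 1L)
  }
  sort(unique(starts[starts >= 1L & starts <= n - L + 1L]))
}

# verify candidate starts: returns data.frame(start, site, n_mismatch,
# positions) in EBE (binding-orientation) coordinates. `strand` controls
# the orientation mapping; `contig_str` is the forward contig string.
verify_windows <- function(ebe, contig_str, starts, strand, max_mismatch) {
  L <- nchar(ebe)
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0L), site = character(0L),
                      n_mismatch = integer(0L), positions = character(0L)))
  }
  wins <- substring(contig_str, starts, starts + L - 1L)
  ebe_chars <- strsplit(ebe, "", fixed = TRUE)[[1L]]
  pat_chars <- if (strand == "+") ebe_chars else
    strsplit(revcomp(ebe), "", fixed = TRUE)[[1L]]
  win_mat <- matrix(unlist(strsplit(wins, "", fixed = TRUE), use.names = FALSE),
                    ncol = L, byrow = TRUE)
  valid <- rowSums(matrix(win_mat %in% DNA_BASES, ncol = L)) == L
  mm <- win_mat != matrix(pat_chars, nrow = nrow(win_mat), ncol = L,
                          byrow = TRUE)
  counts <- rowSums(mm)
  keep <- which(valid & counts <= max_mismatch)
  if (length(keep) == 0L) {
    return(data.frame(start = integer(0L), site = character(0L),
                      n_mismatch = integer(0L), positions = character(0L)))
  }
  pos_str <- vapply(keep, function(i) {
    p <- which(mm[i, ])
    if (strand == "-") p <- sort(L + 1L - p)
    paste(p, collapse = ",")
  }, character(1L))
  site <- wins[keep]
  if (strand == "-") site <- vapply(site, revcomp, character(1L),
                                    USE.NAMES = FALSE)
  data.frame(start = as.integer(starts[keep]), site = site,
             n_mismatch = as.integer(counts[keep]), positions = pos_str)
}

finalize_hits <- function(parts) {
  hits <- do.call(rbind, parts)
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(chrom = character(0L), start = integer(0L),
                       end = integer(0L), strand = character(0L),
                       site = character(0L), n_mismatch = integer(0L),
                       positions = character(0L))
  }
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("offtarget_hits", "data.frame")
  hits
}

#' Scan a genome for near-match windows of an EBE
#'
#' Finds every window on the requested strand(s) within `max_mismatch`
#' mismatches of the EBE. Windows containing any non-ACGT character are
#' excluded. The scan uses a pigeonhole seed filter — the EBE is split
#' into `max_mismatch + 1` disjoint blocks and any qualifying window must
#' contain at least one block exactly, located with
#' `Biostrings::matchPattern` — followed by full verification of each
#' candidate window, so the result is exactly equivalent to the
#' brute-force sliding scan ([brute_force_scan()]).
#'
#' @param ebe The EBE (`"ebe"` or string).
#' @param genome Anything accepted by [read_genome()].
#' @param max_mismatch Mismatch budget (default 4, i.e. >= 75% identity
#'   for a 19-mer).
#' @param strands `"both"` (default), `"+"`, or `"-"`.
#' @return Data frame with class `"offtarget_hits"`: `chrom`, `start`
#'   (0-based), `end` (exclusive), `strand`, `site` (binding
#'   orientation), `n_mismatch`, `positions` (comma-joined 1-based EBE
#'   positions), sorted by (chrom, start, strand).
#' @export
scan_genome <- function(ebe, genome, max_mismatch = 4L, strands = "both") {
  ebe <- as_ebe_string(ebe)
  if (max_mismatch < 0L) ot_stop("config", "max_mismatch must be >= 0")
  g <- read_genome(genome)
  strands <- strand_set(strands)
  L <- nchar(ebe)
  parts <- list()
  for (contig in names(g)) {
    cstr <- g[[contig]]
    if (nchar(cstr) < L) next
    cdna <- Biostrings::DNAString(gsub("[^ACGT]", "N", cstr))
    for (s in strands) {
      pattern <- if (s == "+") ebe else revcomp(ebe)
      starts <- pigeonhole_candidates(pattern, cdna, max_mismatch)
      v <- verify_windows(ebe, cstr, starts, s, max_mismatch)
      if (nrow(v) > 0L) {
        parts[[length(parts) + 1L]] <- data.frame(
          chrom = contig, start = v$start - 1L, end = v$start - 1L + L,
          strand = s, site = v$site, n_mismatch = v$n_mismatch,
          positions = v$positions)
      }
    }
  }
  finalize_hits(parts)
}

#' Brute-force sliding-window scan (testing oracle)
#'
#' Position-by-position sliding comparison with no seed filter: for each
#' window start the mismatch count is accumulated one EBE position at a
#' time. Same contract and output as [scan_genome()]; intended for tests
#' and small inputs.
#'
#' @inheritParams scan_genome
#' @return Same as [scan_genome()].
#' @export
brute_force_scan <- function(ebe, genome, max_mismatch = 4L,
                             strands = "both") {
  ebe <- as_ebe_string(ebe)
  if (max_mismatch < 0L) ot_stop("config", "max_mismatch must be >= 0")
  g <- read_genome(genome)
  strands <- strand_set(strands)
  L <- nchar(ebe)
  parts <- list()
  for (contig in names(g)) {
    cstr <- g[[contig]]
    n <- nchar(cstr)
    if (n < L) next
    chars <- strsplit(cstr, "", fixed = TRUE)[[1L]]
    nwin <- n - L + 1L
    for (s in strands) {
      pat <- if (s == "+") ebe else revcomp(ebe)
      pat_chars <- strsplit(pat, "", fixed = TRUE)[[1L]]
      counts <- integer(nwin)
      invalid <- logical(nwin)
      for (i in seq_len(L)) {
        ci <- chars[i:(i + nwin - 1L)]
        counts <- counts + (ci != pat_chars[i])
        invalid <- invalid | !(ci %in% DNA_BASES)
      }
      starts <- which(!invalid & counts <= max_mismatch)
      v <- verify_windows(ebe, cstr, starts, s, max_mismatch)
      if (nrow(v) > 0L) {
        parts[[length(parts) + 1L]] <- data.frame(
          chrom = contig, start = v$start - 1L, end = v$start - 1L + L,
          strand = s, site = v$site, n_mismatch = v$n_mismatch,
          positions = v$positions)
      }
    }
  }
  finalize_hits(parts)
}

# parse a comma-joined positions string back to an integer vector
parse_positions <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE),
         function(p) as.integer(p[nzchar(p)]))
}

#' Mismatch census of a hit set
#'
#' Histogram of distinct sites per mismatch count, 0..`max_mismatch`.
#' Site identity is (chrom, start, strand); duplicates are counted once.
#'
#' @param hits Hit table from [scan_genome()].
#' @param max_mismatch Largest mismatch class to report (default 4).
#' @return Data frame `n_mismatch` (0..max) / `n_sites`, with class
#'   `"mismatch_census"`.
#' @export
census_by_mismatch <- function(hits, max_mismatch = 4L) {
  key <- paste(hits$chrom, hits$start, hits$strand, sep = "\r")
  h <- hits[!duplicated(key), , drop = FALSE]
  counts <- table(factor(h$n_mismatch, levels = 0:max_mismatch))
  out <- data.frame(n_mismatch = 0:max_mismatch,
                    n_sites = as.integer(counts))
  class(out) <- c("mismatch_census", "data.frame")
  out
}

#' Select the n closest off-targets for scoring
#'
#' Filters to hits with at least `min_mismatch` mismatches (the standard
#' design scores sites 3+ mismatches away; anything closer disqualifies
#' the candidate upstream) and returns the `n` closest: mismatch count
#' ascending, ties broken by the total position weight of the mismatches
#' (sum of F_P, descending — the more T0-proximal configuration is the
#' "closer" threat), then genomic coordinate.
#'
#' @param hits Hit table.
#' @param n Number of sites to keep (default 200).
#' @param min_mismatch Minimum mismatch count (default 3).
#' @return Hit table of up to `n` rows; attribute `short_set` is TRUE
#'   when fewer than `n` eligible sites exist.
#' @export
closest_offtargets <- function(hits, n = 200L, min_mismatch = 3L) {
  if (n < 1L) ot_stop("config", "n must be >= 1")
  h <- hits[hits$n_mismatch >= min_mismatch, , drop = FALSE]
  fp_sum <- vapply(parse_positions(h$positions),
                   function(p) sum(position_factor(p)), numeric(1L))
  o <- order(h$n_mismatch, -fp_sum, h$chrom, h$start, h$strand)
  out <- h[head(o, n), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "short_set") <- nrow(out) < n
  out
}

#' Minimum genome distance of a sequence
#'
#' Smallest Hamming distance between `seq` and any same-length genomic
#' window on the requested strands, searched up to `ceiling` mismatches.
#'
#' @param seq The query (EBE or plain string).
#' @param genome Anything accepted by [read_genome()].
#' @param ceiling Largest distance worth distinguishing (default 6);
#'   returns `Inf` when no window is within it.
#' @param strands Strand setting, as in [scan_genome()].
#' @return Integer distance, or `Inf`.
#' @export
min_genome_distance <- function(seq, genome, ceiling = 6L, strands = "both") {
  hits <- scan_genome(seq, genome, max_mismatch = ceiling, strands = strands)
  if (nrow(hits) == 0L) Inf else min(hits$n_mismatch)
}

#' Write hits as BED6
#'
#' 0-based half-open; name = mismatch count; when an `s_off` column is
#' present the BED score is `round(1000 * s_off / max(s_off))`, else 0.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  score <- if (!is.null(hits$s_off) && nrow(hits) > 0L && max(hits$s_off) > 0) {
    as.integer(round(1000 * hits$s_off / max(hits$s_off)))
  } else {
    rep(0L, nrow(hits))
  }
  bed <- data.frame(hits$chrom, hits$start, hits$end, hits$n_mismatch,
                    score, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write hits with full mismatch profiles as TSV
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(hits), collapse = "\t")), con)
  write.table(hits, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a hits TSV written by [write_hits_tsv()]
#'
#' @param path TSV path.
#' @return Hit table (`"offtarget_hits"` data frame).
#' @export
read_hits_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- read.delim(path, skip = 1L, header = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  names(df) <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$n_mismatch <- as.integer(df$n_mismatch)
  if (!is.null(df$s_off)) df$s_off <- as.numeric(df$s_off)
  if (is.null(df$positions)) df$positions <- ""
  df$positions[is.na(df$positions)] <- ""
  class(df) <- c("offtarget_hits", "data.frame")
  df
}
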