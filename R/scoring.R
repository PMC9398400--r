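#' Off-target score S_OFF for one near-match site
#'
#' The off-target score is the sum over mismatch positions of the
#' position factor times the mismatch score, `S_OFF = sum(F_P * S_M)`.
#' A perfect match has an empty sum, S_OFF = 0. Matched positions never
#' contribute. The RVD at a mismatch is the one the design places at that
#' EBE position; the base is the genomic base at the off-target site. T0
#' (position 1) has no RVD, so a non-T there is scored with a fixed
#' configurable preference (default 0: maximally disfavored, S_M = 1 at
#' F_P = 1).
#'
#' @param ebe An `"ebe"` or string.
#' @param site DNA string of the same length, in binding orientation.
#' @param matrix A `"preference_matrix"` (default built-in).
#' @param rvds Optional precomputed RVD array for `ebe`.
#' @param t0_preference Preference used for a T0 mismatch (default 0).
#' @return List with class `"offtarget_score"`: `s_off` and
#'   `contributions` (data.frame position / rvd / base / f_p / s_m).
#' @examples
#' score_offtarget("TCCCCGCATAGCTGAACAT", "TCCCCGCATAGCTGAACAT")$s_off # 0
#' @export
score_offtarget <- function(ebe, site, matrix = default_preference_matrix(),
                            rvds = NULL, t0_preference = 0) {
  prof <- mismatch_profile(ebe, site)
  if (is.null(rvds)) rvds <- ebe_to_rvds(ebe)
  rvds <- as.character(rvds)
  site_chars <- strsplit(toupper(as.character(site)[1L]), "",
                         fixed = TRUE)[[1L]]
  pos <- prof$positions
  if (length(pos) == 0L) {
    contrib <- data.frame(position = integer(0L), rvd = character(0L),
                          base = character(0L), f_p = numeric(0L),
                          s_m = numeric(0L))
    return(structure(list(s_off = 0, contributions = contrib,
                          profile = prof), class = "offtarget_score"))
  }
  f_p <- position_factor(pos)
  s_m <- vapply(pos, function(p) {
    if (p == 1L) {
      (t0_preference - 0.5) * -2
    } else {
      mismatch_score(matrix, rvds[p - 1L], site_chars[p])
    }
  }, numeric(1L))
  contrib <- data.frame(
    position = pos,
    rvd = ifelse(pos == 1L, "T0", rvds[pmax(pos - 1L, 1L)]),
    base = site_chars[pos],
    f_p = f_p,
    s_m = s_m)
  structure(list(s_off = sum(f_p * s_m), contributions = contrib,
                 profile = prof), class = "offtarget_score")
}

#' @export
print.offtarget_score <- function(x, ...) {
  cat(sprintf("<off-target score> S_OFF = %.4f over %d mismatch(es)\n",
              x$s_off, nrow(x$contributions)))
  if (nrow(x$contributions)) print(x$contributions)
  invisible(x)
}

#' Score every hit of a genome scan
#'
#' @param ebe The designed EBE.
#' @param hits Hit table from [scan_genome()] / [closest_offtargets()].
#' @param matrix Preference matrix.
#' @param t0_preference See [score_offtarget()].
#' @return `hits` with an `s_off` column appended.
#' @export
score_hits <- function(ebe, hits, matrix = default_preference_matrix(),
                       t0_preference = 0) {
  rvds <- ebe_to_rvds(ebe)
  hits$s_off <- vapply(hits$site, function(s) {
    score_offtarget(ebe, s, matrix = matrix, rvds = rvds,
                    t0_preference = t0_preference)$s_off
  }, numeric(1L), USE.NAMES = FALSE)
  hits
}

#' Neverword score S_N and score-distribution ratio
#'
#' `S_N` is the arithmetic mean of the off-target scores of the scored
#' set (the 200 closest off-targets in the standard design). The ratio is
#' the mean of the lowest half of the scores divided by the mean of the
#' remaining half (100/100 when 200 sites are scored; floor(n/2) versus
#' the remainder otherwise). The closer the ratio is to 1, the more
#' evenly distributed the off-target risk; values well below 1 flag a
#' dangerous low-score tail.
#'
#' @param scores Numeric vector of S_OFF values (or a list of
#'   `"offtarget_score"` objects).
#' @return List: `s_n`, `ratio` (NA with an `orthotale_warning_ratio`
#'   warning when undefined: n < 2 or an all-zero upper half), `n`.
#' @examples
#' neverword_score(c(rep(1, 100), rep(2, 100))) # s_n 1.5, ratio 0.5
#' @export
neverword_score <- function(scores) {
  if (is.list(scores)) {
    scores <- vapply(scores, function(s) {
      if (inherits(s, "offtarget_score")) s$s_off else as.numeric(s)
    }, numeric(1L))
  }
  if (length(scores) == 0L) ot_stop("empty", "no off-target scores given")
  s_n <- mean(scores)
  n <- length(scores)
  n_low <- n %/% 2L
  sorted <- sort(scores)
  if (n_low == 0L) {
    ot_warn("ratio", "fewer than 2 scores: distribution ratio undefined")
    ratio <- NA_real_
  } else {
    upper_mean <- mean(sorted[(n_low + 1L):n])
    if (upper_mean == 0) {
      ot_warn("ratio", "upper-half mean is zero: ratio undefined")
      ratio <- NA_real_
    } else {
      ratio <- mean(sorted[seq_len(n_low)]) / upper_mean
    }
  }
  list(s_n = s_n, ratio = ratio, n = n)
}

#' Rank candidate EBEs by neverword score and distribution ratio
#'
#' The selection rule is lexicographic: highest S_N first; candidates
#' whose S_N values tie within `tol` are ordered by |ratio - 1|
#' ascending; remaining ties break deterministically by sequence
#' lexicographic order. Rank 1 is the selected design. The alternative
#' `method = "topk"` instead filters to the `k` highest-S_N candidates
#' and orders those by |ratio - 1| alone.
#'
#' @param reports Data frame with columns `sequence`, `s_n`, `ratio`.
#' @param tol Absolute S_N tolerance that counts as a tie (default 1e-9).
#' @param method `"lexicographic"` (default) or `"topk"`.
#' @param k Top-k pool size for `method = "topk"` (default 10).
#' @return `reports` reordered, with a `rank` column.
#' @export
rank_candidates <- function(reports, tol = 1e-9,
                            method = c("lexicographic", "topk"), k = 10L) {
  method <- match.arg(method)
  stopifnot(all(c("sequence", "s_n", "ratio") %in% names(reports)))
  if (nrow(reports) == 0L) {
    reports$rank <- integer(0L)
    return(reports)
  }
  dev <- abs(reports$ratio - 1)
  dev[is.na(dev)] <- Inf
  if (method == "lexicographic") {
    o <- order(-reports$s_n)
    sn_sorted <- reports$s_n[o]
    # chain near-ties: same group while consecutive gaps stay within tol
    grp <- cumsum(c(1L, as.integer(diff(sn_sorted) < -tol |
                                     abs(diff(sn_sorted)) > tol)))
    o2 <- o[order(grp, dev[o], reports$sequence[o])]
  } else {
    pool <- order(-reports$s_n, dev, reports$sequence)[seq_len(min(k, nrow(reports)))]
    rest <- setdiff(order(-reports$s_n, dev, reports$sequence), pool)
    o2 <- c(pool[order(dev[pool], reports$sequence[pool])], rest)
  }
  out <- reports[o2, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write candidate reports as TSV / JSON
#'
#' Flat TSV: one row per candidate ('#'-prefixed header, tab-separated);
#' JSON mirrors the same records.
#'
#' @param reports Ranked report data frame.
#' @param path Output path; extension `.json` selects JSON.
#' @return `path`, invisibly.
#' @export
write_candidate_reports <- function(reports, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(reports, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(names(reports), collapse = "\t")), con)
    write.table(reports, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a candidate-report TSV written by [write_candidate_reports()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_candidate_reports <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- read.delim(path, skip = 1L, header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  df
}
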