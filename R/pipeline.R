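#' End-to-end orthogonal EBE design
#'
#' Runs the full design loop against a genome: generate random T0
#' candidates, drop those with any genomic window closer than
#' `min_genome_distance` mismatches, scan for near-match sites up to
#' `score_ceiling` mismatches, keep the `n_closest` closest sites with
#' at least `min_score_mismatch` mismatches, score them, and rank
#' candidates by neverword score and distribution ratio. Rank 1 is the
#' selected design. Deterministic under a fixed `config$seed`.
#'
#' @param genome Anything accepted by [read_genome()].
#' @param config A [generation_config()].
#' @param matrix Preference matrix (default built-in).
#' @param n_closest Number of closest off-targets to score (default 200).
#' @param min_score_mismatch Minimum mismatch count of scored sites
#'   (default 3).
#' @param score_ceiling Scan budget for the scoring stage (default 6).
#' @param strands Strand setting (default both).
#' @param out Optional output directory: writes `candidates.fa`,
#'   `report.tsv`, `report.json`, and per-candidate hit TSVs.
#' @param verbose Log stage counts with `message()` (default TRUE).
#' @return List with class `"design_run"`: `report` (ranked data frame:
#'   sequence, s_n, ratio, n_scored, short_set, per-mismatch-class
#'   counts, rank), `hits` (named list of scored hit tables),
#'   `selected` (rank-1 `"ebe"`), `config`.
#' @export
run_design <- function(genome, config = generation_config(),
                       matrix = default_preference_matrix(),
                       n_closest = 200L, min_score_mismatch = 3L,
                       score_ceiling = 6L, strands = "both",
                       out = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  g <- read_genome(genome)

  candidates <- generate_candidates(config)
  say("stage generate: %d candidates (seed %s)", length(candidates),
      if (is.null(config$seed)) "none" else config$seed)

  kept <- filter_by_genome_distance(candidates, g,
                                    min_distance = config$min_genome_distance,
                                    strands = strands)
  say("stage filter: %d/%d candidates at genome distance >= %d",
      length(kept), length(candidates), config$min_genome_distance)
  if (length(kept) == 0L) {
    ot_stop("design", "stage filter: no candidate passes the genome-distance filter")
  }

  reports <- list()
  hit_tables <- list()
  for (cand in kept) {
    seq <- as_ebe_string(cand)
    hits <- scan_genome(cand, g, max_mismatch = score_ceiling,
                        strands = strands)
    closest <- closest_offtargets(hits, n = n_closest,
                                  min_mismatch = min_score_mismatch)
    census <- census_by_mismatch(hits, max_mismatch = score_ceiling)
    if (nrow(closest) == 0L) {
      # genome has nothing within the ceiling: flawless but unrankable
      rep <- data.frame(sequence = seq, s_n = NA_real_, ratio = NA_real_,
                        n_scored = 0L, short_set = TRUE)
    } else {
      closest <- score_hits(cand, closest, matrix = matrix)
      nv <- withCallingHandlers(
        neverword_score(closest$s_off),
        orthotale_warning_ratio = function(w) invokeRestart("muffleWarning"))
      rep <- data.frame(sequence = seq, s_n = nv$s_n, ratio = nv$ratio,
                        n_scored = nv$n,
                        short_set = isTRUE(attr(closest, "short_set")))
    }
    for (k in seq_len(score_ceiling)) {
      rep[[sprintf("n_mismatch_%d", k)]] <-
        census$n_sites[census$n_mismatch == k]
    }
    reports[[seq]] <- rep
    hit_tables[[seq]] <- closest
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  scored <- report[!is.na(report$s_n), , drop = FALSE]
  if (nrow(scored) == 0L) {
    ot_stop("design", "stage score: no candidate has scorable off-targets within the ceiling")
  }
  ranked <- rank_candidates(scored)
  say("stage rank: %d candidates ranked; selected %s (S_N=%.4f, ratio=%.4f)",
      nrow(ranked), ranked$sequence[1L], ranked$s_n[1L], ranked$ratio[1L])

  result <- list(report = ranked, hits = hit_tables,
                 selected = validate_ebe(ranked$sequence[1L],
                                         length = config$length),
                 config = config)
  class(result) <- "design_run"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_ebes(lapply(ranked$sequence, validate_ebe,
                      length = config$length),
               file.path(out, "candidates.fa"),
               ids = sprintf("rank%03d", ranked$rank))
    write_candidate_reports(ranked, file.path(out, "report.tsv"))
    write_candidate_reports(ranked, file.path(out, "report.json"))
    for (seq in names(hit_tables)) {
      write_hits_tsv(hit_tables[[seq]],
                     file.path(out, sprintf("hits_%s.tsv", seq)))
    }
  }
  result
}

#' @export
print.design_run <- function(x, ...) {
  cat(sprintf("<design run> %d ranked candidate(s)\n", nrow(x$report)))
  cat(sprintf("selected: %s (S_N = %.4f, ratio = %.4f, n = %d)\n",
              x$report$sequence[1L], x$report$s_n[1L], x$report$ratio[1L],
              x$report$n_scored[1L]))
  invisible(x)
}

#' Off-target audit of one EBE against a genome
#'
#' Produces the mismatch census of all near-match sites, the scored hit
#' table, and — when an annotation is given — the per-category gene
#' table, optionally intersected with externally supplied expressed /
#' up- / downregulated gene-ID lists.
#'
#' @param ebe The EBE to audit.
#' @param genome Anything accepted by [read_genome()].
#' @param annotation Optional GFF3 path or GRanges.
#' @param expressed,up,down Optional character vectors of gene IDs.
#' @param max_mismatch Census budget (default 4).
#' @param strands Strand setting (default both).
#' @param matrix Preference matrix for scoring (default built-in).
#' @param window Gene-association window in bp (default 5000).
#' @param out Optional output directory: writes `census.tsv`,
#'   `hits.bed`, `hits.tsv`, and `categories.tsv` when annotated.
#' @return List with class `"audit_run"`: `census`, `hits` (scored),
#'   `annotations` and `categories` (NULL without annotation).
#' @export
run_audit <- function(ebe, genome, annotation = NULL, expressed = NULL,
                      up = NULL, down = NULL, max_mismatch = 4L,
                      strands = "both", matrix = default_preference_matrix(),
                      window = 5000L, out = NULL) {
  ebe <- if (inherits(ebe, "ebe")) ebe else validate_ebe(ebe, nchar(ebe))
  hits <- scan_genome(ebe, genome, max_mismatch = max_mismatch,
                      strands = strands)
  hits <- score_hits(ebe, hits, matrix = matrix)
  census <- census_by_mismatch(hits, max_mismatch = max_mismatch)
  annotations <- NULL
  categories <- NULL
  if (!is.null(annotation)) {
    genes <- build_gene_models(annotation)
    annotations <- classify_sites(hits, genes, window = window)
    categories <- summarize_categories(annotations, expressed = expressed,
                                       up = up, down = down)
  }
  result <- list(ebe = ebe, census = census, hits = hits,
                 annotations = annotations, categories = categories)
  class(result) <- "audit_run"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.table(census, file.path(out, "census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_hits_bed(hits, file.path(out, "hits.bed"))
    write_hits_tsv(hits, file.path(out, "hits.tsv"))
    if (!is.null(categories)) {
      write_category_table(categories, file.path(out, "categories.tsv"))
    }
  }
  result
}

#' @export
print.audit_run <- function(x, ...) {
  cat(sprintf("<audit> EBE %s\n", as_ebe_string(x$ebe)))
  print(as.data.frame(x$census))
  if (!is.null(x$categories)) {
    cat("gene categories:\n")
    print(x$categories)
  }
  invisible(x)
}
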