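#' Candidate-generation configuration
#'
#' Defaults encode the standard design conditions: 19-mer elements,
#' generation base weights A:C:G:T = 4:5:5:5 (approximately the rice
#' genome GC content, with T0 fixed rather than sampled), a minimum
#' Hamming distance of 3 to every genomic window, and a minimum pairwise
#' Hamming distance of 2 between candidates.
#'
#' @param length Element length (default 19, >= 12).
#' @param n_candidates Number of candidates to draw (default 100).
#' @param base_weights Named positive weights for A, C, G, T
#'   (default `c(A = 4, C = 5, G = 5, T = 5)`).
#' @param min_genome_distance Minimum Hamming distance to the genome
#'   (default 3).
#' @param min_pairwise_distance Minimum pairwise Hamming distance between
#'   accepted candidates (default 2).
#' @param seed Optional RNG seed; fixed seed gives identical output.
#' @param max_attempts_factor Rejection-sampling budget: at most
#'   `max_attempts_factor * n_candidates` draws (default 100).
#' @return List with class `"generation_config"`.
#' @export
generation_config <- function(length = 19L, n_candidates = 100L,
                              base_weights = c(A = 4, C = 5, G = 5, T = 5),
                              min_genome_distance = 3L,
                              min_pairwise_distance = 2L,
                              seed = NULL, max_attempts_factor = 100L) {
  if (length < 12L) ot_stop("config", "element length must be >= 12")
  if (n_candidates < 1L) ot_stop("config", "n_candidates must be >= 1")
  if (!all(DNA_BASES %in% names(base_weights)) ||
      any(base_weights[DNA_BASES] <= 0)) {
    ot_stop("config", "base_weights must be positive and name A, C, G, T")
  }
  if (min_genome_distance < 0L || min_pairwise_distance < 0L) {
    ot_stop("config", "distances must be >= 0")
  }
  structure(list(length = as.integer(length),
                 n_candidates = as.integer(n_candidates),
                 base_weights = base_weights[DNA_BASES],
                 min_genome_distance = as.integer(min_genome_distance),
                 min_pairwise_distance = as.integer(min_pairwise_distance),
                 seed = seed,
                 max_attempts_factor = as.integer(max_attempts_factor)),
            class = "generation_config")
}

# Hamming distance between a char vector and each row of a char matrix
hamming_to_rows <- function(chars, mat) {
  if (nrow(mat) == 0L) return(integer(0L))
  rowSums(mat != matrix(chars, nrow = nrow(mat), ncol = length(chars),
                        byrow = TRUE))
}

#' Generate random candidate EBEs
#'
#' Draws distinct `n_candidates` sequences of the configured length:
#' first base fixed to T0, remaining bases i.i.d. with the configured
#' composition weights. Rejection sampling enforces a pairwise Hamming
#' distance of at least `min_pairwise_distance`; an infeasible request
#' errors after the bounded attempt budget.
#'
#' @param config A [generation_config()].
#' @return List of `"ebe"` objects.
#' @export
generate_candidates <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$length
  n <- config$n_candidates
  accepted <- matrix(character(0L), ncol = L, nrow = 0L)
  seqs <- character(0L)
  attempts <- 0L
  budget <- config$max_attempts_factor * n
  while (length(seqs) < n) {
    attempts <- attempts + 1L
    if (attempts > budget) {
      ot_stop("infeasible", sprintf(
        "could not draw %d candidates at pairwise distance >= %d after %d attempts",
        n, config$min_pairwise_distance, budget))
    }
    chars <- c("T", sample(DNA_BASES, L - 1L, replace = TRUE,
                           prob = config$base_weights))
    if (nrow(accepted) > 0L &&
        any(hamming_to_rows(chars, accepted) <
              max(1L, config$min_pairwise_distance))) {
      next  # duplicates are always rejected, even at distance 0
    }
    accepted <- rbind(accepted, chars)
    seqs <- c(seqs, paste(chars, collapse = ""))
  }
  lapply(seqs, validate_ebe, length = L)
}

#' Filter candidates by minimum distance to a genome
#'
#' Keeps only candidates whose closest genomic window, on either strand,
#' is at least `min_distance` mismatches away (ungapped Hamming over all
#' same-length windows). Order-preserving subset of the input.
#'
#' @param candidates List of EBEs.
#' @param genome Anything accepted by [read_genome()].
#' @param min_distance Minimum Hamming distance (default 3). A candidate
#'   with any window at distance `< min_distance` is dropped.
#' @param strands Strand setting (default both).
#' @return The retained candidates, in input order.
#' @export
filter_by_genome_distance <- function(candidates, genome, min_distance = 3L,
                                      strands = "both") {
  if (min_distance <= 0L) return(candidates)
  g <- read_genome(genome)
  keep <- vapply(candidates, function(cand) {
    nrow(scan_genome(cand, g, max_mismatch = min_distance - 1L,
                     strands = strands)) == 0L
  }, logical(1L))
  candidates[keep]
}
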