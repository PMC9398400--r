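#' Published off-target site tables for dTALE1 and dTALE2
#'
#' The package ships the reported off-target inventories for two
#' designer TALEs characterized in rice (KitaakeX): the genomic 19-mer
#' at each reported off-target locus, with the positions flagged as
#' mismatched against the dTALE's binding element, and the location of
#' the site relative to the associated gene. These serve as in-package
#' test vectors for the mismatch-profiling and scoring machinery.
#'
#' @param which `"dtale1"` or `"dtale2"`.
#' @return Data frame: `gene_id`, `site`, `bold_positions`
#'   (comma-joined 1-based positions flagged as mismatches), `location`.
#' @export
dtale_offtarget_sites <- function(which = c("dtale1", "dtale2")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("%s_offtarget_sites.tsv", which),
                      package = "orthotale", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published genome-wide off-target census for dTALE1 and dTALE2
#'
#' The reported number of KitaakeX genomic sites at 1–4 mismatches from
#' each dTALE's binding element (sites at 5+ mismatches, below 75%
#' identity, were not considered).
#'
#' @return Data frame: `n_mismatch`, `dtale1`, `dtale2`.
#' @export
published_offtarget_census <- function() {
  path <- system.file("extdata", "published_offtarget_census.tsv",
                      package = "orthotale", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published per-category gene counts near dTALE off-target sites
#'
#' The reported number of genes with an off-target site in or within
#' 5 kbp of the gene, per positional category, together with how many of
#' those genes were expressed / consistently up- or downregulated in the
#' transgenic lines.
#'
#' @param which `"dtale1"` or `"dtale2"`.
#' @return Data frame: `category`, `n_genes`, `n_expressed`, `n_up`,
#'   `n_down`.
#' @export
published_gene_categories <- function(which = c("dtale1", "dtale2")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("published_gene_categories_%s.tsv", which),
                      package = "orthotale", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Reconstruct an EBE from annotated off-target sites
#'
#' Each published off-target site shows the genomic 19-mer with its
#' mismatched positions flagged; at every unflagged position the site
#' equals the EBE. Taking the per-position consensus of unflagged bases
#' across sites therefore recovers the EBE. The function reports, per
#' position, whether all unflagged bases agree (`consistent`), which
#' positions had no unflagged base at all (`undetermined`, returned as
#' `N` in the sequence), and uses the majority base (ties broken
#' alphabetically) where sites disagree.
#'
#' @param sites Character vector of equal-length site sequences.
#' @param bold_positions List of integer vectors (or comma-joined
#'   strings) of flagged positions, one per site.
#' @return List: `sequence` (consensus, `N` at undetermined positions),
#'   `undetermined` (positions with no unflagged base),
#'   `conflicts` (positions where unflagged bases disagree).
#' @export
reconstruct_ebe <- function(sites, bold_positions) {
  sites <- toupper(as.character(sites))
  L <- unique(nchar(sites))
  if (length(L) != 1L) ot_stop("length", "sites must share one length")
  if (is.character(bold_positions)) {
    bold_positions <- parse_positions(bold_positions)
  }
  stopifnot(length(bold_positions) == length(sites))
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  consensus <- character(L)
  undetermined <- integer(0L)
  conflicts <- integer(0L)
  for (p in seq_len(L)) {
    unflagged <- vapply(seq_along(sites), function(i)
      !(p %in% bold_positions[[i]]), logical(1L))
    bases <- mat[unflagged, p]
    if (length(bases) == 0L) {
      consensus[p] <- "N"
      undetermined <- c(undetermined, p)
      next
    }
    tab <- sort(table(bases), decreasing = TRUE)
    if (length(tab) > 1L) conflicts <- c(conflicts, p)
    top <- tab[tab == max(tab)]
    consensus[p] <- sort(names(top))[1L]
  }
  list(sequence = paste(consensus, collapse = ""),
       undetermined = undetermined, conflicts = conflicts)
}

#' The dTALE1 binding element reconstructed from its off-target table
#'
#' Convenience wrapper: consensus reconstruction over the five published
#' dTALE1 off-target sites. The reconstruction determines every position
#' (one site carries an unflagged fourth mismatch at position 6; the
#' other four sites agree there and the majority base is used).
#'
#' @return An `"ebe"` object.
#' @export
dtale1_ebe <- function() {
  tab <- dtale_offtarget_sites("dtale1")
  rec <- reconstruct_ebe(tab$site, tab$bold_positions)
  validate_ebe(rec$sequence)
}
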