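#' Build gene models from a GFF3 annotation
#'
#' One model per gene, based on its longest mRNA as the representative
#' transcript. Introns are derived as the gaps between that mRNA's
#' exons; UTRs come from explicit `five_prime_UTR` / `three_prime_UTR`
#' features when present, otherwise as the exonic regions outside the
#' CDS, assigned 5'/3' by strand. Malformed records (missing parentage,
#' CDS outside the mRNA span) generate a warning and skip that gene.
#'
#' @param annotation GFF3 path or a `GRanges` as returned by
#'   `rtracklayer::import`.
#' @return List of gene models with class `"gene_model_set"`; each model
#'   is a list with `gene_id`, `chrom`, `strand`, `start`, `end`, and
#'   `IRanges` components `exons`, `cds`, `utr5`, `utr3`, `introns`.
#' @export
build_gene_models <- function(annotation) {
  gr <- if (methods::is(annotation, "GRanges")) {
    annotation
  } else {
    if (!file.exists(annotation)) {
      ot_stop("io", sprintf("annotation not found: %s", annotation))
    }
    rtracklayer::import(annotation, format = "gff3")
  }
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }, character(1L))

  genes <- gr[type == "gene"]
  models <- list()
  for (i in seq_along(genes)) {
    gene <- genes[i]
    gid <- as.character(gene$ID)
    model <- tryCatch(
      build_one_gene_model(gene, gid, gr, type, parents),
      error = function(e) {
        ot_warn("gff", sprintf("skipping gene %s: %s", gid,
                               conditionMessage(e)))
        NULL
      })
    if (!is.null(model)) models[[gid]] <- model
  }
  structure(models, class = "gene_model_set")
}

build_one_gene_model <- function(gene, gid, gr, type, parents) {
  chrom <- as.character(GenomicRanges::seqnames(gene))
  strand <- as.character(BiocGenerics::strand(gene))
  if (!strand %in% c("+", "-")) strand <- "+"
  gspan <- IRanges::IRanges(BiocGenerics::start(gene), BiocGenerics::end(gene))

  tx_idx <- which(type %in% c("mRNA", "transcript") & parents == gid)
  if (length(tx_idx) == 0L) stop("no mRNA child")
  # representative transcript = longest mRNA; deterministic tie-break by ID
  widths <- BiocGenerics::width(gr[tx_idx])
  tids <- as.character(gr$ID[tx_idx])
  best <- tx_idx[order(-widths, tids)][1L]
  tid <- as.character(gr$ID[best])

  child <- function(t) {
    idx <- which(type == t & parents == tid)
    IRanges::reduce(IRanges::IRanges(BiocGenerics::start(gr[idx]),
                                     BiocGenerics::end(gr[idx])))
  }
  exons <- child("exon")
  cds <- child("CDS")
  if (length(exons) == 0L) exons <- if (length(cds)) cds else gspan
  if (length(cds) > 0L &&
      (min(BiocGenerics::start(cds)) < BiocGenerics::start(gene) ||
       max(BiocGenerics::end(cds)) > BiocGenerics::end(gene))) {
    stop("CDS outside gene span")
  }
  tx_span <- IRanges::IRanges(min(BiocGenerics::start(exons)),
                              max(BiocGenerics::end(exons)))
  introns <- BiocGenerics::setdiff(tx_span, exons)

  utr5 <- child("five_prime_UTR")
  utr3 <- child("three_prime_UTR")
  if (length(utr5) == 0L && length(utr3) == 0L && length(cds) > 0L) {
    noncds <- BiocGenerics::setdiff(exons, cds)
    cds_start <- min(BiocGenerics::start(cds))
    cds_end <- max(BiocGenerics::end(cds))
    left <- noncds[BiocGenerics::end(noncds) < cds_start]
    right <- noncds[BiocGenerics::start(noncds) > cds_end]
    if (strand == "+") { utr5 <- left; utr3 <- right }
    else { utr5 <- right; utr3 <- left }
  }
  list(gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
       start = BiocGenerics::start(gene), end = BiocGenerics::end(gene),
       exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
       introns = introns)
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene model set> %d gene(s)\n", length(x)))
  invisible(x)
}

# categories in precedence order (highest first)
CATEGORY_PRECEDENCE <- c("CDS", "5'UTR", "3'UTR", "intron",
                         "upstream", "downstream", "intergenic")

overlaps_interval <- function(ranges, lo, hi) {
  length(ranges) > 0L &&
    any(BiocGenerics::start(ranges) <= hi & BiocGenerics::end(ranges) >= lo)
}

#' Classify an off-target site relative to gene models
#'
#' For each gene whose span extended by `window` overlaps the site, one
#' annotation is produced. Genic overlap uses feature precedence
#' CDS > 5'UTR > 3'UTR > intron with distance 0. A non-overlapping site
#' is labeled upstream/downstream of a gene only when that gene is the
#' *nearest* gene to the site midpoint and the midpoint lies within
#' `window` bp of the gene boundary on the corresponding strand-aware
#' side; associations with farther genes inside the window are labeled
#' intergenic. (The upstream/intergenic boundary is an interpretation:
#' both lie within the 5 kbp window, and only the nearest-gene reading
#' makes the labels deterministic.) A site with no gene inside the
#' window yields one `unassociated` record.
#'
#' @param site One hit row (from [scan_genome()]) or a list/data.frame
#'   with `chrom`, `start` (0-based), `end`.
#' @param genes A `"gene_model_set"`.
#' @param window Association window in bp (default 5000).
#' @return Data frame: `chrom`, `start`, `end`, `gene_id`, `category`,
#'   `distance_bp`.
#' @export
classify_site <- function(site, genes, window = 5000L) {
  chrom <- as.character(site$chrom)
  start1 <- as.integer(site$start) + 1L  # to 1-based
  end1 <- as.integer(site$end)
  mid <- (start1 + end1) %/% 2L

  cand <- Filter(function(g) {
    g$chrom == chrom && g$start - window <= end1 && g$end + window >= start1
  }, unclass(genes))
  if (length(cand) == 0L) {
    return(data.frame(chrom = chrom, start = start1 - 1L, end = end1,
                      gene_id = NA_character_, category = "unassociated",
                      distance_bp = NA_integer_))
  }
  # midpoint distance to each candidate gene span (0 when inside)
  dist_mid <- vapply(cand, function(g) {
    max(0L, g$start - mid, mid - g$end)
  }, integer(1L))
  nearest <- names(cand)[which.min(dist_mid)]

  rows <- lapply(seq_along(cand), function(i) {
    g <- cand[[i]]
    overlap <- g$start <= end1 && g$end >= start1
    if (overlap) {
      category <- "intron"  # residual genic category
      for (feat in list(c("cds", "CDS"), c("utr5", "5'UTR"),
                        c("utr3", "3'UTR"), c("introns", "intron"))) {
        if (overlaps_interval(g[[feat[1L]]], start1, end1)) {
          category <- feat[2L]
          break
        }
      }
      dist <- 0L
    } else {
      dist <- dist_mid[i]
      side5 <- if (g$strand == "+") mid < g$start else mid > g$end
      if (g$gene_id == nearest && dist <= window) {
        category <- if (side5) "upstream" else "downstream"
      } else {
        category <- "intergenic"
      }
    }
    data.frame(chrom = chrom, start = start1 - 1L, end = end1,
               gene_id = g$gene_id, category = category,
               distance_bp = dist)
  })
  do.call(rbind, rows)
}

#' Classify every hit in a table
#'
#' @param hits Hit table from [scan_genome()].
#' @param genes A `"gene_model_set"`.
#' @param window Association window (default 5000).
#' @return Row-bound annotations of [classify_site()] with a `site_id`
#'   column (`chrom:start:strand`).
#' @export
classify_sites <- function(hits, genes, window = 5000L) {
  if (nrow(hits) == 0L) {
    return(data.frame(site_id = character(0L), chrom = character(0L),
                      start = integer(0L), end = integer(0L),
                      gene_id = character(0L), category = character(0L),
                      distance_bp = integer(0L)))
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    ann <- classify_site(hits[i, ], genes, window = window)
    cbind(site_id = paste(hits$chrom[i], hits$start[i], hits$strand[i],
                          sep = ":"), ann)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize site annotations into a per-category gene table
#'
#' Counts distinct genes per category. In mode `"first"` (default) a
#' gene associated with several sites is counted once, under its
#' highest-precedence category (CDS > 5'UTR > 3'UTR > intron > upstream
#' > downstream > intergenic); mode `"all"` counts it in every category
#' it occurs in. Optional gene-ID sets add `n_expressed` / `n_up` /
#' `n_down` columns by intersection.
#'
#' @param annotations Output of [classify_sites()].
#' @param expressed,up,down Optional character vectors of gene IDs.
#' @param mode `"first"` or `"all"`.
#' @return Data frame `category` / `n_genes` (+ optional set columns),
#'   one row per non-empty category, in precedence order.
#' @export
summarize_categories <- function(annotations, expressed = NULL, up = NULL,
                                 down = NULL, mode = c("first", "all")) {
  mode <- match.arg(mode)
  ann <- annotations[!is.na(annotations$gene_id) &
                       annotations$category != "unassociated", , drop = FALSE]
  if (nrow(ann) == 0L) {
    out <- data.frame(category = character(0L), n_genes = integer(0L))
    return(out)
  }
  prec <- match(ann$category, CATEGORY_PRECEDENCE)
  if (mode == "first") {
    o <- order(ann$gene_id, prec)
    ann <- ann[o, , drop = FALSE]
    ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  } else {
    ann <- ann[!duplicated(paste(ann$gene_id, ann$category)), , drop = FALSE]
  }
  cats <- CATEGORY_PRECEDENCE[CATEGORY_PRECEDENCE %in% ann$category]
  count_in <- function(set) {
    vapply(cats, function(ct) {
      g <- unique(ann$gene_id[ann$category == ct])
      if (is.null(set)) length(g) else length(intersect(g, set))
    }, integer(1L))
  }
  out <- data.frame(category = cats, n_genes = count_in(NULL))
  if (!is.null(expressed)) out$n_expressed <- count_in(expressed)
  if (!is.null(up)) out$n_up <- count_in(up)
  if (!is.null(down)) out$n_down <- count_in(down)
  rownames(out) <- NULL
  out
}

#' Write / read a category summary table
#'
#' TSV mirroring the per-category layout ('#'-prefixed header).
#'
#' @param table Output of [summarize_categories()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(table), collapse = "\t")), con)
  write.table(table, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_category_table
#' @export
read_category_table <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- read.delim(path, skip = 1L, header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  df
}
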