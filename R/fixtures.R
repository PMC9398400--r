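#' Fixture specification for synthetic genomes
#'
#' Describes a synthetic genome with planted near-match sites and,
#' optionally, gene models: the ground truth against which the scanning
#' and annotation machinery is tested without any real-genome download.
#'
#' @param genome_length Total length in bp (split evenly over contigs).
#' @param n_contigs Number of contigs (default 1).
#' @param gc Background GC fraction (default 0.435, rice-like).
#' @param plants List of plant requests; each is a list with `ebe`
#'   (string), `n_mismatch` (>= 0), and optionally `positions` (integer
#'   vector of that many 1-based positions, or `"random"`), `strand`
#'   (`"+"`, `"-"`, or `"random"`), `contig` and `start` (1-based locus,
#'   or `"random"`).
#' @param n_genes Number of synthetic gene models (default 0).
#' @param seed RNG seed; a fixed seed reproduces the fixture exactly.
#' @param max_retries Bound on locus redraws when plants would overlap
#'   or the background creates an unintended closer match (default 20).
#' @return List with class `"fixture_spec"`.
#' @export
fixture_spec <- function(genome_length = 10000L, n_contigs = 1L,
                         gc = 0.435, plants = list(), n_genes = 0L,
                         seed = 1L, max_retries = 20L) {
  if (genome_length < 1L || n_contigs < 1L) {
    ot_stop("config", "genome_length and n_contigs must be positive")
  }
  if (gc <= 0 || gc >= 1) ot_stop("config", "gc must be in (0, 1)")
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs), gc = gc,
                 plants = plants, n_genes = as.integer(n_genes),
                 seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "fixture_spec")
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate exactly `positions` of `seq` to a different base each
mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted near-match sites
#'
#' Background sequence is i.i.d. at the requested GC; each plant mutates
#' exactly the requested number of EBE positions (at the requested or
#' randomly drawn positions) and writes the variant — reverse-complemented
#' for minus-strand plants — at a non-overlapping locus. After planting,
#' the genome is checked with [brute_force_scan()]: if the background
#' happens to contain an unintended window at or below the largest
#' planted mismatch count, the fixture is redrawn (bounded retries), so
#' the truth table is the complete hit inventory at that budget.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory; when given, writes
#'   `genome.fa` and `truth.tsv` there.
#' @return List: `genome` (named character vector), `truth` (data frame
#'   chrom / start 0-based / strand / ebe / n_mismatch / positions /
#'   site), and `paths` when `dir` was given.
#' @export
make_synthetic_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  per_contig <- spec$genome_length %/% spec$n_contigs
  contig_names <- sprintf("ctg%02d", seq_len(spec$n_contigs))

  for (attempt in seq_len(spec$max_retries)) {
    genome <- setNames(
      vapply(seq_len(spec$n_contigs), function(i)
        random_dna(per_contig, spec$gc), character(1L)),
      contig_names)
    truth <- plant_sites(genome, spec)
    if (is.null(truth)) next  # overlap infeasible this draw
    genome <- attr(truth, "genome")
    if (truth_is_clean(genome, truth)) {
      out <- list(genome = genome, truth = truth)
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        fa <- file.path(dir, "genome.fa")
        Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
        tt <- file.path(dir, "truth.tsv")
        write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
        out$paths <- c(genome = fa, truth = tt)
      }
      return(out)
    }
  }
  ot_stop("fixture", sprintf(
    "could not build a clean fixture in %d attempts (genome too short or plants too dense?)",
    spec$max_retries))
}

# place every plant; returns truth df with the updated genome attached,
# or NULL when non-overlapping placement failed for this background
plant_sites <- function(genome, spec) {
  rows <- list()
  occupied <- list()  # per contig: matrix of (start,end) 1-based
  for (k in seq_along(spec$plants)) {
    p <- spec$plants[[k]]
    ebe <- as_ebe_string(p$ebe)
    L <- nchar(ebe)
    n_mm <- as.integer(p$n_mismatch)
    positions <- p$positions
    if (is.null(positions) || identical(positions, "random")) {
      positions <- sort(sample(seq_len(L), n_mm))
    } else {
      positions <- sort(as.integer(positions))
      if (length(positions) != n_mm || any(positions < 1L | positions > L)) {
        ot_stop("fixture", sprintf("plant %d: invalid mismatch positions", k))
      }
    }
    strand <- p$strand
    if (is.null(strand) || identical(strand, "random")) {
      strand <- sample(c("+", "-"), 1L)
    }
    contig <- p$contig
    if (is.null(contig) || identical(contig, "random")) {
      contig <- sample(names(genome), 1L)
    }
    clen <- nchar(genome[[contig]])
    if (clen < L) ot_stop("fixture", "genome too short for plant")

    site <- mutate_at(ebe, positions)           # binding orientation
    insert <- if (strand == "+") site else revcomp(site)

    placed <- FALSE
    for (try in seq_len(50L)) {
      start1 <- if (!is.null(p$start) && !identical(p$start, "random")) {
        as.integer(p$start)
      } else {
        sample.int(clen - L + 1L, 1L)
      }
      occ <- occupied[[contig]]
      clash <- !is.null(occ) &&
        any(start1 <= occ[, 2L] & start1 + L - 1L >= occ[, 1L])
      if (!clash) {
        substr(genome[[contig]], start1, start1 + L - 1L) <- insert
        occupied[[contig]] <- rbind(occ, c(start1, start1 + L - 1L))
        rows[[k]] <- data.frame(
          chrom = contig, start = start1 - 1L, strand = strand, ebe = ebe,
          n_mismatch = n_mm, positions = paste(positions, collapse = ","),
          site = site)
        placed <- TRUE
        break
      }
      if (!is.null(p$start) && !identical(p$start, "random")) {
        ot_stop("fixture", sprintf("plant %d: requested locus overlaps", k))
      }
    }
    if (!placed) return(NULL)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0L), start = integer(0L),
               strand = character(0L), ebe = character(0L),
               n_mismatch = integer(0L), positions = character(0L),
               site = character(0L))
  attr(truth, "genome") <- genome
  truth
}

# TRUE when the oracle finds exactly the planted sites (per EBE) at the
# largest planted budget — no unintended background near-matches
truth_is_clean <- function(genome, truth) {
  if (nrow(truth) == 0L) return(TRUE)
  for (ebe in unique(truth$ebe)) {
    t_e <- truth[truth$ebe == ebe, , drop = FALSE]
    budget <- max(t_e$n_mismatch)
    hits <- brute_force_scan(ebe, genome, max_mismatch = budget,
                             strands = "both")
    want <- sort(paste(t_e$chrom, t_e$start, t_e$strand, t_e$n_mismatch))
    got <- sort(paste(hits$chrom, hits$start, hits$strand, hits$n_mismatch))
    if (!identical(want, got)) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic GFF3 annotation for a fixture genome
#'
#' Writes `n_genes` non-overlapping gene/mRNA/exon/CDS (+UTR) models
#' with random strands and 1–4 exons per gene; the output is valid GFF3
#' that round-trips through [build_gene_models()].
#'
#' @param spec A [fixture_spec()] (its `n_genes` and `seed` are used).
#' @param genome Named character vector (from [make_synthetic_genome()]).
#' @param path Output GFF3 path.
#' @return List: `path`, and `truth` — a data frame of the generated
#'   feature intervals (gene_id, chrom, strand, type, start, end,
#'   1-based inclusive).
#' @export
make_synthetic_annotation <- function(spec, genome, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  lines <- "##gff-version 3"
  truth <- list()
  if (spec$n_genes > 0L) {
    slots <- allocate_gene_slots(genome, spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      s <- slots[[i]]
      gid <- sprintf("gene%03d", i)
      strand <- sample(c("+", "-"), 1L)
      feats <- random_gene_features(s$start, s$end, strand)
      lines <- c(lines, gene_gff_lines(gid, s$chrom, strand, feats))
      truth[[i]] <- cbind(gene_id = gid, chrom = s$chrom, strand = strand,
                          feats)
    }
  }
  writeLines(lines, path)
  list(path = path,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(gene_id = character(0L), chrom = character(0L),
                    strand = character(0L), type = character(0L),
                    start = integer(0L), end = integer(0L)))
}

allocate_gene_slots <- function(genome, n_genes) {
  # spread genes over contigs, evenly spaced with margins
  lens <- nchar(genome)
  total <- sum(lens)
  slots <- list()
  per <- pmax(1L, round(n_genes * lens / total))
  while (sum(per) > n_genes) per[which.max(per)] <- per[which.max(per)] - 1L
  while (sum(per) < n_genes) per[which.min(per)] <- per[which.min(per)] + 1L
  for (ci in seq_along(genome)) {
    k <- per[ci]
    if (k == 0L) next
    span <- lens[ci] %/% k
    if (span < 400L) ot_stop("fixture", "insufficient space for n_genes")
    for (j in seq_len(k)) {
      lo <- (j - 1L) * span + 1L
      hi <- j * span
      glen <- min(hi - lo - 100L, sample(600:2400, 1L))
      gstart <- lo + sample.int(max(1L, hi - lo - glen - 50L), 1L)
      slots[[length(slots) + 1L]] <-
        list(chrom = names(genome)[ci], start = gstart,
             end = gstart + glen - 1L)
    }
  }
  slots
}

random_gene_features <- function(gstart, gend, strand) {
  n_exons <- sample(1:4, 1L)
  len <- gend - gstart + 1L
  # exon boundaries: split the span into alternating exon/intron chunks
  if (n_exons == 1L) {
    exons <- data.frame(start = gstart, end = gend)
  } else {
    cuts <- sort(sample(seq(gstart + 50L, gend - 50L, by = 10L),
                        2L * (n_exons - 1L)))
    starts <- c(gstart, cuts[seq(2L, length(cuts), by = 2L)] + 1L)
    ends <- c(cuts[seq(1L, length(cuts), by = 2L)], gend)
    exons <- data.frame(start = starts, end = ends)
  }
  # CDS: trim UTR margins off the first and last exonic 60 bp
  utr_left <- min(60L, exons$end[1L] - exons$start[1L])
  utr_right <- min(60L, exons$end[nrow(exons)] - exons$start[nrow(exons)])
  cds_lo <- exons$start[1L] + utr_left
  cds_hi <- exons$end[nrow(exons)] - utr_right
  cds <- exons
  cds$start <- pmax(cds$start, cds_lo)
  cds$end <- pmin(cds$end, cds_hi)
  cds <- cds[cds$start <= cds$end, , drop = FALSE]
  rbind(
    data.frame(type = "gene", start = gstart, end = gend),
    data.frame(type = "mRNA", start = gstart, end = gend),
    data.frame(type = "exon", start = exons$start, end = exons$end),
    data.frame(type = "CDS", start = cds$start, end = cds$end))
}

gene_gff_lines <- function(gid, chrom, strand, feats) {
  tid <- paste0(gid, ".1")
  mk <- function(type, start, end, attrs) {
    paste(chrom, "orthotale", type, start, end, ".", strand,
          if (type == "CDS") "0" else ".", attrs, sep = "\t")
  }
  out <- character(0L)
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    attrs <- switch(as.character(f$type),
      gene = sprintf("ID=%s", gid),
      mRNA = sprintf("ID=%s;Parent=%s", tid, gid),
      exon = sprintf("ID=%s.exon%d;Parent=%s", tid, i, tid),
      CDS = sprintf("ID=%s.cds;Parent=%s", tid, tid))
    out <- c(out, mk(as.character(f$type), f$start, f$end, attrs))
  }
  out
}
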