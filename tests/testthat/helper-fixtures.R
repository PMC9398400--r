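# shared helpers for the orthotale test suite

DTALE1_EBE <- "TCCCCGCATAGCTGAACAT"

# a random T0-constrained element, plain string
random_ebe <- function(L = 19L) {
  paste(c("T", sample(c("A", "C", "G", "T"), L - 1L, replace = TRUE)),
        collapse = "")
}

# uniform random background sequence as a plain string
random_genome_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent per-position mismatch count (the simplest possible oracle)
naive_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

# independent off-target score: explicit loop over positions, no reuse of
# score_offtarget internals
naive_s_off <- function(ebe, site, matrix, t0_preference = 0) {
  ce <- strsplit(ebe, "")[[1]]
  cs <- strsplit(site, "")[[1]]
  rvds <- unname(RVD_CODE[ce[-1]])
  total <- 0
  for (p in seq_along(ce)) {
    if (ce[p] == cs[p]) next
    pref <- if (p == 1L) t0_preference else matrix[rvds[p - 1L], cs[p]]
    total <- total + (1 / sqrt(p)) * ((pref - 0.5) * -2)
  }
  total
}

# hit-set fingerprint for set comparisons
hit_key <- function(hits) {
  sort(paste(hits$chrom, hits$start, hits$strand, hits$n_mismatch,
             hits$positions, sep = "|"))
}

# toy two-gene GFF3 used by the gene-context tests; coordinates shifted
# by `offset` to check translation invariance
write_toy_gff3 <- function(path, offset = 0L, strand2 = "-") {
  o <- function(x) x + offset
  lines <- c(
    "##gff-version 3",
    sprintf("chr1\ttest\tgene\t%d\t%d\t.\t+\t.\tID=geneA", o(1001), o(3000)),
    sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t+\t.\tID=geneA.1;Parent=geneA",
            o(1001), o(3000)),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t+\t.\tID=geneA.1.e1;Parent=geneA.1",
            o(1001), o(1500)),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t+\t.\tID=geneA.1.e2;Parent=geneA.1",
            o(2001), o(3000)),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=geneA.1.c;Parent=geneA.1",
            o(1201), o(1500)),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=geneA.1.c;Parent=geneA.1",
            o(2001), o(2800)),
    sprintf("chr1\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=geneB",
            o(20001), o(22000), strand2),
    sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=geneB.1;Parent=geneB",
            o(20001), o(22000), strand2),
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tID=geneB.1.e1;Parent=geneB.1",
            o(20001), o(22000), strand2),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=geneB.1.c;Parent=geneB.1",
            o(20001), o(22000), strand2))
  writeLines(lines, path)
  path
}

# site row in the shape classify_site() expects (0-based start)
site_row <- function(chrom, start0, len = 19L) {
  data.frame(chrom = chrom, start = start0, end = start0 + len,
             strand = "+")
}
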