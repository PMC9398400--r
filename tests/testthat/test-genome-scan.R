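test_that("planted sites are recovered at their planted distance and strand", {
  spec <- fixture_spec(
    genome_length = 10000, seed = 42,
    plants = list(list(ebe = DTALE1_EBE, n_mismatch = 0, strand = "+"),
                  list(ebe = DTALE1_EBE, n_mismatch = 2, strand = "-"),
                  list(ebe = DTALE1_EBE, n_mismatch = 3, strand = "+"),
                  list(ebe = DTALE1_EBE, n_mismatch = 4, strand = "-")))
  fx <- make_synthetic_genome(spec)
  hits <- scan_genome(DTALE1_EBE, fx$genome, max_mismatch = 4)
  expect_identical(nrow(hits), nrow(fx$truth))
  key_h <- sort(paste(hits$chrom, hits$start, hits$strand, hits$n_mismatch))
  key_t <- sort(paste(fx$truth$chrom, fx$truth$start, fx$truth$strand,
                      fx$truth$n_mismatch))
  expect_identical(key_h, key_t)
  # planted mismatch positions are reported exactly
  m <- merge(as.data.frame(hits), fx$truth,
             by = c("chrom", "start", "strand"))
  expect_identical(m$positions.x, m$positions.y)
})

test_that("a tighter budget excludes more distant sites", {
  spec <- fixture_spec(
    genome_length = 8000, seed = 9,
    plants = list(list(ebe = DTALE1_EBE, n_mismatch = 2)))
  fx <- make_synthetic_genome(spec)
  expect_identical(nrow(scan_genome(DTALE1_EBE, fx$genome,
                                    max_mismatch = 1)), 0L)
  expect_identical(nrow(scan_genome(DTALE1_EBE, fx$genome,
                                    max_mismatch = 2)), 1L)
})

test_that("seeded scan equals the brute-force oracle on random genomes", {
  set.seed(77)
  for (rep in 1:12) {
    ebe <- random_ebe()
    n_plants <- sample(1:3, 1)
    plants <- lapply(seq_len(n_plants), function(i)
      list(ebe = ebe, n_mismatch = sample(0:4, 1)))
    fx <- make_synthetic_genome(
      fixture_spec(genome_length = 5000, seed = sample.int(1e6, 1),
                   plants = plants))
    for (mm in c(0L, 2L, 5L)) {
      for (st in c("both", "+")) {
        s <- scan_genome(ebe, fx$genome, max_mismatch = mm, strands = st)
        b <- brute_force_scan(ebe, fx$genome, max_mismatch = mm,
                              strands = st)
        expect_identical(hit_key(s), hit_key(b))
      }
    }
  }
})

test_that("windows containing N never match and degenerate inputs are empty", {
  genome <- c(ctg = paste0(random_genome_str(100), DTALE1_EBE,
                           random_genome_str(100)))
  # poison one base of the planted window with N
  g2 <- genome
  substr(g2[["ctg"]], 105, 105) <- "N"
  expect_identical(nrow(scan_genome(DTALE1_EBE, genome, max_mismatch = 0)), 1L)
  expect_identical(nrow(scan_genome(DTALE1_EBE, g2, max_mismatch = 4)), 0L)
  expect_identical(nrow(brute_force_scan(DTALE1_EBE, g2, max_mismatch = 4)), 0L)
  # contig shorter than the element yields no hits, not an error
  short <- c(tiny = "ACGTACGT")
  expect_identical(nrow(scan_genome(DTALE1_EBE, short, max_mismatch = 4)), 0L)
  expect_identical(nrow(brute_force_scan(DTALE1_EBE, short,
                                         max_mismatch = 4)), 0L)
  expect_error(scan_genome(DTALE1_EBE, "/no/such/genome.fa"),
               class = "orthotale_error_io")
})

test_that("reverse-complementing the genome mirrors the hit set", {
  spec <- fixture_spec(
    genome_length = 4000, seed = 13,
    plants = list(list(ebe = DTALE1_EBE, n_mismatch = 1, strand = "+"),
                  list(ebe = DTALE1_EBE, n_mismatch = 3, strand = "-")))
  fx <- make_synthetic_genome(spec)
  g <- fx$genome
  g_rc <- vapply(g, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  h <- scan_genome(DTALE1_EBE, g, max_mismatch = 4)
  h_rc <- scan_genome(DTALE1_EBE, g_rc, max_mismatch = 4)
  L <- nchar(DTALE1_EBE)
  n <- nchar(g[[1]])
  # map rc coordinates back: start' = n - end, strand flipped
  mapped <- data.frame(start = n - h_rc$end, strand = ifelse(
    h_rc$strand == "+", "-", "+"), n_mismatch = h_rc$n_mismatch,
    site = h_rc$site)
  expect_identical(
    sort(paste(mapped$start, mapped$strand, mapped$n_mismatch, mapped$site)),
    sort(paste(h$start, h$strand, h$n_mismatch, h$site)))
})

test_that("the census deduplicates sites and is cumulative in the budget", {
  spec <- fixture_spec(
    genome_length = 9000, seed = 21,
    plants = list(list(ebe = DTALE1_EBE, n_mismatch = 0),
                  list(ebe = DTALE1_EBE, n_mismatch = 2),
                  list(ebe = DTALE1_EBE, n_mismatch = 2),
                  list(ebe = DTALE1_EBE, n_mismatch = 3)))
  fx <- make_synthetic_genome(spec)
  hits <- scan_genome(DTALE1_EBE, fx$genome, max_mismatch = 4)
  cen <- census_by_mismatch(hits, max_mismatch = 4)
  expect_identical(cen$n_sites[cen$n_mismatch == 0], 1L)
  expect_identical(cen$n_sites[cen$n_mismatch == 2], 2L)
  expect_identical(cen$n_sites[cen$n_mismatch == 3], 1L)
  # duplicated rows count once
  cen2 <- census_by_mismatch(rbind(hits, hits), max_mismatch = 4)
  expect_identical(cen2$n_sites, cen$n_sites)
  # empty hit list gives an all-zero census
  empty <- census_by_mismatch(hits[0, ], max_mismatch = 4)
  expect_identical(empty$n_sites, rep(0L, 5L))
  # cumulative counts grow with the budget
  totals <- vapply(0:4, function(k)
    sum(census_by_mismatch(scan_genome(DTALE1_EBE, fx$genome,
                                       max_mismatch = k),
                           max_mismatch = k)$n_sites), integer(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("closest_offtargets sorts by distance then T0-proximity weight", {
  mk <- function(start, nm, pos) {
    data.frame(chrom = "c", start = start, end = start + 19, strand = "+",
               site = "x", n_mismatch = nm, positions = pos)
  }
  hits <- rbind(mk(1, 4, "1,2,3,4"), mk(2, 3, "17,18,19"),
                mk(3, 3, "2,3,4"), mk(4, 2, "1,2"))
  sel <- closest_offtargets(hits, n = 3, min_mismatch = 3)
  # count ascending; among count-3 the more T0-proximal set first
  expect_identical(sel$start, c(3, 2, 1))
  expect_false(attr(sel, "short_set"))
  sel2 <- closest_offtargets(hits, n = 200, min_mismatch = 3)
  expect_identical(nrow(sel2), 3L)
  expect_true(attr(sel2, "short_set"))
  sel3 <- closest_offtargets(hits, n = 5, min_mismatch = 5)
  expect_identical(nrow(sel3), 0L)
  expect_true(attr(sel3, "short_set"))
})

test_that("hits round-trip through the BED and TSV writers", {
  spec <- fixture_spec(genome_length = 3000, seed = 3,
                       plants = list(list(ebe = DTALE1_EBE, n_mismatch = 2)))
  fx <- make_synthetic_genome(spec)
  hits <- score_hits(DTALE1_EBE,
                     scan_genome(DTALE1_EBE, fx$genome, max_mismatch = 4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, tsv)
  back <- read_hits_tsv(tsv)
  expect_identical(back$start, hits$start)
  expect_identical(back$positions, hits$positions)
  expect_equal(back$s_off, hits$s_off)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, bed)
  fields <- read.delim(bed, header = FALSE)
  expect_identical(nrow(fields), nrow(hits))
  expect_identical(fields$V2, hits$start)  # 0-based starts
})
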