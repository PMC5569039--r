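# Promoter extraction, motif scanning, target tiers, gene structure.

toy_gff <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(seqid = r$seqid, source = "toy", type = r$type,
               start = r$start, end = r$end, score = ".", strand = r$strand,
               phase = ".", ID = r$ID,
               Parent = if (is.null(r$Parent)) NA_character_ else r$Parent,
               line = NA_integer_, stringsAsFactors = FALSE)
  }))
}

test_that("plus-strand promoter coordinates are exact", {
  set.seed(41)
  contig <- random_dna(2000)
  ann <- toy_gff(list(
    list(seqid = "c1", type = "gene", start = 1501, end = 1800, strand = "+",
         ID = "g1"),
    list(seqid = "c1", type = "CDS", start = 1501, end = 1800, strand = "+",
         ID = "g1.c", Parent = "g1")))
  r <- extract_promoters(c(c1 = contig), ann, 1000)
  expect_equal(r$length, 1000)
  expect_false(r$truncated)
  expect_equal(r$sequence, substr(contig, 501, 1500))
  expect_equal(c(r$g_start, r$g_end), c(500, 1500))
})

test_that("minus-strand promoters reverse-complement the downstream window", {
  # hand-built 60-nt toy contig: gene occupies [11, 30] on the minus strand,
  # so its promoter is the reverse complement of the 20 nt at [31, 50]
  set.seed(42)
  contig <- random_dna(60)
  ann <- toy_gff(list(
    list(seqid = "c1", type = "gene", start = 11, end = 30, strand = "-",
         ID = "g1"),
    list(seqid = "c1", type = "CDS", start = 11, end = 30, strand = "-",
         ID = "g1.c", Parent = "g1")))
  r <- extract_promoters(c(c1 = contig), ann, 20)
  expect_equal(r$sequence, revcomp(substr(contig, 31, 50)))
  expect_false(r$truncated)
  # wider window than the contig allows: truncated
  r2 <- extract_promoters(c(c1 = contig), ann, 50)
  expect_equal(r2$length, 30)
  expect_true(r2$truncated)
})

test_that("edge genes truncate and CDS-less genes are skipped", {
  set.seed(43)
  contig <- random_dna(800)
  ann <- toy_gff(list(
    list(seqid = "c1", type = "gene", start = 301, end = 500, strand = "+",
         ID = "gA"),
    list(seqid = "c1", type = "CDS", start = 301, end = 500, strand = "+",
         ID = "gA.c", Parent = "gA"),
    list(seqid = "c1", type = "gene", start = 601, end = 700, strand = "+",
         ID = "gB")))
  r <- suppressMessages(extract_promoters(c(c1 = contig), ann, 1000))
  expect_equal(r$gene_id, "gA")
  expect_equal(r$length, 300)
  expect_true(r$truncated)
})

test_that("scan_motif reproduces the worked W-box example", {
  # single CTGACC with its leftmost base 106 bases upstream of ATG
  region <- paste0(strrep("A", 1000 - 106), "CTGACC", strrep("A", 100))
  hits <- scan_motif(region, gene_id = "g")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$offset, -106L)

  expect_equal(nrow(scan_motif(strrep("A", 1000), gene_id = "g")), 0)
  expect_error(scan_motif("ACGT", pattern = "CTGAZC"), "non-IUPAC")
})

test_that("overlapping matches are each reported", {
  region <- paste0(strrep("A", 200), "CTGACTTGACC", strrep("A", 50))
  hits <- scan_motif(region, gene_id = "g")
  expect_equal(sum(hits$strand == "+"), 2)
  f <- oracle_match(region, "YTGACY")
  expect_equal(sort(hits$offset[hits$strand == "+"]),
               sort(f - nchar(region) - 1L))
})

test_that("scanning matches brute force on both strands", {
  set.seed(44)
  for (rep in 1:25) {
    L <- sample(50:400, 1)
    region <- random_dna(L)
    pattern <- sample(c("YTGACY", "ACGTG", "CCGAC", "CNGTTR", "RCCGAC"), 1)
    hits <- scan_motif(region, pattern, gene_id = "g")
    expect_equal(sort(hits$offset[hits$strand == "+"]),
                 sort(oracle_match(region, pattern) - L - 1L))
    expect_equal(sort(hits$offset[hits$strand == "-"]),
                 sort(oracle_match(region, oracle_revcomp(pattern)) - L - 1L))
    # every hit satisfies the MotifHit interval invariant
    m <- nchar(pattern)
    expect_true(all(hits$offset >= -L & hits$offset <= -m))
  }
})

test_that("strand symmetry: hits map across reverse complementation", {
  set.seed(45)
  for (rep in 1:10) {
    L <- sample(100:300, 1)
    region <- random_dna(L)
    pattern <- "YTGACY"
    fwd <- scan_motif(region, pattern, gene_id = "g")
    rev <- scan_motif(revcomp(region), pattern, gene_id = "g")
    m <- nchar(pattern)
    # a + hit at offset o maps to a - hit at -(L + o) - m + ... reflect:
    reflect <- function(o) -(2 * L + o + m) + L      # = -L - o - m
    expect_equal(sort(reflect(fwd$offset[fwd$strand == "+"])),
                 sort(rev$offset[rev$strand == "-"]))
    expect_equal(sort(reflect(fwd$offset[fwd$strand == "-"])),
                 sort(rev$offset[rev$strand == "+"]))
  }
})

test_that("target tiers follow counts and are monotone in min_sites", {
  sim <- gen_genome(setNames(list(c(-106, -33, -127), c(-900, -10),
                                  c(-500), numeric(0)),
                             c("g3", "g2", "g1", "g0")), seed = 46)
  regions <- extract_promoters(sim$genome, sim$annotation)
  hits <- scan_regions(regions)
  tg <- call_targets(hits, regions$gene_id)
  expect_equal(tg$wbox_count[match(c("g3", "g2", "g1", "g0"), tg$gene_id)],
               c(3L, 2L, 1L, 0L))
  expect_true(all(tg$tier3 <= tg$tier2 & tg$tier2 <= tg$tier1))
  expect_equal(tg$gene_id[tg$target], "g3")
  expect_equal(tg$positions[tg$gene_id == "g3"], "-127,-106,-33")
  for (k in 1:3) {
    t_lo <- call_targets(hits, regions$gene_id, min_sites = k)
    t_hi <- call_targets(hits, regions$gene_id, min_sites = k + 1)
    expect_true(all(t_hi$gene_id[t_hi$target] %in% t_lo$gene_id[t_lo$target]))
  }
})

test_that("scan_catalog aggregates counts by category", {
  catalog <- read_cis_catalog()
  lt <- catalog[catalog$category == "low temperature-responsive", ]
  planted <- data.frame(
    element_id = c(rep("LTRECOREATCOR15", 5), rep("LTRE1HVBLT49", 4),
                   "ABRELATERD1"),
    pattern = c(rep("CCGAC", 5), rep("CCGAAA", 4), "ACGTG"),
    offset = c(-900, -800, -700, -600, -500, -400, -300, -200, -100, -50),
    stringsAsFactors = FALSE)
  sim <- gen_genome(list(gLT = planted),
                    exclude_patterns = catalog$pattern, seed = 47)
  regions <- extract_promoters(sim$genome, sim$annotation)
  res <- scan_catalog(regions, catalog)
  s <- res$summary
  expect_equal(s$count[s$category == "low temperature-responsive"], 9L)
  expect_equal(s$count[s$category == "ABA-responsive"], 1L)
  expect_equal(s$count[s$category == "WRKY-binding"], 0L)
  # conservation: category count equals the sum of its elements' hits
  for (categ in unique(catalog$category)) {
    expect_equal(s$count[s$category == categ],
                 sum(res$hits$category == categ))
  }
  empty <- scan_catalog(regions, catalog[0, ])
  expect_equal(nrow(empty$hits), 0)
  expect_equal(nrow(empty$summary), 0)
})

test_that("gene_structure counts exons of the longest mRNA", {
  sim <- gen_genome(setNames(rep(list(numeric(0)), 3), c("e1", "e3", "e5")),
                    n_exons = c(1, 3, 5), seed = 48)
  gs <- gene_structure(sim$annotation)
  expect_equal(gs$n_exons[match(c("e1", "e3", "e5"), gs$gene_id)],
               c(1L, 3L, 5L))
  expect_equal(gs$n_introns, gs$n_exons - 1L)
  # two mRNAs: the longer one decides
  ann <- toy_gff(list(
    list(seqid = "c", type = "gene", start = 1, end = 100, strand = "+",
         ID = "g"),
    list(seqid = "c", type = "mRNA", start = 1, end = 100, strand = "+",
         ID = "m_long", Parent = "g"),
    list(seqid = "c", type = "mRNA", start = 1, end = 50, strand = "+",
         ID = "m_short", Parent = "g"),
    list(seqid = "c", type = "exon", start = 1, end = 40, strand = "+",
         ID = "x1", Parent = "m_long"),
    list(seqid = "c", type = "exon", start = 60, end = 100, strand = "+",
         ID = "x2", Parent = "m_long"),
    list(seqid = "c", type = "exon", start = 1, end = 50, strand = "+",
         ID = "x3", Parent = "m_short")))
  expect_equal(gene_structure(ann)$n_exons, 2L)
})
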