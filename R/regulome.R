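# Promoter extraction, degenerate-motif scanning on both strands, target-gene
# calling by W-box count tiers, and exon/intron summaries.
#
# Offset convention (reported positions like "-106"): the offset of the
# match's leftmost base in gene orientation, with -1 the base immediately 5'
# of the A of ATG; a match of length m therefore satisfies
# -window <= offset <= -m.

WBOX_PATTERN <- "YTGACY"

#' Extract upstream regulatory regions (promoter proxies)
#'
#' For a plus-strand gene with 0-based CDS start `s` the region is
#' `contig[max(0, s-window) .. s)` as-is; for a minus-strand gene with
#' 0-based exclusive CDS end `e` it is the reverse complement of
#' `contig[e .. e+window)`.  Regions shorter than `window` (contig edge) are
#' returned as-is with `truncated = TRUE`.  Genes without CDS features are
#' skipped with a log notice.
#'
#' @param genome named character vector of contig sequences.
#' @param annotation data.frame from [read_gff3()].
#' @param window upstream window in nt (default 1000).
#' @return data.frame: gene_id, sequence (gene orientation, 5'->3' toward
#'   ATG), length, truncated, contig, strand, g_start, g_end (0-based
#'   half-open genomic interval).
#' @export
extract_promoters <- function(genome, annotation, window = 1000L) {
  genes <- annotation[annotation$type == "gene", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    if (!g$seqid %in% names(genome)) {
      stop("contig '", g$seqid, "' for gene '", g$ID, "' not in genome")
    }
    mrna_ids <- annotation$ID[annotation$type == "mRNA" &
                                !is.na(annotation$Parent) &
                                annotation$Parent == g$ID]
    parents <- c(g$ID, mrna_ids)    # tolerate gene+CDS without mRNA
    cds <- annotation[annotation$type == "CDS" & !is.na(annotation$Parent) &
                        annotation$Parent %in% parents, , drop = FALSE]
    if (nrow(cds) == 0) {
      wrky_log("info", "gene '", g$ID, "' has no CDS; skipped")
      next
    }
    contig <- genome[[g$seqid]]
    clen <- nchar(contig)
    if (g$strand == "+") {
      s0 <- min(cds$start) - 1L                    # 0-based CDS start
      from0 <- max(0L, s0 - window)
      seq <- substr(contig, from0 + 1L, s0)
      g_start <- from0; g_end <- s0
    } else if (g$strand == "-") {
      e0 <- max(cds$end)                           # 0-based exclusive end
      to0 <- min(clen, e0 + window)
      seq <- revcomp(substr(contig, e0 + 1L, to0))
      g_start <- e0; g_end <- to0
    } else {
      stop("gene '", g$ID, "' has no usable strand ('", g$strand, "')")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$ID, sequence = seq, length = nchar(seq),
      truncated = nchar(seq) < window, contig = g$seqid, strand = g$strand,
      g_start = g_start, g_end = g_end, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), sequence = character(0),
                      length = integer(0), truncated = logical(0),
                      contig = character(0), strand = character(0),
                      g_start = integer(0), g_end = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 1-based start positions of IUPAC pattern matches on a plain DNA string.
match_iupac <- function(sequence, pattern) {
  pattern <- validate_iupac(pattern)
  m <- nchar(pattern)
  L <- nchar(sequence)
  if (L < m || m == 0) return(integer(0))
  ch <- strsplit(toupper(sequence), "")[[1]]
  pch <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & ch[seq_len(L - m + 1L) + j - 1L] %in% IUPAC_DNA[[pch[j]]]
  }
  which(ok)
}

#' Scan a promoter region for a degenerate motif on both strands
#'
#' Forward-orientation matches are reported with strand `+`; matches of the
#' pattern's reverse complement with strand `-`.  Overlapping matches are all
#' reported.  Offsets follow the leftmost-base convention described above.
#'
#' @param region one row of [extract_promoters()] output, or a plain
#'   character sequence (then supply `gene_id`).
#' @param pattern IUPAC pattern; the W-box is `YTGACY`.
#' @param element_id identifier recorded with each hit.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param gene_id gene identifier when `region` is a plain string.
#' @return data.frame: gene_id, element_id, pattern, strand, offset.
#' @export
scan_motif <- function(region, pattern = WBOX_PATTERN, element_id = "WBOX",
                       both_strands = TRUE, gene_id = NULL) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1)
    sequence <- region$sequence
    gene_id <- region$gene_id
  } else {
    sequence <- region
    if (is.null(gene_id)) gene_id <- NA_character_
  }
  pattern <- validate_iupac(pattern)
  m <- nchar(pattern)
  L <- nchar(sequence)
  fwd <- match_iupac(sequence, pattern)
  hits <- data.frame(gene_id = rep(gene_id, length(fwd)),
                     element_id = rep(element_id, length(fwd)),
                     pattern = rep(pattern, length(fwd)),
                     strand = rep("+", length(fwd)),
                     offset = fwd - L - 1L, stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- match_iupac(sequence, revcomp(pattern))
    hits <- rbind(hits, data.frame(
      gene_id = rep(gene_id, length(rev)),
      element_id = rep(element_id, length(rev)),
      pattern = rep(pattern, length(rev)),
      strand = rep("-", length(rev)),
      offset = rev - L - 1L, stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan many promoter regions for one pattern
#'
#' @param regions [extract_promoters()] output.
#' @inheritParams scan_motif
#' @return row-bound [scan_motif()] hits.
#' @export
scan_regions <- function(regions, pattern = WBOX_PATTERN,
                         element_id = "WBOX", both_strands = TRUE) {
  if (nrow(regions) == 0) {
    return(data.frame(gene_id = character(0), element_id = character(0),
                      pattern = character(0), strand = character(0),
                      offset = integer(0)))
  }
  out <- lapply(seq_len(nrow(regions)), function(k) {
    scan_motif(regions[k, ], pattern, element_id, both_strands)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call potential WRKY target genes by W-box count tiers
#'
#' @param hits data.frame of W-box hits ([scan_motif()]/[scan_regions()]).
#' @param gene_ids universe of scanned genes (zero-hit genes are included
#'   with count 0); defaults to the genes present in `hits`.
#' @param min_sites site count defining the target list (default 3).
#' @return data.frame: gene_id, wbox_count, tier1/2/3, target (count >=
#'   min_sites), positions (comma-joined ascending offsets).
#' @export
call_targets <- function(hits, gene_ids = unique(hits$gene_id),
                         min_sites = 3L) {
  rows <- lapply(gene_ids, function(g) {
    off <- sort(hits$offset[hits$gene_id == g])
    data.frame(gene_id = g, wbox_count = length(off),
               tier1 = length(off) >= 1, tier2 = length(off) >= 2,
               tier3 = length(off) >= 3,
               target = length(off) >= min_sites,
               positions = paste(off, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan promoters against a full cis-element catalog
#'
#' Applies [scan_motif()] per catalog entry and aggregates hit counts per
#' gene and category.
#'
#' @param regions [extract_promoters()] output.
#' @param catalog [read_cis_catalog()] output.
#' @param both_strands scan both strands (default TRUE).
#' @return list with `hits` (gene_id, element_id, category, pattern, strand,
#'   offset) and `summary` (gene_id, category, count).
#' @export
scan_catalog <- function(regions, catalog = read_cis_catalog(),
                         both_strands = TRUE) {
  if (nrow(catalog) == 0) {
    empty <- data.frame(gene_id = character(0), element_id = character(0),
                        category = character(0), pattern = character(0),
                        strand = character(0), offset = integer(0))
    return(list(hits = empty,
                summary = data.frame(gene_id = character(0),
                                     category = character(0),
                                     count = integer(0))))
  }
  parts <- lapply(seq_len(nrow(catalog)), function(k) {
    h <- scan_regions(regions, catalog$pattern[k], catalog$element_id[k],
                      both_strands)
    if (nrow(h) > 0) h$category <- catalog$category[k]
    h
  })
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  hits <- if (length(parts) == 0) {
    data.frame(gene_id = character(0), element_id = character(0),
               pattern = character(0), strand = character(0),
               offset = integer(0), category = character(0))
  } else {
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  hits <- hits[, c("gene_id", "element_id", "category", "pattern", "strand",
                   "offset")]
  combos <- expand.grid(gene_id = regions$gene_id,
                        category = unique(catalog$category),
                        stringsAsFactors = FALSE)
  combos$count <- vapply(seq_len(nrow(combos)), function(k) {
    sum(hits$gene_id == combos$gene_id[k] &
          hits$category == combos$category[k])
  }, integer(1))
  list(hits = hits, summary = combos)
}

#' Exon/intron counts per gene
#'
#' Counts exon features of the longest mRNA per gene (ties broken by
#' lexicographically smallest mRNA id); genes annotated without mRNA
#' features use exons attached to the gene directly.  Genes without exons
#' are skipped with a log notice.
#'
#' @param annotation data.frame from [read_gff3()].
#' @return data.frame: gene_id, n_exons, n_introns.
#' @export
gene_structure <- function(annotation) {
  genes <- annotation[annotation$type == "gene", , drop = FALSE]
  exons <- annotation[annotation$type == "exon", , drop = FALSE]
  mrnas <- annotation[annotation$type == "mRNA", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    gm <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(gm) > 0) {
      span <- gm$end - gm$start + 1L
      pick <- gm$ID[order(-span, gm$ID)][1]
      n_ex <- sum(!is.na(exons$Parent) & exons$Parent == pick)
    } else {
      n_ex <- sum(!is.na(exons$Parent) & exons$Parent == g$ID)
    }
    if (n_ex == 0) {
      wrky_log("info", "gene '", g$ID, "' has no exon features; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(gene_id = g$ID,
                                            n_exons = n_ex,
                                            n_introns = n_ex - 1L,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), n_exons = integer(0),
                      n_introns = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
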