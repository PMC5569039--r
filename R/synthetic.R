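# Synthetic-data generators.  Every generator is deterministic under its
# seed and returns the generated dataset together with a ground-truth record
# sufficient to predict every downstream pipeline output (exactly for
# domain/motif scans, to stated tolerance for expression).
#
# Protein backgrounds use alphabet restriction (no W/C/H/Y, so heptapeptide
# and zinc-finger anchors exist only where planted); genome backgrounds stay
# ACGT and are certified motif-free by scan-and-repair.

SAFE_AA <- strsplit("ADEFGIKLMNPQRSTV", "")[[1]]

rand_aa <- function(n) paste(sample(SAFE_AA, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# One domain block: heptapeptide + linker + zinc finger; returns the block
# string plus 1-based protected (anchor) indices within the block.
domain_block <- function(motif = "WRKYGQK", linker_len = 10L, spacer1 = 4L,
                         spacer2 = 23L, terminal = "H") {
  block <- paste0(motif, rand_aa(linker_len),
                  "C", rand_aa(spacer1), "C", rand_aa(spacer2),
                  "H", rand_aa(1), terminal)
  c1 <- 7L + linker_len + 1L
  c2 <- c1 + spacer1 + 1L
  h <- c2 + spacer2 + 1L
  # the whole heptapeptide is protected: variants are planted via `motif`,
  # never created by mutation, so detector tolerance is respected by design
  list(block = block,
       anchors = c(1:7, c1, c2, h, h + 2L),
       zf_rel = c1 - 1L)                       # 0-based finger start in block
}

mutate_block <- function(block, anchors, rate) {
  if (rate <= 0) return(block)
  ch <- strsplit(block, "")[[1]]
  free <- setdiff(seq_along(ch), anchors)
  hit <- free[runif(length(free)) < rate]
  for (i in hit) ch[i] <- sample(setdiff(SAFE_AA, ch[i]), 1)
  paste(ch, collapse = "")
}

group_grammar <- function(group) {
  switch(group,
         I   = list(s1 = 4L, s2 = 22L, term = "H"),
         IIa = , IIb = , IId = , IIe = list(s1 = 5L, s2 = 23L, term = "H"),
         IIc = list(s1 = 4L, s2 = 23L, term = "H"),
         III = list(s1 = 7L, s2 = 23L, term = "C"),
         NG  = list(s1 = 4L, s2 = 23L, term = "H"),
         stop("unknown group: ", group))
}

#' Generate a synthetic proteome with planted WRKY domains
#'
#' Proteins are built from subgroup templates on W/C/H/Y-free backgrounds so
#' no spurious anchor can arise: group I proteins carry two
#' heptapeptide+finger blocks (CX4CX22-HXH then CX4CX23-HXH), group III a
#' single CCHC block, groups IIa-IIe a single CCHH block copied from the
#' matching reference-panel entry, and NG proteins a CCHH block unrelated to
#' any panel entry.  Point mutations (per-site probability `mutation_rate`)
#' avoid the anchor positions and never introduce W/C/H/Y.
#'
#' @param n_per_group named integer vector over groups I, IIa-IIe, III, NG.
#' @param mutation_rate per-site mutation probability in `[0, 0.5]`.
#' @param seed integer RNG seed.
#' @param panel reference panel whose entries seed the II* templates.
#' @return list with `proteins` (named character vector) and `truth` (named
#'   list: group, template, hep_starts, zf_starts, motifs per protein).
#' @export
gen_proteome <- function(n_per_group = c(I = 5, IIa = 5, IIb = 5, IIc = 5,
                                         IId = 5, IIe = 5, III = 5, NG = 5),
                         mutation_rate = 0, seed = 1L,
                         panel = read_reference_panel()) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.5)
  set.seed(seed)
  proteins <- character(0)
  truth <- list()
  for (group in names(n_per_group)) {
    gg <- group_grammar(group)
    for (i in seq_len(n_per_group[[group]])) {
      id <- sprintf("SYN_%s_%02d", group, i)
      template <- NA_character_
      if (group == "I") {
        b1 <- domain_block(spacer1 = 4L, spacer2 = 22L, terminal = "H")
        b2 <- domain_block(spacer1 = 4L, spacer2 = 23L, terminal = "H")
        blocks <- list(b1, b2)
      } else if (group %in% c("IIa", "IIb", "IIc", "IId", "IIe")) {
        cand <- panel[panel$subgroup == group, , drop = FALSE]
        if (nrow(cand) == 0) stop("panel has no entries for subgroup ", group)
        pick <- cand[((i - 1) %% nrow(cand)) + 1, ]
        template <- pick$reference_id
        # panel entries are heptapeptide+linker+finger blocks already
        zf <- find_zinc_finger(pick$sequence, from_index = 7L)
        blocks <- list(list(block = pick$sequence,
                            anchors = c(1:7, zf$start + 1L,
                                        zf$start + zf$spacer1 + 2L,
                                        zf$start + zf$spacer1 + zf$spacer2 + 3L,
                                        zf$start + zf$spacer1 + zf$spacer2 + 5L),
                            zf_rel = zf$start))
      } else if (group == "NG") {
        # non-group members mostly carry variant heptapeptides and drift far
        # from every reference; a longer linker keeps panel identity low
        motif <- sample(c("WRKYGKK", "WRKYGRD", "WRKYATN", "WKKYGQK",
                          "WNKYGQK", "WTKYGQK", "WRKYGQK"), 1)
        blocks <- list(domain_block(motif = motif, linker_len = 18L,
                                    spacer1 = gg$s1, spacer2 = gg$s2,
                                    terminal = gg$term))
      } else {
        blocks <- list(domain_block(spacer1 = gg$s1, spacer2 = gg$s2,
                                    terminal = gg$term))
      }
      parts <- rand_aa(sample(10:30, 1))
      hep_starts <- integer(0); zf_starts <- integer(0); motifs <- character(0)
      for (b in blocks) {
        mb <- mutate_block(b$block, b$anchors, mutation_rate)
        hep_starts <- c(hep_starts, nchar(parts))
        zf_starts <- c(zf_starts, nchar(parts) + b$zf_rel)
        motifs <- c(motifs, substr(mb, 1, 7))
        parts <- paste0(parts, mb, rand_aa(sample(10:30, 1)))
      }
      proteins[[id]] <- parts
      truth[[id]] <- list(group = group, template = template,
                          hep_starts = hep_starts, zf_starts = zf_starts,
                          motifs = motifs)
    }
  }
  list(proteins = proteins, truth = truth)
}

# Resolve an IUPAC pattern into one concrete instance.
resolve_iupac <- function(pattern) {
  paste(vapply(strsplit(validate_iupac(pattern), "")[[1]], function(code) {
    set <- IUPAC_DNA[[code]]
    set[sample.int(length(set), 1)]
  }, character(1)), collapse = "")
}

# A random ACGT string certified free of every pattern (both strands):
# scan-and-repair rather than whole-region rejection, which stalls at 1 kb.
clean_background <- function(len, patterns, max_iter = 500L) {
  seq <- rand_dna(len)
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (p in unique(patterns)) {
      for (q in unique(c(p, revcomp(p)))) {
        hits <- match_iupac(seq, q)
        if (length(hits) > 0) {
          dirty <- TRUE
          for (h in hits) {
            pos <- h + nchar(q) %/% 2
            substr(seq, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
          }
        }
      }
    }
    if (!dirty) return(seq)
  }
  stop("could not build a motif-free background of length ", len)
}

#' Generate a synthetic genome + GFF3 with planted promoter elements
#'
#' One gene per contig.  Each gene's promoter background is certified free
#' of every planted pattern (and of `exclude_patterns`) on both strands
#' before instances are planted at the requested offsets; the generator
#' re-scans after planting and repairs any junction artifact, so the
#' reported ground truth is exact.  Genes are placed on the requested
#' strand; a `promoter_len` below `window` puts the gene at the contig edge
#' to exercise truncation.
#'
#' @param planted named list (names = gene ids); each element either a
#'   numeric vector of W-box offsets or a data.frame with columns
#'   element_id, pattern, offset.  Offsets are negative, leftmost-base
#'   convention.
#' @param strand per-gene strand ("+"/"-"), recycled; default alternates.
#' @param promoter_len per-gene available upstream length, recycled
#'   (default = window).
#' @param cds_len,n_exons gene-body layout, recycled.
#' @param window promoter window the pipeline will use.
#' @param exclude_patterns extra patterns the background must not contain.
#' @param seed integer RNG seed.
#' @return list with `genome` (named character), `annotation` (GFF3-layout
#'   data.frame), and `truth` (per gene: strand, promoter_len, planted
#'   data.frame with element_id, pattern, offset, instance).
#' @export
gen_genome <- function(planted, strand = NULL, promoter_len = NULL,
                       cds_len = 300L, n_exons = 1L, window = 1000L,
                       exclude_patterns = WBOX_PATTERN, seed = 1L) {
  gene_ids <- names(planted)
  stopifnot(!is.null(gene_ids))
  n <- length(gene_ids)
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
  strand <- rep(strand, length.out = n)
  promoter_len <- rep(if (is.null(promoter_len)) window else promoter_len,
                      length.out = n)
  cds_len <- rep(cds_len, length.out = n)
  n_exons <- rep(n_exons, length.out = n)
  set.seed(seed)
  genome <- character(0)
  feat <- list()
  truth <- list()
  for (k in seq_len(n)) {
    gid <- gene_ids[k]
    pl <- planted[[k]]
    if (is.numeric(pl)) {
      pl <- if (length(pl) == 0) {
        data.frame(element_id = character(0), pattern = character(0),
                   offset = integer(0))
      } else {
        data.frame(element_id = "WBOX", pattern = WBOX_PATTERN,
                   offset = as.integer(pl), stringsAsFactors = FALSE)
      }
    }
    L <- promoter_len[k]
    if (nrow(pl) > 0) {
      if (any(pl$offset > -nchar(pl$pattern)) || any(pl$offset < -L)) {
        stop("gene '", gid, "': planted offset outside the promoter bounds")
      }
    }
    all_patterns <- unique(c(pl$pattern, exclude_patterns))
    promoter <- clean_background(L, all_patterns)
    # per-position allowed base sets; overlapping plants are legal as long
    # as the overlapping pattern positions are jointly satisfiable (the
    # printed target tables do contain W-boxes overlapping by one base)
    allowed <- vector("list", L)
    for (r in seq_len(nrow(pl))) {
      from <- L + pl$offset[r] + 1L
      pch <- strsplit(pl$pattern[r], "")[[1]]
      for (j in seq_along(pch)) {
        pos <- from + j - 1L
        set <- IUPAC_DNA[[pch[j]]]
        cur <- if (is.null(allowed[[pos]])) set else
          intersect(allowed[[pos]], set)
        if (length(cur) == 0) {
          stop("gene '", gid, "': planted elements overlap incompatibly ",
               "at promoter offset ", pos - L - 1L)
        }
        allowed[[pos]] <- cur
      }
    }
    planted_pos <- which(!vapply(allowed, is.null, logical(1)))
    for (pos in planted_pos) {
      substr(promoter, pos, pos) <-
        allowed[[pos]][sample.int(length(allowed[[pos]]), 1)]
    }
    pl$instance <- vapply(seq_len(nrow(pl)), function(r) {
      from <- L + pl$offset[r] + 1L
      substr(promoter, from, from + nchar(pl$pattern[r]) - 1L)
    }, character(1))
    for (iter in 1:200) {
      spurious <- integer(0)
      for (p in unique(pl$pattern)) {
        expected <- sort(L + pl$offset[pl$pattern == p] + 1L)
        got_f <- match_iupac(promoter, p)
        got_r <- match_iupac(promoter, revcomp(p))
        extra <- c(setdiff(got_f, expected), got_r)
        for (h in extra) {
          cand <- setdiff(seq(h, h + nchar(p) - 1L), planted_pos)
          if (length(cand) == 0) {
            stop("gene '", gid, "': planted elements interact irreparably")
          }
          spurious <- c(spurious, cand[1])
        }
      }
      for (p in setdiff(all_patterns, pl$pattern)) {
        for (q in unique(c(p, revcomp(p)))) {
          for (h in match_iupac(promoter, q)) {
            cand <- setdiff(seq(h, h + nchar(q) - 1L), planted_pos)
            if (length(cand) > 0) spurious <- c(spurious, cand[1])
          }
        }
      }
      if (length(spurious) == 0) break
      for (pos in unique(spurious)) {
        substr(promoter, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (iter == 200) stop("gene '", gid, "': background repair failed")
    }
    # gene body: ATG + exons (CDS) separated by introns
    ex_len <- rep(max(10L, cds_len[k] %/% n_exons[k]), n_exons[k])
    intron <- if (n_exons[k] > 1) {
      vapply(seq_len(n_exons[k] - 1), function(z) rand_dna(30L), character(1))
    } else character(0)
    body <- "ATG"
    ex_bounds <- list()
    pos <- nchar(body)
    body_parts <- character(0)
    cur <- 0L
    for (e in seq_len(n_exons[k])) {
      ex_bounds[[e]] <- c(cur, cur + ex_len[e])         # 0-based half-open
      body_parts <- c(body_parts, rand_dna(ex_len[e] - if (e == 1) 3L else 0L))
      cur <- cur + ex_len[e]
      if (e < n_exons[k]) {
        body_parts <- c(body_parts, intron[e])
        cur <- cur + 30L
      }
    }
    body <- paste0("ATG", paste(body_parts, collapse = ""))
    body_len <- nchar(body)
    left_pad <- if (L < window) 0L else sample(0:30, 1)
    contig_id <- paste0("ctg_", gid)
    if (strand[k] == "+") {
      contig <- paste0(rand_dna(left_pad), promoter, body)
      gs <- left_pad + L + 1L
      ge <- left_pad + L + body_len
      ex_coords <- lapply(ex_bounds, function(b)
        c(gs + b[1], gs + b[2] - 1L))
    } else {
      contig <- paste0(revcomp(body), revcomp(promoter), rand_dna(left_pad))
      gs <- 1L
      ge <- body_len
      ex_coords <- lapply(ex_bounds, function(b)
        c(body_len - b[2] + 1L, body_len - b[1]))
    }
    mid <- paste0(gid, ".m1")
    rows <- list(
      data.frame(seqid = contig_id, source = "wrkyscan", type = "gene",
                 start = gs, end = ge, score = ".", strand = strand[k],
                 phase = ".", ID = gid, Parent = NA_character_,
                 line = NA_integer_, stringsAsFactors = FALSE),
      data.frame(seqid = contig_id, source = "wrkyscan", type = "mRNA",
                 start = gs, end = ge, score = ".", strand = strand[k],
                 phase = ".", ID = mid, Parent = gid, line = NA_integer_,
                 stringsAsFactors = FALSE))
    for (e in seq_along(ex_coords)) {
      for (tp in c("exon", "CDS")) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = contig_id, source = "wrkyscan", type = tp,
          start = ex_coords[[e]][1], end = ex_coords[[e]][2], score = ".",
          strand = strand[k], phase = if (tp == "CDS") "0" else ".",
          ID = paste0(mid, ".", tp, e), Parent = mid, line = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    genome[[contig_id]] <- contig
    feat[[length(feat) + 1L]] <- do.call(rbind, rows)
    truth[[gid]] <- list(strand = strand[k], promoter_len = L,
                         n_exons = n_exons[k], planted = pl)
  }
  annotation <- do.call(rbind, feat)
  rownames(annotation) <- NULL
  out <- list(genome = genome, annotation = annotation, truth = truth,
              window = window)
  # certification: the scan must recover exactly the planted hits
  regions <- extract_promoters(genome, annotation, window)
  for (gid in gene_ids) {
    pl <- truth[[gid]]$planted
    for (p in unique(c(pl$pattern, exclude_patterns))) {
      got <- scan_motif(regions[regions$gene_id == gid, ], p, p)
      want <- sort(pl$offset[pl$pattern == p])
      if (!identical(sort(got$offset), as.integer(want))) {
        stop("internal: certification failed for gene '", gid,
             "', pattern ", p)
      }
    }
  }
  out
}

#' Generate a qPCR Ct table with known fold changes
#'
#' The reference gene's Ct is constant up to noise; each target gene's Ct is
#' shifted by `-log2(fold)` in each condition relative to its control
#' baseline.  Fold changes in the control condition are forced to 1.
#'
#' @param gene_ids target gene ids.
#' @param conditions condition labels; the first is the control.
#' @param fold_changes matrix (genes x conditions) or a single value
#'   recycled; true fold change vs control.
#' @param sigma replicate noise (standard deviation, cycles).
#' @param replicates replicates per gene/condition (>= 2).
#' @param seed integer RNG seed.
#' @param reference_gene id used for the internal control rows.
#' @return list with `ct` (gene_id, condition, replicate, ct),
#'   `reference_gene`, `control_condition` and `truth` (folds, sigma,
#'   baselines).
#' @export
gen_ct_table <- function(gene_ids, conditions = c("0h", "2h", "6h", "12h"),
                         fold_changes = 1, sigma = 0.1, replicates = 3L,
                         seed = 1L, reference_gene = "actin") {
  stopifnot(sigma >= 0, replicates >= 2)
  set.seed(seed)
  ng <- length(gene_ids); nc <- length(conditions)
  folds <- matrix(fold_changes, ng, nc,
                  dimnames = list(gene_ids, conditions))
  folds[, 1] <- 1
  baselines <- setNames(runif(ng, 24, 28), gene_ids)
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = reference_gene, condition = cond, replicate = r,
        ct = 20 + rnorm(1, 0, sigma), stringsAsFactors = FALSE)
      for (g in gene_ids) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, condition = cond, replicate = r,
          ct = baselines[[g]] - log2(folds[g, cond]) + rnorm(1, 0, sigma),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ct = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reference_gene = reference_gene, control_condition = conditions[1],
       truth = list(folds = folds, sigma = sigma, baselines = baselines))
}

#' Generate a negative-binomial RNA-seq count table
#'
#' Counts per gene and sample follow `NB(mu = base * libsize * fold,
#' size = 1/dispersion)` with treated-arm fold changes as requested; gene
#' lengths are drawn once per gene.
#'
#' @param gene_ids gene ids.
#' @param n_control,n_treated replicates per arm.
#' @param dispersion NB dispersion (> 0).
#' @param fold_changes per-gene treated/control fold, recycled.
#' @param base_mean per-gene control-arm expected count, recycled.
#' @param seed integer RNG seed.
#' @return list with `counts` (gene_id, sample, count, length), `control_samples`,
#'   `treated_samples` and `truth`.
#' @export
gen_counts <- function(gene_ids, n_control = 3L, n_treated = 3L,
                       dispersion = 0.05, fold_changes = 1,
                       base_mean = 500, seed = 1L) {
  stopifnot(dispersion > 0)
  set.seed(seed)
  ng <- length(gene_ids)
  folds <- setNames(rep(fold_changes, length.out = ng), gene_ids)
  base <- setNames(rep(base_mean, length.out = ng), gene_ids)
  lengths <- setNames(round(runif(ng, 500, 3000)), gene_ids)
  samples <- c(paste0("ctrl_", seq_len(n_control)),
               paste0("trt_", seq_len(n_treated)))
  libsize <- setNames(runif(length(samples), 0.8, 1.2), samples)
  rows <- list()
  for (s in samples) {
    treated <- startsWith(s, "trt_")
    mu <- base * libsize[[s]] * (if (treated) folds else 1)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_ids, sample = s,
      count = stats::rnbinom(ng, mu = mu, size = 1 / dispersion),
      length = as.numeric(lengths), stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       control_samples = samples[seq_len(n_control)],
       treated_samples = samples[n_control + seq_len(n_treated)],
       truth = list(folds = folds, base_mean = base, dispersion = dispersion,
                    lengths = lengths, libsize = libsize))
}

#' Generate a family of sequences diverged from one ancestor
#'
#' Substitution-only divergence (no indels) at non-conserved positions, so
#' the recorded conserved columns are homologous across the family and a
#' correct multiple alignment places them in register.
#'
#' @param n number of descendants.
#' @param length ancestor length.
#' @param conserved indices held invariant in every descendant.
#' @param mutation_rate per-site substitution probability elsewhere.
#' @param seed integer RNG seed.
#' @return list with `sequences` (named character) and `truth` (ancestor,
#'   conserved indices).
#' @export
gen_divergent_family <- function(n = 5L, length = 80L,
                                 conserved = seq(1, 80, by = 8),
                                 mutation_rate = 0.2, seed = 1L) {
  set.seed(seed)
  anc <- strsplit(rand_aa(length), "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    ch <- anc
    free <- setdiff(seq_along(ch), conserved)
    hit <- free[runif(base::length(free)) < mutation_rate]
    for (p in hit) ch[p] <- sample(setdiff(SAFE_AA, ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  list(sequences = setNames(seqs, sprintf("fam%02d", seq_len(n))),
       truth = list(ancestor = paste(anc, collapse = ""),
                    conserved = conserved))
}
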