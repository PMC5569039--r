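# Independent brute-force oracles used across the suite.  These deliberately
# re-derive results from first principles (exhaustive window enumeration,
# full alignment enumeration) and share no code path with the package
# implementations they check.

AA_ALL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, with_x = FALSE) {
  pool <- if (with_x) c(AA_ALL, "X") else AA_ALL
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# every 7-residue window checked directly against the anchor + Hamming rule
oracle_hepta <- function(sequence, max_mismatches = 3) {
  canon <- strsplit("WRKYGQK", "")[[1]]
  ch <- strsplit(sequence, "")[[1]]
  out <- list()
  for (i in seq_len(max(0, length(ch) - 6))) {
    win <- ch[i:(i + 6)]
    if (win[1] != "W" || win[3] != "K" || win[4] != "Y") next
    mm <- sum(win != canon)
    if (mm <= max_mismatches) {
      out[[length(out) + 1]] <- data.frame(
        start = i - 1L, motif = paste(win, collapse = ""),
        mismatches = mm, canonical = mm == 0, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    data.frame(start = integer(0), motif = character(0),
               mismatches = integer(0), canonical = logical(0))
  } else do.call(rbind, out)
}

# all (start, a, b) combinations enumerated in the contract's priority order
oracle_zf <- function(sequence, from_index = 0, s1 = c(3, 7), s2 = c(5, 27)) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  for (c1 in seq_len(n)) {
    if (c1 - 1 < from_index || ch[c1] != "C") next
    for (a in s1[1]:s1[2]) {
      c2 <- c1 + 1 + a
      if (c2 > n || ch[c2] != "C") next
      for (b in s2[1]:s2[2]) {
        h <- c2 + 1 + b
        if (h + 2 > n) next
        if (ch[h] == "H" && ch[h + 2] %in% c("H", "C", "Y")) {
          return(list(start = c1 - 1L, spacer1 = a, spacer2 = b,
                      terminal = ch[h + 2]))
        }
      }
    }
  }
  NULL
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# character-by-character window check, forward strand only
oracle_match <- function(sequence, pattern) {
  ch <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc); L <- length(ch)
  hits <- integer(0)
  for (i in seq_len(max(0, L - m + 1))) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!ch[i + j - 1] %in% IUPAC_SETS[[pc[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# exhaustive global-alignment enumeration for tiny sequences: builds every
# alignment explicitly and scores the finished strings (affine runs scored
# by walking the columns), so no dynamic programming is involved.
oracle_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  score_alignment <- function(colsA, colsB) {
    s <- 0; run <- ""
    for (k in seq_along(colsA)) {
      if (colsA[k] == "-" || colsB[k] == "-") {
        this <- if (colsA[k] == "-") "A" else "B"
        s <- s - if (run == this) gap_extend else gap_open
        run <- this
      } else {
        s <- s + submat[colsA[k], colsB[k]]
        run <- ""
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, colsA, colsB) {
    if (i > length(ca) && j > length(cb)) {
      sc <- score_alignment(colsA, colsB)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, c(colsA, ca[i]), c(colsB, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1, j, c(colsA, ca[i]), c(colsB, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(colsA, "-"), c(colsB, cb[j]))
    invisible(NULL)
  }
  rec(1, 1, character(0), character(0))
  best
}
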