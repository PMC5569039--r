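# Global alignment (Gotoh affine-gap) on sequences and profiles, and a
# progressive multiple alignment built on it.  Pure R; intended for domain-
# scale sequences (hundreds of residues), not chromosomes.
#
# Gap cost convention: a run of L gap columns costs gap_open + (L-1) *
# gap_extend.  The brute-force oracle in the test suite shares this
# convention.

profile_freq <- function(profile, alphabet) {
  # profile: character matrix, rows = sequences, cols = alignment columns
  f <- matrix(0, nrow = length(alphabet), ncol = ncol(profile),
              dimnames = list(alphabet, NULL))
  for (j in seq_len(ncol(profile))) {
    col <- profile[, j]
    col <- col[col != "-"]
    if (length(col) > 0) {
      tb <- table(factor(col, levels = alphabet))
      f[, j] <- as.numeric(tb) / length(col)
    }
  }
  f
}

# Align two profiles; returns index vectors (0 = gap) into each profile.
align_profiles <- function(pa, pb, submat, gap_open = 10, gap_extend = 1) {
  alphabet <- rownames(submat)
  la <- ncol(pa); lb <- ncol(pb)
  if (la == 0 || lb == 0) {
    return(list(ia = c(seq_len(la), rep(0L, lb)),
                ib = c(rep(0L, la), seq_len(lb)),
                score = if (la + lb == 0) 0 else
                  -(gap_open + (la + lb - 1) * gap_extend)))
  }
  fa <- profile_freq(pa, alphabet)
  fb <- profile_freq(pb, alphabet)
  S <- t(fa) %*% submat %*% fb     # average substitution score per column pair
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)  # gap in B (A column consumed)
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in A
  M[1, 1] <- 0
  if (la >= 1) X[2:(la + 1), 1] <- -(gap_open + (seq_len(la) - 1) * gap_extend)
  if (lb >= 1) Y[1, 2:(lb + 1)] <- -(gap_open + (seq_len(lb) - 1) * gap_extend)
  tbM <- matrix(0L, la + 1, lb + 1)
  tbX <- matrix(0L, la + 1, lb + 1)
  tbY <- matrix(0L, la + 1, lb + 1)
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- S[i - 1, j - 1] + cand[k]; tbM[i, j] <- k
      cand <- c(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend,
                Y[i - 1, j] - gap_open)
      k <- which.max(cand)
      X[i, j] <- cand[k]; tbX[i, j] <- k
      cand <- c(M[i, j - 1] - gap_open, X[i, j - 1] - gap_open,
                Y[i, j - 1] - gap_extend)
      k <- which.max(cand)
      Y[i, j] <- cand[k]; tbY[i, j] <- k
    }
  }
  # also fill X/Y along the first row/column boundaries used above
  ends <- c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  state <- which.max(ends)
  score <- ends[state]
  ia <- integer(0); ib <- integer(0)
  i <- la + 1; j <- lb + 1
  while (i > 1 || j > 1) {
    if (i == 1) {                      # leading gaps in A
      ia <- c(0L, ia); ib <- c(j - 1L, ib); j <- j - 1; next
    }
    if (j == 1) {
      ia <- c(i - 1L, ia); ib <- c(0L, ib); i <- i - 1; next
    }
    if (state == 1) {
      ia <- c(i - 1L, ia); ib <- c(j - 1L, ib)
      state <- tbM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ia <- c(i - 1L, ia); ib <- c(0L, ib)
      state <- tbX[i, j]; i <- i - 1
    } else {
      ia <- c(0L, ia); ib <- c(j - 1L, ib)
      state <- tbY[i, j]; j <- j - 1
    }
  }
  list(ia = ia, ib = ib, score = score)
}

seq_to_profile <- function(s) {
  matrix(if (nchar(s) == 0) character(0) else strsplit(s, "")[[1]], nrow = 1)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh dynamic programming under the configured
#' substitution matrix and affine gap penalties (a gap of length L costs
#' `gap_open + (L-1) * gap_extend`).  Fractional identity is the number of
#' identical aligned residue pairs divided by the number of alignment
#' columns.  An empty input yields the defined all-gap alignment with
#' identity 0.
#'
#' @param a,b protein strings.
#' @param submat substitution matrix (default packaged BLOSUM62).
#' @param gap_open,gap_extend positive gap costs.
#' @return list with score, a_aligned, b_aligned, identity, n_columns.
#' @export
align_pair <- function(a, b, submat = read_substitution_matrix(),
                       gap_open = 10, gap_extend = 1) {
  a <- toupper(a); b <- toupper(b)
  res <- align_profiles(seq_to_profile(a), seq_to_profile(b), submat,
                        gap_open, gap_extend)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  aa <- ifelse(res$ia == 0, "-", ca[pmax(res$ia, 1)])
  bb <- ifelse(res$ib == 0, "-", cb[pmax(res$ib, 1)])
  ncol_aln <- length(aa)
  ident <- if (ncol_aln == 0) 0 else
    sum(aa == bb & aa != "-") / ncol_aln
  list(score = res$score,
       a_aligned = paste(aa, collapse = ""),
       b_aligned = paste(bb, collapse = ""),
       identity = ident, n_columns = ncol_aln)
}

#' Progressive multiple sequence alignment
#'
#' Pairwise identity distances feed a UPGMA guide tree; profiles are merged
#' along it with profile-profile Gotoh alignment.  Removing gaps from any
#' output row recovers the input sequence exactly.
#'
#' @param sequences named character vector (>= 2 sequences).
#' @param submat substitution matrix.
#' @param gap_open,gap_extend affine gap costs.
#' @return named character vector of gapped rows, all the same width, in the
#'   input order.
#' @export
build_msa <- function(sequences, submat = read_substitution_matrix(),
                      gap_open = 10, gap_extend = 1) {
  n <- length(sequences)
  if (n < 2) stop("build_msa needs at least 2 sequences")
  stopifnot(!is.null(names(sequences)))
  sequences <- toupper(sequences)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        1 - align_pair(sequences[[i]], sequences[[j]], submat,
                       gap_open, gap_extend)$identity
    }
  }
  profiles <- lapply(sequences, seq_to_profile)
  members <- as.list(seq_len(n))
  if (n == 2) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]], submat,
                             gap_open, gap_extend)
    rows <- apply(merged, 1, paste, collapse = "")
    return(setNames(rows[order(unlist(members))], names(sequences)))
  }
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", n - 1)
  node_members <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    pick <- function(idx) {
      if (idx < 0) list(p = profiles[[-idx]], m = -idx)
      else list(p = nodes[[idx]], m = node_members[[idx]])
    }
    l <- pick(hc$merge[k, 1]); r <- pick(hc$merge[k, 2])
    nodes[[k]] <- merge_profiles(l$p, r$p, submat, gap_open, gap_extend)
    node_members[[k]] <- c(l$m, r$m)
  }
  final <- nodes[[n - 1]]
  ord <- node_members[[n - 1]]
  rows <- apply(final, 1, paste, collapse = "")
  setNames(rows[order(ord)], names(sequences)[sort(ord)])[names(sequences)]
}

merge_profiles <- function(pa, pb, submat, gap_open, gap_extend) {
  res <- align_profiles(pa, pb, submat, gap_open, gap_extend)
  ncols <- length(res$ia)
  out <- matrix("-", nrow = nrow(pa) + nrow(pb), ncol = ncols)
  for (c in seq_len(ncols)) {
    if (res$ia[c] > 0) out[seq_len(nrow(pa)), c] <- pa[, res$ia[c]]
    if (res$ib[c] > 0) out[nrow(pa) + seq_len(nrow(pb)), c] <- pb[, res$ib[c]]
  }
  out
}

#' Pairwise p-distances over a multiple alignment
#'
#' Distance = fraction of mismatching columns among columns where at least
#' one of the pair has a residue (double-gap columns excluded; gap-vs-residue
#' counts as a mismatch).
#'
#' @param msa named character vector as returned by [build_msa()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistance <- function(msa) {
  n <- length(msa)
  chars <- lapply(msa, function(s) strsplit(s, "")[[1]])
  w <- unique(vapply(chars, length, 1L))
  if (length(w) != 1) stop("alignment rows differ in width")
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- chars[[i]]; b <- chars[[j]]
      use <- !(a == "-" & b == "-")
      d[i, j] <- d[j, i] <- if (sum(use) == 0) 0 else
        sum(a[use] != b[use]) / sum(use)
    }
  }
  d
}
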