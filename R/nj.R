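# Neighbor-Joining (Saitou-Nei) with deterministic tie-breaking, plus
# bootstrap support over alignment columns.  Trees are returned as ape
# "phylo" objects so the surrounding ecosystem (plot, write.tree,
# cophenetic) applies; the agglomeration itself is implemented here because
# the contract fixes tie-breaking (lexicographically smallest active pair)
# and negative-branch clamping, which library implementations leave
# unspecified.

validate_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` is joined; ties are broken by the
#' lexicographically smallest active pair (input order).  Negative branch
#' lengths are clamped to 0 with a log notice.  On an additive matrix the
#' generating tree (topology and path lengths) is recovered exactly.
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix over at
#'   least 3 taxa; rownames are taxon labels.
#' @return an unrooted `phylo` object (trifurcation at the root node).
#' @export
nj_tree <- function(d) {
  validate_dist(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  active <- seq_len(n)          # node ids; tips are 1..n
  next_node <- n + 1L
  D <- d
  rownames(D) <- colnames(D) <- NULL
  edges <- matrix(0L, 0, 2)
  elens <- numeric(0)
  clamped <- 0L
  clamp <- function(v) {
    if (v < 0) { clamped <<- clamped + 1L; 0 } else v
  }
  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    vi <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))))
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    elens <- c(elens, vi, vj)
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], u)
  }
  # final trifurcating join of the last three nodes
  x <- D[1, 2]; y <- D[1, 3]; z <- D[2, 3]
  u <- next_node
  edges <- rbind(edges, c(u, active[1]), c(u, active[2]), c(u, active[3]))
  elens <- c(elens, clamp((x + y - z) / 2), clamp((x + z - y) / 2),
             clamp((y + z - x) / 2))
  if (clamped > 0) {
    wrky_log("info", clamped, " negative branch length(s) clamped to 0")
  }
  n_internal <- n - 2L
  # renumber internal nodes: root (last created) becomes n+1, preorder after
  root_old <- u
  children <- split(seq_len(nrow(edges)), edges[, 1])
  newid <- integer(max(edges))
  newid[seq_len(n)] <- seq_len(n)
  counter <- n + 1L
  edge_out <- matrix(0L, 0, 2); len_out <- numeric(0)
  visit <- function(old) {
    newid[old] <<- counter; counter <<- counter + 1L
    for (e in children[[as.character(old)]]) {
      child <- edges[e, 2]
      if (child > n) {
        visit(child)
      }
    }
  }
  visit(root_old)
  # emit edges in preorder
  emit <- function(old) {
    for (e in children[[as.character(old)]]) {
      child <- edges[e, 2]
      edge_out <<- rbind(edge_out, c(newid[old], newid[child]))
      len_out <<- c(len_out, elens[e])
      if (child > n) emit(child)
    }
  }
  emit(root_old)
  tr <- list(edge = edge_out, edge.length = len_out, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr
}

# Tip sets below each internal node; keys are canonical bipartition strings
# (the side not containing the alphabetically smallest tip label).
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  # edges are in preorder, so walk them backwards to accumulate descendants
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  keys <- character(0); nodes <- integer(0)
  root <- n + 1L
  for (node in setdiff(seq_len(n + tree$Nnode), c(seq_len(n), root))) {
    side <- sort(desc[[node]])
    if (all_tips[1] %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2 || length(side) > length(all_tips) - 2) next
    keys <- c(keys, paste(side, collapse = "|"))
    nodes <- c(nodes, node)
  }
  setNames(keys, nodes)
}

#' Bootstrap support for an NJ tree built from an alignment
#'
#' Builds the base tree from p-distances over the full alignment, then
#' resamples alignment columns with replacement `n_replicates` times,
#' recomputes distances and the NJ tree for each replicate, and reports for
#' every internal edge of the base tree the percentage of replicates whose
#' tree contains the same bipartition.  Deterministic given `seed`.
#'
#' @param msa named character vector of gapped rows ([build_msa()]).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return the base `phylo` tree with `node.label` holding supports (root
#'   label empty) and an attribute `support` (data.frame node/support).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  base <- nj_tree(pdistance(msa))
  bip <- tree_bipartitions(base)
  counts <- setNames(numeric(length(bip)), bip)
  chars <- do.call(rbind, strsplit(msa, ""))
  rownames(chars) <- names(msa)
  L <- ncol(chars)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_msa <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                              collapse = ""), names(msa))
    rep_tree <- nj_tree(pdistance(rep_msa))
    rep_keys <- unique(tree_bipartitions(rep_tree))
    seen <- names(counts) %in% rep_keys
    counts[seen] <- counts[seen] + 1
  }
  support <- 100 * counts / n_replicates
  n <- length(base$tip.label)
  node.label <- rep("", base$Nnode)
  for (k in seq_along(bip)) {
    node <- as.integer(names(bip)[k])
    node.label[node - n] <- format(support[[k]], trim = TRUE)
  }
  base$node.label <- node.label
  attr(base, "support") <- data.frame(node = as.integer(names(bip)),
                                      bipartition = unname(bip),
                                      support = unname(support))
  base
}

#' Write a tree to newick with support values as internal node labels
#'
#' @param tree a `phylo` object (optionally with `node.label`).
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  write_lines_atomic(ape::write.tree(tree), path)
}
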