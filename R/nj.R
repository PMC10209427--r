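# Neighbour-joining on population distance matrices, with locus-bootstrap
# supports. The agglomeration is implemented here so that tie-breaking and
# the treatment of negative branch lengths are fully specified; ape supplies
# the phylo container and newick I/O.

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining with the standard Q criterion. Ties in Q
#' are broken deterministically by the (alphabetical) labels of the joined
#' nodes, a joined node inheriting the smallest label among its tips. A
#' negative branch length arising from the estimation formulas is clamped
#' to zero and the deficit moved to the sibling branch, preserving the
#' path length between the joined pair.
#'
#' @param D symmetric distance matrix with zero diagonal (labelled).
#' @return an unrooted `phylo` tree (ape) whose leaves are the row labels.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop_("distance matrix must be symmetric")
  }
  n <- nrow(D)
  if (n < 3L) stop_("need at least 3 populations")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  if (any(is.na(D))) stop_("distance matrix contains NA")
  # active node bookkeeping: newick fragment + ordering label
  frag <- labels
  ordlab <- labels
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: alphabetically smallest (label_i, label_j)
    keyi <- pmin(ordlab[cand[, 1]], ordlab[cand[, 2]])
    keyj <- pmax(ordlab[cand[, 1]], ordlab[cand[, 2]])
    pick <- order(keyi, keyj)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newlab <- min(ordlab[c(i, j)])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    ordlab <- c(ordlab[keep], newlab)
    dimnames(D2) <- NULL
    D <- D2
  }
  # final three-point resolution
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- c(b1, b2, b3)
  for (k in 1:3) if (bl[k] < 0) {
    others <- setdiff(1:3, k)
    bl[others] <- bl[others] + bl[k] / 2
    bl[k] <- 0
  }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(bl[1]),
                    frag[2], fmt(bl[2]), frag[3], fmt(bl[3]))
  ape::read.tree(text = newick)
}

# Canonical bipartitions induced by the internal edges of an unrooted tree:
# each split is represented by the sorted tip labels of the side not
# containing the reference tip (the alphabetically first label overall).
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) %in% c(0L, length(tips))) next  # root/trivial
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Neighbour-joining tree with locus-bootstrap supports
#'
#' Builds the best tree from the full data (allele frequencies, chord
#' distances, NJ), then resamples loci with replacement `n_boot` times,
#' recomputing frequencies, distances and the NJ tree per replicate.
#' The support of each internal edge of the best tree is the percentage of
#' replicates whose tree contains the same bipartition; supports are stored
#' as internal node labels so they survive newick round-trips.
#'
#' @param G a [genotype_matrix()] with at least 3 populations and 2 loci.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional RNG seed.
#' @return a `phylo` tree with node labels holding percent supports.
#' @export
bootstrap_support <- function(G, n_boot = 1000, seed = NULL) {
  if (length(populations(G)) < 3L) stop_("need at least 3 populations")
  if (length(G$loci) < 2L) stop_("need at least 2 loci for locus bootstrap")
  F <- allele_frequencies(G)
  D <- chord_distance_matrix(F)
  if (all(D < 1e-12)) {
    warn_("all populations have (near-)identical frequencies; supports are not meaningful")
  }
  best <- nj_tree(D)
  best_splits <- tree_bipartitions(best)
  hits <- stats::setNames(numeric(length(best_splits)), best_splits)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      loci_b <- sample(G$loci, replace = TRUE)
      Gb <- genotype_matrix(G$a1[, loci_b, drop = FALSE],
                            G$a2[, loci_b, drop = FALSE], G$pop,
                            loci = paste0("B", seq_along(loci_b)),
                            ids = G$ids)
      Db <- chord_distance_matrix(allele_frequencies(Gb))
      splits_b <- tree_bipartitions(nj_tree(Db))
      seen <- best_splits %in% splits_b
      hits[seen] <- hits[seen] + 1
    }
  })
  support <- 100 * hits / n_boot
  # map splits back onto internal nodes of the best tree
  tips <- best$tip.label
  ref <- sort(tips)[1]
  parts <- ape::prop.part(best)
  node_lab <- rep("", best$Nnode)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) == length(tips)) next
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      node_lab[k] <- as.character(round(support[[key]], 1))
    }
  }
  best$node.label <- node_lab
  best
}

#' Write / read a support-annotated tree as newick
#' @param tree a `phylo`.
#' @param path newick path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) ape::read.tree(path)
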