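#' Pairwise p-distance between two fingerprints
#'
#' Fraction of mismatched positions; positions where either sequence
#' carries a non-standard residue are excluded from both numerator and
#' denominator.
#'
#' @param fp_a,fp_b Equal-length amino-acid strings.
#' @return Distance in [0, 1].
#' @examples
#' p_distance("AAAA", "AAAB")  # position 4 excluded (B ambiguous) -> 0
#' p_distance("AAAA", "AAAC")  # 0.25
#' @export
p_distance <- function(fp_a, fp_b) {
  if (nchar(fp_a) != nchar(fp_b)) stop("fingerprint lengths differ")
  a <- residue_index(strsplit(fp_a, "")[[1]])
  b <- residue_index(strsplit(fp_b, "")[[1]])
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(0)
  sum(a[ok] != b[ok]) / sum(ok)
}

#' p-distance matrix over a set of fingerprints
#'
#' @param fingerprints Named character vector of equal-length sequences.
#' @return Symmetric n x n matrix with zero diagonal, entries in [0, 1],
#'   dimnames set to the sequence ids, attribute `metric` = "p-distance".
#' @export
p_distance_matrix <- function(fingerprints) {
  n <- length(fingerprints)
  chars <- seq_char_matrix(fingerprints)
  idx <- matrix(residue_index(chars), nrow = n)
  mism <- matrix(0, n, n)
  valid <- matrix(0, n, n)
  for (j in seq_len(ncol(idx))) {
    col <- idx[, j]
    std <- !is.na(col)
    both <- outer(std, std, "&")
    col0 <- col
    col0[!std] <- 0L
    mism <- mism + (outer(col0, col0, "!=") & both)
    valid <- valid + both
  }
  D <- ifelse(valid > 0, mism / valid, 0)
  diag(D) <- 0
  dimnames(D) <- list(names(fingerprints), names(fingerprints))
  attr(D, "metric") <- "p-distance"
  validate_distance_matrix(D)
  D
}

validate_distance_matrix <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q criterion is joined, with branch lengths from the usual rate-corrected
#' formulas and reduced distances d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2.
#' Ties in Q are broken deterministically toward the smallest (i, j) label
#' pair. Negative branch lengths are clamped to zero with the deficit moved
#' to the sibling edge, preserving the joined pair's path length. The
#' result is the usual unrooted tree with a basal trichotomy.
#'
#' @param D Symmetric distance matrix with zero diagonal and unique
#'   dimnames; n >= 3.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (is.null(dimnames(D)[[1]])) stop("distance matrix needs dimnames")
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  validate_distance_matrix(D)

  frag <- dimnames(D)[[1]]       # newick fragment per active cluster
  D <- unname(as.matrix(D))
  fmt <- function(x) sprintf("%.12g", max(x, 0))

  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    m <- min(Q)
    cand <- which(Q - m <= 1e-12 * max(1, abs(m)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }

  # resolve the final three clusters around the central node exactly
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

# Tip set on the child side of every edge of a phylo tree. Returns a list
# parallel to tree$edge rows; each element is a character vector of tip
# labels.
edge_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) sets[[t]] <- tree$tip.label[t]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(e) sort(sets[[tree$edge[e, 2]]]))
}

# Canonical bipartition key for a tip set: the side NOT containing the
# alphabetically first tip, sorted and pasted. Only non-trivial splits
# (2..n-2 tips a side) are informative.
bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  sets <- edge_tip_sets(tree)
  keys <- vapply(sets, function(s) {
    side <- if (ref %in% s) setdiff(tips, s) else s
    if (length(side) < 2 || length(side) > length(tips) - 2)
      return(NA_character_)
    paste(side, collapse = "|")
  }, "")
  keys
}

#' Bootstrapped neighbor-joining tree over fingerprints
#'
#' Builds the NJ tree from the full p-distance matrix, then resamples the
#' fingerprint columns with replacement `n_trials` times (the classical
#' column bootstrap), rebuilding distances and tree each trial. The support
#' of an internal edge is the fraction of trial trees containing the same
#' bipartition, stored in [0, 1] as node labels of the returned tree.
#'
#' @param fingerprints Named character vector of 36-mers.
#' @param n_trials Number of bootstrap trials (default 1000, the
#'   conventional choice; tests and desk-scale runs use 100).
#' @param seed Integer seed for the resampling.
#' @return List of class `gh57_phylo`: `tree` (an [ape::phylo] with
#'   bootstrap supports as node labels), `supports` (data.frame key /
#'   support), `n_trials`, `seed`.
#' @export
bootstrap_support <- function(fingerprints, n_trials = 1000, seed = 1602) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  tree <- neighbor_joining(p_distance_matrix(fingerprints))
  keys0 <- bipartition_keys(tree)
  informative <- !is.na(keys0)
  counts <- setNames(rep(0, sum(informative)), keys0[informative])

  chars <- seq_char_matrix(fingerprints)
  ncol_fp <- ncol(chars)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      cols <- sample.int(ncol_fp, ncol_fp, replace = TRUE)
      fps_b <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      names(fps_b) <- names(fingerprints)
      tb <- neighbor_joining(p_distance_matrix(fps_b))
      kb <- bipartition_keys(tb)
      hit <- names(counts) %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / n_trials

  # attach supports as node labels (child node of each internal edge)
  nt <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    if (!is.na(keys0[e])) {
      chd <- tree$edge[e, 2]
      if (chd > nt)
        node_lab[chd - nt] <- sprintf("%.3f", support[[keys0[e]]])
    }
  }
  tree$node.label <- node_lab
  structure(list(tree = tree,
                 supports = data.frame(key = names(support),
                                       support = unname(support),
                                       stringsAsFactors = FALSE),
                 n_trials = n_trials, seed = seed),
            class = "gh57_phylo")
}

#' Monophyly fraction of labeled groups on an unrooted tree
#'
#' For each group the score is 1 if some edge of the tree induces exactly
#' the group's leaf set on one side; otherwise it is the best Jaccard
#' overlap between the group and any edge-induced leaf set (either side).
#' Terminal edges count, so singleton groups always score 1.
#'
#' @param tree An [ape::phylo].
#' @param labels Named character vector mapping every tip label to a group.
#' @return Named numeric vector of per-group scores in (0, 1].
#' @export
monophyly_fraction <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("labels must cover all tree leaves")
  labels <- labels[tips]
  sets <- edge_tip_sets(tree)
  groups <- sort(unique(labels))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  vapply(setNames(groups, groups), function(g) {
    S <- tips[labels == g]
    best <- 0
    for (s in sets) {
      best <- max(best, jac(S, s), jac(S, setdiff(tips, s)))
      if (best == 1) break
    }
    best
  }, 0)
}

#' Write a tree with supports to Newick
#'
#' @param phy A `gh57_phylo` or [ape::phylo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(phy, path) {
  tree <- if (inherits(phy, "gh57_phylo")) phy$tree else phy
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(tree, file = path)
  invisible(path)
}
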