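# Independent oracles used to validate the dynamic-programming placement
# and the neighbor-joining implementation. These deliberately avoid the
# code paths they check.

# Exhaustive enumeration of every valid ordered placement of the five CSR
# windows; returns the leftmost maximum-score placement. Enumerates
# non-decreasing slack tuples via combinations, in lexicographic order, so
# the first argmax is the lexicographically smallest placement.
brute_force_placement <- function(sequence, profiles,
                                  schema = fingerprint_schema(),
                                  min_spacer = 5L) {
  widths <- schema$csr_spans$width
  res_idx <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)
  L <- length(res_idx)
  slack <- L - sum(widths) - 4L * min_spacer
  stopifnot(slack >= 0)
  W <- lapply(1:5, function(k) {
    w <- widths[k]
    vapply(seq_len(L - w + 1L), function(s) {
      v <- profiles$csr[[k]]$logodds[cbind(res_idx[s:(s + w - 1L)],
                                           seq_len(w))]
      v[is.na(v)] <- 0
      sum(v)
    }, 0)
  })
  offs <- cumsum(c(0, widths[1:4] + min_spacer))
  u <- utils::combn(slack + 5L, 5L)        # strictly increasing tuples
  v <- u - (0:4)                           # non-decreasing slack tuples
  starts <- v + offs                       # 5 x ncomb matrix of starts
  total <- W[[1]][starts[1, ]] + W[[2]][starts[2, ]] +
    W[[3]][starts[3, ]] + W[[4]][starts[4, ]] + W[[5]][starts[5, ]]
  best <- which.max(total)                 # first occurrence = leftmost
  list(starts = starts[, best], total = total[best])
}

# Least-squares branch-length fit of a fixed topology to a distance
# matrix; returns the residual sum of squares. Exhaustive search over
# phangorn::allTrees is the oracle for NJ on additive matrices.
ls_rss <- function(topology, D) {
  tips <- rownames(D)
  stopifnot(setequal(topology$tip.label, tips))
  pairs <- t(utils::combn(length(tips), 2))
  nedge <- nrow(topology$edge)
  A <- matrix(0, nrow(pairs), nedge)
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- match(tips[pairs[r, 1]], topology$tip.label)
    j <- match(tips[pairs[r, 2]], topology$tip.label)
    path <- ape::nodepath(topology, i, j)
    for (s in seq_len(length(path) - 1)) {
      e <- which((topology$edge[, 1] == path[s] &
                    topology$edge[, 2] == path[s + 1]) |
                   (topology$edge[, 1] == path[s + 1] &
                      topology$edge[, 2] == path[s]))
      A[r, e] <- 1
    }
    d[r] <- D[tips[pairs[r, 1]], tips[pairs[r, 2]]]
  }
  fit <- lm.fit(A, d)
  sum(fit$residuals^2)
}

# Best topology for D among all unrooted topologies on its taxa (n <= 6).
best_ls_topology <- function(D) {
  tips <- rownames(D)
  topos <- phangorn::allTrees(length(tips), rooted = FALSE,
                              tip.label = tips)
  rss <- vapply(topos, ls_rss, 0, D = D)
  topos[[which.min(rss)]]
}
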