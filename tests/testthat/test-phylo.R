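test_that("p-distance counts mismatches over comparable positions", {
  fp <- paste(rep("A", 36), collapse = "")
  expect_equal(p_distance(fp, fp), 0)
  nine <- paste0(strrep("C", 9), strrep("A", 27))
  expect_equal(p_distance(fp, nine), 0.25)        # 9 of 36
  expect_equal(p_distance(fp, strrep("W", 36)), 1)
  # ambiguous residues drop out of numerator and denominator
  expect_equal(p_distance("AAAX", "AAAC"), 0)
  expect_equal(p_distance("CAAX", "AAAC"), 1 / 3)
  expect_error(p_distance("AA", "AAA"), "lengths differ")
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  fx <- small_fixture()
  fps <- setNames(fx$ds$truth$fingerprint[!fx$ds$truth$decoy],
                  fx$ds$truth$id[!fx$ds$truth$decoy])[1:40]
  D <- p_distance_matrix(fps)
  expect_true(isSymmetric(unname(D)))
  expect_equal(unname(diag(D)), rep(0, 40))
  expect_true(all(D >= 0 & D <= 1))
  expect_identical(attr(D, "metric"), "p-distance")
  # matrix agrees with the pairwise scalar definition
  for (i in c(1, 7, 19)) for (j in c(3, 25))
    expect_equal(D[i, j], p_distance(fps[[i]], fps[[j]]))
})

test_that("neighbor joining recovers the 4-taxon additive tree exactly", {
  # distances from the tree ((A:2,B:3):1,(C:4,D:5))
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_identical(sort(tr$tip.label), LETTERS[1:4])
  # the reconstructed tree reproduces the additive distances, hence the
  # split AB|CD and the generating branch lengths
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               ignore_attr = TRUE)
  ab_edge <- ape::getMRCA(ape::root(tr, "C"), c("A", "B"))
  expect_identical(sort(ape::extract.clade(ape::root(tr, "C"),
                                           ab_edge)$tip.label), c("A", "B"))
})

test_that("three taxa resolve with the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("neighbor joining validates its input", {
  D2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_error(neighbor_joining(D2), "at least 3")
  D3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
})

test_that("leaf set equals the input id set", {
  gh57csr:::with_seed(4, {
    for (n in c(5, 11, 23)) {
      fps <- setNames(vapply(seq_len(n), function(i) random_aa(36), ""),
                      paste0("s", seq_len(n)))
      tr <- neighbor_joining(p_distance_matrix(fps))
      expect_setequal(tr$tip.label, names(fps))
      expect_true(all(tr$edge.length >= 0))
    }
  })
})

test_that("topologies agree with an independent NJ implementation", {
  gh57csr:::with_seed(12, {
    for (i in 1:10) {
      n <- sample(5:12, 1)
      ref <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1))
      D <- ape::cophenetic.phylo(ref)
      D <- D + matrix(stats::runif(n * n, 0, 1e-4), n, n)  # break ties
      D <- (D + t(D)) / 2
      diag(D) <- 0
      t_ours <- neighbor_joining(D)
      t_ape <- ape::nj(D)
      expect_equal(ape::dist.topo(ape::unroot(t_ours), ape::unroot(t_ape)),
                   0, ignore_attr = TRUE)
    }
  })
})

test_that("column bootstrap is deterministic and well-scaled", {
  fx <- small_fixture()
  tr <- fx$ds$truth[!fx$ds$truth$decoy, ]
  fps <- setNames(tr$fingerprint, tr$id)[seq(1, 160, by = 8)]
  b1 <- bootstrap_support(fps, n_trials = 25, seed = 6)
  b2 <- bootstrap_support(fps, n_trials = 25, seed = 6)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports$support >= 0 & b1$supports$support <= 1))
  one <- bootstrap_support(fps, n_trials = 1, seed = 6)
  expect_true(all(one$supports$support %in% c(0, 1)))
})

test_that("well-separated groups get near-unit support between them", {
  fx <- small_fixture()
  cons <- fx$ds$consensus
  gh57csr:::with_seed(8, {
    emit <- function(g, n) vapply(seq_len(n), function(i) {
      fp <- strsplit(cons[[g]], "")[[1]]
      flip <- sample(36, 2)                   # light within-group noise
      for (p in flip) fp[p] <- sample(AA_ALPHABET, 1)
      paste(fp, collapse = "")
    }, "")
    fps <- c(setNames(emit("AAMY", 8), paste0("a", 1:8)),
             setNames(emit("GBE", 8), paste0("g", 1:8)))
    ph <- bootstrap_support(fps, n_trials = 100, seed = 13)
    # the bipartition separating the two groups exists and is strong
    tips <- sort(names(fps))
    side <- paste0("g", 1:8)
    if (tips[1] %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    expect_true(key %in% ph$supports$key)
    expect_gte(ph$supports$support[ph$supports$key == key], 0.95)
  })
})

test_that("monophyly fraction is 1 for clean clades and less when split", {
  cfg <- synthetic_config(counts = setNames(c(8, 0, 8, 0, 8, 0, 0, 0, 0, 0,
                                              0, 8, 8, 0),
                                            default_catalogue()$group),
                          seed = 14, conservation = 1, dropout_fraction = 0)
  ds <- generate_dataset(cfg)
  fps <- setNames(ds$truth$fingerprint, ds$truth$id)
  labels <- setNames(ds$truth$group, ds$truth$id)
  tr <- neighbor_joining(p_distance_matrix(fps))
  mf <- monophyly_fraction(tr, labels)
  expect_equal(unname(mf), rep(1, length(mf)))
  # relabel one member of another group into AAMY: no edge isolates the
  # union, so the score drops below 1
  bad <- labels
  bad[which(bad == "GBE")[1]] <- "AAMY"
  expect_lt(monophyly_fraction(tr, bad)[["AAMY"]], 1)
  # singleton groups always score 1 via their terminal edge
  single <- labels
  single[1] <- "lonely"
  expect_equal(monophyly_fraction(tr, single)[["lonely"]], 1)
  expect_error(monophyly_fraction(tr, labels[-1]), "cover")
})

test_that("newick output preserves topology and supports", {
  fx <- small_fixture()
  tr <- fx$ds$truth[!fx$ds$truth$decoy, ]
  fps <- setNames(tr$fingerprint, tr$id)[1:12]
  ph <- bootstrap_support(fps, n_trials = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(ph, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, names(fps))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(ph$tree)), 0,
               ignore_attr = TRUE)
})
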