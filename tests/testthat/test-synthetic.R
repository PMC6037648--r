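test_that("group consensi obey catalytic and diagnostic constraints", {
  cat <- default_catalogue()
  rules <- diagnostic_rules()
  for (seed in c(1602, 7, 99)) {
    cons <- build_group_consensus(cat, rules, seed)
    for (g in names(cons)) {
      expect_identical(substr(cons[[g]], 15, 15), "E")
      expect_identical(substr(cons[[g]], 20, 20), "D")
    }
    expect_identical(substr(cons[["AAMY"]], 35, 36), "YY")
    expect_identical(substr(cons[["4AGT"]], 23, 23), "K")
    expect_identical(substr(cons[["MGA"]], 35, 36), "FW")
    expect_identical(substr(cons[["AGAL"]], 35, 36), "GW")
  }
})

test_that("consensus pairs differ at no fewer than 8 free positions", {
  cons <- build_group_consensus(default_catalogue(), diagnostic_rules(),
                                1602)
  free <- setdiff(1:36, c(1, 12, 15, 20, 23, 35, 36))
  mats <- lapply(cons, function(x) strsplit(x, "")[[1]][free])
  for (i in seq_along(mats)) for (j in seq_len(i - 1))
    expect_gte(sum(mats[[i]] != mats[[j]]), 8)
})

test_that("emitted sequences embed their fingerprint at recorded coords", {
  fx <- small_fixture()
  tr <- fx$ds$truth[!fx$ds$truth$decoy, ]
  for (i in seq_len(nrow(tr))) {
    s <- fx$ds$sequences[[tr$id[i]]]
    fp <- paste(substring(s, unlist(tr[i, paste0("csr", 1:5, "_start")]),
                          unlist(tr[i, paste0("csr", 1:5, "_end")])),
                collapse = "")
    expect_identical(nchar(fp), 36L)
    expect_identical(fp, tr$fingerprint[i])
  }
  # CSR ranges ordered with the minimum spacer respected
  starts <- as.matrix(tr[, paste0("csr", 1:5, "_start")])
  ends <- as.matrix(tr[, paste0("csr", 1:5, "_end")])
  expect_true(all(starts[, 2:5] - ends[, 1:4] - 1 >= fx$cfg$min_spacer))
})

test_that("machinery is complete for enzymes and broken for like groups", {
  fx <- small_fixture()
  tr <- fx$ds$truth[!fx$ds$truth$decoy, ]
  kind <- default_catalogue()$kind[match(tr$group, default_catalogue()$group)]
  e15 <- substr(tr$fingerprint, 15, 15)
  d20 <- substr(tr$fingerprint, 20, 20)
  expect_true(all(e15[kind == "enzyme"] == "E"))
  expect_true(all(d20[kind == "enzyme"] == "D"))
  expect_true(all(tr$machinery[kind == "enzyme"] == "complete"))
  # like members never retain the full pair
  expect_false(any(e15[kind == "like"] == "E" & d20[kind == "like"] == "D"))
  expect_true(all(tr$machinery[kind == "like"] != "complete"))
})

test_that("taxonomy labels honour the catalogue splits", {
  fx <- small_fixture()
  tr <- fx$ds$truth[!fx$ds$truth$decoy, ]
  expect_true(all(tr$taxonomy[tr$group == "GBE-like"] == "bacterial"))
  expect_true(all(tr$taxonomy[tr$group == "MGA"] == "archaeal"))
  expect_true(all(tr$taxonomy[tr$group == "AGAL"] == "archaeal"))
})

test_that("sequence lengths concentrate around the group mean", {
  fx <- small_fixture()
  tr <- fx$ds$truth[!fx$ds$truth$decoy, ]
  cat <- default_catalogue()
  for (g in c("AAMY", "APU", "GBE")) {
    mu <- cat$mean_length[cat$group == g]
    len <- tr$length[tr$group == g]
    expect_true(all(abs(len - mu) <= 3 * fx$cfg$length_jitter * mu))
  }
})

test_that("catalytic knockouts substitute the right residues and label", {
  fx <- small_fixture()
  cons <- fx$ds$consensus
  with_seed <- gh57csr:::with_seed
  with_seed(5, {
    rec <- emit_sequence("AAMY", cons, fx$cfg)
    ko <- knock_out_catalytics(rec, "nucleophile")
    expect_identical(ko$group, "AAMY-like")
    expect_identical(ko$machinery, "nucleophile-substituted")
    expect_false(substr(ko$fingerprint, 15, 15) == "E")
    expect_identical(substr(ko$fingerprint, 20, 20),
                     substr(rec$fingerprint, 20, 20))
    # the full sequence was edited at the mapped coordinate
    pos15 <- ko$csr$start[3] + 3
    expect_identical(substr(ko$sequence, pos15, pos15),
                     substr(ko$fingerprint, 15, 15))

    rec4 <- emit_sequence("4AGT", cons, fx$cfg)
    ko4 <- knock_out_catalytics(rec4, "both")
    expect_identical(ko4$machinery, "both-substituted")
    expect_false(substr(ko4$fingerprint, 15, 15) == "E")
    expect_false(substr(ko4$fingerprint, 20, 20) == "D")

    kod <- knock_out_catalytics(emit_sequence("GBE", cons, fx$cfg), "donor")
    expect_identical(substr(kod$fingerprint, 15, 15), "E")  # untouched
    expect_error(knock_out_catalytics(kod, "donor"), "complete")
    expect_error(knock_out_catalytics(rec, "everything"))
  })
})

test_that("dataset generation is deterministic and decodes its config", {
  cfg <- synthetic_config(counts = small_counts(), seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$truth, d2$truth)
  # byte-identical files on rewrite
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  write_dataset(d1, t1)
  write_dataset(d2, t2)
  for (f in c("sequences.fasta", "truth.tsv", "manifest.json"))
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
  expect_identical(nrow(d1$truth),
                   as.integer(sum(cfg$counts) +
                                round(cfg$dropout_fraction * sum(cfg$counts))))
  expect_false(any(duplicated(d1$truth$id)))
})

test_that("zero counts yield an empty dataset", {
  cfg <- synthetic_config(counts = setNames(rep(0L, 14),
                                            default_catalogue()$group))
  ds <- generate_dataset(cfg)
  expect_identical(length(ds$sequences), 0L)
  expect_identical(nrow(ds$truth), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(conservation = 0), "conservation")
  expect_error(synthetic_config(conservation = 1.2), "conservation")
  expect_error(synthetic_config(counts = c(AAMY = -1)), ">= 0")
  bad <- setNames(rep(0.1, 20), AA_ALPHABET)
  expect_error(synthetic_config(linker_composition = bad), "sum to 1")
})
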