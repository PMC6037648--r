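mk_fp <- function(base = strrep("A", 36), ...) {
  subs <- list(...)
  for (pos in names(subs)) {
    p <- as.integer(pos)
    substr(base, p, p) <- subs[[pos]]
  }
  base
}

test_that("catalytic machinery status follows positions 15 and 20", {
  expect_identical(check_catalytic_machinery(mk_fp(`15` = "E", `20` = "D")),
                   "complete")
  expect_identical(check_catalytic_machinery(mk_fp(`15` = "Q", `20` = "D")),
                   "nucleophile-substituted")
  expect_identical(check_catalytic_machinery(mk_fp(`15` = "E", `20` = "N")),
                   "donor-substituted")
  expect_identical(check_catalytic_machinery(mk_fp(`15` = "Q", `20` = "N")),
                   "both-substituted")
  expect_error(check_catalytic_machinery("SHORT"), "length 36")
})

test_that("diagnostic flags recognize the documented group features", {
  fl <- diagnostic_match(mk_fp(`23` = "T", `35` = "Y", `36` = "Y"))
  expect_true(fl["AAMY", "p23"])
  expect_true(fl["AAMY", "pair"])
  expect_false(fl["NSA", "pair"])
  expect_true(diagnostic_match(mk_fp(`35` = "G", `36` = "W"))["AGAL", "pair"])
  expect_true(diagnostic_match(mk_fp(`35` = "T", `36` = "K"))["AGAL-related",
                                                              "pair"])
  expect_true(diagnostic_match(mk_fp(`35` = "T", `36` = "H"))["AGAL-related",
                                                              "pair"])
  # GBE accepts any non-aromatic terminal residue after F
  expect_true(diagnostic_match(mk_fp(`35` = "F", `36` = "A"))["GBE", "pair"])
  expect_false(diagnostic_match(mk_fp(`35` = "F", `36` = "W"))["GBE", "pair"])
  # groups without a documented rule stay NA
  expect_true(is.na(diagnostic_match(mk_fp())["APU-CMD", "p23"]))
})

test_that("every group consensus scores highest against its own profile", {
  fx <- small_fixture()
  for (g in names(fx$pr$classify)) {
    sc <- score_against_groups(fx$ds$consensus[[g]], fx$pr$classify)
    expect_identical(names(which.max(sc)), g)
  }
})

test_that("score ties break deterministically by name", {
  # two artificial groups whose profiles are mirror images; a half-and-half
  # fingerprint scores identically against both
  a <- strrep("A", 36)
  b <- paste0(strrep("C", 18), strrep("A", 18))
  mixed <- paste0(strrep("C", 9), strrep("A", 27))  # matches b at 9, a at 27
  profs <- list(G2 = profiles_from_alignment(rep(a, 10)),
                G1 = profiles_from_alignment(rep(b, 10)))
  sc <- score_against_groups(mixed, profs)
  expect_equal(unname(sc["G1"]), unname(sc["G2"]), tolerance = 1e-12)
  fl <- matrix(NA, 2, 2, dimnames = list(c("G1", "G2"), c("p23", "pair")))
  asn <- assign_group(mixed, "complete", sc, fl)
  expect_identical(asn$best_group, "G1")   # lexicographic tie-break
})

test_that("assignment follows machinery, threshold and best group", {
  fx <- small_fixture()
  profs <- fx$pr$classify
  fp <- fx$ds$consensus[["AAMY"]]
  sc <- score_against_groups(fp, profs)
  fl <- diagnostic_match(fp)
  base <- assign_group(fp, "complete", sc, fl)
  expect_identical(base$label, "AAMY")
  expect_false(base$diagnostic_warning)
  # knocked-out nucleophile moves to the like partner without changing
  # the best base group
  fpq <- fp
  substr(fpq, 15, 15) <- "Q"
  scq <- score_against_groups(fpq, profs)
  asq <- assign_group(fpq, check_catalytic_machinery(fpq), scq,
                      diagnostic_match(fpq))
  expect_identical(asq$best_group, "AAMY")
  expect_identical(asq$label, "AAMY-like")
  # a background fingerprint scores under the threshold
  gh57csr:::with_seed(3, {
    junk <- random_aa(36)
    scj <- score_against_groups(junk, profs)
    expect_identical(assign_group(junk, "both-substituted", scj,
                                  diagnostic_match(junk))$label,
                     "unclassified")
  })
})

test_that("knockouts always re-label to the partner like group", {
  fx <- small_fixture()
  profs <- fx$pr$classify
  enzymes <- names(profs)
  gh57csr:::with_seed(17, {
    for (i in 1:50) {
      g <- sample(enzymes, 1)
      rec <- emit_sequence(g, fx$ds$consensus, fx$cfg)
      sc0 <- score_against_groups(rec$fingerprint, profs)
      if (names(which.max(sc0)) != g) next  # only correctly classified ones
      ko <- knock_out_catalytics(rec, sample(c("nucleophile", "donor",
                                               "both"), 1))
      sc1 <- score_against_groups(ko$fingerprint, profs)
      asn <- assign_group(ko$fingerprint,
                          check_catalytic_machinery(ko$fingerprint),
                          sc1, diagnostic_match(ko$fingerprint))
      expect_identical(asn$best_group, g)
      expect_identical(asn$label, partner_like_label(g))
    }
  })
})

test_that("assignment is a pure function of its inputs", {
  fx <- small_fixture()
  fp <- fx$ds$truth$fingerprint[1]
  sc <- score_against_groups(fp, fx$pr$classify)
  fl <- diagnostic_match(fp)
  a1 <- assign_group(fp, "complete", sc, fl)
  a2 <- assign_group(fp, "complete", sc, fl)
  expect_identical(a1, a2)
})

test_that("summaries reconcile with their inputs", {
  fx <- small_fixture()
  det <- detect_fingerprints(fx$ds$sequences, fx$pr$detect)
  asg <- classify_fingerprints(det, fx$pr$classify)
  tax <- setNames(fx$ds$truth$taxonomy, fx$ds$truth$id)
  sm <- summarize_assignments(asg, tax)
  expect_identical(sum(sm$n), nrow(asg))
  expect_true(all(sm$n_archaea + sm$n_bacteria <= sm$n))
  # empty input
  empty <- summarize_assignments(asg[0, ])
  expect_identical(nrow(empty), 0L)
  # archaeal-only subset has no bacterial counts
  arch <- asg[asg$id %in% names(tax)[tax == "archaeal"], ]
  sm_a <- summarize_assignments(arch, tax)
  expect_identical(sum(sm_a$n_bacteria), 0L)
  expect_identical(sum(sm_a$n), nrow(arch))
})
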