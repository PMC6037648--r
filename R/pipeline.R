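#' Train detection and classification profiles from the group consensi
#'
#' Generates a seeded training set of fingerprints per group (free
#' positions flipped with probability `1 - conservation`, catalytic and
#' diagnostic positions held fixed) and builds three profile collections:
#' `detect`, per-group profile sets over all 14 groups used during CSR
#' location (like-group training fingerprints carry knocked-out catalytic
#' residues, as the real family alignment does); `classify`,
#' per-enzyme-group sets used to decide specificity; and `pooled`, the
#' all-groups mixture profile. Detection scans with the per-group sets and
#' keeps the best-scoring placement, so the elimination floor is
#' calibrated against a profile the sequence could actually match —
#' a pooled mixture systematically under-scores minority and like groups.
#'
#' @param config A `gh57_synth_config` (supplies consensi, conservation and
#'   the catalogue).
#' @param rules A `gh57_rules` table.
#' @param n_per_group Training fingerprints per group (default 60).
#' @param pseudocount Profile pseudocount (default 1, add-one smoothing:
#'   keeps per-position mismatch penalties bounded so elimination tests
#'   the presence of a region rather than punishing point variation).
#' @param seed Seed for the training draws; defaults to a stream derived
#'   from the config seed.
#' @return List with elements `detect` (named list of `gh57_profiles`,
#'   all groups), `classify` (named list over enzyme groups) and `pooled`
#'   (single `gh57_profiles`).
#' @export
train_profiles <- function(config = synthetic_config(),
                           rules = diagnostic_rules(),
                           n_per_group = 60, pseudocount = 1,
                           seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(config$seed, 3)
  consensus <- group_consensus_map(config, rules)
  schema <- fingerprint_schema()
  free <- free_positions(schema)
  cat <- config$catalogue

  sample_fps <- function(cons, n, knockout) {
    base <- strsplit(cons, "")[[1]]
    vapply(seq_len(n), function(i) {
      fp <- base
      flip <- free[stats::runif(length(free)) > config$conservation]
      for (p in flip) fp[p] <- sample(setdiff(AA_ALPHABET, base[p]), 1)
      if (knockout) {
        mode <- sample(names(config$knockout_probs), 1,
                       prob = config$knockout_probs)
        if (mode %in% c("nucleophile", "both"))
          fp[schema$nucleophile_pos] <- sample(setdiff(AA_ALPHABET, "E"), 1)
        if (mode %in% c("donor", "both"))
          fp[schema$donor_pos] <- sample(setdiff(AA_ALPHABET, "D"), 1)
      }
      paste(fp, collapse = "")
    }, "")
  }

  with_seed(seed, {
    train <- lapply(setNames(cat$group, cat$group), function(g)
      sample_fps(consensus[[g]], n_per_group, cat$kind[cat$group == g] == "like"))
    enzymes <- cat$group[cat$kind == "enzyme"]
    mk <- function(fps) profiles_from_alignment(fps, pseudocount = pseudocount,
                                                schema = schema)
    list(
      detect = lapply(train, mk),
      classify = lapply(train[enzymes], mk),
      pooled = mk(unlist(train, use.names = FALSE))
    )
  })
}

#' Simulate a dataset and write it to disk
#'
#' Wraps [generate_dataset()] and [write_dataset()]; the manifest records
#' the seed and a configuration hash so reruns are verifiable.
#'
#' @param config A `gh57_synth_config`.
#' @param out_dir Output directory.
#' @param rules A `gh57_rules` table.
#' @return Invisibly, the `gh57_dataset` with an attribute `paths`.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir,
                         rules = diagnostic_rules()) {
  ds <- generate_dataset(config, rules)
  paths <- write_dataset(ds, out_dir)
  attr(ds, "paths") <- paths
  invisible(ds)
}

#' Run the full CSR analysis pipeline on a FASTA input
#'
#' Stages, in order: CSR detection (with elimination of sequences lacking
#' a region), classification by catalytic machinery and profile score,
#' per-group sequence-logo matrices, and a bootstrapped neighbor-joining
#' tree over the fingerprints (subsampled to at most `max_tree_leaves`
#' leaves, stratified by assigned label, for tractability). Eliminated
#' sequences are excluded from all downstream stages and reported in the
#' summary. All TSV outputs carry `# seed=` and `# config=` header lines.
#'
#' @param fasta Path to the input FASTA.
#' @param out_dir Output directory.
#' @param profiles Profile list as returned by [train_profiles()]; built
#'   from the default synthetic configuration when NULL.
#' @param seed Integer seed controlling subsampling and bootstrap.
#' @param bootstrap_trials Bootstrap trials for the tree (default 1000).
#' @param score_floor Per-CSR elimination floor fraction (default 0.3).
#' @param threshold Classification score threshold (default 0).
#' @param max_tree_leaves Leaf cap for the tree stage (default 200).
#' @param rules,catalogue,schema Configuration objects.
#' @return Invisibly, a list with `detections`, `assignments`, `summary`,
#'   `logos`, `phylo`, `paths`.
#' @export
run_analyze <- function(fasta, out_dir, profiles = NULL, seed = 1602,
                        bootstrap_trials = 1000, score_floor = 0.3,
                        threshold = 0, max_tree_leaves = 200,
                        rules = diagnostic_rules(),
                        catalogue = default_catalogue(),
                        schema = fingerprint_schema()) {
  seqs <- read_fasta(fasta)
  if (is.null(profiles)) profiles <- train_profiles()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("seed=", seed),
           paste0("config=", fnv1a_hash(paste(seed, score_floor, threshold,
                                              bootstrap_trials,
                                              max_tree_leaves))))

  det <- detect_fingerprints(seqs, profiles$detect, schema,
                             score_floor = score_floor)
  n_elim <- sum(det$status != "accepted")
  message(sprintf("detect: %d sequences read, %d eliminated",
                  nrow(det), n_elim))
  write_tsv_with_header(det, file.path(out_dir, "fingerprints.tsv"), hdr)

  asg <- classify_fingerprints(det, profiles$classify, rules, threshold,
                               catalogue)
  message(sprintf("classify: %d classified, %d unclassified",
                  sum(!asg$label %in% c("eliminated", "unclassified")),
                  sum(asg$label == "unclassified")))
  write_tsv_with_header(asg, file.path(out_dir, "assignments.tsv"), hdr)

  smry <- summarize_assignments(asg)
  write_tsv_with_header(smry, file.path(out_dir, "summary.tsv"), hdr)

  ok <- asg$label != "eliminated"
  fps <- setNames(det$fingerprint[ok], det$id[ok])
  labels <- setNames(asg$label[ok], asg$id[ok])
  grouped <- split(fps, labels[names(fps)])
  logos <- lapply(names(grouped), function(g)
    logo_from_fingerprints(grouped[[g]], group = g, schema = schema))
  names(logos) <- names(grouped)
  write_logos_json(logos, file.path(out_dir, "logos.json"),
                   meta = list(seed = seed))

  phylo <- NULL
  if (length(fps) >= 3) {
    keep <- stratified_subsample(names(fps), labels[names(fps)],
                                 max_tree_leaves, derive_seed(seed, 4))
    phylo <- bootstrap_support(fps[keep], n_trials = bootstrap_trials,
                               seed = derive_seed(seed, 5))
    write_tree_newick(phylo, file.path(out_dir, "tree.nwk"))
    write_tsv_with_header(
      data.frame(id = keep, label = unname(labels[keep])),
      file.path(out_dir, "tree_annotation.tsv"), hdr)
  } else {
    # nothing tree-worthy survived detection; record the empty result
    writeLines(";", file.path(out_dir, "tree.nwk"))
  }

  out <- list(detections = det, assignments = asg, summary = smry,
              logos = logos, phylo = phylo,
              paths = file.path(out_dir,
                                c("fingerprints.tsv", "assignments.tsv",
                                  "summary.tsv", "logos.json", "tree.nwk")))
  invisible(out)
}

# Proportional stratified subsample of ids by label, at least one member
# per label, deterministic given the seed.
stratified_subsample <- function(ids, labels, max_n, seed) {
  if (length(ids) <= max_n) return(ids)
  with_seed(seed, {
    by_lab <- split(ids, labels)
    quota <- pmax(1L, floor(lengths(by_lab) / length(ids) * max_n))
    # trim overshoot from the largest strata
    while (sum(quota) > max_n) {
      k <- which.max(quota)
      quota[k] <- quota[k] - 1L
    }
    unlist(Map(function(v, q) if (length(v) <= q) v else sample(v, q),
               by_lab, quota), use.names = FALSE)
  })
}
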