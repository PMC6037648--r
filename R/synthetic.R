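#' Configuration for the synthetic GH57 dataset generator
#'
#' The generator emulates the statistical structure of the 1602-sequence
#' GH57 study set: 14 labeled groups with their member counts,
#' archaeal/bacterial split and mean sequence lengths, group-specific
#' 36-position fingerprints embedded in unalignable linker sequence, "like"
#' proteins with substituted catalytic residues, and a small fraction of
#' decoy sequences lacking one CSR to exercise the elimination rule.
#'
#' @param seed Integer master seed (default 1602; arbitrary, fixed for
#'   reproducibility).
#' @param catalogue A `gh57_catalogue` supplying group structure and
#'   defaults.
#' @param counts Named integer vector of per-group member counts; defaults
#'   to the catalogue counts.
#' @param conservation Probability that a non-diagnostic fingerprint
#'   position matches its group consensus (default 0.9).
#' @param linker_composition Background amino-acid distribution for linker
#'   residues; named probability vector over [AA_ALPHABET] (default
#'   uniform).
#' @param length_jitter Fractional standard deviation of sequence length
#'   around the group mean (default 0.1).
#' @param dropout_fraction Fraction of additional decoy sequences generated
#'   with one CSR excised (default 0.02).
#' @param min_spacer Minimum number of linker residues between consecutive
#'   CSRs (default 5).
#' @param like_divergence Number of free fingerprint positions at which a
#'   like-group consensus diverges from its partner enzyme consensus
#'   (default 12: large enough that like lineages form their own
#'   clusters beside the partner enzyme clade, as in the family tree).
#' @param knockout_probs Probabilities of the nucleophile / donor / both
#'   substitution modes for like-group members.
#' @return A list of class `gh57_synth_config`.
#' @export
synthetic_config <- function(seed = 1602,
                             catalogue = default_catalogue(),
                             counts = NULL,
                             conservation = 0.9,
                             linker_composition = NULL,
                             length_jitter = 0.1,
                             dropout_fraction = 0.02,
                             min_spacer = 5L,
                             like_divergence = 12L,
                             knockout_probs = c(nucleophile = 0.4,
                                                donor = 0.4, both = 0.2)) {
  if (is.null(counts)) counts <- setNames(catalogue$n, catalogue$group)
  if (is.null(linker_composition))
    linker_composition <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!(conservation > 0 && conservation <= 1))
    stop("conservation must be in (0, 1]")
  if (abs(sum(linker_composition) - 1) > 1e-8)
    stop("linker_composition must sum to 1")
  if (abs(sum(knockout_probs) - 1) > 1e-8)
    stop("knockout_probs must sum to 1")
  structure(list(
    seed = as.integer(seed), catalogue = catalogue, counts = counts,
    conservation = conservation, linker_composition = linker_composition,
    length_jitter = length_jitter, dropout_fraction = dropout_fraction,
    min_spacer = as.integer(min_spacer),
    like_divergence = as.integer(like_divergence),
    knockout_probs = knockout_probs
  ), class = "gh57_synth_config")
}

# positions free of catalytic/diagnostic constraints (29 of 36)
free_positions <- function(schema = fingerprint_schema()) {
  setdiff(1:36, c(schema$nucleophile_pos, schema$donor_pos,
                  schema$diagnostic_positions))
}

#' Build the per-group 36-residue consensus fingerprints
#'
#' Models the family structure of the CSRs: the five regions are the best
#' conserved segments of the whole family, on top of which each enzyme
#' specificity carries its own near-invariant features. A family-wide base
#' consensus is drawn once, and each enzyme group's consensus mutates
#' `group_divergence` of the 29 free positions away from it, so that CSRs
#' stay detectable family-wide while groups remain separable. Every
#' enzyme-group consensus carries the catalytic glutamate at position 15
#' and aspartate at position 20, and obeys the diagnostic-position rules
#' (e.g. K at position 23 for 4AGT, the YY terminal pair for AAMY);
#' diagnostic positions without a documented rule inherit the family base
#' residue. Consensi are redrawn until every pair differs at no fewer than
#' `min_pair_diff` free positions.
#'
#' @param catalogue A `gh57_catalogue`.
#' @param rules A `gh57_rules` table covering all enzyme groups.
#' @param seed Integer seed.
#' @param min_pair_diff Minimum pairwise consensus difference over the free
#'   positions (default 12: large enough that like lineages form their own
#'   clusters beside the partner enzyme clade, as in the family tree).
#' @param group_divergence Number of free positions each group's consensus
#'   mutates away from the family base (default 6).
#' @return Named list mapping each enzyme group to a 36-character
#'   consensus, with the family base consensus in attribute `base`.
#' @examples
#' cons <- build_group_consensus(default_catalogue(), diagnostic_rules(), 1602)
#' substr(cons[["4AGT"]], 23, 23)  # "K"
#' @export
build_group_consensus <- function(catalogue, rules, seed,
                                  min_pair_diff = 8L,
                                  group_divergence = 6L) {
  enzymes <- catalogue$group[catalogue$kind == "enzyme"]
  missing <- setdiff(enzymes, names(rules))
  if (length(missing))
    stop("diagnostic rules missing for enzyme groups: ",
         paste(missing, collapse = ", "))
  schema <- fingerprint_schema()
  free <- free_positions(schema)
  if (group_divergence > length(free))
    stop("group_divergence cannot exceed the ", length(free),
         " free positions")

  with_seed(seed, {
    base <- character(36)
    base[free] <- sample(AA_ALPHABET, length(free), replace = TRUE)
    base[schema$nucleophile_pos] <- "E"
    base[schema$donor_pos] <- "D"
    base[schema$diagnostic_positions] <-
      sample(AA_ALPHABET, length(schema$diagnostic_positions),
             replace = TRUE)

    draw_one <- function(g) {
      fp <- base
      mut <- sample(free, group_divergence)
      for (p in mut) fp[p] <- sample(setdiff(AA_ALPHABET, fp[p]), 1)
      r <- rules[[g]]
      diag_map <- c(p1 = 1L, p12 = 12L, p23 = 23L, p35 = 35L, p36 = 36L)
      for (nm in names(diag_map)) {
        if (!is.null(r[[nm]])) fp[diag_map[[nm]]] <- r[[nm]][1]
      }
      fp
    }
    cons <- lapply(setNames(enzymes, enzymes), draw_one)
    # enforce pairwise separation on the free positions
    ok <- FALSE
    for (iter in 1:200) {
      ok <- TRUE
      for (i in seq_along(cons)) {
        for (j in seq_len(i - 1L)) {
          d <- sum(cons[[i]][free] != cons[[j]][free])
          if (d < min_pair_diff) {
            cons[[i]] <- draw_one(names(cons)[i])
            ok <- FALSE
          }
        }
      }
      if (ok) break
    }
    if (!ok) stop("could not satisfy pairwise consensus separation; ",
                  "rules may conflict")
    out <- lapply(cons, paste, collapse = "")
    attr(out, "base") <- paste(base, collapse = "")
    out
  })
}

# Like-group consensus: partner enzyme consensus mutated at
# `like_divergence` free positions. Catalytic E15/D20 are retained here;
# each emitted member is knocked out individually.
derive_like_consensus <- function(base, like_divergence,
                                  schema = fingerprint_schema()) {
  fp <- strsplit(base, "")[[1]]
  mut <- sample(free_positions(schema), like_divergence)
  for (p in mut) fp[p] <- sample(setdiff(AA_ALPHABET, fp[p]), 1)
  paste(fp, collapse = "")
}

#' Consensus fingerprints for all catalogued groups
#'
#' Enzyme-group consensi from [build_group_consensus()] plus like-group
#' consensi derived from their partner enzyme consensus by mutating
#' `like_divergence` free positions, modelling like proteins as
#' base-adjacent lineages rather than point mutants.
#'
#' @param config A `gh57_synth_config`.
#' @param rules A `gh57_rules` table.
#' @return Named list of 36-character consensi, one per catalogued group.
#' @export
group_consensus_map <- function(config = synthetic_config(),
                                rules = diagnostic_rules()) {
  cat <- config$catalogue
  cons <- build_group_consensus(cat, rules, config$seed)
  likes <- cat[cat$kind == "like", ]
  with_seed(derive_seed(config$seed, 1), {
    for (i in seq_len(nrow(likes))) {
      cons[[likes$group[i]]] <-
        derive_like_consensus(cons[[likes$partner[i]]],
                              config$like_divergence)
    }
  })
  cons[cat$group]
}

#' Emit one labeled synthetic sequence
#'
#' Copies the group consensus into a fingerprint, flipping each free
#' position to a random different residue with probability
#' `1 - conservation` (catalytic and diagnostic positions are never
#' flipped), then embeds the five CSR blocks in background linker sequence.
#' Total length is drawn from Normal(group mean, jitter * mean) and the
#' non-CSR residues are apportioned over the six segments (N-terminus, four
#' spacers, C-terminus) via a symmetric Dirichlet, with at least
#' `min_spacer` residues between consecutive CSRs. Uses the current RNG
#' stream.
#'
#' @param group Group name present in the catalogue.
#' @param consensus Named list of group consensi (see
#'   [group_consensus_map()]).
#' @param config A `gh57_synth_config`.
#' @return A list of class `gh57_labeled_seq` with elements `sequence`,
#'   `group`, `taxonomy` (NA until assigned), `machinery`, `csr`
#'   (data.frame csr/start/end in full-sequence coordinates), `fingerprint`.
#' @export
emit_sequence <- function(group, consensus, config) {
  cat <- config$catalogue
  row <- cat[cat$group == group, ]
  if (nrow(row) != 1L) stop("unknown group: ", group)
  schema <- fingerprint_schema()
  cons <- strsplit(consensus[[group]], "")[[1]]

  fp <- cons
  free <- free_positions(schema)
  flip <- free[stats::runif(length(free)) > config$conservation]
  for (p in flip) fp[p] <- sample(setdiff(AA_ALPHABET, cons[p]), 1)

  ms <- config$min_spacer
  len <- round(stats::rnorm(1, row$mean_length,
                            config$length_jitter * row$mean_length))
  len <- max(len, 36L + 5L * ms)

  # apportion the non-CSR residues: inner spacers get min_spacer up front,
  # the remainder is split over 6 segments by a symmetric Dirichlet(2)
  extra <- len - 36L - 4L * ms
  w <- stats::rgamma(6, shape = 2)
  alloc <- as.integer(floor(extra * w / sum(w)))
  short <- extra - sum(alloc)
  if (short > 0) {
    ord <- order(-(extra * w / sum(w) - alloc), seq_len(6))
    alloc[ord[seq_len(short)]] <- alloc[ord[seq_len(short)]] + 1L
  }
  seg <- c(alloc[1], ms + alloc[2:5], alloc[6])

  widths <- schema$csr_spans$width
  aa <- names(config$linker_composition)
  linker <- function(n) if (n > 0)
    sample(aa, n, replace = TRUE, prob = config$linker_composition)
    else character(0)

  parts <- character(0)
  starts <- integer(5)
  pos <- 0L
  fp_blocks <- split(fp, rep(1:5, widths))
  for (k in 1:5) {
    lk <- linker(seg[k])
    parts <- c(parts, lk)
    pos <- pos + seg[k]
    starts[k] <- pos + 1L
    parts <- c(parts, fp_blocks[[k]])
    pos <- pos + widths[k]
  }
  parts <- c(parts, linker(seg[6]))

  structure(list(
    sequence = paste(parts, collapse = ""),
    group = group,
    taxonomy = NA_character_,
    machinery = "complete",
    csr = data.frame(csr = 1:5, start = starts,
                     end = starts + widths - 1L),
    fingerprint = paste(fp, collapse = "")
  ), class = "gh57_labeled_seq")
}

#' Substitute catalytic residues in a labeled sequence
#'
#' Replaces the glutamate nucleophile (fingerprint position 15) and/or the
#' aspartate proton donor (position 20) with a random non-E / non-D residue,
#' in both the stored fingerprint and the full sequence, updates the
#' machinery status and relabels the record to the partner "-like" group.
#' Uses the current RNG stream.
#'
#' @param record A `gh57_labeled_seq` with complete machinery.
#' @param mode One of "nucleophile", "donor", "both".
#' @param catalogue A `gh57_catalogue` used to resolve the like label.
#' @return The modified `gh57_labeled_seq`.
#' @export
knock_out_catalytics <- function(record, mode = c("nucleophile", "donor",
                                                  "both"),
                                 catalogue = default_catalogue()) {
  mode <- match.arg(mode)
  if (!identical(record$machinery, "complete"))
    stop("record must have complete catalytic machinery")
  schema <- fingerprint_schema()
  fp <- strsplit(record$fingerprint, "")[[1]]
  seqc <- strsplit(record$sequence, "")[[1]]

  sub_at <- function(pos, forbid) {
    new <- sample(setdiff(AA_ALPHABET, forbid), 1)
    m <- logo_position_to_csr(pos, schema)
    full <- record$csr$start[m["csr"]] + m["offset"] - 1L
    fp[pos] <<- new
    seqc[full] <<- new
  }
  if (mode %in% c("nucleophile", "both"))
    sub_at(schema$nucleophile_pos, "E")
  if (mode %in% c("donor", "both"))
    sub_at(schema$donor_pos, "D")

  record$fingerprint <- paste(fp, collapse = "")
  record$sequence <- paste(seqc, collapse = "")
  record$machinery <- switch(mode,
                             nucleophile = "nucleophile-substituted",
                             donor = "donor-substituted",
                             both = "both-substituted")
  record$group <- partner_like_label(sub("-like$", "", record$group),
                                     catalogue)
  record
}

# excise one CSR from a record, producing a dropout decoy
make_decoy <- function(record, drop_csr) {
  seqc <- strsplit(record$sequence, "")[[1]]
  s <- record$csr$start[drop_csr]
  e <- record$csr$end[drop_csr]
  w <- e - s + 1L
  record$sequence <- paste(seqc[-(s:e)], collapse = "")
  record$csr[drop_csr, c("start", "end")] <- NA_integer_
  later <- which(record$csr$csr > drop_csr)
  record$csr$start[later] <- record$csr$start[later] - w
  record$csr$end[later] <- record$csr$end[later] - w
  record$group <- NA_character_
  record$machinery <- NA_character_
  record$fingerprint <- NA_character_
  record
}

#' Generate a labeled synthetic GH57 dataset
#'
#' Deterministic given the config seed. Produces one sequence per catalogue
#' count (like-group members are emitted from their like consensus and then
#' knocked out with a random substitution mode), plus
#' `round(dropout_fraction * total)` decoy sequences with one CSR excised.
#' Taxonomy labels realize the per-group archaeal/bacterial counts exactly,
#' in shuffled order.
#'
#' @param config A `gh57_synth_config`.
#' @param rules A `gh57_rules` table.
#' @return List of class `gh57_dataset`: `sequences` (named character),
#'   `truth` (data.frame with columns id, group, kind, taxonomy, machinery,
#'   decoy, length, csr1_start..csr5_end, fingerprint), `consensus`,
#'   `config`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             rules = diagnostic_rules()) {
  cat <- config$catalogue
  counts <- config$counts
  consensus <- group_consensus_map(config, rules)

  with_seed(derive_seed(config$seed, 2), {
    records <- list()
    for (g in cat$group) {
      n <- counts[[g]]
      if (is.null(n) || n == 0) next
      row <- cat[cat$group == g, ]
      # realize the archaeal/bacterial split exactly, scaled to the
      # requested count if it differs from the catalogue default
      n_arch <- if (row$n > 0) round(n * row$n_archaea / row$n) else 0L
      tax <- sample(c(rep("archaeal", n_arch), rep("bacterial", n - n_arch)))
      is_like <- row$kind == "like"
      for (i in seq_len(n)) {
        rec <- emit_sequence(g, consensus, config)
        if (is_like) {
          mode <- sample(names(config$knockout_probs), 1,
                         prob = config$knockout_probs)
          # emitted from the like consensus (full machinery); the knockout
          # realizes the substitution and restores the like label
          rec$group <- row$partner
          rec <- knock_out_catalytics(rec, mode, catalogue = cat)
        }
        rec$taxonomy <- tax[i]
        rec$decoy <- FALSE
        records[[length(records) + 1L]] <- rec
      }
    }
    n_decoy <- round(config$dropout_fraction * sum(counts))
    enzymes <- Filter(function(g) !is.null(counts[[g]]) && counts[[g]] > 0,
                      cat$group[cat$kind == "enzyme"])
    if (length(enzymes) == 0) n_decoy <- 0L
    for (i in seq_len(n_decoy)) {
      g <- sample(enzymes, 1)
      rec <- make_decoy(emit_sequence(g, consensus, config), sample(5, 1))
      rec$taxonomy <- sample(c("archaeal", "bacterial"), 1)
      rec$decoy <- TRUE
      records[[length(records) + 1L]] <- rec
    }

    ids <- sprintf("GH57SYN_%05d", seq_along(records))
    seqs <- setNames(vapply(records, `[[`, "", "sequence"), ids)
    coord <- do.call(rbind, lapply(records, function(r) {
      v <- as.vector(t(as.matrix(r$csr[, c("start", "end")])))
      setNames(v, paste0("csr", rep(1:5, each = 2), c("_start", "_end")))
    }))
    truth <- data.frame(
      id = ids,
      group = vapply(records, `[[`, "", "group"),
      taxonomy = vapply(records, `[[`, "", "taxonomy"),
      machinery = vapply(records, `[[`, "", "machinery"),
      decoy = vapply(records, `[[`, TRUE, "decoy"),
      length = nchar(seqs),
      stringsAsFactors = FALSE
    )
    truth <- cbind(truth, as.data.frame(coord))
    truth$fingerprint <- vapply(records, `[[`, "", "fingerprint")
    rownames(truth) <- NULL

    structure(list(sequences = seqs, truth = truth, consensus = consensus,
                   config = config),
              class = "gh57_dataset")
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes a multi-FASTA, a truth TSV and a small JSON manifest carrying the
#' seed and a hash of the configuration.
#'
#' @param dataset A `gh57_dataset`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fasta")
  truth <- file.path(dir, "truth.tsv")
  manifest <- file.path(dir, "manifest.json")
  cfg_hash <- config_hash(dataset$config)
  if (length(dataset$sequences)) write_fasta(dataset$sequences, fasta)
  else writeLines(character(0), fasta)
  write_tsv_with_header(dataset$truth, truth,
                        header = c(paste0("seed=", dataset$config$seed),
                                   paste0("config=", cfg_hash)))
  jsonlite::write_json(
    list(seed = dataset$config$seed, config_hash = cfg_hash,
         n_sequences = length(dataset$sequences),
         n_decoys = sum(dataset$truth$decoy),
         counts = as.list(dataset$config$counts)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta = fasta, truth = truth, manifest = manifest))
}

config_hash <- function(config) {
  fnv1a_hash(paste(
    config$seed, config$conservation, config$length_jitter,
    config$dropout_fraction, config$min_spacer, config$like_divergence,
    paste(names(config$counts), config$counts, collapse = ","),
    paste(round(config$linker_composition, 10), collapse = ","),
    paste(round(config$knockout_probs, 10), collapse = ","),
    collapse = "|"))
}

#' @importFrom utils modifyList
NULL
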