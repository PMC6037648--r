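#' Determine the catalytic machinery status of a fingerprint
#'
#' The GH57 machinery is complete when the catalytic nucleophile position
#' (15) holds glutamate and the proton-donor position (20) holds aspartate.
#'
#' @param fp Character scalar, a 36-residue fingerprint.
#' @param schema A `gh57_schema`.
#' @return One of "complete", "nucleophile-substituted",
#'   "donor-substituted", "both-substituted".
#' @examples
#' fp <- strrep("A", 36)
#' substr(fp, 15, 15) <- "E"; substr(fp, 20, 20) <- "D"
#' check_catalytic_machinery(fp)  # "complete"
#' @export
check_catalytic_machinery <- function(fp, schema = fingerprint_schema()) {
  if (nchar(fp) != 36) stop("fingerprint must have length 36")
  has_e <- substr(fp, schema$nucleophile_pos, schema$nucleophile_pos) == "E"
  has_d <- substr(fp, schema$donor_pos, schema$donor_pos) == "D"
  if (has_e && has_d) "complete"
  else if (!has_e && has_d) "nucleophile-substituted"
  else if (has_e && !has_d) "donor-substituted"
  else "both-substituted"
}

#' Diagnostic-position agreement flags per enzyme group
#'
#' Checks the fingerprint against each enzyme group's documented residues
#' at position 23 and at the terminal pair 35-36. Flags are advisory: they
#' inform tie-breaking and warnings during assignment but never veto a
#' profile score, since several once-unique features are no longer strictly
#' invariant in the family.
#'
#' @param fp A 36-residue fingerprint.
#' @param rules A `gh57_rules` table.
#' @return Logical matrix, one row per enzyme group, columns `p23` and
#'   `pair` (positions 35-36); NA where a group has no documented rule.
#' @examples
#' fp <- paste0(strrep("A", 22), "T", strrep("A", 11), "YY")
#' diagnostic_match(fp)["AAMY", ]  # both TRUE
#' @export
diagnostic_match <- function(fp, rules = diagnostic_rules()) {
  if (nchar(fp) != 36) stop("fingerprint must have length 36")
  r23 <- substr(fp, 23, 23)
  r35 <- substr(fp, 35, 35)
  r36 <- substr(fp, 36, 36)
  out <- t(vapply(rules, function(r) {
    p23 <- if (is.null(r$p23)) NA else r23 %in% r$p23
    pair <- if (is.null(r$p35) && is.null(r$p36)) NA
    else (is.null(r$p35) || r35 %in% r$p35) &&
      (is.null(r$p36) || r36 %in% r$p36)
    c(p23 = p23, pair = pair)
  }, logical(2)))
  out
}

#' Score a fingerprint against per-group profiles
#'
#' Total log-odds of the fingerprint under each group's CSR profiles.
#' Scores share one background, so they are comparable across groups.
#'
#' @param fp A 36-residue fingerprint.
#' @param group_profiles Named list of `gh57_profiles`, one per enzyme
#'   group.
#' @return Named numeric vector of scores.
#' @export
score_against_groups <- function(fp, group_profiles) {
  if (nchar(fp) != 36) stop("fingerprint must have length 36")
  res_idx <- residue_index(strsplit(fp, "")[[1]])
  vapply(group_profiles, function(ps) {
    s <- 0
    pos <- 1L
    for (p in ps$csr) {
      idx <- res_idx[pos:(pos + p$width - 1L)]
      v <- p$logodds[cbind(idx, seq_len(p$width))]
      v[is.na(v)] <- 0
      s <- s + sum(v)
      pos <- pos + p$width
    }
    s
  }, 0)
}

#' Assign a fingerprint to a specificity group
#'
#' The best base group is the profile-score argmax (ties broken by the
#' number of agreeing diagnostic flags, then lexicographic group name). A
#' best score below `threshold` yields "unclassified"; otherwise an
#' incomplete catalytic machinery assigns the partner "-like" group of the
#' best base group, and a complete machinery assigns the base group
#' itself. Diagnostic disagreement with the winning group is recorded as a
#' warning flag, never as a veto.
#'
#' @param fp A 36-residue fingerprint.
#' @param machinery Machinery status from [check_catalytic_machinery()].
#' @param scores Named per-group scores from [score_against_groups()].
#' @param flags Flag matrix from [diagnostic_match()].
#' @param threshold Minimum best score for classification (default 0,
#'   permissive: the study set contained a single unclassifiable sequence).
#' @param catalogue A `gh57_catalogue` for like-label resolution.
#' @return List of class `gh57_assignment`: `machinery`, `best_group`,
#'   `label`, `score`, `diagnostic_warning`, `flags`.
#' @export
assign_group <- function(fp, machinery, scores, flags, threshold = 0,
                         catalogue = default_catalogue()) {
  agree <- rowSums(flags[names(scores), , drop = FALSE], na.rm = TRUE)
  ord <- order(-scores, -agree, names(scores))
  best <- names(scores)[ord[1]]
  best_score <- unname(scores[best])

  label <- if (best_score < threshold) "unclassified"
  else if (identical(machinery, "complete")) best
  else partner_like_label(best, catalogue)

  structure(list(machinery = machinery, best_group = best, label = label,
                 score = best_score,
                 diagnostic_warning = any(flags[best, ] %in% FALSE),
                 flags = flags[best, ]),
            class = "gh57_assignment")
}

#' Classify a table of detected fingerprints
#'
#' Runs machinery check, diagnostic flags, profile scoring and assignment
#' for every accepted row of a [detect_fingerprints()] table; eliminated
#' sequences are carried through with label "eliminated".
#'
#' @param detections data.frame from [detect_fingerprints()].
#' @param group_profiles Named list of per-group `gh57_profiles`.
#' @param rules A `gh57_rules` table.
#' @param threshold Assignment threshold (default 0).
#' @param catalogue A `gh57_catalogue`.
#' @return data.frame: `id`, `status`, `machinery`, `best_group`, `label`,
#'   `score`, `diagnostic_warning`.
#' @export
classify_fingerprints <- function(detections, group_profiles,
                                  rules = diagnostic_rules(),
                                  threshold = 0,
                                  catalogue = default_catalogue()) {
  rows <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    if (!identical(d$status, "accepted")) {
      return(data.frame(id = d$id, status = d$status,
                        machinery = NA_character_,
                        best_group = NA_character_, label = "eliminated",
                        score = NA_real_, diagnostic_warning = NA,
                        stringsAsFactors = FALSE))
    }
    fp <- d$fingerprint
    mach <- check_catalytic_machinery(fp)
    fl <- diagnostic_match(fp, rules)
    sc <- score_against_groups(fp, group_profiles)
    a <- assign_group(fp, mach, sc, fl, threshold, catalogue)
    data.frame(id = d$id, status = d$status, machinery = a$machinery,
               best_group = a$best_group, label = a$label, score = a$score,
               diagnostic_warning = a$diagnostic_warning,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize assignments into a catalogue-style report
#'
#' Per-group totals with archaeal/bacterial splits plus eliminated and
#' unclassified counts; the counts sum to the number of input sequences.
#'
#' @param assignments data.frame from [classify_fingerprints()].
#' @param taxonomy Named character vector mapping sequence id to
#'   "archaeal"/"bacterial" (optional).
#' @return data.frame with columns `group`, `n`, `n_archaea`, `n_bacteria`.
#'   Rows include special labels "eliminated" and "unclassified" when
#'   present.
#' @export
summarize_assignments <- function(assignments, taxonomy = NULL) {
  if (nrow(assignments) == 0)
    return(data.frame(group = character(0), n = integer(0),
                      n_archaea = integer(0), n_bacteria = integer(0)))
  lab <- assignments$label
  tax <- if (is.null(taxonomy)) rep(NA_character_, nrow(assignments))
  else unname(taxonomy[assignments$id])
  groups <- sort(unique(lab))
  out <- data.frame(
    group = groups,
    n = as.integer(table(factor(lab, levels = groups))),
    n_archaea = vapply(groups, function(g)
      sum(lab == g & tax %in% "archaeal"), 0L),
    n_bacteria = vapply(groups, function(g)
      sum(lab == g & tax %in% "bacterial"), 0L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
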