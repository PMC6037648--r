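#' Build position-specific CSR profiles from aligned fingerprints
#'
#' Splits each 36-residue fingerprint into its five CSR blocks and counts
#' residues per position. Frequencies use Laplace smoothing,
#' `(count + pseudocount) / (n + 20 * pseudocount)`, and are converted to
#' log2 odds against a background distribution (uniform by default).
#' Residues outside the 20-letter alphabet are ignored during counting and
#' score as log-odds 0 (the background expectation) during scanning.
#'
#' @param fingerprints Character vector of 36-mers.
#' @param pseudocount Positive smoothing constant (default 0.5).
#' @param background Named background probability vector over
#'   [AA_ALPHABET].
#' @param schema A `gh57_schema`.
#' @return Object of class `gh57_profiles`: list with `csr` (a list of five
#'   per-CSR profiles, each holding `width`, `freq` and `logodds` 20 x width
#'   matrices and `consensus_score`), `n`, `pseudocount`, `background`.
#' @examples
#' ps <- profiles_from_alignment(rep(strrep("A", 36), 10))
#' ps$csr[[1]]$freq["A", 1]  # (10 + 0.5) / (10 + 10)
#' @export
profiles_from_alignment <- function(fingerprints, pseudocount = 0.5,
                                    background = NULL,
                                    schema = fingerprint_schema()) {
  if (length(fingerprints) == 0) stop("no fingerprints supplied")
  if (any(nchar(fingerprints) != 36))
    stop("all fingerprints must have length 36")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)

  chars <- seq_char_matrix(fingerprints)
  spans <- schema$csr_spans
  csr <- vector("list", 5)
  for (k in 1:5) {
    w <- spans$width[k]
    cols <- spans$start[k]:spans$end[k]
    freq <- matrix(0, nrow = 20, ncol = w,
                   dimnames = list(AA_ALPHABET, NULL))
    for (j in seq_len(w)) {
      cnt <- table(factor(chars[, cols[j]], levels = AA_ALPHABET))
      n_std <- sum(cnt)
      freq[, j] <- (as.numeric(cnt) + pseudocount) /
        (n_std + 20 * pseudocount)
    }
    lo <- log2(freq / background[rownames(freq)])
    csr[[k]] <- list(csr = k, width = w, freq = freq, logodds = lo,
                     consensus_score = sum(apply(lo, 2, max)))
  }
  structure(list(csr = csr, n = length(fingerprints),
                 pseudocount = pseudocount, background = background),
            class = "gh57_profiles")
}

# Window scores of one CSR profile along a sequence: W[s] = sum of
# per-position log-odds for the window starting at s. Ambiguous residues
# contribute 0.
csr_window_scores <- function(res_idx, profile) {
  L <- length(res_idx)
  w <- profile$width
  ns <- L - w + 1L
  if (ns < 1L) return(numeric(0))
  W <- numeric(ns)
  lo <- profile$logodds
  for (j in seq_len(w)) {
    v <- lo[res_idx[j:(j + ns - 1L)], j]
    v[is.na(v)] <- 0
    W <- W + v
  }
  W
}

#' Locate the five CSRs in a protein sequence
#'
#' Finds the ordered, non-overlapping placement of the five CSR windows
#' that maximizes the total profile log-odds, subject to at least
#' `min_spacer` residues between consecutive windows. The search is an
#' exact dynamic program over window start positions (suffix maxima over
#' the per-CSR window-score vectors), not a greedy scan; ties are broken
#' toward the leftmost placement (lexicographically smallest starts). Any
#' CSR whose score in the optimal placement falls below its floor yields an
#' elimination record naming the missing CSR(s) — the in silico
#' realization of discarding sequences that obviously lack a CSR.
#'
#' @param sequence Single amino-acid sequence (character scalar).
#' @param profiles A `gh57_profiles` set.
#' @param schema A `gh57_schema`.
#' @param min_spacer Minimum residues between consecutive CSRs (default 5).
#' @param score_floor Either a numeric vector of five per-CSR floors or a
#'   single fraction in (0, 1) applied to each profile's consensus score;
#'   default 0.3 of the consensus score.
#' @return Object of class `gh57_csr_hits`: list with `status`
#'   ("accepted"/"eliminated"), `reason`, `missing` (integer CSR indices),
#'   `csr` (data.frame csr/start/end/score), `total_score`, `floors`.
#' @export
locate_csrs <- function(sequence, profiles, schema = fingerprint_schema(),
                        min_spacer = 5L, score_floor = 0.3) {
  widths <- schema$csr_spans$width
  floors <- if (length(score_floor) == 5L) as.numeric(score_floor)
  else vapply(profiles$csr, function(p) score_floor * p$consensus_score, 0)

  res_idx <- residue_index(strsplit(sequence, "")[[1]])
  L <- length(res_idx)
  min_len <- sum(widths) + 4L * min_spacer
  if (L < min_len) {
    return(structure(list(status = "eliminated", reason = "too short",
                          missing = 1:5, csr = NULL, total_score = NA_real_,
                          floors = floors), class = "gh57_csr_hits"))
  }

  W <- lapply(1:5, function(k) csr_window_scores(res_idx, profiles$csr[[k]]))
  # latest feasible start for CSR k so that the remaining CSRs still fit
  tail_need <- rev(cumsum(rev(widths + c(rep(min_spacer, 4), 0))))
  last_start <- L - tail_need + 1L

  # backward DP: B[[k]][s] = best total score of CSRs k..5 with CSR k at s
  B <- vector("list", 5)
  M <- vector("list", 5)  # suffix maxima of B[[k]]
  B[[5]] <- W[[5]][seq_len(last_start[5])]
  M[[5]] <- rev(cummax(rev(B[[5]])))
  for (k in 4:1) {
    ns <- last_start[k]
    off <- widths[k] + min_spacer   # CSR k at s allows CSR k+1 from s+off
    B[[k]] <- W[[k]][seq_len(ns)] + M[[k + 1]][seq_len(ns) + off]
    M[[k]] <- rev(cummax(rev(B[[k]])))
  }

  starts <- integer(5)
  starts[1] <- which.max(B[[1]])            # first max = leftmost
  for (k in 2:5) {
    from <- starts[k - 1] + widths[k - 1] + min_spacer
    starts[k] <- from - 1L + which.max(B[[k]][from:last_start[k]])
  }
  scores <- vapply(1:5, function(k) W[[k]][starts[k]], 0)
  missing <- which(scores < floors)

  hits <- data.frame(csr = 1:5, start = starts,
                     end = starts + widths - 1L, score = scores)
  structure(list(
    status = if (length(missing)) "eliminated" else "accepted",
    reason = if (length(missing))
      paste0("missing CSR-", paste(missing, collapse = ",CSR-")) else NA,
    missing = missing, csr = hits, total_score = sum(scores),
    floors = floors
  ), class = "gh57_csr_hits")
}

#' Extract the 36-residue fingerprint from located CSRs
#'
#' Concatenates the five CSR subsequences in order CSR-1..CSR-5.
#'
#' @param sequence The full amino-acid sequence.
#' @param hits A `gh57_csr_hits` with all five CSRs accepted.
#' @return Character scalar of length 36.
#' @export
extract_fingerprint <- function(sequence, hits) {
  if (!identical(hits$status, "accepted"))
    stop("cannot extract a fingerprint from an eliminated sequence (",
         hits$reason, ")")
  paste(substring(sequence, hits$csr$start, hits$csr$end), collapse = "")
}

#' Detect CSR fingerprints across a set of sequences
#'
#' Applies [locate_csrs()] and [extract_fingerprint()] to every sequence
#' and tabulates the outcome. When `profiles` is a named list of profile
#' sets (one per group, the default produced by `train_profiles()`), each
#' sequence is scanned with every set and the placement with the highest
#' total log-odds wins (ties: first set in list order); elimination is then
#' judged against the winning profile's floors, so the rule is calibrated
#' per group rather than against a pooled mixture.
#'
#' @param sequences Named character vector or `AAStringSet`.
#' @param profiles A `gh57_profiles` set, or a named list of them.
#' @param schema A `gh57_schema`.
#' @inheritParams locate_csrs
#' @return data.frame with one row per sequence: `id`, `status`, `reason`,
#'   `best_profile`, `csr1_start`..`csr5_end`, `score1`..`score5`,
#'   `total_score`, `fingerprint`.
#' @export
detect_fingerprints <- function(sequences, profiles,
                                schema = fingerprint_schema(),
                                min_spacer = 5L, score_floor = 0.3) {
  seqs <- as_named_sequences(sequences)
  single <- inherits(profiles, "gh57_profiles")
  if (!single && is.null(names(profiles)))
    stop("profile list must be named by group")
  rows <- lapply(seq_along(seqs), function(i) {
    if (single) {
      h <- locate_csrs(seqs[[i]], profiles, schema, min_spacer, score_floor)
      best_name <- NA_character_
    } else {
      hs <- lapply(profiles, function(p)
        locate_csrs(seqs[[i]], p, schema, min_spacer, score_floor))
      totals <- vapply(hs, function(h)
        if (is.na(h$total_score)) -Inf else h$total_score, 0)
      best_name <- names(hs)[which.max(totals)]
      h <- hs[[best_name]]
    }
    coords <- if (is.null(h$csr)) rep(NA_integer_, 10) else
      as.vector(t(as.matrix(h$csr[, c("start", "end")])))
    scores <- if (is.null(h$csr)) rep(NA_real_, 5) else h$csr$score
    fp <- if (identical(h$status, "accepted"))
      extract_fingerprint(seqs[[i]], h) else NA_character_
    c(list(id = names(seqs)[i], status = h$status,
           reason = if (is.na(h$reason[1])) "" else h$reason,
           best_profile = best_name),
      setNames(as.list(coords),
               paste0("csr", rep(1:5, each = 2), c("_start", "_end"))),
      setNames(as.list(scores), paste0("score", 1:5)),
      list(total_score = h$total_score, fingerprint = fp))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Serialize CSR profiles to JSON
#'
#' @param profiles A `gh57_profiles` set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_json <- function(profiles, path) {
  doc <- list(
    n = profiles$n, pseudocount = profiles$pseudocount,
    background = as.list(profiles$background),
    csr = lapply(profiles$csr, function(p)
      list(csr = p$csr, width = p$width,
           freq = as.data.frame(p$freq),
           consensus_score = p$consensus_score))
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read CSR profiles from JSON
#'
#' @param path Path written by [write_profiles_json()].
#' @return A `gh57_profiles` object.
#' @export
read_profiles_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  background <- unlist(doc$background)
  csr <- lapply(seq_len(nrow(doc$csr)), function(k) {
    freq <- as.matrix(doc$csr$freq[[k]])
    dimnames(freq) <- list(AA_ALPHABET, NULL)
    lo <- log2(freq / background[rownames(freq)])
    list(csr = doc$csr$csr[k], width = doc$csr$width[k], freq = freq,
         logodds = lo, consensus_score = doc$csr$consensus_score[k])
  })
  structure(list(csr = csr, n = doc$n, pseudocount = doc$pseudocount,
                 background = background), class = "gh57_profiles")
}
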