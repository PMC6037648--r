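#' Shannon information content of one logo column
#'
#' IC = log2(20) + sum(p * log2(p)) in bits, with 0*log2(0) = 0. No
#' small-sample correction is applied (the WebLogo convention applies one
#' by default; it is omitted here so closed-form values hold exactly, which
#' is documented behaviour, not an oversight).
#'
#' @param freqs Numeric vector of residue frequencies summing to 1.
#' @return Information content in bits, in [0, log2(20)] for a 20-letter
#'   column.
#' @examples
#' information_content(c(1, rep(0, 19)))    # log2(20) = 4.3219...
#' information_content(rep(0.05, 20))       # 0
#' @export
information_content <- function(freqs) {
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  log2(20) + sum(p * log2(p))
}

#' Sequence-logo matrix of a set of fingerprints
#'
#' Per-position residue frequencies (plain counts, no pseudocount — this is
#' the display convention) and per-position information content for a set
#' of 36-residue fingerprints. This is the numerical content of a sequence
#' logo; rendering is left to external tools.
#'
#' @param fingerprints Character vector of 36-mers, n >= 1.
#' @param group Optional group name stored with the matrix.
#' @param schema A `gh57_schema` (CSR boundaries are carried along for
#'   annotation).
#' @return Object of class `gh57_logo`: list with `freq` (36 x 20 matrix),
#'   `ic` (length-36 vector of bits), `n`, `group`, `csr` (per-position CSR
#'   index).
#' @export
logo_from_fingerprints <- function(fingerprints, group = NULL,
                                   schema = fingerprint_schema()) {
  if (length(fingerprints) == 0) stop("no fingerprints supplied")
  if (any(nchar(fingerprints) != 36))
    stop("all fingerprints must have length 36")
  chars <- seq_char_matrix(fingerprints)
  freq <- matrix(0, nrow = 36, ncol = 20,
                 dimnames = list(NULL, AA_ALPHABET))
  for (pos in 1:36) {
    cnt <- table(factor(chars[, pos], levels = AA_ALPHABET))
    tot <- sum(cnt)
    if (tot == 0) stop("position ", pos, " has no standard residues")
    freq[pos, ] <- as.numeric(cnt) / tot
  }
  ic <- apply(freq, 1, information_content)
  csr_of <- rep(schema$csr_spans$csr, schema$csr_spans$width)
  structure(list(freq = freq, ic = ic, n = length(fingerprints),
                 group = group, csr = csr_of), class = "gh57_logo")
}

#' Modal residue per logo position
#'
#' @param logo A `gh57_logo`.
#' @return Character vector of length 36 (first alphabetically on ties).
#' @export
logo_consensus <- function(logo) {
  AA_ALPHABET[apply(logo$freq, 1, which.max)]
}

#' Export a logo matrix as TSV
#'
#' One row per fingerprint position with its CSR index, information
#' content and the 20 residue frequencies.
#'
#' @param logo A `gh57_logo`.
#' @param path Output path.
#' @param header Extra `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path, header = character()) {
  df <- data.frame(position = 1:36, csr = logo$csr,
                   ic_bits = logo$ic, as.data.frame(logo$freq),
                   check.names = FALSE)
  write_tsv_with_header(df, path, header = c(
    if (!is.null(logo$group)) paste0("group=", logo$group),
    paste0("n=", logo$n), header))
}

#' Export one or more logo matrices as JSON
#'
#' @param logos A `gh57_logo` or named list of them.
#' @param path Output path.
#' @param meta Named list of metadata stored alongside the matrices.
#' @return `path`, invisibly.
#' @export
write_logos_json <- function(logos, path, meta = list()) {
  if (inherits(logos, "gh57_logo")) logos <- list(logo = logos)
  doc <- c(meta, list(logos = lapply(logos, function(lg)
    list(group = lg$group, n = lg$n, csr = lg$csr, ic_bits = lg$ic,
         freq = as.data.frame(lg$freq)))))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
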