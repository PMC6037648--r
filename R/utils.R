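# Internal helpers: RNG scoping, hashing, sequence/string utilities.

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stream index; stays < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483587
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# output files with a digest of the configuration.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f")) %% 256
  h <- 2166136261
  for (b in bytes) {
    # xor only the low byte; h is kept as a double in [0, 2^32)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, split to avoid
    # double-precision overflow
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Split a character vector of sequences into a character matrix (rows =
# sequences, cols = positions). All sequences must share one length.
seq_char_matrix <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences differ in length")
  matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE,
         dimnames = list(names(seqs), NULL))
}

# Residue -> 1..20 index; NA for anything outside the standard alphabet.
residue_index <- function(chars) match(chars, AA_ALPHABET)

# Coerce Biostrings::AAStringSet or named character to named character.
as_named_sequences <- function(x) {
  if (methods::is(x, "AAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("seq_%04d", seq_along(x))
    return(x)
  }
  stop("expected an AAStringSet or a named character vector of sequences")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector, the representation used internally.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  as_named_sequences(Biostrings::readAAStringSet(path))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path; parent directory is created if missing.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- names(seqs)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

# Write a data.frame as TSV with '# key=value' header comment lines.
write_tsv_with_header <- function(df, path, header = character()) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @importFrom methods is
NULL
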