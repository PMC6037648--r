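#' @importFrom stats rnorm setNames
#' @importFrom utils write.table read.table
NULL

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Standard residues in alphabetical one-letter order. Residues outside this
#' set (X, B, Z, U, ...) are treated as ambiguous and score as background.
#'
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Aromatic residue class
#'
#' Used by the diagnostic rules at fingerprint positions 12 and 36.
#' Histidine is included conservatively.
#'
#' @export
AA_AROMATIC <- c("F", "W", "Y", "H")

#' GH57 fingerprint schema
#'
#' The fixed layout of the 36-position GH57 fingerprint: five conserved
#' sequence regions (CSR-1..CSR-5) spanning positions 1-5, 6-11, 12-17,
#' 18-27 and 28-36, the catalytic nucleophile (Glu) at position 15 in CSR-3,
#' the proton donor (Asp) at position 20 in CSR-4, and the diagnostic
#' positions 1, 12, 23, 35 and 36 whose residues discriminate the enzyme
#' specificities.
#'
#' @return An object of class `gh57_schema`: a list with elements
#'   `csr_spans` (data.frame with columns `csr`, `start`, `end`, `width`),
#'   `nucleophile_pos`, `donor_pos`, `diagnostic_positions`, `version`.
#' @examples
#' sch <- fingerprint_schema()
#' sch$csr_spans
#' @export
fingerprint_schema <- function() {
  spans <- data.frame(
    csr   = 1:5,
    start = c(1L, 6L, 12L, 18L, 28L),
    end   = c(5L, 11L, 17L, 27L, 36L)
  )
  spans$width <- spans$end - spans$start + 1L
  structure(list(
    csr_spans            = spans,
    nucleophile_pos      = 15L,
    donor_pos            = 20L,
    diagnostic_positions = c(1L, 12L, 23L, 35L, 36L),
    version              = "1.0"
  ), class = "gh57_schema")
}

#' Map a fingerprint position to its CSR and within-CSR offset
#'
#' @param pos Integer fingerprint position, 1..36.
#' @param schema A `gh57_schema`, by default [fingerprint_schema()].
#' @return Named integer vector `c(csr = , offset = )`, both 1-based.
#' @examples
#' logo_position_to_csr(15) # catalytic nucleophile: CSR-3, offset 4
#' logo_position_to_csr(20) # proton donor: CSR-4, offset 3
#' @export
logo_position_to_csr <- function(pos, schema = fingerprint_schema()) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > 36L)
    stop("fingerprint position must be a single integer in 1..36, got: ",
         paste(pos, collapse = ","))
  sp <- schema$csr_spans
  k <- which(sp$start <= pos & pos <= sp$end)
  c(csr = sp$csr[k], offset = pos - sp$start[k] + 1L)
}

#' The GH57 group catalogue
#'
#' The 14 enzyme-specificity and "like"-protein groups of family GH57 with
#' their member counts, archaeal/bacterial split, number of experimentally
#' characterized enzymes, and mean sequence lengths. The defaults describe
#' the 1602-sequence study set: 383 archaeal and 1219 bacterial members, 27
#' characterized enzymes. "Like" groups name their partner enzyme group;
#' AGAL-related is a (candidate) enzyme group in its own right, not a like
#' group.
#'
#' @return A data.frame of class `gh57_catalogue` with columns `group`,
#'   `kind` ("enzyme" or "like"), `partner` (base group of a like group, NA
#'   otherwise), `n`, `n_archaea`, `n_bacteria`, `n_characterized`,
#'   `mean_length`.
#' @examples
#' cat <- default_catalogue()
#' sum(cat$n)          # 1602
#' sum(cat$n_archaea)  # 383
#' @export
default_catalogue <- function() {
  cat <- data.frame(
    group   = c("AAMY", "AAMY-like", "4AGT", "4AGT-like", "APU", "APU-CMD",
                "APU-CMD-like", "MGA", "MGA-like", "AGAL", "AGAL-related",
                "NSA", "GBE", "GBE-like"),
    kind    = c("enzyme", "like", "enzyme", "like", "enzyme", "enzyme",
                "like", "enzyme", "like", "enzyme", "enzyme",
                "enzyme", "enzyme", "like"),
    partner = c(NA, "AAMY", NA, "4AGT", NA, NA,
                "APU-CMD", NA, "MGA", NA, NA,
                NA, NA, "GBE"),
    n               = c(154L, 126L, 107L, 63L, 268L, 40L, 5L, 34L, 1L, 14L,
                        15L, 170L, 545L, 60L),
    n_archaea       = c(99L, 60L, 38L, 0L, 74L, 20L, 0L, 34L, 0L, 14L,
                        0L, 18L, 26L, 0L),
    n_bacteria      = c(55L, 66L, 69L, 63L, 194L, 20L, 5L, 0L, 1L, 0L,
                        15L, 152L, 519L, 60L),
    n_characterized = c(1L, 0L, 5L, 0L, 8L, 4L, 0L, 3L, 0L, 1L,
                        0L, 1L, 4L, 0L),
    mean_length     = c(414L, 443L, 670L, 623L, 814L, 529L, 728L, 590L,
                        479L, 362L, 660L, 785L, 546L, 520L),
    stringsAsFactors = FALSE
  )
  class(cat) <- c("gh57_catalogue", "data.frame")
  cat
}

#' Diagnostic residue rules per enzyme group
#'
#' Expected residues at the diagnostic fingerprint positions for each enzyme
#' group. Position 23 carries an almost invariant, group-specific residue
#' (T for alpha-amylases, S for non-specified amylases, A for maltogenic
#' amylases, K for 4-alpha-glucanotransferases, L for branching enzymes, F
#' for alpha-galactosidases and the AGAL-related group). The terminal pair
#' 35-36 is the strongest single discriminator: YY (AAMY), FF (NSA), FW
#' (MGA), WW (APU, not invariant), F + non-aromatic (GBE), GW (AGAL) and
#' T + K-or-H (AGAL-related). Position 12 is a tryptophan, or at least an
#' aromatic residue, in every group except the alpha-amylases and their like
#' proteins, where arginine/glutamate dominate; position 1 of AAMY is mostly
#' glutamate/glutamine.
#'
#' Entries are allowed-residue sets; `NULL` means no documented constraint.
#' The first element of each set is the consensus choice used by the
#' synthetic-data generator. These rules flag agreement during
#' classification; they never veto a profile-score assignment, since several
#' features have lost strict invariance as the family grew.
#'
#' @return Named list of class `gh57_rules`; one entry per enzyme group,
#'   each a list with elements `p1`, `p12`, `p23`, `p35`, `p36`
#'   (character vectors of allowed residues, or NULL).
#' @export
diagnostic_rules <- function() {
  nonaromatic <- setdiff(AA_ALPHABET, AA_AROMATIC)
  # allowed sets are ordered: the first element is the consensus choice the
  # synthetic generator uses (tryptophan at position 12, per the logos)
  arom <- c("W", "F", "Y", "H")
  rules <- list(
    "AAMY"         = list(p1 = c("E", "Q"), p12 = c("R", "E"), p23 = "T",
                          p35 = "Y", p36 = "Y"),
    "NSA"          = list(p1 = NULL, p12 = arom, p23 = "S",
                          p35 = "F", p36 = "F"),
    "MGA"          = list(p1 = NULL, p12 = arom, p23 = "A",
                          p35 = "F", p36 = "W"),
    "4AGT"         = list(p1 = NULL, p12 = arom, p23 = "K",
                          p35 = NULL, p36 = NULL),
    "APU"          = list(p1 = NULL, p12 = arom, p23 = NULL,
                          p35 = "W", p36 = "W"),
    "APU-CMD"      = list(p1 = NULL, p12 = arom, p23 = NULL,
                          p35 = NULL, p36 = NULL),
    "GBE"          = list(p1 = NULL, p12 = arom, p23 = "L",
                          p35 = "F", p36 = nonaromatic),
    "AGAL"         = list(p1 = NULL, p12 = arom, p23 = "F",
                          p35 = "G", p36 = "W"),
    "AGAL-related" = list(p1 = NULL, p12 = arom, p23 = "F",
                          p35 = "T", p36 = c("K", "H"))
  )
  class(rules) <- "gh57_rules"
  rules
}

#' Label of the "like" partner group for a base enzyme group
#'
#' Looks up the catalogued like group whose partner is `group`; for enzyme
#' groups without a catalogued like group the label is synthesized as
#' `<group>-like`.
#'
#' @param group Enzyme group name.
#' @param catalogue A `gh57_catalogue`.
#' @return Character label of the like group.
#' @export
partner_like_label <- function(group, catalogue = default_catalogue()) {
  hit <- catalogue$group[catalogue$kind == "like" &
                           !is.na(catalogue$partner) &
                           catalogue$partner == group]
  if (length(hit) == 1L) hit else paste0(group, "-like")
}

#' Serialize schema, catalogue and rules to a versioned JSON document
#'
#' @param path Output file path.
#' @param schema,catalogue,rules Configuration objects; defaults describe
#'   family GH57. Alternative families can be configured by editing the JSON.
#' @return `path`, invisibly.
#' @seealso [read_schema_json()]
#' @export
write_schema_json <- function(path, schema = fingerprint_schema(),
                              catalogue = default_catalogue(),
                              rules = diagnostic_rules()) {
  doc <- list(
    format_version = "1.0",
    schema = list(
      csr_spans            = schema$csr_spans[, c("csr", "start", "end")],
      nucleophile_pos      = schema$nucleophile_pos,
      donor_pos            = schema$donor_pos,
      diagnostic_positions = schema$diagnostic_positions,
      version              = schema$version
    ),
    catalogue = as.data.frame(catalogue),
    rules = lapply(unclass(rules), function(r) lapply(r, function(x) x))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a schema/catalogue/rules JSON document
#'
#' @param path Path to a JSON file written by [write_schema_json()].
#' @return List with elements `schema` (`gh57_schema`), `catalogue`
#'   (`gh57_catalogue`) and `rules` (`gh57_rules`).
#' @export
read_schema_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  spans <- as.data.frame(doc$schema$csr_spans)
  spans$width <- spans$end - spans$start + 1L
  schema <- structure(list(
    csr_spans            = spans,
    nucleophile_pos      = as.integer(doc$schema$nucleophile_pos),
    donor_pos            = as.integer(doc$schema$donor_pos),
    diagnostic_positions = as.integer(doc$schema$diagnostic_positions),
    version              = doc$schema$version
  ), class = "gh57_schema")
  catalogue <- as.data.frame(doc$catalogue)
  catalogue$partner[catalogue$partner %in% c("", "NA")] <- NA
  class(catalogue) <- c("gh57_catalogue", "data.frame")
  rules <- lapply(doc$rules, function(r) {
    lapply(r, function(x) if (is.null(x) || length(x) == 0L) NULL
           else as.character(unlist(x)))
  })
  class(rules) <- "gh57_rules"
  list(schema = schema, catalogue = catalogue, rules = rules)
}

validate_schema <- function(schema) {
  sp <- schema$csr_spans
  stopifnot(nrow(sp) == 5L)
  covered <- unlist(Map(seq.int, sp$start, sp$end))
  if (!identical(sort(covered), 1:36))
    stop("CSR spans must partition positions 1..36")
  invisible(TRUE)
}
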