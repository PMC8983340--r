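## Controlled vocabularies shared across the annotation model and the scorers.
## The MoA vocabulary is deliberately user-extensible: values outside it are
## kept, flagged as "other:<free text>", and still compared by string equality.

#' Controlled vocabularies
#'
#' Vocabularies used by the annotation tables and the scoring rules. The MoA
#' (mechanism-of-action) vocabulary is an editorial default and is
#' user-extensible: values outside it are preserved as `"other:<free text>"`
#' and still participate in same-MoA comparisons by string equality.
#'
#' @return A named list of character vectors with elements `moa_class`,
#'   `target_kind`, `replication_stage`, `immunomodulatory`, `routes`,
#'   `infected_systems` and `activity_status`.
#' @examples
#' bsa_vocabulary()$activity_status
#' @export
bsa_vocabulary <- function() {
  list(
    moa_class = c(
      "nucleoside_analog", "protease_inhibitor", "ns5a_inhibitor",
      "interferon", "impdh_inhibitor", "endonuclease_inhibitor", "nnrti",
      "entry_inhibitor", "kinase_inhibitor", "ion_channel_blocker",
      "dhodh_inhibitor", "cyclophilin_inhibitor"
    ),
    target_kind = c("virus", "host", "both", "unknown"),
    replication_stage = c("entry", "replication", "exit", "unknown"),
    immunomodulatory = c("yes", "no", "unknown"),
    routes = c(
      "oral", "intravenous", "inhalation", "topical", "subcutaneous",
      "intramuscular", "other"
    ),
    infected_systems = c(
      "respiratory", "digestive", "cardiovascular", "nervous",
      "integumentary", "urogenital", "multiple"
    ),
    activity_status = c(
      "approved_or_phase4", "phase1_3", "in_vivo", "in_vitro", "untested"
    )
  )
}

## Development-status ladder for the C_DDS component.
.dds_ladder <- c(
  approved_or_phase4 = 1, phase1_3 = 0.75, in_vivo = 0.5,
  in_vitro = 0.25, untested = 0
)

## Taxonomic-relation ladder for the C_Phyl component.
.phyl_ladder <- c(same_genus = 1, same_family = 0.5, related_family = 0.25)

#' Normalize a free-text name into a join key
#'
#' Drug and virus annotations come from free-text sources; joins need a stable
#' key. Keys are lower-cased, trimmed, and internal whitespace is collapsed to
#' a single underscore.
#'
#' @param x Character vector of names or ids.
#' @return Character vector of normalized ids.
#' @examples
#' normalize_id(" Ebola  Virus ")
#' @export
normalize_id <- function(x) {
  x <- trimws(tolower(as.character(x)))
  gsub("\\s+", "_", x)
}

#' Canonical ordering of an unordered drug pair
#'
#' Combinations are unordered; one canonical representation (lexicographic on
#' the normalized ids) is stored and compared everywhere.
#'
#' @param drug_a,drug_b Drug ids (normalized internally).
#' @return Character vector of length 2, sorted.
#' @examples
#' canonical_pair("ribavirin", "favipiravir")
#' @export
canonical_pair <- function(drug_a, drug_b) {
  a <- normalize_id(drug_a)
  b <- normalize_id(drug_b)
  if (length(a) != 1L || length(b) != 1L) {
    stop("canonical_pair() takes exactly two single ids", call. = FALSE)
  }
  if (identical(a, b)) {
    stop("degenerate pair: both drugs are '", a, "'", call. = FALSE)
  }
  sort(c(a, b), method = "radix")
}

## Split/join semicolon-delimited set cells. Empty cells are empty sets.
split_set <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  unique(out[nzchar(out)])
}

join_set <- function(x) paste(x, collapse = ";")

## Map a scalar enum value into its vocabulary; out-of-vocabulary values
## become "unknown" with a warning (MoA has its own "other:" rule).
normalize_enum <- function(x, vocab, field, id) {
  x <- trimws(tolower(as.character(x)))
  if (length(x) != 1L || is.na(x) || !nzchar(x)) x <- "unknown"
  if (!x %in% vocab) {
    warning(sprintf("%s: unknown %s value '%s' recorded as 'unknown'", id, field, x),
            call. = FALSE)
    x <- "unknown"
  }
  x
}

normalize_moa <- function(x, vocab, id) {
  x <- trimws(tolower(as.character(x)))
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return("other:unspecified")
  if (x %in% vocab || startsWith(x, "other:")) return(x)
  warning(sprintf("%s: moa_class '%s' outside vocabulary, flagged as 'other:%s'", id, x, x),
          call. = FALSE)
  paste0("other:", x)
}
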