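# Normalized residue numbering: map any LDH/MalDH-family sequence onto the
# family-standard numbering via global pairwise alignment to the packaged
# reference, so that positions like 68/102/171/246/250 are comparable across
# proteins.

#' Map a query sequence onto the normalized LDH numbering
#'
#' Globally aligns `query` to the reference profile (BLOSUM62 scores, affine
#' gaps) and reads one `(query_index, normalized_number)` pair off every
#' aligned column.  Query residues falling in insertions relative to the
#' reference are reported in `unmapped_query` rather than being forced onto
#' a number; insertion codes (102A-style) are deliberately not modelled.
#'
#' @param query One-letter amino-acid sequence (length >= 30), or a named
#'   character of length 1 (name used as `query_id`).
#' @param ref A [reference_profile()]; defaults to the packaged LDH
#'   reference.
#' @param query_id Identifier stored on the map.
#' @param gap_opening,gap_extension Affine gap penalties for the alignment.
#' @param identity_floor Fraction of identical aligned columns below which
#'   the map is flagged `low_identity` (family membership doubtful).
#' @return A `residue_map`: list with `query_id`, `pairs` (data.frame
#'   `query_index`, `normalized_number`), `unmapped_query` (integer vector),
#'   `identity`, `low_identity` flag.
#' @export
#' @examples
#' ref <- ldh_reference()
#' m <- build_residue_map(ref$sequence, ref)
#' nrow(m$pairs) == nchar(ref$sequence)
build_residue_map <- function(query, ref = ldh_reference(),
                              query_id = NULL,
                              gap_opening = 10, gap_extension = 0.5,
                              identity_floor = 0.15) {
  if (is.null(query_id))
    query_id <- if (!is.null(names(query))) names(query)[1] else "query"
  query <- toupper(as.character(query)[1])
  if (is.na(query) || !nzchar(query))
    stop("empty query sequence", call. = FALSE)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", query))
    stop("query is not a valid one-letter protein sequence", call. = FALSE)
  if (nchar(query) < 30)
    stop("query shorter than 30 residues; not alignable to the family reference",
         call. = FALSE)
  stopifnot(inherits(ref, "reference_profile"))

  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = ref$sequence,
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  qi <- cumsum(qa != "-")
  si <- cumsum(sa != "-")
  both <- qa != "-" & sa != "-"
  pairs <- data.frame(query_index = qi[both],
                      normalized_number = ref$normalized_numbers[si[both]])
  unmapped <- qi[qa != "-" & sa == "-"]
  identity <- if (any(both)) mean(qa[both] == sa[both]) else 0

  map <- structure(list(query_id = query_id,
                        query_sequence = query,
                        reference_id = ref$reference_id,
                        pairs = pairs,
                        unmapped_query = as.integer(unmapped),
                        identity = identity,
                        low_identity = identity < identity_floor,
                        reference_range = range(ref$normalized_numbers)),
                   class = "residue_map")
  if (map$low_identity)
    warning(sprintf("alignment identity %.1f%% below %.0f%% floor for '%s'; family membership doubtful",
                    100 * identity, 100 * identity_floor, query_id),
            call. = FALSE)
  .validate_residue_map(map)
  map
}

.validate_residue_map <- function(map) {
  p <- map$pairs
  if (nrow(p)) {
    if (any(diff(p$query_index) <= 0) || any(diff(p$normalized_number) <= 0))
      stop("residue map violates colinearity (crossing pairs)", call. = FALSE)
  }
  invisible(map)
}

#' Residue occupying a normalized position
#'
#' @param map A `residue_map` built from `seq` (defaults to the sequence
#'   recorded on the map).
#' @param normalized Normalized residue number to look up.
#' @param seq Optional override of the query sequence.
#' @return Single amino-acid character, or `NA_character_` if the position
#'   is deleted in the query.
#' @export
residue_at <- function(map, normalized, seq = NULL) {
  stopifnot(inherits(map, "residue_map"))
  seq <- if (is.null(seq)) map$query_sequence else toupper(as.character(seq))
  normalized <- as.integer(normalized)
  ref_nums <- map$pairs$normalized_number
  rng <- map$reference_range
  if (is.null(rng)) rng <- range(ref_nums)
  if (normalized < rng[1] || normalized > rng[2])
    stop(sprintf("normalized position %d outside reference range [%d, %d]",
                 normalized, rng[1], rng[2]), call. = FALSE)
  i <- match(normalized, ref_nums)
  if (is.na(i)) return(NA_character_)
  substr(seq, map$pairs$query_index[i], map$pairs$query_index[i])
}

#' @export
print.residue_map <- function(x, ...) {
  cat("<residue_map> ", x$query_id, " -> ", x$reference_id, ": ",
      nrow(x$pairs), " mapped, ", length(x$unmapped_query),
      " unmapped, identity ", sprintf("%.1f%%", 100 * x$identity),
      if (isTRUE(x$low_identity)) " [LOW IDENTITY]" else "", "\n", sep = "")
  invisible(x)
}

#' Write a residue map as CSV and JSON
#'
#' @param map A `residue_map`.
#' @param path_prefix Output path without extension; `.csv` and `.json`
#'   files are written next to each other.
#' @return Invisibly, the two paths written.
#' @export
write_residue_map <- function(map, path_prefix) {
  stopifnot(inherits(map, "residue_map"))
  csv <- paste0(path_prefix, ".csv")
  json <- paste0(path_prefix, ".json")
  utils::write.csv(map$pairs, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(query_id = map$query_id, reference_id = map$reference_id,
         identity = map$identity, low_identity = map$low_identity,
         pairs = map$pairs, unmapped_query = map$unmapped_query),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a plain named
#' character vector, the currency of this package's sequence operations.
#'
#' @param path FASTA file (single- or multi-record).
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
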