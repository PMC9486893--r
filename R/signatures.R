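# Catalytic-site signature residues at normalized positions 68, 102, 199,
# 246 and 250, and their LDH-like vs MalDH-type-3-like classification, with
# iTOL-style tree annotation export.

# Rule set: position -> (LDH_like residues, MalDH_like residues).
# 199 has no MalDH_like class: the figure convention marks only the acidic
# D/E as LDH-like; the typical MalDH M199 is reported as "other" with the
# raw residue kept alongside, so acidic-vs-not remains reproducible.
.SIGNATURE_RULES <- list(
  `68`  = list(LDH_like = "H",        MalDH_like = c("D", "Q")),
  `102` = list(LDH_like = "Q",        MalDH_like = "R"),
  `199` = list(LDH_like = c("D", "E"), MalDH_like = character(0)),
  `246` = list(LDH_like = "T",        MalDH_like = c("A", "S")),
  `250` = list(LDH_like = "I",        MalDH_like = "P")
)

#' Signature positions with classification rules
#' @return Integer vector of supported normalized positions.
#' @export
signature_positions <- function() as.integer(names(.SIGNATURE_RULES))

#' Classify a residue at a signature position
#'
#' Pure positional rule set: 102 Q/R, 246 T vs A/S, 250 I/P, 68 H vs D/Q
#' discriminate LDH-like from MalDH-type-3-like; 199 marks only the acidic
#' LDH residue (D/E), everything else being `other`.
#'
#' @param position Normalized position, one of 68, 102, 199, 246, 250.
#' @param residue One-letter amino acid (or `NA` for an absent position).
#' @return One of `"LDH_like"`, `"MalDH_like"`, `"other"`, `"absent"`.
#' @export
#' @examples
#' classify_position(102, "Q")  # LDH_like
#' classify_position(68, "D")   # MalDH_like
classify_position <- function(position, residue) {
  key <- as.character(as.integer(position))
  rule <- .SIGNATURE_RULES[[key]]
  if (is.null(rule))
    stop(sprintf("position %s is not a supported signature position (%s)",
                 key, paste(names(.SIGNATURE_RULES), collapse = ", ")),
         call. = FALSE)
  if (length(residue) != 1 || is.na(residue) || !nzchar(residue))
    return("absent")
  residue <- toupper(residue)
  if (residue %in% rule$LDH_like) "LDH_like"
  else if (residue %in% rule$MalDH_like) "MalDH_like"
  else "other"
}

#' Signature table for a set of sequences
#'
#' Maps each sequence onto the normalized numbering ([build_residue_map()]),
#' extracts the residues at the requested signature positions and classifies
#' them.  Unmappable sequences are kept as flagged rows, never dropped.
#'
#' @param seqs Named character vector of protein sequences (aligned or not;
#'   gap characters are stripped before mapping).
#' @param positions Signature positions to report (subset of
#'   [signature_positions()]).
#' @param ref Reference profile for the numbering.
#' @return Data frame with one row per sequence: `id`, `mapped`,
#'   `identity`, and per position `res_<p>` / `class_<p>` columns.
#' @export
signature_table <- function(seqs, positions = signature_positions(),
                            ref = ldh_reference()) {
  positions <- as.integer(positions)
  bad <- setdiff(positions, signature_positions())
  if (length(bad))
    stop("unsupported signature positions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))

  rows <- lapply(names(seqs), function(id) {
    s <- gsub("[-.]", "", seqs[[id]])
    row <- list(id = id, mapped = FALSE, identity = NA_real_)
    map <- tryCatch(suppressWarnings(build_residue_map(s, ref, query_id = id)),
                    error = function(e) NULL)
    for (p in positions) {
      res <- if (is.null(map)) NA_character_ else residue_at(map, p)
      row[[paste0("res_", p)]] <- if (is.na(res)) NA_character_ else res
      row[[paste0("class_", p)]] <- classify_position(p, res)
    }
    if (!is.null(map)) {
      row$mapped <- TRUE
      row$identity <- map$identity
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "positions") <- positions
  out
}

#' Export iTOL-style binary annotation datasets for a tree
#'
#' Writes one plain-text DATASET_BINARY-dialect file per signature position,
#' with one field per class (LDH_like, MalDH_like, other) so each circle of
#' a tree figure can be rendered from one file.  Leaf matching is exact
#' string match after whitespace trimming; orphan table ids are reported
#' with a warning, never fuzzily matched.
#'
#' @param table A [signature_table()] result.
#' @param tree An [ape::phylo] tree or path to a Newick file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths of the files written.
#' @export
export_tree_annotation <- function(table, tree, out_dir) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  leaves <- trimws(tree$tip.label)
  ids <- trimws(table$id)
  keep <- ids %in% leaves
  if (!any(keep))
    stop("no overlap between signature table ids and tree leaf labels",
         call. = FALSE)
  if (any(!keep))
    warning("signature table ids not present in tree (omitted): ",
            paste(ids[!keep], collapse = ", "), call. = FALSE)

  positions <- attr(table, "positions")
  if (is.null(positions))
    positions <- as.integer(sub("^class_", "",
                                grep("^class_", names(table), value = TRUE)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- c("LDH_like", "MalDH_like", "other")
  paths <- character(0)
  for (p in positions) {
    path <- file.path(out_dir, sprintf("signature_pos%d.txt", p))
    cls <- table[[paste0("class_", p)]]
    res <- table[[paste0("res_", p)]]
    lines <- c(
      "DATASET_BINARY",
      "SEPARATOR COMMA",
      sprintf("DATASET_LABEL,position %d", p),
      "COLOR,#2c7fb8",
      "FIELD_SHAPES,2,2,2",
      paste0("FIELD_LABELS,", paste(classes, collapse = ",")),
      "DATA")
    for (i in which(keep)) {
      if (cls[i] == "absent") next  # absent positions are omitted, not invented
      flags <- ifelse(classes == cls[i], "1", "-1")
      lines <- c(lines, paste(c(ids[i], flags,
                                if (is.na(res[i])) "" else res[i]),
                              collapse = ","))
    }
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Parse back an annotation file written by [export_tree_annotation()]
#'
#' @param path Annotation file path.
#' @return Data frame `id`, `class`, `residue`.
#' @export
read_tree_annotation <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(sub("^FIELD_LABELS,", "",
                         grep("^FIELD_LABELS,", lines, value = TRUE)), ",")[[1]]
  data_at <- match("DATA", lines)
  rows <- lines[seq.int(data_at + 1, length(lines))]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, ",")
  data.frame(
    id = vapply(parts, `[`, "", 1),
    class = vapply(parts, function(x) fields[which(x[2:4] == "1")[1]], ""),
    residue = vapply(parts, function(x) if (length(x) >= 5) x[5] else NA_character_, ""),
    stringsAsFactors = FALSE)
}
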