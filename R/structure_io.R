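# Conformer ensembles: multi-model PDB in/out and resolution of
# (chain, normalized residue, atom name) triplets to coordinates.
#
# Multi-model PDB is the interchange format for structural ensembles here;
# an MD trajectory exported frame-by-frame to PDB models is read with the
# same code path as a crystal structure (1 model = 1 frame).

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", HSD = "H", HSE = "H", HSP = "H")

#' Construct a conformer ensemble
#'
#' @param atoms Data frame with columns `chain`, `resid`, `resname`, `atom`
#'   (PDB atom-name convention, e.g. `CA`, `CG`), one row per atom; ordering
#'   is identical across frames.
#' @param coords Numeric array `n_atoms x 3 x n_frames` in Angstrom.
#' @param frame_times Optional numeric vector of frame labels in
#'   picoseconds.
#' @return A `conformer_ensemble` object.
#' @export
conformer_ensemble <- function(atoms, coords, frame_times = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "resid", "resname", "atom") %in% names(atoms)))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[1] == nrow(atoms))
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in ensemble", call. = FALSE)
  if (!is.null(frame_times))
    stopifnot(length(frame_times) == dim(coords)[3])
  structure(list(atoms = atoms, coords = coords,
                 frame_times = frame_times, residue_maps = NULL),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", n_frames(x), " frame(s), ", nrow(x$atoms),
      " atoms, chains ", paste(ensemble_chains(x), collapse = ","),
      if (!is.null(x$residue_maps)) " [numbering attached]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble A `conformer_ensemble`.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Protein chains present in an ensemble
#' @param ensemble A `conformer_ensemble`.
#' @export
ensemble_chains <- function(ensemble) unique(ensemble$atoms$chain)

#' Read a (multi-model) PDB file as a conformer ensemble
#'
#' ATOM records only (solvent/ligand HETATM skipped); every MODEL becomes
#' one frame and all models must share atom count and ordering.  Alternate
#' locations keep the highest-occupancy conformer; insertion-coded residues
#' are rejected.
#'
#' @param path PDB file.
#' @return A `conformer_ensemble`.  Frame times, if present as
#'   `REMARK 250 FRAME_TIME_PS` records, are attached.
#' @export
read_pdb_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  if (!any(rec == "ATOM  "))
    stop("no ATOM records found; unknown or non-PDB format: ", path,
         call. = FALSE)

  model_starts <- which(rec == "MODEL ")
  model_ends <- which(rec == "ENDMDL")
  times <- suppressWarnings(as.numeric(sub("^REMARK 250 FRAME_TIME_PS\\s+", "",
    grep("^REMARK 250 FRAME_TIME_PS", lines, value = TRUE))))
  if (!length(times)) times <- NULL

  parse_block <- function(block) {
    block <- block[substr(block, 1, 6) == "ATOM  "]
    altloc <- substr(block, 17, 17)
    icode <- substr(block, 27, 27)
    if (any(icode != " "))
      stop("insertion-coded residues are not supported", call. = FALSE)
    df <- data.frame(
      atom = trimws(substr(block, 13, 16)),
      altloc = altloc,
      resname = trimws(substr(block, 18, 20)),
      chain = substr(block, 22, 22),
      resid = as.integer(substr(block, 23, 26)),
      x = as.numeric(substr(block, 31, 38)),
      y = as.numeric(substr(block, 39, 46)),
      z = as.numeric(substr(block, 47, 54)),
      occ = suppressWarnings(as.numeric(substr(block, 55, 60))),
      stringsAsFactors = FALSE)
    if (any(df$altloc != " ")) {
      df$occ[is.na(df$occ)] <- 1
      key <- paste(df$chain, df$resid, df$atom)
      ord <- order(key, -df$occ)
      df <- df[ord, ][!duplicated(key[ord]), ]
      df <- df[order(as.integer(rownames(df))), ]
    }
    df
  }

  if (length(model_starts) == 0) {
    blocks <- list(parse_block(lines))
  } else {
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    blocks <- mapply(function(s, e) parse_block(lines[s:e]),
                     model_starts, model_ends, SIMPLIFY = FALSE)
  }

  n0 <- nrow(blocks[[1]])
  for (i in seq_along(blocks))
    if (nrow(blocks[[i]]) != n0)
      stop(sprintf("atom-count mismatch between frames: frame 1 has %d atoms, frame %d has %d",
                   n0, i, nrow(blocks[[i]])), call. = FALSE)

  coords <- array(NA_real_, c(n0, 3, length(blocks)))
  for (i in seq_along(blocks))
    coords[, , i] <- as.matrix(blocks[[i]][, c("x", "y", "z")])
  atoms <- blocks[[1]][, c("chain", "resid", "resname", "atom")]
  rownames(atoms) <- NULL
  conformer_ensemble(atoms, coords,
                     frame_times = if (!is.null(times) &&
                                       length(times) == length(blocks)) times)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  a <- ensemble$atoms
  nf <- n_frames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ensemble$frame_times))
    writeLines(sprintf("REMARK 250 FRAME_TIME_PS %.3f", ensemble$frame_times),
               con)
  name_field <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                       sprintf("%-4s", a$atom))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$coords[, , f]
    writeLines(sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       seq_len(nrow(a)) %% 100000L, name_field, a$resname,
                       a$chain, a$resid, xyz[, 1], xyz[, 2], xyz[, 3],
                       1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' One-letter sequence of each chain in an ensemble
#'
#' Derived from CA-carrying residues in residue-index order; unknown
#' residue names become `X`.
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Named character vector, one sequence per chain.
#' @export
ensemble_sequences <- function(ensemble) {
  a <- ensemble$atoms
  ca <- a[a$atom == "CA", ]
  vapply(ensemble_chains(ensemble), function(ch) {
    sub <- ca[ca$chain == ch, ]
    sub <- sub[order(sub$resid), ]
    paste(ifelse(is.na(.AA3TO1[sub$resname]), "X", .AA3TO1[sub$resname]),
          collapse = "")
  }, character(1))
}

#' Attach normalized numbering to an ensemble
#'
#' Builds one [build_residue_map()] per chain (from supplied sequences or
#' from the structure itself) so that atoms can be addressed by normalized
#' residue number via [atom_ref()].
#'
#' @param ensemble A `conformer_ensemble`.
#' @param sequences Optional named character vector of per-chain sequences;
#'   defaults to [ensemble_sequences()].
#' @param ref Reference profile.
#' @param identity_maps If `TRUE`, bypass alignment and number each chain by
#'   its own residue indices (correct for structures already in normalized
#'   numbering, e.g. the synthetic ensembles of this package).
#' @return The ensemble with `residue_maps` populated.
#' @export
attach_numbering <- function(ensemble, sequences = NULL,
                             ref = ldh_reference(), identity_maps = FALSE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  chains <- ensemble_chains(ensemble)
  if (is.null(sequences)) sequences <- ensemble_sequences(ensemble)
  maps <- list()
  for (ch in chains) {
    a <- ensemble$atoms
    resids <- sort(unique(a$resid[a$chain == ch & a$atom == "CA"]))
    if (identity_maps) {
      maps[[ch]] <- list(identity = TRUE,
                         resids = sort(unique(a$resid[a$chain == ch])))
    } else {
      if (is.na(sequences[ch]))
        stop("no sequence available for chain ", ch, call. = FALSE)
      map <- suppressWarnings(
        build_residue_map(sequences[[ch]], ref, query_id = ch))
      # query_index is 1-based along the chain sequence; convert to resid
      maps[[ch]] <- list(identity = FALSE, resids = resids, map = map)
    }
  }
  ensemble$residue_maps <- maps
  ensemble
}

#' Reference to one atom by chain, normalized residue number and atom name
#'
#' @param chain Chain identifier.
#' @param normalized Normalized residue number.
#' @param atom PDB atom name; `"CG"` also matches `CG1` (the isoleucine
#'   gamma carbon), matching the field's loose use of "Cgamma" across
#'   Arg/Gln/His/Ile.
#' @return An `atom_ref` object.
#' @export
atom_ref <- function(chain, normalized, atom) {
  structure(list(chain = as.character(chain),
                 normalized = as.integer(normalized),
                 atom = toupper(as.character(atom))),
            class = "atom_ref")
}

#' @export
format.atom_ref <- function(x, ...)
  sprintf("%s/%d/%s", x$chain, x$normalized, x$atom)

# Resolve an atom_ref to a row index of ensemble$atoms.
resolve_atom <- function(ensemble, ref) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(ref, "atom_ref"))
  maps <- ensemble$residue_maps
  if (is.null(maps))
    stop("ensemble has no numbering attached; call attach_numbering() first",
         call. = FALSE)
  m <- maps[[ref$chain]]
  if (is.null(m))
    stop("no residue map for chain ", ref$chain, call. = FALSE)
  if (isTRUE(m$identity)) {
    resid <- ref$normalized
    if (!(resid %in% m$resids))
      stop(sprintf("normalized position %d absent in chain %s",
                   ref$normalized, ref$chain), call. = FALSE)
  } else {
    i <- match(ref$normalized, m$map$pairs$normalized_number)
    if (is.na(i))
      stop(sprintf("normalized position %d is deleted/absent in chain %s",
                   ref$normalized, ref$chain), call. = FALSE)
    resid <- m$resids[m$map$pairs$query_index[i]]
  }
  a <- ensemble$atoms
  rows <- which(a$chain == ref$chain & a$resid == resid)
  hit <- rows[a$atom[rows] == ref$atom]
  if (!length(hit) && ref$atom == "CG")
    hit <- rows[a$atom[rows] == "CG1"]
  if (!length(hit))
    stop(sprintf("atom %s missing in %s %s%d (have: %s)",
                 ref$atom, a$resname[rows[1]], ref$chain, resid,
                 paste(a$atom[rows], collapse = " ")), call. = FALSE)
  hit[1]
}

#' Coordinates of one atom in one frame
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param ref An [atom_ref()].
#' @param frame Frame index (1-based).
#' @return Numeric length-3 vector (Angstrom).
#' @export
coordinates <- function(ensemble, ref, frame = 1L) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > n_frames(ensemble))
    stop(sprintf("frame %d out of range [1, %d]", frame, n_frames(ensemble)),
         call. = FALSE)
  ensemble$coords[resolve_atom(ensemble, ref), , frame]
}

#' Export the atom table of an ensemble as CSV
#' @param ensemble A `conformer_ensemble`.
#' @param path Output CSV path.
#' @export
write_atom_table <- function(ensemble, path) {
  utils::write.csv(ensemble$atoms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
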