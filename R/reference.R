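# Packaged reference profile for normalized (Eventoff-style) LDH numbering.
#
# SYNTHETIC STAND-IN: the canonical correspondence table between a real LDH
# primary sequence and the normalized numbering is published only as
# supplementary material elsewhere and is not redistributed here.  This
# profile is a constructed 320-residue LDH-like sequence in which the
# normalized number of every residue equals its sequence index, and the
# family's conserved catalytic-site residues are planted at their normalized
# positions: H68, Q102, R109, P141, L167, D168, R171, N181, H195, D199,
# T246, I250, S251.  All numbering operations are exact on this profile by
# construction; mappings of real sequences through it are alignment-based
# approximations and should be flagged, not silently trusted.

.LDH_REF_SEQ <- paste0(
  "MEGRTMFARQAKLFNHGTSALRARTEQSPSVGPTLAMSIEDLASSRSDSLNYLTCRLGPKLNAA",
  "YLRHLKQTLGLPWDGQSAVLCVEHALGGHQEAKVKENQSIGGDGRYHHSASDYESMAIRTPSPH",
  "LLILDIKNNIHTPTAACLTPVQKPIVSLKVEPEQPLAHLDPLRDQPLLRTLVNSSESTCGSILT",
  "KPHCEFDVVASQEVLSQPRENDERADELRVLMVVFSYVTMLWPSSERVAAMKFTQSFISKVPAL",
  "KQIMAELLSPGMLCNRANDWIFKSKQILMVLAPDGMLQKQLDVDAGIPFSVSEMDLGRVISIAV"
)

#' Reference profile carrying the normalized LDH numbering
#'
#' Builds a [reference_profile] for the packaged synthetic LDH-like
#' reference.  The normalized number of each reference residue equals its
#' 1-based sequence index, so positions discussed throughout the package
#' (68, 102, 109, 141, 167, 171, 181, 199, 246, 250) address this sequence
#' directly.  See the source file header for why this reference is a
#' synthetic stand-in rather than a published dogfish-numbered LDH.
#'
#' @return A `reference_profile` object.
#' @export
#' @examples
#' ref <- ldh_reference()
#' substr(ref$sequence, 102, 102)  # "Q"
ldh_reference <- function() {
  reference_profile("builtin:ldh_synthetic", .LDH_REF_SEQ,
                    seq_len(nchar(.LDH_REF_SEQ)))
}

#' Construct a reference profile
#'
#' A reference profile ties an amino-acid sequence to a strictly increasing
#' vector of normalized residue numbers (one per residue).  It is the anchor
#' against which query sequences are mapped by [build_residue_map()].
#'
#' @param reference_id Identifier string.
#' @param sequence One-letter amino-acid sequence.
#' @param normalized_numbers Integer vector, one per residue, strictly
#'   increasing.
#' @return A `reference_profile` object (list with fields `reference_id`,
#'   `sequence`, `normalized_numbers`).
#' @export
reference_profile <- function(reference_id, sequence, normalized_numbers) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence) || !grepl("^[ACDEFGHIKLMNPQRSTVWYX*-]+$", sequence))
    stop("invalid amino-acid sequence for reference profile", call. = FALSE)
  normalized_numbers <- as.integer(normalized_numbers)
  if (length(normalized_numbers) != nchar(sequence))
    stop("normalized_numbers must have one entry per reference residue",
         call. = FALSE)
  if (any(diff(normalized_numbers) <= 0))
    stop("normalized_numbers must be strictly increasing", call. = FALSE)
  structure(list(reference_id = as.character(reference_id),
                 sequence = sequence,
                 normalized_numbers = normalized_numbers),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile> ", x$reference_id, ": ", nchar(x$sequence),
      " residues, normalized ", min(x$normalized_numbers), "-",
      max(x$normalized_numbers), "\n", sep = "")
  invisible(x)
}
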