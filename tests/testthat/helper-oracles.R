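# Independent oracles and small fixture builders used across the suite.

# Brute-force affine-gap global alignment (Gotoh), independent of the
# Biostrings-backed implementation path.  Returns the aligned index pairs.
oracle_global_align <- function(q, s, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  qa <- strsplit(q, "")[[1]]; sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M  # X: gap in s, Y: gap in q
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 2) * ext
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 2) * ext
  ptr <- array("", c(n + 1, m + 1, 3))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- B[qa[i - 1], sa[j - 1]]
    cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    M[i, j] <- max(cand) + sc
    ptr[i, j, 1] <- c("M", "X", "Y")[which.max(cand)]
    cand <- c(M[i - 1, j] - open, X[i - 1, j] - ext)
    X[i, j] <- max(cand); ptr[i, j, 2] <- c("M", "X")[which.max(cand)]
    cand <- c(M[i, j - 1] - open, Y[i, j - 1] - ext)
    Y[i, j] <- max(cand); ptr[i, j, 3] <- c("M", "Y")[which.max(cand)]
  }
  st <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                     Y[n + 1, m + 1]))]
  i <- n + 1; j <- m + 1
  pairs <- NULL; unmapped <- integer(0)
  while (i > 1 || j > 1) {
    if (st == "M") {
      pairs <- rbind(c(i - 1, j - 1), pairs)
      st <- ptr[i, j, 1]; i <- i - 1; j <- j - 1
    } else if (st == "X") {
      unmapped <- c(i - 1, unmapped)
      st <- ptr[i, j, 2]; i <- i - 1
    } else {
      st <- ptr[i, j, 3]; j <- j - 1
    }
  }
  list(pairs = pairs, unmapped_query = unmapped,
       score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
}

# Rodrigues rotation matrix about a unit axis (test-side oracle).
oracle_rotation <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2)); th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# CA-only single-chain ensemble whose residue names spell out `sequence`;
# resids start at `first_resid`.  Used to exercise the alignment-backed
# numbering path on structures.
one2three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
ca_ensemble_from_sequence <- function(sequence, chain = "A",
                                      first_resid = 1L) {
  aas <- strsplit(sequence, "")[[1]]
  n <- length(aas)
  i <- seq_len(n)
  atoms <- data.frame(chain = chain, resid = first_resid + i - 1L,
                      resname = unname(one2three[aas]), atom = "CA")
  coords <- array(cbind(10 * cos(0.4 * i), 1.6 * i, 10 * sin(0.4 * i)),
                  c(n, 3, 1))
  conformer_ensemble(atoms, coords)
}

# Tiny hand-built ensemble: two residues, planted coordinates.
toy_two_atom_ensemble <- function(p1 = c(0, 0, 0), p2 = c(3, 4, 0)) {
  atoms <- data.frame(chain = "A", resid = c(141L, 171L),
                      resname = c("PRO", "ARG"), atom = c("CA", "CG"))
  ens <- conformer_ensemble(atoms, array(rbind(p1, p2), c(2, 3, 1)))
  attach_numbering(ens, identity_maps = TRUE)
}
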