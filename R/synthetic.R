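# Synthetic ground-truth generators: dimeric conformer ensembles with
# planted R-in/T-out side-chain positions, helix rotations and dihedral
# substates; substrate-saturation curves from the three rate laws; and
# sequence-family fixtures with planted signature residues.
#
# The pseudo-structures are geometric, not chemical: only the atoms the
# analyses touch are emitted, and residues sit on an idealized backbone
# curve so rigid-body superposition is well-conditioned.

#' Specification for a synthetic conformer ensemble
#'
#' Defaults encode the stated world of the analyses: a dimer whose monomers
#' sample an R-like basin (R171 in, d(R171-P141) ~ 14.5 A, helix angle ~ 0)
#' and a T-like basin (R171 out at ~ 21 A by default, or the printed
#' out-state doublet 17/20 A when requested, helix rotated "under" ~ 12
#' degrees), a mobile loop whose closed state sits at the printed
#' (13.1, 9.6) A exemplar, and a position-250 isoleucine whose (chi1, chi2)
#' side chain hops between three planted rotamer modes with occupancies
#' 0.5/0.3/0.2.
#'
#' @param n_frames Frames per chain.
#' @param fractions Named fractions for `R_like`, `T_like`, `intermediate`
#'   frames (must sum to 1).
#' @param d_in_mean,d_in_sd In-state R171(CG)-P141(CA) distance, A.
#' @param d_out_means,d_out_sd Out-state distance mode(s), A; give two
#'   means for a doublet.
#' @param d_int_mean,d_int_sd Intermediate-band distance, A.
#' @param theta_R_sd SD of the helix angle in R-like frames (mean 0), deg.
#' @param theta_T_mean,theta_T_sd Helix angle in T-like frames, deg.
#' @param theta_int_mean,theta_int_sd Helix angle in intermediate frames.
#' @param loop_fractions Named fractions for loop `closed`, `open`,
#'   `intermediate` frames.
#' @param loop_closed,loop_open,loop_int Planted (d102, d109) means, A.
#' @param loop_sd SD of loop distances, A.
#' @param chi_modes Matrix with columns `chi1`, `chi2`, `occupancy`
#'   (degrees; occupancies sum to 1).
#' @param chi_sd SD of dihedral modes, degrees.
#' @param res250 `"ILE"` (chi-defined side chain) or `"PRO"` (no chi2;
#'   substate analysis refuses it).
#' @param coord_noise_sd Isotropic Gaussian coordinate noise, A.
#' @param seed Mandatory RNG seed.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_frames = 500L,
                          fractions = c(R_like = 0.7, T_like = 0.3,
                                        intermediate = 0),
                          d_in_mean = 14.5, d_in_sd = 0.5,
                          d_out_means = 21, d_out_sd = 0.5,
                          d_int_mean = 17, d_int_sd = 0.3,
                          theta_R_sd = 1.5,
                          theta_T_mean = 12, theta_T_sd = 1.5,
                          theta_int_mean = 6, theta_int_sd = 0.8,
                          loop_fractions = c(closed = 1, open = 0,
                                             intermediate = 0),
                          loop_closed = c(d102 = 13.1, d109 = 9.6),
                          loop_open = c(d102 = 22, d109 = 21),
                          loop_int = c(d102 = 17, d109 = 13),
                          loop_sd = 0.3,
                          chi_modes = cbind(chi1 = c(-60, 65, 180),
                                            chi2 = c(170, -60, 60),
                                            occupancy = c(0.5, 0.3, 0.2)),
                          chi_sd = 8,
                          res250 = c("ILE", "PRO"),
                          coord_noise_sd = 0.1,
                          seed) {
  if (missing(seed)) stop("seed is mandatory for ensemble_spec", call. = FALSE)
  res250 <- match.arg(res250)
  spec <- list(n_frames = as.integer(n_frames), fractions = fractions,
               d_in_mean = d_in_mean, d_in_sd = d_in_sd,
               d_out_means = d_out_means, d_out_sd = d_out_sd,
               d_int_mean = d_int_mean, d_int_sd = d_int_sd,
               theta_R_sd = theta_R_sd, theta_T_mean = theta_T_mean,
               theta_T_sd = theta_T_sd, theta_int_mean = theta_int_mean,
               theta_int_sd = theta_int_sd,
               loop_fractions = loop_fractions, loop_closed = loop_closed,
               loop_open = loop_open, loop_int = loop_int, loop_sd = loop_sd,
               chi_modes = chi_modes, chi_sd = chi_sd, res250 = res250,
               coord_noise_sd = coord_noise_sd, seed = as.integer(seed))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("state fractions must sum to 1", call. = FALSE)
  if (abs(sum(loop_fractions) - 1) > 1e-9)
    stop("loop fractions must sum to 1", call. = FALSE)
  if (abs(sum(chi_modes[, "occupancy"]) - 1) > 1e-9)
    stop("chi-mode occupancies must sum to 1", call. = FALSE)
  if (any(c(d_in_sd, d_out_sd, theta_R_sd, theta_T_sd, loop_sd, chi_sd,
            coord_noise_sd) < 0))
    stop("SDs must be non-negative", call. = FALSE)
  structure(spec, class = "ensemble_spec")
}

# place atom D from A-B-C with bond |CD|, angle B-C-D (deg) and torsion
# A-B-C-D (deg): natural extension reference frame.
.place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# integer state counts honouring fractions exactly (largest remainder)
.alloc_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  counts
}

#' Generate a synthetic dimer conformer ensemble with known truth
#'
#' Builds a two-chain pseudo-protein (residues at normalized numbering,
#' CA everywhere; side-chain atoms only where the analyses need them) and
#' `n_frames` conformers realizing the planted state schedule of the spec:
#' per frame and chain, the R171 Cgamma sits at the scheduled distance from
#' P141 Calpha on the line towards N181 Calpha (which produces the mirror
#' anti-correlation), the alpha2F helix (167-181) is rotated in the X-Z
#' plane by the scheduled angle, loop Cgammas of 102/109 sit at scheduled
#' distances from L167 Calpha, and the 250 side chain realizes scheduled
#' (chi1, chi2) rotamers.
#'
#' @param spec An [ensemble_spec()].
#' @return List `ensemble` (a `conformer_ensemble`, numbering attached as
#'   identity), `reference` (the 1-frame noise-free R-state template,
#'   X-aligned), and `truth` (per-frame planted schedule and the spec).
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  chains <- c("A", "B")
  n_res <- 260L
  nf <- spec$n_frames

  # --- template (one chain), helix 167..181 straight along +X ------------
  i <- seq_len(n_res)
  ca <- cbind(10 * cos(0.35 * i), 1.5 * i, 10 * sin(0.35 * i))
  h0 <- ca[141, ] + c(0, 21.5, 0)          # CA167; |CA141-CA181| ~ 30.5 A
  for (k in 0:14) ca[167 + k, ] <- h0 + c(1.55 * k, 0, 0)

  resname <- rep("ALA", n_res)
  resname[c(68, 195)] <- "HIS"; resname[102] <- "GLN"
  resname[c(109, 171)] <- "ARG"; resname[141] <- "PRO"
  resname[167] <- "LEU"; resname[181] <- "ASN"; resname[246] <- "THR"
  resname[250] <- spec$res250

  build_atoms <- function(chain) {
    rows <- data.frame(chain = chain, resid = i, resname = resname,
                       atom = "CA", stringsAsFactors = FALSE)
    extra <- data.frame(chain = chain,
                        resid = c(68L, 102L, 109L, 171L),
                        resname = resname[c(68, 102, 109, 171)],
                        atom = "CG", stringsAsFactors = FALSE)
    if (spec$res250 == "ILE")
      extra <- rbind(extra, data.frame(chain = chain, resid = 250L,
                                       resname = "ILE",
                                       atom = c("N", "CB", "CG1", "CD1")))
    rbind(rows, extra)
  }
  atoms <- rbind(build_atoms("A"), build_atoms("B"))
  offset <- rbind(A = c(0, 0, 0), B = c(60, 0, 0))

  # row lookup helpers
  row_of <- function(chain, resid, atom)
    which(atoms$chain == chain & atoms$resid == resid & atoms$atom == atom)

  # static directions for planted side-chain placements (per chain)
  u_out <- (ca[181, ] - ca[141, ])
  u_out <- u_out / sqrt(sum(u_out^2))      # R171 CG slide direction
  L_mirror <- sqrt(sum((ca[181, ] - ca[141, ])^2))
  u102 <- c(0.30, -0.80, 0.52); u102 <- u102 / sqrt(sum(u102^2))
  u109 <- c(-0.65, -0.55, 0.52); u109 <- u109 / sqrt(sum(u109^2))

  # --- per-chain schedules ----------------------------------------------
  schedule <- function(chain) {
    st <- rep(names(spec$fractions), .alloc_counts(spec$fractions, nf))
    st <- sample(st)
    lp <- rep(names(spec$loop_fractions),
              .alloc_counts(spec$loop_fractions, nf))
    lp <- sample(lp)
    nmode <- nrow(spec$chi_modes)
    cm <- rep(seq_len(nmode), .alloc_counts(spec$chi_modes[, "occupancy"], nf))
    cm <- sample(cm)
    d <- numeric(nf); theta <- numeric(nf)
    for (f in seq_len(nf)) {
      if (st[f] == "R_like") {
        d[f] <- stats::rnorm(1, spec$d_in_mean, spec$d_in_sd)
        theta[f] <- stats::rnorm(1, 0, spec$theta_R_sd)
      } else if (st[f] == "T_like") {
        mu <- spec$d_out_means[sample.int(length(spec$d_out_means), 1)]
        d[f] <- stats::rnorm(1, mu, spec$d_out_sd)
        theta[f] <- stats::rnorm(1, spec$theta_T_mean, spec$theta_T_sd)
      } else {
        d[f] <- stats::rnorm(1, spec$d_int_mean, spec$d_int_sd)
        theta[f] <- stats::rnorm(1, spec$theta_int_mean, spec$theta_int_sd)
      }
    }
    loop_mean <- rbind(closed = spec$loop_closed, open = spec$loop_open,
                       intermediate = spec$loop_int)
    d102 <- stats::rnorm(nf, loop_mean[lp, 1], spec$loop_sd)
    d109 <- stats::rnorm(nf, loop_mean[lp, 2], spec$loop_sd)
    chi1 <- stats::rnorm(nf, spec$chi_modes[cm, "chi1"], spec$chi_sd)
    chi2 <- stats::rnorm(nf, spec$chi_modes[cm, "chi2"], spec$chi_sd)
    data.frame(state = st, theta = theta, d = d, loop = lp,
               d102 = d102, d109 = d109, chi_mode = cm,
               chi1 = ((chi1 + 180) %% 360) - 180,
               chi2 = ((chi2 + 180) %% 360) - 180)
  }
  sched <- lapply(stats::setNames(chains, chains), function(ch) schedule(ch))

  # --- realize coordinates ----------------------------------------------
  coords <- array(NA_real_, c(nrow(atoms), 3, nf))
  template_chain <- function(chain, f, noise = TRUE) {
    s <- sched[[chain]][f, ]
    xyz <- ca
    # helix rotation in the X-Z plane about CA167
    th <- s$theta * pi / 180
    for (k in 0:14)
      xyz[167 + k, ] <- h0 + 1.55 * k * c(cos(th), 0, sin(th))
    m <- matrix(NA_real_, nrow(atoms[atoms$chain == chain, ]), 3)
    sub <- atoms[atoms$chain == chain, ]
    m[sub$atom == "CA", ] <- xyz
    put <- function(resid, atom, p) m[sub$resid == resid & sub$atom == atom, ] <<- p
    put(171, "CG", ca[141, ] + s$d * u_out)
    put(102, "CG", h0 + s$d102 * u102)
    put(109, "CG", h0 + s$d109 * u109)
    put(68, "CG", ca[68, ] + c(1.1, 1.1, 0.5))
    if (spec$res250 == "ILE") {
      n250 <- ca[250, ] + c(-0.9, 1.1, 0.3)
      put(250, "N", n250)
      cb <- .place_atom(ca[249, ], n250, ca[250, ], 1.53, 110, -122)
      put(250, "CB", cb)
      cg1 <- .place_atom(n250, ca[250, ], cb, 1.53, 114, s$chi1)
      put(250, "CG1", cg1)
      put(250, "CD1", .place_atom(ca[250, ], cb, cg1, 1.53, 114, s$chi2))
    }
    m <- m + matrix(offset[chain, ], nrow(m), 3, byrow = TRUE)
    if (noise && spec$coord_noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$coord_noise_sd),
                      nrow(m), 3)
    m
  }
  idxA <- which(atoms$chain == "A"); idxB <- which(atoms$chain == "B")
  for (f in seq_len(nf)) {
    coords[idxA, , f] <- template_chain("A", f)
    coords[idxB, , f] <- template_chain("B", f)
  }
  ens <- conformer_ensemble(atoms, coords,
                            frame_times = 100 * seq_len(nf))
  ens <- attach_numbering(ens, identity_maps = TRUE)

  # noise-free R-state template as reference (theta = 0, d at in-state mean)
  ref_coords <- array(NA_real_, c(nrow(atoms), 3, 1))
  ref_sched <- lapply(sched, function(s) {
    s[1, ] <- list("R_like", 0, spec$d_in_mean, "closed",
                   spec$loop_closed[1], spec$loop_closed[2], 1L,
                   spec$chi_modes[1, "chi1"], spec$chi_modes[1, "chi2"])
    s
  })
  old <- sched; sched <- ref_sched
  ref_coords[idxA, , 1] <- template_chain("A", 1, noise = FALSE)
  ref_coords[idxB, , 1] <- template_chain("B", 1, noise = FALSE)
  sched <- old
  reference <- attach_numbering(
    conformer_ensemble(atoms, ref_coords), identity_maps = TRUE)
  # template helix is built along +X already; make that explicit/robust
  reference <- align_reference_to_x(reference, "A")

  truth <- list(spec = unclass(spec),
                per_frame = do.call(rbind, lapply(chains, function(ch)
                  cbind(chain = ch, frame = seq_len(nf), sched[[ch]]))))
  list(ensemble = ens, reference = reference, truth = truth)
}

#' Write a synthetic ensemble fixture to disk
#'
#' Multi-model PDB, reference PDB, and a sidecar truth JSON; tests read
#' planted values only from the truth file.
#'
#' @param spec An [ensemble_spec()].
#' @param dir Output directory.
#' @return Invisibly, the list of paths.
#' @export
write_ensemble_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- make_ensemble(spec)
  paths <- list(pdb = file.path(dir, "ensemble.pdb"),
                reference = file.path(dir, "reference.pdb"),
                truth = file.path(dir, "truth.json"))
  write_pdb_ensemble(out$ensemble, paths$pdb)
  write_pdb_ensemble(out$reference, paths$reference)
  jsonlite::write_json(out$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Specification for synthetic saturation data
#'
#' @param model Rate-law name (see [rate()]).
#' @param params True parameters (defaults: the mutant-1 pyruvate row of
#'   the kinetics table, Km 5.6 mM, kcat 40 s^-1).
#' @param n_conc Number of concentrations, log-spaced.
#' @param span Concentration span as multiples of the half-saturation
#'   parameter (must cover at least 0.2x-5x).
#' @param replicates Replicates per concentration.
#' @param cv Multiplicative noise: v_obs = v exp(e), e ~ N(0, cv^2).
#' @param seed Mandatory RNG seed.
#' @return A `kinetics_spec` list.
#' @export
kinetics_spec <- function(model = "michaelis_menten",
                          params = c(Vmax = 40, Km = 5.6),
                          n_conc = 12L, span = c(0.2, 10),
                          replicates = 3L, cv = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory for kinetics_spec", call. = FALSE)
  model <- match.arg(model, .KINETIC_MODELS)
  half <- unname(params[if (model == "allosteric_sigmoidal") "S05" else "Km"])
  if (is.na(half)) stop("params lack the half-saturation parameter",
                        call. = FALSE)
  if (span[1] > 0.2 + 1e-9 || span[2] < 5 - 1e-9)
    stop(sprintf("concentration span [%gx, %gx] must cover at least 0.2x-5x the half-saturation parameter",
                 span[1], span[2]), call. = FALSE)
  structure(list(model = model, params = params, n_conc = as.integer(n_conc),
                 span = span, replicates = as.integer(replicates), cv = cv,
                 half = half, seed = as.integer(seed)),
            class = "kinetics_spec")
}

#' Generate a synthetic saturation dataset with known truth
#'
#' @param spec A [kinetics_spec()].
#' @return List `dataset` (a `saturation_dataset`) and `truth` (the spec).
#' @export
make_saturation <- function(spec) {
  stopifnot(inherits(spec, "kinetics_spec"))
  set.seed(spec$seed)
  S <- rep(exp(seq(log(spec$span[1] * spec$half),
                   log(spec$span[2] * spec$half),
                   length.out = spec$n_conc)), each = spec$replicates)
  v_true <- rate(spec$model, S, spec$params)
  v <- v_true * exp(stats::rnorm(length(S), 0, spec$cv))
  ds <- saturation_dataset(S, v,
                           replicate = rep(seq_len(spec$replicates),
                                           times = spec$n_conc))
  list(dataset = ds, truth = unclass(spec))
}

#' Generate a toy sequence family with planted signature residues
#'
#' Each leaf sequence is the packaged reference with the requested residues
#' substituted at normalized signature positions, plus optional random
#' neutral mutations away from all signature positions; the tree over the
#' leaves is a balanced coalescent-free topology.
#'
#' @param assignments Named list: leaf id -> named character vector of
#'   residues keyed by signature position, e.g.
#'   `list(afu = c("68" = "H", "102" = "R", "246" = "T", "250" = "P"))`.
#' @param n_neutral Number of random substitutions per leaf away from
#'   signature positions.
#' @param seed Mandatory RNG seed.
#' @param ref Reference profile.
#' @return List `sequences` (named character), `tree` ([ape::phylo]),
#'   `truth` (assignments).
#' @export
make_family_fixture <- function(assignments, n_neutral = 0L, seed,
                                ref = ldh_reference()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  sig <- signature_positions()
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(names(assignments), function(id) {
    s <- strsplit(ref$sequence, "")[[1]]
    asg <- assignments[[id]]
    pos <- as.integer(names(asg))
    if (any(!pos %in% sig))
      stop("assignment at non-signature position: ",
           paste(setdiff(pos, sig), collapse = ", "), call. = FALSE)
    idx <- match(pos, ref$normalized_numbers)
    s[idx] <- toupper(asg)
    if (n_neutral > 0) {
      free <- setdiff(seq_along(s), match(sig, ref$normalized_numbers))
      at <- sample(free, n_neutral)
      s[at] <- sample(aa20, n_neutral, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  ids <- names(assignments)
  tree <- if (length(ids) >= 2)
    ape::read.tree(text = paste0("(", paste(ids, collapse = ","), ");"))
  else NULL
  list(sequences = seqs, tree = tree, truth = assignments)
}

#' Write a family fixture to disk (FASTA + Newick + truth JSON)
#' @param fixture Result of [make_family_fixture()].
#' @param dir Output directory.
#' @export
write_family_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "family.fa")
  writeLines(paste0(">", names(fixture$sequences), "\n", fixture$sequences),
             fa)
  nwk <- file.path(dir, "family.nwk")
  if (!is.null(fixture$tree)) ape::write.tree(fixture$tree, nwk)
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(c(fasta = fa, newick = nwk))
}
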