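# Landscape analysis: distance probability distributions with peak
# detection, 2D helix-angle/distance landscapes with R-like vs T-like state
# calls, position-250 side-chain dihedral substates, and mobile-loop
# open/closed state.

#' Default R-like/T-like classification thresholds
#'
#' Declared heuristics anchored loosely to the printed out-state peak
#' distances (17 and 20 Angstrom) versus in-state geometry; the underlying
#' trajectory study classified states visually, so these bands are package
#' choices and are always embedded in output metadata.
#'
#' @return List with `d_R`, `d_T` (Angstrom) and `theta_R`, `theta_T`
#'   (degrees).
#' @export
default_state_thresholds <- function()
  list(d_R = 16, d_T = 18, theta_R = 4, theta_T = 8)

#' Empirical distance distribution with peak detection
#'
#' Gaussian kernel density estimate of a distance series on a regular grid,
#' normalized to integrate to 1, plus the peaks passing prominence and
#' separation filters.
#'
#' @param series A `distance_series` or bare numeric vector (Angstrom).
#' @param bandwidth Kernel SD in Angstrom (default 0.3).
#' @param grid_step Grid spacing in Angstrom (default 0.05).
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   maximum density (default 0.05).
#' @param min_separation Minimum distance between reported peaks, Angstrom.
#' @return A `distance_distribution`: list with `grid`, `density`,
#'   `bandwidth`, `peaks` (data.frame `location`, `height`, `prominence`),
#'   `degenerate` flag.
#' @export
make_distribution <- function(series, bandwidth = 0.3, grid_step = 0.05,
                              min_prominence = 0.05, min_separation = 1.0) {
  x <- if (inherits(series, "distance_series")) series$values else
    as.numeric(series)
  if (length(x) < 50)
    warning("fewer than 50 samples; density estimate will be rough",
            call. = FALSE)
  if (stats::sd(x) < 1e-9) {
    # constant series: delta-like, flagged, no peak search
    grid <- seq(x[1] - 1, x[1] + 1, by = grid_step)
    dens <- rep(0, length(grid)); dens[which.min(abs(grid - x[1]))] <-
      1 / grid_step
    return(structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                          peaks = data.frame(location = numeric(0),
                                             height = numeric(0),
                                             prominence = numeric(0)),
                          degenerate = TRUE),
                     class = "distance_distribution"))
  }
  lo <- min(x) - 4 * bandwidth; hi <- max(x) + 4 * bandwidth
  n_grid <- ceiling((hi - lo) / grid_step) + 1
  kd <- stats::density(x, bw = bandwidth, from = lo, to = hi, n = n_grid)
  dens <- kd$y / (sum(kd$y) * diff(kd$x[1:2]))  # exact grid normalization
  dist <- structure(list(grid = kd$x, density = dens, bandwidth = bandwidth,
                         peaks = NULL, degenerate = FALSE),
                    class = "distance_distribution")
  dist$peaks <- find_peaks(dist, min_prominence = min_prominence,
                           min_separation = min_separation)
  dist
}

#' Detect peaks in a distance distribution
#'
#' Local maxima of the density curve filtered by topographic prominence
#' (height above the higher of the two flanking saddles) and by a minimum
#' mutual separation; when two candidate peaks are closer than
#' `min_separation` the lower one is discarded.
#'
#' @param dist A `distance_distribution`.
#' @param min_prominence Fraction of the maximum density.
#' @param min_separation Angstrom.
#' @return Data frame `location`, `height`, `prominence`, sorted by
#'   location.  Empty for degenerate distributions.
#' @export
find_peaks <- function(dist, min_prominence = 0.05, min_separation = 1.0) {
  stopifnot(inherits(dist, "distance_distribution"))
  empty <- data.frame(location = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (isTRUE(dist$degenerate)) return(empty)
  y <- dist$density; g <- dist$grid; n <- length(y)
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(cand)) return(empty)

  prominence <- vapply(cand, function(i) {
    # walk left/right to the first point higher than the peak (or the edge);
    # the saddle on each side is the minimum along that walk
    left_min <- y[i]; j <- i
    while (j > 1 && y[j] <= y[i]) { j <- j - 1; left_min <- min(left_min, y[j]) }
    if (y[j] <= y[i]) left_min <- min(y[seq_len(i)])
    right_min <- y[i]; j <- i
    while (j < n && y[j] <= y[i]) { j <- j + 1; right_min <- min(right_min, y[j]) }
    if (y[j] <= y[i]) right_min <- min(y[i:n])
    y[i] - max(left_min, right_min)
  }, numeric(1))

  keep <- prominence >= min_prominence * max(y)
  cand <- cand[keep]; prominence <- prominence[keep]
  if (!length(cand)) return(empty)
  # separation filter: greedy by height
  ord <- order(y[cand], decreasing = TRUE)
  sel <- integer(0)
  for (k in ord) {
    if (!length(sel) || all(abs(g[cand[k]] - g[cand[sel]]) >= min_separation))
      sel <- c(sel, k)
  }
  sel <- sel[order(g[cand[sel]])]
  data.frame(location = g[cand[sel]], height = y[cand[sel]],
             prominence = prominence[sel])
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("<distance_distribution> grid [",
      sprintf("%.1f", min(x$grid)), ", ", sprintf("%.1f", max(x$grid)),
      "] A, bw ", x$bandwidth,
      if (isTRUE(x$degenerate)) " [DEGENERATE]" else
        paste0(", ", nrow(x$peaks), " peak(s) at ",
               paste(sprintf("%.1f", x$peaks$location), collapse = "/"), " A"),
      "\n", sep = "")
  invisible(x)
}

#' Classify one (theta, d) point as R-like, T-like or intermediate
#'
#' T-like iff `d >= d_T` and `|theta| >= theta_T`; R-like iff `d <= d_R`
#' and `|theta| <= theta_R`; anything else is intermediate.  The bands are
#' heuristics (see [default_state_thresholds()]).
#'
#' @param theta Helix angle, degrees.
#' @param d R171(Cgamma)-P141(Calpha) distance, Angstrom.
#' @param thresholds List with `d_R < d_T` and `theta_R < theta_T`.
#' @return `"R_like"`, `"T_like"` or `"intermediate"` (vectorized).
#' @export
classify_state <- function(theta, d, thresholds = default_state_thresholds()) {
  th <- thresholds
  if (!(th$d_R < th$d_T) || !(th$theta_R < th$theta_T))
    stop("inconsistent thresholds: need d_R < d_T and theta_R < theta_T",
         call. = FALSE)
  out <- rep("intermediate", length(theta))
  out[d >= th$d_T & abs(theta) >= th$theta_T] <- "T_like"
  out[d <= th$d_R & abs(theta) <= th$theta_R] <- "R_like"
  out
}

#' Two-dimensional conformational landscape of one monomer
#'
#' Per frame: helix angle theta ([helix_angle()]) and the same-chain
#' R171(Cgamma)-P141(Calpha) distance, plus the R-like/T-like/intermediate
#' call.  This is the scatter-plot representation in which R-to-T-like
#' excursions of a monomer become a second cloud at large distance and
#' deflected helix angle.
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param chain Chain identifier.
#' @param reference X-aligned numbered reference ensemble.
#' @param thresholds Classification bands.
#' @param fit Per-monomer Calpha superposition before the angle (default
#'   `TRUE`).
#' @return Data frame `frame`, `chain`, `theta_deg`, `d_A`, `label`, with
#'   the thresholds attached as attribute `thresholds`.
#' @export
landscape <- function(ensemble, chain, reference,
                      thresholds = default_state_thresholds(), fit = TRUE) {
  ds <- distance_series(ensemble, atom_ref(chain, 171L, "CG"),
                        atom_ref(chain, 141L, "CA"))
  theta <- vapply(seq_len(n_frames(ensemble)), function(f)
    tryCatch(helix_angle(ensemble, chain, reference, frame = f, fit = fit),
             error = function(e)
               stop(sprintf("frame %d: %s", f, conditionMessage(e)),
                    call. = FALSE)),
    numeric(1))
  out <- data.frame(frame = seq_len(n_frames(ensemble)), chain = chain,
                    theta_deg = theta, d_A = ds$values,
                    label = classify_state(theta, ds$values, thresholds))
  attr(out, "thresholds") <- thresholds
  out
}

#' Side-chain dihedral substates of a residue
#'
#' Computes the chi1 (N-CA-CB-CG) and chi2 (CA-CB-CG-CD) dihedrals of the
#' residue at a normalized position in every frame and clusters them on the
#' torus: each angle is embedded as (cos, sin) so that modes straddling
#' +/-180 degrees are one cluster.  k is chosen in `k_range` by average
#' silhouette width (k = 1 is selected when no split reaches
#' `min_silhouette`).  Clusters are labelled Cs1..Csk by decreasing
#' occupancy.
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param chain Chain identifier.
#' @param normalized Normalized residue number (default 250).
#' @param k_range Candidate cluster counts (default 1:4).
#' @param min_silhouette Mean silhouette below which k = 1 wins.
#' @param seed Seed for k-means restarts.
#' @return A `substate_assignment`: list with `angles` (data.frame `frame`,
#'   `chi1`, `chi2`), `cluster` (Cs labels per frame), `k`, `occupancy`
#'   (named, descending), `centers` (degrees), `silhouette`.
#' @export
sidechain_substates <- function(ensemble, chain, normalized = 250L,
                                k_range = 1:4, min_silhouette = 0.5,
                                seed = 1L) {
  # chi-defining atoms; CG resolves CG1 (Ile), CD resolves CD1 via names
  get_atom <- function(name) {
    ref <- atom_ref(chain, normalized, name)
    tryCatch(resolve_atom(ensemble, ref), error = function(e) NA_integer_)
  }
  ia <- c(N = get_atom("N"), CA = get_atom("CA"), CB = get_atom("CB"),
          CG = get_atom("CG"), CD = get_atom("CD"))
  if (is.na(ia["CD"])) {
    ref <- atom_ref(chain, normalized, "CD1")
    ia["CD"] <- tryCatch(resolve_atom(ensemble, ref),
                         error = function(e) NA_integer_)
  }
  if (anyNA(ia)) {
    a <- ensemble$atoms
    rn <- tryCatch(a$resname[resolve_atom(ensemble,
                                          atom_ref(chain, normalized, "CA"))],
                   error = function(e) "?")
    stop(sprintf("residue %s at normalized %d (chain %s) lacks chi1/chi2-defining atoms (%s missing); side-chain substate analysis unsupported",
                 rn, normalized, chain,
                 paste(names(ia)[is.na(ia)], collapse = ",")), call. = FALSE)
  }
  nf <- n_frames(ensemble)
  chi <- t(vapply(seq_len(nf), function(f) {
    co <- ensemble$coords[, , f]
    c(dihedral_angle(co[ia["N"], ], co[ia["CA"], ], co[ia["CB"], ],
                     co[ia["CG"], ]),
      dihedral_angle(co[ia["CA"], ], co[ia["CB"], ], co[ia["CG"], ],
                     co[ia["CD"], ]))
  }, numeric(2)))
  colnames(chi) <- c("chi1", "chi2")

  rad <- chi * pi / 180
  emb <- cbind(cos(rad[, 1]), sin(rad[, 1]), cos(rad[, 2]), sin(rad[, 2]))
  k_range <- sort(unique(as.integer(k_range)))
  best <- list(k = 1L, sil = NA_real_,
               cluster = rep(1L, nf), centers = NULL)
  if (nf > 3 && any(k_range > 1)) {
    set.seed(seed)
    d_emb <- stats::dist(emb)
    for (k in k_range[k_range > 1 & k_range < nf]) {
      km <- stats::kmeans(emb, centers = k, nstart = 10, iter.max = 50)
      if (min(km$size) == 0) next
      sil <- mean(cluster::silhouette(km$cluster, d_emb)[, 3])
      if (is.na(best$sil) || sil > best$sil)
        best <- list(k = k, sil = sil, cluster = km$cluster,
                     centers = km$centers)
    }
    if (is.na(best$sil) || best$sil < min_silhouette)
      best <- list(k = 1L, sil = best$sil, cluster = rep(1L, nf),
                   centers = NULL)
  }
  if (1L %in% k_range == FALSE && best$k == 1L && any(k_range > 1))
    warning("no acceptable split found though k = 1 not requested",
            call. = FALSE)

  occ <- sort(table(best$cluster) / nf, decreasing = TRUE)
  relabel <- stats::setNames(seq_along(occ), names(occ))
  cs <- paste0("Cs", relabel[as.character(best$cluster)])
  occupancy <- stats::setNames(as.numeric(occ), paste0("Cs", seq_along(occ)))
  centers_deg <- NULL
  if (!is.null(best$centers)) {
    centers_deg <- t(vapply(as.integer(names(occ)), function(cl) c(
      chi1 = atan2(best$centers[cl, 2], best$centers[cl, 1]) * 180 / pi,
      chi2 = atan2(best$centers[cl, 4], best$centers[cl, 3]) * 180 / pi),
      numeric(2)))
    rownames(centers_deg) <- paste0("Cs", seq_len(nrow(centers_deg)))
  }
  structure(list(angles = data.frame(frame = seq_len(nf), chain = chain,
                                     chi1 = chi[, 1], chi2 = chi[, 2]),
                 cluster = cs, k = best$k, occupancy = occupancy,
                 centers = centers_deg, silhouette = best$sil),
            class = "substate_assignment")
}

#' @export
print.substate_assignment <- function(x, ...) {
  cat("<substate_assignment> k = ", x$k, "; occupancies: ",
      paste(sprintf("%s %.2f", names(x$occupancy), x$occupancy),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mobile-loop open/closed state per frame
#'
#' Monitors the active-site loop through the distances from the Calpha of
#' the conserved L167 to the Cgamma of the loop residues 102 and 109.
#' Closed iff `d102 <= 15` and `d109 <= 12`; open iff `d102 >= 20` and
#' `d109 >= 15`; else intermediate.  Bands are anchored to the printed
#' closed-state exemplar (13.1 / 9.6 Angstrom) and open-state exemplar
#' (both above 20 Angstrom).
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param chain Chain identifier.
#' @param thresholds List with `closed_d102`, `closed_d109`, `open_d102`,
#'   `open_d109` (Angstrom).
#' @return Data frame `frame`, `chain`, `d102_A`, `d109_A`, `state`.
#' @export
loop_state <- function(ensemble, chain,
                       thresholds = list(closed_d102 = 15, closed_d109 = 12,
                                         open_d102 = 20, open_d109 = 15)) {
  d102 <- distance_series(ensemble, atom_ref(chain, 167L, "CA"),
                          atom_ref(chain, 102L, "CG"))$values
  d109 <- distance_series(ensemble, atom_ref(chain, 167L, "CA"),
                          atom_ref(chain, 109L, "CG"))$values
  data.frame(frame = seq_along(d102), chain = chain,
             d102_A = d102, d109_A = d109,
             state = classify_loop(d102, d109, thresholds))
}

#' Classify loop distances as open/closed/intermediate
#' @param d102,d109 Distances in Angstrom (vectorized).
#' @param thresholds As in [loop_state()].
#' @return Character vector of states.
#' @export
classify_loop <- function(d102, d109,
                          thresholds = list(closed_d102 = 15, closed_d109 = 12,
                                            open_d102 = 20, open_d109 = 15)) {
  th <- thresholds
  out <- rep("intermediate", length(d102))
  out[d102 <= th$closed_d102 & d109 <= th$closed_d109] <- "closed"
  out[d102 >= th$open_d102 & d109 >= th$open_d109] <- "open"
  out
}
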