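# Rigid-body geometry on conformer ensembles: least-squares superposition
# (Kabsch with proper-rotation correction), the alpha2F helix orientation
# angle, inter-atom distance series and side-chain dihedrals.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing
#' the (weighted) RMSD between `mobile %*% t(R) + t` and `reference`.
#'
#' @param mobile,reference Numeric `n x 3` matrices, `n >= 3`,
#'   non-collinear.
#' @param weights Optional non-negative per-point weights.
#' @return List `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (post-fit, Angstrom).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be equal-sized n x 3 matrices",
         call. = FALSE)
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)

  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm); Rf <- sweep(reference, 2, cr)
  # collinearity check on the mobile set
  sv_m <- svd(M * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1))
    stop("degenerate (collinear) point set; rotation is not determined",
         call. = FALSE)
  H <- t(M * w) %*% Rf
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fitted <- mobile %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` matrix.
#' @param transform A list with `rotation` and `translation` as returned by
#'   [superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as.matrix(coords)
  coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
.rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * K %*% K
}

# CA coordinate matrix for one chain/frame with normalized numbers as
# rownames; only positions resolvable through the attached numbering.
.ca_by_normalized <- function(ensemble, chain, frame) {
  m <- ensemble$residue_maps[[chain]]
  if (is.null(m))
    stop("no residue map for chain ", chain,
         "; call attach_numbering() first", call. = FALSE)
  a <- ensemble$atoms
  rows <- which(a$chain == chain & a$atom == "CA")
  resid <- a$resid[rows]
  if (isTRUE(m$identity)) {
    norm <- resid
  } else {
    idx <- match(resid, m$resids[m$map$pairs$query_index])
    norm <- m$map$pairs$normalized_number[idx]
    rows <- rows[!is.na(norm)]; norm <- norm[!is.na(norm)]
  }
  out <- ensemble$coords[rows, , frame, drop = FALSE]
  dim(out) <- c(length(rows), 3)
  rownames(out) <- norm
  out
}

#' Align a reference frame so its alpha2F helix lies along +X
#'
#' Rotates the whole ensemble rigidly so that the helix vector, from the
#' Calpha of normalized residue 167 to the Calpha of 181, points along +X.
#' The result is the "reference state" against which helix orientation
#' angles are measured.
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param chain Chain whose helix defines the alignment.
#' @param frame Frame to use (default 1).
#' @param helix_ends Normalized numbers of the helix extrema.
#' @return The ensemble with all frames rigidly rotated.
#' @export
align_reference_to_x <- function(ensemble, chain, frame = 1L,
                                 helix_ends = c(167L, 181L)) {
  p0 <- coordinates(ensemble, atom_ref(chain, helix_ends[1], "CA"), frame)
  p1 <- coordinates(ensemble, atom_ref(chain, helix_ends[2], "CA"), frame)
  v <- p1 - p0
  if (sqrt(sum(v^2)) < 1e-9)
    stop("degenerate helix vector (zero norm)", call. = FALSE)
  R <- .rotation_between(v, c(1, 0, 0))
  for (f in seq_len(n_frames(ensemble)))
    ensemble$coords[, , f] <- ensemble$coords[, , f] %*% t(R)
  ensemble
}

#' Helix orientation angle theta
#'
#' The angle between the projection of the frame's Calpha167 -> Calpha181
#' helix vector on the X-Z plane and the +X axis of the X-aligned reference
#' state.  By default the frame's monomer is first superposed on the
#' reference using all common Calpha atoms of that chain, so theta is
#' invariant to global rigid motion.  Positive theta means the projected
#' vector has a positive Z component (the "under" direction of the T-like
#' state under this package's sign convention; flip `z_sign` to invert).
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param chain Chain identifier.
#' @param reference X-aligned reference ensemble (see
#'   [align_reference_to_x()]).
#' @param frame Frame index.
#' @param fit Superpose the monomer's Calpha set on the reference first
#'   (default `TRUE`, matching trajectory analysis practice).  `FALSE`
#'   measures the raw projected angle in the laboratory frame.
#' @param z_sign Sign convention multiplier for the Z axis.
#' @param helix_ends Normalized numbers of the helix extrema.
#' @return Angle in degrees.
#' @export
helix_angle <- function(ensemble, chain, reference, frame = 1L,
                        fit = TRUE, z_sign = 1,
                        helix_ends = c(167L, 181L)) {
  p0 <- coordinates(ensemble, atom_ref(chain, helix_ends[1], "CA"), frame)
  p1 <- coordinates(ensemble, atom_ref(chain, helix_ends[2], "CA"), frame)
  if (fit) {
    mob <- .ca_by_normalized(ensemble, chain, frame)
    ref <- .ca_by_normalized(reference, chain, 1L)
    common <- intersect(rownames(mob), rownames(ref))
    if (length(common) < 3)
      stop("fewer than 3 common Calpha positions for the monomer fit",
           call. = FALSE)
    tr <- superpose(mob[common, , drop = FALSE], ref[common, , drop = FALSE])
    p0 <- as.numeric(apply_transform(rbind(p0), tr))
    p1 <- as.numeric(apply_transform(rbind(p1), tr))
  }
  v <- p1 - p0
  proj <- c(v[1], z_sign * v[3])
  if (sqrt(sum(proj^2)) < 1e-9 * sqrt(sum(v^2)))
    stop("helix vector nearly perpendicular to the X-Z plane; angle undefined",
         call. = FALSE)
  atan2(proj[2], proj[1]) * 180 / pi
}

#' Inter-atom distance series across an ensemble
#'
#' Euclidean distance between two atoms in every frame.  Cross-chain pairs
#' (e.g. R171 of one monomer vs H68 of the adjacent monomer) are supported
#' by giving `a` and `b` different chains.
#'
#' @param ensemble A numbered `conformer_ensemble`.
#' @param a,b [atom_ref()] objects.
#' @return A `distance_series`: list with `a`, `b`, `values` (Angstrom, one
#'   per frame) and `frame_times`.
#' @export
distance_series <- function(ensemble, a, b) {
  ia <- tryCatch(resolve_atom(ensemble, a), error = function(e)
    stop(sprintf("cannot resolve %s at frame 1: %s", format(a),
                 conditionMessage(e)), call. = FALSE))
  ib <- tryCatch(resolve_atom(ensemble, b), error = function(e)
    stop(sprintf("cannot resolve %s at frame 1: %s", format(b),
                 conditionMessage(e)), call. = FALSE))
  d <- ensemble$coords[ia, , ] - ensemble$coords[ib, , ]
  if (is.null(dim(d))) d <- matrix(d, nrow = 3)
  vals <- sqrt(colSums(d^2))
  structure(list(a = a, b = b, values = as.numeric(vals),
                 frame_times = ensemble$frame_times),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat("<distance_series> ", format(x$a), " - ", format(x$b), ": ",
      length(x$values), " frames, mean ",
      sprintf("%.1f", mean(x$values)), " A\n", sep = "")
  invisible(x)
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Export distance series as CSV
#' @param series A `distance_series` or list of them.
#' @param path Output CSV path.
#' @export
write_distance_series <- function(series, path) {
  if (inherits(series, "distance_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(frame = seq_along(s$values),
               time_ps = if (is.null(s$frame_times)) NA_real_ else s$frame_times,
               pair = paste(format(s$a), format(s$b), sep = "--"),
               distance_A = round(s$values, 3))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
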