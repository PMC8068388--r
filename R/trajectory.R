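#' Coordinate trajectory container
#'
#' A frames x atoms x 3 coordinate array (Angstrom) plus per-atom metadata.
#'
#' @param coords numeric array `c(n_frames, n_atoms, 3)` with >= 2 frames and
#'   finite coordinates.
#' @param atoms data.frame with columns `eleno`, `elety` (atom name),
#'   `resid` (residue name), `chain`, `resno` (1-based residue index).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("'coords' must be a frames x atoms x 3 array")
  if (dim(coords)[1] < 2) stop("a trajectory needs >= 2 frames")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  need <- c("eleno", "elety", "resid", "chain", "resno")
  if (!all(need %in% names(atoms)))
    stop("atom metadata must have columns ", paste(need, collapse = ", "))
  if (nrow(atoms) != dim(coords)[2])
    stop("atom metadata rows must match the coordinate atom count")
  structure(list(coords = coords, atoms = atoms), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d atoms (%d residues)\n",
              d[1], d[2], length(unique(x$atoms$resno))))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

# frames x 3N matrix (x1 y1 z1 x2 ...), the layout shared with bio3d
.as_xyz_mat <- function(coords) {
  d <- dim(coords)
  out <- matrix(NA_real_, d[1], d[2] * 3)
  for (k in 1:3) out[, seq(k, d[2] * 3, by = 3)] <- coords[, , k]
  out
}

.from_xyz_mat <- function(m) {
  na <- ncol(m) / 3
  arr <- array(NA_real_, c(nrow(m), na, 3))
  for (k in 1:3) arr[, , k] <- m[, seq(k, na * 3, by = 3)]
  arr
}

#' Write a trajectory as a multi-model PDB file
#'
#' Frames become MODEL/ENDMDL records (coordinates at the PDB fixed-width
#' 0.001 A precision).
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = .as_xyz_mat(traj$coords),
                   eleno = a$eleno, elety = a$elety, resid = a$resid,
                   chain = a$chain, resno = a$resno)
  invisible(path)
}

.read_xyz_file <- function(path) {
  lines <- readLines(path)
  frames <- list(); meta <- NULL; i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) stop("malformed XYZ atom-count line at line ", i)
    if (i + 1L + na > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + na)]
    tok <- strsplit(trimws(block), "\\s+")
    name <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(meta)) meta <- name
    else if (!identical(meta, name) || length(name) != length(meta))
      stop("inconsistent atom list across XYZ frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  coords <- array(NA_real_, c(length(frames), length(meta), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  atoms <- data.frame(eleno = seq_along(meta), elety = meta, resid = "UNK",
                      chain = "A", resno = seq_along(meta),
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms)
}

#' Read a coordinate trajectory
#'
#' Multi-model PDB files (MODEL records map to frames; parsed with bio3d) or
#' plain XYZ files (repeated atom-count / comment / atom blocks). Atom order
#' must be consistent across frames, and at least two frames are required.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"xyz"`.
#' @return a [trajectory].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (format == "xyz") return(.read_xyz_file(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 2)
    stop("file has a single MODEL; a trajectory needs >= 2 frames")
  a <- pdb$atom
  atoms <- data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      resno = a$resno, stringsAsFactors = FALSE)
  trajectory(.from_xyz_mat(xyz), atoms)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping `mobile` onto `reference`
#' by SVD of the weighted cross-covariance, with the determinant correction
#' that guarantees a proper rotation (no reflection). The returned RMSD is
#' the minimum over all rigid transforms.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3, `det = +1`), `translation` (length
#'   3), `rmsd`, and the transformed coordinates `aligned`
#'   (`mobile %*% t(rotation) + translation`). A near-degenerate (collinear)
#'   point spread is flagged with a warning since the in-plane rotation is
#'   then poorly determined.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("'mobile' and 'reference' must be equal-size N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs >= 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  spread <- svd(t(P * sqrt(w)) %*% (P * sqrt(w)))$d
  if (spread[2] < 1e-10 * max(spread[1], 1))
    warning("degenerate (collinear) point set: rotation poorly determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  aligned <- sweep(aligned, 2, cr, `+`)
  list(rotation = R, translation = as.numeric(cr - (R %*% cm)),
       rmsd = rmsd, aligned = aligned)
}

.resolve_selection <- function(traj, selection) {
  if (!is.null(selection)) {
    sel <- as.integer(selection)
    if (!length(sel) || any(sel < 1) || any(sel > nrow(traj$atoms)))
      stop("empty or out-of-range atom selection")
    return(sel)
  }
  ca <- which(traj$atoms$elety == "CA")
  if (length(ca) >= 3) ca else seq_len(nrow(traj$atoms))
}

# superpose every frame onto 'ref' (N_sel x 3) using the selection; returns
# the full-atom coordinate array after applying each frame's fit transform
.superpose_all <- function(traj, ref, sel) {
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    k <- kabsch_superpose(traj$coords[f, sel, , drop = TRUE], ref)
    out[f, , ] <- traj$coords[f, , ] %*% t(k$rotation) +
      matrix(k$translation, dim(out)[2], 3, byrow = TRUE)
  }
  out
}

.mean_structure <- function(coords) apply(coords, c(2, 3), mean)

# iterated-mean superposition: start from frame 1 as reference, then refine
# the mean structure to a fixed point so the result does not depend on any
# global rigid motion of the input frames
.aligned_to_mean <- function(traj, sel, tol = 1e-12, max_iter = 50L) {
  ref <- traj$coords[1, sel, , drop = TRUE]
  aligned <- .superpose_all(traj, ref, sel)
  for (it in seq_len(max_iter)) {
    m <- .mean_structure(aligned)[sel, , drop = FALSE]
    aligned <- .superpose_all(traj, m, sel)
    m2 <- .mean_structure(aligned)[sel, , drop = FALSE]
    if (max(abs(m2 - m)) < tol * max(1, max(abs(m)))) break
  }
  aligned
}

#' Per-frame RMSD time series
#'
#' Each frame is rigid-body superposed onto the reference frame on the
#' analysis selection before the deviation is computed, so the series
#' reflects internal motion only. `series[reference_frame] = 0` by
#' construction.
#'
#' @param traj a [trajectory].
#' @param reference_frame frame index used as reference (default 1).
#' @param selection atom indices; default: CA atoms (all atoms when no CA).
#' @return numeric vector of per-frame RMSD (Angstrom), length `n_frames`.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_selection(traj, selection)
  ref <- traj$coords[reference_frame, sel, , drop = TRUE]
  vapply(seq_len(n_frames(traj)), function(f)
    kabsch_superpose(traj$coords[f, sel, , drop = TRUE], ref)$rmsd,
    numeric(1))
}

#' Per-residue RMSF mobility profile
#'
#' Root-mean-square fluctuation about the mean structure after per-frame
#' superposition (the mean structure is refined iteratively to a fixed
#' point, standard essential-dynamics practice, which also makes the result
#' invariant to any global rigid motion of the input frames). For a residue
#' displaced isotropically with
#' per-coordinate sigma the expected RMSF is `sigma * sqrt(3)`. RMSF values
#' are quartile-binned into mobility classes by [classify_mobility()].
#'
#' @param traj a [trajectory].
#' @param selection atom indices to analyze; default CA atoms.
#' @return a `data.frame` of class `mobility_profile` with columns `resno`,
#'   `rmsf` (Angstrom), `class`.
#' @export
rmsf_profile <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_selection(traj, selection)
  al <- .aligned_to_mean(traj, sel)[, sel, , drop = FALSE]
  m <- .mean_structure(al)
  dev2 <- sweep(al, c(2, 3), m)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)   # mean over frames and coords, x3
  out <- data.frame(resno = traj$atoms$resno[sel], rmsf = rmsf)
  out$class <- classify_mobility(out$rmsf)
  class(out) <- c("mobility_profile", "data.frame")
  out
}

#' Quartile mobility classes
#'
#' Bins RMSF values into `low` / `intermediate` / `high` / `highest` at the
#' quartiles, the coloring convention of mobility cartoons (thin blue =
#' lowest mobility, thick red = highest). Ties break toward the lower bin.
#'
#' @param rmsf numeric vector of per-residue RMSF values (or a
#'   `mobility_profile`).
#' @param scheme binning scheme; only `"quartile"` is defined.
#' @return factor with levels `low < intermediate < high < highest`.
#' @export
classify_mobility <- function(rmsf, scheme = "quartile") {
  if (inherits(rmsf, "mobility_profile")) rmsf <- rmsf$rmsf
  scheme <- match.arg(scheme, "quartile")
  q <- stats::quantile(rmsf, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lab <- c("low", "intermediate", "high", "highest")
  idx <- 1L + (rmsf > q[1]) + (rmsf > q[2]) + (rmsf > q[3])
  factor(lab[idx], levels = lab, ordered = TRUE)
}

#' Principal component analysis of trajectory fluctuations
#'
#' Eigendecomposition of the 3N x 3N positional covariance matrix after
#' superposition to the refined mean structure. Large eigenvalues mark the
#' dominant collective motions; the eigenvalue sum equals the total
#' positional variance (trace identity).
#'
#' @param traj a [trajectory].
#' @param selection atom indices; default CA atoms.
#' @param k number of modes to return (default all `3N`).
#' @return list with `values` (all 3N eigenvalues, descending, >= 0 up to
#'   round-off), `vectors` (3N x k), `amplitudes` (per-residue displacement
#'   norm of each mode, N x k), `total_variance`.
#' @export
pca_modes <- function(traj, selection = NULL, k = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_selection(traj, selection)
  al <- .aligned_to_mean(traj, sel)[, sel, , drop = FALSE]
  X <- .as_xyz_mat(al)
  if (!is.null(k) && k > ncol(X)) stop("k cannot exceed 3N coordinates")
  if (is.null(k)) k <- ncol(X)
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  vals <- eig$values
  amp <- apply(eig$vectors[, seq_len(k), drop = FALSE], 2, function(v)
    sqrt(rowSums(matrix(v, ncol = 3, byrow = TRUE)^2)))
  list(values = vals, vectors = eig$vectors[, seq_len(k), drop = FALSE],
       amplitudes = amp, total_variance = sum(diag(C)),
       resno = traj$atoms$resno[sel])
}

#' Per-residue RMSF difference between two conditions
#'
#' Aligns two mobility profiles by residue index and reports where the
#' second condition (e.g. drug-bound) is *less* mobile than the first (e.g.
#' apo): `decrease = rmsf_a - rmsf_b`, with contiguous runs of decrease
#' beyond `threshold` summarized and ranked by total decrease.
#'
#' @param profile_a,profile_b [rmsf_profile()] results over the same residue
#'   set (mismatched sets are an error).
#' @param threshold minimum per-residue decrease (Angstrom) for a residue to
#'   count toward a decrease region.
#' @return list with `delta` (data.frame: resno, rmsf_a, rmsf_b, decrease)
#'   and `decrease_regions` (data.frame: start_resno, end_resno, n_residues,
#'   total_decrease, max_decrease; ordered by total decrease).
#' @export
delta_rmsf <- function(profile_a, profile_b, threshold = 0.1) {
  stopifnot(inherits(profile_a, "mobility_profile"),
            inherits(profile_b, "mobility_profile"))
  if (!identical(sort(profile_a$resno), sort(profile_b$resno)))
    stop("profiles cover different residue sets; cannot compare")
  a <- profile_a[order(profile_a$resno), ]
  b <- profile_b[order(profile_b$resno), ]
  delta <- data.frame(resno = a$resno, rmsf_a = a$rmsf, rmsf_b = b$rmsf,
                      decrease = a$rmsf - b$rmsf)
  hit <- delta$decrease > threshold
  regions <- data.frame(start_resno = integer(), end_resno = integer(),
                        n_residues = integer(), total_decrease = numeric(),
                        max_decrease = numeric())
  if (any(hit)) {
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      ix <- starts[j]:ends[j]
      regions <- rbind(regions, data.frame(
        start_resno = delta$resno[starts[j]],
        end_resno = delta$resno[ends[j]],
        n_residues = length(ix),
        total_decrease = sum(delta$decrease[ix]),
        max_decrease = max(delta$decrease[ix])))
    }
    regions <- regions[order(-regions$total_decrease), ]
    rownames(regions) <- NULL
  }
  list(delta = delta, decrease_regions = regions)
}

.acidic_atoms <- function(atoms) {
  which((atoms$resid == "ASP" & atoms$elety %in% c("OD1", "OD2")) |
        (atoms$resid == "GLU" & atoms$elety %in% c("OE1", "OE2")) |
        atoms$elety == "OXT")
}

.basic_atoms <- function(atoms) {
  which((atoms$resid == "LYS" & atoms$elety == "NZ") |
        (atoms$resid == "ARG" & atoms$elety %in% c("NH1", "NH2", "NE")))
}

#' Salt-bridge occupancy over a trajectory
#'
#' A salt bridge between an acidic and a basic residue exists in a frame
#' when any side-chain carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2, or a
#' C-terminal OXT) lies within `cutoff` of any Lys NZ or Arg NH1/NH2/NE
#' nitrogen. Occupancy is the fraction of frames in which the bridge is
#' formed; only pairs with non-zero occupancy are reported.
#'
#' @param traj a [trajectory] with side-chain atoms (a CA-only trajectory
#'   yields an empty result with a warning).
#' @param cutoff N-O distance cutoff in Angstrom (default 4.0, the common
#'   convention).
#' @return data.frame with columns `acidic_resno`, `acidic_resid`,
#'   `basic_resno`, `basic_resid`, `occupancy`.
#' @export
salt_bridge_occupancy <- function(traj, cutoff = 4.0) {
  stopifnot(inherits(traj, "trajectory"))
  ai <- .acidic_atoms(traj$atoms)
  bi <- .basic_atoms(traj$atoms)
  empty <- data.frame(acidic_resno = integer(), acidic_resid = character(),
                      basic_resno = integer(), basic_resid = character(),
                      occupancy = numeric())
  if (!length(ai) || !length(bi)) {
    warning("trajectory lacks charged side-chain atoms; no bridges detectable")
    return(empty)
  }
  pairs <- expand.grid(a = ai, b = bi)
  pairs$key <- paste(traj$atoms$resno[pairs$a], traj$atoms$resno[pairs$b])
  keys <- unique(pairs$key)
  hits <- stats::setNames(numeric(length(keys)), keys)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    pa <- matrix(traj$coords[f, pairs$a, ], ncol = 3)
    pb <- matrix(traj$coords[f, pairs$b, ], ncol = 3)
    d <- sqrt(rowSums((pa - pb)^2))
    formed <- unique(pairs$key[d <= cutoff])
    hits[formed] <- hits[formed] + 1
  }
  occ <- hits / nf
  keep <- occ > 0
  if (!any(keep)) return(empty)
  first <- pairs[match(names(occ)[keep], pairs$key), ]
  data.frame(acidic_resno = traj$atoms$resno[first$a],
             acidic_resid = traj$atoms$resid[first$a],
             basic_resno = traj$atoms$resno[first$b],
             basic_resid = traj$atoms$resid[first$b],
             occupancy = as.numeric(occ[keep]))
}
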