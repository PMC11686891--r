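#' Simulate an MRF fingerprint for one tissue
#'
#' Integrates the Bloch equations for a single isochromat through the
#' acquisition schedule: each excitation rotates the magnetization by the
#' scheduled flip angle about a transverse axis at the scheduled RF phase,
#' the complex transverse signal is read at the echo time with T2 decay,
#' and the magnetization then relaxes exponentially (T1 towards
#' equilibrium, T2 towards zero) over the remainder of the TR. No
#' off-resonance precession is modelled. The sequence is balanced (no
#' spoiling) by default; `spoil = TRUE` destroys transverse magnetization
#' at the end of every TR (ideal spoiling).
#'
#' The returned signal is exactly 1-homogeneous in `pd`: the proton
#' density enters only as the equilibrium magnetization amplitude.
#'
#' @param schedule an [acquisition_schedule()].
#' @param t1,t2 relaxation times in ms; must satisfy `0 < t2 <= t1`.
#' @param pd proton density (non-negative scale factor, default 1).
#' @param spoil ideal spoiling flag.
#' @return Complex vector of length `schedule$n_excitations`.
#' @export
simulate_fingerprint <- function(schedule, t1, t2, pd = 1, spoil = FALSE) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  check_tissue(t1, t2, pd)
  drop(simulate_fingerprints(schedule, t1, t2, pd, spoil = spoil))
}

check_tissue <- function(t1, t2, pd) {
  if (any(t1 <= 0) || any(t2 <= 0))
    stop("relaxation times must be positive")
  if (any(t2 > t1))
    stop("non-physical tissue: t2 exceeds t1")
  if (any(pd < 0)) stop("proton density must be non-negative")
  invisible(TRUE)
}

# Vectorized Bloch recursion over many tissues at once. The state is a
# 3 x n matrix of (Mx, My, Mz); each step applies one shared 3x3 rotation
# and per-tissue exponential relaxation factors.
simulate_fingerprints <- function(schedule, t1, t2, pd = 1, spoil = FALSE) {
  n <- max(length(t1), length(t2), length(pd))
  t1 <- rep_len(t1, n); t2 <- rep_len(t2, n); pd <- rep_len(pd, n)
  M <- rbind(numeric(n), numeric(n), rep(1, n))  # unit equilibrium; scale at end
  if (schedule$invert_first) {
    M[3, ] <- -M[3, ]
    d <- schedule$inversion_delay
    M[1, ] <- M[1, ] * exp(-d / t2)
    M[2, ] <- M[2, ] * exp(-d / t2)
    M[3, ] <- 1 + (M[3, ] - 1) * exp(-d / t1)
  }
  sig <- matrix(0i, nrow = schedule$n_excitations, ncol = n)
  for (i in seq_len(schedule$n_excitations)) {
    R <- rf_rotation(schedule$flip_angle[i], schedule$rf_phase[i])
    M <- R %*% M
    e2te <- exp(-schedule$te[i] / t2)
    sig[i, ] <- (M[1, ] + 1i * M[2, ]) * e2te
    e1 <- exp(-schedule$tr[i] / t1)
    e2 <- exp(-schedule$tr[i] / t2)
    M[1, ] <- M[1, ] * e2
    M[2, ] <- M[2, ] * e2
    M[3, ] <- 1 + (M[3, ] - 1) * e1
    if (spoil) M[1, ] <- M[2, ] <- numeric(n)
  }
  sweep(sig, 2, pd, "*")
}

# Rotation by alpha (deg) about a transverse axis at azimuth phi (deg):
# Rz(phi) %*% Rx(alpha) %*% Rz(-phi).
rf_rotation <- function(alpha_deg, phi_deg) {
  a <- alpha_deg * pi / 180
  p <- phi_deg * pi / 180
  ca <- cos(a); sa <- sin(a); cp <- cos(p); sp <- sin(p)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3)
  Rz(p) %*% Rx %*% Rz(-p)
}

#' Build an MRF dictionary over a (T1, T2) grid
#'
#' Simulates one fingerprint per grid pair (unit proton density) and
#' L2-normalizes it into a dictionary atom. Grid order is row-major with
#' T1 as the outer loop and T2 as the inner loop; pairs violating the
#' physical constraint `t2 <= t1` are dropped.
#'
#' @param schedule an [acquisition_schedule()].
#' @param t1_values,t2_values grid axis values in ms.
#' @param spoil passed to the Bloch simulation.
#' @return An `mrf_dictionary` with fields `grid` (data.frame of t1, t2),
#'   `atoms` (complex matrix, time points x atoms, unit-norm columns) and
#'   `schedule`.
#' @export
build_dictionary <- function(schedule, t1_values, t2_values, spoil = FALSE) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  if (!length(t1_values) || !length(t2_values))
    stop("t1_values and t2_values must be non-empty")
  grid <- expand.grid(t2 = as.numeric(t2_values), t1 = as.numeric(t1_values),
                      KEEP.OUT.ATTRS = FALSE)[, c("t1", "t2")]
  grid <- grid[grid$t2 <= grid$t1, , drop = FALSE]
  rownames(grid) <- NULL
  if (!nrow(grid)) stop("empty dictionary grid after enforcing t2 <= t1")
  atoms <- simulate_fingerprints(schedule, grid$t1, grid$t2, pd = 1,
                                 spoil = spoil)
  nrm <- sqrt(colSums(Mod(atoms)^2))
  if (any(nrm == 0)) stop("zero-signal atom; check the schedule")
  atoms <- sweep(atoms, 2, nrm, "/")
  structure(list(grid = grid, atoms = atoms, schedule = schedule),
            class = "mrf_dictionary")
}

#' Default dictionary grid
#'
#' T1 from 100 to 3000 ms in 20 ms steps and T2 from 10 to 300 ms in 5 ms
#' steps, spanning the relaxometry range reported for normal brain at 3T.
#' @return list with `t1` and `t2` numeric vectors.
#' @export
default_grid <- function() {
  list(t1 = seq(100, 3000, by = 20), t2 = seq(10, 300, by = 5))
}

#' Compress a dictionary by temporal SVD
#'
#' Computes the singular value decomposition of the atom matrix and
#' retains the first `k` temporal singular vectors as an orthonormal
#' basis; every atom is stored as its `k` complex projection coefficients.
#' Among all rank-`k` bases this minimizes the total squared
#' reconstruction residual of the atom set.
#'
#' @param dict an `mrf_dictionary`.
#' @param k retained rank (default 4, the number of singular-value
#'   channels carried through the rest of the pipeline).
#' @return An `mrf_compressed_dictionary` with fields `grid`, `basis`
#'   (time points x k, orthonormal columns), `sv_atoms` (k x atoms),
#'   `k`, `singular_values` (all singular values, for energy accounting)
#'   and `schedule`.
#' @export
compress_dictionary <- function(dict, k = 4) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  n_t <- nrow(dict$atoms); n_a <- ncol(dict$atoms)
  if (k < 1 || k > min(n_t, n_a))
    stop("k must lie in [1, min(time points, atoms)]")
  sv <- svd(dict$atoms, nu = k, nv = 0)
  basis <- sv$u  # temporal singular vectors (time x k), orthonormal
  sv_atoms <- Conj(t(basis)) %*% dict$atoms
  structure(list(grid = dict$grid, basis = basis, sv_atoms = sv_atoms,
                 k = as.integer(k), singular_values = sv$d,
                 schedule = dict$schedule),
            class = "mrf_compressed_dictionary")
}

#' Retained-energy fraction of a compressed dictionary
#'
#' Fraction of the atoms' total squared norm captured by the retained
#' rank: the sum of the first `k` squared singular values over the sum of
#' all of them.
#' @param cdict an `mrf_compressed_dictionary`.
#' @return scalar in (0, 1\].
#' @export
retained_energy <- function(cdict) {
  d2 <- cdict$singular_values^2
  sum(d2[seq_len(cdict$k)]) / sum(d2)
}

#' Project voxel time series onto the compressed basis
#'
#' @param ts complex matrix (voxels x time points) of signal evolutions.
#' @param cdict an `mrf_compressed_dictionary` whose basis length matches
#'   the number of time points.
#' @return complex matrix (voxels x k) of projection coefficients.
#' @export
project_timeseries <- function(ts, cdict) {
  stopifnot(inherits(cdict, "mrf_compressed_dictionary"))
  ts <- as.matrix(ts)
  if (ncol(ts) != nrow(cdict$basis))
    stop("time-series length does not match the compression basis")
  ts %*% Conj(cdict$basis)
}

#' Phase-normalize singular-value vectors
#'
#' Multiplies each voxel's SV vector by the unit phasor that makes its
#' first component purely real and non-negative. After this step the real
#' part of SV1 approximately carries the proton-density distribution, and
#' the imaginary part of SV1 is identically zero, so four complex channels
#' reduce to seven real ones. Per-channel moduli and pairwise
#' inner-product magnitudes are unchanged.
#'
#' Voxels whose |SV1| falls below `floor_frac` times the volume maximum
#' |SV1| carry no usable phase reference; they pass through unchanged and
#' are flagged.
#'
#' @param sv complex matrix (voxels x k).
#' @param floor_frac relative floor on |SV1| (default 1e-12).
#' @return list with `sv` (phase-normalized matrix) and `degenerate`
#'   (logical vector flagging voxels left untouched).
#' @export
phase_normalize <- function(sv, floor_frac = 1e-12) {
  sv <- as.matrix(sv)
  a1 <- Mod(sv[, 1])
  floor_abs <- floor_frac * max(a1, 0)
  degenerate <- a1 <= floor_abs
  phasor <- rep(1 + 0i, nrow(sv))
  ok <- !degenerate
  phasor[ok] <- Conj(sv[ok, 1] / a1[ok])
  list(sv = sv * phasor, degenerate = degenerate)
}

#' Match SV-domain signals to the dictionary
#'
#' Per voxel, finds the dictionary entry maximizing the magnitude of the
#' complex inner product between the voxel's SV vector and the unit-norm
#' compressed atom; the winning grid pair gives T1 and T2, and the inner
#' product magnitude with the unit atom gives the proton density. Ties are
#' broken deterministically by the lowest grid index. Zero (or masked-out)
#' voxels receive the sentinel value 0 in all three maps.
#'
#' @param sv complex matrix (voxels x k) of SV coefficients.
#' @param cdict an `mrf_compressed_dictionary` with matching `k`.
#' @param mask optional logical vector (length voxels); voxels outside the
#'   mask are skipped and zero-filled.
#' @param chunk number of voxels per matching block (memory control).
#' @return list with numeric vectors `t1`, `t2`, `pd` (length voxels) and
#'   logical `flagged` (zero-signal voxels inside the mask).
#' @export
match_dictionary <- function(sv, cdict, mask = NULL, chunk = 2048L) {
  stopifnot(inherits(cdict, "mrf_compressed_dictionary"))
  sv <- as.matrix(sv)
  if (ncol(sv) != cdict$k)
    stop("SV channel count does not match the dictionary rank")
  n_atoms <- ncol(cdict$sv_atoms)
  if (!n_atoms) stop("empty dictionary")
  nv <- nrow(sv)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  stopifnot(length(mask) == nv)
  # unit-normalize compressed atoms (truncation leaves norms slightly < 1)
  anorm <- sqrt(colSums(Mod(cdict$sv_atoms)^2))
  atoms <- sweep(cdict$sv_atoms, 2, anorm, "/")
  t1 <- t2 <- pd <- numeric(nv)
  flagged <- logical(nv)
  vox <- which(mask)
  for (start in seq(1, length(vox), by = chunk)) {
    idx <- vox[start:min(start + chunk - 1L, length(vox))]
    scores <- Mod(sv[idx, , drop = FALSE] %*% Conj(atoms))
    best <- max.col(scores, ties.method = "first")
    bscore <- scores[cbind(seq_along(idx), best)]
    zero <- rowSums(Mod(sv[idx, , drop = FALSE])^2) == 0
    t1[idx] <- ifelse(zero, 0, cdict$grid$t1[best])
    t2[idx] <- ifelse(zero, 0, cdict$grid$t2[best])
    pd[idx] <- ifelse(zero, 0, bscore)
    flagged[idx] <- zero
  }
  list(t1 = t1, t2 = t2, pd = pd, flagged = flagged)
}

#' Snap tissue values to the dictionary grid
#'
#' Returns, for each (t1, t2) pair, the grid pair of `cdict` whose
#' Euclidean distance in (t1, t2) space is smallest (first index on ties).
#' @param cdict an `mrf_compressed_dictionary` (or `mrf_dictionary`).
#' @param t1,t2 numeric vectors (recycled to common length).
#' @return data.frame with columns `t1`, `t2`, `index`.
#' @export
snap_to_grid <- function(cdict, t1, t2) {
  n <- max(length(t1), length(t2))
  t1 <- rep_len(t1, n); t2 <- rep_len(t2, n)
  g <- cdict$grid
  idx <- vapply(seq_len(n), function(i) {
    which.min((g$t1 - t1[i])^2 + (g$t2 - t2[i])^2)
  }, integer(1))
  data.frame(t1 = g$t1[idx], t2 = g$t2[idx], index = idx)
}

#' Convert complex SV coefficients to real channel layout
#'
#' The pipeline's real-valued channel order is
#' `[Re SV1, Re SV2, Im SV2, Re SV3, Im SV3, Re SV4, Im SV4]`
#' (SV1 is purely real after phase normalization, so its imaginary part
#' is dropped).
#' @param sv complex matrix (voxels x 4).
#' @return numeric matrix (voxels x 7).
#' @export
sv_to_channels <- function(sv) {
  stopifnot(ncol(sv) == 4)
  cbind(Re(sv[, 1]), Re(sv[, 2]), Im(sv[, 2]), Re(sv[, 3]), Im(sv[, 3]),
        Re(sv[, 4]), Im(sv[, 4]))
}

#' Convert the 7-channel real layout back to complex SV coefficients
#' @param ch numeric matrix (voxels x 7) in the layout of
#'   [sv_to_channels()].
#' @return complex matrix (voxels x 4).
#' @export
channels_to_sv <- function(ch) {
  stopifnot(ncol(ch) == 7)
  cbind(ch[, 1] + 0i, ch[, 2] + 1i * ch[, 3], ch[, 4] + 1i * ch[, 5],
        ch[, 6] + 1i * ch[, 7])
}

#' Names of the seven real SV channels
#' @return character vector of length 7.
#' @export
sv_channel_names <- function() {
  c("sv1_re", "sv2_re", "sv2_im", "sv3_re", "sv3_im", "sv4_re", "sv4_im")
}

#' Save / load a compressed dictionary
#'
#' The container is a directory holding plain-text arrays (`basis_re.csv`,
#' `basis_im.csv`, `atoms_re.csv`, `atoms_im.csv`, `grid.csv`) plus a JSON
#' sidecar with the schedule and rank.
#' @param cdict an `mrf_compressed_dictionary`.
#' @param path directory to create.
#' @return `path`, invisibly (`save_dictionary`); the dictionary
#'   (`load_dictionary`).
#' @export
save_dictionary <- function(cdict, path) {
  stopifnot(inherits(cdict, "mrf_compressed_dictionary"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) utils::write.table(
    m, file.path(path, f), sep = ",", row.names = FALSE, col.names = FALSE)
  wr(Re(cdict$basis), "basis_re.csv"); wr(Im(cdict$basis), "basis_im.csv")
  wr(Re(cdict$sv_atoms), "atoms_re.csv"); wr(Im(cdict$sv_atoms), "atoms_im.csv")
  utils::write.csv(cdict$grid, file.path(path, "grid.csv"), row.names = FALSE)
  meta <- list(k = cdict$k, singular_values = cdict$singular_values,
               schedule = unclass(cdict$schedule))
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  rd <- function(f) as.matrix(utils::read.table(file.path(path, f), sep = ","))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sch <- meta$schedule
  schedule <- acquisition_schedule(sch$flip_angle, sch$tr, sch$te,
                                   sch$rf_phase, sch$invert_first,
                                   sch$inversion_delay)
  basis <- rd("basis_re.csv") + 1i * rd("basis_im.csv")
  atoms <- rd("atoms_re.csv") + 1i * rd("atoms_im.csv")
  dimnames(basis) <- dimnames(atoms) <- NULL
  structure(list(grid = utils::read.csv(file.path(path, "grid.csv")),
                 basis = basis, sv_atoms = atoms, k = as.integer(meta$k),
                 singular_values = as.numeric(meta$singular_values),
                 schedule = schedule),
            class = "mrf_compressed_dictionary")
}
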