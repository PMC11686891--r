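#' Digital brain phantom specification
#'
#' Describes a multi-subject synthetic cohort of paired MPRAGE / MRF
#' volumes. Geometry is schematic on purpose: concentric ellipsoidal
#' shells of CSF, gray matter and white matter inside a brain mask, split
#' into angular parcels that play the role of anatomical regions. Tissue
#' relaxometry is piecewise constant per subject, with inter-subject
#' variability drawn from truncated Gaussians around the class means.
#'
#' @param grid_size voxels per side (power of 2, default 64).
#' @param n_subjects number of subjects in the cohort (default 6).
#' @param tissue_classes data.frame with columns `label`, `t1`, `t2`,
#'   `pd`, `t1_sd`, `t2_sd`, `pd_sd` (ms / dimensionless). Default: CSF
#'   3000/1500/1.0, GM 1300/80/0.8, WM 850/60/0.7, SDs 5% of means.
#' @param n_regions angular parcel count (default 8).
#' @param noise_sigma additive Gaussian noise level as a fraction of the
#'   signal maximum (default 0.02).
#' @param seed integer base seed; all randomness derives from
#'   `(seed, subject_index)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64, n_subjects = 6,
                         tissue_classes = default_tissue_classes(),
                         n_regions = 8, noise_sigma = 0.02, seed = 0) {
  if (bitwAnd(grid_size, grid_size - 1L) != 0L || grid_size < 8)
    stop("grid_size must be a power of 2 (>= 8)")
  stopifnot(n_subjects >= 1, n_regions >= 1, noise_sigma >= 0)
  tc <- tissue_classes
  need <- c("label", "t1", "t2", "pd", "t1_sd", "t2_sd", "pd_sd")
  if (!all(need %in% names(tc))) stop("tissue_classes missing columns")
  if (any(tc$t2 > tc$t1)) stop("tissue class means must satisfy t2 <= t1")
  structure(list(grid_size = as.integer(grid_size),
                 n_subjects = as.integer(n_subjects), tissue_classes = tc,
                 n_regions = as.integer(n_regions),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_tissue_classes <- function() {
  data.frame(label = c("csf", "gm", "wm"),
             t1 = c(3000, 1300, 850), t2 = c(1500, 80, 60),
             pd = c(1.0, 0.8, 0.7),
             t1_sd = 0.05 * c(3000, 1300, 850),
             t2_sd = 0.05 * c(1500, 80, 60),
             pd_sd = 0.05 * c(1.0, 0.8, 0.7))
}

#' MPRAGE acquisition parameters
#'
#' Defaults follow a standard 3T protocol: TR 2130 ms, TE 2.6 ms, flip 8
#' degrees, inversion time 900 ms.
#' @param ti inversion time, ms.
#' @param tr repetition (shot) time, ms.
#' @param te echo time, ms.
#' @param flip excitation flip angle, degrees.
#' @return list of class `mprage_params`.
#' @export
mprage_params <- function(ti = 900, tr = 2130, te = 2.6, flip = 8) {
  stopifnot(ti > 0, tr > 0, te > 0, flip > 0, ti < tr)
  structure(list(ti = ti, tr = tr, te = te, flip = flip),
            class = "mprage_params")
}

#' MPRAGE signal model
#'
#' Long-TR inversion-recovery approximation of the magnitude MPRAGE
#' intensity:
#' `S = pd * |1 - 2 exp(-ti/t1) + exp(-tr/t1)| * sin(flip)`.
#' The (small) T2* decay over the short echo time is deliberately
#' neglected; at TE of a few ms its effect on brain tissue contrast is
#' below the phantom's noise floor.
#' @param t1 longitudinal relaxation time, ms (vectorized).
#' @param pd proton density (vectorized).
#' @param params an [mprage_params()].
#' @return magnitude signal, same length as the inputs.
#' @export
mprage_signal <- function(t1, pd, params = mprage_params()) {
  stopifnot(inherits(params, "mprage_params"))
  s <- 1 - 2 * exp(-params$ti / t1) + exp(-params$tr / t1)
  pd * abs(s) * sin(params$flip * pi / 180)
}

# deterministic 32-bit sub-seed from (seed, subject index)
subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 48271 + subject_index * 16807 + 11) %%
               2147483647)
}

#' Generate one phantom subject's ground truth
#'
#' Builds the label/tissue geometry and draws the subject's tissue
#' relaxometry from the spec's Gaussians (truncated to positive values
#' with `t2 <= t1`), deterministically in `(spec$seed, subject_index)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index 1-based subject number.
#' @return list with `mask` (logical array), `tissue` (integer array,
#'   0 = background, 1..nrow(tissue_classes)), `labels` (integer array of
#'   angular parcels over the parenchymal classes, 0 in the CSF rim and
#'   outside the mask), `t1`, `t2`, `pd` (ground-truth arrays, ms /
#'   dimensionless), and `tissue_values` (the subject's drawn per-class
#'   parameters).
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "phantom_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects)
  g <- spec$grid_size
  ax <- c(0.42, 0.36, 0.33) * g          # ellipsoid semi-axes, voxels
  ctr <- (g - 1) / 2
  x <- (seq_len(g) - 1 - ctr)
  X <- array(rep(x, times = g * g), dim = c(g, g, g))
  Y <- array(rep(rep(x, each = g), times = g), dim = c(g, g, g))
  Z <- array(rep(x, each = g * g), dim = c(g, g, g))
  r <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
  mask <- r <= 1
  tissue <- array(0L, dim = dim(mask))
  tissue[mask & r > 0.88] <- 1L                 # CSF rim
  tissue[mask & r > 0.62 & r <= 0.88] <- 2L     # GM shell
  tissue[mask & r <= 0.62] <- 3L                # WM core
  ang <- atan2(Y, X)                             # (-pi, pi]
  parcel <- 1L + ((floor((ang + pi) / (2 * pi) * spec$n_regions)) %%
                    spec$n_regions)
  # parcels emulate a parenchymal parcellation: the outermost shell
  # (first tissue class, the CSF rim) carries no region label, like the
  # CSF compartment outside anatomical regions of interest
  parenchyma <- tissue >= 2L
  labels <- array(0L, dim = dim(mask))
  labels[parenchyma] <- parcel[parenchyma]

  set.seed(subject_seed(spec$seed, subject_index))
  tc <- spec$tissue_classes
  draw <- function(i) {
    for (trial in 1:1000) {
      t1 <- stats::rnorm(1, tc$t1[i], tc$t1_sd[i])
      t2 <- stats::rnorm(1, tc$t2[i], tc$t2_sd[i])
      pd <- stats::rnorm(1, tc$pd[i], tc$pd_sd[i])
      if (t1 > 0 && t2 > 0 && t2 <= t1 && pd > 0)
        return(c(t1 = t1, t2 = t2, pd = pd))
    }
    stop("could not draw physical tissue values")
  }
  vals <- t(vapply(seq_len(nrow(tc)), draw, numeric(3)))
  tissue_values <- data.frame(label = tc$label, t1 = vals[, "t1"],
                              t2 = vals[, "t2"], pd = vals[, "pd"])
  lut <- function(col) {
    v <- array(0, dim = dim(tissue))
    for (i in seq_len(nrow(tc))) v[tissue == i] <- tissue_values[[col]][i]
    v
  }
  list(mask = mask, tissue = tissue, labels = labels,
       t1 = lut("t1"), t2 = lut("t2"), pd = lut("pd"),
       tissue_values = tissue_values)
}

#' Generate one paired MPRAGE / compressed-MRF observation
#'
#' Produces what the pipeline consumes for one subject: a noisy,
#' max-normalized magnitude MPRAGE volume and a phase-normalized
#' 7-channel SV volume obtained by projecting per-voxel Bloch-simulated
#' fingerprints onto the dictionary's compression basis, plus ground
#' truth. The subject's tissue (t1, t2) values are snapped to the
#' dictionary grid before simulation so that ground truth is exactly
#' representable and noiseless matching is an identity on the grid.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index 1-based subject number.
#' @param cdict an `mrf_compressed_dictionary` (with its schedule).
#' @param params an [mprage_params()].
#' @return list with `mprage` (3D array in \[0, 1\]), `sv` (4D array,
#'   grid x grid x grid x 7 real channels), `sv_complex` (voxels x 4
#'   complex matrix), plus the `generate_subject` fields with `t1`, `t2`
#'   snapped to the dictionary grid.
#' @export
generate_pair <- function(spec, subject_index, cdict,
                          params = mprage_params()) {
  stopifnot(inherits(cdict, "mrf_compressed_dictionary"))
  if (cdict$k != 4)
    stop("the paired-volume pipeline uses k = 4 (7 real channels)")
  sub <- generate_subject(spec, subject_index)
  tc <- sub$tissue_values
  snap <- snap_to_grid(cdict, tc$t1, tc$t2)
  tc$t1 <- snap$t1
  tc$t2 <- snap$t2
  sub$tissue_values <- tc
  for (i in seq_len(nrow(tc))) {
    sub$t1[sub$tissue == i] <- tc$t1[i]
    sub$t2[sub$tissue == i] <- tc$t2[i]
  }
  set.seed(subject_seed(spec$seed, subject_index) %/% 2L + 1L)

  # per-class compressed fingerprints (atoms are unit-norm; scale by the
  # norm of the raw fingerprint times nothing -- pd scales the signal)
  fp <- simulate_fingerprints(cdict$schedule, tc$t1, tc$t2, pd = tc$pd)
  sv_class <- t(fp) %*% Conj(cdict$basis)       # classes x 4
  nv <- length(sub$mask)
  sv <- matrix(0i, nrow = nv, ncol = cdict$k)
  for (i in seq_len(nrow(tc))) {
    vox <- which(sub$tissue == i)
    sv[vox, ] <- matrix(sv_class[i, ], nrow = length(vox), ncol = cdict$k,
                        byrow = TRUE)
  }
  if (spec$noise_sigma > 0) {
    s <- spec$noise_sigma * max(Mod(sv))
    sv <- sv + matrix(complex(real = stats::rnorm(nv * cdict$k, sd = s),
                              imaginary = stats::rnorm(nv * cdict$k, sd = s)),
                      nrow = nv)
    sv[!sub$mask, ] <- 0i
  }
  pn <- phase_normalize(sv)
  ch <- sv_to_channels(pn$sv)
  g <- spec$grid_size
  sv_arr <- array(ch, dim = c(g, g, g, 7))

  mp <- mprage_signal(sub$t1, sub$pd, params)
  mp[!sub$mask] <- 0
  if (spec$noise_sigma > 0) {
    mp <- mp + array(stats::rnorm(nv, sd = spec$noise_sigma * max(mp)),
                     dim = dim(mp))
    mp[!sub$mask] <- 0
  }
  mp <- pmax(mp, 0)
  mp <- normalize_intensity(mp)

  c(sub, list(mprage = mp, sv = sv_arr, sv_complex = pn$sv))
}

#' Write a phantom cohort to disk
#'
#' One directory per subject holding NIfTI volumes (`mprage`, `sv`
#' 4-dimensional, `t1`, `t2`, `pd`, `labels`, `mask`) plus a JSON
#' manifest.
#' @param spec a [phantom_spec()].
#' @param cdict compressed dictionary used for the MRF side.
#' @param path output directory.
#' @param params an [mprage_params()].
#' @return `path`, invisibly.
#' @export
write_phantom <- function(spec, cdict, path, params = mprage_params()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  geom <- volume_geometry(spec$grid_size, spacing = 1)
  for (s in seq_len(spec$n_subjects)) {
    d <- file.path(path, sprintf("subject%02d", s))
    dir.create(d, showWarnings = FALSE)
    pair <- generate_pair(spec, s, cdict, params)
    write_volume(pair$mprage, file.path(d, "mprage.nii.gz"), geom)
    write_volume(pair$sv, file.path(d, "sv.nii.gz"), geom)
    write_volume(pair$t1, file.path(d, "t1.nii.gz"), geom)
    write_volume(pair$t2, file.path(d, "t2.nii.gz"), geom)
    write_volume(pair$pd, file.path(d, "pd.nii.gz"), geom)
    write_volume(pair$labels + 0, file.path(d, "labels.nii.gz"), geom)
    write_volume(pair$mask + 0, file.path(d, "mask.nii.gz"), geom)
    jsonlite::write_json(
      list(subject = s, seed = spec$seed, grid_size = spec$grid_size,
           noise_sigma = spec$noise_sigma,
           tissue_values = pair$tissue_values),
      file.path(d, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
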