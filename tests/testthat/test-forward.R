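test_that("fingerprints match a brute-force Bloch stepping oracle", {
  set.seed(1)
  for (rep in 1:3) {
    sched <- acquisition_schedule(
      flip_angle = runif(20, 0, 90), tr = runif(20, 8, 14),
      te = runif(20, 1, 4), rf_phase = runif(20, 0, 360),
      invert_first = rep %% 2 == 0, inversion_delay = 18)
    t1 <- runif(1, 300, 2500); t2 <- runif(1, 30, 250)
    t2 <- min(t2, t1)
    pd <- runif(1, 0.5, 1.5)
    got <- simulate_fingerprint(sched, t1, t2, pd)
    want <- bloch_oracle(sched, t1, t2, pd)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-10)
  }
})

test_that("zero flip angles produce an identically zero signal", {
  sched <- acquisition_schedule(rep(0, 25), tr = 10, te = 2,
                                invert_first = FALSE)
  expect_equal(Mod(simulate_fingerprint(sched, 1000, 80)), rep(0, 25))
})

test_that("a constant schedule approaches the closed-form steady state", {
  # fixed point of the affine per-TR map M -> A M + b, solved directly
  n <- 3000
  alpha <- 35; tr <- 12; te <- 3; t1 <- 900; t2 <- 70
  sched <- acquisition_schedule(rep(alpha, n), tr = tr, te = te,
                                invert_first = FALSE)
  sig <- simulate_fingerprint(sched, t1, t2)
  a <- alpha * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  E <- diag(c(exp(-tr / t2), exp(-tr / t2), exp(-tr / t1)))
  b <- c(0, 0, 1 - exp(-tr / t1))
  # state just before each RF pulse: M' = E (Rx M) + b
  A <- E %*% Rx
  M_ss <- solve(diag(3) - A, b)
  M_post <- Rx %*% M_ss
  want <- complex(real = M_post[1], imaginary = M_post[2]) * exp(-te / t2)
  late <- sig[n]
  expect_lt(Mod(late - want) / Mod(want), 1e-8)
})

test_that("fingerprints scale linearly with proton density", {
  sched <- small_schedule()
  s1 <- simulate_fingerprint(sched, 1200, 90, pd = 1)
  s3 <- simulate_fingerprint(sched, 1200, 90, pd = 3.7)
  expect_equal(s3, 3.7 * s1, tolerance = 1e-12)
})

test_that("non-physical tissue parameters are rejected", {
  sched <- small_schedule()
  expect_error(simulate_fingerprint(sched, 100, 200), "t2 exceeds t1")
  expect_error(simulate_fingerprint(sched, -5, 50), "positive")
  expect_error(acquisition_schedule(c(10, 200), tr = 10, te = 2), "flip")
  expect_error(acquisition_schedule(10, tr = 2, te = 5), "te")
})

test_that("dictionary grid enumerates t2 <= t1 pairs in row-major order", {
  sched <- small_schedule()
  d1 <- build_dictionary(sched, 1000, 80)
  expect_equal(ncol(d1$atoms), 1)
  expect_equal(sum(Mod(d1$atoms)^2), 1, tolerance = 1e-9)

  t1v <- c(100, 500, 1000); t2v <- c(50, 80, 200)
  d <- build_dictionary(sched, t1v, t2v)
  surviving <- 0
  expected_grid <- NULL
  for (t1 in t1v) for (t2 in t2v) if (t2 <= t1) {
    surviving <- surviving + 1
    expected_grid <- rbind(expected_grid, c(t1, t2))
  }
  expect_equal(nrow(d$grid), surviving)
  expect_equal(as.matrix(d$grid), expected_grid, ignore_attr = TRUE)
  expect_equal(sqrt(colSums(Mod(d$atoms)^2)), rep(1, surviving),
               tolerance = 1e-9)
  # atom equals the normalized unit-pd fingerprint by definition
  fp <- simulate_fingerprint(sched, 1000, 80)
  expect_equal(d$atoms[, which(d$grid$t1 == 1000 & d$grid$t2 == 80)],
               fp / sqrt(sum(Mod(fp)^2)), tolerance = 1e-12)
  expect_error(build_dictionary(sched, 40, 300), "empty")
})

test_that("SVD compression is exact at full rank and energy-optimal at k", {
  d <- small_dictionary()
  n_t <- nrow(d$atoms)
  full_k <- min(n_t, ncol(d$atoms))
  cf <- compress_dictionary(d, full_k)
  recon <- cf$basis %*% cf$sv_atoms
  expect_lt(max(Mod(recon - d$atoms)) / max(Mod(d$atoms)), 1e-8)

  c4 <- small_cdict(4)
  expect_lt(max(Mod(Conj(t(c4$basis)) %*% c4$basis - diag(4))), 1e-9)
  # retained energy against an independent eigendecomposition of the Gram
  G <- Conj(t(d$atoms)) %*% d$atoms
  ev <- sort(Re(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  expect_equal(retained_energy(c4), sum(ev[1:4]) / sum(ev),
               tolerance = 1e-10)
  expect_error(compress_dictionary(d, 0), "k must")
  expect_error(compress_dictionary(d, 10 * full_k), "k must")
})

test_that("a rank-one dictionary compresses losslessly at k = 1", {
  d <- small_dictionary()
  d$atoms <- outer(d$atoms[, 1], complex(modulus = 1,
                                         argument = seq(0, 1, length.out = ncol(d$atoms))))
  c1 <- compress_dictionary(d, 1)
  recon <- c1$basis %*% c1$sv_atoms
  expect_lt(max(Mod(recon - d$atoms)), 1e-9)
})

test_that("projection onto the basis is the expected inner product", {
  cd <- small_cdict()
  k <- cd$k
  # a voxel equal to basis vector j projects to unit coordinate j
  for (j in c(1, k)) {
    p <- project_timeseries(t(cd$basis[, j]), cd)
    want <- rep(0, k); want[j] <- 1
    expect_equal(as.vector(Mod(p - t(want))), rep(0, k), tolerance = 1e-10)
  }
  expect_equal(project_timeseries(t(rep(0i, nrow(cd$basis))), cd),
               matrix(0i, 1, k))
  # full-rank round trip reproduces arbitrary input
  d <- small_dictionary()
  cf <- compress_dictionary(d, nrow(d$atoms))
  set.seed(2)
  v <- complex(real = rnorm(nrow(d$atoms)), imaginary = rnorm(nrow(d$atoms)))
  p <- project_timeseries(t(v), cf)
  recon <- as.vector(cf$basis %*% t(p))
  expect_lt(max(Mod(recon - v)), 1e-8)
  expect_error(project_timeseries(matrix(0i, 1, 3), cd), "length")
})

test_that("phase normalization zeroes Im(SV1) and preserves structure", {
  pn <- phase_normalize(matrix(c(3 + 4i, 1 - 2i), 1))
  expect_equal(pn$sv[1, 1], 5 + 0i, tolerance = 1e-12)
  expect_false(pn$degenerate[1])

  already <- matrix(c(2 + 0i, 1 + 1i), 1)
  expect_equal(phase_normalize(already)$sv, already)

  set.seed(3)
  sv <- matrix(complex(real = rnorm(80), imaginary = rnorm(80)), 20, 4)
  pn <- phase_normalize(sv)
  expect_equal(Mod(pn$sv), Mod(sv), tolerance = 1e-12)
  expect_equal(Im(pn$sv[, 1]), rep(0, 20), tolerance = 1e-12)
  expect_true(all(Re(pn$sv[, 1]) >= 0))
  # pairwise inner-product magnitudes across voxels are preserved
  expect_equal(Mod(pn$sv %*% Conj(t(pn$sv))), Mod(sv %*% Conj(t(sv))),
               tolerance = 1e-11)
  # degenerate voxels flagged and passed through
  sv[3, ] <- 0i
  pn <- phase_normalize(sv)
  expect_true(pn$degenerate[3])
  expect_equal(pn$sv[3, ], sv[3, ])
})

test_that("matching recovers scaled on-grid atoms exactly", {
  cd <- small_cdict()
  i <- 17
  voxels <- rbind(2.5 * cd$sv_atoms[, i], rep(0i, cd$k))
  m <- match_dictionary(voxels, cd)
  expect_equal(m$t1[1], cd$grid$t1[i])
  expect_equal(m$t2[1], cd$grid$t2[i])
  norm_i <- sqrt(sum(Mod(cd$sv_atoms[, i])^2))
  expect_equal(m$pd[1], 2.5 * norm_i, tolerance = 1e-9)
  # zero voxel inside the mask: sentinel + flag
  expect_equal(m$t1[2], 0)
  expect_true(m$flagged[2])
  expect_error(match_dictionary(matrix(0i, 1, 2), cd), "channel")
})

test_that("production matching equals brute-force exhaustive search", {
  cd <- small_cdict()
  set.seed(4)
  voxels <- matrix(complex(real = rnorm(30 * 4), imaginary = rnorm(30 * 4)),
                   30, 4)
  m <- match_dictionary(voxels, cd)
  anorm <- sqrt(colSums(Mod(cd$sv_atoms)^2))
  for (v in seq_len(nrow(voxels))) {
    scores <- vapply(seq_len(ncol(cd$sv_atoms)), function(j)
      Mod(sum(voxels[v, ] * Conj(cd$sv_atoms[, j] / anorm[j]))), numeric(1))
    best <- which.max(scores)
    expect_equal(m$t1[v], cd$grid$t1[best])
    expect_equal(m$t2[v], cd$grid$t2[best])
    expect_equal(m$pd[v], scores[best], tolerance = 1e-10)
  }
})

test_that("noisy atoms are recovered within one grid step at pilot SNR", {
  # noise level frozen from a pilot run: complex Gaussian sd 5e-4 per
  # component on unit-norm compressed atoms
  cd <- pipeline_cdict()
  A <- sweep(cd$sv_atoms, 2, sqrt(colSums(Mod(cd$sv_atoms)^2)), "/")
  set.seed(5)
  sub <- seq(1, ncol(A), by = 7)
  X <- t(A[, sub])
  X <- X + matrix(complex(real = rnorm(length(X), sd = 5e-4),
                          imaginary = rnorm(length(X), sd = 5e-4)),
                  nrow = nrow(X))
  m <- match_dictionary(X, cd)
  step_t1 <- 40; step_t2 <- 10  # grid spacing of the pipeline dictionary
  ok <- abs(m$t1 - cd$grid$t1[sub]) <= step_t1 &
    abs(m$t2 - cd$grid$t2[sub]) <= step_t2
  expect_gte(mean(ok), 0.95)
})

test_that("match pd output is 1-homogeneous in input scale", {
  cd <- small_cdict()
  set.seed(6)
  v <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 1)
  m1 <- match_dictionary(v, cd)
  m2 <- match_dictionary(4.2 * v, cd)
  expect_equal(m2$pd, 4.2 * m1$pd, tolerance = 1e-10)
  expect_equal(m2$t1, m1$t1)
})

test_that("compress-project-match is the identity on noiseless volumes", {
  cd <- small_cdict()
  d <- small_dictionary()
  set.seed(7)
  idx <- sample(ncol(d$atoms), 25)
  pdv <- runif(25, 0.5, 2)
  ts <- t(d$atoms[, idx]) * pdv
  sv <- project_timeseries(ts, cd)
  m <- match_dictionary(sv, cd)
  expect_equal(m$t1, d$grid$t1[idx])
  expect_equal(m$t2, d$grid$t2[idx])
})

test_that("dictionaries survive a save/load round trip", {
  cd <- small_cdict()
  path <- withr::local_tempdir()
  save_dictionary(cd, path)
  back <- load_dictionary(path)
  expect_equal(back$grid, cd$grid)
  expect_equal(back$sv_atoms, cd$sv_atoms, tolerance = 1e-12)
  expect_equal(back$basis, cd$basis, tolerance = 1e-12)
  expect_equal(back$k, cd$k)
  expect_equal(back$schedule$flip_angle, cd$schedule$flip_angle)
})
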