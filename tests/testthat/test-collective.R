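test_that("superposition recovers exact rigid motions", {
  set.seed(5)
  P <- matrix(stats::rnorm(30), ncol = 3)
  s0 <- superpose(P, P)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Q <- sweep(P %*% t(R), 2L, c(1, 2, 3), "+")
  s1 <- superpose(P, Q)
  expect_equal(s1$rmsd, 0, tolerance = 1e-8)
  expect_equal(s1$rotation, R, tolerance = 1e-8)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-8)
  expect_error(superpose(P[1:2, ], Q[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line + 1), "collinear|degenerate")
})

test_that("superposed RMSD beats a quaternion-grid search oracle", {
  set.seed(11)
  for (rep in 1:3) {
    P <- matrix(stats::rnorm(15), ncol = 3)
    Q <- matrix(stats::rnorm(15), ncol = 3)
    k <- superpose(P, Q)
    Pc <- sweep(P, 2L, colMeans(P)); Qc <- sweep(Q, 2L, colMeans(Q))
    best <- Inf
    for (i in 1:4000) {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      R <- rbind(
        c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
      best <- min(best, sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2))))
    }
    # the analytic optimum can never lose to a sampled rotation, and a
    # dense enough sample comes close to it
    expect_lte(k$rmsd, best + 1e-9)
    expect_lt(best - k$rmsd, 0.05)
  }
})

test_that("rmsd trace and rmsf vanish for a static trajectory", {
  gen <- generate_trajectory(tiny_spec(seed = 41L), 6L)
  ca <- select_atoms(gen$trajectory$topology, "name CA")
  rt <- rmsd_trace(gen$trajectory, ca)
  expect_true(all(rt$rmsd_A < 1e-8))
  rf <- rmsf_profile(gen$trajectory, ca)
  expect_true(all(rf$rmsf_A < 1e-8))
})

test_that("rmsf matches the closed form for a planted square wave", {
  # one atom oscillating +/- a along x around its mean, fit disabled
  a_amp <- 0.8
  atoms <- data.frame(name = "CA", resid = 1:8, resname = "ALA", chain = "A")
  base <- cbind(seq(0, 35, by = 5), 0, 0)
  coords <- array(rep(base, 10L), dim = c(8L, 3L, 10L))
  coords[3L, 1L, ] <- coords[3L, 1L, ] + rep(c(a_amp, -a_amp), 5L)
  traj <- poregate:::new_trajectory(
    hand_system(atoms, base)$topology, coords)
  rf <- rmsf_profile(traj, window = NULL, fit = FALSE)
  expect_equal(rf$rmsf_A[rf$resid == 3L], a_amp, tolerance = 1e-9)
  expect_true(all(rf$rmsf_A[rf$resid != 3L] < 1e-12))
  # duplicated trajectory gives identical profiles
  rf2 <- rmsf_profile(traj, window = NULL, fit = FALSE)
  expect_identical(rf, rf2)
})

test_that("combined PCA conserves variance and finds a planted mode", {
  specA <- channel_spec(residues_per_subunit = 16L, seed = 42L)
  genA <- generate_trajectory(specA, 250L,
                              modes = list(breathing_plan(8L, amplitude = 2)))
  genB <- generate_trajectory(channel_spec(residues_per_subunit = 16L,
                                           seed = 43L), 250L)
  sa <- select_atoms(genA$trajectory$topology, "name CA")
  sb <- select_atoms(genB$trajectory$topology, "name CA")
  pca <- combined_pca(genA$trajectory, genB$trajectory, sa, sb)
  # eigenvalue sum vs independent two-pass variance of the ensemble
  mu <- colMeans(pca$ensemble)
  two_pass <- sum(colMeans(sweep(pca$ensemble, 2L, mu)^2))
  expect_equal(sum(pca$eigenvalues), two_pass, tolerance = 1e-6 * two_pass)
  share <- pca$eigenvalues[1L] / sum(pca$eigenvalues)
  expect_gt(share, 0.99)
  # cosine with the planted radial breathing direction
  a <- genA$trajectory$topology$atoms[poregate:::sel_rows(sa), ]
  dirv <- numeric(3L * nrow(a))
  for (ch in c("A", "B", "C", "D")) {
    i <- which(a$chain == ch & a$resid == 8L)
    th <- poregate:::subunit_angle(ch)
    dirv[(i - 1L) * 3L + 1L] <- cos(th)
    dirv[(i - 1L) * 3L + 2L] <- sin(th)
  }
  dirv <- dirv / sqrt(sum(dirv^2))
  expect_gt(abs(sum(dirv * pca$eigenvectors[, 1L])), 0.99)
})

test_that("PCA of two static copies has all-zero eigenvalues", {
  gen <- generate_trajectory(tiny_spec(seed = 44L), 5L)
  ca <- select_atoms(gen$trajectory$topology, "name CA")
  pca <- combined_pca(gen$trajectory, gen$trajectory, ca, ca)
  expect_true(all(pca$eigenvalues < 1e-10))
})

test_that("PCA rejects mismatched residue lists", {
  genA <- generate_trajectory(tiny_spec(seed = 45L), 3L)
  genB <- generate_trajectory(channel_spec(residues_per_subunit = 18L,
                                           seed = 45L), 3L)
  expect_error(combined_pca(genA$trajectory, genB$trajectory,
                            select_atoms(genA$trajectory$topology, "name CA"),
                            select_atoms(genB$trajectory$topology, "name CA")),
               "unmatched|match")
})

test_that("PCA morph export writes the requested interpolation steps", {
  genA <- generate_trajectory(tiny_spec(seed = 46L), 40L,
                              modes = list(breathing_plan(8L)))
  ca <- select_atoms(genA$trajectory$topology, "name CA")
  pca <- combined_pca(genA$trajectory, genA$trajectory, ca, ca)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pca_morph(pca, genA$trajectory$topology, f, ev = 1L, steps = 6L)
  expect_equal(sum(startsWith(readLines(f), "MODEL")), 6L)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  spec <- channel_spec(residues_per_subunit = 16L, seed = 47L)
  gen <- generate_trajectory(spec, 400L,
    correlations = list(correlation_plan(res_ref("A", 13), res_ref("C", 13),
                                         0.7)),
    modes = list(breathing_plan(8L, amplitude = 1)))
  cm <- correlation_matrix(gen$trajectory,
                           select_atoms(gen$trajectory$topology, "name CA"))
  expect_equal(cm$matrix, t(cm$matrix), tolerance = 1e-12)
  moving <- abs(diag(cm$matrix) - 1) < 1e-8
  expect_true(any(moving))
  expect_true(all(abs(cm$matrix) <= 1 + 1e-8))
})

test_that("identical planted displacements correlate to exactly 1", {
  spec <- channel_spec(residues_per_subunit = 16L, seed = 48L)
  gen <- generate_trajectory(spec, 300L,
                             modes = list(breathing_plan(8L, amplitude = 2)))
  cm <- suppressWarnings(
    correlation_matrix(gen$trajectory,
                       select_atoms(gen$trajectory$topology,
                                    "name CA and resid 8")))
  # A and C move radially in opposite directions: perfect anticorrelation;
  # A and B are orthogonal radial directions: zero correlation
  expect_equal(cm$matrix["A:8", "C:8"], -1, tolerance = 1e-9)
  expect_equal(cm$matrix["A:8", "B:8"], 0, tolerance = 1e-9)
})

test_that("planted correlations are recovered through the full DCCM", {
  spec <- channel_spec(residues_per_subunit = 24L, seed = 7L)
  gen <- generate_trajectory(spec, 5000L,
    correlations = list(correlation_plan(res_ref("A", 13), res_ref("C", 13),
                                         0.8)))
  cm <- correlation_matrix(gen$trajectory,
                           select_atoms(gen$trajectory$topology, "name CA"))
  expect_equal(cm$matrix["A:13", "C:13"], 0.8, tolerance = 0.05)
})

test_that("zero-variance residues yield 0 with a warning", {
  gen <- generate_trajectory(tiny_spec(seed = 49L), 10L,
                             modes = list(breathing_plan(8L)))
  expect_warning(
    cm <- correlation_matrix(gen$trajectory,
                             select_atoms(gen$trajectory$topology, "name CA")),
    "zero variance")
  static <- which(cm$residues$resid != 8L)[1L]
  expect_equal(cm$matrix[static, static], 0)
})

test_that("correlation differences follow the holo - apo convention", {
  pairs <- data.frame(pair = c("G63-S325", "T343-G70"),
                      c_apo = c(0.6885, -0.1971),
                      c_holo = c(-0.3178, 0.6466))
  d <- correlation_difference(pairs = pairs)
  expect_equal(d$delta, c(-1.0063, 0.8437), tolerance = 1e-9)
  # matrix route: identical matrices -> all zero; antisymmetry
  gen <- generate_trajectory(channel_spec(residues_per_subunit = 16L,
                                          seed = 50L), 200L,
                             modes = list(breathing_plan(8L)))
  cm <- suppressWarnings(
    correlation_matrix(gen$trajectory,
                       select_atoms(gen$trajectory$topology, "name CA")))
  d0 <- correlation_difference(cm, cm)
  expect_true(all(d0$delta == 0))
  gen2 <- generate_trajectory(channel_spec(residues_per_subunit = 16L,
                                           seed = 51L), 200L,
                              correlations = list(
                                correlation_plan(res_ref("A", 13),
                                                 res_ref("C", 13), 0.6)))
  cm2 <- suppressWarnings(
    correlation_matrix(gen2$trajectory,
                       select_atoms(gen2$trajectory$topology, "name CA")))
  d12 <- correlation_difference(cm, cm2)
  d21 <- correlation_difference(cm2, cm)
  expect_equal(d12$delta, -d21$delta)
})

test_that("torsion summaries use circular statistics", {
  plans <- list(torsion_plan(res_ref("A", 13), phi = -82.96, psi = 21.52))
  gen <- generate_trajectory(tiny_spec(seed = 52L), 5L, torsions = plans)
  ts <- torsion_summary(gen$trajectory)
  row <- ts$table[ts$table$chain == "A" & ts$table$resid == 13L, ]
  expect_equal(row$phi_mean, -82.96, tolerance = 1e-3)
  expect_equal(row$psi_mean, 21.52, tolerance = 1e-3)
  expect_equal(row$phi_sd, 0, tolerance = 1e-6)
  # wraparound series averages to 180, never 0
  expect_equal(circular_mean(c(179, -179)), 180)
  expect_equal(circular_mean(c(170, -170, 180)), 180, tolerance = 1e-9)
  # invariance under adding 360 to a subset
  set.seed(3)
  x <- stats::runif(50, -180, 180)
  y <- x; y[1:20] <- y[1:20] + 360
  expect_equal(circular_mean(x), circular_mean(y), tolerance = 1e-9)
  expect_equal(circular_sd(rep(42, 10)), 0, tolerance = 1e-6)
})

test_that("torsion jitter shows up as circular spread around the mean", {
  plans <- list(torsion_plan(res_ref("A", 13), phi = 175, psi = -60,
                             jitter_sd = 8))
  gen <- generate_trajectory(tiny_spec(seed = 53L), 2000L, torsions = plans)
  ts <- torsion_summary(gen$trajectory)
  row <- ts$table[ts$table$chain == "A" & ts$table$resid == 13L, ]
  # circular estimates stay near the planted values even though the
  # series wraps across +/-180 (an arithmetic mean would not)
  expect_equal(row$phi_mean, 175, tolerance = 1)
  expect_equal(row$phi_sd, 8, tolerance = 1)
  wrapped <- gen$manifest$torsions[[1]]
  expect_equal(wrapped$phi, 175)
})

test_that("chain termini omit the undefined angle", {
  gen <- generate_trajectory(tiny_spec(seed = 54L), 2L)
  ts <- torsion_summary(gen$trajectory)
  first <- ts$table[ts$table$chain == "A" & ts$table$resid == 1L, ]
  last <- ts$table[ts$table$chain == "A" & ts$table$resid == 16L, ]
  expect_true(is.na(first$phi_mean) && !is.na(first$psi_mean))
  expect_true(!is.na(last$phi_mean) && is.na(last$psi_mean))
})
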