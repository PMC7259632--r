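test_that("ca_span measures the Calpha-Calpha distance and reports errors", {
  st <- structure_from_rows(
    atom_row("CA", 0, 0, 0, resseq = 25),
    atom_row("CA", 7, 0, 0, resseq = 29))
  expect_equal(ca_span(st, "A", 25, 29), 7.0)
  expect_equal(ca_span(st, "A", 29, 25), 7.0)  # symmetric
  expect_error(ca_span(st, "A", 25, 30), "residue 30")
  expect_error(ca_span(st, "B", 25, 29), "selection error")
})

test_that("ca_span is invariant under rigid-body transformation", {
  st <- make_turn_peptide(9.0)
  s0 <- ca_span(st, "A", 25, 29)
  set.seed(11)
  for (k in 1:5) {
    st2 <- transform_structure(st, random_rotation(), rnorm(3, sd = 20))
    expect_equal(ca_span(st2, "A", 25, 29), s0, tolerance = 1e-9)
  }
})

test_that("classify_turn reproduces the published span classes", {
  # spans printed for the octadecamer, tetramer and zipper-like models
  expect_equal(classify_turn(7.8), "sharp")
  expect_equal(classify_turn(11.66), "wide")
  expect_equal(classify_turn(15.04), "extended")
  expect_equal(classify_turn(c(5.55, 9.47, 13.4)),
               c("sharp", "wide", "wide"))
  expect_error(classify_turn(-1), "domain error")
  expect_error(classify_turn(5, sharp_max = 10, wide_max = 8))
})

test_that("classify_turn is monotone in span", {
  spans <- seq(0.5, 20, by = 0.25)
  cls <- classify_turn(spans)
  rank <- match(cls, c("sharp", "wide", "extended"))
  expect_true(all(diff(rank) >= 0))
})

test_that("kabsch recovers rigid-body transforms exactly", {
  set.seed(42)
  X <- matrix(rnorm(30), 10, 3)
  fit_t <- kabsch_superpose(sweep(X, 2, c(5, 5, 5), `+`), X)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-10)
  fit_r <- kabsch_superpose(X %*% t(rotation_z(pi / 2)), X)
  expect_equal(fit_r$rmsd, 0, tolerance = 1e-10)
  # transform() maps mobile onto reference
  moved <- sweep(X %*% t(rotation_z(1.1)), 2, c(3, -2, 7), `+`)
  fit <- kabsch_superpose(moved, X)
  expect_equal(fit$transform(moved), X, tolerance = 1e-9)
})

test_that("kabsch rejects degenerate input", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(kabsch_superpose(X[1:5, ], X), "shape error")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("kabsch rmsd equals the quaternion-search minimum", {
  set.seed(7)
  for (k in 1:3) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- sweep(X %*% t(random_rotation()), 2, rnorm(3), `+`) +
      matrix(rnorm(30, sd = 0.3), 10, 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, oracle_min_rmsd(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("kabsch never exceeds the unsuperposed rmsd", {
  set.seed(13)
  for (k in 1:25) {
    X <- matrix(rnorm(24), 8, 3)
    Y <- matrix(rnorm(24), 8, 3)
    raw <- sqrt(mean(rowSums((X - Y)^2)))
    expect_lte(kabsch_superpose(X, Y)$rmsd, raw + 1e-12)
  }
})

make_wiggle_traj <- function(n_frames = 5) {
  st <- make_turn_peptide(6.6)
  frames <- lapply(seq_len(n_frames), function(k) {
    s <- transform_structure(st, rotation_z(0.2 * k), c(k, -k, 2 * k))
    s$model_id <- k
    s
  })
  new_trajectory(frames)
}

test_that("lrmsd_series is zero for identical and rigid-body frames", {
  traj <- make_wiggle_traj()
  expect_equal(lrmsd_series(traj)$lrmsd, rep(0, 5), tolerance = 1e-9)
  expect_error(lrmsd_series(traj, atom_names = "XX"), "empty selection")
})

test_that("lrmsd_series matches the quaternion oracle on perturbed frames", {
  set.seed(3)
  st <- make_turn_peptide(6.6)
  frames <- lapply(1:4, function(k) {
    s <- st
    s$model_id <- k
    ca <- s$atoms$name == "CA"
    s$atoms$x[ca] <- s$atoms$x[ca] + rnorm(sum(ca), sd = 0.4)
    s$atoms$y[ca] <- s$atoms$y[ca] + rnorm(sum(ca), sd = 0.4)
    transform_structure(s, random_rotation(), rnorm(3, sd = 5))
  })
  traj <- new_trajectory(frames)
  got <- lrmsd_series(traj)$lrmsd
  ref <- coords(select_atoms(traj$frames[[1]], atom_names = "CA"))
  for (k in 2:4) {
    mob <- coords(select_atoms(traj$frames[[k]], atom_names = "CA"))
    expect_equal(got[k], oracle_min_rmsd(mob, ref), tolerance = 1e-6)
  }
})

test_that("rmsf is zero for rigid motion and d for an oscillating atom", {
  traj <- make_wiggle_traj()
  expect_equal(rmsf_profile(traj)$rmsf, rep(0, 11), tolerance = 1e-9)
  expect_error(rmsf_profile(new_trajectory(traj$frames[1])), "2 frames")

  # one side-chain atom oscillates +/- d along x; align on the rigid Calphas
  st <- make_turn_peptide(6.6)
  nz <- st$atoms$name == "NZ"
  d <- 0.8
  f1 <- st; f1$atoms$x[nz] <- f1$atoms$x[nz] + d
  f2 <- st; f2$atoms$x[nz] <- f2$atoms$x[nz] - d; f2$model_id <- 2L
  traj2 <- new_trajectory(list(f1, f2))
  prof <- rmsf_profile(traj2, atom_names = "NZ",
                       align = list(atom_names = "CA"))
  expect_equal(prof$rmsf, d, tolerance = 1e-10)
})

test_that("rmsf matches a brute-force per-atom computation", {
  set.seed(21)
  st <- make_turn_peptide(6.6)
  frames <- lapply(1:20, function(k) {
    s <- st
    s$model_id <- k
    jitter <- matrix(rnorm(nrow(s$atoms) * 3, sd = 0.3), ncol = 3)
    s$atoms$x <- s$atoms$x + jitter[, 1]
    s$atoms$y <- s$atoms$y + jitter[, 2]
    s$atoms$z <- s$atoms$z + jitter[, 3]
    transform_structure(s, random_rotation(), rnorm(3, sd = 3))
  })
  traj <- new_trajectory(frames)
  prof <- rmsf_profile(traj)
  # brute force: superpose every frame's Calphas, then loop atoms/frames
  ref <- coords(select_atoms(traj$frames[[1]], atom_names = "CA"))
  al <- lapply(traj$frames, function(f) {
    ca <- coords(select_atoms(f, atom_names = "CA"))
    kabsch_superpose(ca, ref)$transform(ca)
  })
  n_at <- nrow(ref)
  expected <- numeric(n_at)
  for (i in seq_len(n_at)) {
    pos <- t(vapply(al, function(m) m[i, ], numeric(3)))
    mu <- colMeans(pos)
    expected[i] <- sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
  }
  expect_equal(prof$rmsf, expected, tolerance = 1e-9)
})
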