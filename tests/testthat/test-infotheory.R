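test_that("bin optimization handles constant series and matches the literal scan", {
  b0 <- optimize_bins(rep(1.5, 100))
  expect_true(b0$constant)
  expect_equal(b0$n_bins, 1L)
  expect_equal(entropy_estimate(rep(1.5, 100), b0)$H, 0)

  set.seed(101)
  for (k in 1:6) {
    x <- switch(1 + (k %% 3),
                rnorm(400), rexp(400), abs(rnorm(400, sd = 2)))
    b <- optimize_bins(x)
    expect_equal(b$n_bins, oracle_optimal_bins(x))
  }
})

test_that("uniform samples track the log2 entropy law along the scan trace", {
  set.seed(103)
  x <- runif(1e5)
  b <- optimize_bins(x)
  tr <- b$trace
  expect_true(all(abs(tr$H - log2(tr$n_bins)) < 0.01))
})

test_that("the bin count is capped at sqrt of the sample count", {
  ## a uniform grid keeps gaining ~log2 N entropy per refinement at small
  ## N, so the 2% criterion is never met below the cap
  x <- seq(0, 1, length.out = 100)
  b <- optimize_bins(x)
  expect_lte(b$n_bins, floor(sqrt(100)))
  expect_true(b$capped)
})

test_that("entropy and its finite-sampling correction are exact arithmetic", {
  ## two equiprobable bins -> 1 bit
  x <- rep(c(0.25, 0.75), 500)
  b <- structure(list(n_bins = 2L, width = 0.5, range = c(0, 1),
                      constant = FALSE), class = "BinSpec")
  e <- entropy_estimate(x, b)
  expect_equal(e$H, 1)
  ## correction adds (N_b - 1)/N_c exactly, as printed
  expect_equal(e$H_corrected, 1 + (2 - 1) / 1000)

  st <- c(rep(1L, 100), rep(2:9, each = 112), rep(2L, 4))
  e2 <- entropy_estimate(st[1:1000])
  expect_equal(e2$H_corrected - e2$H, (e2$n_occupied - 1) / 1000)
  expect_gte(e2$H_corrected, e2$H)
})

test_that("binned entropy approaches the distribution entropy at scale", {
  set.seed(109)
  ## discrete distribution rendered as bin-center values
  p <- c(0.5, 0.25, 0.125, 0.125)
  x <- sample(c(0.125, 0.375, 0.625, 0.875), 1e5, TRUE, prob = p)
  b <- structure(list(n_bins = 4L, width = 0.25, range = c(0, 1),
                      constant = FALSE), class = "BinSpec")
  expect_lt(abs(entropy_estimate(x, b)$H - (-sum(p * log2(p)))), 0.02)
})

test_that("MI of a series with itself is its observed entropy", {
  set.seed(113)
  x <- rnorm(2000)
  b <- optimize_bins(x)
  d <- mi_calpha(x, x, b, b, details = TRUE)
  expect_equal(d$mi_observed, entropy_estimate(x, b)$H, tolerance = 1e-12)
})

test_that("the MI correction follows the printed formula exactly", {
  set.seed(127)
  x <- rnorm(500); y <- rnorm(500)
  d <- mi_calpha(x, y, details = TRUE)
  expect_equal(d$correction,
               (d$nb_ij - d$nb_i - d$nb_j + 1) / (2 * 500))
  expect_equal(max(0, d$mi_observed - d$correction), d$mi)
  ## corrected <= observed whenever N_b(i,j) >= N_b(i) + N_b(j) - 1
  if (d$nb_ij >= d$nb_i + d$nb_j - 1) expect_lte(d$mi, d$mi_observed)
})

test_that("MI equals the nested-loop oracle on small fixtures", {
  set.seed(131)
  for (k in 1:5) {
    x <- rnorm(150); y <- x * 0.5 + rnorm(150, sd = 0.8)
    bx <- optimize_bins(x); by <- optimize_bins(y)
    d <- mi_calpha(x, y, bx, by, details = TRUE)
    o <- oracle_mi(mdmi:::.discretize(x, bx), mdmi:::.discretize(y, by),
                   bx$n_bins, by$n_bins)
    expect_equal(d$mi_observed, o$mi_observed, tolerance = 1e-10)
    expect_equal(d$mi, o$floored, tolerance = 1e-10)
  }
})

test_that("merging histogram bins never increases uncorrected MI", {
  set.seed(137)
  x <- rnorm(1000); y <- 0.7 * x + rnorm(1000, sd = 0.5)
  mk <- function(nb, v) structure(list(n_bins = nb, width = diff(range(v)) / nb,
                                       range = range(v), constant = FALSE),
                                  class = "BinSpec")
  ## halving the bin count merges adjacent bins pairwise
  for (nb in c(16L, 8L, 4L)) {
    fine <- mi_calpha(x, y, mk(nb, x), mk(nb, y), details = TRUE)
    coarse <- mi_calpha(x, y, mk(nb / 2L, x), mk(nb / 2L, y), details = TRUE)
    expect_lte(coarse$mi_observed, fine$mi_observed + 1e-12)
  }
})

test_that("the correction magnitude shrinks as 1/N_c", {
  set.seed(139)
  corr <- vapply(c(500, 5000, 50000), function(n) {
    x <- rnorm(n); y <- rnorm(n)
    mk <- function(v) structure(list(n_bins = 10L,
                                     width = diff(range(v)) / 10,
                                     range = range(v), constant = FALSE),
                                class = "BinSpec")
    mi_calpha(x, y, mk(x), mk(y), details = TRUE)$correction
  }, numeric(1))
  expect_gt(corr[1] / corr[2], 5)     # ~10x per decade, occupancy-limited
  expect_gt(corr[2] / corr[3], 5)
})

test_that("a 3-residue ensemble with identical series duplicates the entropy", {
  ## a breathing mode (radial, rigid-free): every residue's displacement
  ## norm series is identical, so each off-diagonal MI reduces to the
  ## common entropy with the degenerate-joint correction
  set.seed(149)
  amp <- rnorm(300, sd = 1)
  ang <- 2 * pi * (0:2) / 3
  radial <- cbind(cos(ang), sin(ang), 0)
  base <- 100 * radial
  frames <- lapply(seq_along(amp), function(t) base + amp[t] * radial)
  tr <- toy_traj(frames)
  mim <- mi_matrix_calpha(tr)
  fl <- fluctuation_series(pool_align(tr), NULL)
  expect_lt(max(abs(fl[, 1] - fl[, 2])), 1e-6)
  b <- optimize_bins(fl[, 1])
  e <- entropy_estimate(fl[, 1], b)
  ## MI(X, X) observed = H(X); the Eq-9 correction of the degenerate joint
  ## (N_b bins on the diagonal) ADDS (N_b - 1)/(2 N_c)
  expect_equal(mim$matrix[1, 2], e$H + (e$n_occupied - 1) / (2 * 300),
               tolerance = 1e-6)
  ## diagonal carries the Eq-8 corrected entropy
  expect_equal(mim$matrix[1, 1], e$H_corrected, tolerance = 1e-6)
})

test_that("dihedral angles honor cis/trans conventions and chirality", {
  ## SER chi1 quadruple planted eclipsed, anti, and at a chiral angle
  mk <- function(og) {
    at <- data.frame(serial = 1:5,
                     name = c("N", "CA", "CB", "OG", "C"),
                     element = c("N", "C", "C", "O", "C"),
                     res_name = "SER", res_id = 1L, chain = "A",
                     stringsAsFactors = FALSE)
    co <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1.5), og, c(-1, 1, 0))
    trajectory(at, matrix(as.vector(t(co)), 1L))
  }
  cis <- extract_dihedrals(mk(c(1, 0, 1.5) + c(0, 0, 0)), 1L)
  expect_equal(unname(cis[1, "chi1"]), 0, tolerance = 1e-8)
  trans <- extract_dihedrals(mk(c(-1, 0, 1.5)), 1L)
  expect_equal(abs(unname(trans[1, "chi1"])), 180, tolerance = 1e-8)
  plus <- mk(c(cos(1), sin(1), 1.5))
  minus <- mk(c(cos(1), -sin(1), 1.5))
  a1 <- unname(extract_dihedrals(plus, 1L)[1, "chi1"])
  a2 <- unname(extract_dihedrals(minus, 1L)[1, "chi1"])
  expect_equal(a1, -a2, tolerance = 1e-8)
  ## phi/psi need neighbors: both are marked absent here, never zero-filled
  expect_setequal(attr(cis, "absent"), c("phi", "psi"))
})

test_that("torsions agree with an independent implementation", {
  set.seed(151)
  for (k in 1:5) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    mine <- mdmi:::.torsion(p[1, , drop = FALSE], p[2, , drop = FALSE],
                            p[3, , drop = FALSE], p[4, , drop = FALSE])
    expect_equal(mine, bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("rotamer state sectors follow the stated conventions", {
  lib <- default_rotamer_library()
  dh <- matrix(c(65, -180, 130, -60), 1, 4)
  colnames(dh) <- c("chi1", "phi", "psi", "chi1")  # names drive the rule
  ## sp3 sectors: chi = 65 -> g+ (state 1)
  d1 <- matrix(65, 1, 1, dimnames = list(NULL, "chi1"))
  attr(d1, "res_name") <- "SER"
  s1 <- assign_rotamer_states(structure(d1, class = class(d1)), "SER")
  expect_equal(unname(s1[1, 1]), 1L)
  ## backbone phi = -180 -> state 1 (lower sector closed edge)
  d2 <- matrix(c(-180, -60, 0, 60, 61, 180), 6, 1,
               dimnames = list(NULL, "phi"))
  s2 <- assign_rotamer_states(d2, "ALA")
  expect_equal(unname(s2[, 1]), c(1L, 1L, 2L, 2L, 3L, 1L))
  ## sp2 two-state rule on ASP chi2
  d3 <- matrix(c(30, -150), 2, 1, dimnames = list(NULL, "chi2"))
  s3 <- assign_rotamer_states(d3, "ASP")
  expect_equal(unname(s3[, 1]), c(1L, 2L))
  expect_equal(attr(s3, "n_states"), 2L)
  expect_error(assign_rotamer_states(d1, "XYZ"), "library error")
})

test_that("state sequences survive an angle round trip at sector centers", {
  set.seed(157)
  centers_sp3 <- c(60, 180, -60)          # g+, t, g-
  centers_bb <- c(-120, 0, 120)
  centers_sp2 <- c(0, 180)
  states <- sample(1:3, 200, TRUE)
  ## sp3 round trip
  d <- matrix(centers_sp3[states], ncol = 1, dimnames = list(NULL, "chi1"))
  s <- assign_rotamer_states(d, "SER")
  expect_equal(unname(s[, 1]), states)
  ## backbone round trip
  db <- matrix(centers_bb[states], ncol = 1, dimnames = list(NULL, "phi"))
  sb <- assign_rotamer_states(db, "GLY")
  expect_equal(unname(sb[, 1]), states)
  ## sp2 round trip
  st2 <- sample(1:2, 200, TRUE)
  d2 <- matrix(centers_sp2[st2], ncol = 1, dimnames = list(NULL, "chi2"))
  s2 <- assign_rotamer_states(d2, "PHE")
  expect_equal(unname(s2[, 1]), st2)
})

test_that("dihedral MI reduces to entropy for identical single sequences", {
  set.seed(163)
  a <- matrix(sample(1:3, 4000, TRUE, prob = c(0.5, 0.3, 0.2)), ncol = 1)
  v <- mi_dihedral(a, a)
  expect_equal(attr(v, "pairs")$mi_observed,
               entropy_estimate(a[, 1])$H, tolerance = 1e-12)
})

test_that("dihedral MI recovers exact planted-table values", {
  joint <- matrix(c(0.30, 0.04, 0.02,
                    0.04, 0.25, 0.05,
                    0.02, 0.05, 0.23), 3, 3, byrow = TRUE)
  g <- gen_rotamer_series(joint, n_frames = 1e5, seed = 167)
  est <- mi_dihedral(matrix(g$states_i, ncol = 1),
                     matrix(g$states_j, ncol = 1))
  expect_lt(abs(as.numeric(est) - g$mi_exact), 0.02)
})

test_that("absent dihedrals are flagged, not returned as zero MI", {
  empty <- matrix(integer(0), nrow = 100, ncol = 0)
  full <- matrix(sample(1:3, 100, TRUE), ncol = 1)
  v <- mi_dihedral(empty, full)
  expect_true(is.na(v))
  expect_true(attr(v, "absent"))
})

test_that("dihedral aggregation modes reduce over dihedral pairs", {
  set.seed(173)
  a <- matrix(sample(1:3, 1000, TRUE), ncol = 2)
  b <- matrix(sample(1:3, 1000, TRUE), ncol = 2)
  colnames(a) <- colnames(b) <- c("phi", "chi1")
  vs <- mi_dihedral(a, b, aggregate = "sum")
  vm <- mi_dihedral(a, b, aggregate = "mean")
  vx <- mi_dihedral(a, b, aggregate = "max")
  p <- attr(vs, "pairs")
  expect_equal(as.numeric(vs), sum(p$mi))
  expect_equal(as.numeric(vm), mean(p$mi))
  expect_equal(as.numeric(vx), max(p$mi))
  expect_equal(nrow(p), 4L)
})

test_that("MI matrices are symmetric with corrected entropies on the diagonal", {
  g <- gen_gaussian_traj(n_res = 8, n_frames = 400,
                         blocks = list(list(residues = 2:3, rho = 0.9)),
                         seed = 179)
  mim <- mi_matrix_calpha(g$trajectory)
  m <- mim$matrix
  expect_identical(m, t(m))
  expect_true(all(m[upper.tri(m)] >= 0))
  pooled <- pool_align(g$trajectory, select_atoms(g$trajectory, name = "CA"))
  fl <- fluctuation_series(pooled)
  b1 <- optimize_bins(fl[, 1])
  expect_equal(m[1, 1],
               entropy_estimate(mdmi:::.discretize(fl[, 1], b1))$H_corrected,
               tolerance = 1e-10)
})

test_that("planted correlation ranks within-block MI above cross-block", {
  reps <- lapply(1:2, function(r)
    gen_gaussian_traj(n_res = 16, n_frames = 1500,
                      blocks = list(list(residues = 5:7, rho = 0.9)),
                      seed = 190 + r)$trajectory)
  mim <- mi_matrix_calpha(reps)
  m <- mim$matrix
  blk <- 5:7
  within <- m[blk, blk][upper.tri(diag(length(blk)))]
  mask <- outer(1:16 %in% blk, 1:16 %in% blk, "&")
  cross <- m[!mask & upper.tri(m)]
  expect_gt(min(within), max(cross))
})

test_that("MI aggregation schemes are consistent on planted structure", {
  ## uniform matrix: every aggregate equals the common value
  res <- data.frame(chain = "A", res_id = 1:10,
                    res_name = rep(c("LYS", "GLN", "ALA", "SER", "GLU"), 2),
                    stringsAsFactors = FALSE)
  m <- matrix(1, 10, 10); diag(m) <- NA
  mim <- structure(list(matrix = m, residues = res, mode = "dihedral",
                        n_c = 100L, min_sep = 2L), class = "MIMatrix")
  rm_ <- aggregate_mi(mim, "residue_mean")
  expect_true(all(rm_$mean_mi == 1))
  bt <- aggregate_mi(mim, "by_type")
  expect_true(all(bt$mean_mi == 1))
  bc <- aggregate_mi(mim, "by_class")
  expect_true(all(bc$mean_mi == 1))
  tp <- aggregate_mi(mim, "type_pair")
  expect_true(all(tp[!is.na(tp)] == 1))

  ## delta of a matrix with itself is zero
  dd <- aggregate_mi(mim, "delta", ref = mim)
  expect_true(all(dd$delta_mi == 0))

  ## one planted high-MI LYS-GLN pair tops the per-type ranking
  m2 <- matrix(0.01, 10, 10); diag(m2) <- NA
  m2[1, 7] <- m2[7, 1] <- 0.9          # LYS1 - GLN7
  mim2 <- structure(list(matrix = m2, residues = res, mode = "dihedral",
                         n_c = 100L, min_sep = 2L), class = "MIMatrix")
  bt2 <- aggregate_mi(mim2, "by_type")
  top2 <- bt2$res_name[order(-bt2$mean_mi)][1:2]
  expect_setequal(top2, c("LYS", "GLN"))
  ## and the class ranking puts basic and amide first
  bc2 <- aggregate_mi(mim2, "by_class")
  topc <- bc2$class[order(-bc2$mean_mi)][1:2]
  expect_setequal(topc, c("basic", "amide"))
  ## rotatable-bond grouping keys on the chi-count table
  bn <- aggregate_mi(mim2, "by_nchi")
  expect_true(all(c(0, 1, 3, 4) %in% bn$n_chi))
})
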