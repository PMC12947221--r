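# hand-posed donor/H/acceptor scene: N-H along +x, acceptor placed by
# distance from H and deviation from collinearity
hb_scene <- function(ha_dist, dha_angle) {
  ## D-H-A angle measured at H; 180 deg = collinear extension of N->H
  theta <- (180 - dha_angle) * pi / 180
  o_pos <- c(1.0, 0, 0) + ha_dist * c(cos(theta), sin(theta), 0)
  at <- data.frame(
    serial = 1:5,
    name = c("N", "H", "CA", "C", "O"),
    element = c("N", "H", "C", "C", "O"),
    res_name = "ALA",
    res_id = c(1L, 1L, 1L, 5L, 5L),
    chain = "A", stringsAsFactors = FALSE)
  co <- rbind(c(0, 0, 0), c(1.0, 0, 0), c(-0.8, 1.2, 0),
              o_pos + c(1.23, 0.3, 0), o_pos)
  trajectory(at, matrix(as.vector(t(co)), 1L))
}

test_that("hydrogen-bond detection honors both geometric criteria", {
  hit <- detect_hbonds_frame(hb_scene(2.0, 180))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$dist, 2.0, tolerance = 1e-8)
  expect_equal(hit$angle, 180, tolerance = 1e-6)

  expect_equal(nrow(detect_hbonds_frame(hb_scene(2.6, 180))), 0L)  # distance fails
  expect_equal(nrow(detect_hbonds_frame(hb_scene(1.9, 110))), 0L)  # angle fails
  ## boundary values are inclusive
  expect_equal(nrow(detect_hbonds_frame(hb_scene(2.5, 120))), 1L)
})

test_that("detection without hydrogens is an explicit error", {
  g <- gen_gaussian_traj(n_res = 5, n_frames = 2, seed = 3)
  expect_error(detect_hbonds_frame(g$trajectory), "no hydrogens")
})

test_that("occupancy thresholding keeps 0.001 and drops below", {
  ## 1 bonded frame out of 2000 (0.0005) -> dropped;
  ## 2 out of 1000 (0.002) -> retained
  mk <- function(n_on, n_off) {
    frames <- c(rep(list(hb_scene(2.0, 180)$xyz), n_on),
                rep(list(hb_scene(3.5, 180)$xyz), n_off))
    trajectory(hb_scene(2.0, 180)$atoms, do.call(rbind, frames))
  }
  tab1 <- hbond_table(mk(1L, 1999L))
  expect_equal(nrow(tab1$records), 0L)
  tab2 <- hbond_table(mk(2L, 998L))
  expect_equal(nrow(tab2$records), 1L)
  expect_equal(tab2$records$occupancy, 0.002)
  ## exactly at the threshold: retained
  tab3 <- hbond_table(mk(1L, 999L))
  expect_equal(tab3$records$occupancy, 0.001)
})

test_that("scheduled occupancy is recovered within binomial error", {
  sc <- gen_hbond_scene(list(list(occupancy = 0.30)), n_frames = 5000,
                        seed = 77)
  tab <- hbond_table(sc$trajectory)
  expect_equal(nrow(tab$records), 1L)
  expect_lt(abs(tab$records$occupancy - 0.30), 0.02)
  ## the realized on-frames are the ground truth count exactly
  expect_equal(tab$records$n_frames,
               length(sc$ground_truth$triples[[1]]$on_frames))
})

test_that("multi-hydrogen donors give distinct records per hydrogen", {
  sc <- gen_hbond_scene(list(list(occupancy = 1.0)), n_frames = 10,
                        multi_h = TRUE, seed = 5)
  hits <- detect_hbonds_frame(sc$trajectory, 1)
  at <- sc$trajectory$atoms
  lys_h <- hits[at$res_name[hits$donor] == "LYS", ]
  ## all three NZ hydrogens point somewhere; records are keyed per H
  expect_equal(anyDuplicated(paste(hits$donor, hits$h, hits$acceptor)), 0L)
})

test_that("residue aggregates equal a brute-force recount of the records", {
  sc <- gen_hbond_scene(list(list(occupancy = 0.6), list(occupancy = 0.4)),
                        n_frames = 500, seed = 11)
  tab <- hbond_table(sc$trajectory)
  rec <- tab$records
  for (i in seq_len(nrow(tab$by_residue))) {
    r <- tab$by_residue[i, ]
    as_d <- rec$donor_res == r$res_id & rec$donor_chain == r$chain
    as_a <- rec$acceptor_res == r$res_id & rec$acceptor_chain == r$chain
    expect_equal(r$n_as_donor, sum(as_d))
    expect_equal(r$n_as_acceptor, sum(as_a))
    expect_equal(r$unique_acceptors,
                 length(unique(rec$acceptor_res[as_d])))
    occ <- rec$occupancy[as_d | as_a]
    expect_equal(r$persistence,
                 if (length(occ)) mean(occ) else NA_real_)
  }
})

test_that("detection is invariant under a global rigid motion", {
  set.seed(83)
  sc <- hb_scene(2.2, 150)
  moved <- rigid_move_traj(sc)
  h1 <- detect_hbonds_frame(sc)
  h2 <- detect_hbonds_frame(moved)
  expect_equal(h1$dist, h2$dist, tolerance = 1e-8)
  expect_equal(h1$angle, h2$angle, tolerance = 1e-6)
})

# two-residue C-alpha + sidechain-carbon toy at a planted closest approach
contact_scene <- function(min_dists) {
  at <- data.frame(serial = 1:4,
                   name = c("CA", "CB", "CA", "CB"),
                   element = "C", res_name = "ALA",
                   res_id = c(1L, 1L, 2L, 2L), chain = "A",
                   stringsAsFactors = FALSE)
  frames <- lapply(min_dists, function(d)
    as.vector(t(rbind(c(0, 0, 0), c(1, 0, 0),
                      c(1 + d + 3, 0, 0), c(1 + d, 0, 0)))))
  trajectory(at, do.call(rbind, frames))
}

test_that("contact calls follow the cutoff and persistence rules", {
  expect_true(contact_map(contact_scene(rep(5, 4)))$contact[1, 2])
  expect_false(contact_map(contact_scene(rep(6.5, 4)))$contact[1, 2])
  ## within cutoff 70% of frames: fraction recorded, not persistent at 0.75
  cm <- contact_map(contact_scene(c(rep(5, 7), rep(8, 3))))
  expect_equal(cm$fraction[1, 2], 0.7)
  expect_false(cm$contact[1, 2])
  expect_true(contact_map(contact_scene(c(rep(5, 7), rep(8, 3))),
                          persistence = 0.7)$contact[1, 2])
})

test_that("contact maps are symmetric and monotone in their thresholds", {
  g <- gen_gaussian_traj(n_res = 8, n_frames = 20, sigma = 0.8, seed = 19)
  cm1 <- contact_map(g$trajectory, cutoff = 5)
  cm2 <- contact_map(g$trajectory, cutoff = 7)
  expect_identical(cm1$contact, t(cm1$contact))
  expect_equal(cm1$fraction, t(cm1$fraction))
  expect_true(all(cm2$contact[cm1$contact]))        # raising R_c keeps contacts
  cm3 <- contact_map(g$trajectory, cutoff = 5, persistence = 0.9)
  expect_true(all(cm1$contact[cm3$contact]))        # raising persistence never adds
  expect_false(any(diag(cm1$contact)))
})
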