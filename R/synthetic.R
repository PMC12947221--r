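#' Ideal helical C-alpha trace
#'
#' A toy alpha-helix C-alpha backbone: radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees of twist, used as the mean structure of synthetic
#' ensembles.
#'
#' @param n_res number of residues.
#' @return n_res x 3 coordinate matrix (Angstrom).
#' @export
helix_calpha_trace <- function(n_res) {
  i <- seq_len(n_res) - 1L
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

## atom table for a C-alpha-only chain
.calpha_atoms <- function(n_res, res_names = "ALA") {
  res_names <- rep_len(res_names, n_res)
  data.frame(serial = seq_len(n_res), name = "CA", element = "C",
             res_name = res_names, res_id = seq_len(n_res), chain = "A",
             stringsAsFactors = FALSE)
}

#' Generate a Gaussian synthetic C-alpha trajectory with planted structure
#'
#' Frames are drawn about a mean structure with independent isotropic
#' jitter per residue, optionally with (i) correlated blocks: for each
#' block, every member residue moves along a shared random unit axis with
#' scalar amplitudes of pairwise correlation `rho` (the construction
#' `a_i = sqrt(rho) z_common + sqrt(1 - rho) z_i` makes the axis-projection
#' correlation exactly `rho`), with the remaining jitter confined to the
#' perpendicular plane so the projection is undiluted; and (ii) planted
#' collective modes: fixed 3N displacement patterns with Gaussian
#' amplitudes, for principal-component recovery checks.
#'
#' @param n_res residues (C-alpha only atom table).
#' @param n_frames frames to draw.
#' @param sigma per-coordinate jitter SD in Angstrom (recycled per
#'   residue; default 0.5).
#' @param blocks list of `list(residues=, rho=, sigma_axis=)` planted
#'   correlation blocks (`sigma_axis` defaults to the residue's `sigma`).
#' @param modes list of `list(vector=, sd=)` planted collective modes;
#'   `vector` is a 3N displacement pattern (normalized internally).
#' @param mean_structure n_res x 3 matrix (default [helix_calpha_trace()]).
#' @param res_names residue names for the atom table (recycled).
#' @param frame_spacing ns per frame.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `trajectory` (a [trajectory()]) and `ground_truth`
#'   (per-block axis vectors and exact projection correlation, normalized
#'   mode vectors, sigma table).
#' @export
gen_gaussian_traj <- function(n_res, n_frames, sigma = 0.5, blocks = list(),
                              modes = list(), mean_structure = NULL,
                              res_names = "ALA", frame_spacing = 0.04,
                              seed = 1L) {
  sigma <- rep_len(sigma, n_res)
  blocks <- lapply(blocks, function(b) {
    b$residues <- as.integer(unlist(b$residues))  # YAML lists arrive nested
    b
  })
  for (b in blocks) {
    if (is.null(b$residues) || is.null(b$rho))
      stop("generator error: block needs residues and rho")
    if (b$rho <= -1 || b$rho >= 1)
      stop("generator error: rho must be in (-1, 1)")
    if (any(b$residues < 1L | b$residues > n_res))
      stop("generator error: block residues out of range")
  }
  if (is.null(mean_structure)) mean_structure <- helix_calpha_trace(n_res)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  mu <- .flatten_coords(mean_structure)
  xyz <- matrix(mu, n_frames, 3L * n_res, byrow = TRUE)
  in_block <- logical(n_res)
  gt_blocks <- list()
  for (b in blocks) {
    axis <- stats::rnorm(3L); axis <- axis / sqrt(sum(axis^2))
    z_common <- stats::rnorm(n_frames)
    s_axis <- b$sigma_axis %||% sigma[b$residues[1L]]
    for (r in b$residues) {
      a <- s_axis * (sqrt(b$rho) * z_common +
                     sqrt(1 - b$rho) * stats::rnorm(n_frames))
      perp <- matrix(stats::rnorm(3L * n_frames, sd = sigma[r]),
                     n_frames, 3L)
      perp <- perp - outer(as.vector(perp %*% axis), axis)
      disp <- outer(a, axis) + perp
      cols <- (3L * r - 2L):(3L * r)
      xyz[, cols] <- xyz[, cols] + disp
      in_block[r] <- TRUE
    }
    gt_blocks[[length(gt_blocks) + 1L]] <-
      list(residues = b$residues, rho = b$rho, axis = axis,
           sigma_axis = s_axis)
  }
  free <- which(!in_block)
  if (length(free) > 0L) {
    for (r in free) {
      cols <- (3L * r - 2L):(3L * r)
      xyz[, cols] <- xyz[, cols] +
        matrix(stats::rnorm(3L * n_frames, sd = sigma[r]), n_frames, 3L)
    }
  }
  gt_modes <- list()
  if (length(modes) > 0L) {
    ## planted modes are internal motions: project out the 6 rigid-body
    ## patterns (translations, infinitesimal rotations about the centroid)
    ## so superposition-based analyses see the planted vector unchanged
    ctr <- sweep(mean_structure, 2L, colMeans(mean_structure))
    rigid <- cbind(
      rep(c(1, 0, 0), n_res), rep(c(0, 1, 0), n_res), rep(c(0, 0, 1), n_res),
      .flatten_coords(cbind(0, -ctr[, 3L], ctr[, 2L])),
      .flatten_coords(cbind(ctr[, 3L], 0, -ctr[, 1L])),
      .flatten_coords(cbind(-ctr[, 2L], ctr[, 1L], 0)))
    rigid <- qr.Q(qr(rigid))
    for (md in modes) {
      v <- md$vector - rigid %*% crossprod(rigid, md$vector)
      v <- as.vector(v) / sqrt(sum(v^2))
      amp <- stats::rnorm(n_frames, sd = md$sd)
      xyz <- xyz + outer(amp, v)
      gt_modes[[length(gt_modes) + 1L]] <- list(vector = v, sd = md$sd)
    }
  }
  traj <- trajectory(.calpha_atoms(n_res, res_names), xyz,
                     frame_spacing = frame_spacing)
  list(trajectory = traj,
       ground_truth = list(blocks = gt_blocks, modes = gt_modes,
                           sigma = sigma, mean = mean_structure))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Exact mutual information of a joint probability table
#'
#' `MI = sum_kl p_kl log2( p_kl / (p_k. p_.l) )`, the analytic MI of a
#' categorical joint distribution.
#'
#' @param joint matrix of joint probabilities (non-negative, sums to 1).
#' @return MI in bits.
#' @export
table_mi <- function(joint) {
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-8)
    stop("generator error: joint table must be non-negative and sum to 1")
  pi_ <- rowSums(joint); pj <- colSums(joint)
  occ <- which(joint > 0, arr.ind = TRUE)
  sum(joint[occ] * log2(joint[occ] / (pi_[occ[, 1L]] * pj[occ[, 2L]])))
}

#' Draw paired rotamer-state series from a planted joint table
#'
#' i.i.d. per-frame draws of a categorical state pair from `joint`; the
#' exact MI of the table ([table_mi()]) is returned as ground truth so
#' estimator tests never re-derive their target.
#'
#' @param joint joint probability matrix (states_i x states_j).
#' @param n_frames number of draws.
#' @param seed integer seed.
#' @return list with `states_i`, `states_j` (integer vectors),
#'   `mi_exact` (bits), `joint`.
#' @export
gen_rotamer_series <- function(joint, n_frames, seed = 1L) {
  mi_exact <- table_mi(joint)  # validates the table
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  cell <- sample.int(length(joint), n_frames, replace = TRUE,
                     prob = as.vector(joint))
  ni <- nrow(joint)
  list(states_i = ((cell - 1L) %% ni) + 1L,
       states_j = ((cell - 1L) %/% ni) + 1L,
       mi_exact = mi_exact, joint = joint)
}

#' Generate a toy trajectory with scheduled hydrogen bonds
#'
#' Builds a small explicit-hydrogen scene: for each scheduled triple, a
#' donor residue (backbone N-H) and an acceptor residue (carbonyl O) are
#' placed in an isolated spatial cluster.  In frames drawn "on" (Bernoulli
#' at the target occupancy), the acceptor O sits collinear with N-H at
#' `on_dist` from H (satisfying both criteria with margin); in "off"
#' frames it is retracted to `off_dist` so exactly the distance criterion
#' fails.  A lysine-like donor with three hydrogens is available via
#' `multi_h`.
#'
#' @param triples list of `list(occupancy=)` scheduled bonds, one cluster
#'   each.
#' @param n_frames frames to generate.
#' @param on_dist H--acceptor distance in bonded frames (default 2.0 A).
#' @param off_dist H--acceptor distance in non-bonded frames (default
#'   3.5 A).
#' @param multi_h add a lysine-like ammonium donor (three H on one N) to
#'   the first cluster's acceptor.
#' @param seed integer seed.
#' @return list with `trajectory` and `ground_truth` (per-triple scheduled
#'   occupancy and realized on-frame indices).
#' @export
gen_hbond_scene <- function(triples, n_frames, on_dist = 2.0,
                            off_dist = 3.5, multi_h = FALSE, seed = 1L) {
  if (on_dist > 2.4)
    stop("generator error: on_dist must satisfy the 2.5 A criterion with >= 0.1 A margin")
  if (off_dist < 2.6)
    stop("generator error: off_dist must violate the 2.5 A criterion with >= 0.1 A margin")
  for (tp in triples)
    if (tp$occupancy < 0 || tp$occupancy > 1)
      stop("generator error: occupancy must be in [0, 1]")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  atoms <- list(); base <- list()
  serial <- 0L; res_id <- 0L
  add_atom <- function(name, element, res_name, rid, pos) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(serial = serial, name = name,
                                   element = element, res_name = res_name,
                                   res_id = rid, chain = "A",
                                   stringsAsFactors = FALSE)
    base[[serial]] <<- pos
    serial
  }
  sched <- list()
  for (k in seq_along(triples)) {
    off <- c(50 * (k - 1L), 0, 0)
    ## donor residue: N-H along +x, with CA to give the residue bulk
    res_id <- res_id + 1L
    n_i <- add_atom("N", "N", "ALA", res_id, off + c(0, 0, 0))
    h_i <- add_atom("H", "H", "ALA", res_id, off + c(1.0, 0, 0))
    add_atom("CA", "C", "ALA", res_id, off + c(-0.8, 1.2, 0))
    ## acceptor residue: carbonyl C=O, O on the N-H axis
    res_id <- res_id + 1L
    o_pos <- off + c(1.0 + on_dist, 0, 0)
    add_atom("C", "C", "ALA", res_id, o_pos + c(1.23, 0, 0))
    o_i <- add_atom("O", "O", "ALA", res_id, o_pos)
    sched[[k]] <- list(h = h_i, o = o_i, n = n_i,
                       occupancy = triples[[k]]$occupancy)
  }
  if (multi_h) {
    res_id <- res_id + 1L
    off <- c(-50, 0, 0)
    nz <- add_atom("NZ", "N", "LYS", res_id, off)
    for (m in 1:3) {
      ang <- 2 * pi * (m - 1) / 3
      add_atom(paste0("HZ", m), "H", "LYS", res_id,
               off + c(0.35, cos(ang), sin(ang)) /
                 sqrt(sum(c(0.35, cos(ang), sin(ang))^2)))
    }
  }
  at <- do.call(rbind, atoms)
  base_m <- do.call(rbind, base)
  xyz <- matrix(rep(.flatten_coords(base_m), n_frames), n_frames,
                byrow = TRUE)
  on_frames <- vector("list", length(sched))
  for (k in seq_along(sched)) {
    on <- stats::runif(n_frames) < sched[[k]]$occupancy
    on_frames[[k]] <- which(on)
    ## in off frames retract the acceptor O (and its C) along +x
    shift <- off_dist - on_dist
    for (ai in c(sched[[k]]$o, sched[[k]]$o - 1L)) {
      col <- 3L * ai - 2L
      xyz[!on, col] <- xyz[!on, col] + shift
    }
  }
  traj <- trajectory(at, xyz, frame_spacing = 0.04)
  list(trajectory = traj,
       ground_truth = list(
         triples = lapply(seq_along(sched), function(k)
           list(donor_res = at$res_id[sched[[k]]$n],
                acceptor_res = at$res_id[sched[[k]]$o],
                occupancy = sched[[k]]$occupancy,
                on_frames = on_frames[[k]]))))
}
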