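# Independent brute-force oracles and small fixture builders.
# Every oracle is written from the definition, independently of the
# package's implementation path.

# --- geometry ---------------------------------------------------------------

# Horn quaternion superposition: optimal RMSD between two point sets from
# the largest eigenvalue of the 4x4 quaternion matrix.
oracle_quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  p <- sweep(mobile, 2L, colMeans(mobile))
  q <- sweep(reference, 2L, colMeans(reference))
  s <- crossprod(p, q)  # S[a,b] = sum p_a q_b
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[1,3]+s[3,1],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],        -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[1,3]+s[3,1],        s[2,3]+s[3,2],        -s[1,1]-s[2,2]+s[3,3]
  ), 4L, 4L, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
           2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3L, 3L, byrow = TRUE)
}

rigid_move <- function(coords, rot = random_rotation(),
                       shift = rnorm(3, sd = 5)) {
  sweep(coords %*% rot, 2L, shift, "+")
}

rigid_move_traj <- function(traj, rot = random_rotation(),
                            shift = rnorm(3, sd = 5)) {
  xyz <- t(apply(traj$xyz, 1L, function(row) {
    co <- matrix(row, ncol = 3L, byrow = TRUE)
    as.vector(t(sweep(co %*% rot, 2L, shift, "+")))
  }))
  trajectory(traj$atoms, xyz, frame_spacing = traj$frame_spacing)
}

# --- information theory -----------------------------------------------------

# entropy in bits straight from the definition
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# literal equal-width binning over the series range
oracle_bin <- function(x, nb) {
  rng <- range(x)
  w <- diff(rng) / nb
  b <- floor((x - rng[1]) / w) + 1
  pmin(pmax(b, 1), nb)
}

# literal scan: smallest N with (H(N+1) - H(N)) / H(N) <= tol, capped
oracle_optimal_bins <- function(x, tol = 0.02, cap = floor(sqrt(length(x)))) {
  h <- function(nb) oracle_entropy(tabulate(oracle_bin(x, nb), nbins = nb))
  for (nb in 2:(cap - 1)) {
    if (h(nb) > 0 && (h(nb + 1) - h(nb)) / h(nb) <= tol) return(nb)
  }
  cap
}

# corrected MI by naive nested loops over the joint histogram
oracle_mi <- function(di, dj, ni = max(di), nj = max(dj)) {
  n <- length(di)
  joint <- matrix(0, ni, nj)
  for (t in seq_len(n)) joint[di[t], dj[t]] <- joint[di[t], dj[t]] + 1
  pi_ <- rowSums(joint) / n
  pj <- colSums(joint) / n
  mi <- 0
  for (a in seq_len(ni)) for (b in seq_len(nj)) {
    if (joint[a, b] > 0)
      mi <- mi + (joint[a, b] / n) * log2((joint[a, b] / n) / (pi_[a] * pj[b]))
  }
  nb_ij <- sum(joint > 0); nb_i <- sum(pi_ > 0); nb_j <- sum(pj > 0)
  corr <- (nb_ij - nb_i - nb_j + 1) / (2 * n)
  list(mi_observed = mi, corrected = mi - corr, floored = max(0, mi - corr))
}

# --- graphs -----------------------------------------------------------------

# betweenness by exhaustive enumeration of all shortest paths (simple
# paths of minimal hop count), per unordered pair
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    found <- list()
    recurse <- function(path) {
      last <- path[length(path)]
      if (last == t) { found[[length(found) + 1L]] <<- path; return() }
      for (v in which(adj[last, ] > 0))
        if (!v %in% path) recurse(c(path, v))
    }
    recurse(s)
    found
  }
  cb <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      through <- sum(vapply(shortest, function(p) i %in% p, logical(1)))
      cb[i] <- cb[i] + through / sigma
    }
  }
  cb
}

# --- fixture builders -------------------------------------------------------

# C-alpha-only trajectory from an explicit frames x atoms x 3 array
toy_traj <- function(coords_list, res_names = "ALA", frame_spacing = 0.04) {
  n_res <- nrow(coords_list[[1L]])
  at <- data.frame(serial = seq_len(n_res), name = "CA", element = "C",
                   res_name = rep_len(res_names, n_res),
                   res_id = seq_len(n_res), chain = "A",
                   stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(coords_list, function(m) as.vector(t(m))))
  trajectory(at, xyz, frame_spacing = frame_spacing)
}

# write PDB lines for hand-built parser fixtures
pdb_atom_line <- function(serial, name, res_name, chain, res_id, xyz,
                          element = "", altloc = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, altloc, res_name, chain, res_id,
          xyz[1], xyz[2], xyz[3], element)
}
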