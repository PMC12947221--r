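# wrap an explicit adjacency into a ResidueGraph via build_graph
graph_from_adj <- function(adj) {
  n <- nrow(adj)
  res <- data.frame(chain = "A", res_id = seq_len(n) * 10L,  # sep always > 6
                    res_name = "ALA", stringsAsFactors = FALSE)
  mi <- structure(list(matrix = ifelse(adj > 0, 1, 0), residues = res,
                       mode = "calpha", n_c = 1L, min_sep = 6L),
                  class = "MIMatrix")
  dm <- structure(list(matrix = matrix(100, n, n), residues = res),
                  class = "DistanceMatrix")
  build_graph(mi, dm, network_config(mi_threshold = 0.5))
}

test_that("distance matrices match hand-computed and per-frame oracles", {
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 12, 0))
  tr <- toy_traj(list(base))
  dm <- distance_matrix(tr)
  expect_equal(dm$matrix[1, 2], 5)
  expect_equal(dm$matrix[2, 3], 12)
  expect_equal(dm$matrix[1, 3], 13)
  expect_equal(dm$matrix, t(dm$matrix))
  expect_true(all(diag(dm$matrix) == 0))

  set.seed(211)
  frames <- lapply(1:6, function(t) base + matrix(rnorm(9, sd = 0.5), 3, 3))
  tr2 <- toy_traj(frames)
  dm2 <- distance_matrix(tr2)
  oracle <- mean(vapply(frames, function(m)
    sqrt(sum((m[1, ] - m[2, ])^2)), numeric(1)))
  expect_equal(dm2$matrix[1, 2], oracle, tolerance = 1e-10)
  dmin <- distance_matrix(tr2, reduce = "min")
  expect_equal(dmin$matrix[1, 2],
               min(vapply(frames, function(m)
                 sqrt(sum((m[1, ] - m[2, ])^2)), numeric(1))),
               tolerance = 1e-10)
})

test_that("edges require all three conditions of the long-range rule", {
  res <- data.frame(chain = "A", res_id = c(1L, 8L, 20L),
                    res_name = "ALA", stringsAsFactors = FALSE)
  mk <- function(mi_12, d_12) {
    m <- matrix(0.3, 3, 3); diag(m) <- NA
    m[1, 2] <- m[2, 1] <- mi_12
    d <- matrix(10, 3, 3); diag(d) <- 0
    d[1, 2] <- d[2, 1] <- d_12
    mi <- structure(list(matrix = m, residues = res, mode = "calpha",
                         n_c = 1L, min_sep = 6L), class = "MIMatrix")
    dm <- structure(list(matrix = d, residues = res),
                    class = "DistanceMatrix")
    build_graph(mi, dm, network_config())
  }
  has_edge <- function(g, a, b)
    any((g$edges$res_i == a & g$edges$res_j == b) |
        (g$edges$res_i == b & g$edges$res_j == a))
  expect_true(has_edge(mk(0.3, 10), "A1", "A8"))     # all conditions met
  expect_false(has_edge(mk(0.3, 4), "A1", "A8"))     # too close in space
  expect_false(has_edge(mk(0.2, 10), "A1", "A8"))    # MI below threshold
  ## residues 1 and 8: separation 7 > 6; with min_sep 8 the edge vanishes
  g <- mk(0.3, 10)
  expect_true(has_edge(g, "A1", "A8"))
  m_all <- matrix(0.3, 3, 3); diag(m_all) <- NA
  g2 <- build_graph(
    structure(list(matrix = m_all,
                   residues = res, mode = "calpha", n_c = 1L,
                   min_sep = 6L), class = "MIMatrix"),
    structure(list(matrix = matrix(10, 3, 3), residues = res),
              class = "DistanceMatrix"),
    network_config(min_sep = 8L))   # 1-8 separation 7: no longer distant
  expect_false(has_edge(g2, "A1", "A8"))
})

test_that("an empty edge set is a valid graph with a warning", {
  res <- data.frame(chain = "A", res_id = c(1L, 2L), res_name = "ALA",
                    stringsAsFactors = FALSE)
  mi <- structure(list(matrix = matrix(0.9, 2, 2), residues = res,
                       mode = "calpha", n_c = 1L, min_sep = 6L),
                  class = "MIMatrix")
  dm <- structure(list(matrix = matrix(10, 2, 2), residues = res),
                  class = "DistanceMatrix")
  expect_warning(g <- build_graph(mi, dm), "empty edge set")
  expect_equal(nrow(g$edges), 0L)
  cd <- degree_centrality(g)
  expect_equal(cd$degree_centrality, c(0, 0))
  expect_equal(betweenness_centrality(g)$betweenness, c(0, 0))
})

test_that("edge weights are MI normalized to a unit maximum", {
  set.seed(223)
  n <- 8
  res <- data.frame(chain = "A", res_id = seq_len(n) * 10L,
                    res_name = "ALA", stringsAsFactors = FALSE)
  m <- matrix(runif(n * n, 0.3, 0.9), n, n); m[] <- (m + t(m)) / 2
  diag(m) <- NA
  mi <- structure(list(matrix = m, residues = res, mode = "calpha",
                       n_c = 1L, min_sep = 6L), class = "MIMatrix")
  dm <- structure(list(matrix = matrix(50, n, n), residues = res),
                  class = "DistanceMatrix")
  g <- build_graph(mi, dm, network_config(mi_threshold = 0.25))
  expect_equal(max(g$edges$weight), 1)
  expect_equal(g$edges$weight, g$edges$mi / max(g$edges$mi))
  ## raising tau_mi never adds edges
  g2 <- build_graph(mi, dm, network_config(mi_threshold = 0.6))
  expect_true(all(paste(g2$edges$res_i, g2$edges$res_j) %in%
                    paste(g$edges$res_i, g$edges$res_j)))
  ## degree sum = 2 |E|
  expect_equal(sum(degree_centrality(g)$degree), 2L * nrow(g$edges))
})

test_that("degree centrality matches the definition on canonical graphs", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  g <- graph_from_adj(star)
  cd <- degree_centrality(g)
  expect_equal(cd$degree_centrality[1], 1.0)
  expect_equal(cd$degree_centrality[2:5], rep(0.25, 4))

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  cdi <- degree_centrality(graph_from_adj(iso))
  expect_equal(cdi$degree_centrality[3], 0)

  set.seed(227)
  adj <- matrix(0, 12, 12)
  for (i in 1:11) for (j in (i + 1):12)
    if (runif(1) < 0.3) adj[i, j] <- adj[j, i] <- 1
  cdr <- degree_centrality(graph_from_adj(adj))
  expect_equal(cdr$degree_centrality, rowSums(adj) / 11)
})

test_that("betweenness centrality matches canonical values and enumeration", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  cb <- betweenness_centrality(graph_from_adj(path3))
  expect_equal(cb$betweenness, c(0, 1, 0))

  complete5 <- matrix(1, 5, 5); diag(complete5) <- 0
  cbk <- betweenness_centrality(graph_from_adj(complete5))
  expect_equal(cbk$betweenness, rep(0, 5))

  set.seed(229)
  for (k in 1:3) {
    n <- 10
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.25) adj[i, j] <- adj[j, i] <- 1
    cbr <- betweenness_centrality(graph_from_adj(adj))
    expect_equal(cbr$betweenness, oracle_betweenness(adj),
                 tolerance = 1e-10)
  }
})

test_that("graphs are bit-reproducible from identical inputs", {
  set.seed(233)
  g <- gen_gaussian_traj(n_res = 10, n_frames = 100,
                         blocks = list(list(residues = 2:4, rho = 0.8)),
                         seed = 239)
  mim <- mi_matrix_calpha(g$trajectory)
  dm <- distance_matrix(g$trajectory)
  cfg <- network_config(mi_threshold = 0.02)
  g1 <- build_graph(mim, dm, cfg)
  g2 <- build_graph(mim, dm, cfg)
  expect_identical(g1$edges, g2$edges)
})
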