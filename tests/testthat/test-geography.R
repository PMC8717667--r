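test_that("edge-list graphs carry symmetric adjacency and neighbor counts", {
  g <- path_graph()
  expect_identical(unname(g$n_neighbors), c(1L, 2L, 1L))
  A <- adjacency_matrix(g)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_identical(rowSums(A), colSums(A))
  expect_error(build_adjacency_graph(data.frame(a = c("A", "A"),
                                                b = c("B", "A"))),
               "self-edge")
  expect_error(build_adjacency_graph(data.frame(a = "A", b = "B"),
                                     region_ids = c("A", "B", "B")),
               "duplicate")
  expect_warning(build_adjacency_graph(data.frame(a = "A", b = "B"),
                                       region_ids = c("A", "B", "C")),
                 "island")
})

test_that("queen contiguity over a 2x2 polygon grid links every cell to 3", {
  g <- build_adjacency_graph(grid_polygons(2, 2))
  expect_identical(unname(g$n_neighbors), rep(3L, 4))
})

test_that("GeoJSON polygons round-trip into a graph", {
  gj <- list(type = "FeatureCollection", features = lapply(
    grid_polygons(2, 2), function(f) {
      list(type = "Feature",
           properties = list(region_id = f$id),
           geometry = list(type = "Polygon",
                           coordinates = list(apply(f$coords, 1L, as.list,
                                                    simplify = FALSE))))
    }))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  feats <- read_polygons(path)
  g <- build_adjacency_graph(feats)
  expect_identical(unname(g$n_neighbors), rep(3L, 4))
})

test_that("edge list writer/reader round-trips", {
  g <- path_graph(c("A", "B", "C", "D"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- build_adjacency_graph(read_edge_list(path))
  expect_identical(g$n_neighbors, g2$n_neighbors)
  expect_identical(g$neighbors, g2$neighbors)
})

test_that("ICAR structure matrix follows K = D - A with component rank deficiency", {
  K <- icar_structure_matrix(path_graph())
  expect_equal(unname(K$entries),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_identical(K$rank_deficiency, 1L)
  # two disconnected edges: one deficiency per component
  g2 <- build_adjacency_graph(data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_identical(icar_structure_matrix(g2)$rank_deficiency, 2L)
  # 4-cycle from the formula
  g4 <- build_adjacency_graph(data.frame(a = c("A", "B", "C", "D"),
                                         b = c("B", "C", "D", "A")))
  K4 <- icar_structure_matrix(g4)$entries
  expect_equal(unname(diag(K4)), rep(2, 4))
  expect_equal(K4["A", "B"], -1)
  expect_equal(K4["A", "C"], 0)
  expect_error(icar_structure_matrix(
    suppressWarnings(build_adjacency_graph(data.frame(a = "A", b = "B"),
                                           region_ids = c("A", "B", "C")))),
    "island")
})

test_that("RW1 structure matrix is the first-difference penalty", {
  expect_equal(unname(rw1_structure_matrix(3)$entries),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(unname(rw1_structure_matrix(2)$entries),
               rbind(c(1, -1), c(-1, 1)))
  expect_error(rw1_structure_matrix(1), "T >= 2")
})

test_that("all intrinsic structure matrices row-sum to zero and are PSD", {
  g <- generate_lattice(4, 4, 0.3, seed = 5)
  for (K in list(icar_structure_matrix(g), rw1_structure_matrix(7),
                 interaction_structure_matrix(icar_structure_matrix(g),
                                              rw1_structure_matrix(4)))) {
    expect_lt(max(abs(rowSums(K$entries))), 1e-10)
    expect_gt(min(eigen(K$entries, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
    # quadratic form of a constant vector vanishes
    one <- rep(1, nrow(K$entries))
    expect_lt(abs(drop(one %*% K$entries %*% one)), 1e-9)
  }
})

test_that("Kronecker interaction structure has product rank", {
  Ks <- icar_structure_matrix(path_graph())
  Kt <- rw1_structure_matrix(3)
  Kd <- interaction_structure_matrix(Ks, Kt)
  expect_identical(dim(Kd$entries), c(9L, 9L))
  expect_identical(num_rank(Kd$entries), 4L)       # (3-1) * (3-1)
  expect_identical(Kd$rank_deficiency, 5L)
  # identity time factor: block-diagonal replication of K_space
  I3 <- identity_structure_matrix(c("t1", "t2", "t3"))
  Kb <- interaction_structure_matrix(Ks, I3)$entries
  expect_equal(unname(Kb[1:3, 1:3]), unname(diag(3) * Ks$entries[1, 1]))
  expect_equal(unname(Kb[1:3, 4:6]), unname(diag(3) * Ks$entries[1, 2]))
  # null-space inheritance: const in space factor (x) anything
  w <- kronecker(rep(1, 3), rnorm(3))
  expect_lt(max(abs(Kd$entries %*% w)), 1e-9)
  # product-rank property on random small factors
  for (r in 1:3) {
    set.seed(r)
    g <- generate_lattice(2, 2 + r, 0.3, seed = r)
    Ks2 <- icar_structure_matrix(g)
    Kt2 <- rw1_structure_matrix(2 + r)
    Kd2 <- interaction_structure_matrix(Ks2, Kt2)
    expect_identical(num_rank(Kd2$entries),
                     num_rank(Ks2$entries) * num_rank(Kt2$entries))
  }
})

test_that("structure matrices export/import as sparse coordinate text", {
  K <- icar_structure_matrix(path_graph())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structure_matrix(K, path)
  K2 <- read_structure_matrix(path, K$labels, K$rank_deficiency)
  expect_equal(K2$entries, K$entries)
})

test_that("Moran's I matches the dense-matrix oracle and its analytic null", {
  g <- generate_lattice(4, 4, 0, seed = 1)
  W <- adjacency_matrix(g)
  # checkerboard +/-1 coloring: strong negative autocorrelation
  coords <- attr(g, "coords")
  chk <- ifelse((coords$row + coords$col) %% 2 == 0, 1, -1)
  names(chk) <- coords$region_id
  res <- morans_i_test(chk + seq_along(chk) * 1e-3, g, 199, seed = 9)
  expect_lt(res$statistic, 0)
  expect_equal(res$statistic,
               oracle_moran(chk + seq_along(chk) * 1e-3, W), tolerance = 1e-12)
  expect_equal(res$expected_null, -1 / 15)
  g96 <- generate_lattice(12, 8, 0.2, seed = 2)
  set.seed(3)
  r96 <- morans_i_test(rnorm(96), g96, 99, seed = 4)
  expect_equal(r96$expected_null, -1 / 95)
  expect_error(morans_i_test(rep(1, 96), g96, 99, seed = 1), "constant")
})

test_that("Moran permutation p-value is invariant to joint relabeling", {
  g <- generate_lattice(3, 4, 0.4, seed = 6)
  set.seed(7)
  vals <- setNames(rnorm(12), g$region_ids)
  perm <- sample(g$region_ids)
  edges <- data.frame(a = perm[match(g$edges[, 1L], g$region_ids)],
                      b = perm[match(g$edges[, 2L], g$region_ids)])
  g2 <- build_adjacency_graph(edges, region_ids = sort(perm))
  vals2 <- setNames(vals, perm[match(names(vals), g$region_ids)])
  r1 <- morans_i_test(vals, g, 999, seed = 11)
  r2 <- morans_i_test(vals2, g2, 999, seed = 11)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$expected_null, r2$expected_null)
  # p-values agree up to permutation Monte-Carlo noise
  expect_equal(r1$p_value, r2$p_value, tolerance = 0.05)
})
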