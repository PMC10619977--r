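make_series <- function(forces, pairs, residue_index = NULL, label = "X") {
  pair_force_series(forces, pairs, condition_label = label,
                    residue_index = residue_index)
}

test_that("average_pair_forces takes the arithmetic time mean", {
  pairs <- data.frame(i = c(1, 2), j = c(2, 3))
  f <- rbind(c(10, -4), c(30, -8), c(20, 0))
  avg <- average_pair_forces(make_series(f, pairs))
  expect_equal(avg$pairs$mean_force_pN, c(20, -4))
  expect_equal(avg$n_frames, 3)
  # particle pairs mapping to the same residue pair are summed first
  pairs2 <- data.frame(i = c(1, 2, 3), j = c(3, 4, 4))
  f2 <- matrix(c(1, 1, 2, 2, 5, 7), 2, 3)
  # particles 1,2 -> residue 1; 3 -> 2; 4 -> 3
  avg2 <- average_pair_forces(make_series(f2, pairs2,
                                          residue_index = c(1, 1, 2, 3)))
  # (1,3): particle pair 1-3 -> (1,2) mean 1; 2-4 -> (1,3) mean 2;
  # 3-4 -> (2,3) mean 6
  expect_equal(avg2$pairs,
               data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                          mean_force_pN = c(1, 2, 6)))
  # frame-count weighting across replicates via concatenation
  sa <- make_series(matrix(0, 1, 2), pairs)
  sb <- make_series(matrix(30, 3, 2), pairs)
  avg3 <- average_pair_forces(concat_force_series(list(sa, sb)))
  expect_equal(avg3$pairs$mean_force_pN, c(22.5, 22.5))
  # diagnostic per-replicate averages
  avg4 <- average_pair_forces(concat_force_series(list(sa, sb)),
                              per_replicate = TRUE)
  expect_equal(unname(avg4$per_replicate[[1]]), c(0, 0))
  expect_equal(unname(avg4$per_replicate[[2]]), c(30, 30))
})

test_that("difference_network thresholds |delta| and is symmetric", {
  pairs <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3))
  ma <- average_pair_forces(make_series(rbind(c(100, -50, 5)), pairs))
  mb <- average_pair_forces(make_series(rbind(c(40, -50, -40)), pairs))
  g <- difference_network(ma, mb, threshold = 45)
  expect_equal(g$edges$i, c(1, 2))
  expect_equal(g$edges$j, c(2, 3))
  expect_equal(g$edges$weight_pN, c(60, 45))          # >= is inclusive
  g_rev <- difference_network(mb, ma, threshold = 45)
  expect_equal(g_rev$edges, g$edges)                  # symmetric in arguments
  # a pair missing from one condition counts as zero mean force
  mc <- average_pair_forces(make_series(rbind(c(100, -50)), pairs[1:2, ],
                                        residue_index = 1:3))
  g2 <- difference_network(mc, mb, threshold = 40)
  expect_true(any(g2$edges$i == 2 & g2$edges$j == 3 & g2$edges$weight_pN == 40))
  # magnitude mode compares |mean| instead of signed means
  g3 <- difference_network(ma, mb, threshold = 30, mode = "magnitude")
  # (1,2): ||100|-|40|| = 60; (1,3): 0; (2,3): ||5|-|-40|| = 35
  expect_equal(g3$edges$weight_pN, c(60, 35))
  expect_error(difference_network(ma, mb, threshold = 0))
  # mismatched residue sets are rejected, naming the offenders
  md <- average_pair_forces(make_series(rbind(c(1, 1)),
                                        data.frame(i = c(1, 2), j = c(2, 4))))
  expect_error(difference_network(ma, md, 10), "4")
})

test_that("components agree with a union-find oracle on random graphs", {
  for (trial in 1:20) {
    set.seed(trial)
    n_edge <- sample(1:25, 1)
    edges <- unique(data.frame(i = sample(1:15, n_edge, replace = TRUE),
                               j = sample(16:30, n_edge, replace = TRUE)))
    edges$weight_pN <- runif(nrow(edges), 10, 100)
    g <- allokit:::force_diff_graph(edges, residues = 1:30, threshold = 10)
    oracle <- uf_components(edges)
    expect_equal(lapply(g$components, as.integer),
                 lapply(oracle, as.integer))
    # edge component labels match node membership
    for (e in seq_len(nrow(g$edges))) {
      comp <- g$components[[g$edges$component[e]]]
      expect_true(g$edges$i[e] %in% comp && g$edges$j[e] %in% comp)
    }
  }
})

test_that("filter_components enforces node and edge minimums", {
  # triangle {1,2,3}, pair {10,11}, star {20,21,22,23}
  edges <- data.frame(
    i = c(1, 2, 1, 10, 20, 20, 20),
    j = c(2, 3, 3, 11, 21, 22, 23),
    weight_pN = c(5, 5, 5, 9, 1, 1, 1))
  g <- allokit:::force_diff_graph(edges, residues = 1:23, threshold = 1)
  f3 <- filter_components(g, min_size = 3)           # default unit: residues
  expect_equal(lapply(f3$components, sort), list(c(20L, 21L, 22L, 23L),
                                                 c(1L, 2L, 3L)))
  f4 <- filter_components(g, min_size = 4)
  expect_equal(f4$components, list(c(20L, 21L, 22L, 23L)))
  # edge unit: the triangle has 3 edges, the star 3, the pair 1
  fe <- filter_components(g, min_size = 3, unit = "edges")
  expect_equal(length(fe$components), 2)
  expect_equal(nrow(fe$edges), 6)
  # brute-force oracle for the node filter
  oracle <- Filter(function(cc) length(cc) >= 3, uf_components(edges))
  expect_equal(lapply(f3$components, as.integer), lapply(oracle, as.integer))
  # empty graph passes through untouched
  g0 <- allokit:::force_diff_graph(
    data.frame(i = integer(), j = integer(), weight_pN = numeric()),
    residues = 1:5, threshold = 1)
  expect_equal(length(filter_components(g0)$components), 0)
})

test_that("largest_component breaks ties by weight then smallest id", {
  edges <- data.frame(i = c(1, 2, 10, 11), j = c(2, 3, 11, 12),
                      weight_pN = c(5, 5, 50, 50))
  g <- allokit:::force_diff_graph(edges, residues = 1:12, threshold = 1)
  win <- largest_component(g)                      # equal size: heavier wins
  expect_equal(win$components, list(c(10L, 11L, 12L)))
  edges$weight_pN <- c(5, 5, 5, 5)                 # full tie: smallest id
  g2 <- allokit:::force_diff_graph(edges, residues = 1:12, threshold = 1)
  expect_equal(largest_component(g2)$components, list(c(1L, 2L, 3L)))
  g0 <- allokit:::force_diff_graph(
    data.frame(i = integer(), j = integer(), weight_pN = numeric()),
    residues = 1:3, threshold = 1)
  expect_warning(largest_component(g0), "empty")
})

test_that("planted_edge_recovery computes precision and recall", {
  edges <- data.frame(i = c(1, 2, 5), j = c(2, 3, 6), weight_pN = 10)
  g <- allokit:::force_diff_graph(edges, residues = 1:6, threshold = 1)
  rec <- planted_edge_recovery(g, data.frame(i = c(1, 3, 4), j = c(2, 2, 5)))
  expect_equal(rec$precision, 2 / 3)               # (1,2) and (2,3) found
  expect_equal(rec$recall, 2 / 3)
  g0 <- allokit:::force_diff_graph(
    data.frame(i = integer(), j = integer(), weight_pN = numeric()),
    residues = 1:6, threshold = 1)
  rec0 <- planted_edge_recovery(g0, data.frame(i = 1, j = 2))
  expect_true(is.na(rec0$precision))
  expect_equal(rec0$recall, 0)
})

test_that("network export round-trips and annotates structures", {
  fx <- planted_fixture()
  g <- difference_network(average_pair_forces(fx$forces_a),
                          average_pair_forces(fx$forces_b), threshold = 60)
  path <- tempfile(fileext = ".tsv")
  pdb_in <- tempfile(fileext = ".pdb")
  pdb_out <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(path, pdb_in, pdb_out)))
  write_pdb_trajectory(fx$ensemble_a, pdb_in)
  export_network(g, path, pdb_in = pdb_in, pdb_out = pdb_out)
  back <- read_network(path, residues = g$residues, threshold = g$threshold)
  expect_equal(back$edges$i, g$edges$i)
  expect_equal(back$edges$j, g$edges$j)
  expect_equal(back$edges$weight_pN, g$edges$weight_pN, tolerance = 1e-8)
  expect_equal(back$components, g$components)
  # B-factor column holds component ids (0 outside any component)
  pdb <- bio3d::read.pdb(pdb_out, multi = TRUE)
  in_comp <- unlist(g$components)
  first_model <- pdb$atom[seq_len(16), ]
  expect_true(all(first_model$b[first_model$resno %in% in_comp] > 0))
  expect_true(all(first_model$b[!first_model$resno %in% in_comp] == 0))
})
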