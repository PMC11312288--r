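# Signature comparison: distance and absolute-cosine matrices against hand
# computations and brute-force oracles, panel alignment, classical MDS
# exactness, and average-linkage clustering.

test_that("signature vectors project the DE table onto the panel", {
  deg <- data.frame(gene = c("Spp1", "Itgax", "Aqp4"),
                    log2fc = c(9.06, 2.0, -1.0))
  v <- build_signature(deg, c("Spp1", "Itgax", "Aqp4"))
  expect_equal(unname(v), c(9.06, 2.0, -1.0))
  # permuting the panel permutes the vector identically
  perm <- c("Aqp4", "Spp1", "Itgax")
  expect_equal(build_signature(deg, perm), v[perm])
  expect_error(build_signature(deg, c("Spp1", "Gpnmb", "Trem2")),
               "Gpnmb, Trem2")
})

test_that("panel alignment intersects symbols case-insensitively", {
  s1 <- signature_set(matrix(1:6, 2, 3,
    dimnames = list(c("A", "B"), c("Spp1", "Itgax", "Gpnmb"))))
  s2 <- signature_set(matrix(7:12, 2, 3,
    dimnames = list(c("C", "D"), c("SPP1", "ITGAX", "Apoe"))))
  merged <- align_gene_panels(list(s1, s2))
  expect_equal(colnames(merged$values), c("Itgax", "Spp1"))
  expect_equal(rownames(merged$values), c("A", "B", "C", "D"))
  expect_equal(unname(merged$values["C", ]), c(9, 7))
  # identical collections: the merged panel is the original (sorted)
  expect_message(self <- align_gene_panels(list(s1, s1)), "make.unique")
  expect_setequal(colnames(self$values), colnames(s1$values))
  # case-folding collisions within one collection are rejected
  bad <- signature_set(matrix(1:4, 2, 2,
    dimnames = list(c("X", "Y"), c("Spp1", "SPP1"))))
  expect_error(align_gene_panels(list(bad, s2)), "case-folding")
  s3 <- signature_set(matrix(1:4, 2, 2,
    dimnames = list(c("E", "F"), c("Trem2", "Cd68"))))
  expect_error(align_gene_panels(list(s1, s3)), "no genes shared")
})

test_that("distances match Eq-style hand values and brute force", {
  sig <- signature_set(matrix(c(1, 2, 2, 0, 0, 0), 2, 3, byrow = TRUE,
                              dimnames = list(c("i", "j"), c("a", "b", "c"))))
  d <- distance_matrix(sig)
  expect_equal(d["i", "j"], 3)
  expect_equal(diag(d), c(i = 0, j = 0))
  set.seed(14)
  rsig <- random_signature_set(6, 50)
  expect_equal(distance_matrix(rsig), brute_distance(rsig$values),
               tolerance = 1e-12)
})

test_that("absolute cosine matches hand values, oracle, and invariances", {
  sig <- signature_set(matrix(c(1, 1, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                              dimnames = list(c("i", "j"), c("a", "b", "c"))))
  expect_equal(correlation_matrix(sig)["i", "j"], 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(correlation_matrix(sig)["i", "j"], 0.7071, tolerance = 1e-4)
  col <- signature_set(matrix(c(2, 4, 1, 2), 2, 2, byrow = TRUE,
                              dimnames = list(c("i", "j"), c("a", "b"))))
  expect_equal(correlation_matrix(col)["i", "j"], 1, tolerance = 1e-12)
  anti <- signature_set(matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE,
                               dimnames = list(c("i", "j"), c("a", "b"))))
  expect_equal(correlation_matrix(anti)["i", "j"], 1)   # modulus form
  expect_equal(correlation_matrix(anti, signed = TRUE)["i", "j"], -1)
  zero <- signature_set(matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE,
                               dimnames = list(c("ok", "null"), c("a", "b"))))
  expect_error(correlation_matrix(zero), "null")
  set.seed(15)
  rsig <- random_signature_set(6, 40)
  C <- correlation_matrix(rsig)
  expect_equal(C, brute_abs_cosine(rsig$values), tolerance = 1e-12)
  # scale invariance: c(alpha * i, j) = c(i, j)
  scaled <- rsig$values
  scaled[1, ] <- -3.7 * scaled[1, ]
  expect_equal(correlation_matrix(signature_set(scaled)), C,
               tolerance = 1e-12)
  # for unit vectors with non-negative cosine, d^2 = 2 (1 - cos theta)
  unit <- abs(rsig$values) / sqrt(rowSums(rsig$values^2))
  usig <- signature_set(unit)
  d <- distance_matrix(usig)
  expect_equal(d^2, 2 * (1 - correlation_matrix(usig)) * (1 - diag(6)) + 0,
               tolerance = 1e-9)
})

test_that("classical MDS embeds Euclidean configurations exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  emb <- classical_mds(d, k = 2)
  expect_equal(as.matrix(dist(emb$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lte(emb$stress, 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))
  # one dimension cannot carry a triangle: positive stress
  expect_gt(classical_mds(d, k = 1)$stress, 0.01)
  # planar points re-embed exactly at k = 2 and match cmdscale's distances
  set.seed(16)
  pts <- matrix(rnorm(14), 7, 2)
  dp <- as.matrix(dist(pts))
  dimnames(dp) <- list(paste0("p", 1:7), paste0("p", 1:7))
  emb2 <- classical_mds(dp, k = 2)
  expect_lte(emb2$stress, 1e-9)
  expect_equal(as.matrix(dist(emb2$coordinates)),
               as.matrix(dist(cmdscale(dp, k = 2))),
               tolerance = 1e-9, ignore_attr = TRUE)
  # axis signs are pinned: largest-|coordinate| entry of each axis positive
  expect_true(all(apply(emb2$coordinates, 2,
                        function(x) x[which.max(abs(x))] > 0)))
  # embed -> distances -> re-embed is idempotent to tolerance
  emb3 <- classical_mds(as.matrix(dist(emb2$coordinates)) |>
                          `dimnames<-`(dimnames(dp)), k = 2)
  expect_equal(emb3$coordinates, emb2$coordinates, tolerance = 1e-6)
  expect_error(classical_mds(dp, k = 7), "1..")
  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  embz <- classical_mds(zero, k = 1)
  expect_equal(embz$stress, 0)
  expect_equal(unname(embz$coordinates[, 1]), c(0, 0), tolerance = 1e-12)
})

test_that("average-linkage clustering matches brute force and recovers blocks", {
  d2 <- matrix(c(0, 1.5, 1.5, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$height, 1.5)
  expect_error(hierarchical_cluster(d2[1, 1, drop = FALSE]), "square|2")
  set.seed(17)
  for (r in 1:5) {
    sig <- random_signature_set(5, 8)
    d <- distance_matrix(sig)
    hc <- hierarchical_cluster(d)
    expect_equal(sort(hc$height), brute_average_linkage_heights(d),
                 tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
  # merge heights do not depend on the input row order
  sig <- random_signature_set(6, 10)
  d <- distance_matrix(sig)
  perm <- sample(rownames(d))
  expect_equal(hierarchical_cluster(d)$height,
               hierarchical_cluster(d[perm, perm])$height, tolerance = 1e-12)
  # planted two-block structure is recovered at the 2-cluster cut
  for (s in 1:3) {
    sig <- simulate_signature_collection(two_block_sim_config(s))
    cl <- cutree(hierarchical_cluster(distance_matrix(sig)), k = 2)
    expect_equal(adjusted_rand_index(cl[names(attr(sig, "blocks"))],
                                     attr(sig, "blocks")), 1)
  }
})

test_that("dendrograms export to Newick and read back with the same tips", {
  sig <- random_signature_set(5, 10)
  hc <- hierarchical_cluster(distance_matrix(sig))
  path <- tempfile(fileext = ".nwk")
  on.exit(unlink(path))
  dendrogram_newick(hc, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(sig$values))
})
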