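test_that("condition-effect profiles are exact group means", {
  conds <- rbind(tiny_conditions(c("a1", "a2", "a3"), strain = "wt"),
                 tiny_conditions(c("b1", "b2"), strain = "mut"))
  mat <- rand_matrix(6, 5, seed = 1)
  colnames(mat) <- conds$profile_id
  comp <- compendium(list(transcript = mat), conds)
  prof <- condition_effect_profiles(comp, "strain")
  expect_equal(prof[, "wt"], rowMeans(mat[, 1:3]))
  expect_equal(prof[, "mut"], rowMeans(mat[, 4:5]))
  # invariant to replicate order
  comp2 <- compendium(list(transcript = mat[, c(3, 1, 2, 5, 4)]), conds)
  expect_equal(condition_effect_profiles(comp2, "strain"), prof)
  # control filter can empty the set
  expect_error(condition_effect_profiles(comp, "strain",
                                         control_filter = function(cd)
                                           cd$medium == "nope"),
               "no profiles|fewer than 2")
})

test_that("ontology clustering merges the most correlated groups first", {
  set.seed(2)
  base <- rnorm(50)
  prof <- cbind(a = base + rnorm(50, 0, 0.05),
                b = base + rnorm(50, 0, 0.05),
                c = rnorm(50))
  hc <- build_ontology(prof)
  expect_setequal(hc$labels, c("a", "b", "c"))
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("a", "b"))
  # identical groups merge at height 0
  hc0 <- build_ontology(cbind(a = base, b = base, c = rnorm(50)))
  expect_equal(hc0$height[1], 0, tolerance = 1e-12)
  expect_error(build_ontology(cbind(a = base, b = base, c = rep(1, 50))),
               "constant group")
  expect_error(build_ontology(prof[, 1:2]), ">= 3 groups")
})

test_that("cophenetic correlation matches a hand computation on 4 leaves", {
  # tree A: ((a,b),(c,d)) with merge heights 1, 2, 4
  dA <- as.dist(matrix(c(0, 1, 4, 4,
                         1, 0, 4, 4,
                         4, 4, 0, 2,
                         4, 4, 2, 0), 4, 4,
                       dimnames = list(letters[1:4], letters[1:4])))
  # tree B: ((a,c),(b,d))
  dB <- as.dist(matrix(c(0, 6, 1, 6,
                         6, 0, 6, 3,
                         1, 6, 0, 6,
                         6, 3, 6, 0), 4, 4,
                       dimnames = list(letters[1:4], letters[1:4])))
  hcA <- hclust(dA, method = "average")
  hcB <- hclust(dB, method = "average")
  # both dist inputs are ultrametric, so the cophenetic matrices equal the
  # inputs; the aligned upper-triangle vectors are written out by hand
  vecA <- c(1, 4, 4, 4, 4, 2)   # ab, ac, ad, bc, bd, cd
  vecB <- c(6, 1, 6, 6, 3, 6)
  expected <- cor(vecA, vecB)
  expect_equal(cophenetic_correlation(hcA, hcB), expected)
  expect_equal(cophenetic_correlation(hcA, hcA), 1.0)
  expect_equal(cophenetic_correlation(hcA, hcB),
               cophenetic_correlation(hcB, hcA))
  # works across representations (hclust vs newick/phylo)
  phB <- ape::as.phylo(hcB)
  expect_equal(cophenetic_correlation(hcA, phB),
               cophenetic_correlation(hcA, hcB), tolerance = 1e-10)
  # leaf mismatch errors with the symmetric difference
  hcC <- hclust(as.dist(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                               dimnames = list(c("a", "b", "x"),
                                               c("a", "b", "x")))))
  expect_error(cophenetic_correlation(hcA, hcC), "differ")
})

toy_annotations <- function() {
  data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    namespace = c("BP", "MF", "BP", "BP", "BP", "MF", "MF"),
    term = c("t1", "t2", "t1", "t3", "t4", "t2", "t5"),
    stringsAsFactors = FALSE)
}

test_that("term coverage counts represented terms per namespace", {
  ann <- toy_annotations()
  expect_equal(go_coverage(character(0), ann), c(BP = 0, MF = 0))
  expect_equal(go_coverage(c("g1", "g2", "g3", "g4"), ann),
               c(BP = 1, MF = 1))
  # hand count: g1, g2 perturbed -> BP {t1,t3}/3, MF {t2}/2
  expect_equal(go_coverage(c("g1", "g2"), ann), c(BP = 2 / 3, MF = 1 / 2))
  expect_message(go_coverage("gX", ann), "without annotation")
  # monotone: adding a perturbation never lowers coverage
  c1 <- go_coverage("g1", ann); c2 <- go_coverage(c("g1", "g3"), ann)
  expect_true(all(c2 >= c1))
})

test_that("greedy knockout ranking matches the exhaustive oracle", {
  ann <- toy_annotations()
  got <- rank_knockouts_by_coverage_gain(ann, character(0), k = 3)
  orc <- greedy_oracle(ann, character(0), 3)
  expect_equal(got$gene, orc$gene)
  expect_equal(as.numeric(got$gain), as.numeric(orc$gain))
  expect_true(all(diff(got$gain) <= 0))      # submodular gains

  # randomized maps, greedy vs oracle, gains non-increasing
  set.seed(5)
  for (i in 1:5) {
    ann2 <- data.frame(
      gene = sample(sprintf("g%d", 1:8), 40, TRUE),
      namespace = sample(c("BP", "MF", "KEGG"), 40, TRUE),
      term = sample(sprintf("t%d", 1:15), 40, TRUE))
    cur <- sample(sprintf("g%d", 1:8), 2)
    a <- rank_knockouts_by_coverage_gain(ann2, cur, k = 4)
    b <- greedy_oracle(ann2, cur, 4)
    expect_equal(a$gene, b$gene)
    expect_equal(a$gain, b$gain)
    expect_true(all(diff(a$gain) <= 0))
  }

  # everything covered -> empty list (with a note)
  expect_message(
    empty <- rank_knockouts_by_coverage_gain(ann, c("g1", "g2", "g3", "g4"),
                                             k = 2),
    "positive coverage gain")
  expect_equal(nrow(empty), 0)
})

test_that("newick export round-trips leaf sets", {
  set.seed(6)
  prof <- matrix(rnorm(40 * 4), 40, 4,
                 dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  hc <- build_ontology(prof)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_ontology_newick(hc, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, colnames(prof))
})
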