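test_that("the pan-recurrent set keeps exactly the keys seen in two or more donors", {
  cat1 <- new_catalog(data.frame(
    donor_id = c("d1", "d2", "d1"), cancer_type = "T1", chromosome = "1",
    start = c(5L, 5L, 9L), ref = "A", alt = "T",
    consequence = "missense_variant", gene = "G1"))
  rec <- pan_recurrent_set(recurrence_counts(cat1, "PanCancer"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$start, 5L)
  # per-type tables are rejected; empty set when nothing recurs
  expect_error(pan_recurrent_set(recurrence_counts(cat1, "T1")), "PanCancer")
  solo <- new_catalog(data.frame(
    donor_id = c("d1", "d2"), cancer_type = "T1", chromosome = "1",
    start = c(1L, 2L), ref = "A", alt = "T",
    consequence = "missense_variant", gene = "G1"))
  expect_equal(nrow(pan_recurrent_set(recurrence_counts(solo))), 0L)
})

test_that("gene-donor cells count distinct donors, not calls", {
  # d1 and d2 carry recurrent m1 in G; d2 also carries recurrent m2 in G
  calls <- data.frame(
    donor_id = c("d1", "d2", "d2", "d3", "d9"),
    cancer_type = c("T", "T", "T", "T", "U"),
    chromosome = "1", start = c(1L, 1L, 2L, 2L, 7L),
    ref = "A", alt = "T", consequence = "missense_variant",
    gene = c("G", "G", "G", "G", "H"))
  cat1 <- new_catalog(calls)
  rec <- data.frame(chromosome = "1", start = c(1L, 2L), ref = "A", alt = "T")
  m <- gene_donor_matrix(cat1, rec)
  expect_equal(m["T", "G"], 3L)
  # gene recurrent only in one type still gets a column, zero elsewhere
  rec2 <- rbind(rec, data.frame(chromosome = "1", start = 7L, ref = "A",
                                alt = "T"))
  m2 <- gene_donor_matrix(cat1, rec2)
  expect_equal(m2["U", "H"], 1L)
  expect_equal(m2["T", "H"], 0L)
  expect_error(gene_donor_matrix(cat1, rec[0, ]), "no recurrent")
  # all recurrent keys lacking gene labels is an error
  nogene <- new_catalog(transform(calls, gene = ""))
  expect_error(gene_donor_matrix(nogene, rec), "gene label")
})

test_that("gene-donor matrices match a brute-force triple loop", {
  for (seed in 1:10) {
    cat1 <- random_catalog(seed, donors = 30L, types = 3L)
    rec <- pan_recurrent_set(recurrence_counts(cat1))
    if (nrow(rec) == 0L) next
    m <- gene_donor_matrix(cat1, rec)
    oracle <- brute_gene_matrix(cat1$calls,
                                paste(rec$chromosome, rec$start, rec$ref,
                                      rec$alt, sep = ":"))
    expect_equal(m[rownames(oracle), colnames(oracle)], oracle)
  }
})

test_that("cosine similarity matches closed forms and is scale-invariant", {
  m <- rbind(t1 = c(1, 2, 0), t2 = c(2, 4, 0), t3 = c(0, 0, 3))
  s <- cosine_similarity_matrix(m)
  expect_equal(s["t1", "t2"], 1)         # parallel
  expect_equal(s["t1", "t3"], 0)         # orthogonal
  m2 <- rbind(a = c(1, 1), b = c(1, 0))
  expect_equal(cosine_similarity_matrix(m2)["a", "b"], 1 / sqrt(2))
  expect_error(cosine_similarity_matrix(rbind(z = c(0, 0), y = c(1, 0))), "z")
  # invariance under positive rescaling of any row
  for (seed in 1:20) {
    set.seed(seed)
    v <- matrix(rpois(12, 3), nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
    v <- v + 1  # keep rows nonzero
    scaled <- v * c(runif(1, 0.1, 10), runif(1, 0.1, 10), runif(1, 0.1, 10))
    expect_equal(cosine_similarity_matrix(v), cosine_similarity_matrix(scaled))
  }
  # symmetry, unit diagonal, [0, 1] range
  s3 <- cosine_similarity_matrix(matrix(rpois(40, 2) + 1, nrow = 4,
                                        dimnames = list(letters[1:4], NULL)))
  expect_identical(s3, t(s3))
  expect_equal(unname(diag(s3)), rep(1, 4))
  expect_true(all(s3 >= 0 & s3 <= 1))
})

test_that("average-linkage dendrograms follow hand-executed merges", {
  # two types: single merge at distance 1 - 0.8
  s2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  hc2 <- hierarchical_dendrogram(s2)
  expect_equal(hc2$height, 0.2)
  # three types: merge {A,B} at 0.1, then with C at mean distance 0.9
  s3 <- matrix(c(1, 0.9, 0.1,
                 0.9, 1, 0.1,
                 0.1, 0.1, 1), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- hierarchical_dendrogram(s3)
  expect_equal(hc3$height, c(0.1, 0.9))
  expect_equal(sort(hc3$labels[hc3$merge[1, ] * -1]), c("A", "B"))
  expect_error(hierarchical_dendrogram(s2[1, , drop = FALSE]), "at least 2")
})

test_that("merge structure equals a naive agglomerative reference", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rpois(5 * 12, 2) + 1, nrow = 5,
                dimnames = list(paste0("t", 1:5), NULL))
    s <- cosine_similarity_matrix(m)
    hc <- hierarchical_dendrogram(s)
    d <- 1 - s
    oracle <- brute_average_cophenetic(d)
    got <- as.matrix(stats::cophenetic(hc))
    expect_equal(got[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("dendrogram leaves are a permutation of the inputs with monotone heights", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:8, 1)
    m <- matrix(rpois(n * 15, 2) + 1, nrow = n,
                dimnames = list(sprintf("type%02d", seq_len(n)), NULL))
    hc <- hierarchical_dendrogram(cosine_similarity_matrix(m))
    expect_setequal(hc$labels, rownames(m))
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("Newick serialization uses ultrametric height-halving and round-trips", {
  s3 <- matrix(c(1, 0.9, 0.1,
                 0.9, 1, 0.1,
                 0.1, 0.1, 1), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- hierarchical_dendrogram(s3)
  nwk <- to_newick(hc3)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # leaf depths: A and B sit at 0.05 below their merge, total root depth 0.45
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths[match(c("A", "B", "C"), phy$tip.label)]),
               c(0.45, 0.45, 0.45))
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(coph["A", "B"], 0.1)
  expect_equal(coph["A", "C"], 0.9)
  # two leaves merging at 0.2 serialize at half height each
  s2 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_newick(hierarchical_dendrogram(s2)), "(A:0.1,B:0.1);")
  # round trip preserves topology
  phy2 <- ape::read.tree(text = to_newick(hc3))
  expect_true(ape::all.equal.phylo(phy, phy2))
})

test_that("group-specific hotspot pools are recovered as the first bipartition", {
  cat1 <- generate_catalog(planted_panel(), seed = 5)
  cat1 <- filter_consequences(cat1)
  rec <- pan_recurrent_set(recurrence_counts(cat1))
  hc <- hierarchical_dendrogram(
    cosine_similarity_matrix(gene_donor_matrix(cat1, rec)))
  cut <- stats::cutree(hc, k = 2)
  groups <- substr(names(cut), 1, 2)
  expect_equal(length(unique(cut[groups == "GA"])), 1L)
  expect_equal(length(unique(cut[groups == "GB"])), 1L)
  expect_false(cut[groups == "GA"][1] == cut[groups == "GB"][1])
})
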