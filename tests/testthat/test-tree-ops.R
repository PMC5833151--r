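test_that("total length sums branch lengths (token-sum oracle)", {
  expect_equal(total_length(read_tree(text = "(A:1,B:2):0;")), 3)
  expect_equal(total_length(read_tree(text = "(A:0,B:0);")), 0)
  tr <- make_tree(50L, seed = 10L)
  toks <- regmatches(write_tree(tr), gregexpr(":[0-9.eE+-]+", write_tree(tr)))[[1]]
  expect_equal(total_length(tr), sum(as.numeric(sub(":", "", toks))),
               tolerance = 1e-8)
})

test_that("midpoint rooting equalizes the two deepest tips", {
  m <- midpoint_root(read_tree(text = "(A:1,B:3);"))
  expect_equal(unname(otu_depths(m)), c(2, 2))

  # idempotence up to the patristic matrix and depth profile
  t0 <- make_tree(12L, seed = 3L)
  m1 <- midpoint_root(t0)
  m2 <- midpoint_root(m1)
  expect_equal(sort(otu_depths(m1)), sort(otu_depths(m2)), tolerance = 1e-9)
  d1 <- patristic_distances(m1)
  expect_lt(max(abs(d1 - patristic_distances(m2)[rownames(d1), colnames(d1)])),
            1e-9)
  expect_error(midpoint_root(read_tree(text = "(A:0,B:0);")), "zero-length")
})

test_that("outgroup rerooting forces the outgroup basal and keeps distances", {
  t <- read_tree(text = "(A:1,(B:1,C:1):1);")
  r <- reroot_outgroup(t, "A")
  root_kids <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1L, 2]
  expect_true(which(r$tip.label == "A") %in% root_kids)
  d0 <- patristic_distances(t)
  d1 <- patristic_distances(r)
  expect_lt(max(abs(d0 - d1[rownames(d0), colnames(d0)])), 1e-9)

  r2 <- reroot_outgroup(r, "A")   # idempotent up to isomorphism
  expect_lt(max(abs(patristic_distances(r2)[rownames(d0), colnames(d0)] - d0)),
            1e-9)
  expect_equal(sort(otu_depths(r)), sort(otu_depths(r2)), tolerance = 1e-9)
  expect_error(reroot_outgroup(t, "Z"), "unknown OTU")
})

test_that("OTU deletion splices unifurcations and keeps distances", {
  t <- read_tree(text = "((A:1,B:1):1,C:2);")
  d <- delete_otus(t, "C")
  expect_setequal(d$tip.label, c("A", "B"))
  expect_equal(unname(patristic_distances(d)["A", "B"]), 2)

  t2 <- make_tree(20L, seed = 4L)
  drop <- c("L3", "L7")
  kept <- setdiff(t2$tip.label, drop)
  before <- patristic_distances(t2)[kept, kept]
  after <- patristic_distances(delete_otus(t2, drop))[kept, kept]
  expect_lt(max(abs(before - after)), 1e-9)
  expect_error(delete_otus(t2, "nope"), "unknown OTU")
  expect_error(delete_otus(t, c("A", "B")), "fewer than 2")
})

test_that("subtree extraction spans OTUs or lifts a named clade", {
  t <- read_tree(text = "((A:1,B:2)node1:1,(C:1,D:1)node2:2);")
  s <- subset_tree(t, c("A", "B"))
  expect_setequal(s$tip.label, c("A", "B"))
  expect_equal(total_length(s), 3)   # path lengths to the LCA survive

  clade <- subset_tree(t, "node2")
  expect_setequal(clade$tip.label, c("C", "D"))

  t2 <- make_tree(15L, seed = 5L)
  keep <- c("L2", "L5", "L9", "L11")
  sub <- subset_tree(t2, keep)
  expect_lt(max(abs(patristic_distances(t2)[keep, keep] -
                    patristic_distances(sub)[keep, keep])), 1e-9)
  expect_error(subset_tree(t, "ghost"), "unknown OTU")
})

test_that("low-support collapsing contracts edges below threshold", {
  t <- read_tree(text = "(((A:1,B:1)40:1,C:1)90:1,D:3);")
  same <- collapse_low_support(t, 30)
  expect_equal(sort(same$tip.label), sort(t$tip.label))
  expect_true("40" %in% same$node.label)

  collapsed <- collapse_low_support(t, 60)
  expect_false("40" %in% collapsed$node.label)
  expect_true("90" %in% collapsed$node.label)   # surviving labels retained
  # depths preserved by absorbing the contracted edge length
  expect_equal(otu_depths(collapsed)[t$tip.label], otu_depths(t)[t$tip.label])

  star <- collapse_low_support(t, 1000)
  expect_equal(length(star$edge.length), ape::Ntip(star))  # star over leaves

  # postcondition scan on random labeled trees
  for (seed in 1:10) {
    tr <- make_tree(15L, support_range = c(0, 100), seed = seed)
    out <- collapse_low_support(tr, 50)
    expect_setequal(out$tip.label, tr$tip.label)
    sup <- suppressWarnings(as.numeric(out$node.label))
    expect_false(any(sup[-1] < 50, na.rm = TRUE))   # root label exempt
    expect_equal(otu_depths(out)[tr$tip.label], otu_depths(tr)[tr$tip.label],
                 tolerance = 1e-9)
  }
  expect_error(collapse_low_support(t, "high"), "numeric")
  expect_warning(collapse_low_support(read_tree(text = "((A:1,B:1):1,C:1);"),
                                      50), "unlabeled")
})

test_that("patristic distances match the LCA-depth oracle", {
  t <- read_tree(text = "(A:1,B:2);")
  expect_equal(unname(patristic_distances(t)["A", "B"]), 3)
  for (seed in 1:5) {
    tr <- make_tree(10L, seed = seed)
    m <- patristic_distances(tr)
    expect_true(all(diag(m) == 0))
    expect_equal(m, t(m))
    o <- oracle_patristic(tr)
    expect_lt(max(abs(m - o[rownames(m), colnames(m)])), 1e-9)
  }
})

test_that("OTU depths are root-to-leaf path sums", {
  t <- read_tree(text = "(A:1,B:2):0;")
  expect_equal(otu_depths(t), c(A = 1, B = 2))
  tr <- make_tree(20L, seed = 6L)
  m <- midpoint_root(tr)
  expect_equal(max(otu_depths(m)), max(patristic_distances(m)) / 2,
               tolerance = 1e-9)
})

test_that("ASCII preview is deterministic and shows every leaf once", {
  t <- read_tree(text = "((A:1,B:1)90:1,C:2);")
  art <- ascii_tree(t)
  expect_gte(length(art), 3L)
  for (leaf in t$tip.label) {
    expect_equal(sum(grepl(paste0("\\b", leaf, "\\b"), art)), 1L)
  }
  expect_identical(art, ascii_tree(t))
  art2 <- ascii_tree(make_tree(2L, seed = 1L))
  expect_equal(sum(grepl("L1|L2", art2)), 2L)
})

test_that("every tree operation emits re-readable Newick", {
  tr <- make_tree(12L, seed = 7L)
  outs <- list(midpoint_root(tr), reroot_outgroup(tr, "L4"),
               delete_otus(tr, "L1"), subset_tree(tr, c("L2", "L5", "L8")),
               collapse_low_support(tr, 75))
  for (o in outs) {
    back <- read_tree(text = write_tree(o))
    expect_s3_class(back, "phylo")
    expect_setequal(back$tip.label, o$tip.label)
  }
})
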