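test_that("column filtering implements the three deletion policies", {
  recs <- c(a = "MKVLSTRYEW", b = "MKVLSTRYEW", c = "MK-LSTRYEW",
            d = "MKVLSTRYEW")
  fam <- make_family(recs, rep("X", 4))
  # one column is 25% gapped; partial at 0.95 drops it, at 0.7 keeps it
  expect_equal(filter_columns(fam, deletion_policy("partial", 0.95))$ncols, 9L)
  expect_equal(filter_columns(fam, deletion_policy("partial", 0.70))$ncols, 10L)
  expect_equal(filter_columns(fam, deletion_policy("complete"))$ncols, 9L)
  expect_identical(filter_columns(fam, deletion_policy("pairwise")), fam)
  gapless <- make_family(c(a = "MKV", b = "MKV", c = "MKL"), rep("X", 3))
  for (m in c("complete", "partial", "pairwise"))
    expect_equal(filter_columns(gapless, deletion_policy(m))$records,
                 gapless$records)
  allgap <- make_family(c(a = "M-V", b = "-K-", c = "M-L"), rep("X", 3))
  expect_error(filter_columns(allgap, deletion_policy("complete")), "all")
})

test_that("Poisson correction matches its closed form and a recount oracle", {
  expect_equal(poisson_distance("MKVL", "MKVL"), 0)
  expect_equal(poisson_distance("AAAA", "AAGG"), -log(1 - 0.5))  # p = 0.5
  expect_equal(poisson_distance("AAAAAAAA", "AAAAAAGG"), -log(0.75))
  # gap columns excluded from the comparison
  expect_equal(poisson_distance("MK-L", "MKV-"), 0)
  expect_error(poisson_distance("--", "AA"), "comparable")
  expect_error(poisson_distance("AAAA", "GGGG"), "saturated")
  expect_warning(d <- poisson_distance("AAAA", "GGGG", saturation = "cap"))
  expect_equal(d, log(4))
  # brute-force recount on random gapped pairs
  set.seed(5)
  for (k in 1:20) {
    n <- 40
    a <- strsplit(random_protein(n), "")[[1]]
    b <- a
    b[sample(n, 8)] <- sample(AAset, 8, replace = TRUE)
    a[sample(n, 3)] <- "-"
    both <- a != "-" & b != "-"
    p <- sum(a[both] != b[both]) / sum(both)
    if (p >= 1) next
    expect_equal(poisson_distance(paste(a, collapse = ""),
                                  paste(b, collapse = "")),
                 -log(1 - p), tolerance = 1e-12)
  }
  # Jensen-type bound: d >= p, equality iff p = 0
  expect_gt(poisson_distance("AAAA", "AAAG"), 0.25)
})

test_that("distance matrices are symmetric and match per-pair recomputation", {
  fam <- make_family(c(a = "MKVL", b = "MKVL", c = "MKVL"), rep("X", 3))
  D <- distance_matrix(fam)
  expect_equal(unname(D), matrix(0, 3, 3))
  sim <- simulate_family(random_family_spec(n_per_clade = 3, ncols = 120,
                                            n_planted = 0, seed = 21))
  D2 <- distance_matrix(sim$family, deletion_policy("pairwise"))
  expect_equal(D2, t(D2))
  expect_equal(diag(D2), stats::setNames(rep(0, 6), rownames(D2)))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D2[i, j],
                 poisson_distance(sim$family$records[[i]],
                                  sim$family$records[[j]]))
  }
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  v <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(v[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(v[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(v[["c"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ is consistent on additive matrices and matches ape", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  # 4-taxon additive matrix from a hand-built quartet: ((a,b),(c,d))
  tr4 <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.25):0.05);")
  D4 <- stats::cophenetic(tr4)
  nj4 <- neighbor_joining(D4)
  expect_equal(rf_distance(nj4, ape::unroot(tr4)), 0)
  expect_equal(phangorn::RF.dist(nj4, ape::unroot(tr4)), 0)
  # recovered path lengths reproduce the additive matrix
  expect_equal(stats::cophenetic(nj4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-6)
  # random 8-taxon additive matrices: exact topology recovery, and
  # agreement with ape's independent NJ implementation
  for (k in 1:25) {
    ad <- random_additive_matrix(8)
    ours <- neighbor_joining(ad$D)
    expect_equal(rf_distance(ours, ad$tree), 0)
    expect_equal(phangorn::RF.dist(ours, ad$tree), 0)
    expect_equal(phangorn::RF.dist(ours, ape::nj(ad$D)), 0)
    expect_equal(stats::cophenetic(ours)[rownames(ad$D), colnames(ad$D)],
                 ad$D, tolerance = 1e-6)
  }
})

test_that("newick round trip preserves topology, lengths and supports", {
  sim <- simulate_family(random_family_spec(n_per_clade = 4, ncols = 200,
                                            n_planted = 0, seed = 8))
  tr <- bootstrap_support(sim$family, n_reps = 20, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(rf_distance(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
})

test_that("bootstrap supports behave as frequencies of recovered splits", {
  # two well-separated clades -> full support
  sim <- simulate_family(random_family_spec(n_per_clade = 4, ncols = 300,
                                            depth = 0.5, n_planted = 0,
                                            seed = 13))
  tr <- bootstrap_support(sim$family, n_reps = 100, seed = 99)
  sup <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(sup >= 0 & sup <= 1))
  # the clade split itself is strongly supported
  split_support <- function(tree, ids) {
    ntip <- length(tree$tip.label)
    for (nd in (ntip + 1):(ntip + tree$Nnode)) {
      below <- tree$tip.label[sdpfinder:::descendant_tips(tree, nd)]
      if (setequal(below, ids) || setequal(below, setdiff(tree$tip.label, ids)))
        return(as.numeric(tree$node.label[nd - ntip]))
    }
    NA_real_
  }
  m_ids <- grep("^m", tr$tip.label, value = TRUE)
  expect_gte(split_support(tr, m_ids), 0.95)
  # n_reps = 1: supports are 0 or 1
  tr1 <- bootstrap_support(sim$family, n_reps = 1, seed = 5)
  s1 <- as.numeric(tr1$node.label[nzchar(tr1$node.label)])
  expect_true(all(s1 %in% c(0, 1)))
  # determinism
  tr2 <- bootstrap_support(sim$family, n_reps = 25, seed = 7)
  tr3 <- bootstrap_support(sim$family, n_reps = 25, seed = 7)
  expect_identical(tr2$node.label, tr3$node.label)
})

test_that("monophyly queries enumerate bipartitions correctly", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d", "e")))
  expect_true(is_monophyletic(tr, "c"))
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("d", "e")))
  expect_true(is_monophyletic(tr, c("c", "d", "e")))
  expect_false(is_monophyletic(tr, c("a", "c")))
  expect_false(is_monophyletic(tr, c("b", "d", "e")))
  expect_error(is_monophyletic(tr, "zz"), "unknown")
  # agreement with ape on the rooted representation
  expect_equal(is_monophyletic(tr, c("d", "e")),
               ape::is.monophyletic(tr, c("d", "e")))
})
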