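test_that("property tables validate and match the printed groupings", {
  tabs <- property_tables()
  for (dim in c("charge", "hydrophobicity", "size"))
    expect_setequal(unlist(tabs[[dim]]), AAset)
  expect_setequal(unlist(tabs$polarity), setdiff(AAset, "C"))
  expect_setequal(unlist(tabs$flexibility), setdiff(AAset, "G"))
  rep_tabs <- property_tables(repair = TRUE)
  expect_setequal(unlist(rep_tabs$polarity), AAset)
  expect_setequal(unlist(rep_tabs$flexibility), AAset)
  expect_true("C" %in% rep_tabs$polarity$`non-polar`)
  expect_true("G" %in% rep_tabs$flexibility$high)
})

test_that("property-change annotation matches the lookup oracle for all 400 pairs", {
  tabs <- property_tables()
  n_unclassified <- 0L
  for (a in AAset) for (b in AAset) {
    got <- annotate_property_change(a, b, tabs)
    for (dim in names(ORACLE_PROPS)) {
      la <- ORACLE_PROPS[[dim]][a]; lb <- ORACLE_PROPS[[dim]][b]
      if (is.na(la) || is.na(lb)) {
        expect_true(dim %in% got$unclassified, info = paste(a, b, dim))
      } else if (la != lb) {
        row <- got$changes[got$changes$dimension == dim, ]
        expect_equal(nrow(row), 1L, info = paste(a, b, dim))
        expect_equal(row$from, unname(la), info = paste(a, b, dim))
        expect_equal(row$to, unname(lb), info = paste(a, b, dim))
      } else {
        expect_false(dim %in% got$changes$dimension, info = paste(a, b, dim))
      }
    }
    n_unclassified <- n_unclassified + length(got$unclassified)
  }
  # exactly C (polarity) and G (flexibility) are unclassified:
  # pairs involving C contribute polarity, pairs involving G flexibility
  expect_equal(n_unclassified, 39L + 39L)
  expect_error(annotate_property_change("B", "A"), "non-standard")
})

test_that("property annotation is antisymmetric and matches known cases", {
  tabs <- property_tables()
  # A -> I: size small->large, flexibility limited->moderate, rest same
  ai <- annotate_property_change("A", "I", tabs)
  expect_setequal(ai$changes$dimension, c("size", "flexibility"))
  expect_equal(ai$changes$from[ai$changes$dimension == "size"], "small")
  expect_equal(ai$changes$to[ai$changes$dimension == "size"], "large")
  expect_equal(ai$changes$from[ai$changes$dimension == "flexibility"], "limited")
  expect_length(ai$unclassified, 0L)
  # K -> R: conservative in all five dimensions
  kr <- annotate_property_change("K", "R", tabs)
  expect_equal(nrow(kr$changes), 0L)
  # H -> Y: charge and polarity change, rest stay
  hy <- annotate_property_change("H", "Y", tabs)
  expect_setequal(hy$changes$dimension, c("charge", "polarity"))
  # C -> Y: polarity unclassified for C; size small->large among changes
  cy <- annotate_property_change("C", "Y", tabs)
  expect_true("polarity" %in% cy$unclassified)
  expect_true("size" %in% cy$changes$dimension)
  # antisymmetry over random pairs
  set.seed(2)
  for (k in 1:25) {
    ab <- sample(AAset, 2)
    f <- annotate_property_change(ab[1], ab[2], tabs)
    r <- annotate_property_change(ab[2], ab[1], tabs)
    expect_setequal(f$changes$dimension, r$changes$dimension)
    if (nrow(f$changes)) {
      ford <- f$changes[order(f$changes$dimension), ]
      rord <- r$changes[order(r$changes$dimension), ]
      expect_equal(ford$from, rord$to)
      expect_equal(ford$to, rord$from)
    }
    expect_setequal(f$unclassified, r$unclassified)
  }
})

test_that("column frequencies and information content follow their closed forms", {
  fam <- make_family(c(a = "AAK", b = "AAK", c = "GAK", d = "-AK"),
                     rep("X", 4))
  f1 <- column_frequencies(fam, names(fam$records), 1)
  expect_equal(unname(f1[c("A", "G")]), c(2 / 3, 1 / 3))
  expect_equal(sum(f1), 1, tolerance = 1e-12)
  f2 <- column_frequencies(fam, names(fam$records), 2)
  expect_equal(unname(f2["A"]), 1)
  expect_error(column_frequencies(fam, names(fam$records), 9), "range")
  # IC closed forms
  expect_equal(information_content(f2), log2(20))
  expect_equal(information_content(rep(1 / 20, 20)), 0)
  two <- c(0.5, 0.5, rep(0, 18))
  expect_equal(information_content(two), log2(20) - 1)
  set.seed(6)
  for (k in 1:10) {
    p <- stats::runif(20); p <- p / sum(p)
    ic <- information_content(p)
    expect_gte(ic, 0); expect_lte(ic, log2(20))
  }
})

test_that("group consensus respects threshold and gap rules", {
  recs <- c(paste0(rep("K", 1), collapse = ""))
  fam <- make_family(stats::setNames(
    c(rep("K", 9), "R"), paste0("s", 1:10)), rep("X", 10))
  expect_equal(group_consensus(fam, names(fam$records), 1, threshold = 0.8), "K")
  fam2 <- make_family(stats::setNames(
    c(rep("K", 7), "R", "R", "R"), paste0("s", 1:10)), rep("X", 10))
  expect_true(is.na(group_consensus(fam2, names(fam2$records), 1, threshold = 0.8)))
  expect_true(is.na(group_consensus(fam, names(fam$records), 1, threshold = 1)))
  # > 50% gaps in the group: no consensus even if residues agree
  fam3 <- make_family(stats::setNames(
    c("K", "K", "-", "-", "-", "-"), paste0("s", 1:6)), rep("X", 6))
  expect_true(is.na(group_consensus(fam3, names(fam3$records), 1)))
  expect_error(group_consensus(fam, names(fam$records), 1, threshold = 0.4))
})

test_that("clade polymorphism detection applies the consensus rule", {
  ids <- paste0("s", 1:20)
  clades <- rep(c("mono", "brass"), each = 10)
  base <- strrep("M", 6)
  recs <- vapply(1:20, function(i) {
    s <- base
    # col 2: A in mono, I in brass (planted polymorphism)
    substr(s, 2, 2) <- if (clades[i] == "mono") "A" else "I"
    # col 4: K in mono, R in brass (conservative polymorphism)
    substr(s, 4, 4) <- if (clades[i] == "mono") "K" else "R"
    # col 6: H conserved in mono; brass only 60% Y
    substr(s, 6, 6) <- if (clades[i] == "mono") "H"
      else if (i <= 16) "Y" else "W"
    s
  }, "")
  names(recs) <- ids
  fam <- make_family(recs, rep("GA3OX", 20), clades)
  pol <- detect_group_polymorphisms(fam, "mono", "brass", threshold = 0.8)
  expect_setequal(pol$column, c(2L, 4L))
  a_i <- pol[pol$column == 2L, ]
  expect_equal(a_i$consensusA, "A"); expect_equal(a_i$consensusB, "I")
  expect_match(a_i$property_changes, "size: small->large")
  expect_match(a_i$property_changes, "flexibility: limited->moderate")
  expect_false(grepl("charge|hydrophobicity|polarity", a_i$property_changes))
  k_r <- pol[pol$column == 4L, ]
  expect_equal(k_r$n_changes, 0L)
  expect_error(detect_group_polymorphisms(fam, c("s1", "s2"), c("s2", "s3")),
               "overlap")
})

test_that("column classification assigns the four categories and shading", {
  ids <- paste0("s", 1:12)
  classes <- rep(c("GA3OX", "GA20OX", "GA2OX"), each = 4)
  set.seed(1)
  recs <- vapply(1:12, function(i) {
    s <- "MMMMM"
    substr(s, 2, 2) <- if (classes[i] == "GA3OX") "S" else "G"  # characteristic
    substr(s, 3, 3) <- sample(AAset, 1)                         # unconserved
    s
  }, "")
  names(recs) <- ids
  fam <- make_family(recs, classes)
  rep_ <- suppressWarnings(classify_columns(fam, threshold = 0.8))
  expect_equal(rep_$category[1], "core_conserved")
  expect_equal(rep_$category[2], "class_characteristic")
  expect_equal(rep_$detail[2], "GA3OX")
  expect_equal(rep_$shading[1], "100")
  # pooled majority at column 2 is 8/12 = 66.7% -> "60-80" bin
  expect_equal(rep_$shading[2], "60-80")
  # pocket flags attach orthogonally
  pf <- data.frame(column = 2L, flag = "substrate_contact")
  rep2 <- classify_columns(fam, pocket_flags = pf, threshold = 0.8)
  expect_equal(rep2$pocket_flag[2], "substrate_contact")
  expect_equal(rep2$pocket_flag[1], "")
  # reference numbering maps through gaps
  recs2 <- c(x = "A-CD", y = "AACD", z = "AACD", w = "AGCD")
  fam2 <- make_family(recs2, c("c1", "c1", "c2", "c2"))
  rep3 <- classify_columns(fam2, reference = "x", threshold = 0.8)
  expect_equal(rep3$ref_position, c(1L, NA, 2L, 3L))
})

test_that("polymorphism recovery degrades gracefully with noise", {
  recall_at <- function(noise, seed) {
    sim <- simulate_family(random_family_spec(noise = noise, seed = seed))
    pol <- detect_group_polymorphisms(sim$family, "monocot", "brassicales")
    truth <- sim$truth$polymorphic_columns
    length(intersect(pol$column, truth)) / length(truth)
  }
  seeds <- 1:5
  r0 <- mean(vapply(seeds, function(s) recall_at(0, s), 0))
  r1 <- mean(vapply(seeds, function(s) recall_at(0.1, s), 0))
  r3 <- mean(vapply(seeds, function(s) recall_at(0.3, s), 0))
  expect_equal(r0, 1)
  expect_gte(r0, r1)
  expect_gte(r1, r3)
})
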