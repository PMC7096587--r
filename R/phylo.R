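# Poisson-corrected distances, neighbor joining, bootstrap, monophyly.

#' Column-deletion policy for distance computation
#'
#' @param mode `"complete"` keeps only gap-free columns; `"partial"` keeps
#'   columns whose residue coverage is at least `coverage_cutoff`;
#'   `"pairwise"` defers gap handling to each pairwise distance.
#' @param coverage_cutoff Coverage fraction for partial deletion
#'   (default 0.95, the usual site-coverage default).
#' @return A list of class `deletion_policy`.
#' @export
deletion_policy <- function(mode = c("partial", "complete", "pairwise"),
                            coverage_cutoff = 0.95) {
  mode <- match.arg(mode)
  if (!(coverage_cutoff > 0 && coverage_cutoff <= 1))
    stop("coverage_cutoff must be in (0, 1]")
  structure(list(mode = mode, coverage_cutoff = coverage_cutoff),
            class = "deletion_policy")
}

family_matrix <- function(family) {
  do.call(rbind, strsplit(unname(family$records), ""))
}

family_from_matrix <- function(mat, family) {
  recs <- apply(mat, 1L, paste, collapse = "")
  names(recs) <- names(family$records)
  aligned_family(recs, family$class_of, family$clade_of)
}

#' Filter alignment columns under a deletion policy
#'
#' @param family An `aligned_family`.
#' @param policy A [deletion_policy()].
#' @return The filtered `aligned_family` (unchanged for `"pairwise"`).
#' @export
filter_columns <- function(family, policy = deletion_policy()) {
  if (policy$mode == "pairwise") return(family)
  mat <- family_matrix(family)
  cover <- colMeans(mat != "-")
  keep <- if (policy$mode == "complete") cover == 1 else cover >= policy$coverage_cutoff
  if (!any(keep)) stop("column filtering removed all alignment columns")
  family_from_matrix(mat[, keep, drop = FALSE], family)
}

#' Poisson-corrected distance between two aligned sequences
#'
#' Computes the proportion `p` of differing residue pairs over columns
#' where both sequences have residues, then returns the multiple-hit
#' corrected distance `d = -ln(1 - p)` in substitutions per site.
#'
#' @param a,b Equal-length gapped strings.
#' @param saturation What to do when `p = 1`: `"error"` (default) or
#'   `"cap"` at `-ln(1/ncols)` with a warning, `ncols` being the number of
#'   compared columns.
#' @return Non-negative distance.
#' @export
poisson_distance <- function(a, b, saturation = c("error", "cap")) {
  saturation <- match.arg(saturation)
  cha <- strsplit(toupper(a), "")[[1]]; chb <- strsplit(toupper(b), "")[[1]]
  if (length(cha) != length(chb)) stop("aligned strings differ in length")
  both <- cha != "-" & chb != "-"
  ncomp <- sum(both)
  if (ncomp == 0L) stop("no comparable columns (all gapped)")
  p <- sum(cha[both] != chb[both]) / ncomp
  if (p >= 1) {
    if (saturation == "error")
      stop("saturated distance (p = 1); rerun with saturation = \"cap\"")
    warning("saturated distance capped at -ln(1/", ncomp, ")")
    return(log(ncomp))
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix for a family
#'
#' @param family An `aligned_family` with at least 3 sequences.
#' @param policy A [deletion_policy()] applied before pairwise distances;
#'   residual in-pair gaps are always pairwise-deleted.
#' @param saturation Passed to [poisson_distance()].
#' @return A symmetric `dist`-free base matrix with zero diagonal, labeled
#'   by sequence id.
#' @export
distance_matrix <- function(family, policy = deletion_policy(),
                            saturation = c("error", "cap")) {
  saturation <- match.arg(saturation)
  if (length(family$records) < 3L) stop("need at least 3 sequences")
  fam <- filter_columns(family, policy)
  ids <- names(fam$records)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(poisson_distance(fam$records[[i]], fam$records[[j]], saturation),
                  error = function(e) stop("pair (", ids[i], ", ", ids[j], "): ",
                                           conditionMessage(e), call. = FALSE))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with the
#' standard branch-length formulas, until three nodes remain, which are
#' joined at an unrooted trifurcation. Q ties are broken by the lowest
#' `(i, j)` index pair in current label order. Negative branch lengths
#' are clamped to zero with the deficit transferred to the sibling branch.
#'
#' @param D Symmetric labeled distance matrix (or `dist`).
#' @return An unrooted `ape::phylo` tree with branch lengths in
#'   substitutions per site.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix not symmetric")
  # node newick fragments, grown bottom-up
  frag <- ids
  fmt <- function(x) sprintf("%.6g", max(x, 0))
  while (n > 3L) {
    rs <- rowSums(D)
    Q <- (n - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- as.character(seq_len(n - 1L))
    D <- D2
    n <- n - 1L
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(v1), ",", frag[2], ":", fmt(v2),
                ",", frag[3], ":", fmt(v3), ");")
  tr <- ape::read.tree(text = nwk)
  tr
}

#' Leaf bipartitions induced by the internal edges of an unrooted tree
#'
#' Each internal edge splits the leaves into two sets; the canonical form
#' returned here is the side not containing the alphabetically first leaf
#' label, sorted. Trivial (leaf-adjacent) splits are excluded.
#'
#' @param tree An `ape::phylo`.
#' @return A list of sorted character vectors.
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  ntip <- length(tips)
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  splits <- lapply(internal, function(nd) {
    below <- tips[descendant_tips(tree, nd)]
    if (anchor %in% below) below <- setdiff(tips, below)
    sort(below)
  })
  splits <- splits[vapply(splits, function(s)
    length(s) >= 2L && length(s) <= ntip - 2L, NA)]
  unique(splits)
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counts bipartitions present in one tree but not the other, via
#' [tree_bipartitions()].
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer; 0 means identical unrooted topologies.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1); b2 <- tree_bipartitions(t2)
  key <- function(b) vapply(b, paste, "", collapse = "|")
  k1 <- key(b1); k2 <- key(b2)
  sum(!k1 %in% k2) + sum(!k2 %in% k1)
}

#' Is a set of leaves monophyletic on an unrooted tree?
#'
#' True iff some edge bipartition separates exactly `id_set` from its
#' complement; the full leaf set and single leaves are trivially true.
#'
#' @param tree An `ape::phylo`.
#' @param id_set Character vector of leaf labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, id_set) {
  unknown <- setdiff(id_set, tree$tip.label)
  if (length(unknown)) stop("unknown ids: ", paste(unknown, collapse = ", "))
  nt <- length(tree$tip.label)
  k <- length(unique(id_set))
  if (k == nt || k == 1L) return(TRUE)
  target <- sort(unique(id_set))
  comp <- sort(setdiff(tree$tip.label, target))
  for (b in tree_bipartitions(tree)) {
    if (identical(b, target) || identical(b, comp)) return(TRUE)
  }
  FALSE
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' resamples alignment columns with replacement `n_reps` times, rebuilding
#' the tree each time. The support of each internal edge of the point tree
#' is the fraction of replicate trees containing the same leaf
#' bipartition; supports are stored as node labels (fractions in `[0,1]`).
#'
#' Replicates whose distance matrix saturates are skipped with a warning
#' and the denominator reduced; more than 20% skipped is an error.
#'
#' @param family An `aligned_family` (>= 3 sequences).
#' @param policy A [deletion_policy()].
#' @param n_reps Number of bootstrap replicates (paper-scale default 500).
#' @param seed Integer seed controlling the column resampling.
#' @return An `ape::phylo` with `node.label` supports.
#' @export
bootstrap_support <- function(family, policy = deletion_policy(),
                              n_reps = 500L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  fam <- filter_columns(family, policy)
  point <- neighbor_joining(distance_matrix(fam, deletion_policy("pairwise")))
  mat <- family_matrix(fam)
  nc <- ncol(mat)
  key <- function(b) vapply(b, paste, "", collapse = "|")
  target <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(length(target)), key(target))
  done <- 0L; skipped <- 0L
  set.seed(as.integer(seed))
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    repfam <- family_from_matrix(mat[, cols, drop = FALSE], fam)
    tr <- tryCatch(
      neighbor_joining(distance_matrix(repfam, deletion_policy("pairwise"))),
      error = function(e) NULL)
    if (is.null(tr)) { skipped <- skipped + 1L; next }
    done <- done + 1L
    kk <- key(tree_bipartitions(tr))
    hit <- names(counts) %in% kk
    counts[hit] <- counts[hit] + 1
  }
  if (skipped > 0L) warning(skipped, " bootstrap replicate(s) skipped (saturation)")
  if (skipped > 0.2 * n_reps) stop("more than 20% of bootstrap replicates skipped")
  support <- counts / done
  # attach supports to internal nodes of the point tree
  ntip <- length(point$tip.label)
  nnode <- point$Nnode
  labels <- character(nnode)
  anchor <- sort(point$tip.label)[1L]
  for (nd in (ntip + 1L):(ntip + nnode)) {
    below <- point$tip.label[descendant_tips(point, nd)]
    if (anchor %in% below) below <- setdiff(point$tip.label, below)
    kk <- paste(sort(below), collapse = "|")
    labels[nd - ntip] <- if (kk %in% names(support))
      sprintf("%.6g", support[[kk]]) else ""
  }
  point$node.label <- labels
  attr(point, "bootstrap") <- list(n_reps = n_reps, used = done, skipped = skipped,
                                   seed = as.integer(seed))
  point
}

#' Write a tree to a newick file (supports as node labels)
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path Newick file path.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a distance matrix as PHYLIP square-matrix text
#' @param D Labeled symmetric matrix.
#' @param path Output path.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(formatC(D[i, ], format = "f", digits = 6),
                           collapse = "  ")), con)
  }
  invisible(path)
}
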