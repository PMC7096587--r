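# Seeded generators for families and toy structures with known ground
# truth; every pipeline stage is testable against these.

#' Specification for a simulated protein family
#'
#' @param tree An `ape::phylo` with branch lengths in expected
#'   substitutions per site, or a newick string.
#' @param groups Data frame with columns `id`, `class`, `clade` covering
#'   every leaf.
#' @param length Number of alignment columns.
#' @param planted_polymorphisms Optional data frame `column`, plus one
#'   residue column per clade (named by clade label): at each planted
#'   column every member of a clade is overwritten with that clade's
#'   residue. Residues must differ between clades at each planted column.
#' @param planted_motifs Optional list of `list(consensus =, classes =,
#'   start =)`: the consensus string is written at `start` into every
#'   sequence of the named classes.
#' @param noise Per-site probability that a planted residue is flipped to
#'   a random different residue (default 0).
#' @param guard_threshold Consensus threshold used to homogenize
#'   incidental clade-fixed background columns (default 0.8; see
#'   [simulate_family()]). Set to `NA` to disable the guard.
#' @param seed Integer seed; output is deterministic given it.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(tree, groups, length = 300L,
                        planted_polymorphisms = NULL, planted_motifs = NULL,
                        noise = 0, guard_threshold = 0.8, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!all(tree$tip.label %in% groups$id))
    stop("groups must cover every leaf")
  if (!is.null(planted_polymorphisms)) {
    pp <- planted_polymorphisms
    if (anyDuplicated(pp$column)) stop("planted columns must be distinct")
    if (any(pp$column > length)) stop("planted column beyond alignment length")
    res_cols <- setdiff(names(pp), "column")
    if (length(res_cols) >= 2L) {
      same <- apply(pp[res_cols], 1L, function(r) any(duplicated(r)))
      if (any(same)) stop("planted residues must differ between clades")
    }
  }
  structure(list(tree = tree, groups = groups, length = as.integer(length),
                 planted_polymorphisms = planted_polymorphisms,
                 planted_motifs = planted_motifs, noise = noise,
                 guard_threshold = guard_threshold,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Random two-clade family specification (study-scale defaults)
#'
#' Builds a random two-clade tree (clades named `monocot` and
#' `brassicales`, 10 leaves each by default) with root-to-tip depth about
#' 0.3 substitutions per site, and plants 5 clade-polymorphic columns.
#' These defaults mirror the conditions under which clade-polymorphism
#' recovery and tree recovery are evaluated.
#'
#' @param n_per_clade Leaves per clade (default 10).
#' @param ncols Alignment columns (default 300).
#' @param depth Root-to-tip depth in substitutions/site (default 0.3).
#' @param n_planted Number of planted clade-polymorphic columns (default 5).
#' @param noise Planted-site flip probability (default 0).
#' @param seed Integer seed.
#' @return A `family_spec`.
#' @export
random_family_spec <- function(n_per_clade = 10L, ncols = 300L, depth = 0.3,
                               n_planted = 5L, noise = 0, seed = 1L) {
  set.seed(as.integer(seed))
  clades <- c("monocot", "brassicales")
  prefix <- c("m", "b")
  subtrees <- lapply(1:2, function(k) {
    t <- ape::rtree(n_per_clade, rooted = TRUE,
                    tip.label = paste0(prefix[k], seq_len(n_per_clade)))
    # edge lengths bounded away from zero so every internal edge carries
    # resolvable signal at a few hundred columns
    t$edge.length <- stats::runif(length(t$edge.length), 0.5, 1)
    # rescale so root-to-tip depth (clade subtree plus its stem) is `depth`
    d <- max(ape::node.depth.edgelength(t)[seq_len(n_per_clade)])
    t$edge.length <- t$edge.length / d * (depth - depth / 6)
    t
  })
  stem <- depth / 6
  nwk <- paste0("(", sub(";$", "", ape::write.tree(subtrees[[1]])), ":", stem,
                ",", sub(";$", "", ape::write.tree(subtrees[[2]])), ":", stem,
                ");")
  tree <- ape::read.tree(text = nwk)
  groups <- data.frame(
    id = tree$tip.label,
    class = ifelse(grepl("^m", tree$tip.label), clades[1], clades[2]),
    clade = ifelse(grepl("^m", tree$tip.label), clades[1], clades[2]),
    stringsAsFactors = FALSE)
  planted <- NULL
  if (n_planted > 0L) {
    cols <- sort(sample.int(ncols, n_planted))
    pairs <- t(vapply(seq_len(n_planted),
                      function(i) sample(AA20, 2L), character(2)))
    planted <- data.frame(column = cols,
                          monocot = pairs[, 1], brassicales = pairs[, 2],
                          stringsAsFactors = FALSE)
  }
  family_spec(tree, groups, length = ncols,
              planted_polymorphisms = planted, noise = noise,
              seed = as.integer(seed) + 1L)
}

evolve_sequence <- function(parent, t) {
  # Poisson substitution process: per site, Poisson(t) replacement events,
  # each drawing uniformly among the 19 other residues
  n_events <- stats::rpois(length(parent), t)
  hit <- which(n_events > 0L)
  for (i in hit) {
    for (k in seq_len(n_events[i])) {
      parent[i] <- sample(setdiff(AA20, parent[i]), 1L)
    }
  }
  parent
}

#' Simulate a protein family along a known tree
#'
#' Sequences evolve leaf-ward from a uniform-random root sequence under a
#' 20-state Poisson replacement process (events at the branch-length rate,
#' uniform replacement among the other 19 residues). Planted
#' clade-polymorphic columns are then overwritten per clade and flipped
#' with probability `noise`; planted motif consensus strings are written
#' into the sequences of their class sets. Alignments are generated
#' gapless.
#'
#' The generator guarantees that the planted columns are the *only*
#' clade-conserved polymorphisms at the `guard_threshold`: drift along
#' the clade stems occasionally fixes different residues in the two
#' clades at unplanted columns, and any such incidental column is
#' homogenized (the second clade is rewritten to the first clade's
#' consensus residue) so that ground truth is exact by construction.
#'
#' @param spec A [family_spec()].
#' @return List with `family` (an `aligned_family`) and `truth`: the
#'   generating `tree`, `polymorphic_columns`, and `motif_positions`.
#' @export
simulate_family <- function(spec) {
  set.seed(spec$seed)
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- sample(AA20, spec$length, replace = TRUE)
  # preorder (cladewise) edge traversal: parents before children
  tr2 <- ape::reorder.phylo(tree, "cladewise")
  edge_order <- tr2$edge
  len <- tr2$edge.length
  for (e in seq_len(nrow(edge_order))) {
    par <- edge_order[e, 1L]; child <- edge_order[e, 2L]
    seqs[[child]] <- evolve_sequence(seqs[[par]], len[e])
  }
  leafseq <- seqs[seq_len(ntip)]
  names(leafseq) <- tree$tip.label
  clade_of <- stats::setNames(spec$groups$clade, spec$groups$id)
  class_of <- stats::setNames(spec$groups$class, spec$groups$id)
  # homogenize incidental clade-fixed background columns so that planted
  # columns are the only clade-conserved polymorphisms
  clades <- unique(clade_of[!is.na(clade_of) & nzchar(clade_of)])
  planted_cols <- if (is.null(spec$planted_polymorphisms)) integer(0) else
    spec$planted_polymorphisms$column
  if (!is.na(spec$guard_threshold) && length(clades) >= 2L) {
    members <- lapply(clades, function(cl) names(clade_of)[clade_of == cl])
    for (col in setdiff(seq_len(spec$length), planted_cols)) {
      cons <- vapply(members, function(ids) {
        res <- vapply(leafseq[ids], `[`, "", col)
        tab <- table(res)
        top <- names(tab)[which.max(tab)]
        if (max(tab) / length(res) >= spec$guard_threshold) top else NA_character_
      }, "")
      if (!anyNA(cons) && length(unique(cons)) > 1L) {
        for (ids in members) for (id in ids) leafseq[[id]][col] <- cons[[1L]]
      }
    }
  }
  # plant clade polymorphisms
  truth_poly <- integer(0)
  if (!is.null(spec$planted_polymorphisms)) {
    pp <- spec$planted_polymorphisms
    truth_poly <- pp$column
    for (r in seq_len(nrow(pp))) {
      for (cl in setdiff(names(pp), "column")) {
        members <- names(clade_of)[clade_of == cl]
        for (id in members) {
          aa <- pp[[cl]][r]
          if (spec$noise > 0 && stats::runif(1) < spec$noise)
            aa <- sample(setdiff(AA20, aa), 1L)
          leafseq[[id]][pp$column[r]] <- aa
        }
      }
    }
  }
  # plant motifs
  truth_motifs <- NULL
  if (!is.null(spec$planted_motifs)) {
    rows <- list()
    for (pm in spec$planted_motifs) {
      cons <- strsplit(toupper(pm$consensus), "")[[1]]
      members <- names(class_of)[class_of %in% pm$classes]
      for (id in members) {
        st <- pm$start
        leafseq[[id]][st:(st + length(cons) - 1L)] <- cons
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = id, consensus = pm$consensus, start = st,
          stringsAsFactors = FALSE)
      }
    }
    truth_motifs <- do.call(rbind, rows)
  }
  records <- vapply(leafseq, paste, "", collapse = "")
  fam <- aligned_family(records, class_of, clade_of)
  list(family = fam,
       truth = list(tree = tree, polymorphic_columns = truth_poly,
                    motif_positions = truth_motifs))
}

#' Specification for a toy pocket structure
#'
#' @param n_contact Residues planted inward within 3.5-4.9 A of the
#'   substrate (true substrate contacts).
#' @param n_lining Residues planted at contact distance but with the
#'   sidechain pointing away (pocket lining only).
#' @param n_cofactor Residues planted with a sidechain atom 2.2 A from
#'   the iron site (cofactor coordinating; also inward and within the
#'   substrate cutoff).
#' @param n_background Residues planted farther than 6 A from all ligand
#'   atoms (ignored when `sequence` is given: every residue not assigned
#'   a pocket role becomes background).
#' @param sequence Optional 1-letter residue string; the chain is built
#'   with exactly these residue types in order, pocket roles assigned to
#'   randomly chosen positions, so the chain maps 1:1 onto that sequence.
#' @param seed Integer seed.
#' @return A list of class `structure_spec`.
#' @export
structure_spec <- function(n_contact = 3L, n_lining = 2L, n_cofactor = 2L,
                           n_background = 5L, sequence = NULL, seed = 1L) {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) < n_contact + n_lining + n_cofactor)
      stop("sequence shorter than the planted role sets")
  }
  structure(list(n_contact = n_contact, n_lining = n_lining,
                 n_cofactor = n_cofactor, n_background = n_background,
                 sequence = sequence, seed = as.integer(seed)),
            class = "structure_spec")
}

rand_dir_up <- function() {
  # unit vector with non-negative z (keeps planted residues on the
  # substrate side of the iron, so "inward" is well defined)
  repeat {
    v <- stats::rnorm(3)
    if (sqrt(sum(v^2)) > 1e-6) break
  }
  v <- v / sqrt(sum(v^2))
  if (v[3] < 0) v[3] <- -v[3]
  v
}

#' Simulate a toy pocket structure with known residue roles
#'
#' Builds a minimal protein around a planted ligand site: a 3-atom
#' substrate surrogate (`LIG`) at the origin, an iron site (`FE`) 4 A
#' below it, and a 2-atom 2-oxoglutarate (`AKG`) beside the iron. Each
#' residue gets a CA and a 2-atom pseudo-sidechain placed so its role
#' under [select_contact_residues()] is known by construction. Geometry
#' is re-checked after placement; generation retries up to 100 times.
#'
#' @param spec A [structure_spec()].
#' @param path Optional path to also write the structure as PDB text.
#' @return List with `structure` (a `structure_model`), `site` (a
#'   `ligand_site`), `truth` (data frame `resno`, `role`), and `pdb_path`
#'   (if written).
#' @export
simulate_structure <- function(spec, path = NULL) {
  set.seed(spec$seed)
  sub_xyz <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.2, 0))
  fe_xyz <- c(0, 0, -4)
  og_xyz <- rbind(c(1.6, 0, -4), c(2.6, 0.5, -4.2))
  lig_atoms <- rbind(sub_xyz, fe_xyz, og_xyz)
  resnames <- c("SER", "THR", "ASP", "LEU", "PHE", "LYS", "ARG", "HIS",
                "TYR", "VAL", "GLU", "ASN")

  aa1to3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

  for (attempt in seq_len(100L)) {
    if (is.null(spec$sequence)) {
      n_total <- spec$n_contact + spec$n_lining + spec$n_cofactor +
        spec$n_background
      roles <- c(rep("substrate_contact", spec$n_contact),
                 rep("pocket_lining_only", spec$n_lining),
                 rep("cofactor_coordinating", spec$n_cofactor),
                 rep("none", spec$n_background))
      resid3 <- sample(resnames, n_total, replace = TRUE)
    } else {
      aa <- strsplit(spec$sequence, "")[[1]]
      n_total <- length(aa)
      roles <- rep("none", n_total)
      pick <- sample.int(n_total, spec$n_contact + spec$n_lining + spec$n_cofactor)
      roles[pick[seq_len(spec$n_contact)]] <- "substrate_contact"
      roles[pick[spec$n_contact + seq_len(spec$n_lining)]] <- "pocket_lining_only"
      roles[pick[spec$n_contact + spec$n_lining + seq_len(spec$n_cofactor)]] <-
        "cofactor_coordinating"
      resid3 <- unname(aa1to3[aa])
      if (anyNA(resid3)) stop("sequence contains non-standard residues")
    }
    rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      geom <- switch(roles[i],
        substrate_contact = {
          u <- rand_dir_up(); d <- stats::runif(1, 3.5, 4.9)
          list(ca = (d + 1.8) * u, s1 = d * u, s2 = (d + 0.7) * u)
        },
        pocket_lining_only = {
          u <- rand_dir_up(); d <- stats::runif(1, 3.5, 4.9)
          list(ca = d * u, s1 = (d + 1.5) * u, s2 = (d + 2.2) * u)
        },
        cofactor_coordinating = {
          ang <- stats::runif(1, 0, 2 * pi)
          w <- c(0.25 * cos(ang), 0.25 * sin(ang), 1)
          w <- w / sqrt(sum(w^2))
          list(ca = fe_xyz + 4.5 * w, s1 = fe_xyz + 2.2 * w,
               s2 = fe_xyz + 2.9 * w)
        },
        {
          u <- rand_dir_up(); d <- stats::runif(1, 10, 14)
          list(ca = d * u, s1 = (d + 1) * u, s2 = (d + 1.7) * u)
        })
      rows[[i]] <- data.frame(
        resno = i, resid = resid3[i], elety = c("CA", "CB", "CG"),
        x = c(geom$ca[1], geom$s1[1], geom$s2[1]),
        y = c(geom$ca[2], geom$s1[2], geom$s2[2]),
        z = c(geom$ca[3], geom$s1[3], geom$s2[3]), stringsAsFactors = FALSE)
    }
    at <- do.call(rbind, rows)
    truth <- data.frame(resno = seq_len(n_total), role = roles,
                        stringsAsFactors = FALSE)

    atoms <- data.frame(type = "ATOM", chain = "A", resno = at$resno,
                        insert = "", resid = at$resid, elety = at$elety,
                        x = at$x, y = at$y, z = at$z, o = 1,
                        stringsAsFactors = FALSE)
    het <- data.frame(
      type = "HETATM", chain = "L",
      resno = c(1L, 1L, 1L, 2L, 3L, 3L), insert = "",
      resid = c("LIG", "LIG", "LIG", "FE", "AKG", "AKG"),
      elety = c("C1", "C2", "C3", "FE", "O1", "O2"),
      x = lig_atoms[, 1], y = lig_atoms[, 2], z = lig_atoms[, 3], o = 1,
      stringsAsFactors = FALSE)
    struct <- structure(list(atoms = atoms, het = het, path = NA_character_),
                        class = "structure_model")
    site <- ligand_site(struct, "LIG", "FE", "AKG")
    got <- select_contact_residues(struct, site)
    ok <- identical(got$role[match(truth$resno, got$resno)], truth$role)
    if (ok) {
      pdb_path <- NULL
      if (!is.null(path)) {
        write_toy_pdb(atoms, het, path)
        pdb_path <- path
      }
      return(list(structure = struct, site = site, truth = truth,
                  pdb_path = pdb_path))
    }
  }
  stop("could not realize a structure matching the spec in 100 attempts")
}

write_toy_pdb <- function(atoms, het, path) {
  all <- rbind(atoms, het)
  elesy <- ifelse(all$elety == "FE", "FE", substr(all$elety, 1L, 1L))
  bio3d::write.pdb(file = path,
                   type = all$type,
                   xyz = as.numeric(t(as.matrix(all[c("x", "y", "z")]))),
                   resno = all$resno, resid = all$resid,
                   eleno = seq_len(nrow(all)), elety = all$elety,
                   chain = all$chain, o = all$o, b = rep(0, nrow(all)),
                   elesy = elesy)
  invisible(path)
}

#' Write a simulated family bundle to disk
#'
#' Writes aligned FASTA, a groups TSV and a ground-truth JSON next to
#' each other, the on-disk form consumed by [run_pipeline()].
#'
#' @param sim Output of [simulate_family()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem (default `"family"`).
#' @return Named character vector of the three paths.
#' @export
write_family_bundle <- function(sim, dir, stem = "family") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  groups <- file.path(dir, paste0(stem, ".groups.tsv"))
  truth <- file.path(dir, paste0(stem, ".truth.json"))
  write_alignment(sim$family, fasta)
  ids <- names(sim$family$records)
  clade <- sim$family$clade_of[ids]
  clade[is.na(clade)] <- ""
  utils::write.table(
    data.frame(id = ids, class = unname(sim$family$class_of[ids]),
               clade = unname(clade)),
    groups, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(polymorphic_columns = sim$truth$polymorphic_columns,
         tree = ape::write.tree(sim$truth$tree)),
    truth, auto_unbox = TRUE)
  c(fasta = fasta, groups = groups, truth = truth)
}
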