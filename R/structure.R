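# Structure input and substrate-pocket residue triage: distance cutoffs,
# sidechain orientation, cofactor partition, and alignment mapping.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read a protein structure from a PDB file
#'
#' Wraps `bio3d::read.pdb`: the first MODEL only; alternate locations are
#' resolved by keeping the highest-occupancy copy of each atom (ties go to
#' altloc `"A"`); hydrogens are dropped. ATOM records become the polymer
#' model; HETATM records are kept separately, keyed by residue name.
#'
#' @param path Path to a PDB-format text file.
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`),
#'   `het` (same layout for HETATM records), and `path`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse PDB ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atom records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # drop hydrogens
  elesy <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                 substr(trimws(at$elety), 1L, 1L), at$elesy)))
  at <- at[elesy != "H" & elesy != "D", , drop = FALSE]
  # altloc: highest occupancy per atom slot, ties -> 'A' (then first)
  at$o[is.na(at$o)] <- 1
  keykey <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety)
  ord <- order(keykey, -at$o, at$alt != "A", at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(keykey[ord]), , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite coordinates in ", path)
  cols <- c("type", "chain", "resno", "insert", "resid", "elety",
            "x", "y", "z", "o")
  at <- at[order(at$chain, at$resno, at$insert), cols]
  atoms <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  rownames(atoms) <- rownames(het) <- NULL
  structure(list(atoms = atoms, het = het, path = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", nrow(x$atoms), "atoms,",
      nrow(unique(x$atoms[c("chain", "resno", "insert")])), "residues,",
      length(unique(x$het$resid)), "het group(s)\n")
  invisible(x)
}

residue_table <- function(struct) {
  unique(struct$atoms[c("chain", "resno", "insert", "resid")])
}

residue_key <- function(df) paste(df$chain, df$resno, df$insert, sep = "_")

#' Extract a ligand site from a structure's HETATM groups
#'
#' @param struct A `structure_model`.
#' @param substrate_het Residue name of the docked substrate surrogate.
#' @param fe_het Residue name of the iron site (single atom expected;
#'   centroid used if several).
#' @param og_het Residue name of the 2-oxoglutarate co-substrate; optional.
#' @param reaction_center `"fe"` (default: the reactive center is the iron
#'   coordinate) or `"substrate_centroid"`.
#' @return A list of class `ligand_site` with `substrate_atoms` (n x 3),
#'   `fe_site` (length-3), `og_site` (m x 3 or NULL), `reaction_center`
#'   (length-3).
#' @export
ligand_site <- function(struct, substrate_het, fe_het = "FE", og_het = NULL,
                        reaction_center = c("fe", "substrate_centroid")) {
  reaction_center <- match.arg(reaction_center)
  pick <- function(name) {
    h <- struct$het[struct$het$resid == name, , drop = FALSE]
    if (nrow(h) == 0L) stop("no HETATM group named '", name, "'")
    as.matrix(h[c("x", "y", "z")])
  }
  sub <- pick(substrate_het)
  fe <- colMeans(pick(fe_het))
  og <- if (!is.null(og_het)) pick(og_het) else NULL
  rc <- if (reaction_center == "fe") fe else colMeans(sub)
  structure(list(substrate_atoms = sub, fe_site = fe, og_site = og,
                 reaction_center = rc),
            class = "ligand_site")
}

min_dist_to_points <- function(xyz, points) {
  # min Euclidean distance from any row of xyz to any row of points
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(points))) +
    outer(rep(1, nrow(xyz)), rowSums(points^2)) - 2 * xyz %*% t(points)
  sqrt(max(0, min(d2)))
}

#' Residues with any atom within a distance cutoff of a point set
#'
#' @param struct A `structure_model`.
#' @param points Numeric matrix (n x 3) or length-3 vector.
#' @param cutoff Distance cutoff in Angstrom; the comparison is inclusive
#'   (`<=`), matching the "within 5 A" convention.
#' @return Data frame of included residues (`chain`, `resno`, `insert`,
#'   `resid`, `min_dist`), sorted by distance.
#' @export
residues_within <- function(struct, points, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (nrow(points) == 0L) stop("empty point set")
  res <- residue_table(struct)
  key <- residue_key(struct$atoms)
  res$min_dist <- vapply(seq_len(nrow(res)), function(i) {
    rows <- key == residue_key(res[i, ])
    min_dist_to_points(as.matrix(struct$atoms[rows, c("x", "y", "z")]), points)
  }, 0)
  out <- res[res$min_dist <= cutoff, , drop = FALSE]
  out <- out[order(out$min_dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sidechain_atoms <- function(struct, chain, resno, insert = "") {
  a <- struct$atoms
  rows <- a$chain == chain & a$resno == resno & a$insert == insert
  a <- a[rows, , drop = FALSE]
  list(all = a, sidechain = a[!a$elety %in% BACKBONE_ATOMS, , drop = FALSE],
       ca = a[a$elety == "CA", , drop = FALSE])
}

#' Does a residue's sidechain point inward toward the reactive center?
#'
#' The default test compares distances: `TRUE` iff the centroid of the
#' sidechain heavy atoms is strictly closer to `reaction_center` than the
#' CA atom is. Glycine (no sidechain heavy atoms) returns `FALSE` with
#' attribute `flag = "no_sidechain"`. The `"angle"` variant instead
#' requires the CA->centroid direction to be within 90 degrees of the
#' CA->center direction.
#'
#' @param struct A `structure_model`.
#' @param chain,resno,insert Residue identity.
#' @param reaction_center Length-3 coordinate.
#' @param method `"centroid"` (default) or `"angle"`.
#' @return Logical scalar (possibly with attribute `flag`).
#' @export
sidechain_inward <- function(struct, chain, resno, insert = "",
                             reaction_center,
                             method = c("centroid", "angle")) {
  method <- match.arg(method)
  sc <- sidechain_atoms(struct, chain, resno, insert)
  if (nrow(sc$ca) == 0L)
    stop("residue ", chain, ":", resno, insert, " has no CA atom")
  if (nrow(sc$sidechain) == 0L)
    return(structure(FALSE, flag = "no_sidechain"))
  ca <- as.numeric(sc$ca[1L, c("x", "y", "z")])
  centroid <- colMeans(as.matrix(sc$sidechain[c("x", "y", "z")]))
  if (method == "centroid") {
    sqrt(sum((centroid - reaction_center)^2)) < sqrt(sum((ca - reaction_center)^2))
  } else {
    v1 <- centroid - ca; v2 <- reaction_center - ca
    sum(v1 * v2) > 0
  }
}

#' Pocket-selection configuration
#'
#' @param substrate_cutoff Distance to the substrate defining the pocket
#'   (default 5 Angstrom, inclusive).
#' @param fe_cutoff Sidechain distance to the iron site below which a
#'   residue counts as iron-coordinating (default 2.6 Angstrom, typical
#'   Fe-ligand coordination).
#' @param og_cutoff Sidechain distance to the 2-oxoglutarate below which a
#'   residue counts as co-substrate-orienting (default 3.5 Angstrom,
#'   H-bond/salt-bridge range).
#' @param orientation Orientation test; see [sidechain_inward()].
#' @return A list of class `pocket_config`.
#' @export
pocket_config <- function(substrate_cutoff = 5, fe_cutoff = 2.6,
                          og_cutoff = 3.5,
                          orientation = c("centroid", "angle")) {
  orientation <- match.arg(orientation)
  structure(list(substrate_cutoff = substrate_cutoff, fe_cutoff = fe_cutoff,
                 og_cutoff = og_cutoff, orientation = orientation),
            class = "pocket_config")
}

#' Triage pocket residues into substrate-contact and cofactor roles
#'
#' Implements the contact-residue criteria: a residue is *flagged* when it
#' has any atom within `substrate_cutoff` of the docked substrate AND its
#' sidechain points inward toward the reactive center. Flagged residues
#' whose sidechain comes within `fe_cutoff` of the iron or `og_cutoff` of
#' the 2-oxoglutarate are partitioned off as `cofactor_coordinating`; the
#' remainder are `substrate_contact`. Within-cutoff residues that fail the
#' orientation test are `pocket_lining_only`; everything else is `none`.
#'
#' @param struct A `structure_model`.
#' @param site A [ligand_site()].
#' @param cfg A [pocket_config()].
#' @return Data frame of class `pocket_residue_set`: one row per residue
#'   with `chain`, `resno`, `insert`, `resid`, `dist_substrate`,
#'   `sc_dist_fe`, `sc_dist_og`, `orientation_pass`, `no_sidechain`,
#'   `role`.
#' @export
select_contact_residues <- function(struct, site, cfg = pocket_config()) {
  res <- residue_table(struct)
  key_all <- residue_key(struct$atoms)
  n <- nrow(res)
  dist_sub <- sc_fe <- sc_og <- rep(NA_real_, n)
  orient <- nosc <- logical(n)
  for (i in seq_len(n)) {
    rows <- key_all == residue_key(res[i, ])
    xyz <- as.matrix(struct$atoms[rows, c("x", "y", "z")])
    dist_sub[i] <- min_dist_to_points(xyz, site$substrate_atoms)
    sc <- struct$atoms[rows, , drop = FALSE]
    scat <- sc[!sc$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(scat)) {
      sxyz <- as.matrix(scat[c("x", "y", "z")])
      sc_fe[i] <- min_dist_to_points(sxyz, site$fe_site)
      sc_og[i] <- if (!is.null(site$og_site))
        min_dist_to_points(sxyz, site$og_site) else Inf
      o <- sidechain_inward(struct, res$chain[i], res$resno[i], res$insert[i],
                            site$reaction_center, cfg$orientation)
      orient[i] <- isTRUE(as.logical(o))
    } else {
      nosc[i] <- TRUE
      sc_fe[i] <- Inf; sc_og[i] <- Inf
      orient[i] <- FALSE
    }
  }
  within <- dist_sub <= cfg$substrate_cutoff
  flagged <- within & orient
  cofactor <- flagged & (sc_fe <= cfg$fe_cutoff | sc_og <= cfg$og_cutoff)
  role <- rep("none", n)
  role[within & !orient] <- "pocket_lining_only"
  role[flagged & !cofactor] <- "substrate_contact"
  role[cofactor] <- "cofactor_coordinating"
  out <- cbind(res,
               data.frame(dist_substrate = dist_sub, sc_dist_fe = sc_fe,
                          sc_dist_og = sc_og, orientation_pass = orient,
                          no_sidechain = nosc, role = role,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("pocket_residue_set", "data.frame")
  out
}

#' @export
print.pocket_residue_set <- function(x, ...) {
  tab <- table(x$role)
  cat("<pocket_residue_set>", nrow(x), "residues |",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Map alignment columns to structure residue numbers
#'
#' Matches the ungapped aligned sequence of `seq_id` to the chain's
#' residue sequence (3-to-1 letter translation): the k-th non-gap
#' character corresponds to the k-th residue of the chain. Sequences must
#' be the same length and at least `min_identity` identical.
#'
#' @param family An `aligned_family`.
#' @param seq_id Reference sequence id (e.g. the modeled protein).
#' @param struct A `structure_model`.
#' @param chain Chain identifier.
#' @param min_identity Identity required between sequence and chain
#'   (default 0.95).
#' @return Data frame with `column` (alignment column), `position`
#'   (1-based ungapped sequence position), `chain`, `resno`, `insert`,
#'   `aa`; one row per non-gap column of `seq_id`.
#' @export
map_columns_to_residues <- function(family, seq_id, struct, chain,
                                    min_identity = 0.95) {
  aligned <- family$records[[seq_id]]
  if (is.null(aligned)) stop("unknown sequence id: ", seq_id)
  ch <- strsplit(aligned, "")[[1]]
  seqres <- ch[ch != "-"]
  res <- residue_table(struct)
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) stop("no chain '", chain, "' in structure")
  chain_seq <- unname(AA3TO1[res$resid])
  chain_seq[is.na(chain_seq)] <- "X"
  if (length(seqres) != length(chain_seq))
    stop("sequence (", length(seqres), " aa) and chain (", length(chain_seq),
         " aa) differ in length")
  ident <- mean(seqres == chain_seq)
  if (ident < min_identity) {
    first <- which(seqres != chain_seq)[1L]
    stop(sprintf("sequence/structure identity %.1f%% below %.0f%%; first mismatch at position %d (%s vs %s)",
                 100 * ident, 100 * min_identity, first, seqres[first],
                 chain_seq[first]))
  }
  data.frame(column = which(ch != "-"),
             position = seq_along(seqres),
             chain = chain, resno = res$resno, insert = res$insert,
             aa = seqres, stringsAsFactors = FALSE)
}

#' Project a motif architecture onto structure residues
#'
#' @param arch A `motif_hits` architecture (ungapped sequence
#'   coordinates).
#' @param colmap Output of [map_columns_to_residues()].
#' @return `colmap` with an added `motif_id` column (`NA` where no motif
#'   covers the residue); non-overlap of architectures guarantees at most
#'   one label per residue.
#' @export
project_motifs <- function(arch, colmap) {
  colmap$motif_id <- NA_character_
  for (r in seq_len(nrow(arch))) {
    span <- colmap$position >= arch$start[r] & colmap$position <= arch$end[r]
    colmap$motif_id[span] <- as.character(arch$motif_id[r])
  }
  colmap
}

#' Motif composition of a pocket role set
#'
#' @param pocket A `pocket_residue_set`.
#' @param projection Output of [project_motifs()].
#' @param roles Roles to summarize (default substrate contact).
#' @return Sorted table of motif ids over the selected residues.
#' @export
pocket_motif_composition <- function(pocket, projection,
                                     roles = "substrate_contact") {
  sel <- pocket[pocket$role %in% roles, , drop = FALSE]
  m <- merge(sel[c("chain", "resno", "insert")], projection,
             by = c("chain", "resno", "insert"))
  sort(table(m$motif_id[!is.na(m$motif_id)]), decreasing = TRUE)
}

#' Export a pocket residue set as TSV
#' @param pocket A `pocket_residue_set`.
#' @param path Output path.
#' @export
write_pocket_tsv <- function(pocket, path) {
  utils::write.table(pocket, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
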