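# Pipeline orchestration: phylogeny -> motifs -> conservation -> pocket
# triage -> intersection report, with a reproducibility manifest.

#' Assemble and validate a pipeline configuration
#'
#' Either pass a YAML file path or a named list with the same layout.
#' Required entries: `alignment`, `groups` (file paths). Optional:
#' `motifs` (MEME minimal file), `structure` (PDB file), `site` (list
#' `substrate_het`, `fe_het`, `og_het`), `reference` (sequence id mapped
#' onto the structure), `chain` (default `"A"`), `clades` (two labels for
#' the clade-polymorphism channel), `out_dir`, `seed`, and stage
#' parameters `threshold` (0.8), `deletion` (`"partial"`), `coverage`
#' (0.95), `bootstrap` (0 = off), `substrate_cutoff` (5), `fe_cutoff`
#' (2.6), `og_cutoff` (3.5), `min_bits` (NULL = per-motif default).
#'
#' @param config YAML path or named list.
#' @return Validated config list of class `pipeline_config` with all
#'   defaults resolved.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(chain = "A", clades = NULL, out_dir = "sdpfinder_out",
                   seed = 1L, threshold = 0.8, deletion = "partial",
                   coverage = 0.95, bootstrap = 0L, substrate_cutoff = 5,
                   fe_cutoff = 2.6, og_cutoff = 3.5, min_bits = NULL,
                   motifs = NULL, structure = NULL, site = NULL,
                   reference = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- list(defaults[[nm]])
  for (nm in c("alignment", "groups"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")
  for (nm in c("alignment", "groups", "motifs", "structure")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("config path '", nm, "' does not exist: ", p)
  }
  if (!is.null(config$structure) && is.null(config$site))
    stop("a structure requires a 'site' entry (substrate_het/fe_het/og_het)")
  structure(config, class = "pipeline_config")
}

#' Run the full specificity-residue nomination pipeline
#'
#' Stage order: (1) phylogeny — Poisson-corrected NJ tree with optional
#' bootstrap; (2) motif scan — per-sequence architectures and
#' class-specificity of each motif; (3) conservation — column
#' classification and clade-polymorphism detection; (4) pocket —
#' structure triage into cofactor-coordinating and substrate-contact
#' residues; (5) report — intersection of clade-polymorphic columns and
#' class-characteristic motifs with the substrate-contact residue set.
#' Every output and a reproducibility manifest are written under
#' `out_dir`.
#'
#' @param config A [pipeline_config()], YAML path, or named list.
#' @return List of class `pipeline_result` with elements `family`,
#'   `tree`, `architectures`, `motif_classes`, `columns`, `polymorphisms`,
#'   `pocket`, `colmap`, `report` (named counts), `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  family <- stage("input", read_alignment(cfg$alignment, cfg$groups))
  policy <- deletion_policy(cfg$deletion, cfg$coverage)

  tree <- stage("phylo", {
    if (cfg$bootstrap > 0L) {
      bootstrap_support(family, policy, n_reps = cfg$bootstrap, seed = cfg$seed)
    } else {
      neighbor_joining(distance_matrix(family, policy))
    }
  })
  write_newick(tree, file.path(cfg$out_dir, "tree.nwk"))

  architectures <- NULL; motif_classes <- NULL; motifs <- NULL
  if (!is.null(cfg$motifs)) {
    motifs <- stage("motifscan", read_meme_minimal(cfg$motifs))
    architectures <- stage("motifscan", {
      a <- lapply(names(family$records), function(id)
        architecture(ungapped(family, id), motifs, cfg$min_bits))
      names(a) <- names(family$records)
      a
    })
    motif_classes <- classify_motif_specificity(architectures, family$class_of)
    write_hits_tsv(do.call(rbind, architectures),
                   file.path(cfg$out_dir, "architectures.tsv"))
    utils::write.table(motif_classes,
                       file.path(cfg$out_dir, "motif_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  columns <- stage("polymorph",
    classify_columns(family, clades = cfg$clades, threshold = cfg$threshold,
                     reference = cfg$reference))
  poly <- attr(columns, "polymorphisms")
  utils::write.table(columns, file.path(cfg$out_dir, "columns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(poly))
    utils::write.table(poly, file.path(cfg$out_dir, "polymorphisms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  pocket <- NULL; colmap <- NULL; site <- NULL
  if (!is.null(cfg$structure)) {
    pocket <- stage("pocket", {
      struct <- read_pdb(cfg$structure)
      site <- ligand_site(struct, cfg$site$substrate_het,
                           fe_het = if (is.null(cfg$site$fe_het)) "FE" else cfg$site$fe_het,
                           og_het = cfg$site$og_het)
      pcfg <- pocket_config(cfg$substrate_cutoff, cfg$fe_cutoff, cfg$og_cutoff)
      ps <- select_contact_residues(struct, site, pcfg)
      if (!is.null(cfg$reference))
        colmap <- map_columns_to_residues(family, cfg$reference, struct,
                                           cfg$chain)
      ps
    })
    write_pocket_tsv(pocket, file.path(cfg$out_dir, "pocket.tsv"))
  }

  report <- stage("report", {
    rep <- list(n_sequences = length(family$records), n_columns = family$ncols,
                n_core_conserved = sum(columns$category == "core_conserved"),
                n_class_characteristic = sum(columns$category == "class_characteristic"),
                n_clade_polymorphic = sum(columns$category == "clade_polymorphic"))
    if (!is.null(pocket)) {
      rep$n_pocket_within_cutoff <- sum(pocket$role != "none")
      rep$n_flagged <- sum(pocket$role %in% c("substrate_contact",
                                              "cofactor_coordinating"))
      rep$n_cofactor_coordinating <- sum(pocket$role == "cofactor_coordinating")
      rep$n_substrate_contact <- sum(pocket$role == "substrate_contact")
    }
    if (!is.null(pocket) && !is.null(colmap)) {
      contact <- pocket[pocket$role == "substrate_contact", , drop = FALSE]
      cm <- merge(contact[c("chain", "resno", "insert")], colmap,
                  by = c("chain", "resno", "insert"))
      # clade-polymorphic columns landing on substrate-contact residues
      if (!is.null(poly))
        rep$n_clade_polymorphic_contacts <- sum(cm$column %in% poly$column)
      # contact residues inside class-characteristic motifs of the
      # reference sequence's class
      if (!is.null(architectures) && !is.null(cfg$reference)) {
        refclass <- family$class_of[[cfg$reference]]
        charmotifs <- motif_classes$motif_id[
          motif_classes$category %in% c("exclusive", "predominant") &
          vapply(strsplit(motif_classes$classes, ","),
                 function(cl) refclass %in% cl, NA)]
        proj <- project_motifs(architectures[[cfg$reference]], colmap)
        pm <- merge(contact[c("chain", "resno", "insert")], proj,
                    by = c("chain", "resno", "insert"))
        rep$n_contacts_in_class_motifs <-
          sum(!is.na(pm$motif_id) & pm$motif_id %in% charmotifs)
      }
    }
    rep
  })

  manifest <- list(
    package = "sdpfinder",
    version = as.character(utils::packageVersion("sdpfinder")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("out_dir"))])
  jsonlite::write_json(list(report = report, manifest = manifest),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)

  structure(list(family = family, tree = tree, architectures = architectures,
                 motif_classes = motif_classes, columns = columns,
                 polymorphisms = poly, pocket = pocket, colmap = colmap,
                 site = site, report = report, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$report)) cat(sprintf("  %-28s %s\n", nm, x$report[[nm]]))
  invisible(x)
}
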