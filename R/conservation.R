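# Column classification (core / class-characteristic / clade-polymorphic),
# biochemical property annotation, and logo statistics.

#' The five amino-acid biochemical property tables
#'
#' Residues are grouped along five dimensions: charge, hydrophobicity,
#' size, polarity (H-bond capability) and sidechain flexibility. Two
#' residues are deliberately unclassified as printed in the source
#' tables: cysteine has no polarity label and glycine no flexibility
#' label. [annotate_property_change()] reports these through the
#' `unclassified` channel. `repair = TRUE` optionally adds C to non-polar
#' and G to high flexibility; it is off by default because fidelity to
#' the published tables is the contract.
#'
#' The tables are validated at load: charge, hydrophobicity and size must
#' cover all 20 residues; polarity must cover exactly the 19 without C and
#' flexibility the 19 without G; no residue may carry two labels in one
#' dimension.
#'
#' @param repair Add the two missing classifications (default `FALSE`).
#' @return Named list of five named lists (label -> residue vector), of
#'   class `property_tables`.
#' @export
property_tables <- function(repair = FALSE) {
  tabs <- list(
    charge = list(
      positive  = c("R", "H", "K"),
      negative  = c("D", "E"),
      uncharged = c("A", "N", "C", "Q", "G", "I", "L", "M", "F", "P",
                    "S", "T", "W", "Y", "V")),
    hydrophobicity = list(
      hydrophobic           = c("I", "L", "V", "C", "A", "M", "F"),
      `neutral/hydrophilic` = c("G", "Y", "W", "H", "K", "T", "R", "E",
                                "Q", "D", "N", "S", "P")),
    size = list(
      small  = c("A", "G", "C", "S"),
      medium = c("V", "T", "N", "P", "D"),
      large  = c("Q", "E", "H", "K", "R", "F", "Y", "W", "M", "I", "L")),
    polarity = list(
      `charged polar`   = c("H", "R", "K", "E", "D"),
      `uncharged polar` = c("Q", "T", "S", "N", "Y", "W"),
      `non-polar`       = c("A", "G", "V", "L", "I", "P", "F", "M")),
    flexibility = list(
      high       = c("K", "E", "M", "Q", "R"),
      moderate   = c("D", "F", "H", "I", "L", "N", "W", "Y"),
      low        = c("C", "S", "T", "V"),
      limited    = c("A"),
      restricted = c("P")))
  if (repair) {
    tabs$polarity$`non-polar` <- c(tabs$polarity$`non-polar`, "C")
    tabs$flexibility$high <- c(tabs$flexibility$high, "G")
  }
  validate_property_tables(tabs, repaired = repair)
  structure(tabs, class = "property_tables", repaired = repair)
}

validate_property_tables <- function(tabs, repaired = FALSE) {
  for (dim in names(tabs)) {
    all_res <- unlist(tabs[[dim]], use.names = FALSE)
    if (anyDuplicated(all_res))
      stop("property table '", dim, "': residue in two labels")
    expected <- switch(dim,
      polarity    = if (repaired) AA20 else setdiff(AA20, "C"),
      flexibility = if (repaired) AA20 else setdiff(AA20, "G"),
      AA20)
    if (!setequal(all_res, expected))
      stop("property table '", dim, "': coverage mismatch (",
           paste(sort(symdiff(all_res, expected)), collapse = ","), ")")
  }
  invisible(TRUE)
}

symdiff <- function(a, b) c(setdiff(a, b), setdiff(b, a))

property_label <- function(tabs, dim, aa) {
  for (lab in names(tabs[[dim]])) if (aa %in% tabs[[dim]][[lab]]) return(lab)
  NA_character_
}

#' Annotate the biochemical property change of a substitution
#'
#' @param aaA,aaB Standard one-letter residues (consensus of group A and
#'   group B at a column).
#' @param tables A [property_tables()] object.
#' @return List with `changes`: data frame (`dimension`, `from`, `to`) of
#'   dimensions where both residues are classified and the labels differ,
#'   and `unclassified`: character vector of dimensions where either
#'   residue lacks a label (C in polarity, G in flexibility).
#' @export
annotate_property_change <- function(aaA, aaB, tables = property_tables()) {
  if (!aaA %in% AA20 || !aaB %in% AA20)
    stop("non-standard residue: ", aaA, "/", aaB)
  changes <- data.frame(dimension = character(0), from = character(0),
                        to = character(0), stringsAsFactors = FALSE)
  unclassified <- character(0)
  for (dim in names(tables)) {
    la <- property_label(tables, dim, aaA)
    lb <- property_label(tables, dim, aaB)
    if (is.na(la) || is.na(lb)) {
      unclassified <- c(unclassified, dim)
    } else if (la != lb) {
      changes <- rbind(changes, data.frame(dimension = dim, from = la, to = lb,
                                           stringsAsFactors = FALSE))
    }
  }
  list(changes = changes, unclassified = unclassified)
}

#' Gap-excluded residue frequencies of an alignment column within a group
#'
#' @param family An `aligned_family`.
#' @param group Character vector of sequence ids (or a single clade/class
#'   label resolved via [group_ids()]).
#' @param column 1-based alignment column.
#' @return Named length-20 numeric vector summing to 1, with attributes
#'   `n_residues`, `n_gaps`, and `all_gap` flag (vector of zeros if the
#'   whole column is gapped in the group).
#' @export
column_frequencies <- function(family, group, column) {
  if (length(group) == 1L && !group %in% names(family$records))
    group <- group_ids(family, group)
  if (!length(group)) stop("empty group")
  if (column < 1L || column > family$ncols)
    stop("column ", column, " out of range 1..", family$ncols)
  ch <- vapply(family$records[group], function(s) substr(s, column, column), "")
  res <- ch[ch != "-"]
  freqs <- stats::setNames(rep(0, 20), AA20)
  if (length(res)) {
    tab <- table(factor(res[res %in% AA20], levels = AA20))
    if (sum(tab)) freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- AA20
  }
  attr(freqs, "n_residues") <- length(res)
  attr(freqs, "n_gaps") <- sum(ch == "-")
  attr(freqs, "all_gap") <- length(res) == 0L
  freqs
}

#' Information content of a frequency vector
#'
#' `IC = log2(20) - H(freqs)` in bits, without small-sample correction;
#' the height of a sequence-logo stack.
#'
#' @param freqs Frequency vector summing to 1 (zeros allowed).
#' @return Bits in `[0, log2(20)]`.
#' @export
information_content <- function(freqs) {
  p <- freqs[freqs > 0]
  log2(20) - sum(-p * log2(p))
}

#' Consensus residue of a group at a column
#'
#' @inheritParams column_frequencies
#' @param threshold Gap-excluded frequency a residue must reach,
#'   in `(0.5, 1]` (default 0.8, the 80-100% conservation shading bin
#'   boundary).
#' @param max_gap_fraction A column with more than this fraction of gaps
#'   in the group yields no consensus (default 0.5).
#' @return Single residue character, or `NA_character_` if no residue
#'   reaches the threshold or the column is too gapped.
#' @export
group_consensus <- function(family, group, column, threshold = 0.8,
                            max_gap_fraction = 0.5) {
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must be in (0.5, 1]")
  f <- column_frequencies(family, group, column)
  ng <- attr(f, "n_gaps"); nr <- attr(f, "n_residues")
  if (nr == 0L || ng / (ng + nr) > max_gap_fraction) return(NA_character_)
  top <- which.max(f)
  if (f[top] >= threshold) AA20[top] else NA_character_
}

#' Detect clade-conserved polymorphic columns between two groups
#'
#' A column is a conserved polymorphism when both groups have a consensus
#' residue (gap-excluded frequency >= `threshold`) and the two consensus
#' residues differ. Each record is annotated with the biochemical property
#' changes of the substitution.
#'
#' @param family An `aligned_family`.
#' @param groupA,groupB Disjoint id vectors or clade/class labels.
#' @param threshold Consensus threshold (default 0.8).
#' @param tables A [property_tables()].
#' @return A data frame of class `polymorphism_records` with columns
#'   `column`, `consensusA`, `consensusB`, `property_changes` (semicolon
#'   list of `dimension: from->to`), `n_changes`, `unclassified`
#'   (semicolon list); plus attribute `details`, a list of
#'   [annotate_property_change()] results keyed by column.
#' @export
detect_group_polymorphisms <- function(family, groupA, groupB, threshold = 0.8,
                                       tables = property_tables()) {
  if (length(groupA) == 1L && !groupA %in% names(family$records))
    groupA <- group_ids(family, groupA)
  if (length(groupB) == 1L && !groupB %in% names(family$records))
    groupB <- group_ids(family, groupB)
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  rows <- list(); details <- list()
  for (col in seq_len(family$ncols)) {
    ca <- group_consensus(family, groupA, col, threshold)
    cb <- group_consensus(family, groupB, col, threshold)
    if (is.na(ca) || is.na(cb) || ca == cb) next
    ann <- annotate_property_change(ca, cb, tables)
    pc <- if (nrow(ann$changes))
      paste(sprintf("%s: %s->%s", ann$changes$dimension, ann$changes$from,
                    ann$changes$to), collapse = "; ") else ""
    rows[[length(rows) + 1L]] <- data.frame(
      column = col, consensusA = ca, consensusB = cb,
      property_changes = pc, n_changes = nrow(ann$changes),
      unclassified = paste(ann$unclassified, collapse = "; "),
      stringsAsFactors = FALSE)
    details[[as.character(col)]] <- ann
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(0), consensusA = character(0),
               consensusB = character(0), property_changes = character(0),
               n_changes = integer(0), unclassified = character(0))
  attr(out, "details") <- details
  attr(out, "threshold") <- threshold
  class(out) <- c("polymorphism_records", "data.frame")
  out
}

shading_bin <- function(freq) {
  if (freq >= 1) "100"
  else if (freq >= 0.8) "80-100"
  else if (freq >= 0.6) "60-80"
  else "<60"
}

#' Classify every alignment column
#'
#' Applies the column taxonomy: `core_conserved` when a single residue is
#' the consensus of every class; `class_characteristic` when one class has
#' a consensus that differs from the shared consensus of all other
#' classes; `clade_polymorphic` (between the two designated clades) per
#' [detect_group_polymorphisms()]; otherwise `unconserved`. Structure-side
#' pocket flags are attached orthogonally, and each column gets the
#' conservation shading bin of its pooled majority-residue prevalence
#' (100, 80-100, 60-80, <60).
#'
#' @param family An `aligned_family` (>= 2 classes).
#' @param clades Optional character vector of two clade labels for the
#'   clade-polymorphism channel.
#' @param pocket_flags Optional data frame with columns `column` and
#'   `flag` (e.g. `"pocket_lining"`, `"substrate_contact"`) from the
#'   structure module.
#' @param threshold Consensus threshold (default 0.8).
#' @param others One of `"strict"` (all other classes share one consensus;
#'   default) or `"majority"` (majority residue of the pooled others).
#' @param reference Optional sequence id; adds `ref_position`, the 1-based
#'   ungapped position in that sequence (NA at its gap columns).
#' @param tables A [property_tables()].
#' @return A data frame of class `column_report`: `column`, `category`,
#'   `detail` (class or clade pair), `shading`, per-class consensus
#'   columns, `pocket_flag`, optional `ref_position`.
#' @export
classify_columns <- function(family, clades = NULL, pocket_flags = NULL,
                             threshold = 0.8,
                             others = c("strict", "majority"),
                             reference = NULL, tables = property_tables()) {
  others <- match.arg(others)
  classes <- unique(family$class_of)
  if (length(classes) < 2L) stop("need at least 2 classes")
  class_members <- lapply(classes, function(cl)
    names(family$class_of)[family$class_of == cl])
  names(class_members) <- classes
  small <- classes[vapply(class_members, length, 0L) < 2L]
  if (length(small)) {
    warning("classes with <2 members skipped: ", paste(small, collapse = ", "))
    classes <- setdiff(classes, small)
  }
  poly <- NULL
  if (!is.null(clades)) {
    stopifnot(length(clades) == 2L)
    poly <- detect_group_polymorphisms(family, clades[1L], clades[2L],
                                       threshold, tables)
  }
  all_ids <- names(family$records)
  mat <- family_matrix(family)
  ref_pos <- NULL
  if (!is.null(reference)) {
    refrow <- strsplit(family$records[[reference]], "")[[1]]
    ref_pos <- ifelse(refrow == "-", NA_integer_, cumsum(refrow != "-"))
  }
  reports <- vector("list", family$ncols)
  for (col in seq_len(family$ncols)) {
    cons <- vapply(classes, function(cl)
      group_consensus(family, class_members[[cl]], col, threshold),
      NA_character_)
    category <- "unconserved"; detail <- ""
    if (!anyNA(cons) && length(unique(cons)) == 1L) {
      category <- "core_conserved"
    } else {
      for (cl in classes) {
        rest <- setdiff(classes, cl)
        if (is.na(cons[[cl]])) next
        if (others == "strict") {
          rest_cons <- cons[rest]
          if (!anyNA(rest_cons) && length(unique(rest_cons)) == 1L &&
              unique(rest_cons) != cons[[cl]]) {
            category <- "class_characteristic"; detail <- cl
            break
          }
        } else {
          pooled <- unlist(class_members[rest], use.names = FALSE)
          f <- column_frequencies(family, pooled, col)
          maj <- AA20[which.max(f)]
          if (max(f) > 0.5 && maj != cons[[cl]]) {
            category <- "class_characteristic"; detail <- cl
            break
          }
        }
      }
    }
    if (!is.null(poly) && col %in% poly$column && category != "core_conserved") {
      category <- "clade_polymorphic"
      detail <- paste(clades, collapse = ",")
    }
    colchars <- mat[, col]
    resid <- colchars[colchars != "-"]
    pooled_major <- if (length(resid)) max(table(resid)) / length(resid) else 0
    reports[[col]] <- data.frame(
      column = col, category = category, detail = detail,
      shading = shading_bin(pooled_major),
      stringsAsFactors = FALSE)
    for (cl in classes) reports[[col]][[paste0("consensus_", cl)]] <- cons[[cl]]
  }
  out <- do.call(rbind, reports)
  out$pocket_flag <- ""
  if (!is.null(pocket_flags) && nrow(pocket_flags)) {
    m <- match(out$column, pocket_flags$column)
    out$pocket_flag <- ifelse(is.na(m), "", as.character(pocket_flags$flag[m]))
  }
  if (!is.null(ref_pos)) out$ref_position <- ref_pos
  attr(out, "polymorphisms") <- poly
  attr(out, "threshold") <- threshold
  class(out) <- c("column_report", "data.frame")
  out
}

#' Export per-column logo data (stacked frequencies + IC) as TSV
#'
#' @param family An `aligned_family`.
#' @param group Id vector or group label.
#' @param path Output path.
#' @return The data frame written, invisibly: one row per (column,
#'   residue) with `freq`, plus per-column `ic` bits.
#' @export
write_logo_tsv <- function(family, group, path) {
  if (length(group) == 1L && !group %in% names(family$records))
    group <- group_ids(family, group)
  rows <- list()
  for (col in seq_len(family$ncols)) {
    f <- column_frequencies(family, group, col)
    ic <- information_content(f)
    nz <- which(f > 0)
    if (!length(nz)) next
    rows[[col]] <- data.frame(column = col, residue = AA20[nz],
                              freq = unname(f[nz]), ic = ic)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
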