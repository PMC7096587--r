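# Sequence I/O, group assignments, and pairwise identity/similarity.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in the conventional
#' substitution-matrix order, plus `"X"` for an unknown residue.
#'
#' @format Character vectors.
#' @name alphabet
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA21 <- c(AA20, "X")

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A list of `protein_sequence` objects, one per record, in file
#'   order. Each has fields `id` (first whitespace-delimited header token),
#'   `residues` (upper-case), and `description` (remainder of the header).
#' @details Residues are validated against the 20 standard one-letter codes
#'   plus `X`; any other character is an error naming the record and the
#'   offending position. Gap characters are not allowed here; use
#'   [read_alignment()] for aligned FASTA.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            whole.header = TRUE)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  lapply(raw, function(r) {
    header <- attr(r, "name")
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1L]
    desc <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else ""
    protein_sequence(id, as.character(r), description = desc)
  })
}

#' Construct a validated protein sequence
#'
#' @param id Sequence identifier (accession or label).
#' @param residues Residue string; upper-cased on input.
#' @param description Optional free-text description.
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, description = "") {
  residues <- toupper(gsub("\\s", "", residues))
  if (nchar(residues) == 0L) stop("sequence '", id, "' is empty")
  ch <- strsplit(residues, "")[[1]]
  bad <- which(!ch %in% AA21)
  if (length(bad)) {
    stop("sequence '", id, "': illegal residue '", ch[bad[1L]],
         "' at position ", bad[1L])
  }
  structure(list(id = id, residues = residues, description = description),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence>", x$id, paste0("(", nchar(x$residues), " aa)\n"))
  invisible(x)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A list of `protein_sequence` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(lapply(seqs, function(s) s$residues),
                      names = vapply(seqs, function(s) {
                        if (nzchar(s$description))
                          paste(s$id, s$description) else s$id
                      }, ""),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Read an aligned protein family with class/clade assignments
#'
#' Reads a MUSCLE-style aligned FASTA (all records the same length, `-`
#' for gaps) plus a tab-separated groups file with columns
#' `id<TAB>class[<TAB>clade]` and `#` comment lines.
#'
#' @param path Aligned FASTA path.
#' @param groups_path Groups file path.
#' @return An [aligned_family()] object.
#' @export
read_alignment <- function(path, groups_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            whole.header = TRUE)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(raw, function(r) strsplit(trimws(attr(r, "name")), "\\s+")[[1]][1], "")
  aln <- toupper(vapply(raw, as.character, ""))
  names(aln) <- ids
  grp <- read_groups(groups_path)
  aligned_family(aln, class_of = grp$class_of, clade_of = grp$clade_of)
}

#' Read a groups file
#'
#' @param path Tab-separated file `id<TAB>class[<TAB>clade]`, `#` comments.
#' @return A list with named character vectors `class_of` and `clade_of`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("groups file needs at least id and class columns")
  class_of <- stats::setNames(tab[[2L]], tab[[1L]])
  clade_of <- if (ncol(tab) >= 3L) {
    cl <- stats::setNames(tab[[3L]], tab[[1L]])
    cl[nzchar(cl)]
  } else stats::setNames(character(0), character(0))
  list(class_of = class_of, clade_of = clade_of)
}

#' Construct a validated aligned family
#'
#' The container all sequence-side stages operate on: aligned residues,
#' one class label per sequence, and optional clade labels.
#'
#' @param records Named character vector of equal-length aligned strings
#'   (gaps as `-`); names are sequence ids.
#' @param class_of Named character vector mapping every id to a class label.
#' @param clade_of Optional named character vector mapping ids to clades.
#' @return An object of class `aligned_family` with fields `records`,
#'   `class_of`, `clade_of`, `ncols`.
#' @export
aligned_family <- function(records, class_of, clade_of = NULL) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named by sequence id")
  ids <- names(records)
  if (anyDuplicated(ids)) stop("duplicate ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- toupper(records)
  lens <- nchar(records)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != stats::median(lens)]
    stop("ragged alignment; offending sequences: ", paste(off, collapse = ", "))
  }
  ok <- vapply(strsplit(records, ""), function(ch) all(ch %in% c(AA21, "-")), NA)
  if (any(!ok)) stop("illegal characters in: ", paste(ids[!ok], collapse = ", "))
  missing <- setdiff(ids, names(class_of))
  if (length(missing)) stop("ids missing from groups: ",
                            paste(missing, collapse = ", "))
  if (is.null(clade_of)) clade_of <- stats::setNames(character(0), character(0))
  structure(list(records = records,
                 class_of = class_of[ids],
                 clade_of = clade_of[intersect(ids, names(clade_of))],
                 ncols = unname(lens[1L])),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("<aligned_family>", length(x$records), "sequences x", x$ncols,
      "columns;", length(unique(x$class_of)), "classes\n")
  invisible(x)
}

#' Write an aligned family back to aligned FASTA
#' @param family An `aligned_family`.
#' @param path Output path.
#' @export
write_alignment <- function(family, path) {
  seqinr::write.fasta(as.list(family$records), names = names(family$records),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Ids belonging to a clade (or class) label
#' @param family An `aligned_family`.
#' @param label Clade label (looked up first) or class label.
#' @return Character vector of sequence ids.
#' @export
group_ids <- function(family, label) {
  ids <- names(family$clade_of)[family$clade_of == label]
  if (!length(ids)) ids <- names(family$class_of)[family$class_of == label]
  if (!length(ids)) stop("no sequences labeled '", label, "'")
  ids
}

# ---- substitution matrix ---------------------------------------------------

#' Read an NCBI-format substitution matrix
#'
#' @param path Path to an NCBI-format matrix text file (rows/columns headed
#'   by one-letter residue codes, `#` comments). Defaults to the bundled
#'   BLOSUM62.
#' @param name Matrix name stored on the object.
#' @return A `substitution_matrix`: a symmetric integer matrix over the 20
#'   standard residues with a `name` attribute.
#' @export
read_substitution_matrix <- function(path = system.file("extdata", "BLOSUM62.txt",
                                                        package = "sdpfinder"),
                                     name = "BLOSUM62") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(NA_integer_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, "", 1L), header))
  for (i in seq_along(rows)) m[i, ] <- as.integer(rows[[i]][-1L])
  m <- m[AA20, AA20]
  if (!isSymmetric(unname(m))) stop("substitution matrix is not symmetric")
  if (anyNA(m)) stop("substitution matrix incomplete over the 20 residues")
  structure(m, name = name, class = c("substitution_matrix", class(m)))
}

#' The bundled BLOSUM62 matrix
#' @return A `substitution_matrix` (cached per session).
#' @export
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_substitution_matrix()
    cache
  }
})

#' Look up a substitution score
#'
#' `X` (unknown residue) scores 0 against everything.
#'
#' @param matrix A `substitution_matrix`.
#' @param a,b One-letter residue codes.
#' @return Integer score.
#' @export
sub_score <- function(matrix, a, b) {
  if (a == "X" || b == "X") return(0L)
  matrix[a, b]
}

#' Similarity configuration
#'
#' Bundles the scoring scheme used by [pairwise_align()],
#' [percent_identity()] and [percent_similarity()]. A residue pair counts
#' as "similar" when its matrix score is at least `similar_threshold`;
#' with BLOSUM62 and the default threshold of 1 every identical standard
#' pair is also similar (the BLOSUM62 diagonal is >= 1 throughout).
#'
#' @param matrix A `substitution_matrix`; defaults to BLOSUM62.
#' @param similar_threshold Minimum matrix score for a pair to count as
#'   similar (default 1).
#' @param gap_open Penalty for the first residue of a gap (default 10,
#'   the EMBOSS-needle convention).
#' @param gap_extend Penalty for each subsequent gapped residue (default 0.5).
#' @param denominator One of `"ungapped_columns"` (columns with residues in
#'   both sequences; default), `"alignment_length"` (all columns except
#'   gap-gap), or `"shorter_sequence"`.
#' @return A list of class `similarity_config`.
#' @export
similarity_config <- function(matrix = blosum62(), similar_threshold = 1L,
                              gap_open = 10, gap_extend = 0.5,
                              denominator = c("ungapped_columns",
                                              "alignment_length",
                                              "shorter_sequence")) {
  denominator <- match.arg(denominator)
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, similar_threshold = similar_threshold,
                 gap_open = gap_open, gap_extend = gap_extend,
                 denominator = denominator),
            class = "similarity_config")
}

# ---- pairwise global alignment (Gotoh affine) ------------------------------

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment maximizing the substitution
#' score under an affine gap cost: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Traceback is deterministic with the
#' fixed preference diagonal > up (gap in `b`) > left (gap in `a`).
#'
#' @param a,b `protein_sequence` objects (or plain residue strings).
#' @param cfg A [similarity_config()].
#' @return A list of class `pairwise_alignment` with gapped strings
#'   `aligned_a`, `aligned_b` and the optimal `score`.
#' @export
pairwise_align <- function(a, b, cfg = similarity_config()) {
  sa <- if (inherits(a, "protein_sequence")) a$residues else toupper(a)
  sb <- if (inherits(b, "protein_sequence")) b$residues else toupper(b)
  if (!nchar(sa) || !nchar(sb)) stop("sequences must be non-empty")
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  n <- length(ca); m <- length(cb)
  go <- cfg$gap_open; ge <- cfg$gap_extend
  smat <- cfg$matrix
  score_pair <- function(x, y) if (x == "X" || y == "X") 0 else smat[x, y]

  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in residue-residue column
  X <- matrix(NEG, n + 1L, m + 1L)  # ends with gap in b (consume a; "up")
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends with gap in a (consume b; "left")
  M[1L, 1L] <- 0
  if (n >= 1L) X[2:(n + 1L), 1L] <- -(go + (seq_len(n) - 1L) * ge)
  if (m >= 1L) Y[1L, 2:(m + 1L)] <- -(go + (seq_len(m) - 1L) * ge)

  for (i in seq_len(n)) {
    si <- if (ca[i] == "X") NULL else smat[ca[i], , drop = TRUE]
    for (j in seq_len(m)) {
      s <- if (ca[i] == "X" || cb[j] == "X") 0 else si[[cb[j]]]
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go, X[i, j + 1L] - ge,
                               Y[i, j + 1L] - go)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go, X[i + 1L, j] - go,
                               Y[i + 1L, j] - ge)
    }
  }
  final <- c(M = M[n + 1L, m + 1L], X = X[n + 1L, m + 1L], Y = Y[n + 1L, m + 1L])
  state <- c("M", "X", "Y")[which.max(final)]  # which.max: first max -> M>X>Y
  score <- max(final)

  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      s <- score_pair(ca[i], cb[j])
      prev <- c(M[i, j], X[i, j], Y[i, j]) + s
      k <- which(abs(prev - M[i + 1L, j + 1L]) < eps)[1L]
      out_a <- c(ca[i], out_a); out_b <- c(cb[j], out_b)
      i <- i - 1L; j <- j - 1L
      state <- c("M", "X", "Y")[k]
    } else if (state == "X") {
      prev <- c(M[i, j + 1L] - go, X[i, j + 1L] - ge, Y[i, j + 1L] - go)
      k <- which(abs(prev - X[i + 1L, j + 1L]) < eps)[1L]
      out_a <- c(ca[i], out_a); out_b <- c("-", out_b)
      i <- i - 1L
      state <- c("M", "X", "Y")[k]
    } else {
      prev <- c(M[i + 1L, j] - go, X[i + 1L, j] - go, Y[i + 1L, j] - ge)
      k <- which(abs(prev - Y[i + 1L, j + 1L]) < eps)[1L]
      out_a <- c("-", out_a); out_b <- c(cb[j], out_b)
      j <- j - 1L
      state <- c("M", "X", "Y")[k]
    }
    if (i == 0L && j > 0L) state <- "Y"
    if (j == 0L && i > 0L) state <- "X"
  }
  structure(list(aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = unname(score)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score =", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

column_mask <- function(cha, chb, denominator, na, nb) {
  both_res <- cha != "-" & chb != "-"
  denom <- switch(denominator,
                  ungapped_columns = sum(both_res),
                  alignment_length = sum(cha != "-" | chb != "-"),
                  shorter_sequence = min(na, nb))
  list(both = both_res, denom = denom)
}

#' Percent identity of two gapped strings
#'
#' @param alnA,alnB Equal-length gapped strings (an aligned pair).
#' @param denominator Denominator policy; see [similarity_config()].
#' @return Percentage in `[0, 100]`. Gap-gap columns are never counted;
#'   `X` never counts as identical.
#' @export
percent_identity <- function(alnA, alnB,
                             denominator = c("ungapped_columns",
                                             "alignment_length",
                                             "shorter_sequence")) {
  denominator <- match.arg(denominator)
  cha <- strsplit(toupper(alnA), "")[[1]]; chb <- strsplit(toupper(alnB), "")[[1]]
  if (length(cha) != length(chb)) stop("aligned strings differ in length")
  cm <- column_mask(cha, chb, denominator,
                    sum(cha != "-"), sum(chb != "-"))
  if (cm$denom == 0L) stop("zero denominator")
  ident <- sum(cm$both & cha == chb & cha != "X")
  100 * ident / cm$denom
}

#' Percent similarity of two gapped strings
#'
#' A residue pair is similar when its substitution-matrix score is at
#' least `cfg$similar_threshold` (the ">= 1 BLOSUM62 score" criterion);
#' `X` is never similar.
#'
#' @inheritParams percent_identity
#' @param cfg A [similarity_config()]; supplies matrix, threshold and
#'   denominator policy.
#' @return Percentage in `[0, 100]`.
#' @export
percent_similarity <- function(alnA, alnB, cfg = similarity_config()) {
  cha <- strsplit(toupper(alnA), "")[[1]]; chb <- strsplit(toupper(alnB), "")[[1]]
  if (length(cha) != length(chb)) stop("aligned strings differ in length")
  cm <- column_mask(cha, chb, cfg$denominator,
                    sum(cha != "-"), sum(chb != "-"))
  if (cm$denom == 0L) stop("zero denominator")
  idx <- which(cm$both)
  sim <- sum(vapply(idx, function(k) {
    if (cha[k] == "X" || chb[k] == "X") return(FALSE)
    cfg$matrix[cha[k], chb[k]] >= cfg$similar_threshold
  }, NA))
  100 * sim / cm$denom
}

#' Ungapped residues of an aligned record
#' @param family An `aligned_family`.
#' @param id Sequence id.
#' @return Residue string with gaps removed.
#' @export
ungapped <- function(family, id) {
  if (!id %in% names(family$records)) stop("unknown id: ", id)
  gsub("-", "", family$records[[id]], fixed = TRUE)
}
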