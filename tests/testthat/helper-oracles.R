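# Independent oracles and fixture builders used across the suite.

AAset <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AAset, n, replace = TRUE), collapse = "")

# --- exhaustive global-alignment oracle (lengths <= ~7) ----------------------
# Enumerates every monotone alignment path, renders the two gapped strings,
# and scores them with an independent run-scanning cost function.

score_gapped_pair <- function(ga, gb, cfg) {
  cha <- strsplit(ga, "")[[1]]; chb <- strsplit(gb, "")[[1]]
  total <- 0
  for (k in seq_along(cha)) {
    if (cha[k] != "-" && chb[k] != "-")
      total <- total + cfg$matrix[cha[k], chb[k]]
  }
  gap_cost <- function(s) {
    runs <- regmatches(s, gregexpr("-+", s))[[1]]
    sum(vapply(runs, function(r)
      cfg$gap_open + (nchar(r) - 1L) * cfg$gap_extend, 0))
  }
  total - gap_cost(ga) - gap_cost(gb)
}

enumerate_alignments <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  out <- list()
  recurse <- function(i, j, sa, sb) {
    if (i > length(ca) && j > length(cb)) {
      out[[length(out) + 1L]] <<- c(sa, sb)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1L, j + 1L, paste0(sa, ca[i]), paste0(sb, cb[j]))
    if (i <= length(ca))
      recurse(i + 1L, j, paste0(sa, ca[i]), paste0(sb, "-"))
    if (j <= length(cb))
      recurse(i, j + 1L, paste0(sa, "-"), paste0(sb, cb[j]))
  }
  recurse(1L, 1L, "", "")
  out
}

best_alignment_score_enum <- function(a, b, cfg) {
  max(vapply(enumerate_alignments(a, b),
             function(al) score_gapped_pair(al[1], al[2], cfg), 0))
}

# --- independent brute-force pocket-role oracle ------------------------------

brute_force_roles <- function(struct, site, cfg = pocket_config()) {
  at <- struct$atoms
  ids <- unique(at[c("chain", "resno", "insert")])
  roles <- character(nrow(ids))
  for (i in seq_len(nrow(ids))) {
    sel <- at$chain == ids$chain[i] & at$resno == ids$resno[i] &
      at$insert == ids$insert[i]
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    dmin <- Inf
    for (r in seq_len(nrow(xyz))) for (p in seq_len(nrow(site$substrate_atoms)))
      dmin <- min(dmin, sqrt(sum((xyz[r, ] - site$substrate_atoms[p, ])^2)))
    sc <- at[sel & !at$elety %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
    ca <- at[sel & at$elety == "CA", , drop = FALSE]
    inward <- FALSE; fe_d <- Inf; og_d <- Inf
    if (nrow(sc) > 0L && nrow(ca) == 1L) {
      cent <- colMeans(as.matrix(sc[c("x", "y", "z")]))
      cav <- as.numeric(ca[1, c("x", "y", "z")])
      inward <- sqrt(sum((cent - site$reaction_center)^2)) <
        sqrt(sum((cav - site$reaction_center)^2))
      for (r in seq_len(nrow(sc))) {
        v <- as.numeric(sc[r, c("x", "y", "z")])
        fe_d <- min(fe_d, sqrt(sum((v - site$fe_site)^2)))
        if (!is.null(site$og_site))
          for (p in seq_len(nrow(site$og_site)))
            og_d <- min(og_d, sqrt(sum((v - site$og_site[p, ])^2)))
      }
    }
    within <- dmin <= cfg$substrate_cutoff
    flagged <- within && inward
    cof <- flagged && (fe_d <= cfg$fe_cutoff || og_d <= cfg$og_cutoff)
    roles[i] <- if (cof) "cofactor_coordinating"
    else if (flagged) "substrate_contact"
    else if (within) "pocket_lining_only"
    else "none"
  }
  data.frame(ids, role = roles, stringsAsFactors = FALSE)
}

# --- small builders ----------------------------------------------------------

make_family <- function(records, classes, clades = NULL) {
  ids <- names(records)
  aligned_family(records,
                 class_of = stats::setNames(classes, ids),
                 clade_of = if (is.null(clades)) NULL
                            else stats::setNames(clades, ids))
}

sharp_pwm <- function(consensus, p = 0.905) {
  ch <- strsplit(consensus, "")[[1]]
  t(vapply(ch, function(a) {
    v <- rep((1 - p) / 19, 20)
    names(v) <- AAset
    v[a] <- p
    v
  }, numeric(20)))
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# additive distance matrix from a random tree with safe edge lengths
random_additive_matrix <- function(ntaxa) {
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  list(tree = ape::unroot(tr), D = stats::cophenetic(tr))
}

# Independent copy of the five property groupings, typed directly from the
# published legend, used as the lookup oracle against the package tables.
ORACLE_PROPS <- list(
  charge = c(R = "positive", H = "positive", K = "positive",
             D = "negative", E = "negative",
             A = "uncharged", N = "uncharged", C = "uncharged",
             Q = "uncharged", G = "uncharged", I = "uncharged",
             L = "uncharged", M = "uncharged", F = "uncharged",
             P = "uncharged", S = "uncharged", T = "uncharged",
             W = "uncharged", Y = "uncharged", V = "uncharged"),
  hydrophobicity = c(I = "hydrophobic", L = "hydrophobic", V = "hydrophobic",
                     C = "hydrophobic", A = "hydrophobic", M = "hydrophobic",
                     F = "hydrophobic",
                     G = "neutral/hydrophilic", Y = "neutral/hydrophilic",
                     W = "neutral/hydrophilic", H = "neutral/hydrophilic",
                     K = "neutral/hydrophilic", T = "neutral/hydrophilic",
                     R = "neutral/hydrophilic", E = "neutral/hydrophilic",
                     Q = "neutral/hydrophilic", D = "neutral/hydrophilic",
                     N = "neutral/hydrophilic", S = "neutral/hydrophilic",
                     P = "neutral/hydrophilic"),
  size = c(A = "small", G = "small", C = "small", S = "small",
           V = "medium", T = "medium", N = "medium", P = "medium",
           D = "medium",
           Q = "large", E = "large", H = "large", K = "large", R = "large",
           F = "large", Y = "large", W = "large", M = "large", I = "large",
           L = "large"),
  polarity = c(H = "charged polar", R = "charged polar", K = "charged polar",
               E = "charged polar", D = "charged polar",
               Q = "uncharged polar", T = "uncharged polar",
               S = "uncharged polar", N = "uncharged polar",
               Y = "uncharged polar", W = "uncharged polar",
               A = "non-polar", G = "non-polar", V = "non-polar",
               L = "non-polar", I = "non-polar", P = "non-polar",
               F = "non-polar", M = "non-polar"),
  flexibility = c(K = "high", E = "high", M = "high", Q = "high", R = "high",
                  D = "moderate", F = "moderate", H = "moderate",
                  I = "moderate", L = "moderate", N = "moderate",
                  W = "moderate", Y = "moderate",
                  C = "low", S = "low", T = "low", V = "low",
                  A = "limited", P = "restricted"))

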