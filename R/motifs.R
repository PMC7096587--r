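# Motif models (PWMs), MEME minimal I/O, scanning, architectures,
# class-specificity, and a single-motif ZOOPS EM for testing.

#' Construct a motif model (position weight matrix)
#'
#' @param motif_id Motif identifier (integer or string).
#' @param pwm `width x 20` matrix of letter probabilities; columns named by
#'   the standard residue order. Each row must sum to 1 (to 1e-9) before
#'   smoothing.
#' @param background Length-20 background probabilities (default uniform).
#' @param pseudocount Fraction added per letter before renormalization
#'   (default 0.01); applied once, at construction.
#' @return An object of class `motif_model` with fields `motif_id`,
#'   `width`, `pwm` (smoothed), `pwm_raw`, `background`, `pseudocount`.
#' @details Widths outside the working range `[6, 50]` are allowed by the
#'   constructor (toy tests use shorter motifs) but flagged with a warning
#'   outside `[1, 200]`-free validity; [read_meme_minimal()] enforces
#'   `[1, 200]`.
#' @export
motif_model <- function(motif_id, pwm, background = rep(1 / 20, 20),
                        pseudocount = 0.01) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 20L) stop("pwm must have 20 columns")
  if (is.null(colnames(pwm))) colnames(pwm) <- AA20 else pwm <- pwm[, AA20, drop = FALSE]
  if (any(abs(rowSums(pwm) - 1) > 1e-9)) stop("pwm rows must each sum to 1")
  if (any(pwm < 0)) stop("pwm probabilities must be non-negative")
  rownames(pwm) <- NULL
  background <- background / sum(background)
  names(background) <- AA20
  sm <- (pwm + pseudocount) / (1 + 20 * pseudocount)
  structure(list(motif_id = motif_id, width = nrow(pwm), pwm = sm,
                 pwm_raw = pwm, background = background,
                 pseudocount = pseudocount),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model>", x$motif_id, "width", x$width,
      "consensus", motif_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a motif (highest-probability letter per position)
#' @param motif A `motif_model`.
#' @return Character string of length `width`.
#' @export
motif_consensus <- function(motif) {
  paste(AA20[apply(motif$pwm_raw, 1L, which.max)], collapse = "")
}

#' Read motifs from MEME minimal text format
#'
#' Parses the `MEME version` line, optional `Background letter
#' frequencies` block, and each `MOTIF` / `letter-probability matrix`
#' block. The alphabet must be the 20-letter protein alphabet.
#'
#' @param path Path to a MEME minimal format file.
#' @param pseudocount Passed to [motif_model()].
#' @return List of `motif_model` objects.
#' @export
read_meme_minimal <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines)))
    stop("not MEME minimal format: missing 'MEME version' line")
  alph_i <- grep("^ALPHABET", lines)
  alphabet <- if (length(alph_i)) gsub("^ALPHABET=\\s*", "", lines[alph_i[1L]]) else NULL
  background <- rep(1 / 20, 20)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    bg_toks <- character(0)
    j <- bg_i[1L] + 1L
    while (j <= length(lines) && nzchar(trimws(lines[j])) &&
           !grepl("^MOTIF", lines[j])) {
      bg_toks <- c(bg_toks, strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(bg_toks) >= 2L) {
      lets <- bg_toks[seq(1L, length(bg_toks), 2L)]
      vals <- as.numeric(bg_toks[seq(2L, length(bg_toks), 2L)])
      bg <- stats::setNames(rep(1 / 20, 20), AA20)
      bg[lets[lets %in% AA20]] <- vals[lets %in% AA20]
      background <- bg / sum(bg)
    }
  }
  motif_i <- grep("^MOTIF", lines)
  if (!length(motif_i)) stop("no MOTIF blocks found")
  out <- vector("list", length(motif_i))
  for (k in seq_along(motif_i)) {
    mline <- strsplit(trimws(lines[motif_i[k]]), "\\s+")[[1]]
    mid <- mline[2L]
    lp <- grep("^letter-probability matrix", lines)
    lp <- lp[lp > motif_i[k]][1L]
    if (is.na(lp)) stop("motif ", mid, ": missing letter-probability matrix")
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[lp]))
    if (is.na(w) || w < 1L || w > 200L)
      stop("motif ", mid, ": width ", w, " outside [1, 200]")
    rows <- lines[(lp + 1L):(lp + w)]
    pwm <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                    numeric(20)))
    if (any(abs(rowSums(pwm) - 1) > 1e-3))
      stop("motif ", mid, ": matrix rows do not sum to 1")
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- AA20
    out[[k]] <- motif_model(mid, pwm, background, pseudocount)
  }
  out
}

#' Write motifs in MEME minimal text format
#' @param motifs List of `motif_model` objects.
#' @param path Output path.
#' @export
write_meme_minimal <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", ""), con)
  bg <- motifs[[1L]]$background
  writeLines("Background letter frequencies", con)
  writeLines(paste(paste(AA20, formatC(bg, format = "f", digits = 6)),
                   collapse = " "), con)
  writeLines("", con)
  for (m in motifs) {
    writeLines(paste("MOTIF", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 20 w= %d nsites= 20 E= 0",
                       m$width), con)
    for (i in seq_len(m$width))
      writeLines(paste(formatC(m$pwm_raw[i, ], format = "f", digits = 6),
                       collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Log-odds score of every window of a sequence against a motif
#'
#' Each window of length `width` is scored as
#' `sum_i log2(pwm[i, aa_i] / background[aa_i])` with the
#' pseudocount-smoothed PWM; `X` positions contribute 0 bits.
#'
#' @param seq A `protein_sequence` or residue string (ungapped).
#' @param motif A `motif_model`.
#' @param min_bits Score threshold in bits; windows scoring at least this
#'   are returned. Default [default_min_bits()] (consensus score minus 25%).
#' @return A data frame of class `motif_hits` with columns `seq_id`,
#'   `motif_id`, `start`, `end`, `bits`, sorted by descending score.
#' @export
scan_sequence <- function(seq, motif, min_bits = default_min_bits(motif)) {
  id <- if (inherits(seq, "protein_sequence")) seq$id else "seq"
  s <- if (inherits(seq, "protein_sequence")) seq$residues else toupper(seq)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch); w <- motif$width
  if (n < w) stop("sequence shorter than motif width")
  lo <- log2(motif$pwm / matrix(motif$background, w, 20, byrow = TRUE))
  scores <- vapply(seq_len(n - w + 1L), function(st) {
    win <- ch[st:(st + w - 1L)]
    sum(vapply(seq_len(w), function(i)
      if (win[i] == "X") 0 else lo[i, win[i]], 0))
  }, 0)
  keep <- which(scores >= min_bits)
  out <- data.frame(seq_id = rep(id, length(keep)),
                    motif_id = rep(as.character(motif$motif_id), length(keep)),
                    start = keep, end = keep + w - 1L,
                    bits = scores[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$bits, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Default scan threshold for a motif
#'
#' The log-odds score of the motif's consensus sequence minus 25%; a
#' deterministic per-motif threshold standing in for E-value based cutoffs.
#'
#' @param motif A `motif_model`.
#' @return Threshold in bits.
#' @export
default_min_bits <- function(motif) {
  lo <- log2(motif$pwm / matrix(motif$background, motif$width, 20, byrow = TRUE))
  cons <- apply(motif$pwm_raw, 1L, which.max)
  s <- sum(lo[cbind(seq_len(motif$width), cons)])
  0.75 * s
}

#' Motif architecture of a sequence
#'
#' Scans the sequence against every motif, then greedily selects
#' non-overlapping hits by descending score (ties: smaller start, then
#' smaller motif id), and returns them in positional order.
#'
#' @param seq A `protein_sequence` or residue string.
#' @param motifs List of `motif_model` objects.
#' @param min_bits Named numeric vector of per-motif thresholds, a single
#'   number, or `NULL` for per-motif defaults.
#' @return A `motif_hits` data frame sorted by `start`, pairwise
#'   non-overlapping.
#' @export
architecture <- function(seq, motifs, min_bits = NULL) {
  hits <- do.call(rbind, lapply(motifs, function(m) {
    th <- if (is.null(min_bits)) default_min_bits(m)
          else if (length(min_bits) == 1L && is.null(names(min_bits))) min_bits
          else min_bits[[as.character(m$motif_id)]]
    scan_sequence(seq, m, th)
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- data.frame(seq_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0), bits = numeric(0))
    class(out) <- c("motif_hits", "data.frame")
    return(out)
  }
  ord <- order(-hits$bits, hits$start, as.character(hits$motif_id))
  hits <- hits[ord, , drop = FALSE]
  chosen <- hits[0, , drop = FALSE]
  occupied <- logical(max(hits$end))
  for (r in seq_len(nrow(hits))) {
    span <- hits$start[r]:hits$end[r]
    if (!any(occupied[span])) {
      chosen <- rbind(chosen, hits[r, , drop = FALSE])
      occupied[span] <- TRUE
    }
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  class(chosen) <- c("motif_hits", "data.frame")
  chosen
}

#' Classify motifs as ubiquitous, predominant or exclusive to classes
#'
#' For each motif, the fraction of sequences of each class whose
#' architecture contains it is computed. A motif is `exclusive` to the
#' classes where its presence is at least `presence_threshold` if it is
#' absent (presence 0) from all other classes; `predominant` if present at
#' threshold inside and below `1 - presence_threshold` outside;
#' `ubiquitous` if at threshold in every class; otherwise `mixed`.
#'
#' @param architectures Named list (by `seq_id`) of `motif_hits` frames.
#' @param class_of Named character vector mapping seq ids to class labels.
#' @param presence_threshold Default 0.8.
#' @return A data frame with columns `motif_id`, `category`, `classes`
#'   (comma-separated class set, empty for ubiquitous/mixed), plus a
#'   `presence` matrix attribute (motif x class fractions).
#' @export
classify_motif_specificity <- function(architectures, class_of,
                                       presence_threshold = 0.8) {
  ids <- names(architectures)
  unl <- setdiff(ids, names(class_of))
  if (length(unl)) stop("sequences without class labels: ",
                        paste(unl, collapse = ", "))
  classes <- sort(unique(class_of[ids]))
  motifs <- sort(unique(unlist(lapply(architectures, function(a)
    as.character(a$motif_id)))))
  pres <- matrix(0, length(motifs), length(classes),
                 dimnames = list(motifs, classes))
  for (cl in classes) {
    members <- ids[class_of[ids] == cl]
    for (m in motifs) {
      has <- vapply(architectures[members], function(a)
        m %in% as.character(a$motif_id), NA)
      pres[m, cl] <- mean(has)
    }
  }
  res <- lapply(motifs, function(m) {
    p <- pres[m, ]
    inset <- names(p)[p >= presence_threshold]
    outset <- setdiff(classes, inset)
    if (length(inset) == length(classes)) {
      c(category = "ubiquitous", classes = "")
    } else if (length(inset) && all(p[outset] == 0)) {
      c(category = "exclusive", classes = paste(inset, collapse = ","))
    } else if (length(inset) && all(p[outset] < 1 - presence_threshold)) {
      c(category = "predominant", classes = paste(inset, collapse = ","))
    } else {
      c(category = "mixed", classes = "")
    }
  })
  out <- data.frame(motif_id = motifs,
                    category = vapply(res, `[[`, "", "category"),
                    classes = vapply(res, `[[`, "", "classes"),
                    stringsAsFactors = FALSE)
  attr(out, "presence") <- pres
  out
}

#' Export motif hits as TSV
#' @param hits A `motif_hits` data frame.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single-motif ZOOPS EM motif discovery (testing aid)
#'
#' Expectation-maximization over the zero-or-one-occurrence-per-sequence
#' model with a fixed background estimated from the data: each sequence
#' either contains one motif occurrence (uniform prior over positions) or
#' none. Best of `n_starts` seeded restarts by final log-likelihood.
#' This is a deliberately simplified discovery tool used to exercise the
#' scanning stages; multi-motif discovery is delegated to external MEME.
#'
#' @param seqs List of `protein_sequence` objects or residue strings
#'   (>= 5 sequences, each >= `width`).
#' @param width Motif width.
#' @param n_starts Number of random restarts (default 5).
#' @param seed Integer seed; results are deterministic given it.
#' @param max_iter,tol EM stopping controls.
#' @return A `motif_model`, with attributes `loglik` (final) and
#'   `loglik_trace` of the winning start, and `gamma` (occurrence prob).
#' @export
discover_motif_zoops <- function(seqs, width, n_starts = 5L, seed = 1L,
                                 max_iter = 200L, tol = 1e-6) {
  strings <- vapply(seqs, function(s)
    if (inherits(s, "protein_sequence")) s$residues else toupper(s), "")
  if (length(strings) < 5L) stop("need at least 5 sequences")
  if (width > min(nchar(strings))) stop("width exceeds shortest sequence")
  chs <- strsplit(strings, "")
  idx <- lapply(chs, function(ch) match(ch, AA20))  # X -> NA, contributes bg
  counts <- table(factor(unlist(chs), levels = AA20))
  bg <- (as.numeric(counts) + 1) / (sum(counts) + 20)
  names(bg) <- AA20

  run_em <- function(init_pwm = NULL) {
    w <- width
    if (is.null(init_pwm)) {
      # random initialization: a random window per sequence + noise
      pwm <- matrix(1 / 20, w, 20, dimnames = list(NULL, AA20))
      for (s in sample(seq_along(idx), min(10L, length(idx)))) {
        st <- sample.int(length(idx[[s]]) - w + 1L, 1L)
        for (i in seq_len(w)) {
          a <- idx[[s]][st + i - 1L]
          if (!is.na(a)) pwm[i, a] <- pwm[i, a] + 2
        }
      }
      pwm <- pwm / rowSums(pwm)
    } else pwm <- init_pwm
    gamma <- 0.8
    ll_trace <- numeric(0)
    ll_old <- -Inf
    pc <- 0.01
    for (iter in seq_len(max_iter)) {
      lpwm <- log(pwm); lbg <- log(bg)
      new_counts <- matrix(pc, w, 20, dimnames = list(NULL, AA20))
      z_sum <- 0; ll <- 0
      for (s in seq_along(idx)) {
        ii <- idx[[s]]; L <- length(ii); npos <- L - w + 1L
        lbg_tot <- sum(lbg[ii[!is.na(ii)]])
        # log joint for occurrence at each start
        lj <- vapply(seq_len(npos), function(st) {
          span <- st:(st + w - 1L)
          inwin <- ii[span]
          d <- sum(vapply(seq_len(w), function(i) {
            a <- inwin[i]
            if (is.na(a)) 0 else lpwm[i, a] - lbg[a]
          }, 0))
          lbg_tot + d + log(gamma / npos)
        }, 0)
        l0 <- lbg_tot + log(1 - gamma)
        mx <- max(c(lj, l0))
        denom <- mx + log(sum(exp(c(lj, l0) - mx)))
        ll <- ll + denom
        post <- exp(lj - denom)
        z_sum <- z_sum + sum(post)
        for (st in seq_len(npos)) {
          if (post[st] < 1e-12) next
          for (i in seq_len(w)) {
            a <- ii[st + i - 1L]
            if (!is.na(a)) new_counts[i, a] <- new_counts[i, a] + post[st]
          }
        }
      }
      ll_trace <- c(ll_trace, ll)
      pwm <- new_counts / rowSums(new_counts)
      gamma <- min(max(z_sum / length(idx), 1e-3), 1 - 1e-3)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(pwm = pwm, gamma = gamma, ll = ll_trace[length(ll_trace)],
         trace = ll_trace)
  }

  shift_pwm <- function(pwm, sh) {
    w <- nrow(pwm)
    out <- matrix(bg, w, 20, byrow = TRUE, dimnames = list(NULL, AA20))
    src <- seq_len(w) + sh
    keep <- src >= 1L & src <= w
    out[which(keep), ] <- pwm[src[keep], ]
    out
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (k in seq_len(n_starts)) {
    fit <- run_em()
    # phase-shift moves: EM restarted from +-1 shifted PWMs, best kept
    repeat {
      improved <- FALSE
      for (sh in c(-1L, 1L)) {
        cand <- run_em(shift_pwm(fit$pwm, sh))
        if (cand$ll > fit$ll + 1e-6) { fit <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  m <- motif_model("discovered", best$pwm, background = bg, pseudocount = 0)
  attr(m, "loglik") <- best$ll
  attr(m, "loglik_trace") <- best$trace
  attr(m, "gamma") <- best$gamma
  m
}
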