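#' Build a motif model from a position frequency matrix
#'
#' The position weight matrix is `log2((count + 0.1) / (colsum + 0.4) /
#' bg)`, i.e. a 0.1 pseudocount per cell against the supplied background
#' base frequencies.
#'
#' @param counts 4 x L numeric matrix, rows named A, C, G, T.
#' @param name motif name.
#' @param background named background base frequencies (default uniform).
#' @return list of class `motif_model`: `name`, `pfm`, `pwm`, `background`.
#' @export
motif_model <- function(counts, name = "motif",
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PFM needs 4 rows (A, C, G, T)")
  rownames(counts) <- c("A", "C", "G", "T")
  if (any(colSums(counts) <= 0)) stop("PFM column sums must be positive")
  background <- background[c("A", "C", "G", "T")] / sum(background)
  pwm <- log2(sweep(counts + 0.1, 2, colSums(counts) + 0.4, `/`) / background)
  structure(list(name = name, pfm = counts, pwm = pwm, background = background),
            class = "motif_model")
}

#' Motif model from a consensus string
#' @param consensus string over A/C/G/T.
#' @param n pseudo-count total per column.
#' @inheritParams motif_model
#' @return a `motif_model`.
#' @export
motif_from_consensus <- function(consensus, name = consensus, n = 100,
                                 background = c(A = 0.25, C = 0.25, G = 0.25,
                                                T = 0.25)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("consensus must be A/C/G/T")
  counts <- matrix(0, 4, length(bases), dimnames = list(c("A", "C", "G", "T")))
  for (i in seq_along(bases)) counts[bases[i], i] <- n
  motif_model(counts, name = name, background = background)
}

#' Read motif count matrices in JASPAR text format
#'
#' Parses the 2016-style flat format: a `>ID name` header followed by four
#' rows `A [ counts ]` etc.
#'
#' @param path file path.
#' @param background background base frequencies for the PWM.
#' @return named list of `motif_model`s.
#' @export
read_jaspar <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25,
                                             T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR records in ", path)
  out <- list()
  for (h in heads) {
    hdr <- sub("^>\\s*", "", lines[h])
    name <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(name) >= 2) name[2] else name[1]
    rows <- lines[(h + 1):(h + 4)]
    parsed <- lapply(rows, function(l) {
      nums <- gsub("^\\s*[ACGTacgt]\\s*\\[?|\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1)
      stop("ragged PFM rows in ", path)
    counts <- do.call(rbind, parsed)
    out[[name]] <- motif_model(counts, name = name, background = background)
  }
  out
}

#' Write motif models in JASPAR text format
#' @param motifs named list of `motif_model`s.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_jaspar <- function(motifs, path) {
  lines <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$name, " ", m$name),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s  [ %s ]", b, paste(m$pfm[b, ], collapse = "  ")),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

# integer encoding of a sequence; N and other ambiguity codes -> 5
encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

# per-strand score vector for every start position; N positions score the
# background expectation of the column (mean PWM weighted by background)
pwm_scores <- function(enc, pwm, background) {
  L <- ncol(pwm)
  n <- length(enc)
  if (L > n) stop("motif longer than sequence")
  expect <- colSums(pwm * background)
  pw <- rbind(pwm, expect)  # row 5 = N
  npos <- n - L + 1
  sc <- numeric(npos)
  for (j in seq_len(L))
    sc <- sc + pw[cbind(enc[j:(j + npos - 1)], j)]
  sc
}

revcomp_pwm <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Scan sequences with a PSSM on both strands
#'
#' Positions whose score reaches `threshold_fraction` of the motif's score
#' range above its minimum (`score >= min + f (max - min)`) are reported.
#' Minus-strand hits are found by scanning with the reverse-complemented
#' matrix and reported at the forward-strand coordinate of the site.
#' Overlapping hits on the same strand within one motif length are merged
#' to the best-scoring position.
#'
#' @param sequences named character vector (or `DNAStringSet`) over
#'   A/C/G/T/N.
#' @param motif a `motif_model`.
#' @param threshold_fraction score threshold in (0, 1].
#' @param merge_overlaps merge same-strand overlapping hits?
#' @return data frame: seq, start0 (0-based), strand, score,
#'   score_fraction.
#' @export
scan_pssm <- function(sequences, motif, threshold_fraction = 0.85,
                      merge_overlaps = TRUE) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  check_prob(threshold_fraction, "threshold_fraction")
  if (threshold_fraction <= 0) stop("threshold_fraction must be in (0,1]")
  pwm <- motif$pwm
  L <- ncol(pwm)
  smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
  thr <- smin + threshold_fraction * (smax - smin)
  pwm_m <- revcomp_pwm(pwm)
  rows <- list()
  for (nm in names(sequences)) {
    enc <- encode_seq(sequences[[nm]])
    for (strand in c("+", "-")) {
      sc <- pwm_scores(enc, if (strand == "+") pwm else pwm_m, motif$background)
      hit <- which(sc >= thr - 1e-12)
      if (length(hit) == 0) next
      if (merge_overlaps && length(hit) > 1) {
        cl <- cumsum(c(1L, as.integer(diff(hit) >= L)))
        hit <- sort(vapply(split(hit, cl),
                           function(h) h[which.max(sc[h])], numeric(1)))
      }
      rows[[length(rows) + 1]] <- data.frame(
        seq = nm, start0 = hit - 1L, strand = strand, score = sc[hit],
        score_fraction = (sc[hit] - smin) / (smax - smin))
    }
  }
  if (length(rows) == 0)
    return(data.frame(seq = character(0), start0 = integer(0),
                      strand = character(0), score = numeric(0),
                      score_fraction = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$seq, out$start0, out$strand), , drop = FALSE]
}

#' oPOSSUM-style TFBS enrichment statistics
#'
#' The Z score treats every scanned nucleotide as a Bernoulli trial at the
#' background hit rate: with `rate_bg` = background hits per scanned bp,
#' `z = (obs_target - rate_bg * target_bp) / sqrt(rate_bg * target_bp *
#' (1 - rate_bg))`.  The Fisher p is one-sided (enrichment) on the counts
#' of genes with at least one hit in target vs background sets.
#'
#' @param target_hits,background_hits total hit counts.
#' @param target_bp,background_bp scanned base pairs per set.
#' @param target_genes_hit,target_n genes with >= 1 hit / total genes,
#'   target set.
#' @param background_genes_hit,background_n same for the background set.
#' @return list: `z_score`, `fisher_p`, `rate_background`, `significant`
#'   (Z > 10 and Fisher p < 0.01).
#' @export
tfbs_enrichment <- function(target_hits, background_hits, target_bp,
                            background_bp, target_genes_hit, target_n,
                            background_genes_hit, background_n) {
  if (target_bp <= 0 || background_bp <= 0) stop("zero searched length")
  rate_bg <- background_hits / background_bp
  if (background_hits == 0) {
    warning("zero background hits; rate floored at 1/(2 background bp)")
    rate_bg <- 1 / (2 * background_bp)
  }
  mu <- rate_bg * target_bp
  z <- (target_hits - mu) / sqrt(mu * (1 - rate_bg))
  tab <- matrix(c(target_genes_hit, target_n - target_genes_hit,
                  background_genes_hit, background_n - background_genes_hit),
                2, byrow = TRUE)
  fp <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(z_score = z, fisher_p = fp, rate_background = rate_bg,
       significant = z > 10 & fp < 0.01)
}

#' Scan a motif over target and background promoter sets and score
#' enrichment
#'
#' @param target,background named character vectors of sequences.
#' @param motif a `motif_model`.
#' @param threshold_fraction scanner threshold.
#' @return list with the two hit tables and the [tfbs_enrichment()] output.
#' @export
scan_and_score_motif <- function(target, background, motif,
                                 threshold_fraction = 0.85) {
  ht <- scan_pssm(target, motif, threshold_fraction)
  hb <- scan_pssm(background, motif, threshold_fraction)
  enr <- tfbs_enrichment(
    target_hits = nrow(ht), background_hits = nrow(hb),
    target_bp = sum(nchar(target)), background_bp = sum(nchar(background)),
    target_genes_hit = length(unique(ht$seq)), target_n = length(target),
    background_genes_hit = length(unique(hb$seq)),
    background_n = length(background))
  list(target_hits = ht, background_hits = hb, enrichment = enr)
}

#' Composite transcription-factor ranking
#'
#' Each TF is ranked on three statistics (1 = best): largest Z, smallest
#' Fisher p, largest differential-expression `-log10(p)`.  The composite
#' rank is the unweighted mean of the three; output is ordered by composite
#' rank with ties broken by TF name.  TFs missing a statistic are excluded
#' with a warning.
#'
#' @param records data frame with columns `tf`, `z_score`, `fisher_p`,
#'   `de_neg_log10_p`.
#' @return the records with per-statistic ranks, `composite_rank` and a
#'   `significant` flag (Z > 10 and Fisher p < 0.01), ordered best first.
#' @export
composite_tf_rank <- function(records) {
  need <- c("tf", "z_score", "fisher_p", "de_neg_log10_p")
  stopifnot(all(need %in% names(records)))
  ok <- stats::complete.cases(records[, need])
  if (any(!ok))
    warning("TF(s) with missing statistics excluded: ",
            paste(records$tf[!ok], collapse = ", "))
  rec <- records[ok, , drop = FALSE]
  rec <- rec[order(rec$tf), , drop = FALSE]
  rank_on <- function(x, desc) {
    o <- order(if (desc) -x else x, rec$tf)
    r <- integer(length(x)); r[o] <- seq_along(x); r
  }
  rec$z_rank <- rank_on(rec$z_score, desc = TRUE)
  rec$fisher_rank <- rank_on(rec$fisher_p, desc = FALSE)
  rec$de_rank <- rank_on(rec$de_neg_log10_p, desc = TRUE)
  rec$composite_rank <- (rec$z_rank + rec$fisher_rank + rec$de_rank) / 3
  rec$significant <- rec$z_score > 10 & rec$fisher_p < 0.01
  rec <- rec[order(rec$composite_rank, rec$tf), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
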