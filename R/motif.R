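DNA <- c("A", "C", "G", "T")

#' Read position frequency matrices in JASPAR (2020 dialect) format
#'
#' Parses records of the form `>ID name` followed by four lines
#' `A [ 1 2 3 ]` ... `T [ ... ]`.
#'
#' @param path PFM text file.
#' @return Named list of 4 x L count matrices (rows A,C,G,T); names are
#'   `"ID name"` collapsed to the matrix name when present.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stopf("no JASPAR records in %s", path)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]]
    nm <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    rows <- lines[s + 1:4]
    counts <- t(vapply(rows, function(l) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", trimws(l))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub(
      "^[ACGTacgt]\\s*\\[?|\\]$", "", trimws(rows[1]))), "\\s+")[[1]]))))
    rownames(counts) <- DNA
    out[[nm]] <- counts
  }
  out
}

#' Write count matrices in JASPAR bracket format
#'
#' @param pfms named list of 4 x L count matrices (as returned by
#'   [read_jaspar_pfm()]).
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pfms)) {
    writeLines(sprintf(">%s %s", nm, nm), con)
    m <- pfms[[nm]]
    for (b in DNA)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Build a log-odds position weight matrix from counts
#'
#' Column-wise probabilities use a total pseudocount distributed by the
#' background composition, `p_ij = (c_ij + pc * bg_i) / (N_j + pc)`;
#' weights are `log2(p_ij / bg_i)`. The consensus is the per-column argmax,
#' so its relative score is exactly 1.
#'
#' @param counts 4 x L count (or probability) matrix, rows A,C,G,T.
#' @param background length-4 base composition (A,C,G,T), summing to 1.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param name matrix name.
#' @return An object of class `pwm`: list with `weights`, `probs`,
#'   `background`, `name`, `consensus`, `max_score`, `min_score`, `length`.
#' @export
pwm_build <- function(counts, background = rep(0.25, 4), pseudocount = 0.8,
                      name = "pwm") {
  stopifnot(nrow(counts) == 4)
  if (is.null(rownames(counts))) rownames(counts) <- DNA
  counts <- counts[DNA, , drop = FALSE]
  if (abs(sum(background) - 1) > 1e-8)
    stopf("background frequencies must sum to 1")
  n <- colSums(counts)
  probs <- sweep(counts, 2, n + pseudocount, "/") +
    outer(background * pseudocount, 1 / (n + pseudocount))
  weights <- log2(probs / background)
  cons <- paste(DNA[apply(weights, 2, which.max)], collapse = "")
  structure(list(weights = weights, probs = probs, background = background,
                 name = name, consensus = cons,
                 max_score = sum(apply(weights, 2, max)),
                 min_score = sum(apply(weights, 2, min)),
                 length = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, consensus %s, score range [%.3f, %.3f]\n",
              x$name, x$length, x$consensus, x$min_score, x$max_score))
  invisible(x)
}

# reverse-complement a pwm weight matrix (rows A,C,G,T)
rc_weights <- function(w) w[4:1, ncol(w):1, drop = FALSE]

pwm_relative <- function(pwm, score) {
  (score - pwm$min_score) / (pwm$max_score - pwm$min_score)
}

#' Exact null score distribution of a PWM under a background model
#'
#' Dynamic programming over per-position score sums: the distribution of
#' the match score of a random i.i.d. background sequence. Scores are
#' merged at a fine numeric resolution; when the state space would exceed
#' `max_states` the resolution is coarsened with a warning.
#'
#' @param pwm a [pwm_build()] object.
#' @param background base composition of the null model (defaults to the
#'   PWM's own background).
#' @param max_states cap on the number of distinct score states.
#' @return data.frame with columns `score` (ascending), `prob`, and `tail`
#'   (`P(S >= score)`).
#' @export
pwm_score_distribution <- function(pwm, background = NULL,
                                   max_states = 2e5) {
  bg <- background %||% pwm$background
  w <- pwm$weights
  eps <- max(1e-9, (pwm$max_score - pwm$min_score) * 1e-12)
  dist <- c(`0` = 1)
  keys <- 0
  for (j in seq_len(ncol(w))) {
    ns <- as.vector(outer(w[, j], keys, "+"))
    np <- as.vector(outer(bg, unname(dist), "*"))
    repeat {
      bins <- round(ns / eps)
      agg <- rowsum(np, bins)
      if (nrow(agg) <= max_states) break
      eps <- eps * 16
      warnf("score distribution coarsened to resolution %.3g", eps)
    }
    keys <- as.numeric(rownames(agg)) * eps
    dist <- setNames(agg[, 1], rownames(agg))
    ord <- order(keys)
    keys <- keys[ord]; dist <- dist[ord]
  }
  tail_p <- rev(cumsum(rev(unname(dist))))
  data.frame(score = keys, prob = unname(dist), tail = tail_p)
}

#' Raw-score threshold for a scan p-value
#'
#' Smallest score whose null tail probability is at most `p` under the
#' exact background score distribution; `Inf` when no attainable score is
#' that rare (the scan then returns no hits).
#'
#' @inheritParams pwm_score_distribution
#' @param p target p-value in (0, 1].
#' @return Raw score threshold.
#' @export
pwm_score_threshold <- function(pwm, p, background = NULL) {
  if (!(p > 0 && p <= 1)) stopf("p must be in (0, 1]")
  d <- pwm_score_distribution(pwm, background)
  ok <- d$tail <= p + 1e-12
  if (!any(ok)) return(Inf)
  d$score[which(ok)[1]]
}

seq_codes <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], DNA)
  x
}

score_windows <- function(codes, w) {
  m <- ncol(w); L <- length(codes)
  n <- L - m + 1
  if (n < 1) return(numeric(0))
  s <- rep(0, n)
  for (j in seq_len(m)) {
    v <- w[codes[j:(j + n - 1)], j]
    v[is.na(codes[j:(j + n - 1)])] <- NA
    s <- s + v
  }
  s
}

#' Scan sequences with a PWM on both strands
#'
#' Every window at or above the threshold is reported. The threshold is
#' either a relative score (`min_rel`, share of the PWM score range,
#' default 0.85) or an exact-null p-value (`p_value`, takes precedence).
#' Windows containing non-ACGT characters are skipped; sequences shorter
#' than the motif yield no hits. Hits are ordered by (sequence, start,
#' strand).
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param pwm a [pwm_build()] object.
#' @param min_rel relative-score threshold in \[0, 1\].
#' @param p_value optional p-value threshold for [pwm_score_threshold()].
#' @param background null base composition for the p-value mode.
#' @return data.frame of hits: `seq`, `start` (0-based), `strand`,
#'   `score`, `rel_score`, `center`, `pwm`.
#' @export
scan_pwm <- function(seqs, pwm, min_rel = 0.85, p_value = NULL,
                     background = NULL) {
  if (inherits(seqs, "DNAStringSet"))
    seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  thr <- if (!is.null(p_value))
    pwm_score_threshold(pwm, p_value, background)
  else pwm$min_score + min_rel * (pwm$max_score - pwm$min_score)

  w_f <- pwm$weights
  w_r <- rc_weights(w_f)
  m <- pwm$length
  res <- lapply(names(seqs), function(nm) {
    codes <- seq_codes(seqs[[nm]])
    sf <- score_windows(codes, w_f)
    sr <- score_windows(codes, w_r)
    hit_f <- which(!is.na(sf) & sf >= thr - 1e-12)
    hit_r <- which(!is.na(sr) & sr >= thr - 1e-12)
    if (!length(hit_f) && !length(hit_r)) return(NULL)
    data.frame(
      seq = nm,
      start = c(hit_f, hit_r) - 1L,
      strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
      score = c(sf[hit_f], sr[hit_r]),
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, res)
  if (is.null(hits))
    hits <- data.frame(seq = character(), start = integer(),
                       strand = character(), score = numeric(),
                       stringsAsFactors = FALSE)
  hits$rel_score <- pwm_relative(pwm, hits$score)
  hits$center <- hits$start + (m - 1) / 2
  hits$pwm <- rep(pwm$name, nrow(hits))
  hits[order(hits$seq, hits$start, hits$strand), , drop = FALSE]
}

#' De-duplicate motif hits within a center window
#'
#' Among hits (possibly from several related matrices and both strands)
#' whose centers lie within `window` bp of one another on the same
#' sequence, only the best-scoring hit is retained; ties break towards
#' lower start, then forward strand, then matrix name. Idempotent.
#'
#' @param hits data.frame from [scan_pwm()] (rbind several for a matrix
#'   group).
#' @param window center distance in bp (default 3).
#' @return The retained hits, ordered by (sequence, start, strand).
#' @export
dedup_hits <- function(hits, window = 3) {
  if (nrow(hits) < 2) return(hits)
  ord <- order(-hits$score, hits$start, hits$strand, hits$pwm)
  keep <- logical(nrow(hits))
  for (i in ord) {
    prior <- which(keep & hits$seq == hits$seq[i] &
                     abs(hits$center - hits$center[i]) <= window)
    if (length(prior) == 0) keep[i] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$seq, out$start, out$strand), , drop = FALSE]
}

#' Binomial over-representation z-score for motif hits
#'
#' The control set estimates a per-nucleotide hit rate `p = b / B`; under
#' the null the target set's hit count is Binomial(T, p), so
#' `z = (t - T p) / sqrt(T p (1 - p))`. An optional continuity correction
#' subtracts 0.5 from the numerator (off by default).
#'
#' @param t,T_ target hit count and target nucleotide total.
#' @param b,B control hit count and control nucleotide total.
#' @param continuity apply the -0.5 continuity correction.
#' @return list of class `enrichment`: `t`, `T`, `b`, `B`, `rate`, `mu`,
#'   `sigma`, `z` (NA with `flagged = TRUE` when sigma is 0).
#' @export
opossum_zscore <- function(t, T_, b, B, continuity = FALSE) {
  rate <- b / B
  mu <- rate * T_
  sigma <- sqrt(T_ * rate * (1 - rate))
  flagged <- !is.finite(sigma) || sigma == 0
  z <- if (flagged) NA_real_ else {
    num <- t - mu - if (continuity) 0.5 else 0
    num / sigma
  }
  structure(list(t = t, T = T_, b = b, B = B, rate = rate, mu = mu,
                 sigma = sigma, z = z, flagged = flagged),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("enrichment: t=%d/%d, b=%d/%d, z=%.3f%s\n", x$t, x$T, x$b,
              x$B, x$z, if (x$flagged) " (flagged)" else ""))
  invisible(x)
}

# count deduplicated hits and nucleotide totals in a sequence set
count_hits <- function(seqs, pwm, min_rel = 0.85, p_value = NULL,
                       background = NULL, dedup = TRUE, window = 3) {
  if (inherits(seqs, "DNAStringSet"))
    seqs <- setNames(as.character(seqs), names(seqs))
  hits <- scan_pwm(seqs, pwm, min_rel = min_rel, p_value = p_value,
                   background = background)
  if (dedup) hits <- dedup_hits(hits, window = window)
  list(n = nrow(hits), nt = sum(nchar(seqs)), hits = hits)
}

#' Motif over-representation between a target and a control sequence set
#'
#' Counts de-duplicated hits in both sets at the given threshold and
#' returns the binomial z-score of [opossum_zscore()].
#'
#' @param target,control sequence sets (named character or DNAStringSet);
#'   both must be nonempty.
#' @param pwm a [pwm_build()] object.
#' @inheritParams scan_pwm
#' @param continuity passed to [opossum_zscore()].
#' @param dedup de-duplicate hits before counting (default TRUE).
#' @return An `enrichment` object.
#' @export
enrichment_zscore <- function(target, control, pwm, min_rel = 0.85,
                              p_value = NULL, background = NULL,
                              continuity = FALSE, dedup = TRUE) {
  if (length(target) == 0 || length(control) == 0)
    stopf("target and control sequence sets must be nonempty")
  tgt <- count_hits(target, pwm, min_rel, p_value, background, dedup)
  ctl <- count_hits(control, pwm, min_rel, p_value, background, dedup)
  opossum_zscore(tgt$n, tgt$nt, ctl$n, ctl$nt, continuity = continuity)
}

#' Average z-scores from two region representations
#'
#' Arithmetic mean of the finite inputs (upstream-region z and
#' open-chromatin z); when only one is available the result equals it and
#' is flagged single-source.
#'
#' @param z_upstream,z_atac numeric z-scores (NA allowed).
#' @return list with `z`, `single_source`, `undefined`.
#' @export
combined_zscore <- function(z_upstream, z_atac) {
  zs <- c(z_upstream, z_atac)
  fin <- zs[is.finite(zs)]
  if (length(fin) == 0)
    return(list(z = NA_real_, single_source = FALSE, undefined = TRUE))
  list(z = mean(fin), single_source = length(fin) == 1, undefined = FALSE)
}
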