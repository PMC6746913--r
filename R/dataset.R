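# Benchmark-construction logic: stratification of windows by the sequence
# motif at the methylated adenine, negative sampling matched to the positive
# strata, greedy identity-based redundancy filtering, and class balancing.

#' Target motif-stratum proportions
#'
#' The four disjoint central-motif strata used when matching a negative set
#' to the composition of the positives: `GAGG`, `AGG` (not preceded by G),
#' `AG` (not followed by G), and everything else. Defaults are the published
#' proportions observed in the rice 6mA positive set (17.08% GAGG, 15.76%
#' AGG, 14.42% AG), with `other` taking the remainder.
#'
#' @param p_gagg,p_agg,p_ag,p_other stratum proportions in `[0, 1]`; must
#'   sum to 1 (tolerance 1e-9). `p_other` defaults to the remainder.
#' @return named numeric vector of class `m6a_ratios`.
#' @export
motif_ratios <- function(p_gagg = 0.1708, p_agg = 0.1576, p_ag = 0.1442,
                         p_other = NULL) {
  if (is.null(p_other)) p_other <- 1 - (p_gagg + p_agg + p_ag)
  p <- c(GAGG = p_gagg, AGG = p_agg, AG = p_ag, other = p_other)
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1, got ", sum(p))
  structure(p, class = c("m6a_ratios", "numeric"))
}

#' Classify the motif at the central adenine
#'
#' Anchored at the central adenine (position `c = (L + 1) / 2`), the strata
#' are nested and assigned most-specific-first so that they are mutually
#' exclusive: `GAGG` if positions `c-1 .. c+2` read `GAGG`; else `AGG` if
#' `c .. c+2` read `AGG`; else `AG` if `c .. c+1` read `AG`; else `other`.
#'
#' @param windows an `m6a_windows` data frame (or character vector of
#'   window sequences of equal odd length).
#' @return factor with levels `GAGG, AGG, AG, other`, one per window.
#' @examples
#' w <- sample_windows("x", paste0(strrep("C", 19), "GAGG", strrep("C", 18)))
#' classify_central_motif(w)  # GAGG
#' @export
classify_central_motif <- function(windows) {
  seqs <- if (is.data.frame(windows)) windows$seq else toupper(windows)
  if (length(seqs) == 0L) {
    return(factor(character(), levels = c("GAGG", "AGG", "AG", "other")))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("windows must have equal length")
  ctr <- (L + 1L) %/% 2L
  ctx4 <- substr(seqs, ctr - 1L, ctr + 2L)
  ctx3 <- substr(seqs, ctr, ctr + 2L)
  ctx2 <- substr(seqs, ctr, ctr + 1L)
  cls <- rep("other", length(seqs))
  cls[ctx2 == "AG"] <- "AG"
  cls[ctx3 == "AGG"] <- "AGG"
  cls[ctx4 == "GAGG"] <- "GAGG"
  factor(cls, levels = c("GAGG", "AGG", "AG", "other"))
}

#' Largest-remainder apportionment of n among strata
#'
#' Rounds `n * p` down and distributes the remaining units to the strata
#' with the largest fractional remainders (ties broken by stratum order), so
#' the integer counts always sum to exactly `n`.
#'
#' @param n total count to apportion.
#' @param p proportions summing to 1.
#' @return integer vector of counts, named like `p`, summing to `n`.
#' @export
apportion_counts <- function(n, p) {
  n <- as.integer(n)
  quota <- n * as.numeric(p)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  setNames(as.integer(base), names(p))
}

#' Sample negatives matched to the positive motif composition
#'
#' Stratified uniform sampling without replacement: `n` windows are drawn
#' from `candidates` so that the number in each central-motif stratum equals
#' the largest-remainder apportionment of `n * ratios`. Deterministic for a
#' fixed `seed`.
#'
#' @param candidates an `m6a_windows` data frame of candidate (unlabelled or
#'   negative) windows.
#' @param ratios an [motif_ratios()] object.
#' @param n number of windows to draw.
#' @param seed integer seed for the draw.
#' @return an `m6a_windows` data frame of `n` rows with `label = 0`.
#' @export
sample_matched_negatives <- function(candidates, ratios = motif_ratios(),
                                     n, seed) {
  stopifnot(is.data.frame(candidates), n >= 1L)
  if ("label" %in% names(candidates) &&
      any(candidates$label %in% 1L)) {
    stop("candidates must be unlabelled or negative")
  }
  strata <- classify_central_motif(candidates)
  want <- apportion_counts(n, ratios)
  have <- table(strata)
  short <- want > as.integer(have[names(want)])
  if (any(short)) {
    s <- names(want)[short][1L]
    stop("stratum '", s, "': need ", want[[s]], " candidates, have ",
         as.integer(have[[s]]), " (shortfall ",
         want[[s]] - as.integer(have[[s]]), ")")
  }
  idx <- with_seed(seed, {
    unlist(lapply(names(want), function(s) {
      pool <- which(strata == s)
      pool[sample.int(length(pool), want[[s]])]
    }))
  })
  out <- candidates[sort(idx), , drop = FALSE]
  out$label <- 0L
  rownames(out) <- NULL
  class(out) <- c("m6a_windows", "data.frame")
  out
}

#' Greedy sequence-identity redundancy filter
#'
#' Order-dependent incremental clustering over equal-length windows: a
#' window is kept iff its ungapped identity (fraction of matching positions)
#' with every previously kept window is at most `threshold`. This is a
#' documented stand-in for CD-HIT — it does not reproduce CD-HIT's
#' word-filtered global-alignment identity, and full-scale benchmark
#' rebuilding should run CD-HIT externally.
#'
#' @param windows an `m6a_windows` data frame.
#' @param threshold identity threshold in `(0, 1]`; e.g. `0.8` drops any
#'   window sharing more than 80% of positions with a kept window.
#' @return the kept windows, in their original order.
#' @export
greedy_identity_filter <- function(windows, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(windows) <= 1L) return(windows)
  L <- unique(nchar(windows$seq))
  if (length(L) != 1L) stop("windows must have equal length")
  m <- seq_int_matrix(windows$seq)
  keep <- identity_filter_cpp(m, threshold)
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# windows as an integer matrix (rows = windows) for the C++ kernels
seq_int_matrix <- function(seqs) {
  L <- nchar(seqs[1L])
  m <- matrix(0L, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) {
    m[i, ] <- utf8ToInt(seqs[i])
  }
  m
}

#' Balance classes by subsampling negatives
#'
#' Uniformly subsamples the negative set without replacement down to the
#' size of the positive set; deterministic for a fixed `seed`.
#'
#' @param pos,neg `m6a_windows` data frames of positive and negative
#'   windows; `nrow(neg) >= nrow(pos)` is required.
#' @param seed integer seed.
#' @return list with elements `pos` (unchanged) and `neg` (subsampled),
#'   labels set to 1 and 0.
#' @export
balance_classes <- function(pos, neg, seed) {
  if (nrow(neg) < nrow(pos)) {
    stop("need at least as many negatives (", nrow(neg),
         ") as positives (", nrow(pos), ")")
  }
  keep <- if (nrow(neg) == nrow(pos)) {
    seq_len(nrow(neg))
  } else {
    sort(with_seed(seed, sample.int(nrow(neg), nrow(pos))))
  }
  pos$label <- 1L
  neg <- neg[keep, , drop = FALSE]
  neg$label <- 0L
  rownames(neg) <- NULL
  list(pos = pos, neg = neg)
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}
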