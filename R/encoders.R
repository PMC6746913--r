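# Feature encodings for adenine-centred windows: KNFC (k-tuple nucleotide
# frequency component), MNBE (mono-nucleotide binary encoding) and NV
# (natural vector of positional moments). All encoders are pure functions of
# the sequence string; feature order is fixed and documented so that encoded
# matrices are portable across sessions.

all_kmers <- function(k) {
  # lexicographic over (A,C,G,T): first base varies slowest
  if (k == 1L) return(DNA_ALPHABET)
  g <- expand.grid(rev(replicate(k, DNA_ALPHABET, simplify = FALSE)),
                   stringsAsFactors = FALSE)
  do.call(paste0, rev(g))
}

#' K-tuple nucleotide frequency component (KNFC)
#'
#' For each `k` in `k_values`, counts every overlapping k-mer and emits one
#' block of `4^k` values in lexicographic order over `(A, C, G, T)`; blocks
#' are concatenated in ascending `k`. With `normalize = TRUE` (default) the
#' count of each k-mer is divided by the number of k-mer slots
#' `L - k + 1`, so each block is a probability vector summing to 1.
#'
#' With the default `k_values = c(2, 3, 4)` on a 41-nt window the vector has
#' 16 + 64 + 256 = 336 entries.
#'
#' @param seq a single DNA string (or a 1-row windows data frame).
#' @param k_values integer k-mer sizes, each `>= 1` and `< nchar(seq)`.
#' @param normalize divide counts by the number of slots (default `TRUE`);
#'   `FALSE` returns raw overlapping counts.
#' @return named numeric vector; names are `KNFC_k<k>_<kmer>`.
#' @examples
#' encode_knfc("ACGT", k_values = 2)[c("KNFC_k2_AC", "KNFC_k2_CG")]
#' @export
encode_knfc <- function(seq, k_values = c(2L, 3L, 4L), normalize = TRUE) {
  seq <- as_single_seq(seq)
  L <- nchar(seq)
  k_values <- sort(as.integer(k_values))
  if (any(k_values < 1L) || any(k_values >= L)) {
    stop("every k must satisfy 1 <= k < sequence length (", L, ")")
  }
  blocks <- lapply(k_values, function(k) {
    kmers <- all_kmers(k)
    n_slots <- L - k + 1L
    obs <- substring(seq, seq_len(n_slots), seq_len(n_slots) + k - 1L)
    cnt <- setNames(numeric(length(kmers)), kmers)
    tb <- table(obs)
    cnt[names(tb)] <- as.numeric(tb)
    if (normalize) cnt <- cnt / n_slots
    setNames(cnt, paste0("KNFC_k", k, "_", kmers))
  })
  unlist(blocks)
}

#' Mono-nucleotide binary encoding (MNBE)
#'
#' One-hot encodes each position: A -> (1,0,0,0), C -> (0,1,0,0),
#' G -> (0,0,1,0), T -> (0,0,0,1), concatenated in sequence order, giving
#' `4 * L` features for a length-`L` window (164 for the default 41-nt
#' windows). The encoding is bijective; see [decode_mnbe()].
#'
#' @param seq a single DNA string (or a 1-row windows data frame).
#' @return named numeric 0/1 vector; names are `MNBE_p<pos>_<base>`.
#' @export
encode_mnbe <- function(seq) {
  seq <- as_single_seq(seq)
  ch <- strsplit(seq, "")[[1L]]
  idx <- match(ch, DNA_ALPHABET)
  L <- length(ch)
  v <- numeric(4L * L)
  v[(seq_len(L) - 1L) * 4L + idx] <- 1
  names(v) <- paste0("MNBE_p", rep(sprintf("%02d", seq_len(L)), each = 4L),
                     "_", rep(DNA_ALPHABET, L))
  v
}

#' Decode a mono-nucleotide binary encoding back to its sequence
#'
#' @param v a numeric vector of length `4 * L` in which every 4-block is a
#'   one-hot code.
#' @return the DNA string.
#' @export
decode_mnbe <- function(v) {
  if (length(v) %% 4L != 0L) stop("length must be a multiple of 4")
  m <- matrix(v, nrow = 4L)
  if (!all(colSums(m) == 1) || !all(v %in% c(0, 1))) {
    stop("not a one-hot encoding")
  }
  paste(DNA_ALPHABET[apply(m, 2L, which.max)], collapse = "")
}

#' Natural vector (NV) of a DNA sequence
#'
#' The 12-number descriptor `(n_R, mu_R, D2_R)` for `R` in `(A, C, G, T)`:
#' the occurrence count `n_R`, the mean 1-based position `mu_R`, and the
#' second-order normalized central moment of positions
#' `D2_R = sum_i (s_i - mu_R)^2 / (n * n_R)`, where `s_i` enumerates the
#' positions of `R`. The normalizing `n` is the full sequence length by
#' default (the natural-vector convention); `denominator = "count"` uses
#' `n_R` instead, i.e. divides by `n_R^2`. A base that does not occur gets
#' `mu_R = D2_R = 0` (the mean is undefined at `n_R = 0`; zero-fill keeps
#' the vector length fixed).
#'
#' @param seq a single DNA string (or a 1-row windows data frame).
#' @param denominator `"length"` (default, `n = L`) or `"count"` (`n = n_R`).
#' @return named numeric vector of length 12, ordered
#'   `n_A, mu_A, D2_A, n_C, ..., D2_T`.
#' @examples
#' encode_nv("AAAA")[["NV_D2_A"]]  # 0.3125
#' @export
encode_nv <- function(seq, denominator = c("length", "count")) {
  seq <- as_single_seq(seq)
  denominator <- match.arg(denominator)
  ch <- strsplit(seq, "")[[1L]]
  L <- length(ch)
  out <- numeric(12L)
  names(out) <- paste0("NV_", rep(c("n", "mu", "D2"), 4L), "_",
                       rep(DNA_ALPHABET, each = 3L))
  for (j in seq_along(DNA_ALPHABET)) {
    s <- which(ch == DNA_ALPHABET[j])
    n_r <- length(s)
    if (n_r == 0L) next
    mu <- mean(s)
    nn <- if (denominator == "length") L else n_r
    d2 <- sum((s - mu)^2) / (nn * n_r)
    out[(j - 1L) * 3L + 1:3] <- c(n_r, mu, d2)
  }
  out
}

#' Concatenated feature encoding
#'
#' Applies the requested schemes in the given order and concatenates the
#' resulting vectors; names keep their scheme prefixes, so column identity is
#' unambiguous in combined matrices.
#'
#' @param seq a single DNA string (or a 1-row windows data frame).
#' @param schemes ordered character vector drawn from
#'   `c("KNFC", "MNBE", "NV")`, without duplicates.
#' @param k_values passed to [encode_knfc()].
#' @param ... further arguments passed to the individual encoders.
#' @return named numeric vector.
#' @export
encode_combined <- function(seq, schemes, k_values = c(2L, 3L, 4L), ...) {
  schemes <- check_schemes(schemes)
  seq <- as_single_seq(seq)
  parts <- lapply(schemes, function(s) {
    switch(s,
      KNFC = encode_knfc(seq, k_values = k_values),
      MNBE = encode_mnbe(seq),
      NV = encode_nv(seq, ...)
    )
  })
  unlist(parts)
}

check_schemes <- function(schemes) {
  schemes <- toupper(as.character(schemes))
  if (length(schemes) == 0L) stop("at least one scheme is required")
  unknown <- setdiff(schemes, c("KNFC", "MNBE", "NV"))
  if (length(unknown)) stop("unknown scheme(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(schemes)) stop("duplicate scheme tags")
  schemes
}

as_single_seq <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L, "seq" %in% names(seq))
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(seq)
}

#' Encode a window set into a feature matrix
#'
#' Row-wise application of [encode_combined()] over a windows data frame.
#' The result carries window ids as rownames, feature names as colnames, and
#' the label vector (if present) as attribute `"label"` plus the scheme tag
#' as attribute `"scheme"`.
#'
#' @param windows an `m6a_windows` data frame.
#' @param schemes ordered scheme tags (default `"MNBE"`, the scheme the
#'   benchmark study settled on).
#' @param k_values passed to [encode_knfc()].
#' @param ... passed to the individual encoders.
#' @return numeric matrix, one row per window.
#' @export
encode_windows <- function(windows, schemes = "MNBE",
                           k_values = c(2L, 3L, 4L), ...) {
  schemes <- check_schemes(schemes)
  if (nrow(windows) == 0L) stop("no windows to encode")
  rows <- lapply(windows$seq, encode_combined, schemes = schemes,
                 k_values = k_values, ...)
  X <- do.call(rbind, rows)
  rownames(X) <- windows$id
  attr(X, "label") <- if ("label" %in% names(windows)) windows$label else NULL
  attr(X, "scheme") <- paste(schemes, collapse = "-")
  X
}
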