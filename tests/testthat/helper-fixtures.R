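# Shared fixture builders. Everything is generated in code under explicit
# seeds; no data files are read.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

# a random valid window: odd length, central A
rand_window_seq <- function(L = 41L) {
  ch <- sample(BASES, L, replace = TRUE)
  ch[(L + 1L) %/% 2L] <- "A"
  paste(ch, collapse = "")
}

rand_windows <- function(n, L = 41L, label = NA_integer_) {
  sample_windows(sprintf("w%04d", seq_len(n)),
                 vapply(seq_len(n), function(i) rand_window_seq(L), ""),
                 label = label, L = L)
}

# window with an explicit central context: `context` is placed so that its
# adenine (at position `a_at`) lands on the window centre
window_with_context <- function(context, a_at, L = 41L) {
  ctr <- (L + 1L) %/% 2L
  left <- ctr - a_at
  seq <- paste0(strrep("C", left), context,
                strrep("C", L - left - nchar(context)))
  sample_windows("ctx", seq, L = L)
}

# small separable toy feature set: positives shifted up in every feature
toy_features <- function(n_per_class = 10L, p = 3L, gap = 2) {
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p) + gap, ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# brute-force k-mer dictionary oracle for KNFC
knfc_oracle <- function(seq, k, normalize = TRUE) {
  L <- nchar(seq)
  counts <- new.env()
  for (i in seq_len(L - k + 1L)) {
    km <- substr(seq, i, i + k - 1L)
    counts[[km]] <- (counts[[km]] %||% 0) + 1
  }
  kmers <- sort(apply(expand.grid(rep(list(BASES), k)), 1L, paste,
                      collapse = ""))
  out <- vapply(kmers, function(km) counts[[km]] %||% 0, numeric(1))
  if (normalize) out <- out / (L - k + 1L)
  setNames(out, paste0("KNFC_k", k, "_", kmers))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive pairwise Mann-Whitney AUC oracle
auc_oracle <- function(y, s) {
  ps <- s[y == 1]
  ns <- s[y == 0]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# MCC in the rearranged ratio form printed beside Sn/Sp/Acc
mcc_ratio_form <- function(n_pos, n_neg, fn, fp) {
  (1 - (fn / n_pos + fp / n_neg)) /
    sqrt((1 + (fp - fn) / n_pos) * (1 + (fn - fp) / n_neg))
}
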