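#' @useDynLib sixmApred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a validated table of adenine-centred sample windows
#'
#' A sample window is a fixed, odd-length DNA string whose central base is an
#' adenine — the candidate N6-methyladenine (6mA) site. Windows are stored in
#' an ordinary data frame with columns `id`, `seq`, `label` (1 = 6mA,
#' 0 = non-6mA, `NA` = unlabelled) and `source_pos` (1-based coordinate of the
#' central adenine in the sequence the window was cut from, or `NA`).
#'
#' @param id character vector of identifiers.
#' @param seq character vector of DNA strings over `A/C/G/T` (lowercase is
#'   accepted and uppercased).
#' @param label optional binary labels (0/1 or `NA`).
#' @param source_pos optional 1-based centre coordinates.
#' @param L window length; must be odd. Default 41, the canonical window used
#'   for rice 6mA benchmarks.
#' @return a `data.frame` of class `m6a_windows` that passes
#'   [validate_windows()].
#' @examples
#' w <- sample_windows("w1", strrep("C", 20) |> paste0("A", strrep("G", 20)))
#' w$seq
#' @export
sample_windows <- function(id, seq, label = NA, source_pos = NA, L = 41L) {
  seq <- toupper(as.character(seq))
  df <- data.frame(
    id = as.character(id),
    seq = seq,
    label = as.integer(label),
    source_pos = as.integer(source_pos),
    stringsAsFactors = FALSE
  )
  class(df) <- c("m6a_windows", "data.frame")
  validate_windows(df, L = L)
}

#' Validate sample-window invariants
#'
#' Checks that every window has length `L` (odd), a central adenine, an
#' alphabet restricted to `A/C/G/T`, and labels in `{0, 1, NA}`. Characters
#' outside the unambiguous DNA alphabet (including `N`) are rejected rather
#' than skipped: silent coercion would corrupt downstream encodings.
#'
#' @param x a data frame with at least columns `id` and `seq`.
#' @param L expected window length (odd).
#' @return `x`, invisibly classed as `m6a_windows`, if valid; otherwise an
#'   error identifying the offending rows.
#' @export
validate_windows <- function(x, L = 41L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  L <- as.integer(L)
  if (L %% 2L == 0L) stop("window length L must be odd, got ", L)
  if (nrow(x) == 0L) {
    class(x) <- unique(c("m6a_windows", class(x)))
    return(invisible(x))
  }
  x$seq <- toupper(x$seq)
  bad_len <- which(nchar(x$seq) != L)
  if (length(bad_len)) {
    stop("row(s) ", paste(utils::head(bad_len, 5L), collapse = ", "),
         ": sequence length != ", L)
  }
  bad_chr <- which(grepl("[^ACGT]", x$seq))
  if (length(bad_chr)) {
    offend <- gsub("[ACGT]", "", x$seq[bad_chr[1L]])
    stop("row(s) ", paste(utils::head(bad_chr, 5L), collapse = ", "),
         ": non-ACGT characters (e.g. '",
         paste(unique(strsplit(offend, "")[[1L]]), collapse = ""), "')")
  }
  centre <- (L + 1L) %/% 2L
  bad_ctr <- which(substr(x$seq, centre, centre) != "A")
  if (length(bad_ctr)) {
    stop("row(s) ", paste(utils::head(bad_ctr, 5L), collapse = ", "),
         ": centre base (position ", centre, ") is not A")
  }
  if ("label" %in% names(x)) {
    lab <- x$label
    bad_lab <- which(!is.na(lab) & !(lab %in% c(0L, 1L)))
    if (length(bad_lab)) {
      stop("row(s) ", paste(utils::head(bad_lab, 5L), collapse = ", "),
           ": label out of domain {0,1}")
    }
  }
  class(x) <- unique(c("m6a_windows", class(x)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences and returns a plain `(id, seq)` data frame in file order. Any
#' line width and both Unix and Windows line endings are accepted.
#'
#' @param path path to a FASTA file.
#' @return `data.frame` with character columns `id` and `seq`; zero rows for
#'   an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA '", path, "': empty header at record ",
         which(!nzchar(ids))[1L])
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("malformed FASTA '", path, "': empty record at position ",
         which(Biostrings::width(set) == 0L)[1L])
  }
  data.frame(id = ids, seq = unname(toupper(as.character(set))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x data frame with columns `id` and `seq` (e.g. windows).
#' @param path output file path.
#' @param width line width for wrapping.
#' @return `path`, invisibly. Records are written in row order, so output is
#'   deterministic.
#' @export
write_fasta <- function(x, path, width = 60L) {
  set <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Extract adenine-centred windows from a sequence
#'
#' Scans the given strand only. For every adenine at 1-based position `p`
#' with `flank < p <= nchar(seq) - flank`, emits the window
#' `substr(seq, p - flank, p + flank)`. Adenines closer than `flank` to
#' either end are silently skipped; no reverse-complement windows are
#' generated (strand handling is the caller's responsibility).
#'
#' @param seq a single DNA string over `A/C/G/T` (case-insensitive).
#' @param flank number of bases on each side of the adenine; window length is
#'   `2 * flank + 1` (default 20, i.e. 41-nt windows).
#' @param id_prefix prefix used to build window ids (`<prefix>_<pos>`).
#' @return an `m6a_windows` data frame with `source_pos` set to `p`.
#' @examples
#' w <- extract_windows(paste0(strrep("C", 20), "A", strrep("G", 20)))
#' nrow(w)  # 1
#' @export
extract_windows <- function(seq, flank = 20L, id_prefix = "win") {
  stopifnot(length(seq) == 1L, flank >= 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    ch <- strsplit(seq, "")[[1L]]
    bad <- which(!(ch %in% DNA_ALPHABET))
    stop("non-ACGT character(s) ",
         paste0("'", ch[utils::head(bad, 5L)], "'@", utils::head(bad, 5L),
                collapse = ", "))
  }
  flank <- as.integer(flank)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1L]]
  pos <- which(ch == "A")
  pos <- pos[pos > flank & pos <= n - flank]
  if (length(pos) == 0L) {
    out <- data.frame(id = character(), seq = character(),
                      label = integer(), source_pos = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("m6a_windows", "data.frame")
    return(out)
  }
  sample_windows(
    id = paste0(id_prefix, "_", pos),
    seq = substring(seq, pos - flank, pos + flank),
    label = NA_integer_,
    source_pos = pos,
    L = 2L * flank + 1L
  )
}

#' Read a labelled window table
#'
#' Reads a delimited text file with header columns `id`, `sequence` and
#' `label` (0/1), validates every row against the window invariants and
#' returns an `m6a_windows` data frame. Lines starting with `#` are treated
#' as provenance comments and skipped.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param L expected window length.
#' @return an `m6a_windows` data frame with labels attached.
#' @export
read_labelled_table <- function(path, sep = "\t", L = 41L) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(tab))) {
    stop("table must have header columns ", paste(need, collapse = ", "),
         "; got: ", paste(names(tab), collapse = ", "))
  }
  if (nrow(tab) && !all(tab$label %in% c(0L, 1L))) {
    bad <- which(!(tab$label %in% c(0L, 1L)))[1L]
    stop("row ", bad, ": label '", tab$label[bad], "' out of domain {0,1}")
  }
  tryCatch(
    sample_windows(tab$id, tab$sequence, label = tab$label, L = L),
    error = function(e) stop("invalid window table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' Write a labelled window table
#'
#' @param x an `m6a_windows` data frame.
#' @param path output path.
#' @param sep field separator.
#' @param comments optional character vector written as `# ...` header lines
#'   (provenance: seeds, generator settings).
#' @return `path`, invisibly.
#' @export
write_labelled_table <- function(x, path, sep = "\t", comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  out <- data.frame(id = x$id, sequence = x$seq,
                    label = if ("label" %in% names(x)) x$label else NA_integer_,
                    stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
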