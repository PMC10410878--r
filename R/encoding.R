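# One-hot encoding of paired YY1 anchor sequences and pair-table I/O.

# Row order is the fixed channel order A, C, G, T; N maps to the zero row so
# every entry stays in {0,1} and ambiguous positions carry no signal.
.onehot_lut <- matrix(
  c(1, 0, 0, 0,
    0, 1, 0, 0,
    0, 0, 1, 0,
    0, 0, 0, 1,
    0, 0, 0, 0),
  nrow = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T", "N"), c("A", "C", "G", "T"))
)

#' One-hot encode a single nucleotide
#'
#' Maps a base to its 4-dimensional indicator vector in the fixed channel
#' order A, C, G, T: `A -> (1,0,0,0)`, `C -> (0,1,0,0)`, `G -> (0,0,1,0)`,
#' `T -> (0,0,0,1)`. The ambiguous base `N` encodes to the all-zero row
#' (so entries stay binary); set `strict = TRUE` to reject it instead.
#'
#' @param base A single character in `A,C,G,T,N` (case-insensitive).
#' @param strict If `TRUE`, `N` raises an error instead of encoding to zeros.
#' @return A numeric vector of length 4.
#' @examples
#' one_hot_base("A")
#' one_hot_base("t")
#' one_hot_base("N")
#' @export
one_hot_base <- function(base, strict = FALSE) {
  stopifnot(is.character(base), length(base) == 1L, nchar(base) == 1L)
  encode_sequence(base, strict = strict)[1L, ]
}

#' One-hot encode a DNA sequence
#'
#' Converts a DNA string of length `L` into an `L x 4` binary matrix whose
#' row `i` is [one_hot_base()] of the i-th base (columns A, C, G, T). A
#' 506 bp anchor therefore becomes a `506 x 4` matrix.
#'
#' @param seq A DNA string over `A,C,G,T,N` (case-insensitive).
#' @param strict If `TRUE`, ambiguous bases (`N`) are rejected.
#' @return An `nchar(seq) x 4` numeric matrix; each row sums to 1 for an
#'   unambiguous base and to 0 for `N`.
#' @examples
#' encode_sequence("ACGT")
#' @export
encode_sequence <- function(seq, strict = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = 4L,
                  dimnames = list(NULL, c("A", "C", "G", "T"))))
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, rownames(.onehot_lut))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("invalid base '%s' at position %d (alphabet is A,C,G,T,N)",
                 chars[bad], bad), call. = FALSE)
  }
  if (strict && any(idx == 5L)) {
    bad <- which(idx == 5L)[1L]
    stop(sprintf("ambiguous base 'N' at position %d (strict mode)", bad),
         call. = FALSE)
  }
  mat <- .onehot_lut[idx, , drop = FALSE]
  rownames(mat) <- NULL
  mat
}

.required_pair_cols <- c("id", "seq_a", "seq_b", "label")

#' Validate a sequence-pair table
#'
#' Checks the contract shared by all pair tables in the package: columns
#' `id`, `seq_a`, `seq_b`, `label` (plus optional `cell_type`), unique ids,
#' labels in `{0,1}`, sequences over `A,C,G,T,N`, and one common length `L`
#' shared by every sequence of every pair. Sequences are uppercased.
#'
#' @param pairs A data frame of sequence pairs.
#' @return The validated tibble (sequences uppercased), invisibly usable in
#'   a pipe.
#' @export
validate_pairs <- function(pairs) {
  if (!is.data.frame(pairs)) stop("`pairs` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.required_pair_cols, names(pairs))
  if (length(missing_cols) > 0L) {
    stop("pair table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)
  pairs$id <- as.character(pairs$id)
  pairs$seq_a <- toupper(pairs$seq_a)
  pairs$seq_b <- toupper(pairs$seq_b)
  if (nrow(pairs) == 0L) stop("pair table has no rows", call. = FALSE)
  if (anyDuplicated(pairs$id)) {
    stop("duplicated pair id(s): ",
         paste(utils::head(unique(pairs$id[duplicated(pairs$id)]), 3L),
               collapse = ", "), call. = FALSE)
  }
  if (!all(pairs$label %in% c(0, 1))) {
    bad <- pairs$id[!pairs$label %in% c(0, 1)][1L]
    stop(sprintf("label outside {0,1} for pair '%s'", bad), call. = FALSE)
  }
  pairs$label <- as.integer(pairs$label)
  la <- nchar(pairs$seq_a); lb <- nchar(pairs$seq_b)
  mism <- which(la != lb)
  if (length(mism) > 0L) {
    stop(sprintf("length mismatch within pair '%s' (seq_a %d bp, seq_b %d bp)",
                 pairs$id[mism[1L]], la[mism[1L]], lb[mism[1L]]), call. = FALSE)
  }
  if (length(unique(la)) != 1L) {
    stop("all pairs must share one sequence length; found lengths: ",
         paste(sort(unique(la)), collapse = ", "), call. = FALSE)
  }
  bad_chr <- grepl("[^ACGTN]", pairs$seq_a) | grepl("[^ACGTN]", pairs$seq_b)
  if (any(bad_chr)) {
    stop(sprintf("pair '%s' contains characters outside A,C,G,T,N",
                 pairs$id[which(bad_chr)[1L]]), call. = FALSE)
  }
  pairs
}

#' Summarise a pair table
#'
#' @param pairs A validated pair table (see [validate_pairs()]).
#' @return A one-row tibble with `n`, `n_pos`, `n_neg` and `seq_len`.
#' @export
pairs_summary <- function(pairs) {
  pairs <- validate_pairs(pairs)
  tibble::tibble(
    n = nrow(pairs),
    n_pos = sum(pairs$label == 1L),
    n_neg = sum(pairs$label == 0L),
    seq_len = nchar(pairs$seq_a[1L])
  )
}

#' Read a TSV pair table
#'
#' Reads the canonical interchange format: a tab-separated file with a header
#' and columns `id`, `seq_a`, `seq_b`, `label` (an optional `cell_type`
#' column is kept). Sequences are uppercased and the pair-table contract is
#' enforced (see [validate_pairs()]).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble of sequence pairs.
#' @export
read_pairs <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    seq_a = readr::col_character(),
    seq_b = readr::col_character(),
    label = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_pairs(raw)
}

#' Write a TSV pair table
#'
#' @param pairs A pair table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- validate_pairs(pairs)
  keep <- intersect(c(.required_pair_cols, "cell_type"), names(pairs))
  readr::write_tsv(pairs[keep], path, progress = FALSE)
  invisible(path)
}

#' Read paired FASTA anchor files
#'
#' Interoperability loader for benchmark-style distributions: two FASTA files
#' whose records are matched by order (anchor A and anchor B of each pair)
#' plus a label file with one `0`/`1` per line in the same order.
#'
#' @param fasta_a,fasta_b Paths to the two FASTA files.
#' @param labels_path Path to the label file (one 0/1 per line).
#' @param cell_type Optional condition tag stored in a `cell_type` column.
#' @return A validated tibble of sequence pairs; ids are taken from the
#'   record names of `fasta_a`.
#' @export
read_paired_fasta <- function(fasta_a, fasta_b, labels_path, cell_type = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  a <- Biostrings::readDNAStringSet(fasta_a)
  b <- Biostrings::readDNAStringSet(fasta_b)
  if (length(a) != length(b)) {
    stop(sprintf("paired FASTA record counts differ: %d vs %d",
                 length(a), length(b)), call. = FALSE)
  }
  labels <- scan(labels_path, what = integer(), quiet = TRUE)
  if (length(labels) != length(a)) {
    stop(sprintf("label count (%d) does not match record count (%d)",
                 length(labels), length(a)), call. = FALSE)
  }
  ids <- names(a)
  if (is.null(ids) || any(!nzchar(ids))) ids <- sprintf("pair_%05d", seq_along(a))
  ids <- sub("\\s.*$", "", ids)
  out <- tibble::tibble(
    id = ids,
    seq_a = unname(as.character(a)),
    seq_b = unname(as.character(b)),
    label = labels
  )
  if (!is.null(cell_type)) out$cell_type <- cell_type
  validate_pairs(out)
}

#' One-hot encode a pair table
#'
#' Converts every pair into two `L x 4` one-hot matrices, stacked into two
#' `n x L x 4` arrays (branch A and branch B). Order is preserved.
#'
#' @param pairs A pair table.
#' @param strict Passed to [encode_sequence()]; `TRUE` rejects `N`.
#' @return An object of class `encoded_pairs`: a list with arrays `x_a`,
#'   `x_b` (each `n x L x 4`), integer `label`, character `id`, and scalars
#'   `n`, `seq_len`.
#' @export
encode_pairs <- function(pairs, strict = FALSE) {
  pairs <- validate_pairs(pairs)
  n <- nrow(pairs)
  L <- nchar(pairs$seq_a[1L])
  x_a <- array(0, dim = c(n, L, 4L))
  x_b <- array(0, dim = c(n, L, 4L))
  for (i in seq_len(n)) {
    mat_a <- tryCatch(encode_sequence(pairs$seq_a[i], strict = strict),
                      error = function(e) stop(sprintf("pair '%s' (seq_a): %s",
                                                       pairs$id[i], conditionMessage(e)),
                                               call. = FALSE))
    mat_b <- tryCatch(encode_sequence(pairs$seq_b[i], strict = strict),
                      error = function(e) stop(sprintf("pair '%s' (seq_b): %s",
                                                       pairs$id[i], conditionMessage(e)),
                                               call. = FALSE))
    x_a[i, , ] <- mat_a
    x_b[i, , ] <- mat_b
  }
  structure(
    list(x_a = x_a, x_b = x_b, label = pairs$label, id = pairs$id,
         n = n, seq_len = L),
    class = "encoded_pairs"
  )
}

#' @export
print.encoded_pairs <- function(x, ...) {
  cat(sprintf("<encoded_pairs> %d pairs, L = %d (%d positive / %d negative)\n",
              x$n, x$seq_len, sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

# Subset an encoded_pairs object by row index.
encoded_subset <- function(enc, idx) {
  structure(
    list(x_a = enc$x_a[idx, , , drop = FALSE],
         x_b = enc$x_b[idx, , , drop = FALSE],
         label = enc$label[idx], id = enc$id[idx],
         n = length(idx), seq_len = enc$seq_len),
    class = "encoded_pairs"
  )
}
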