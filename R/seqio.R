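#' @title Sequence and annotation input/output
#' @name seqio
#' @description Readers and writers for protein FASTA files and the
#'   per-residue annotation dialect, plus the fixed-size one-hot encodings
#'   consumed by the network.
NULL

# Fixed alphabetical column order of the 20-dimensional one-hot encoding.
# Stable across versions; documented in encode_sequence().
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity letters encoded as all-zero rows, like 'X'.
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

LABEL_ALPHABET <- c("S", "T", "N")

INPUT_LEN <- 96L

#' Construct a protein record
#'
#' A protein record holds one N-terminal sequence, optionally with
#' per-residue class labels: `S` for signal-peptide residues, `T` for
#' transmembrane residues and `N` for everything else.
#'
#' When labels are present two protein-level flags are derived:
#' `true_is_sp` is `TRUE` when the labels begin with at least one `S`
#' (the protein carries a signal peptide), and `true_is_tm` is `TRUE`
#' when a `T` occurs within the first 70 positions and no `S` occurs at
#' all (the protein is an N-terminal transmembrane negative).
#'
#' @param id Character identifier.
#' @param sequence Amino-acid sequence over the 20 standard letters plus
#'   the ambiguity letters X, B, Z, U, O. Upper-cased on input.
#' @param labels Optional label string over {S,T,N}, same length as
#'   `sequence`.
#' @param group Organism group, one of `"eukaryote"`, `"gram_positive"`,
#'   `"gram_negative"`, `"unknown"`.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, labels = NULL,
                           group = c("unknown", "eukaryote",
                                     "gram_positive", "gram_negative")) {
  group <- match.arg(group)
  sequence <- toupper(sequence)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string", call. = FALSE)
  if (nchar(sequence) < 1L)
    stop("record '", id, "': sequence must have length >= 1", call. = FALSE)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(AA_ALPHABET, AA_AMBIGUOUS))
  if (length(bad) > 0L)
    stop("record '", id, "': invalid sequence character(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (!is.null(labels)) {
    labels <- toupper(labels)
    if (nchar(labels) != nchar(sequence))
      stop("record '", id, "': label length (", nchar(labels),
           ") differs from sequence length (", nchar(sequence), ")",
           call. = FALSE)
    badl <- setdiff(strsplit(labels, "")[[1]], LABEL_ALPHABET)
    if (length(badl) > 0L)
      stop("record '", id, "': invalid label character(s): ",
           paste(unique(badl), collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, labels = labels,
                 group = group),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa",
      if (!is.null(x$labels)) ", labeled", ")\n", sep = "")
  invisible(x)
}

# Protein-level truth flags derived from labels; NULL labels -> NA flags.
record_truth <- function(record) {
  if (is.null(record$labels)) return(list(is_sp = NA, is_tm = NA))
  lab <- strsplit(record$labels, "")[[1]]
  is_sp <- lab[1] == "S"
  head70 <- lab[seq_len(min(70L, length(lab)))]
  is_tm <- !any(lab == "S") && any(head70 == "T")
  list(is_sp = is_sp, is_tm = is_tm)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects (labels absent). The record
#'   id is the first whitespace-delimited token of the header line and
#'   sequences are upper-cased.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # BStringSet: keep every byte so that invalid residue letters are
  # caught by the record validator instead of being silently dropped
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) return(list())
  ids <- vapply(strsplit(names(aa), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(aa))
  mapply(function(i, s) protein_record(i, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read per-residue annotations
#'
#' Reads the two-line annotation dialect: for each record a FASTA-style
#' header line, a sequence line, and a label line over {S,T,N} of the same
#' length. Blank lines are ignored.
#'
#' @param path Path to an annotation file.
#' @return A list of labeled [protein_record()] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L)
    stop("malformed annotation file: expected '>' header at line 1",
         call. = FALSE)
  if (length(lines) != 3L * length(starts) ||
      !all(starts == seq(1L, length(lines), by = 3L)))
    stop("malformed annotation file: each record needs header, sequence ",
         "and label lines", call. = FALSE)
  lapply(starts, function(i) {
    id <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]][1]
    protein_record(id, lines[i + 1L], labels = lines[i + 2L])
  })
}

#' Write per-residue annotations
#'
#' Inverse of [read_annotations()]; records must carry labels.
#'
#' @param records List of labeled [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  no_lab <- vapply(records, function(r) is.null(r$labels), logical(1))
  if (any(no_lab))
    stop("record(s) without labels: ",
         paste(vapply(records[no_lab], `[[`, character(1), "id"),
               collapse = ", "), call. = FALSE)
  out <- unlist(lapply(records, function(r)
    c(paste0(">", r$id), r$sequence, r$labels)))
  writeLines(out, path)
  invisible(path)
}

#' One-hot encode a protein sequence into a 96 x 20 matrix
#'
#' Row i is the one-hot indicator of residue i in the fixed alphabetical
#' column order `ACDEFGHIKLMNPQRSTVWY`. Residues beyond position 96 are
#' discarded; ambiguity letters (X, B, Z, U, O) and padding rows beyond
#' the sequence length are all-zero.
#'
#' @param record A [protein_record()] or a plain sequence string.
#' @return A 96 x 20 numeric 0/1 matrix with the residue letters as
#'   column names.
#' @export
encode_sequence <- function(record) {
  if (is.character(record)) record <- protein_record("seq", record)
  chars <- strsplit(record$sequence, "")[[1]]
  if (length(chars) < 1L)
    stop("cannot encode an empty sequence", call. = FALSE)
  chars <- head(chars, INPUT_LEN)
  x <- matrix(0, INPUT_LEN, 20L, dimnames = list(NULL, AA_ALPHABET))
  col <- match(chars, AA_ALPHABET)        # NA for ambiguity letters
  keep <- which(!is.na(col))
  x[cbind(keep, col[keep])] <- 1
  x
}

#' One-hot encode per-residue labels into a 96 x 3 matrix
#'
#' Channel order is (S, T, N). Positions beyond the sequence length
#' (padding) are encoded as class N so that every row is a valid one-hot
#' vector; positions beyond 96 are discarded.
#'
#' @param record A labeled [protein_record()].
#' @return A 96 x 3 numeric 0/1 matrix with columns `S`, `T`, `N`; every
#'   row sums to exactly 1.
#' @export
encode_labels <- function(record) {
  if (is.null(record$labels))
    stop("record '", record$id, "' has no labels", call. = FALSE)
  chars <- head(strsplit(record$labels, "")[[1]], INPUT_LEN)
  y <- matrix(0, INPUT_LEN, 3L, dimnames = list(NULL, LABEL_ALPHABET))
  col <- c(rep(match(chars, LABEL_ALPHABET), length.out = length(chars)),
           rep(3L, INPUT_LEN - length(chars)))
  y[cbind(seq_len(INPUT_LEN), col)] <- 1
  y
}

#' Encode a list of records into network-ready samples
#'
#' @param records List of [protein_record()] objects.
#' @return A list of `encoded_sample` objects, each with the 96 x 20 input
#'   matrix `x`, the 96 x 3 label matrix `y` (when labels are present),
#'   the source id, the number of real (non-padding) positions `n_valid`,
#'   and the protein-level truth flags `true_is_sp` / `true_is_tm`.
#' @export
encode_records <- function(records) {
  lapply(records, function(r) {
    truth <- record_truth(r)
    structure(list(
      x = encode_sequence(r),
      y = if (!is.null(r$labels)) encode_labels(r) else NULL,
      source_id = r$id,
      n_valid = min(nchar(r$sequence), INPUT_LEN),
      true_is_sp = truth$is_sp,
      true_is_tm = truth$is_tm), class = "encoded_sample")
  })
}
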