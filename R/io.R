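#' Read a FASTA file of nucleotide sequences
#'
#' Parses a (possibly multi-line) FASTA file via Biostrings, uppercases the
#' residues and splits each header into an id (up to the first whitespace) and
#' a description (the remainder).  IUPAC ambiguity codes are preserved; they
#' are resolved only when a reference database is built (see
#' [resolve_ambiguity()]).
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A data frame with columns `id`, `description` and `sequence`.
#' @seealso [write_fasta()], [build_reference_db()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (any(ids == "")) stop("FASTA record with empty id in '", path, "'")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for FASTA record: ", ids[nchar(seqs) == 0L][1L])
  bad <- grepl(sprintf("[^%s]", IUPAC_CODES), seqs)
  if (any(bad))
    stop("non-IUPAC characters in FASTA record: ", ids[bad][1L])
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

IUPAC_CODES <- "ACGTNRYSWKMBDHV"

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences, or a data frame with
#'   columns `id` and `sequence` (optional `description`).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    desc <- if (!is.null(seqs$description)) seqs$description else ""
    ss <- seqs$sequence
  } else {
    ids <- names(seqs); desc <- ""; ss <- unname(seqs)
  }
  hdr <- ifelse(nzchar(desc), paste(ids, desc), ids)
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(ss)) {
    chunks <- substring(ss[i], seq(1L, nchar(ss[i]), by = width),
                        pmin(seq(1L, nchar(ss[i]), by = width) + width - 1L,
                             nchar(ss[i])))
    writeLines(c(paste0(">", hdr[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Decodes quality characters with the given Phred offset (33 or 64) and
#' extracts the per-read sample tag from the read id.  Read ids are expected
#' to follow the `"<sample_tag>:<serial>"` convention used throughout the
#' package; reads without a `":"` get an `NA` sample tag (only abundance
#' counting requires tags).  Gzip input is handled transparently.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param phred_offset Phred encoding offset, 33 (default) or 64.
#' @param mate Mate number to record (1 or 2).
#' @return A data frame with columns `id`, `mate`, `sample_tag`, `bases` and a
#'   list column `quals` of integer Phred scores.
#' @export
read_fastq <- function(path, phred_offset = 33L, mate = 1L) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (!phred_offset %in% c(33L, 64L)) stop("phred_offset must be 33 or 64")
  # structural validation first: Biostrings silently pads short quality
  # strings, so the length check must look at the raw records
  raw_lines <- readLines(path)
  if (length(raw_lines) %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': record count not a multiple of 4")
  n_seq <- nchar(raw_lines[seq(2L, length(raw_lines), by = 4L)])
  n_qual <- nchar(raw_lines[seq(4L, length(raw_lines), by = 4L)])
  if (any(n_seq != n_qual))
    stop("malformed FASTQ in '", path,
         "': sequence and quality lengths differ at record ",
         which(n_seq != n_qual)[1L])
  set <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
      path, quality.scoring = if (phred_offset == 33L) "phred" else "illumina")),
    error = function(e) stop("malformed FASTQ in '", path,
                             "' (or wrong Phred offset): ",
                             conditionMessage(e), call. = FALSE))
  bases <- toupper(as.character(set))
  names(bases) <- NULL
  quals <- tryCatch(
    lapply(as.list(methods::as(Biostrings::quality(set), "IntegerList")),
           as.integer),
    error = function(e) stop("malformed FASTQ in '", path,
                             "': bad quality string (",
                             conditionMessage(e), ")", call. = FALSE))
  if (length(quals) && min(unlist(lapply(quals, min), use.names = FALSE)) < 0L)
    stop("negative quality after decoding; wrong phred_offset?")
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids, mate = rep.int(as.integer(mate), length(ids)),
             sample_tag = parse_sample_tag(ids), bases = bases,
             quals = I(quals), stringsAsFactors = FALSE)
}

parse_sample_tag <- function(id) {
  tag <- sub(":.*$", "", id)
  ifelse(grepl(":", id, fixed = TRUE), tag, NA_character_)
}

#' Read a pair of FASTQ files as mated reads
#'
#' Mates are paired by file position; the two files must have the same number
#' of records and matching ids.
#'
#' @inheritParams read_fastq
#' @param path1,path2 Mate-1 and mate-2 FASTQ paths.
#' @return A data frame as in [read_fastq()], with an additional `pair`
#'   column indexing the read pair.
#' @export
read_fastq_pair <- function(path1, path2, phred_offset = 33L) {
  r1 <- read_fastq(path1, phred_offset, mate = 1L)
  r2 <- read_fastq(path2, phred_offset, mate = 2L)
  if (nrow(r1) != nrow(r2))
    stop("mate files have different numbers of reads")
  if (!all(r1$id == r2$id))
    stop("mate files have mismatching read ids")
  r1$pair <- seq_len(nrow(r1))
  r2$pair <- seq_len(nrow(r2))
  out <- rbind(r1, r2)
  rownames(out) <- NULL
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `bases` and list column `quals`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param phred_offset Phred encoding offset.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, phred_offset = 33L) {
  qstr <- vapply(reads$quals, function(q)
    rawToChar(as.raw(q + phred_offset)), character(1))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", qstr))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# SAM

# collapse an extended (=/X/I/D) CIGAR into the classic M/I/D alphabet
collapse_cigar <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    ops$op[ops$op %in% c("=", "X")] <- "M"
    r <- rle(ops$op)
    len <- vapply(seq_along(r$values), function(i) {
      sum(ops$len[cumsum(c(0L, r$lengths))[i] + seq_len(r$lengths[i])])
    }, integer(1))
    paste0(len, r$values, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# parse a CIGAR string into op/len vectors
cigar_ops <- function(cg) {
  len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cg)
  list(op = op, len = len)
}

cigar_ref_span <- function(cg) {
  ops <- cigar_ops(cg)
  sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
}

cigar_read_span <- function(cg) {
  ops <- cigar_ops(cg)
  sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
}

#' Write alignments as a SAM text file
#'
#' Emits a standard SAM file: an `@SQ` header line per reference and one
#' alignment line per record.  Internal coordinates are 0-based; POS is
#' emitted 1-based.  Match/mismatch runs are collapsed to `M` CIGAR
#' operations; the edit distance is carried in the `NM` tag.  Reads aligned
#' to the reverse strand carry flag 16 and their SEQ in reference
#' orientation; non-primary alignments carry flag 256.
#'
#' @param alignments Data frame with columns `read_id`, `gsc_id`, `ref_start`
#'   (0-based), `strand` (`"+"`/`"-"`), `cigar` (extended ops), `nm`, `seq`
#'   (reference-oriented bases), and optionally `qual` (encoded string) and
#'   `primary` (logical).
#' @param refs Named character vector of reference sequences, or a data frame
#'   with `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignments, refs, path) {
  if (is.data.frame(refs)) refs <- stats::setNames(refs$sequence, refs$id)
  if (nrow(alignments) && !all(alignments$gsc_id %in% names(refs)))
    stop("alignment references unknown GSC id: ",
         setdiff(alignments$gsc_id, names(refs))[1L])
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  lines <- hdr
  if (nrow(alignments)) {
    primary <- if (!is.null(alignments$primary)) alignments$primary else TRUE
    flag <- ifelse(alignments$strand == "-", 16L, 0L) +
      ifelse(primary, 0L, 256L)
    qual <- if (!is.null(alignments$qual)) alignments$qual else "*"
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                              alignments$read_id, flag, alignments$gsc_id,
                              alignments$ref_start + 1L,
                              collapse_cigar(alignments$cigar),
                              alignments$seq, qual, alignments$nm))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a SAM text file written by [write_alignment()]
#'
#' Parses the subset of SAM emitted by this package (single-segment records,
#' `NM` tag).  POS is converted back to the 0-based internal convention.
#'
#' @param path Path to a SAM file.
#' @return A list with `refs` (data frame `id`, `length`) and `alignments`
#'   (data frame `read_id`, `gsc_id`, `ref_start`, `strand`, `cigar`, `nm`,
#'   `seq`, `qual`, `primary`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  sq <- lines[startsWith(lines, "@SQ")]
  refs <- data.frame(
    id = sub("^.*\tSN:([^\t]+).*$", "\\1", sq),
    length = as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq)),
    stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body))
    return(list(refs = refs,
                alignments = data.frame(read_id = character(),
                                        gsc_id = character(),
                                        ref_start = integer(),
                                        strand = character(),
                                        cigar = character(), nm = integer(),
                                        seq = character(), qual = character(),
                                        primary = logical())))
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  list(refs = refs, alignments = data.frame(
    read_id = vapply(f, `[`, character(1), 1L),
    gsc_id = vapply(f, `[`, character(1), 3L),
    ref_start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = vapply(f, `[`, character(1), 6L),
    nm = nm,
    seq = vapply(f, `[`, character(1), 10L),
    qual = vapply(f, `[`, character(1), 11L),
    primary = bitwAnd(flag, 256L) == 0L,
    stringsAsFactors = FALSE))
}

#' Recover match/mismatch operations from M CIGARs
#'
#' SAM `M` operations do not distinguish matches from mismatches; given the
#' reference sequences this function re-expands each `M` run into `=`/`X`
#' runs by comparing SEQ with the reference.
#'
#' @param alignments Alignment data frame as returned by [read_sam()].
#' @param refs Named character vector of reference sequences.
#' @return The alignment data frame with extended-alphabet `cigar`.
#' @export
refine_alignment_ops <- function(alignments, refs) {
  if (is.data.frame(refs)) refs <- stats::setNames(refs$sequence, refs$id)
  alignments$cigar <- vapply(seq_len(nrow(alignments)), function(i) {
    ops <- cigar_ops(alignments$cigar[i])
    ref <- strsplit(refs[[alignments$gsc_id[i]]], "")[[1]]
    rd <- strsplit(alignments$seq[i], "")[[1]]
    rpos <- 1L; tpos <- alignments$ref_start[i] + 1L
    out_op <- character(0); out_len <- integer(0)
    push <- function(op, len) {
      n <- length(out_op)
      if (n && out_op[n] == op) out_len[n] <<- out_len[n] + len
      else { out_op <<- c(out_op, op); out_len <<- c(out_len, len) }
    }
    for (j in seq_along(ops$op)) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        eq <- rd[rpos:(rpos + len - 1L)] == ref[tpos:(tpos + len - 1L)]
        r <- rle(eq)
        for (s in seq_along(r$values))
          push(if (r$values[s]) "=" else "X", r$lengths[s])
        rpos <- rpos + len; tpos <- tpos + len
      } else if (op == "I") { push("I", len); rpos <- rpos + len }
      else if (op == "D") { push("D", len); tpos <- tpos + len }
      else stop("unsupported CIGAR op: ", op)
    }
    paste0(out_len, out_op, collapse = "")
  }, character(1))
  alignments
}

# ---------------------------------------------------------------------------
# newick

#' Parse a newick tree
#'
#' Wraps [ape::read.tree()] with the validation this package relies on: tip
#' labels must be unique and missing branch lengths default to 0.  The tree
#' is treated as rooted at its basal node.
#'
#' @param text A newick string, or a path to a newick file.
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch({
    if (length(text) == 1L && !grepl("(", text, fixed = TRUE) &&
        file.exists(text)) ape::read.tree(text)
    else ape::read.tree(text = text)
  }, error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick parse error (unbalanced parentheses or malformed input)")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

#' Patristic (tip-to-tip) distance matrix of a tree
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A symmetric matrix of path-length distances between tips.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

# ---------------------------------------------------------------------------
# TSV tables (samples as rows, GSCs as columns)

#' Write an abundance matrix as TSV
#'
#' Samples are rows, GSCs columns, with a leading `sample` column.
#'
#' @param A Numeric matrix with sample row names and GSC column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(A, path) {
  df <- data.frame(sample = rownames(A), as.data.frame(A),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path Path to a TSV with a `sample` column and one column per GSC.
#' @return Numeric matrix, samples as rows.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
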