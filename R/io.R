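# Readers and writers for the external formats the pipeline touches.
# All readers return tibbles in file order and never reorder records.

#' Read a FASTA file into a transcript table
#'
#' Sequences are upper-cased and U is mapped to T on read. The record id is
#' the header token before the first whitespace; the remainder of the header
#' is kept in `desc`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` and `desc`, one row per record,
#'   in file order. An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) {
    return(tibble::tibble(id = character(), seq = character(), desc = character()))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- normalize_seq(gsub("\\s", "", as.character(set)))
  if (any(nchar(seqs) < 1L)) {
    abort(sprintf(
      "zero-length sequence for id(s): %s",
      paste(ids[nchar(seqs) < 1L], collapse = ", ")
    ))
  }
  tibble::tibble(id = ids, seq = unname(seqs), desc = unname(desc))
}

#' Write a transcript table to FASTA
#'
#' @param transcripts Data frame with columns `id` and `seq` (and optionally
#'   `desc`, appended to the header after a space).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  check_transcripts(transcripts)
  desc <- if ("desc" %in% names(transcripts)) transcripts$desc
          else rep("", nrow(transcripts))
  header <- ifelse(nzchar(desc), paste(transcripts$id, desc), transcripts$id)
  lines <- purrr::map2(header, transcripts$seq, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

blast6_std_cols <- c(
  "query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bit_score"
)

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Accepts the 12 standard columns, optionally extended with `staxids` and
#' `sscinames` (outfmt "6 std staxids sscinames"). Columns beyond those are
#' ignored with a warning. Rows are returned in file order.
#'
#' @param path Path to a tab-separated hit table without header.
#' @return A tibble with the standard columns plus `subject_taxid` (integer,
#'   `NA` when absent) and `subject_sciname` (character, `NA` when absent).
#' @export
read_blast6 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- tibble::as_tibble(setNames(
      c(
        list(character(), character()), rep(list(numeric()), 10),
        list(integer(), character())
      ),
      c(blast6_std_cols, "subject_taxid", "subject_sciname")
    ))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 12L)) {
    abort(sprintf("malformed BLAST tabular row at line %d: fewer than 12 columns",
                  which(ncols < 12L)[1]))
  }
  if (any(ncols > 14L)) {
    warn(sprintf("ignoring columns beyond 14 in %d row(s)", sum(ncols > 14L)))
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  num <- function(i, name) {
    x <- suppressWarnings(as.numeric(get(i)))
    bad <- which(is.na(x))
    if (length(bad) > 0L) {
      abort(sprintf("malformed BLAST tabular row at line %d: non-numeric %s", bad[1], name))
    }
    x
  }
  out <- tibble::tibble(
    query_id = get(1), subject_id = get(2),
    pct_identity = num(3, "pct_identity"), aln_length = num(4, "aln_length"),
    mismatches = num(5, "mismatches"), gap_opens = num(6, "gap_opens"),
    q_start = num(7, "q_start"), q_end = num(8, "q_end"),
    s_start = num(9, "s_start"), s_end = num(10, "s_end"),
    evalue = num(11, "evalue"), bit_score = num(12, "bit_score")
  )
  taxid <- rep(NA_character_, length(fields))
  sci <- rep(NA_character_, length(fields))
  has13 <- ncols >= 13L
  has14 <- ncols >= 14L
  taxid[has13] <- vapply(fields[has13], `[[`, character(1), 13L)
  sci[has14] <- vapply(fields[has14], `[[`, character(1), 14L)
  # staxids may hold multiple ';'-separated ids; keep the first
  out$subject_taxid <- suppressWarnings(as.integer(sub(";.*$", "", taxid)))
  out$subject_sciname <- sci
  bad <- which(out$evalue < 0 | out$aln_length < 1 |
                 out$pct_identity < 0 | out$pct_identity > 100)
  if (length(bad) > 0L) {
    abort(sprintf("invalid hit values at line %d (evalue/aln_length/pct_identity out of range)", bad[1]))
  }
  out
}

#' Read per-read alignment scores from a SAM file
#'
#' Parses the minimal SAM subset the read-filtering rule needs: the unmapped
#' flag (0x4), the query sequence length, and the `AS:i` alignment-score tag.
#' Header lines are skipped. A mapped record without an `AS` tag is an error.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `read_id`, `read_length`, `aln_score`
#'   (`NA` for unmapped reads) and `mapped`.
#' @export
read_sam_scores <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(), read_length = integer(),
      aln_score = numeric(), mapped = logical()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed SAM record at line %d: fewer than 11 fields", bad[1]))
  }
  read_id <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  seq <- vapply(fields, `[[`, character(1), 10L)
  if (any(seq == "*")) {
    abort(sprintf("SAM record at line %d has no stored sequence (SEQ = '*')",
                  which(seq == "*")[1]))
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  score <- vapply(fields, function(f) {
    tag <- grep("^AS:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0L) NA_real_ else as.numeric(sub("^AS:i:", "", tag[[1]]))
  }, numeric(1))
  missing_as <- mapped & is.na(score)
  if (any(missing_as)) {
    abort(sprintf("mapped read '%s' lacks an AS:i alignment-score tag",
                  read_id[which(missing_as)[1]]))
  }
  score[!mapped] <- NA_real_
  tibble::tibble(
    read_id = read_id, read_length = nchar(seq),
    aln_score = score, mapped = mapped
  )
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene (or isoform)
#' ids. Values must be complete (no missing cells).
#'
#' @param path Path to a tab-separated matrix.
#' @param id_col Name given to the first column in the returned tibble.
#' @return A wide tibble: first column `id_col`, one numeric column per sample.
#' @export
read_expression <- function(path, id_col = "gene_id") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("expression table needs an id column and at least one sample")
  names(df)[1] <- id_col
  vals <- df[-1]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("non-numeric sample column in expression table")
  }
  if (anyNA(vals)) abort("expression table contains missing cells")
  tibble::as_tibble(df)
}

#' Write an expression matrix to TSV
#'
#' @param mat Wide tibble (first column ids, remaining columns samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isoform-to-gene map from TSV
#'
#' @param path Two-column tab-separated file (isoform id, gene id), with or
#'   without a header line.
#' @return A tibble with columns `isoform_id` and `gene_id`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("gene map needs two columns: isoform id, gene id")
  if (identical(tolower(df[1, 1]), "isoform_id")) df <- df[-1, , drop = FALSE]
  tibble::tibble(isoform_id = as.character(df[[1]]), gene_id = as.character(df[[2]]))
}

#' Read gene-to-term annotations from TSV
#'
#' Expects columns `gene_id`, `term_id`, `term_name`, `term_level`,
#' `namespace` (GO or KEGG). `(gene_id, term_id)` pairs must be unique.
#'
#' @param path Path to a tab-separated annotation table with a header row.
#' @return A tibble of annotations.
#' @export
read_term_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("gene_id", "term_id", "term_name", "term_level", "namespace")
  if (!all(need %in% names(df))) {
    abort(sprintf("annotation table must have columns: %s", paste(need, collapse = ", ")))
  }
  check_annotations(df)
  df
}

check_annotations <- function(annotations) {
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "term_id") %in% names(annotations))) {
    abort("`annotations` must be a data frame with columns `gene_id` and `term_id`")
  }
  if (anyDuplicated(annotations[c("gene_id", "term_id")])) {
    abort("duplicate (gene_id, term_id) pair in annotations")
  }
  invisible(annotations)
}
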