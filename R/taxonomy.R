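# Taxonomy tables and MEGAN-like last-common-ancestor affiliation.
#
# A taxonomy is a tibble with columns `taxid`, `parent`, `rank`, `name`,
# where the root is its own parent and every parent chain terminates at the
# root. Lineages are walked with a parent lookup, so the table can be the
# NCBI nodes/names dialect or any simplified tree.

#' Read a taxonomy from a 4-column TSV
#'
#' Columns: taxid, parent taxid, rank, name (header optional; detected when
#' the first field is not numeric).
#'
#' @param path Path to the tab-separated taxonomy.
#' @return A validated taxonomy tibble (see [taxonomy_table()]).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) abort("taxonomy TSV needs 4 columns: taxid, parent, rank, name")
  if (is.na(suppressWarnings(as.integer(df[1, 1])))) df <- df[-1, , drop = FALSE]
  taxonomy_table(
    taxid = as.integer(df[[1]]), parent = as.integer(df[[2]]),
    rank = as.character(df[[3]]), name = as.character(df[[4]])
  )
}

#' Read a taxonomy from NCBI nodes.dmp / names.dmp files
#'
#' Only scientific names are kept from `names.dmp`.
#'
#' @param nodes_path Path to `nodes.dmp` (fields separated by `\t|\t`).
#' @param names_path Path to `names.dmp`.
#' @return A validated taxonomy tibble.
#' @export
read_taxonomy_ncbi <- function(nodes_path, names_path) {
  split_dmp <- function(path) {
    lines <- readLines(path)
    strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  }
  nodes <- split_dmp(nodes_path)
  nm <- split_dmp(names_path)
  nm <- nm[vapply(nm, function(f) length(f) >= 4 && f[[4]] == "scientific name", logical(1))]
  name_map <- setNames(
    vapply(nm, `[[`, character(1), 2L),
    vapply(nm, `[[`, character(1), 1L)
  )
  taxid <- as.integer(vapply(nodes, `[[`, character(1), 1L))
  taxonomy_table(
    taxid = taxid,
    parent = as.integer(vapply(nodes, `[[`, character(1), 2L)),
    rank = vapply(nodes, `[[`, character(1), 3L),
    name = unname(name_map[as.character(taxid)])
  )
}

#' Build and validate a taxonomy table
#'
#' @param taxid,parent Integer vectors; the root must be its own parent.
#' @param rank,name Character vectors.
#' @return A tibble of class `taxonomy_tbl` with attribute `root`.
#' @export
taxonomy_table <- function(taxid, parent, rank, name) {
  tax <- tibble::tibble(
    taxid = as.integer(taxid), parent = as.integer(parent),
    rank = as.character(rank), name = as.character(name)
  )
  if (anyDuplicated(tax$taxid)) abort("duplicate taxid in taxonomy")
  root <- tax$taxid[tax$taxid == tax$parent]
  if (length(root) != 1L) abort("taxonomy must have exactly one root (its own parent)")
  parent_of <- setNames(tax$parent, tax$taxid)
  if (!all(tax$parent %in% tax$taxid)) abort("taxonomy parent refers to unknown taxid")
  # every chain must terminate at the root
  for (t in tax$taxid) {
    seen <- integer(0)
    cur <- t
    while (cur != root) {
      if (cur %in% seen) abort(sprintf("taxonomy cycle involving taxid %d", cur))
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  attr(tax, "root") <- root
  class(tax) <- c("taxonomy_tbl", class(tax))
  tax
}

tax_root <- function(taxonomy) attr(taxonomy, "root")

# Root-to-node path of taxids.
tax_path <- function(taxid, taxonomy) {
  parent_of <- setNames(taxonomy$parent, taxonomy$taxid)
  key <- as.character(taxid)
  if (!key %in% names(parent_of)) abort(sprintf("unknown taxid: %s", key))
  root <- tax_root(taxonomy)
  path <- taxid
  cur <- taxid
  while (cur != root) {
    cur <- parent_of[[as.character(cur)]]
    path <- c(cur, path)
  }
  path
}

#' Select the hits that support an LCA affiliation
#'
#' Drops hits below the bit-score floor, then keeps hits whose bit score is
#' within the top fraction of the best survivor (inclusive), the MEGAN-like
#' top-percent rule.
#'
#' @param hits Hit table for one query (see [read_blast6()]).
#' @param bitscore_min Bit-score floor (default 80).
#' @param top_fraction Keep hits with `bit_score >= top_fraction * max`
#'   (default 0.95).
#' @return The retained rows of `hits`, in input order.
#' @export
select_lca_hits <- function(hits, bitscore_min = 80, top_fraction = 0.95) {
  if (top_fraction <= 0 || top_fraction > 1) abort("`top_fraction` must be in (0, 1]")
  keep <- hits$bit_score >= bitscore_min
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  hits[hits$bit_score >= top_fraction * max(hits$bit_score), , drop = FALSE]
}

#' Last common ancestor of a set of taxa
#'
#' The deepest node on the intersection of all root paths. A single taxid is
#' its own LCA.
#'
#' @param taxids Integer vector of taxids present in `taxonomy`.
#' @param taxonomy A taxonomy tibble.
#' @return A single taxid.
#' @export
compute_lca <- function(taxids, taxonomy) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) abort("`taxids` is empty")
  paths <- lapply(taxids, tax_path, taxonomy = taxonomy)
  common <- Reduce(intersect, paths)
  # intersect preserves the order of the first (root-first) path
  common[length(common)]
}

broad_groups <- c(
  "Viridiplantae", "Kinetoplastida", "other Eukaryota",
  "Bacteria", "Archaea", "other cellular organisms", "unclassified"
)

#' Broad taxonomic group of a taxon
#'
#' Specific groups (Viridiplantae, Kinetoplastida) take precedence over the
#' Eukaryota fallback; Bacteria and Archaea are reported as such; anything
#' else is "other cellular organisms". `NA` maps to "unclassified".
#'
#' @param taxid Integer vector of taxids (NA allowed).
#' @param taxonomy A taxonomy tibble.
#' @return Character vector of broad group labels.
#' @export
classify_broad_group <- function(taxid, taxonomy) {
  vapply(taxid, function(t) {
    if (is.na(t)) return("unclassified")
    nm <- taxonomy$name[match(tax_path(t, taxonomy), taxonomy$taxid)]
    if ("Viridiplantae" %in% nm) return("Viridiplantae")
    if ("Kinetoplastida" %in% nm) return("Kinetoplastida")
    if ("Eukaryota" %in% nm) return("other Eukaryota")
    if ("Bacteria" %in% nm) return("Bacteria")
    if ("Archaea" %in% nm) return("Archaea")
    "other cellular organisms"
  }, character(1))
}

#' MEGAN-like LCA affiliation of transcripts from a hit table
#'
#' For each query: apply the bit-score floor and top-fraction rule
#' ([select_lca_hits()]), take the LCA of the retained hit taxa, and report
#' its broad group. Hits without a subject taxid are skipped with a warning.
#'
#' @param hits Hit table with `query_id`, `bit_score`, `subject_taxid`.
#' @param taxonomy A taxonomy tibble.
#' @inheritParams select_lca_hits
#' @return A tibble with `transcript_id`, `taxid` (NA when unclassified),
#'   `name`, `broad_group` and `n_support_hits`, one row per query, in order
#'   of first appearance.
#' @export
assign_lca <- function(hits, taxonomy, bitscore_min = 80, top_fraction = 0.95) {
  if (anyNA(hits$subject_taxid)) {
    warn(sprintf("skipping %d hit(s) without subject taxid", sum(is.na(hits$subject_taxid))))
  }
  queries <- unique(hits$query_id)
  rows <- lapply(queries, function(q) {
    h <- select_lca_hits(
      hits[hits$query_id == q, , drop = FALSE],
      bitscore_min = bitscore_min, top_fraction = top_fraction
    )
    taxa <- h$subject_taxid[!is.na(h$subject_taxid)]
    if (length(taxa) == 0L) {
      return(tibble::tibble(
        transcript_id = q, taxid = NA_integer_, name = NA_character_,
        broad_group = "unclassified", n_support_hits = 0L
      ))
    }
    lca <- compute_lca(taxa, taxonomy)
    tibble::tibble(
      transcript_id = q, taxid = lca,
      name = taxonomy$name[match(lca, taxonomy$taxid)],
      broad_group = classify_broad_group(lca, taxonomy),
      n_support_hits = length(taxa)
    )
  })
  dplyr::bind_rows(rows)
}

#' Decide whether a transcript is organelle-encoded
#'
#' Organelle-encoded proteins are called only on near-perfect evidence: a hit
#' with percent identity at or above the threshold whose alignment covers
#' both query and subject end-to-end with strictly identical lengths.
#'
#' @param hits Hit table for one query against the organelle protein set;
#'   must carry `query_length` and `subject_length` columns.
#' @param identity_min Minimum percent identity (default 99).
#' @param require_identical_length Require
#'   `aln_length == query_length == subject_length` (default TRUE).
#' @return A single logical.
#' @export
is_organelle_encoded <- function(hits, identity_min = 99,
                                 require_identical_length = TRUE) {
  if (nrow(hits) == 0L) return(FALSE)
  if (!all(c("query_length", "subject_length") %in% names(hits)) ||
      anyNA(hits$query_length) || anyNA(hits$subject_length)) {
    abort("organelle rule needs `query_length` and `subject_length` on every hit")
  }
  ok <- hits$pct_identity >= identity_min
  if (require_identical_length) {
    ok <- ok & hits$aln_length == hits$query_length &
      hits$aln_length == hits$subject_length
  }
  any(ok)
}
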