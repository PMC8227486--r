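# Single entry point chaining the analysis stages over files on disk,
# driven by a structured config (R list or YAML path). Each enabled stage
# reads its inputs, writes TSV/JSON outputs into `out_dir`, and the run
# manifest records parameters, seeds, input digests and per-stage row
# counts. TSV outputs use a fixed column order and 6 significant digits so
# reruns are byte-stable.

pipeline_stage_order <- c(
  "stats", "decontam", "sl", "lca", "tnf", "express", "cluster", "enrich"
)

write_tsv6 <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric),
    function(x) ifelse(x == round(x), x, signif(x, 6))
  ))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline from a config
#'
#' Executes the enabled stages in dependency order (stats, decontam, sl,
#' lca, tnf, express, cluster, enrich). The config is a named list (or a
#' YAML file path) with elements `out_dir`, `seed`, `inputs` (paths:
#' `fasta`, `blast6`, `sam`, `taxonomy`, `tpm`, `gene_map`, `annotations`),
#' `stages` (named logical toggles) and optional `params` (per-stage
#' parameter lists passed to the stage function). Unknown top-level or
#' stage keys are rejected. A failing stage aborts with the stage named;
#' its partial output is kept with a `.partial` suffix.
#'
#' @param config Named list or path to a YAML config file.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  allowed <- c("out_dir", "seed", "inputs", "stages", "params")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$out_dir)) abort("config needs `out_dir`")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  bad_stage <- setdiff(names(stages), pipeline_stage_order)
  if (length(bad_stage) > 0L) {
    abort(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  }
  enabled <- pipeline_stage_order[vapply(
    pipeline_stage_order, function(s) isTRUE(stages[[s]]), logical(1)
  )]
  inputs <- config$inputs
  for (p in unlist(inputs)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  params <- config$params

  manifest <- list(
    package = "transqc",
    version = as.character(utils::packageVersion("transqc")),
    seed = seed,
    params = params,
    inputs = lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list()
  )

  run_stage <- function(name, fun) {
    outputs <- tryCatch(
      fun(),
      error = function(e) {
        partials <- list.files(out_dir, pattern = paste0("^", name, "\\."),
                               full.names = TRUE)
        for (f in partials) file.rename(f, paste0(f, ".partial"))
        abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
      }
    )
    manifest$stages[[name]] <<- outputs
  }

  needs <- function(key, stage) {
    if (is.null(inputs[[key]])) {
      abort(sprintf("stage '%s' needs input `%s`", stage, key))
    }
    inputs[[key]]
  }
  stage_params <- function(name) {
    if (is.null(params[[name]])) list() else params[[name]]
  }

  for (s in enabled) {
    switch(
      s,
      stats = run_stage("stats", function() {
        tx <- read_fasta(needs("fasta", "stats"))
        res <- summarize_assembly(tx)
        jsonlite::write_json(as.list(res), file.path(out_dir, "stats.json"),
                             auto_unbox = TRUE, digits = NA)
        list(n_transcripts = nrow(tx), file = "stats.json")
      }),
      decontam = run_stage("decontam", function() {
        hits <- read_blast6(needs("blast6", "decontam"))
        scr <- do.call(screen_contaminants,
                       c(list(best_hit_per_query(hits)), stage_params("decontam")))
        write_tsv6(tidy(scr), file.path(out_dir, "decontam.tally.tsv"))
        writeLines(scr$flagged_transcripts,
                   file.path(out_dir, "decontam.flagged_transcripts.txt"))
        out <- list(n_hits = nrow(hits),
                    n_flagged = length(scr$flagged_transcripts),
                    file = "decontam.tally.tsv")
        if (!is.null(inputs$sam)) {
          reads <- filter_reads(read_sam_scores(inputs$sam))
          out$reads_removed <- sum(reads$removed)
          out$reads_total <- nrow(reads)
          out$rpm <- rpm(sum(reads$removed), nrow(reads))
          write_tsv6(reads[c("read_id", "removed")],
                     file.path(out_dir, "decontam.reads.tsv"))
        }
        out
      }),
      sl = run_stage("sl", function() {
        p <- stage_params("sl")
        if (is.null(p$sl_seq)) abort("sl stage needs params$sl$sl_seq")
        tx <- read_fasta(needs("fasta", "sl"))
        m <- scan_sl(tx, p$sl_seq,
                     min_match = p$min_match %||% 24L,
                     window = p$window %||% 40L)
        write_tsv6(m, file.path(out_dir, "sl.matches.tsv"))
        write_tsv6(sl_summary(m, nrow(tx)), file.path(out_dir, "sl.summary.tsv"))
        list(n_matches = nrow(m), file = "sl.matches.tsv")
      }),
      lca = run_stage("lca", function() {
        hits <- read_blast6(needs("blast6", "lca"))
        tax <- read_taxonomy(needs("taxonomy", "lca"))
        res <- do.call(assign_lca, c(list(hits, tax), stage_params("lca")))
        write_tsv6(res, file.path(out_dir, "lca.tsv"))
        list(n_assigned = sum(res$broad_group != "unclassified"), file = "lca.tsv")
      }),
      tnf = run_stage("tnf", function() {
        p <- stage_params("tnf")
        tx <- read_fasta(needs("fasta", "tnf"))
        prof <- gc_partition(tnf_profiles(tx), n_parts = p$n_parts %||% 4L)
        pca <- tnf_pca(prof, n = p$n %||% 1000L, reps = p$reps %||% 10L,
                       seed = seed)
        write_tsv6(as.data.frame(pca), file.path(out_dir, "tnf.pca.tsv"))
        list(n_profiles = nrow(prof), file = "tnf.pca.tsv")
      }),
      express = run_stage("express", function() {
        p <- stage_params("express")
        tpm <- read_expression(needs("tpm", "express"), id_col = "isoform_id")
        if (!is.null(inputs$gene_map)) {
          tpm <- pool_to_gene(tpm, read_gene_map(inputs$gene_map))
        } else {
          names(tpm)[1] <- "gene_id"
        }
        z <- top_variable(transform_expression(tpm, p$pseudocount %||% 1.0),
                          top_n = p$top_n %||% 2500L)
        write_tsv6(z, file.path(out_dir, "express.z.tsv"))
        list(n_genes = nrow(z), file = "express.z.tsv")
      }),
      cluster = run_stage("cluster", function() {
        p <- stage_params("cluster")
        z <- read_expression(file.path(out_dir, "express.z.tsv"))
        sel <- select_k(z, k_min = p$k_min %||% 5L, k_max = p$k_max %||% 75L)
        write_tsv6(tidy(sel), file.path(out_dir, "cluster.labels.tsv"))
        write_tsv6(sel$scan, file.path(out_dir, "cluster.scan.tsv"))
        list(best_k = sel$best_k, n_genes = nrow(tidy(sel)),
             file = "cluster.labels.tsv")
      }),
      enrich = run_stage("enrich", function() {
        p <- stage_params("enrich")
        labels <- tibble::as_tibble(utils::read.delim(
          file.path(out_dir, "cluster.labels.tsv"), stringsAsFactors = FALSE
        ))
        ann <- read_term_annotations(needs("annotations", "enrich"))
        enr <- do.call(enrich_clusters, c(list(labels, ann), p))
        write_tsv6(enr, file.path(out_dir, "enrich.tsv"))
        net <- build_kappa_network(enr, ann)
        write_tsv6(net$edges, file.path(out_dir, "enrich.edges.tsv"))
        list(n_tested = nrow(enr), n_significant = sum(enr$significant),
             n_edges = nrow(net$edges), file = "enrich.tsv")
      })
    )
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
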