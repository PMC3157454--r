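#' Read and write tab-separated pipeline tables
#'
#' The pipeline interchange dialect: tab-separated, header row, `NA` for
#' missing values.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the imprinting-calling pipeline end to end
#'
#' Orchestrates the analysis stages in the order the calling logic requires:
#' per-gene exact imprinting and cis tests with BH correction and
#' confidence-bound factors on the reciprocal count table, the coverage
#' filter, the final classification, the optional seed-coat contamination
#' filter, and the optional genomic-context stages (DMR association and
#' mini-cluster detection over the called genes). Outputs are written as TSV
#' together with a JSON run manifest (parameters, seed, input checksums,
#' output checksums), so identical inputs, configuration, and seed give
#' byte-identical outputs.
#'
#' @param counts Reciprocal count table (see [imprinting_results()]) or a
#'   path to its TSV.
#' @param tissue `"endosperm"` or `"embryo"`.
#' @param cfg A [criteria_config()].
#' @param reference Optional reference expression table (or TSV path) for
#'   the seed-coat filter.
#' @param seedcoat_threshold Contamination threshold (log2).
#' @param genes Optional `GRanges` of gene bodies with `gene_id` for the
#'   context stages.
#' @param dmrs Optional `GRanges` of DMRs.
#' @param flank_bp,window_bp Context-stage parameters.
#' @param n_draws Random draws for the DMR enrichment.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the enrichment draws (recorded in the manifest).
#' @return Invisibly, a list with `results` (the final per-gene table),
#'   `enrichment`, `clusters`, and `manifest`.
#' @export
run_pipeline <- function(counts, tissue = c("endosperm", "embryo"),
                         cfg = criteria_config(), reference = NULL,
                         seedcoat_threshold = SEEDCOAT_THRESHOLD_DEFAULT,
                         genes = NULL, dmrs = NULL, flank_bp = 2000,
                         window_bp = 10000, n_draws = 1000,
                         out_dir, seed = 1L) {
  tissue <- match.arg(tissue)
  input_files <- character(0)
  if (is.character(counts)) {
    if (!file.exists(counts)) stop("count table not found: ", counts)
    input_files["counts"] <- counts
    counts <- read_tsv_table(counts)
  }
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference table not found: ", reference)
    input_files["reference"] <- reference
    reference <- read_tsv_table(reference)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- imprinting_results(counts, tissue = tissue, cfg = cfg)
  if (!is.null(reference)) {
    results <- apply_seedcoat_filter(results, reference, tissue,
                                     threshold = seedcoat_threshold)
  }
  out_tab <- results
  num <- vapply(out_tab, is.double, logical(1))
  out_tab[num] <- lapply(out_tab[num], signif, 7)
  write_tsv_table(out_tab, file.path(out_dir, "imprinting_results.tsv"))

  enrichment <- NULL
  clusters <- NULL
  if (!is.null(genes) && !is.null(dmrs)) {
    called <- results$gene_id[results$call %in% c("MEG", "PEG")]
    if (length(called) > 0) {
      enrichment <- dmr_enrichment(called, genes, dmrs, flank_bp = flank_bp,
                                   n_draws = n_draws, seed = seed)
      write_tsv_table(as.data.frame(enrichment),
                      file.path(out_dir, "dmr_enrichment.tsv"))
      clusters <- find_miniclusters(genes[genes$gene_id %in% called],
                                    window_bp = window_bp,
                                    informative = genes)
      write_tsv_table(clusters, file.path(out_dir, "miniclusters.tsv"))
    }
  }

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "imprintcall",
    version = as.character(utils::packageVersion("imprintcall")),
    tissue = tissue,
    criteria = unclass(cfg),
    seedcoat_threshold = seedcoat_threshold,
    flank_bp = flank_bp, window_bp = window_bp, n_draws = n_draws,
    seed = seed,
    n_genes = nrow(results),
    calls = as.list(table(results$call)),
    input_md5 = as.list(tools::md5sum(input_files)),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, enrichment = enrichment,
                 clusters = clusters, manifest = manifest))
}
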