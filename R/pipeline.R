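## End-to-end orchestration: simulate (or ingest) -> compare ->
## hemizygosity -> homologs -> de -> promoters -> qc, with a manifest of
## content hashes so unchanged stages can be skipped on re-runs.

file_rows <- function(path) {
  n <- length(readLines(path, warn = FALSE))
  max(n - 1L, 0L)  # header-bearing TSVs dominate; FASTA/VCF approximate
}

stage_record <- function(outputs) {
  lapply(outputs, function(f)
    list(path = f, md5 = unname(tools::md5sum(f)), rows = file_rows(f)))
}

outputs_match <- function(manifest, stage, outputs) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  paths <- vapply(rec$outputs, function(x) x$path, character(1))
  if (!setequal(paths, outputs) || !all(file.exists(outputs)))
    return(FALSE)
  md5 <- vapply(rec$outputs, function(x) x$md5, character(1))
  all(unname(tools::md5sum(paths)) == md5)
}

#' Run the full haplotype-comparison pipeline
#'
#' Executes all stages in dependency order under one output directory,
#' writing every artefact through the package's format writers plus a
#' JSON manifest (config snapshot, seed, per-stage output hashes and row
#' counts, wall status). On re-runs, a stage whose outputs exist and
#' match the manifest hashes is skipped and its outputs are re-ingested;
#' supplying `region_calls_tsv` skips the comparison stage entirely and
#' feeds the ingested calls to every downstream stage.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @param region_calls_tsv optional path to an externally produced
#'   region-call TSV (e.g. converted SyRI output).
#' @param overwrite if `TRUE`, every stage re-runs regardless of hashes.
#' @return the manifest, invisibly; also written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_all <- function(config, outdir, region_calls_tsv = NULL,
                    overwrite = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(outdir, "manifest.json")
  old <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else list(stages = list())
  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = list())
  p <- function(...) file.path(outdir, paste0(...))
  ran <- character(0)

  run_stage <- function(name, outputs, compute, load) {
    t0 <- Sys.time()
    if (!overwrite && outputs_match(old, name, outputs)) {
      val <- load()
      manifest$stages[[name]] <<- list(
        status = "skipped", seconds = round(as.numeric(
          Sys.time() - t0, units = "secs"), 2),
        outputs = stage_record(outputs))
      return(val)
    }
    val <- compute()
    if (!all(file.exists(outputs)))
      stop("stage '", name, "' did not produce: ",
           outputs[!file.exists(outputs)][1])
    manifest$stages[[name]] <<- list(
      status = "ran", seconds = round(as.numeric(
        Sys.time() - t0, units = "secs"), 2),
      outputs = stage_record(outputs))
    ran <<- c(ran, name)
    val
  }

  ## stage: simulate -------------------------------------------------------
  sim_out <- c(p("hap1.fa"), p("hap2.fa"), p("genes_hap1.gff3"),
               p("genes_hap2.gff3"), p("counts_hap1.tsv"),
               p("counts_hap2.tsv"), p("genetic_map.tsv"),
               p("truth_regions.tsv"))
  sim <- run_stage("simulate", sim_out, compute = function() {
    s <- simulate_diploid(config)
    write_genome(s$hap1, p("hap1.fa"))
    write_genome(s$hap2, p("hap2.fa"))
    write_annotation(s$genes_h1, p("genes_hap1.gff3"))
    write_annotation(s$genes_h2, p("genes_hap2.gff3"))
    write_counts(s$expr_h1, p("counts_hap1.tsv"))
    write_counts(s$expr_h2, p("counts_hap2.tsv"))
    write_genetic_map(s$markers, p("genetic_map.tsv"))
    write_region_calls(s$truth$regions, p("truth_regions.tsv"))
    s
  }, load = function() simulate_diploid(config))

  ## stage: compare --------------------------------------------------------
  cmp_out <- c(p("regions.tsv"), p("variants.vcf"),
               p(paste0("regions_", tolower(REGION_TYPES), ".bed")))
  calls <- if (!is.null(region_calls_tsv)) {
    read_region_calls(region_calls_tsv)
  } else {
    run_stage("compare", cmp_out, compute = function() {
      anchors <- find_anchors(sim$hap1, sim$hap2)
      chains <- chain_anchors(anchors)
      calls <- classify_regions(chains, sim$hap1, sim$hap2)
      write_region_calls(calls, p("regions.tsv"))
      write_vcf(calls, sim$hap1, sim$hap2, p("variants.vcf"))
      for (ty in REGION_TYPES) {
        x <- calls[calls$type == ty & !is.na(calls$ref_chrom) &
                     calls$ref_end > calls$ref_start, , drop = FALSE]
        write_bed(data.frame(chrom = x$ref_chrom, start = x$ref_start,
                             end = x$ref_end, name = x$type),
                  p(paste0("regions_", tolower(ty), ".bed")))
      }
      calls
    }, load = function() read_region_calls(p("regions.tsv")))
  }

  ## stage: hemizygosity ---------------------------------------------------
  hemi_out <- c(p("hemizygosity.tsv"), p("hemizygosity_summary.tsv"))
  hemi <- run_stage("hemizygosity", hemi_out, compute = function() {
    rec <- call_hemizygous(sim$genes_h1, sim$genes_h2, calls)
    rec <- categorize_hemizygous(rec, sim$genes_h1, sim$genes_h2, calls)
    utils::write.table(rec, p("hemizygosity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summarize_categories(rec),
                       p("hemizygosity_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rec
  }, load = function()
    utils::read.table(p("hemizygosity.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))

  ## stage: homologs -------------------------------------------------------
  hom_out <- p("homolog_pairs.tsv")
  pairs <- run_stage("homologs", hom_out, compute = function() {
    pr <- pair_homologs(sim$genes_h1, sim$genes_h2, calls)
    utils::write.table(pr, hom_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pr
  }, load = function()
    utils::read.table(hom_out, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))

  ## stage: de -------------------------------------------------------------
  de_out <- p("de_results.tsv")
  de <- run_stage("de", de_out, compute = function() {
    idp <- filter_identical(pairs)
    res <- de_between_haplotypes(compute_tpm(sim$expr_h1),
                                 compute_tpm(sim$expr_h2), idp)
    utils::write.table(res, de_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res
  }, load = function()
    utils::read.table(de_out, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))

  ## stage: promoters ------------------------------------------------------
  prom_out <- c(p("promoter_burden.tsv"), p("promoter_comparison.tsv"),
                p("promoters.bed"))
  run_stage("promoters", prom_out, compute = function() {
    pm <- rbind(extract_promoters(sim$genes_h1, sim$hap1),
                extract_promoters(sim$genes_h2, sim$hap2))
    burden <- count_promoter_variants(pm, calls)
    utils::write.table(burden, p("promoter_burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed(data.frame(chrom = pm$chrom, start = pm$start, end = pm$end,
                         name = pm$gene_id), p("promoters.bed"))
    sm <- de_pair_summary(de)
    idp <- filter_identical(pairs)
    dep <- sm[sm$de_flag, c("gene_id_h1", "gene_id_h2")]
    ndp <- sm[!sm$de_flag, c("gene_id_h1", "gene_id_h2")]
    cmpb <- compare_de_burden(burden, dep, ndp)
    utils::write.table(
      data.frame(n_de = cmpb$n_de, n_nonde = cmpb$n_nonde,
                 median_de = cmpb$median_de,
                 median_nonde = cmpb$median_nonde,
                 p_value = cmpb$p_value, direction = cmpb$direction),
      p("promoter_comparison.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    burden
  }, load = function()
    utils::read.table(p("promoter_burden.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))

  ## stage: qc -------------------------------------------------------------
  qc_out <- c(p("telomere_windows.tsv"), p("map_concordance.tsv"),
              p("assembly_stats.tsv"))
  run_stage("qc", qc_out, compute = function() {
    tel <- telomere_scan(sim$hap1)
    wins <- do.call(rbind, lapply(tel, function(x) x$windows))
    utils::write.table(wins, p("telomere_windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(map_concordance(sim$markers),
                       p("map_concordance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    st <- assembly_stats(sim$hap1)
    utils::write.table(st$chromosomes, p("assembly_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    st
  }, load = function()
    utils::read.table(p("assembly_stats.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))

  manifest$ran <- ran
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}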