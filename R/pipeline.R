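# End-to-end pipeline wiring and publication-style report rendering.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Run the full synthetic pipeline
#'
#' simulate -> render -> type -> phase -> associate -> GWAS, writing
#' every stage's table plus a JSON run manifest (package version, seed,
#' per-file MD5 hashes, per-stage counts) into \code{outdir}. Re-running
#' with the same configuration produces byte-identical outputs.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if absent).
#' @param force overwrite an existing non-empty manifest (default stops
#'   rather than silently overwriting).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir, force = FALSE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifestPath <- file.path(outdir, "manifest.json")
  if (file.exists(manifestPath) && !force)
    stop("outputs already present in ", outdir, "; use force = TRUE")

  lib <- simulateLibrary(config, seed = config$seed)
  cohort <- simulateCohort(config, seed = config$seed + 1L)
  consensus <- renderConsensus(cohort, lib, errorRate = 0)
  samples <- cohort[, c("dog_id", "status")]

  calls <- callGenotypes(consensus, lib)
  phase <- inferHaplotypes(calls, lociNames = loci(lib))
  hapCounts <- countHaplotypes(phase$diplotypes, samples)

  alleleAssoc <- associationReport(tabulateAlleleCounts(calls, samples))
  hapAssoc <- associationReport(tabulateHaplotypeCounts(hapCounts))
  homAssoc <- associationReport(tabulateHomozygosity(calls, samples,
                                                     lociNames = loci(lib)))

  snps <- simulateSnpDataset(config, seed = config$seed + 2L)
  gwas <- gwasRun(snps)

  paths <- c(
    library = writeAlleleLibrary(lib, file.path(outdir, "library.fasta")),
    consensus = writeConsensusFasta(consensus,
                                    file.path(outdir, "consensus.fasta")),
    samples = .writeTsv(samples, file.path(outdir, "samples.tsv")),
    truth = .writeTsv(cohort, file.path(outdir, "truth.tsv")),
    calls = .writeTsv(calls, file.path(outdir, "calls.tsv")),
    haplotypes = .writeTsv(phase$diplotypes,
                           file.path(outdir, "haplotypes.tsv")),
    haplotype_counts = .writeTsv(hapCounts,
                                 file.path(outdir, "haplotype_counts.tsv")),
    assoc_allele = .writeTsv(alleleAssoc,
                             file.path(outdir, "assoc_allele.tsv")),
    assoc_haplotype = .writeTsv(hapAssoc,
                                file.path(outdir, "assoc_haplotype.tsv")),
    assoc_homozygosity = .writeTsv(homAssoc,
                                   file.path(outdir,
                                             "assoc_homozygosity.tsv")),
    gwas_results = .writeTsv(gwas$results,
                             file.path(outdir, "gwas_results.tsv")),
    manhattan = .writeTsv(gwas$manhattan,
                          file.path(outdir, "manhattan.tsv")),
    qq = .writeTsv(gwas$qq, file.path(outdir, "qq.tsv")))
  geno <- writeSnpDataset(snps, file.path(outdir, "geno.tsv"),
                          file.path(outdir, "snps.map.tsv"))
  paths <- c(paths, geno = geno[1L], map = geno[2L])

  manifest <- list(
    package = "dlatyper",
    version = as.character(utils::packageVersion("dlatyper")),
    seed = config$seed,
    files = as.list(stats::setNames(tools::md5sum(unname(paths)),
                                    basename(unname(paths)))),
    counts = list(
      dogs_typed = length(unique(calls$dog_id)),
      haplotypes_discovered = length(phase$haplotypes),
      dogs_unidentified =
        sum(phase$diplotypes$status == "unidentified"),
      snps_input = gwas$summary$n_snps_input,
      snps_tested = gwas$summary$n_snps_after_qc,
      lambda_gc = round(gwas$summary$lambda_gc, 3)))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message(sprintf(
    "pipeline: %d dogs typed, %d haplotypes discovered, %d SNPs tested, lambda %.3f",
    manifest$counts$dogs_typed, manifest$counts$haplotypes_discovered,
    manifest$counts$snps_tested, gwas$summary$lambda_gc))
  invisible(manifest)
}

#' Render a publication-style association report
#'
#' Formats an [associationReport()] table the way the field prints it:
#' frequencies and OR/CI to 2 decimals, P to 4 decimals (configurable),
#' an \code{OR (95\% CI)} column, and a \code{significant} flag at
#' two-sided p < 0.05 (uncorrected, mirroring the presentation
#' convention of candidate-locus typing studies).
#'
#' @param assoc data.frame from [associationReport()].
#' @param orDigits,freqDigits,pDigits rounding for display.
#' @param alpha significance threshold for flagging.
#' @return data.frame of formatted strings plus logical
#'   \code{significant}; full precision stays in the input table.
#' @export
renderReport <- function(assoc, orDigits = 2L, freqDigits = 2L,
                         pDigits = 4L, alpha = 0.05) {
  fmt <- function(x, d) ifelse(is.na(x), "N/A",
                               formatC(round(x, d), format = "f",
                                       digits = d))
  data.frame(
    feature = assoc$feature,
    n_affected = assoc$n_affected,
    freq_affected = fmt(assoc$freq_affected, freqDigits),
    n_control = assoc$n_control,
    freq_control = fmt(assoc$freq_control, freqDigits),
    p_value = fmt(assoc$p_value, pDigits),
    or_ci = ifelse(is.na(assoc$or_value), "N/A",
                   sprintf("%s (%s-%s)", fmt(assoc$or_value, orDigits),
                           fmt(assoc$ci_low, orDigits),
                           fmt(assoc$ci_high, orDigits))),
    significant = !is.na(assoc$p_value) & assoc$p_value < alpha,
    stringsAsFactors = FALSE)
}

#' Write a rendered report as Markdown
#'
#' One pipe table; significant rows are bolded.
#'
#' @param report data.frame from [renderReport()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportMarkdown <- function(report, path) {
  emph <- function(x, sig) ifelse(sig, paste0("**", x, "**"), x)
  hdr <- c("Feature", "N affected", "Freq affected", "N control",
           "Freq control", "P-value", "OR (95% CI)")
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"),
                    "|"))
  for (i in seq_len(nrow(report))) {
    cells <- vapply(
      c("feature", "n_affected", "freq_affected", "n_control",
        "freq_control", "p_value", "or_ci"),
      function(cn) emph(as.character(report[[cn]][i]),
                        report$significant[i]), "")
    lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
  }
  writeLines(lines, path)
  invisible(path)
}
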