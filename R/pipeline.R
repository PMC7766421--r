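#' Assemble a pipeline configuration
#'
#' Defaults follow the study conventions: rare means MAF < 0.01, the genomic
#' SNP track uses a 10,000 bp window with a 1,000 bp step, the protein-space
#' track a 100 aa window with a 10 aa step, and the group-consensus
#' threshold is 0.9.
#'
#' @param vcf,gff3,cds_fasta input paths (required).
#' @param flank_up_bp,flank_down_bp regulatory flank lengths (required).
#' @param seed integer seed for the Monte-Carlo test (required).
#' @param alignment_fasta,groups_tsv,domains_tsv,functional_sites_tsv
#'   optional inputs enabling the conservation, pN/pS-by-domain and
#'   prioritization stages.
#' @param reference_id alignment sequence treated as the reference.
#' @param maf_key VCF INFO key holding the MAF.
#' @param window_genomic,window_protein `c(window, step)` pairs.
#' @param consensus_threshold within-group consensus threshold.
#' @param n_replicates Monte-Carlo replicates for the enrichment test.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, gff3, cds_fasta, flank_up_bp, flank_down_bp,
                            seed, out_dir,
                            alignment_fasta = NULL, groups_tsv = NULL,
                            domains_tsv = NULL, functional_sites_tsv = NULL,
                            reference_id = "ref", maf_key = "MAF",
                            window_genomic = c(10000, 1000),
                            window_protein = c(100, 10),
                            consensus_threshold = 0.9,
                            n_replicates = 10000) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full locus analysis pipeline
#'
#' Reads the SNPs, gene model, CDS and optional alignment/domain inputs,
#' then emits the full report bundle: region summary with rare/common
#' split, domain-partitioned site/density table, pN/pS table with
#' Monte-Carlo p-values for subregions, genomic and protein-space window
#' tracks, the intron report, conservation profiles with kingdom-specific
#' differences, the non-synonymous variant priority table, and a
#' machine-readable run manifest. Reruns with the same configuration
#' produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML file with the same
#'   fields.
#' @return invisible named list of the report tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  tables <- list()

  model <- read_gene_model(config$gff3, config$flank_up_bp,
                           config$flank_down_bp)
  cds <- read_cds(config$cds_fasta)
  snps <- read_snps(config$vcf, maf_key = config$maf_key)

  message("locusvar: ", nrow(snps), " SNPs, locus ",
          model$locus_end - model$locus_start + 1L, " bp, seed ",
          config$seed)

  tables$region_summary <- summarize_regions(snps, model, cds)
  cls <- attr(tables$region_summary, "classified")
  write_report_tsv(tables$region_summary, out("region_summary.tsv"),
                   round_cols = "density")

  # domain-partitioned site counts and pN/pS
  domains <- if (!is.null(config$domains_tsv))
    read_domains(config$domains_tsv) else list()
  n_cod <- nchar(cds) %/% 3L
  counted <- seq_len(n_cod - 1L)          # terminal stop excluded
  regions <- c(list(full_length = counted),
               lapply(domains, function(d) seq(d[1], d[2])))
  if (length(domains)) {
    dom_union <- sort(unique(unlist(regions[names(domains)])))
    regions$domain_total <- dom_union
    regions$non_domain <- setdiff(counted, dom_union)
  }
  coding <- cls[!is.na(cls$effect), , drop = FALSE]
  site_rows <- list(); pnps_rows <- list()
  for (r in names(regions)) {
    cod_set <- intersect(regions[[r]], counted)
    sc <- count_sites(cds, cod_set, region_name = r)
    in_r <- coding$codon_index %in% cod_set
    n_ns <- sum(in_r & coding$effect == "non_synonymous")
    n_s <- sum(in_r & coding$effect == "synonymous")
    site_rows[[r]] <- data.frame(
      region = r,
      snp_type = c("cSNP", "sSNP", "nsSNP"),
      length_bp = c(3 * sc$n_codons, sc$syn_sites, sc$nonsyn_sites),
      n_snps = c(n_ns + n_s, n_s, n_ns),
      density = c(
        snp_density(n_ns + n_s, 3 * sc$n_codons),
        if (sc$syn_sites > 0) snp_density(n_s, sc$syn_sites) else 0,
        if (sc$nonsyn_sites > 0) snp_density(n_ns, sc$nonsyn_sites) else 0))
    ratio <- pn_ps(n_ns, sc$nonsyn_sites, n_s, sc$syn_sites, region_name = r)
    p_val <- NA_real_
    if (r != "full_length") {
      sig <- pnps_significance(cds, cod_set, n_ns, n_s,
                               total_coding_snps = nrow(coding),
                               n_replicates = config$n_replicates,
                               seed = config$seed)
      p_val <- sig$p_value
    }
    pnps_rows[[r]] <- data.frame(
      region = r, n_nsSNP = n_ns, nonsyn_sites = sc$nonsyn_sites,
      n_sSNP = n_s, syn_sites = sc$syn_sites,
      pn = ratio$pn, ps = ratio$ps, ratio = ratio$ratio,
      undefined = ratio$undefined, p_value = p_val)
  }
  tables$site_counts <- do.call(rbind, site_rows)
  tables$pnps <- do.call(rbind, pnps_rows)
  rownames(tables$site_counts) <- rownames(tables$pnps) <- NULL
  write_report_tsv(tables$site_counts, out("site_counts.tsv"),
                   round_cols = c("length_bp", "density"))
  write_report_tsv(tables$pnps, out("pnps.tsv"), round_cols = "ratio")

  # window tracks
  wg <- config$window_genomic
  tables$windows_genomic <- window_counts(
    snps$pos, model$locus_start, model$locus_end + 1L, wg[1], wg[2])
  write_report_tsv(tables$windows_genomic, out("windows_genomic.tsv"))
  wp <- config$window_protein
  tables$windows_protein <- window_counts(
    coding$protein_position, 1L, n_cod + 1L, wp[1], wp[2],
    categories = coding$effect)
  write_report_tsv(tables$windows_protein, out("windows_protein.tsv"))

  # intron report
  tables$introns <- intron_map(model)
  write_report_tsv(tables$introns, out("introns.tsv"))

  # conservation and prioritization
  profile <- NULL
  if (!is.null(config$alignment_fasta)) {
    aln <- read_protein_alignment(config$alignment_fasta)
    profile <- column_conservation(aln, config$reference_id)
    tables$conservation <- profile
    write_report_tsv(profile, out("conservation.tsv"),
                     round_cols = "conservation_pct")
    if (!is.null(config$groups_tsv)) {
      gdf <- utils::read.table(config$groups_tsv, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      groups <- stats::setNames(gdf$group, gdf$name)
      tables$kingdom_differences <-
        kingdom_specific_positions(aln, groups, config$consensus_threshold)
      write_report_tsv(tables$kingdom_differences,
                       out("kingdom_differences.tsv"))
    }
  }
  sites <- if (!is.null(config$functional_sites_tsv))
    read_functional_sites(config$functional_sites_tsv) else NULL
  ns <- coding[coding$effect == "non_synonymous",
               c("snp_id", "ref_aa", "alt_aa", "protein_position", "maf")]
  if (nrow(ns)) {
    tables$priority <- prioritize_variants(ns, functional_sites = sites,
                                           conservation = profile)
    write_report_tsv(tables$priority, out("priority.tsv"),
                     round_cols = "conservation_pct")
  }

  # run manifest: parameters, seed and input hashes (no timestamp, so
  # reruns are byte-identical)
  inputs <- unlist(config[c("vcf", "gff3", "cds_fasta", "alignment_fasta",
                            "groups_tsv", "domains_tsv",
                            "functional_sites_tsv")])
  manifest <- list(
    package = "locusvar",
    version = as.character(utils::packageVersion("locusvar")),
    parameters = config[c("flank_up_bp", "flank_down_bp", "maf_key",
                          "window_genomic", "window_protein",
                          "consensus_threshold", "n_replicates", "seed",
                          "reference_id")],
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(tables)
}
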