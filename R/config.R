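#' Default pipeline configuration
#'
#' Every threshold used by the package is a named configuration key. Defaults
#' are the values applied in the clinical pipeline this package models:
#' base-quality floors for read tallying (15 for SNVs, 5 for indels in
#' capture validation), the four-criteria cross-validation depth floor (20X
#' in normal), the capture-validation adjudication cutoffs (Fisher alpha
#' 0.05, germline normal MAF 0.2, somatic tumor MAF 0.05, homopolymer mutant
#' floor 10), coverage QC fractions (80% of coding exons at >= 20X for
#' germline DNA, 30% for tumor RNA), the detection-power rule (3 reads to
#' detect, 1 to cross-validate), the WES copy-number concordance log2 shift
#' (0.2), and the catalog-curation filters (control carriers > 10 of 6500,
#' hypermutator >= 100 coding variants in the study's top 10%).
#'
#' @return Nested named list of configuration values.
#' @examples
#' defaultConfig()$crossval$min_normal_depth
#' @export
defaultConfig <- function() {
    list(
        crossval = list(
            min_base_quality = 15L,
            min_normal_depth = 20L,
            min_supporting = 3L,
            min_read_quality = 20L,
            window = 5L,
            min_flank = 10L,
            window_scope = "site_and_window"
        ),
        capval = list(
            min_bq_snv = 15L,
            min_bq_indel = 5L,
            wildtype_min_depth = 20L,
            alpha = 0.05,
            germline_normal_maf = 0.2,
            somatic_min_tumor_maf = 0.05,
            homopolymer_min_mutant = 10L,
            homopolymer_run_length = 7L
        ),
        purity = list(
            max_components = 5L,
            maf_transform = "double",
            germline_af_fixed = NULL
        ),
        power = list(
            min_detect_reads = 3L,
            min_support_reads = 1L,
            depth_wgs = 38,
            depth_wes = 110,
            depth_rna = 0
        ),
        svlink = list(
            cna_boundary_tolerance_bp = 1000L,
            gene_body_extension_bp = 5000L,
            strict = TRUE
        ),
        classify = list(
            max_control_carriers = 10L,
            control_cohort_size = 6500L,
            hypermut_min_coding = 100L,
            hypermut_top_fraction = 0.10,
            truncation_fraction_min = 0.3,
            hotspot_min_recurrence = 3L
        ),
        metrics = list(
            germline_exon_fraction = 0.80,
            rna_exon_fraction = 0.30,
            coverage_depth = 20L,
            log2_threshold = 0.2
        )
    )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over \code{\link{defaultConfig}}:
#' keys absent from the file keep their defaults, supplied keys override
#' them (recursively for nested sections).
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @return Nested named list as \code{\link{defaultConfig}}.
#' @export
readConfig <- function(path = NULL) {
    cfg <- defaultConfig()
    if (is.null(path)) return(cfg)
    user <- yaml::read_yaml(path)
    mergeLists(cfg, user)
}

mergeLists <- function(base, override) {
    for (k in names(override)) {
        if (is.list(base[[k]]) && is.list(override[[k]]))
            base[[k]] <- mergeLists(base[[k]], override[[k]])
        else
            base[[k]] <- override[[k]]
    }
    base
}

#' Structured audit record for a filtering decision
#'
#' Every filtering decision in the package reports a variant identifier, the
#' rule that fired and the outcome, so a clinical-style audit trail can be
#' reconstructed from the output tables.
#'
#' @param id Variant/marker identifier.
#' @param rule Rule identifier (e.g. "crossval:criterion2").
#' @param outcome Outcome label.
#' @param detail Optional free-text detail.
#' @return One-row data.frame with columns id, rule, outcome, detail.
#' @export
auditRecord <- function(id, rule, outcome, detail = "") {
    data.frame(id = as.character(id), rule = as.character(rule),
               outcome = as.character(outcome), detail = as.character(detail),
               stringsAsFactors = FALSE)
}

siteKey <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}
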