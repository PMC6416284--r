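# Sample metadata and phenotype tables.
#
# The treatment design is fixed by the study: four phosphate sources with
# known %P2O5 (Control 0, Catalao rock phosphate CA 2.93, Bayovar rock
# phosphate BA 14, simple superphosphate SS 18), crossed with presence/absence
# of mycorrhizal inoculum.

SOURCE_P2O5 <- c(Control = 0, CA = 2.93, BA = 14, SS = 18)

#' %P2O5 of each phosphate source
#'
#' @param source Character vector of source labels
#'   (`"Control"`, `"CA"`, `"BA"`, `"SS"`).
#' @return Numeric vector of soluble phosphate percentages.
#' @export
#' @examples
#' p2o5_for_source(c("Control", "BA"))
p2o5_for_source <- function(source) {
  bad <- setdiff(unique(source), names(SOURCE_P2O5))
  if (length(bad))
    stop("unknown phosphate source label(s): ", paste(bad, collapse = ", "))
  unname(SOURCE_P2O5[source])
}

validate_sample_table <- function(samples) {
  need <- c("sample_id", "source", "inoculum", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  samples$source <- as.character(samples$source)
  expected <- p2o5_for_source(samples$source)  # errors on unknown labels
  if (is.null(samples$p2o5_percent)) {
    samples$p2o5_percent <- expected
  } else if (any(abs(samples$p2o5_percent - expected) > 1e-8)) {
    i <- which(abs(samples$p2o5_percent - expected) > 1e-8)[1]
    stop(sprintf("p2o5_percent %.3f inconsistent with source %s (expected %.3f)",
                 samples$p2o5_percent[i], samples$source[i], expected[i]))
  }
  if (is.character(samples$inoculum))
    samples$inoculum <- samples$inoculum %in% c("TRUE", "true", "yes", "1", "+")
  samples$inoculum <- as.logical(samples$inoculum)
  if (anyNA(samples$inoculum)) stop("inoculum must be logical")
  samples$replicate <- as.integer(samples$replicate)
  samples
}

validate_phenotype_table <- function(phenotypes, samples) {
  if (!"sample_id" %in% names(phenotypes))
    stop("phenotype table missing sample_id")
  phenotypes$sample_id <- as.character(phenotypes$sample_id)
  extra <- setdiff(phenotypes$sample_id, samples$sample_id)
  if (length(extra))
    stop("phenotype sample(s) absent from metadata: ",
         paste(extra, collapse = ", "))
  if (!"total_dry_matter" %in% names(phenotypes))
    stop("phenotype table missing total_dry_matter")
  if (any(phenotypes$total_dry_matter <= 0))
    stop("total_dry_matter must be positive")
  if (!is.null(phenotypes$colonization_index)) {
    ci <- phenotypes$colonization_index
    if (any(ci < 0 | ci > 100)) stop("colonization_index must lie in [0, 100]")
    inoc <- samples$inoculum[match(phenotypes$sample_id, samples$sample_id)]
    if (any(ci[!inoc] > 0))
      stop("nonzero colonization recorded for a sample without inoculum")
  }
  phenotypes
}

#' Read and cross-validate sample metadata and phenotype tables
#'
#' Both files are TSVs with a header row. The metadata table must contain
#' `sample_id`, `source`, `inoculum`, `replicate` (an optional `p2o5_percent`
#' column is checked against the fixed source-to-%P2O5 map). The phenotype
#' table must contain `sample_id` and `total_dry_matter` (g/pot); optional
#' columns are `colonization_index` (% of root cortex colonized, forced to 0
#' without inoculum), `leaf_n`, `leaf_p`, `leaf_k` (g/kg).
#'
#' @param metadata_path Path to the sample metadata TSV.
#' @param phenotype_path Path to the phenotype TSV.
#' @return A list with validated data frames `samples` and `phenotypes`.
#' @export
read_tables <- function(metadata_path, phenotype_path) {
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  if (!file.exists(phenotype_path))
    stop("phenotype file not found: ", phenotype_path)
  samples <- read.delim(metadata_path, stringsAsFactors = FALSE)
  phenotypes <- read.delim(phenotype_path, stringsAsFactors = FALSE)
  samples <- validate_sample_table(samples)
  phenotypes <- validate_phenotype_table(phenotypes, samples)
  list(samples = samples, phenotypes = phenotypes)
}
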