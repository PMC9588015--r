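# Shared readers/writers. Internal coordinates are 0-based half-open;
# everything exported to TSV is 1-based. TSV files carry a '#'-prefixed
# header line and are UTF-8 tab-delimited.

#' Write a TSV with a '#'-prefixed header
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_hash <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  body <- readr::format_tsv(df, col_names = FALSE)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read a TSV with a '#'-prefixed header
#' @param path Input path.
#' @param col_types Optional readr column specification.
#' @return A tibble.
#' @export
read_tsv_hash <- function(path, col_types = NULL) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) {
    abort(sprintf("%s: expected a '#'-prefixed header line.", path),
      class = "mrdtrace_schema_error"
    )
  }
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  readr::read_tsv(
    path,
    skip = 1, col_names = cols, col_types = col_types %||% readr::cols(),
    progress = FALSE, show_col_types = FALSE
  )
}

#' Write paired FASTQ files
#'
#' @param reads Tibble with `read_id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @param path_r1,path_r2 Output paths (".gz" suffixes compress).
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, path_r1, path_r2) {
  check_columns(reads, c("read_id", "seq1", "seq2", "qual1", "qual2"), "Read table")
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- reads$read_id
    Biostrings::writeXStringSet(
      x, path,
      format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path)
    )
  }
  write_one(reads$seq1, reads$qual1, path_r1)
  write_one(reads$seq2, reads$qual2, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read paired FASTQ files
#'
#' Parses Phred+33 paired FASTQ (plain or gzip) into a read-pair tibble.
#' Mismatched pair counts or malformed records are errors.
#'
#' @param path_r1,path_r2 FASTQ paths.
#' @return Tibble with `read_id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  read_one <- function(path) {
    tryCatch(
      {
        # Biostrings notes dropped metadata columns on FASTQ import; the
        # id/seq/qual triple is all this layer carries.
        x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
        list(
          id = unname(sub(" .*", "", names(x))),
          seq = unname(as.character(x)),
          qual = unname(as.character(Biostrings::quality(x)))
        )
      },
      error = function(e) {
        abort(
          sprintf("Malformed FASTQ %s: %s", path, conditionMessage(e)),
          class = "mrdtrace_io_error"
        )
      }
    )
  }
  r1 <- read_one(path_r1)
  r2 <- read_one(path_r2)
  if (length(r1$seq) != length(r2$seq)) {
    abort(
      sprintf(
        "Read-pair count mismatch: %d records in %s vs %d in %s.",
        length(r1$seq), path_r1, length(r2$seq), path_r2
      ),
      class = "mrdtrace_io_error"
    )
  }
  tibble::tibble(
    read_id = r1$id,
    seq1 = r1$seq,
    seq2 = r2$seq,
    qual1 = r1$qual,
    qual2 = r2$qual
  )
}

VARIANT_COLUMNS <- c(
  "patient_id", "chrom", "pos", "ref_allele", "alt_allele", "gene_symbol",
  "consequence_class", "tissue_vaf", "depth", "population_af",
  "mq0_fraction", "known_variant", "confidence"
)

#' Write a somatic variant table
#' @param variants Variant tibble (1-based `pos`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  check_columns(variants, VARIANT_COLUMNS, "Variant table")
  write_tsv_hash(variants[, VARIANT_COLUMNS], path)
}

#' Read a somatic variant table (TSV or minimal VCF)
#'
#' TSV files must carry the defined '#'-header schema; files ending in
#' `.vcf` are parsed as a minimal VCF 4.2 subset whose INFO keys carry the
#' filter covariates (GENE, CLASS, TVAF, DP, PAF, MQ0F, KNOWN, CONF) and
#' whose sample column name is the patient id. Positions are 1-based in
#' both encodings; `pos < 1` is a schema error.
#'
#' @param path Input path.
#' @return A typed tibble of somatic variants.
#' @export
read_variant_table <- function(path) {
  out <- if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_variant_vcf(path)
  } else {
    read_tsv_hash(path, col_types = readr::cols(
      patient_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref_allele = readr::col_character(),
      alt_allele = readr::col_character(),
      gene_symbol = readr::col_character(),
      consequence_class = readr::col_character(),
      tissue_vaf = readr::col_double(),
      depth = readr::col_double(),
      population_af = readr::col_double(),
      mq0_fraction = readr::col_double(),
      known_variant = readr::col_logical(),
      confidence = readr::col_character()
    ))
  }
  check_columns(out, VARIANT_COLUMNS, sprintf("Variant table %s", path))
  if (any(out$pos < 1)) {
    abort("Variant positions must be 1-based (pos >= 1).",
      class = "mrdtrace_schema_error"
    )
  }
  out
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF input requires the vcfR package.", class = "mrdtrace_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  info_field <- function(key) vcfR::extract.info(v, element = key)
  tibble::tibble(
    patient_id = info_field("PATIENT"),
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref_allele = fix$REF,
    alt_allele = fix$ALT,
    gene_symbol = info_field("GENE"),
    consequence_class = info_field("CLASS"),
    tissue_vaf = as.numeric(info_field("TVAF")),
    depth = as.numeric(info_field("DP")),
    population_af = as.numeric(info_field("PAF")),
    mq0_fraction = as.numeric(info_field("MQ0F")),
    known_variant = info_field("KNOWN") == "1",
    confidence = info_field("CONF")
  )
}

#' Write a panel manifest
#'
#' Exports panel targets with 1-based inclusive amplicon coordinates
#' (`start`, `end`) converted from the internal 0-based half-open
#' representation.
#'
#' @param panels Panel tibble from [design_cohort_panels()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel_manifest <- function(panels, path) {
  out <- tibble::tibble(
    patient_id = panels$patient_id,
    chrom = panels$chrom,
    start = panels$amplicon_start + 1L,
    end = panels$amplicon_end,
    pos = panels$pos,
    ref = panels$ref_allele,
    alt = panels$alt_allele,
    gene = panels$gene_symbol,
    amplicon_id = panels$amplicon_id,
    primer_pair_id = panels$primer_pair_id,
    pool_id = if ("pool_id" %in% names(panels)) panels$pool_id else NA_character_
  )
  write_tsv_hash(out, path)
}

#' Read a panel manifest
#' @param path Manifest TSV path.
#' @return Panel tibble with internal 0-based half-open coordinates.
#' @export
read_panel_manifest <- function(path) {
  raw <- read_tsv_hash(path)
  tibble::tibble(
    patient_id = raw$patient_id,
    chrom = raw$chrom,
    amplicon_start = raw$start - 1L,
    amplicon_end = raw$end,
    pos = raw$pos,
    ref_allele = raw$ref,
    alt_allele = raw$alt,
    gene_symbol = raw$gene,
    amplicon_id = raw$amplicon_id,
    primer_pair_id = raw$primer_pair_id,
    pool_id = raw$pool_id
  )
}
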