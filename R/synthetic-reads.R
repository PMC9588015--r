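# Read-level simulator: UMI-tagged paired-end amplicon reads with a
# configurable per-base error model and full per-locus template truth, so
# the UMI consensus and allele-counting stages can be verified exactly
# (zero-error runs round-trip to truth counts).

#' Error model for simulated amplicon reads
#'
#' @param per_base_substitution_rate Probability a sequenced base is
#'   substituted (uniformly to one of the three other bases).
#' @param no_call_rate Probability a sequenced base is an N.
#' @param umi_length UMI length prepended to read 2 (default 10).
#' @param family_size_mean Mean reads per template; family sizes are
#'   1 + Poisson(`family_size_mean` - 1) so every template is read at least
#'   once.
#' @param templates_per_amplicon Unique template molecules per amplicon
#'   (desk-scale default 2000).
#' @return A list of class `error_model`.
#' @export
error_model <- function(per_base_substitution_rate = 0.001,
                        no_call_rate = 0.0005,
                        umi_length = 10,
                        family_size_mean = 4,
                        templates_per_amplicon = 2000) {
  check_probability(per_base_substitution_rate, "per_base_substitution_rate",
    allow_one = FALSE
  )
  check_probability(no_call_rate, "no_call_rate", allow_one = FALSE)
  if (family_size_mean < 1) {
    abort("family_size_mean must be >= 1.", class = "mrdtrace_config_error")
  }
  structure(
    list(
      per_base_substitution_rate = per_base_substitution_rate,
      no_call_rate = no_call_rate,
      umi_length = check_count(umi_length, "umi_length", min = 1),
      family_size_mean = family_size_mean,
      templates_per_amplicon = check_count(
        templates_per_amplicon, "templates_per_amplicon",
        min = 1
      )
    ),
    class = "error_model"
  )
}

BASES <- c("A", "C", "G", "T")

# Apply substitution + no-call noise to an integer-coded base matrix
# (1..4 = ACGT, 5 = N). Substitutions move to one of the three other bases
# uniformly.
apply_noise <- function(mat, sub_rate, n_rate) {
  if (sub_rate > 0) {
    hit <- which(matrix(runif(length(mat)) < sub_rate, nrow(mat)))
    if (length(hit)) {
      mat[hit] <- ((mat[hit] - 1 + sample(1:3, length(hit), replace = TRUE)) %% 4) + 1
    }
  }
  if (n_rate > 0) {
    hit <- which(matrix(runif(length(mat)) < n_rate, nrow(mat)))
    if (length(hit)) mat[hit] <- 5L
  }
  mat
}

int_to_seq <- function(mat) {
  chars <- c(BASES, "N")[mat]
  dim(chars) <- dim(mat)
  apply(chars, 1, paste, collapse = "")
}

seq_to_int <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c(BASES, "N"))
}

#' Attach reference amplicon sequences to a panel
#'
#' Gives each panel target a concrete amplicon context: a random reference
#' sequence spanning the amplicon interval with the reference allele at the
#' variant offset, the corresponding alt sequence, and the primer anchor
#' (the first `anchor_length` bases) used for read assignment.
#'
#' @param panel Panel targets from [select_panel()].
#' @param anchor_length Anchor prefix length (default 20).
#' @return `panel` with `ref_seq`, `alt_seq`, `variant_offset` (0-based)
#'   and `anchor` columns.
#' @export
build_amplicon_sequences <- function(panel, anchor_length = 20) {
  len <- panel$amplicon_end - panel$amplicon_start
  offset <- panel$pos - 1L - panel$amplicon_start # 0-based within amplicon
  seqs <- purrr::pmap_chr(
    list(len, offset, panel$ref_allele),
    function(l, off, ref) {
      v <- sample(BASES, l, replace = TRUE)
      v[off + 1] <- ref
      paste(v, collapse = "")
    }
  )
  alt_seqs <- purrr::pmap_chr(
    list(seqs, offset, panel$alt_allele),
    function(s, off, alt) {
      substr(s, off + 1, off + 1) <- alt
      s
    }
  )
  dplyr::mutate(
    panel,
    ref_seq = seqs,
    alt_seq = alt_seqs,
    variant_offset = offset,
    anchor = substr(seqs, 1, anchor_length)
  )
}

#' Simulate UMI-tagged paired-end amplicon reads
#'
#' For each panel amplicon, draws `templates_per_amplicon` template
#' molecules of which Binomial(`templates`, allele fraction) carry the alt
#' allele, assigns each template a random UMI and a family size of
#' 1 + Poisson, and emits read pairs: read 1 is the amplicon sequence,
#' read 2 is the UMI followed by the template sequence, both with
#' substitution and no-call noise applied per base. Per-locus template
#' truth (the realized alt-template Binomial draw) is returned alongside
#' the reads, and qualities are constant Q30.
#'
#' @param panel Panel with amplicon sequences ([build_amplicon_sequences()]).
#' @param signal_fraction Allele fraction at each locus (scalar, recycled,
#'   or one value per panel row).
#' @param em An [error_model()].
#' @return A list: `reads` (tibble `read_id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`), `truth` (per-amplicon template and alt-template counts),
#'   `templates` (per-template UMI, allele and family size).
#' @export
simulate_amplicon_reads <- function(panel, signal_fraction, em = error_model()) {
  check_columns(panel, c("amplicon_id", "ref_seq", "alt_seq", "variant_offset"), "Panel")
  if (nrow(panel) == 0) {
    abort("Panel is empty.", class = "mrdtrace_panel_error")
  }
  af <- rep_len(signal_fraction, nrow(panel))
  if (any(af < 0 | af > 1)) {
    abort("signal_fraction must be in [0, 1].", class = "mrdtrace_input_error")
  }
  lens <- nchar(panel$ref_seq)
  if (any(panel$variant_offset < 0 | panel$variant_offset >= lens)) {
    abort("Variant locus falls outside its amplicon.", class = "mrdtrace_design_error")
  }

  per_amp <- purrr::pmap(
    list(panel$amplicon_id, panel$ref_seq, panel$alt_seq, af),
    function(amp, ref_seq, alt_seq, afi) {
      n_t <- em$templates_per_amplicon
      n_alt <- rbinom(1, n_t, afi)
      is_alt <- c(rep(TRUE, n_alt), rep(FALSE, n_t - n_alt))
      # Each template gets a distinct UMI (ideal molecular barcodes;
      # barcode collisions are a real-data feature not emulated here).
      codes <- sample.int(4^em$umi_length, n_t) - 1L
      umi_mat <- matrix(0L, nrow = n_t, ncol = em$umi_length)
      for (p in seq_len(em$umi_length)) {
        umi_mat[, p] <- codes %% 4L + 1L
        codes <- codes %/% 4L
      }
      umis <- int_to_seq(umi_mat)
      fam_size <- 1L + rpois(n_t, em$family_size_mean - 1)

      ref_int <- seq_to_int(ref_seq)
      alt_int <- seq_to_int(alt_seq)
      tpl_idx <- rep.int(seq_len(n_t), fam_size)
      read_mat <- matrix(
        rep(ref_int, length(tpl_idx)),
        nrow = length(tpl_idx), byrow = TRUE
      )
      alt_rows <- is_alt[tpl_idx]
      if (any(alt_rows)) {
        read_mat[alt_rows, ] <- matrix(
          rep(alt_int, sum(alt_rows)),
          nrow = sum(alt_rows), byrow = TRUE
        )
      }
      r1_mat <- apply_noise(read_mat, em$per_base_substitution_rate, em$no_call_rate)
      r2_tpl <- apply_noise(read_mat, em$per_base_substitution_rate, em$no_call_rate)
      r2_umi <- apply_noise(
        umi_mat[tpl_idx, , drop = FALSE],
        em$per_base_substitution_rate, em$no_call_rate
      )

      copy_n <- sequence(fam_size)
      list(
        reads = tibble::tibble(
          read_id = sprintf("%s:t%05d:r%d", amp, tpl_idx, copy_n),
          seq1 = int_to_seq(r1_mat),
          seq2 = paste0(int_to_seq(r2_umi), int_to_seq(r2_tpl))
        ),
        truth = tibble::tibble(
          amplicon_id = amp, templates = n_t, alt_templates = n_alt,
          allele_fraction = afi
        ),
        templates = tibble::tibble(
          amplicon_id = amp, template_id = seq_len(n_t),
          umi = umis, is_alt = is_alt, family_size = fam_size
        )
      )
    }
  )

  reads <- dplyr::bind_rows(purrr::map(per_amp, "reads"))
  reads$qual1 <- strrep("?", nchar(reads$seq1))
  reads$qual2 <- strrep("?", nchar(reads$seq2))
  list(
    reads = reads,
    truth = dplyr::bind_rows(purrr::map(per_amp, "truth")),
    templates = dplyr::bind_rows(purrr::map(per_amp, "templates"))
  )
}
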