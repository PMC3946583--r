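# Comparison of predicted (transcriptome) and measured (cloned genomic)
# sequences: base / amino-acid difference percentages and intron
# inference from the global alignment.

# 27x27 identity-style substitution matrix over the amino-acid
# alphabet (match +1, mismatch -1); gaps handled by the aligner
aa_submat <- function(match = 1, mismatch = -1) {
  a <- Biostrings::AA_ALPHABET
  m <- matrix(mismatch, length(a), length(a), dimnames = list(a, a))
  diag(m) <- match
  m
}

#' Optimal global (Needleman-Wunsch) alignment of two sequences
#'
#' Fixed scoring: match +1, mismatch -1, gap open 5, gap extend 1
#' (penalties). Returns the aligned strings plus the column tallies the
#' difference percentages are computed from.
#'
#' @param a,b DNA (or, with `alphabet = "AA"`, protein) strings.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return list with `score`, `aligned_a`, `aligned_b`, `n_col`,
#'   `n_match`, `n_mismatch`, `n_gap_col`.
#' @export
global_align <- function(a, b, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be nonempty")
  if (alphabet == "DNA") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(a), b, type = "global",
      substitutionMatrix = dna_submat(1, -1),
      gapOpening = 5, gapExtension = 1)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = aa_submat(),
      gapOpening = 5, gapExtension = 1)
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  st <- aln_column_stats(pa, sa)
  list(score = BiocGenerics::score(aln), aligned_a = pa, aligned_b = sa,
       n_col = st$n_col, n_match = st$n_match,
       n_mismatch = st$n_mismatch, n_gap_col = st$n_gap_col)
}

# render "P%(x/y)" with half-up two-decimal percentage
render_diff <- function(n_diff, denom) {
  sprintf("%s%%(%d/%d)", fmt_pct2(percent_of(n_diff, denom)),
          n_diff, denom)
}

# translate a CDS, dropping the terminal stop; warn and truncate at an
# internal stop
translate_cds <- function(cds, what = "sequence") {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve"))
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE)) {
    warning("internal stop codon in ", what,
            "; amino-acid comparison truncated at the first stop")
    aa <- sub("\\*.*$", "", aa)
  }
  aa
}

#' Base and amino-acid difference percentages between predicted and
#' measured CDS
#'
#' BDP counts mismatch columns of the global nucleotide alignment over
#' the aligned (non-gap) coding columns; ADP does the same on the
#' aligned translations (terminal stop removed). Both are rendered as
#' `"P%(x/y)"` with the percentage rounded half-up to two decimals.
#'
#' @param predicted_cds,measured_cds coding sequences; lengths must be
#'   multiples of 3.
#' @return list with `bdp`/`adp` sublists (`percent`, `n_diff`,
#'   `denom`, `rendered`).
#' @export
diff_percentages <- function(predicted_cds, measured_cds) {
  predicted_cds <- as.character(predicted_cds)
  measured_cds <- as.character(measured_cds)
  if (nchar(predicted_cds) %% 3 != 0 || nchar(measured_cds) %% 3 != 0) {
    stop("coding sequences must have length divisible by 3")
  }
  nt <- global_align(predicted_cds, measured_cds)
  nt_denom <- nt$n_col - nt$n_gap_col
  bdp <- list(percent = percent_of(nt$n_mismatch, nt_denom),
              n_diff = nt$n_mismatch, denom = nt_denom,
              rendered = render_diff(nt$n_mismatch, nt_denom))
  aa_p <- translate_cds(predicted_cds, "predicted CDS")
  aa_m <- translate_cds(measured_cds, "measured CDS")
  aa <- global_align(aa_p, aa_m, alphabet = "AA")
  aa_denom <- aa$n_col - aa$n_gap_col
  adp <- list(percent = percent_of(aa$n_mismatch, aa_denom),
              n_diff = aa$n_mismatch, denom = aa_denom,
              rendered = render_diff(aa$n_mismatch, aa_denom))
  list(bdp = bdp, adp = adp)
}

#' Infer introns from a genomic clone versus its spliced transcript
#'
#' Gap runs on the transcript side of the global alignment with length
#' at least `min_intron` are reported as introns (1-based genomic
#' coordinates); shorter gaps are treated as ordinary indels.
#'
#' @param genomic_seq measured genomic sequence.
#' @param transcript_seq predicted (spliced) transcript.
#' @param min_intron minimum intron length in bp, default 40.
#' @return data.frame `start`, `end`, `length` (zero rows when
#'   intronless).
#' @export
infer_introns <- function(genomic_seq, transcript_seq, min_intron = 40L) {
  aln <- global_align(transcript_seq, genomic_seq)
  tr <- strsplit(aln$aligned_a, "")[[1]]
  ge <- strsplit(aln$aligned_b, "")[[1]]
  gap <- tr == "-" & ge != "-"
  g_pos <- cumsum(ge != "-")
  r <- rle(gap)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values & r$lengths >= min_intron
  if (!any(keep)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  data.frame(start = g_pos[starts_idx[keep]],
             end = g_pos[ends_idx[keep]],
             length = r$lengths[keep])
}

#' Full predicted-versus-measured comparison for one gene
#'
#' Infers introns from the genomic clone, splices them out, and
#' computes base / amino-acid difference percentages against the
#' predicted CDS.
#'
#' @param gene_id label.
#' @param predicted_cds predicted coding sequence (from the
#'   transcriptome assembly).
#' @param measured_seq measured (cloned) genomic sequence.
#' @param min_intron minimum intron length, default 40 bp.
#' @return data.frame row: gene, predicted/measured lengths, intron
#'   count and lengths, BDP, ADP.
#' @export
clone_comparison <- function(gene_id, predicted_cds, measured_seq,
                             min_intron = 40L) {
  predicted_cds <- as.character(predicted_cds)
  measured_seq <- as.character(measured_seq)
  introns <- infer_introns(measured_seq, predicted_cds, min_intron)
  spliced <- measured_seq
  if (nrow(introns)) {
    keep <- rep(TRUE, nchar(measured_seq))
    for (i in seq_len(nrow(introns))) {
      keep[introns$start[i]:introns$end[i]] <- FALSE
    }
    spliced <- paste(strsplit(measured_seq, "")[[1]][keep],
                     collapse = "")
  }
  # trim to a codon multiple if splicing left a remainder
  extra <- nchar(spliced) %% 3
  if (extra) spliced <- substr(spliced, 1L, nchar(spliced) - extra)
  d <- diff_percentages(predicted_cds, spliced)
  data.frame(gene = gene_id,
             predicted_len = nchar(predicted_cds),
             measured_len = nchar(measured_seq),
             n_introns = nrow(introns),
             intron_lengths = paste(introns$length, collapse = " and "),
             bdp = d$bdp$rendered, adp = d$adp$rendered,
             stringsAsFactors = FALSE)
}
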