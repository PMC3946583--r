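# Read-based RPKM profiling, CATG digital-gene-expression tag
# profiling (TPM), and differential / specific expression calling.

#' Map reads to TE sequences by unique best local alignment
#'
#' Candidate targets for each read are found by exact shared-word
#' seeding on both strands; candidates are scored by optimal local
#' alignment (same scoring as [homology_scan()]). A read is counted for
#' its single best-scoring target when the identity over the aligned
#' columns reaches `min_identity`; reads whose best score is tied
#' between targets are discarded as ambiguous.
#'
#' @param reads DNAStringSet of reads.
#' @param te_seqs DNAStringSet of target TE sequences.
#' @param min_identity identity threshold as a fraction (<= 1) or
#'   percentage.
#' @param word_size exact seed word length.
#' @return list with `counts` (named integer vector over targets),
#'   `n_ambiguous`, `n_unmapped`, and `assignments` (data.frame read ->
#'   target, mapped reads only).
#' @export
map_reads <- function(reads, te_seqs, min_identity = 0.95,
                      word_size = 11L) {
  if (min_identity <= 1) min_identity <- 100 * min_identity
  counts <- integer(length(te_seqs))
  names(counts) <- names(te_seqs)
  if (length(reads) == 0) {
    return(list(counts = counts, n_ambiguous = 0L, n_unmapped = 0L,
                assignments = data.frame(read_id = character(),
                                         target = character())))
  }
  submat <- dna_submat(2, -3)
  te_idx <- word_index(lapply(as.character(te_seqs), word_set,
                              word = word_size))
  r_fwd <- as.character(reads)
  r_rc <- as.character(Biostrings::reverseComplement(reads))

  # candidate (read, target) pairs, grouped by target for vectorized
  # alignment
  cand <- list()
  lookup <- function(words) {
    m <- match(words, names(te_idx))
    unique(unlist(te_idx[m[!is.na(m)]], use.names = FALSE))
  }
  for (i in seq_along(reads)) {
    t_fwd <- lookup(word_set(r_fwd[i], word_size))
    t_rev <- setdiff(lookup(word_set(r_rc[i], word_size)), t_fwd)
    for (t in t_fwd) {
      cand[[length(cand) + 1L]] <- c(read = i, target = t, strand = 1L)
    }
    for (t in t_rev) {
      cand[[length(cand) + 1L]] <- c(read = i, target = t, strand = 2L)
    }
  }
  best_score <- rep(-Inf, length(reads))
  best_target <- integer(length(reads))
  tied <- logical(length(reads))
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    for (t in unique(cd[, "target"])) {
      sel <- cd[cd[, "target"] == t, , drop = FALSE]
      pats <- ifelse(sel[, "strand"] == 1L, r_fwd[sel[, "read"]],
                     r_rc[sel[, "read"]])
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(pats), te_seqs[[t]], type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      p_al <- as.character(Biostrings::alignedPattern(aln))
      s_al <- as.character(Biostrings::alignedSubject(aln))
      sc <- BiocGenerics::score(aln)
      for (k in seq_len(nrow(sel))) {
        st <- aln_column_stats(p_al[k], s_al[k])
        if (is.na(st$identity) || st$identity < min_identity) next
        i <- sel[k, "read"]
        if (sc[k] > best_score[i]) {
          best_score[i] <- sc[k]; best_target[i] <- t; tied[i] <- FALSE
        } else if (sc[k] == best_score[i] && best_target[i] != t) {
          tied[i] <- TRUE
        }
      }
    }
  }
  mapped <- best_target > 0 & !tied
  tab <- table(factor(best_target[mapped], levels = seq_along(te_seqs)))
  counts[] <- as.integer(tab)
  list(counts = counts,
       n_ambiguous = sum(best_target > 0 & tied),
       n_unmapped = sum(best_target == 0),
       assignments = data.frame(
         read_id = names(reads)[mapped] %||% which(mapped),
         target = names(te_seqs)[best_target[mapped]],
         stringsAsFactors = FALSE))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = count * 1e9 / (library_total * length_bp); zero counts give
#' exactly zero.
#'
#' @param count non-negative read count (vectorized).
#' @param te_length_bp transcript length in bp (> 0).
#' @param library_total library size in reads (> 0).
#' @return numeric RPKM values.
#' @export
rpkm <- function(count, te_length_bp, library_total) {
  if (any(te_length_bp <= 0)) stop("te_length_bp must be > 0")
  if (any(library_total <= 0)) stop("library_total must be > 0")
  count * 1e9 / (library_total * te_length_bp)
}

#' Tags per million
#'
#' TPM = count * 1e6 / library_total.
#'
#' @param count tag count (vectorized).
#' @param library_total clean-tag total of the library (> 0).
#' @return numeric TPM values.
#' @export
tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  count * 1e6 / library_total
}

#' Extract CATG-anchored 21-mer DGE tags from a sequence
#'
#' Every CATG occurrence on the sense strand with at least 17
#' downstream bases yields one 21-bp tag (CATG + 17 bp); duplicate tags
#' within one sequence are reported once, at their first offset.
#'
#' @param seq a DNA string.
#' @param id id recorded in the output, default `""`.
#' @return data.frame with `te_id`, `tag`, `offset` (1-based start of
#'   CATG); zero rows when the sequence is undetectable (no valid
#'   site).
#' @export
extract_dge_tags <- function(seq, id = "") {
  s <- toupper(as.character(seq))
  pos <- gregexpr("CATG", s, fixed = TRUE)[[1]]
  pos <- pos[pos > 0 & pos + 20L <= nchar(s)]
  if (!length(pos)) {
    return(data.frame(te_id = character(), tag = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  tags <- substring(s, pos, pos + 20L)
  keep <- !duplicated(tags)
  data.frame(te_id = id, tag = tags[keep], offset = as.integer(pos[keep]),
             stringsAsFactors = FALSE)
}

#' Build the tag catalog for a set of TEs
#'
#' @param te_seqs DNAStringSet.
#' @return data.frame of all tags (`te_id`, `tag`, `offset`) plus an
#'   attribute `undetectable`: ids with no valid CATG site.
#' @export
tag_catalog <- function(te_seqs) {
  per <- lapply(names(te_seqs), function(id) {
    extract_dge_tags(as.character(te_seqs[[id]]), id)
  })
  cat <- do.call(rbind, per)
  if (is.null(cat)) {
    cat <- data.frame(te_id = character(), tag = character(),
                      offset = integer(), stringsAsFactors = FALSE)
  }
  attr(cat, "undetectable") <-
    names(te_seqs)[vapply(per, nrow, integer(1)) == 0]
  cat
}

#' Per-TE tag expression (TPM) from tag counts
#'
#' Sums each TE's tag counts and converts to tags per million. Tag
#' count tables referencing a tag absent from the catalog raise an
#' error.
#'
#' @param tag_counts data.frame with columns `tag` and `count`
#'   (optionally `te_id`; otherwise resolved through the catalog).
#' @param catalog output of [tag_catalog()].
#' @param library_total clean-tag total of the library.
#' @return data.frame `te_id`, `count`, `tpm` covering every TE in the
#'   catalog (zero rows included).
#' @export
tag_expression <- function(tag_counts, catalog, library_total) {
  if (any(!tag_counts$tag %in% catalog$tag)) {
    stop("tag count table references unknown tag(s): ",
         paste(utils::head(setdiff(tag_counts$tag, catalog$tag), 3),
               collapse = ", "))
  }
  te_of <- catalog$te_id[match(tag_counts$tag, catalog$tag)]
  agg <- tapply(tag_counts$count, te_of, sum)
  tes <- unique(catalog$te_id)
  cnt <- ifelse(tes %in% names(agg), agg[tes], 0)
  cnt[is.na(cnt)] <- 0
  data.frame(te_id = tes, count = as.numeric(cnt),
             tpm = tpm(as.numeric(cnt), library_total),
             stringsAsFactors = FALSE)
}

#' Exact hypergeometric (Fisher) test for pairwise differential
#' expression
#'
#' Tests the 2x2 table `[count_a, total_a - count_a; count_b,
#' total_b - count_b]` with the two-sided exact hypergeometric
#' (Fisher) probability. The fold change is pseudocount-shrunk:
#' log2((a + 0.5)/A) - log2((b + 0.5)/B). Status is `up`/`down` (library
#' A relative to B) when p <= `p_cut` and |log2fc| >= `lfc_cut`, else
#' `ns`.
#'
#' @param count_a,count_b counts in the two libraries (vectorized).
#' @param total_a,total_b library totals.
#' @param p_cut p-value cut-off, default 0.05.
#' @param lfc_cut absolute log2 fold-change cut-off, default 1.
#' @return data.frame `p_value`, `log2fc`, `status`.
#' @export
test_de <- function(count_a, total_a, count_b, total_b, p_cut = 0.05,
                    lfc_cut = 1) {
  if (any(total_a <= 0) || any(total_b <= 0)) stop("totals must be > 0")
  if (any(count_a > total_a) || any(count_b > total_b)) {
    stop("counts cannot exceed library totals")
  }
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  ta <- rep_len(total_a, n); tb <- rep_len(total_b, n)
  p <- vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(c(count_a[i], ta[i] - count_a[i],
                                count_b[i], tb[i] - count_b[i]),
                              nrow = 2))$p.value
  }, numeric(1))
  lfc <- log2((count_a + 0.5) / ta) - log2((count_b + 0.5) / tb)
  status <- ifelse(p <= p_cut & abs(lfc) >= lfc_cut,
                   ifelse(lfc > 0, "up", "down"), "ns")
  data.frame(p_value = p, log2fc = lfc, status = status,
             stringsAsFactors = FALSE)
}

#' Pairwise DE table over a count matrix
#'
#' @param mat TE x library count matrix.
#' @param totals named library totals.
#' @param pair character vector of two library names.
#' @param p_cut,lfc_cut cut-offs passed to [test_de()].
#' @param detect_min minimum count defining "expressed" for the
#'   specificity flag.
#' @return data.frame with one row per TE: counts, p, log2fc, status
#'   and `specific` (`none`/`A_only`/`B_only`).
#' @export
de_table <- function(mat, totals, pair, p_cut = 0.05, lfc_cut = 1,
                     detect_min = 1L) {
  stopifnot(all(pair %in% colnames(mat)))
  a <- mat[, pair[1]]; b <- mat[, pair[2]]
  de <- test_de(a, totals[pair[1]], b, totals[pair[2]], p_cut, lfc_cut)
  spec <- ifelse(a >= detect_min & b == 0, "A_only",
                 ifelse(b >= detect_min & a == 0, "B_only", "none"))
  data.frame(te = rownames(mat), count_a = a, count_b = b, de,
             specific = spec, row.names = NULL, stringsAsFactors = FALSE)
}

#' Specifically expressed TEs for one library pair
#'
#' A TE is `A_only` iff its count in A is at least `detect_min` and
#' exactly zero in B (and symmetrically for `B_only`).
#'
#' @param mat TE x library count matrix.
#' @param pair character vector of two library names.
#' @param detect_min detection threshold, default 1.
#' @return data.frame `te`, `specific` for TEs specific to either side.
#' @export
call_setes <- function(mat, pair, detect_min = 1L) {
  stopifnot(all(pair %in% colnames(mat)))
  a <- mat[, pair[1]]; b <- mat[, pair[2]]
  spec <- ifelse(a >= detect_min & b == 0, "A_only",
                 ifelse(b >= detect_min & a == 0, "B_only", "none"))
  data.frame(te = rownames(mat), specific = spec,
             stringsAsFactors = FALSE)[spec != "none", ]
}

#' Expression-breadth statistics over k tissues
#'
#' Breadth is the number of tissues in which a TE is detected (count >=
#' `detect_min`). Percentages are of all detected TEs, rounded half-up
#' to two decimals.
#'
#' @param mat TE x tissue count matrix.
#' @param detect_min detection threshold.
#' @return list with `n_detected`, `breadth` (data.frame breadth 1..k,
#'   n_te, percent) and `per_tissue` (data.frame tissue, n_te,
#'   percent).
#' @export
breadth_stats <- function(mat, detect_min = 1L) {
  k <- ncol(mat)
  stopifnot(k >= 1)
  det <- mat >= detect_min
  breadth <- rowSums(det)
  n_detected <- sum(breadth > 0)
  per_b <- vapply(seq_len(k), function(b) sum(breadth == b), integer(1))
  per_t <- colSums(det)
  pct <- function(n) {
    if (n_detected == 0) rep(0, length(n)) else percent_of(n, n_detected)
  }
  list(n_detected = n_detected,
       breadth = data.frame(breadth = seq_len(k), n_te = per_b,
                            percent = pct(per_b)),
       per_tissue = data.frame(tissue = colnames(mat),
                               n_te = as.integer(per_t),
                               percent = pct(as.integer(per_t)),
                               row.names = NULL,
                               stringsAsFactors = FALSE))
}

#' Compare two detected-TE sets
#'
#' @param set_a,set_b character vectors of TE names.
#' @return named integer vector: `a_only`, `b_only`, `both`.
#' @export
set_compare <- function(set_a, set_b) {
  c(a_only = length(setdiff(set_a, set_b)),
    b_only = length(setdiff(set_b, set_a)),
    both = length(intersect(set_a, set_b)))
}
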