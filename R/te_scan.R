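# Three-route TE discovery (keyword, homology, sub-terminal motif) plus
# the hairpin-based Helitron criterion, redundancy removal, Wicker-style
# classification, Ib_* naming and ORF annotation.

#' Default TE keyword vocabulary
#'
#' Fifteen keywords covering generic transposon terminology and
#' order/superfamily names, each with the TE class it implies and an
#' optional superfamily hint used by [classify_te()]. Matching is
#' case-insensitive substring matching; "hAT" additionally requires
#' word boundaries so that words like "that" never match.
#'
#' @return data.frame with columns `keyword`, `te_class`,
#'   `superfamily_hint` (`NA` when the keyword is generic) and
#'   `word_boundary`.
#' @export
default_keyword_vocabulary <- function() {
  data.frame(
    keyword = c("transposon", "retrotransposon", "transposase",
                "reverse transcriptase", "transposable element",
                "retroelement", "hAT", "En/spm", "Mutator", "MULE",
                "Non-LTR", "PIF", "Copia", "Gypsy", "Mariner"),
    te_class = c("II", "I", "II", "I", "II", "I", "II", "II", "II", "II",
                 "I", "II", "I", "I", "II"),
    superfamily_hint = c(NA, NA, NA, "Non-LTR retro", NA, "Non-LTR retro",
                         "hAT", "CACTA", "Mutator", "Mutator",
                         "Non-LTR retro", "PIF-harbinger", "Ty1/Copia",
                         "Ty3/Gypsy", "Tc1/Mariner"),
    word_boundary = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE),
    stringsAsFactors = FALSE)
}

#' Keyword screening of annotation descriptions
#'
#' A transcript is hit iff at least one vocabulary keyword matches its
#' description (case-insensitive substring; word-boundary keywords use
#' `\\b` anchors). All matching keywords are reported.
#'
#' @param annotations data.frame with columns `id`, `description`
#'   (as from [read_annotation_table()]).
#' @param vocabulary keyword table, default
#'   [default_keyword_vocabulary()].
#' @return data.frame with one row per hit transcript: `id`, `keywords`
#'   (list column), `hints` (list column of superfamily hints).
#' @export
keyword_scan <- function(annotations,
                         vocabulary = default_keyword_vocabulary()) {
  if (is.null(vocabulary) || nrow(vocabulary) == 0) {
    stop("keyword vocabulary is empty")
  }
  desc <- annotations$description
  hit_mat <- vapply(seq_len(nrow(vocabulary)), function(i) {
    kw <- vocabulary$keyword[i]
    if (isTRUE(vocabulary$word_boundary[i])) {
      grepl(paste0("\\b", kw, "\\b"), desc, ignore.case = TRUE)
    } else {
      grepl(kw, desc, ignore.case = TRUE, fixed = FALSE)
    }
  }, logical(length(desc)))
  if (length(desc) == 1L) hit_mat <- matrix(hit_mat, nrow = 1)
  any_hit <- rowSums(hit_mat) > 0
  idx <- which(any_hit)
  data.frame(
    id = annotations$id[idx],
    keywords = I(lapply(idx, function(r) vocabulary$keyword[hit_mat[r, ]])),
    hints = I(lapply(idx, function(r) {
      h <- vocabulary$superfamily_hint[hit_mat[r, ]]
      unique(h[!is.na(h)])
    })),
    classes = I(lapply(idx, function(r) vocabulary$te_class[hit_mat[r, ]])),
    stringsAsFactors = FALSE)
}

# ---- local alignment machinery ---------------------------------------

# Karlin-Altschul lambda for a match/mismatch score system at uniform
# base composition: solves sum_ij p_i p_j exp(lambda s_ij) = 1
ka_lambda <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-9, 10), tol = 1e-12)$root
}

# 5x5 DNA substitution matrix over {A,C,G,T,N}; N scores 0 vs anything
dna_submat <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# summarise one pairwiseAlignment into match/mismatch/gap column counts;
# N-containing columns are excluded from the identity denominator
aln_column_stats <- function(p_chr, s_chr) {
  p <- strsplit(p_chr, "")[[1]]
  s <- strsplit(s_chr, "")[[1]]
  gap <- p == "-" | s == "-"
  has_n <- p == "N" | s == "N"
  match <- !gap & !has_n & p == s
  mism <- !gap & !has_n & p != s
  list(n_col = length(p), n_match = sum(match), n_mismatch = sum(mism),
       n_gap_col = sum(gap), n_n_col = sum(has_n & !gap),
       identity = if (sum(match) + sum(mism) + sum(gap) > 0)
         100 * sum(match) / (length(p) - sum(has_n & !gap)) else NA_real_)
}

# exact shared-word candidate filter: which subjects share at least
# `min_hits` words of length `word` with the query string
word_set <- function(chr, word) {
  n <- nchar(chr)
  if (n < word) return(character(0))
  unique(substring(chr, 1:(n - word + 1L), word:n))
}

# inverted index word -> integer ids of the sequences containing it
word_index <- function(word_sets) {
  split(rep(seq_along(word_sets), lengths(word_sets)),
        unlist(word_sets, use.names = FALSE))
}

# per-subject count of distinct shared words for one query word set
shared_word_counts <- function(qwords, index, n_subjects) {
  m <- match(qwords, names(index))
  hits <- unlist(index[m[!is.na(m)]], use.names = FALSE)
  tabulate(hits %||% integer(0), nbins = n_subjects)
}

# vectorized column statistics for a PairwiseAlignments object;
# identity = matches / aligned columns (N columns excluded, which only
# matters when `has_n`)
aln_stats_fast <- function(aln, has_n = FALSE) {
  if (!has_n) {
    ind <- Biostrings::nindel(aln)
    gap <- Biostrings::insertion(ind)[, "WidthSum"] +
      Biostrings::deletion(ind)[, "WidthSum"]
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    nc <- nm + nmm + gap
    return(data.frame(n_col = nc, n_match = nm, n_mismatch = nmm,
                      n_gap_col = gap, identity = 100 * nm / nc))
  }
  p_al <- as.character(Biostrings::alignedPattern(aln))
  s_al <- as.character(Biostrings::alignedSubject(aln))
  do.call(rbind, lapply(seq_along(p_al), function(k) {
    st <- aln_column_stats(p_al[k], s_al[k])
    data.frame(n_col = st$n_col, n_match = st$n_match,
               n_mismatch = st$n_mismatch, n_gap_col = st$n_gap_col,
               identity = st$identity)
  }))
}

#' Homology screening against a reference TE library
#'
#' Exact shared-word (length `word_size`) two-hit seeding on both
#' strands (a query/reference pair becomes a candidate when it shares
#' at least `min_seed_hits` distinct words) followed by optimal
#' affine-gap local alignment of candidate pairs (match +2, mismatch
#' -3, gap open 5, extend 2 -- the classic nucleotide-search scoring
#' whose break-even identity is 60%). Hits are reported when the
#' Karlin-Altschul E-value (with database-size correction) is at most
#' `max_evalue` and percent identity over the aligned columns (N
#' columns excluded) is at least `min_identity`.
#'
#' @param transcripts DNAStringSet of query transcripts.
#' @param reference DNAStringSet of reference TEs; a
#'   `superfamily=<label>` token in the description metadata or header
#'   is carried into the hit table.
#' @param min_identity percent identity threshold in (0, 100].
#' @param max_evalue E-value threshold.
#' @param word_size exact seed word length.
#' @param min_seed_hits distinct shared words required to trigger the
#'   alignment of a pair.
#' @return data.frame of hits: query/subject ids, percent identity,
#'   aligned length, score, E-value, 1-based query and subject
#'   intervals, strand, subject superfamily.
#' @export
homology_scan <- function(transcripts, reference, min_identity = 70,
                          max_evalue = 1e-10, word_size = 12L,
                          min_seed_hits = 2L) {
  if (length(reference) == 0) stop("reference TE library is empty")
  if (min_identity <= 0 || min_identity > 100) {
    stop("min_identity must be in (0, 100]")
  }
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      aligned_length = integer(), score = numeric(),
                      evalue = numeric(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), strand = character(),
                      superfamily = character(), stringsAsFactors = FALSE)
  if (length(transcripts) == 0) return(empty)
  submat <- dna_submat(2, -3)
  lambda <- ka_lambda(2, -3)
  K <- 0.41
  db_len <- sum(Biostrings::width(reference))
  sf <- reference_superfamilies(reference)
  has_n <- any(grepl("N", as.character(transcripts), fixed = TRUE)) ||
    any(grepl("N", as.character(reference), fixed = TRUE))

  q_chr <- as.character(transcripts)
  q_rc <- as.character(Biostrings::reverseComplement(transcripts))
  ref_idx <- word_index(lapply(as.character(reference), word_set,
                               word = word_size))

  # candidate (query, ref, strand) triples by shared-word count
  cand <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") q_chr else q_rc
    for (i in seq_along(qs)) {
      cnt <- shared_word_counts(word_set(qs[i], word_size), ref_idx,
                                length(reference))
      for (r in which(cnt >= min_seed_hits)) {
        cand[[length(cand) + 1L]] <- data.frame(q = i, r = r,
                                                strand = strand,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  hits <- list()
  for (grp in split(seq_len(nrow(cand)),
                    paste(cand$r, cand$strand))) {
    r <- cand$r[grp[1]]; strand <- cand$strand[grp[1]]
    qi_idx <- cand$q[grp]
    qs <- if (strand == "+") q_chr[qi_idx] else q_rc[qi_idx]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(qs), reference[[r]], type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    st <- aln_stats_fast(aln, has_n)
    score <- BiocGenerics::score(aln)
    ev <- K * nchar(qs) * db_len * exp(-lambda * score)
    keep <- which(ev <= max_evalue & !is.na(st$identity) &
                    st$identity >= min_identity)
    if (!length(keep)) next
    qs_start <- BiocGenerics::start(Biostrings::pattern(aln))[keep]
    qs_end <- BiocGenerics::end(Biostrings::pattern(aln))[keep]
    if (strand == "-") {
      qlen <- nchar(q_chr[qi_idx[keep]])
      tmp <- qs_start
      qs_start <- qlen - qs_end + 1L
      qs_end <- qlen - tmp + 1L
    }
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = names(transcripts)[qi_idx[keep]],
      subject_id = names(reference)[r],
      percent_identity = st$identity[keep],
      aligned_length = st$n_col[keep], score = score[keep],
      evalue = ev[keep], q_start = qs_start, q_end = qs_end,
      s_start = BiocGenerics::start(Biostrings::subject(aln))[keep],
      s_end = BiocGenerics::end(Biostrings::subject(aln))[keep],
      strand = strand, superfamily = sf[r], stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# pull "superfamily=<label>" out of reference descriptions/headers
reference_superfamilies <- function(reference) {
  desc <- S4Vectors::mcols(reference)$description
  if (is.null(desc)) desc <- names(reference)
  src <- ifelse(grepl("superfamily=", desc), desc, names(reference))
  out <- ifelse(grepl("superfamily=", src),
                sub(".*superfamily=(\\S+( retro)?).*", "\\1", src),
                NA_character_)
  out
}

#' Sub-terminal conserved-motif screening
#'
#' Each motif is aligned glocally (motif global, window local) against
#' the first and last `window` bp of each transcript, on both strands;
#' a hit requires percent identity over the aligned columns of at least
#' `min_similarity`.
#'
#' @param transcripts DNAStringSet of queries.
#' @param motifs DNAStringSet of sub-terminal motifs, 8-60 bp; an
#'   optional `superfamily=` label is carried into the hits.
#' @param min_similarity percent identity threshold.
#' @param window bp scanned at each transcript end.
#' @return data.frame of hits: query id, motif id, end (`5p`/`3p`),
#'   similarity, strand, superfamily.
#' @export
subterminal_scan <- function(transcripts, motifs, min_similarity = 70,
                             window = 250L) {
  wd <- Biostrings::width(motifs)
  if (any(wd < 8 | wd > 60)) stop("motifs must be 8-60 bp")
  if (any(wd > window)) stop("motif longer than the terminal window")
  submat <- dna_submat(2, -3)
  sf <- reference_superfamilies(motifs)
  m_fwd <- as.character(motifs)
  m_rev <- as.character(Biostrings::reverseComplement(motifs))
  has_n <- any(grepl("N", as.character(transcripts), fixed = TRUE)) ||
    any(grepl("N", m_fwd, fixed = TRUE))

  # terminal windows across all transcripts, aligned in one batch per
  # (motif, strand): the motif is global, the window local
  chr <- as.character(transcripts)
  n <- nchar(chr)
  win_q <- c(names(transcripts),
             names(transcripts)[n > window])
  win_end <- c(rep("5p", length(chr)), rep("3p", sum(n > window)))
  win_seq <- c(substr(chr, 1L, pmin(window, n)),
               substr(chr[n > window], n[n > window] - window + 1L,
                      n[n > window]))
  windows <- Biostrings::DNAStringSet(win_seq)
  hits <- list()
  for (k in seq_along(motifs)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") m_fwd[k] else m_rev[k]
      aln <- Biostrings::pairwiseAlignment(
        windows, pat, type = "local-global",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      st <- aln_stats_fast(aln, has_n)
      sel <- which(!is.na(st$identity) & st$identity >= min_similarity)
      if (length(sel)) {
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = win_q[sel], motif_id = names(motifs)[k],
          end = win_end[sel], similarity = st$identity[sel],
          strand = strand, superfamily = sf[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(query_id = character(), motif_id = character(),
                      end = character(), similarity = numeric(),
                      strand = character(), superfamily = character(),
                      stringsAsFactors = FALSE))
  }
  # best strand/end per (query, motif)
  all <- do.call(rbind, hits)
  all <- all[order(-all$similarity), ]
  all[!duplicated(all[c("query_id", "motif_id")]), ]
}

#' Scan for the Helitron hairpin signature (18-bp palindrome + CTAG)
#'
#' Reports every position in the 3'-terminal window where CTAG occurs
#' immediately preceded by a `palindrome_len`-mer whose first half
#' reverse-complements its second half with at most `max_mismatch`
#' mismatches.
#'
#' @param seq a single DNA string (character or DNAString).
#' @param palindrome_len even palindrome length, default 18.
#' @param max_mismatch tolerated mismatches between the first half and
#'   the reverse complement of the second half.
#' @param window bp scanned at the 3' end.
#' @return data.frame with 1-based `pal_start`, `ctag_start` and
#'   `mismatches` per site (zero rows when none).
#' @export
hairpin_scan <- function(seq, palindrome_len = 18L, max_mismatch = 1L,
                         window = 50L) {
  if (palindrome_len %% 2 != 0) stop("palindrome_len must be even")
  if (window < palindrome_len + 4L) {
    stop("window must be >= palindrome_len + 4")
  }
  s <- toupper(as.character(seq))
  n <- nchar(s)
  from <- max(1L, n - window + 1L)
  half <- palindrome_len %/% 2L
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  out <- list()
  ct <- gregexpr("CTAG", substr(s, from, n), fixed = TRUE)[[1]]
  for (p in ct[ct > 0]) {
    ctag_start <- from + p - 1L
    pal_start <- ctag_start - palindrome_len
    if (pal_start < 1L) next
    pal <- substr(s, pal_start, ctag_start - 1L)
    a <- strsplit(substr(pal, 1L, half), "")[[1]]
    b <- strsplit(substr(pal, half + 1L, palindrome_len), "")[[1]]
    mism <- sum(a != comp[rev(b)])
    if (mism <= max_mismatch) {
      out[[length(out) + 1L]] <- data.frame(pal_start = pal_start,
                                            ctag_start = ctag_start,
                                            mismatches = mism)
    }
  }
  if (!length(out)) {
    return(data.frame(pal_start = integer(), ctag_start = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

#' Merge route results and remove redundant transcripts
#'
#' Greedy longest-first clustering: sequences are visited in
#' deterministic order (length descending, then id ascending) and join
#' the first existing representative with global identity at or above
#' `identity_threshold` on either strand; otherwise they found a new
#' cluster. Representatives inherit the union of the evidence of their
#' members.
#'
#' @param evidence data.frame with columns `id`, `route`, `detail`
#'   (one row per piece of evidence; multiple routes per id allowed).
#' @param transcripts DNAStringSet holding all evidenced sequences.
#' @param identity_threshold global identity fraction, default 0.95.
#' @return data.frame with one row per representative: `id`, `length`,
#'   `members` (list), `routes` (list), `evidence` (list of
#'   route/detail data.frames).
#' @export
merge_and_dedupe <- function(evidence, transcripts,
                             identity_threshold = 0.95) {
  ids <- unique(evidence$id)
  ids <- ids[ids %in% names(transcripts)]
  if (!length(ids)) {
    return(data.frame(id = character(), length = integer(),
                      members = I(list()), routes = I(list()),
                      evidence = I(list()), stringsAsFactors = FALSE))
  }
  lens <- Biostrings::width(transcripts)[match(ids, names(transcripts))]
  ids <- ids[order_len_desc_id_asc(lens, ids)]
  lens <- Biostrings::width(transcripts)[match(ids, names(transcripts))]
  submat <- dna_submat(1, -1)
  reps <- integer(0)           # indices into ids
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    joined <- 0L
    for (r in reps) {
      # identity can never reach the threshold if lengths differ too much
      if (lens[i] < identity_threshold * lens[r]) next
      gid <- global_identity(as.character(transcripts[[ids[i]]]),
                             as.character(transcripts[[ids[r]]]), submat)
      if (gid >= identity_threshold) { joined <- r; break }
    }
    if (joined == 0L) { reps <- c(reps, i); assign[i] <- i }
    else assign[i] <- joined
  }
  out <- lapply(reps, function(r) {
    members <- ids[assign == r]
    ev <- evidence[evidence$id %in% members, c("route", "detail")]
    ev <- ev[!duplicated(ev), ]
    data.frame(id = ids[r], length = lens[r],
               members = I(list(members)),
               routes = I(list(unique(ev$route))),
               evidence = I(list(ev)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# global identity fraction (matches / alignment columns), best of the
# two strands
global_identity <- function(a, b, submat = dna_submat(1, -1)) {
  best <- 0
  for (x in c(a, revcomp(a))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(x), b, type = "global",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 1)
    st <- aln_column_stats(
      as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln)))
    best <- max(best, st$n_match / st$n_col)
    if (best >= 1) break
  }
  best
}

#' Exclude virus-like records lacking superfamily-level evidence
#'
#' Drops candidates whose annotation description matches an exclusion
#' term (case-insensitive substring) unless the candidate also carries a
#' superfamily-level evidence hint (homology or sub-terminal
#' superfamily, or a superfamily-specific keyword).
#'
#' @param candidates output of [merge_and_dedupe()] augmented with a
#'   `description` and a `superfamily_hints` list column.
#' @param exclusion_vocabulary character vector of exclusion terms.
#' @return filtered candidates.
#' @export
exclude_non_te <- function(candidates,
                           exclusion_vocabulary = c("virus", "viral",
                                                    "retrovirus",
                                                    "polyprotein")) {
  if (!length(exclusion_vocabulary) || nrow(candidates) == 0) {
    return(candidates)
  }
  desc <- candidates$description %||% rep("", nrow(candidates))
  bad <- Reduce(`|`, lapply(exclusion_vocabulary, function(term) {
    grepl(term, desc, ignore.case = TRUE)
  }))
  has_sf <- vapply(candidates$superfamily_hints,
                   function(h) length(h[!is.na(h)]) > 0, logical(1))
  candidates[!(bad & !has_sf), , drop = FALSE]
}

#' Classify one TE from its evidence
#'
#' Evidence precedence is homology > sub-terminal > hairpin > keyword.
#' A hairpin signature alone implies Helitron. Superfamily-specific
#' keyword hints map through the fixed Wicker-style table; generic DNA
#' keywords alone give class II Unclassified (DU) and "retrotransposon"
#' alone class I Unclassified (RU).
#'
#' @param evidence data.frame with columns `route`
#'   (`keyword`/`homology`/`subterminal`/`hairpin`) and `detail` (the
#'   superfamily for homology/subterminal rows, the keyword for keyword
#'   rows).
#' @return list with `te_class`, `te_order`, `superfamily`, `code`.
#' @export
classify_te <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    stop("cannot classify a TE without evidence")
  }
  sf_row <- function(sf) {
    r <- SUPERFAMILY_TABLE[SUPERFAMILY_TABLE$superfamily == sf, ]
    if (nrow(r) == 0) return(NULL)
    list(te_class = r$te_class, te_order = r$te_order,
         superfamily = r$superfamily, code = r$code)
  }
  for (route in c("homology", "subterminal")) {
    det <- evidence$detail[evidence$route == route]
    det <- det[!is.na(det)]
    if (length(det)) {
      # first detail in evidence order (homology hits are pre-sorted by
      # ascending E-value upstream)
      r <- sf_row(det[1])
      if (!is.null(r)) return(r)
    }
  }
  if (any(evidence$route == "hairpin")) return(sf_row("Helitron"))
  kw <- evidence$detail[evidence$route == "keyword"]
  if (length(kw)) {
    voc <- default_keyword_vocabulary()
    hints <- voc$superfamily_hint[match(kw, voc$keyword)]
    hints <- hints[!is.na(hints)]
    if (length(hints)) return(sf_row(hints[1]))
    if ("retrotransposon" %in% kw) return(sf_row("Unclassified retro"))
    return(sf_row("Unclassified DNA"))
  }
  list(te_class = "unknown", te_order = "unknown",
       superfamily = "Unclassified DNA", code = "DU")
}

#' Assign deterministic Ib_<code>_<n> names
#'
#' Records are ordered by length descending then id ascending; numeric
#' suffixes count up within each classification code.
#'
#' @param records data.frame with columns `id`, `length`, `code`.
#' @return `records` with a `name` column added.
#' @export
assign_names <- function(records) {
  if (nrow(records) == 0) {
    records$name <- character(0)
    return(records)
  }
  ord <- order_len_desc_id_asc(records$length, records$id)
  records <- records[ord, , drop = FALSE]
  n <- stats::ave(seq_len(nrow(records)), records$code,
                  FUN = seq_along)
  records$name <- paste0("Ib_", records$code, "_", n)
  rownames(records) <- NULL
  records
}

#' Six-frame ORF finder (ATG to stop)
#'
#' In each of the six reading frames, every stop codon closes the ORF
#' that opens at the first ATG after the previous stop; the stop codon
#' is included in the reported length. Open ends (no stop) are not
#' reported. Coordinates are 1-based inclusive on the forward strand.
#'
#' @param seq a DNA string.
#' @param min_len_nt minimum ORF length in nt (>= 3, multiple of 3).
#' @return data.frame with `frame` (+1..+3, -1..-3), `start`, `end`,
#'   `length`.
#' @export
find_orfs <- function(seq, min_len_nt = 300L) {
  if (min_len_nt < 3 || min_len_nt %% 3 != 0) {
    stop("min_len_nt must be >= 3 and a multiple of 3")
  }
  s <- toupper(as.character(seq))
  n <- nchar(s)
  out <- list()
  for (strand in c(1L, -1L)) {
    str <- if (strand == 1L) s else revcomp(s)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 2) next
      starts <- off + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(str, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      prev_stop <- 0L
      for (ci in which(is_stop)) {
        atg <- which(is_atg[(prev_stop + 1L):(ci - 1L)])
        if (ci > prev_stop + 1L && length(atg)) {
          a <- prev_stop + atg[1]
          len <- 3L * (ci - a + 1L)
          if (len >= min_len_nt) {
            p1 <- starts[a]; p2 <- starts[ci] + 2L
            if (strand == -1L) { t <- p1; p1 <- n - p2 + 1L; p2 <- n - t + 1L }
            out[[length(out) + 1L]] <- data.frame(
              frame = strand * (off + 1L), start = p1, end = p2,
              length = len)
          }
        }
        prev_stop <- ci
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), length = integer()))
  }
  do.call(rbind, out)
}

#' Count records carrying an ORF strictly longer than a threshold
#'
#' @param seqs DNAStringSet.
#' @param threshold_nt length threshold in nt (strict >).
#' @return integer count of sequences with at least one such ORF.
#' @export
count_long_orfs <- function(seqs, threshold_nt = 1000L) {
  sum(vapply(as.character(seqs), function(s) {
    orfs <- find_orfs(s, min_len_nt = 3L)
    nrow(orfs) > 0 && max(orfs$length) > threshold_nt
  }, logical(1)))
}

#' Run the full three-route TE discovery
#'
#' Keyword, homology and sub-terminal screens are run, their hits
#' merged and deduplicated, virus-like records excluded, the hairpin
#' criterion applied, and each representative classified and named.
#'
#' @param transcripts DNAStringSet of assembled transcripts.
#' @param annotations annotation data.frame (`id`, `description`,
#'   `evalue`).
#' @param reference reference TE DNAStringSet (superfamily-labelled).
#' @param motifs sub-terminal motif DNAStringSet.
#' @param min_identity,max_evalue homology thresholds.
#' @param min_similarity sub-terminal threshold.
#' @param identity_threshold dedupe global-identity threshold.
#' @param vocabulary keyword vocabulary.
#' @param exclusion_vocabulary virus-exclusion terms.
#' @return list with `tes` (data.frame: name, id, classification,
#'   routes, orf count, longest orf), `seqs` (DNAStringSet renamed to
#'   Ib_* names), `keyword_counts` (named per-keyword hit counts) and
#'   `n_candidates` (pre-exclusion representative count).
#' @export
te_scan <- function(transcripts, annotations, reference, motifs = NULL,
                    min_identity = 70, max_evalue = 1e-10,
                    min_similarity = 70, identity_threshold = 0.95,
                    vocabulary = default_keyword_vocabulary(),
                    exclusion_vocabulary = c("virus", "viral",
                                             "retrovirus", "polyprotein")) {
  kw <- keyword_scan(annotations, vocabulary)
  kw_counts <- vapply(vocabulary$keyword, function(k) {
    sum(vapply(kw$keywords, function(v) k %in% v, logical(1)))
  }, integer(1))
  hom <- homology_scan(transcripts, reference, min_identity, max_evalue)
  hom <- hom[order(hom$evalue), , drop = FALSE]
  sub <- if (!is.null(motifs) && length(motifs)) {
    subterminal_scan(transcripts, motifs, min_similarity)
  } else {
    data.frame(query_id = character(), superfamily = character())
  }

  ev <- rbind(
    if (nrow(kw)) do.call(rbind, lapply(seq_len(nrow(kw)), function(i) {
      data.frame(id = kw$id[i], route = "keyword",
                 detail = kw$keywords[[i]], stringsAsFactors = FALSE)
    })) else NULL,
    if (nrow(hom)) data.frame(id = hom$query_id, route = "homology",
                              detail = hom$superfamily,
                              stringsAsFactors = FALSE) else NULL,
    if (nrow(sub)) data.frame(id = sub$query_id, route = "subterminal",
                              detail = sub$superfamily,
                              stringsAsFactors = FALSE) else NULL)
  if (is.null(ev) || nrow(ev) == 0) {
    return(list(tes = data.frame(), seqs = Biostrings::DNAStringSet(),
                keyword_counts = kw_counts, n_candidates = 0L))
  }

  cand <- merge_and_dedupe(ev, transcripts, identity_threshold)
  n_candidates <- nrow(cand)
  cand$description <-
    annotations$description[match(cand$id, annotations$id)]
  cand$superfamily_hints <- lapply(seq_len(nrow(cand)), function(i) {
    e <- cand$evidence[[i]]
    sf <- e$detail[e$route %in% c("homology", "subterminal")]
    kwh <- default_keyword_vocabulary()
    kh <- kwh$superfamily_hint[match(e$detail[e$route == "keyword"],
                                     kwh$keyword)]
    unique(c(sf[!is.na(sf)], kh[!is.na(kh)]))
  })
  cand <- exclude_non_te(cand, exclusion_vocabulary)
  if (nrow(cand) == 0) {
    return(list(tes = data.frame(), seqs = Biostrings::DNAStringSet(),
                keyword_counts = kw_counts, n_candidates = n_candidates))
  }

  # hairpin criterion on the retained candidates
  for (i in seq_len(nrow(cand))) {
    hp <- hairpin_scan(as.character(transcripts[[cand$id[i]]]))
    if (nrow(hp)) {
      cand$evidence[[i]] <- rbind(cand$evidence[[i]],
                                  data.frame(route = "hairpin",
                                             detail = "Helitron"))
      cand$routes[[i]] <- unique(c(cand$routes[[i]], "hairpin"))
    }
  }

  cls <- lapply(cand$evidence, classify_te)
  cand$te_class <- vapply(cls, `[[`, character(1), "te_class")
  cand$te_order <- vapply(cls, `[[`, character(1), "te_order")
  cand$superfamily <- vapply(cls, `[[`, character(1), "superfamily")
  cand$code <- vapply(cls, `[[`, character(1), "code")
  cand <- assign_names(cand)

  orfs <- lapply(cand$id, function(id) {
    find_orfs(as.character(transcripts[[id]]), min_len_nt = 300L)
  })
  cand$n_orfs <- vapply(orfs, nrow, integer(1))
  cand$longest_orf <- vapply(orfs, function(o) {
    if (nrow(o)) max(o$length) else 0L
  }, integer(1))

  seqs <- transcripts[cand$id]
  names(seqs) <- cand$name
  tes <- cand[, c("name", "id", "length", "te_class", "te_order",
                  "superfamily", "code", "n_orfs", "longest_orf")]
  tes$routes <- cand$routes
  tes$members <- cand$members
  list(tes = tes, seqs = seqs, keyword_counts = kw_counts,
       n_candidates = n_candidates)
}
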