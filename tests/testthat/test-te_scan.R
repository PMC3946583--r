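test_that("keyword scan reports all matching keywords and hints", {
  ann <- data.frame(
    id = c("t1", "t2", "t3", "t4"),
    description = c("putative Mutator-like transposase",
                    "hypothetical protein",
                    "something that is not a TE",
                    "Non-LTR retroelement reverse transcriptase"),
    evalue = NA_real_, stringsAsFactors = FALSE)
  hits <- keyword_scan(ann)
  expect_equal(hits$id, c("t1", "t4"))
  expect_setequal(hits$keywords[[1]], c("Mutator", "transposase"))
  expect_equal(hits$hints[[1]], "Mutator")
  # "that" must not trigger the word-boundary keyword hAT
  expect_false("t3" %in% hits$id)
  expect_setequal(hits$keywords[[2]],
                  c("Non-LTR", "retroelement", "reverse transcriptase"))
  expect_error(keyword_scan(ann, vocabulary = NULL), "empty")
})

test_that("keyword scan agrees with the exhaustive grep oracle", {
  set.seed(21)
  voc <- default_keyword_vocabulary()
  pieces <- c("putative", "protein", "transposon", "Copia", "gypsy",
              "reverse transcriptase", "kinase", "hAT", "that",
              "El Mutator", "retro", "element", "Mariner-like", "PIF")
  descs <- vapply(1:200, function(i) {
    paste(sample(pieces, sample(1:4, 1), replace = TRUE), collapse = " ")
  }, character(1))
  ann <- data.frame(id = paste0("t", seq_along(descs)),
                    description = descs, evalue = NA_real_,
                    stringsAsFactors = FALSE)
  got <- keyword_scan(ann, voc)
  want <- keyword_oracle(descs, voc)
  want_ids <- ann$id[lengths(want) > 0]
  expect_equal(got$id, want_ids)
  for (k in seq_along(got$id)) {
    expect_setequal(got$keywords[[k]],
                    want[[match(got$id[k], ann$id)]])
  }
})

test_that("homology scan finds self and reverse-complement hits", {
  set.seed(5)
  s <- rand_dna(500)
  q <- Biostrings::DNAStringSet(c(q1 = s, q2 = rc_chr(s)))
  ref <- Biostrings::DNAStringSet(c(`r1 superfamily=Ty3/Gypsy` = s))
  hits <- homology_scan(q, ref)
  h1 <- hits[hits$query_id == "q1", ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$percent_identity, 100)
  expect_equal(h1$strand, "+")
  expect_equal(c(h1$q_start, h1$q_end), c(1, 500))
  expect_equal(h1$superfamily, "Ty3/Gypsy")
  h2 <- hits[hits$query_id == "q2", ]
  expect_equal(h2$strand, "-")
  expect_equal(h2$percent_identity, 100)
  expect_error(homology_scan(q, ref, min_identity = 0), "min_identity")
  expect_error(homology_scan(q, Biostrings::DNAStringSet()), "empty")
})

test_that("local alignment scores agree with the Smith-Waterman oracle", {
  set.seed(31)
  submat <- tescan:::dna_submat(2, -3)
  for (i in 1:10) {
    n1 <- sample(40:200, 1); n2 <- sample(40:200, 1)
    a <- rand_dna(n1)
    b <- if (i %% 3 == 0) mutate_chr(a, 0.2) else rand_dna(n2)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(a), b, type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    expect_equal(BiocGenerics::score(aln),
                 sw_score_oracle(a, b, 2, -3, 5, 2),
                 info = paste("case", i))
  }
})

test_that("random low-identity pairs yield no hit at the 70% threshold", {
  set.seed(41)
  # ~40%-identity pairs: unrelated random sequences
  q <- Biostrings::DNAStringSet(
    stats::setNames(vapply(1:10, function(i) rand_dna(300), character(1)),
                    paste0("q", 1:10)))
  ref <- Biostrings::DNAStringSet(
    stats::setNames(vapply(1:3, function(i) rand_dna(300), character(1)),
                    paste0("r", 1:3)))
  hits <- homology_scan(q, ref, min_identity = 70, max_evalue = 1e-10,
                        min_seed_hits = 1L, word_size = 8L)
  expect_equal(nrow(hits), 0)
})

test_that("diverged copies are found with the expected identity", {
  set.seed(51)
  base <- rand_dna(800)
  q <- Biostrings::DNAStringSet(c(q1 = mutate_chr(base, 0.1)))
  ref <- Biostrings::DNAStringSet(c(`r superfamily=Mutator` = base))
  hits <- homology_scan(q, ref)
  expect_equal(nrow(hits), 1)
  expect_gt(hits$percent_identity, 80)
  expect_lt(hits$evalue, 1e-10)
})

test_that("sub-terminal scan honors the window rule and thresholds", {
  set.seed(61)
  motif <- rand_dna(40)
  flank <- function(n) rand_dna(n)
  tr <- Biostrings::DNAStringSet(c(
    at_start = paste0(flank(9), motif, flank(600)),
    in_middle = paste0(flank(400), motif, flank(400)),
    at_end_rc = paste0(flank(600), rc_chr(motif), flank(10)),
    unrelated = flank(700)))
  motifs <- Biostrings::DNAStringSet(c(`m1 superfamily=hAT` = motif))
  hits <- subterminal_scan(tr, motifs, min_similarity = 70,
                           window = 250)
  expect_true("at_start" %in% hits$query_id)
  h <- hits[hits$query_id == "at_start", ]
  expect_equal(h$similarity, 100)
  expect_equal(h$end, "5p")
  expect_false("in_middle" %in% hits$query_id)
  hrc <- hits[hits$query_id == "at_end_rc", ]
  expect_equal(nrow(hrc), 1)
  expect_equal(hrc$strand, "-")
  expect_false("unrelated" %in% hits$query_id)
  # a 50%-identity motif stays below a 70% threshold
  half <- mutate_chr(motif, 0.5)
  tr2 <- Biostrings::DNAStringSet(c(x = paste0(half, flank(300))))
  expect_false("x" %in%
                 subterminal_scan(tr2, motifs, 70, 250)$query_id)
  expect_error(subterminal_scan(tr, motifs, window = 20), "longer")
  expect_error(
    subterminal_scan(tr, Biostrings::DNAStringSet(c(m = "ACGT"))),
    "8-60")
})

test_that("hairpin scan matches the exhaustive oracle", {
  set.seed(71)
  # planted perfect palindrome + CTAG at the 3' end
  half <- rand_dna(9)
  planted <- paste0(rand_dna(300), half, rc_chr(half), "CTAG",
                    rand_dna(5))
  got <- hairpin_scan(planted)
  expect_equal(nrow(got), 1)
  expect_equal(got$mismatches, 0)
  expect_equal(got$pal_start, 301)
  expect_equal(nrow(hairpin_scan(gsub("CTAG", "AAAA", planted))), 0)
  # random-sequence battery against the oracle
  for (i in 1:40) {
    s <- rand_dna(sample(60:400, 1))
    expect_equal(hairpin_scan(s, 18, 1, 80),
                 hairpin_oracle(s, 18, 1, 80),
                 info = paste("case", i))
  }
  expect_error(hairpin_scan(planted, palindrome_len = 17), "even")
  expect_error(hairpin_scan(planted, window = 10), "window")
})

test_that("dedupe merges identical sequences and unions evidence", {
  set.seed(81)
  s <- rand_dna(400)
  tr <- Biostrings::DNAStringSet(c(a = s, b = s, c = rand_dna(400)))
  ev <- data.frame(id = c("a", "b", "c"),
                   route = c("keyword", "homology", "keyword"),
                   detail = c("transposase", "Mutator", "transposon"),
                   stringsAsFactors = FALSE)
  out <- merge_and_dedupe(ev, tr)
  expect_equal(nrow(out), 2)
  rep_ab <- out[vapply(out$members, function(m) "b" %in% m, logical(1)), ]
  expect_setequal(rep_ab$members[[1]], c("a", "b"))
  expect_setequal(rep_ab$routes[[1]], c("keyword", "homology"))
})

test_that("dedupe is idempotent and matches the brute-force oracle", {
  set.seed(91)
  for (rep in 1:2) {
    base <- rand_dna(80)
    seqs <- c(v1 = base, v2 = mutate_chr(base, 0.02),
              v3 = mutate_chr(base, 0.3), v4 = rand_dna(85),
              v5 = rc_chr(mutate_chr(base, 0.02)), v6 = rand_dna(60))
    tr <- Biostrings::DNAStringSet(seqs)
    ev <- data.frame(id = names(seqs), route = "keyword",
                     detail = "transposon", stringsAsFactors = FALSE)
    out <- merge_and_dedupe(ev, tr)
    expect_equal(sort(out$id), dedupe_oracle(seqs),
                 info = paste("rep", rep))
    # idempotence: re-running on the representatives changes nothing
    ev2 <- data.frame(id = out$id, route = "keyword",
                      detail = "transposon", stringsAsFactors = FALSE)
    out2 <- merge_and_dedupe(ev2, tr[out$id])
    expect_setequal(out2$id, out$id)
  }
})

test_that("virus-like records are excluded unless superfamily evidence", {
  cand <- data.frame(id = c("a", "b", "c"), stringsAsFactors = FALSE)
  cand$description <- c("reverse transcriptase, retrovirus polyprotein",
                        "reverse transcriptase, retrovirus polyprotein",
                        "ordinary transposase")
  cand$superfamily_hints <- list(character(0), "Ty1/Copia",
                                 character(0))
  out <- exclude_non_te(cand)
  expect_setequal(out$id, c("b", "c"))
  # empty exclusion vocabulary is the identity
  expect_equal(exclude_non_te(cand, character(0)), cand)
})

test_that("classification follows the evidence precedence rules", {
  hom_gypsy <- data.frame(route = "homology", detail = "Ty3/Gypsy")
  expect_equal(classify_te(hom_gypsy),
               list(te_class = "I", te_order = "LTR",
                    superfamily = "Ty3/Gypsy", code = "RLG"))
  kw_generic <- data.frame(route = "keyword", detail = "transposase")
  expect_equal(classify_te(kw_generic)$code, "DU")
  expect_equal(classify_te(kw_generic)$te_class, "II")
  kw_retro <- data.frame(route = "keyword", detail = "retrotransposon")
  expect_equal(classify_te(kw_retro)$code, "RU")
  expect_equal(classify_te(kw_retro)$te_class, "I")
  hairpin_only <- data.frame(route = "hairpin", detail = "Helitron")
  cls <- classify_te(hairpin_only)
  expect_equal(cls$superfamily, "Helitron")
  expect_equal(cls$code, "DHH")
  expect_equal(cls$te_order, "Non-TIR")
  # homology outranks keyword
  mixed <- rbind(data.frame(route = "keyword", detail = "Copia"),
                 data.frame(route = "homology", detail = "Mutator"))
  expect_equal(classify_te(mixed)$code, "DTM")
  # keyword hints map through the fixed table
  expect_equal(classify_te(data.frame(route = "keyword",
                                      detail = "MULE"))$code, "DTM")
  expect_equal(classify_te(data.frame(route = "keyword",
                                      detail = "En/spm"))$code, "DTC")
  expect_error(classify_te(data.frame()), "evidence")
})

test_that("names are deterministic Ib_<code>_<n> with stable numbering", {
  rec <- data.frame(id = c("t1", "t2", "t3", "t4"),
                    length = c(900L, 1200L, 800L, 1100L),
                    code = c("RLC", "DTM", "RLC", "DTM"),
                    stringsAsFactors = FALSE)
  out <- assign_names(rec)
  expect_equal(out$name[out$id == "t2"], "Ib_DTM_1")
  expect_equal(out$name[out$id == "t4"], "Ib_DTM_2")
  expect_equal(out$name[out$id == "t1"], "Ib_RLC_1")
  expect_equal(out$name[out$id == "t3"], "Ib_RLC_2")
  expect_identical(assign_names(rec), out)
  # code frequencies equal classification frequencies
  expect_equal(unname(table(out$code)), unname(table(rec$code)))
  one <- assign_names(data.frame(id = "x", length = 500L, code = "RLC"))
  expect_equal(one$name, "Ib_RLC_1")
})

test_that("ORF finding matches the six-frame oracle", {
  # no ATG anywhere: no ORFs
  expect_equal(nrow(find_orfs(strrep("CCT", 60), 3)), 0)
  # constructed ATG + 398 codons + TAA = 1200 nt, no other frame noise
  s <- paste0(strrep("C", 5), "ATG", strrep("CCT", 398), "TAA",
              strrep("C", 4))
  orfs <- find_orfs(s, 3)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$length, 1200)
  expect_gt(orfs$length, 1000)
  expect_equal(orfs$start, 6)
  expect_equal(orfs$end, 6 + 1200 - 1)
  # random battery against the oracle
  set.seed(101)
  for (i in 1:15) {
    s <- rand_dna(sample(300:2000, 1))
    got <- find_orfs(s, 30)
    want <- orf_oracle(s, 30)
    o1 <- got[order(got$frame, got$start), ]
    o2 <- want[order(want$frame, want$start), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2, info = paste("case", i))
  }
  expect_error(find_orfs("ACGT", 10), "multiple of 3")
})

test_that("long-ORF counting applies a strict threshold", {
  s1200 <- paste0("ATG", strrep("CCT", 398), "TAA")   # exactly 1200 nt
  s999 <- paste0("ATG", strrep("CCT", 331), "TAA")    # 999 nt
  seqs <- Biostrings::DNAStringSet(c(a = s1200, b = s999))
  expect_equal(count_long_orfs(seqs, 1000L), 1L)
  expect_equal(count_long_orfs(seqs, 1200L), 0L)  # strict >
})
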