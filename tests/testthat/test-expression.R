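test_that("reads are assigned uniquely and ties are discarded", {
  set.seed(111)
  t1 <- rand_dna(600); t2 <- rand_dna(600)
  shared <- rand_dna(80)
  tes <- Biostrings::DNAStringSet(c(
    te1 = paste0(t1, shared), te2 = paste0(t2, shared), te3 = rand_dna(500)))
  reads <- Biostrings::DNAStringSet(c(
    r_unique = substr(t1, 100, 149),       # exact substring of te1 only
    r_shared = substr(shared, 10, 59),     # identical region in te1+te2
    r_rc = rc_chr(substr(t2, 200, 249)),   # reverse complement of te2
    r_none = rand_dna(50)))                # matches nothing
  res <- map_reads(reads, tes)
  expect_equal(unname(res$counts["te1"]), 1L)
  expect_equal(unname(res$counts["te2"]), 1L)
  expect_equal(unname(res$counts["te3"]), 0L)
  expect_equal(res$n_ambiguous, 1L)
  expect_equal(res$assignments$target[res$assignments$read_id == "r_rc"],
               "te2")
})

test_that("synthetic library counts match the substring-search oracle", {
  set.seed(121)
  cfg <- sim_config(seed = 9, n_te = 1L, n_background = 0L)
  sim <- generate_te_library(cfg)
  mu <- rep(0, nrow(sim$truth$te)); names(mu) <- sim$truth$te$id
  mu[1:3] <- 20
  cfg$library_specs <- list(list(library_id = "L1", total_reads = 1e4,
                                 mean = mu))
  rc <- generate_read_counts(cfg, sim, raw_reads = TRUE)
  res <- map_reads(rc$reads$L1, sim$transcripts[sim$truth$te$id])
  # oracle: a read belongs to every transcript containing it verbatim
  # (either strand); unambiguous reads must be counted at their source
  chr <- as.character(sim$transcripts[sim$truth$te$id])
  for (k in seq_along(rc$reads$L1)) {
    rd <- as.character(rc$reads$L1[[k]])
    holders <- names(chr)[grepl(rd, chr, fixed = TRUE) |
                            grepl(rc_chr(rd), chr, fixed = TRUE)]
    if (length(holders) == 1) {
      expect_equal(
        res$assignments$target[res$assignments$read_id ==
                                 names(rc$reads$L1)[k]],
        holders)
    }
  }
})

test_that("rpkm follows its formula and invariances", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  # doubling count and total together leaves RPKM unchanged
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "total")
})

test_that("tag extraction matches the exhaustive scan oracle", {
  # one CATG at position 5 of a 40-mer: a single 21-bp tag
  s <- paste0("AAAA", "CATG", strrep("T", 32))
  tags <- extract_dge_tags(s, "x")
  expect_equal(nrow(tags), 1)
  expect_equal(tags$offset, 5L)
  expect_equal(tags$tag, substr(s, 5, 25))
  expect_equal(nchar(tags$tag), 21L)
  # CATG 10 bp before the 3' end yields no tag
  s2 <- paste0(strrep("A", 30), "CATG", strrep("T", 10))
  expect_equal(nrow(extract_dge_tags(s2)), 0)
  set.seed(131)
  for (i in 1:25) {
    s <- rand_dna(sample(30:500, 1))
    got <- extract_dge_tags(s, "q")
    want <- tag_oracle(s)
    expect_equal(got$tag, want$tag, info = paste("case", i))
    expect_equal(got$offset, want$offset, info = paste("case", i))
  }
})

test_that("TPM conversion conserves totals across a library", {
  expect_equal(tpm(50, 1e6), 50)
  set.seed(141)
  tes <- Biostrings::DNAStringSet(c(
    a = paste0(rand_dna(50), "CATG", rand_dna(100)),
    b = paste0("CATG", rand_dna(80), "CATG", rand_dna(60))))
  cat <- tag_catalog(tes)
  counts <- data.frame(tag = cat$tag,
                       count = seq(100, by = 75,
                                   length.out = nrow(cat)))
  total <- sum(counts$count)
  te_expr <- tag_expression(counts, cat, total)
  expect_equal(sum(te_expr$tpm), 1e6)
  expect_error(
    tag_expression(data.frame(tag = "CATGAAAAAAAAAAAAAAAAA", count = 1),
                   cat, 1e6),
    "unknown tag")
})

test_that("TEs without CATG are flagged undetectable", {
  tes <- Biostrings::DNAStringSet(c(with = paste0("CATG", strrep("A", 30)),
                                    without = strrep("A", 60)))
  cat <- tag_catalog(tes)
  expect_equal(attr(cat, "undetectable"), "without")
})

test_that("the exact DE test agrees with direct hypergeometric summation", {
  cases <- list(c(0, 100), c(5, 5), c(30, 2), c(1, 0), c(12, 40))
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]
    got <- test_de(a, 1e6, b, 1e6)
    expect_equal(got$p_value, hyper_p_oracle(a, 1e6, b, 1e6),
                 tolerance = 1e-9, info = paste(a, "vs", b))
  }
  # (0 vs 100): strongly down for A
  r <- test_de(0, 1e6, 100, 1e6)
  expect_equal(r$status, "down")
  expect_lt(r$p_value, 1e-10)
})

test_that("the DE test is symmetric and handles edge cases", {
  r1 <- test_de(40, 1e5, 5, 2e5)
  r2 <- test_de(5, 2e5, 40, 1e5)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$status, "up"); expect_equal(r2$status, "down")
  # equal counts and totals: fc exactly 0, ns
  r0 <- test_de(17, 1e5, 17, 1e5)
  expect_equal(r0$log2fc, 0)
  expect_equal(r0$status, "ns")
  expect_error(test_de(10, 5, 1, 100), "exceed")
  expect_error(test_de(1, 0, 1, 100), "totals")
})

test_that("status respects both the p and fold-change cut-offs", {
  # large counts, tiny fold change: significant p but small |lfc| -> ns
  r <- test_de(11000, 1e6, 10000, 1e6)
  expect_lt(r$p_value, 0.05)
  expect_lt(abs(r$log2fc), 1)
  expect_equal(r$status, "ns")
})

test_that("SETE calls require presence in exactly one library", {
  m <- matrix(c(5L, 0L, 0L, 2L,   # library A
                0L, 0L, 3L, 7L),  # library B
              nrow = 4,
              dimnames = list(paste0("te", 1:4), c("A", "B")))
  s <- call_setes(m, c("A", "B"))
  expect_equal(s$specific[s$te == "te1"], "A_only")
  expect_equal(s$specific[s$te == "te3"], "B_only")
  expect_false("te2" %in% s$te)  # (0, 0) is not specific
  expect_false("te4" %in% s$te)
  # antisymmetry under pair swap
  s2 <- call_setes(m, c("B", "A"))
  expect_equal(sum(s$specific == "A_only"), sum(s2$specific == "B_only"))
})

test_that("SETE counts over tissue pairs match direct set arithmetic", {
  set.seed(151)
  k <- 4
  m <- matrix(rpois(40 * k, 2), nrow = 40,
              dimnames = list(paste0("te", 1:40), paste0("T", 1:k)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) {
        s <- call_setes(m, c(colnames(m)[i], colnames(m)[j]))
        expect_equal(sum(s$specific == "A_only"),
                     sum(m[, i] >= 1 & m[, j] == 0))
        expect_equal(sum(s$specific == "B_only"),
                     sum(m[, j] >= 1 & m[, i] == 0))
      }
    }
  }
})

test_that("breadth statistics and set comparison behave on known input", {
  m <- matrix(0L, 5, 3,
              dimnames = list(paste0("te", 1:5), c("A", "B", "C")))
  m["te1", ] <- c(1L, 2L, 3L)   # breadth 3
  m["te2", "A"] <- 4L           # breadth 1
  m["te3", c("A", "B")] <- 1L   # breadth 2
  bs <- breadth_stats(m)
  expect_equal(bs$n_detected, 3)
  expect_equal(bs$breadth$n_te, c(1L, 1L, 1L))
  expect_equal(bs$breadth$percent, c(33.33, 33.33, 33.33))
  expect_equal(bs$per_tissue$n_te[bs$per_tissue$tissue == "A"], 3L)
  zero <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("A", "B")))
  bz <- breadth_stats(zero)
  expect_equal(bz$n_detected, 0)
  expect_true(all(bz$breadth$percent == 0))
  expect_equal(set_compare(c("a", "b", "c"), c("b", "c", "d")),
               c(a_only = 1L, b_only = 1L, both = 2L))
})
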