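# Independent brute-force oracles used to cross-check the package's
# operators. Each is written as plain dynamic programming / exhaustive
# scanning, deliberately not sharing code with the implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# mutate a fraction of bases (substitutions only)
mutate_chr <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  k <- which(runif(length(ch)) < rate)
  for (i in k) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# ---- affine-gap Smith-Waterman oracle (gap of length L costs
# open + L * ext); returns the best local score
sw_score_oracle <- function(a, b, match = 2, mismatch = -3, open = 5,
                            ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1) # gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (B consumed)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# ---- affine-gap Needleman-Wunsch oracle: best global score
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, open = 5,
                            ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# global identity fraction via NW traceback-free counting: computed on
# the optimal-score alignment by full DP with match counting
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  # score DP with simple linear gap (open+ext collapsed) is not the
  # implementation's model; instead count matches along an optimal
  # affine-gap path via a parallel DP carrying (score, matches, cols)
  NEG <- -1e9
  sc <- list(M = matrix(NEG, n + 1, m + 1),
             X = matrix(NEG, n + 1, m + 1),
             Y = matrix(NEG, n + 1, m + 1))
  mt <- list(M = matrix(0, n + 1, m + 1), X = matrix(0, n + 1, m + 1),
             Y = matrix(0, n + 1, m + 1))
  cl <- list(M = matrix(0, n + 1, m + 1), X = matrix(0, n + 1, m + 1),
             Y = matrix(0, n + 1, m + 1))
  sc$M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    sc$X[i, 1] <- -5 - (i - 1); cl$X[i, 1] <- i - 1
  }
  for (j in 2:(m + 1)) {
    sc$Y[1, j] <- -5 - (j - 1); cl$Y[1, j] <- j - 1
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      eq <- A[i - 1] == B[j - 1]
      s <- if (eq) 1 else -1
      prev <- c(M = sc$M[i - 1, j - 1], X = sc$X[i - 1, j - 1],
                Y = sc$Y[i - 1, j - 1])
      w <- names(which.max(prev))
      sc$M[i, j] <- prev[w] + s
      mt$M[i, j] <- mt[[w]][i - 1, j - 1] + as.integer(eq)
      cl$M[i, j] <- cl[[w]][i - 1, j - 1] + 1
      px <- c(M = sc$M[i - 1, j] - 6, X = sc$X[i - 1, j] - 1,
              Y = sc$Y[i - 1, j] - 6)
      wx <- names(which.max(px))
      sc$X[i, j] <- px[wx]; mt$X[i, j] <- mt[[wx]][i - 1, j]
      cl$X[i, j] <- cl[[wx]][i - 1, j] + 1
      py <- c(M = sc$M[i, j - 1] - 6, X = sc$X[i, j - 1] - 6,
              Y = sc$Y[i, j - 1] - 1)
      wy <- names(which.max(py))
      sc$Y[i, j] <- py[wy]; mt$Y[i, j] <- mt[[wy]][i, j - 1]
      cl$Y[i, j] <- cl[[wy]][i, j - 1] + 1
    }
  }
  fin <- c(M = sc$M[n + 1, m + 1], X = sc$X[n + 1, m + 1],
           Y = sc$Y[n + 1, m + 1])
  w <- names(which.max(fin))
  mt[[w]][n + 1, m + 1] / cl[[w]][n + 1, m + 1]
}

# ---- exhaustive six-frame ORF oracle: per frame, each stop closes the
# ORF opened by the first ATG since the previous stop
orf_oracle <- function(s, min_len = 3) {
  s <- toupper(s)
  n <- nchar(s)
  res <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else rc_chr(s)
    for (f in 1:3) {
      i <- f
      seg_atg <- NA
      while (i + 2 <= n) {
        cod <- substr(str, i, i + 2)
        if (cod == "ATG" && is.na(seg_atg)) seg_atg <- i
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(seg_atg)) {
            len <- i + 2 - seg_atg + 1
            if (len >= min_len) {
              st <- seg_atg; en <- i + 2
              if (strand == "-") { t <- st; st <- n - en + 1; en <- n - t + 1 }
              res[[length(res) + 1]] <-
                data.frame(frame = (if (strand == "+") 1 else -1) * f,
                           start = st, end = en, length = len)
            }
          }
          seg_atg <- NA
        }
        i <- i + 3
      }
    }
  }
  if (!length(res)) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), length = integer()))
  }
  do.call(rbind, res)
}

# ---- exhaustive hairpin oracle: every CTAG starting inside the
# 3'-terminal window, preceded by an 18-mer whose first half matches
# the reverse complement of its second half up to max_mismatch
hairpin_oracle <- function(s, pal_len = 18, max_mm = 1, window = 50) {
  s <- toupper(s); n <- nchar(s)
  half <- pal_len / 2
  out <- list()
  for (p in seq_len(n - 3)) {
    if (substr(s, p, p + 3) != "CTAG") next
    if (p < max(1, n - window + 1)) next
    if (p - pal_len < 1) next
    pal <- substr(s, p - pal_len, p - 1)
    fh <- substr(pal, 1, half)
    sh <- substr(pal, half + 1, pal_len)
    mm <- sum(strsplit(fh, "")[[1]] != strsplit(rc_chr(sh), "")[[1]])
    if (mm <= max_mm) {
      out[[length(out) + 1]] <- data.frame(pal_start = p - pal_len,
                                           ctag_start = p,
                                           mismatches = mm)
    }
  }
  if (!length(out)) {
    return(data.frame(pal_start = integer(), ctag_start = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# ---- exhaustive CATG 21-mer tag oracle
tag_oracle <- function(s) {
  s <- toupper(s); n <- nchar(s)
  tags <- character(0); offs <- integer(0)
  for (p in seq_len(max(0, n - 3))) {
    if (substr(s, p, p + 3) == "CATG" && p + 20 <= n) {
      tg <- substr(s, p, p + 20)
      if (!tg %in% tags) { tags <- c(tags, tg); offs <- c(offs, p) }
    }
  }
  data.frame(tag = tags, offset = offs, stringsAsFactors = FALSE)
}

# ---- two-sided exact hypergeometric oracle by direct summation over
# the support of the 2x2 table [a, A-a; b, B-b]
hyper_p_oracle <- function(a, A, b, B) {
  k <- a + b                       # column-one margin
  lo <- max(0, k - B); hi <- min(k, A)
  probs <- dhyper(lo:hi, A, B, k)
  obs <- dhyper(a, A, B, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# ---- exhaustive keyword-grep oracle (fixed substring, lowercased;
# hAT via word boundaries)
keyword_oracle <- function(descriptions, vocabulary) {
  lapply(descriptions, function(d) {
    dl <- tolower(d)
    hits <- character(0)
    for (i in seq_len(nrow(vocabulary))) {
      kw <- vocabulary$keyword[i]
      ok <- if (isTRUE(vocabulary$word_boundary[i])) {
        grepl(paste0("(^|[^a-z0-9])", tolower(kw), "($|[^a-z0-9])"), dl)
      } else {
        grepl(tolower(kw), dl, fixed = TRUE)
      }
      if (ok) hits <- c(hits, kw)
    }
    hits
  })
}

# ---- all-pairs greedy clustering oracle on small sequence sets:
# identical visiting order (length desc, id asc), identity from the NW
# oracle on both strands
dedupe_oracle <- function(seqs, threshold = 0.95) {
  ids <- names(seqs)
  lens <- nchar(seqs)
  ord <- order(-lens, ids, method = "radix")
  ids <- ids[ord]; sq <- seqs[ord]
  reps <- character(0)
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (r in reps) {
      gid <- max(nw_identity_oracle(sq[[i]], seqs[[r]]),
                 nw_identity_oracle(rc_chr(sq[[i]]), seqs[[r]]))
      if (gid >= threshold) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, ids[i])
  }
  sort(reps)
}
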