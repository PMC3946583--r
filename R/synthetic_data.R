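# Seeded generator for every input the pipeline consumes, with full
# ground truth: an annotated transcript mixture (TE transcripts carrying
# superfamily-specific structural features + background genes),
# negative-binomial read/tag counts per library, and qPCR plates whose
# Ct values follow a log-linear standard curve with Gaussian noise.

SUPERFAMILY_TABLE <- data.frame(
  superfamily = c("Ty1/Copia", "Ty3/Gypsy", "Non-LTR retro",
                  "Unclassified retro", "Tc1/Mariner", "hAT", "Mutator",
                  "PIF-harbinger", "CACTA", "MITE", "Helitron", "IS",
                  "Unclassified DNA"),
  te_class    = c("I", "I", "I", "I", "II", "II", "II", "II", "II", "II",
                  "II", "II", "II"),
  te_order    = c("LTR", "LTR", "Non-LTR", "unknown", "TIR", "TIR", "TIR",
                  "TIR", "TIR", "TIR", "Non-TIR", "IS", "unknown"),
  code        = c("RLC", "RLG", "RN", "RU", "DTT", "DTH", "DTM", "DTP",
                  "DTC", "DTX", "DHH", "DIS", "DU"),
  stringsAsFactors = FALSE
)

SIM_SUPERFAMILIES <- c("Ty1/Copia", "Ty3/Gypsy", "Tc1/Mariner", "hAT",
                       "Mutator", "PIF-harbinger", "CACTA", "Helitron")

# TE-keyword description templates per superfamily (drawn for the
# keyword-annotated fraction); background descriptions never contain a
# TE keyword.
TE_DESC_TEMPLATES <- list(
  "Ty1/Copia"     = c("putative Copia-like retrotransposon polyprotein",
                      "Copia LTR retroelement reverse transcriptase"),
  "Ty3/Gypsy"     = c("Gypsy retrotransposon polyprotein",
                      "putative Gypsy reverse transcriptase"),
  "Tc1/Mariner"   = c("Mariner family transposase",
                      "Tc1/Mariner transposable element protein"),
  "hAT"           = c("hAT family dimerisation domain transposase",
                      "putative hAT transposon protein"),
  "Mutator"       = c("Mutator-like transposase",
                      "MULE transposase domain protein"),
  "PIF-harbinger" = c("PIF transposase-like protein",
                      "harbinger PIF transposable element protein"),
  "CACTA"         = c("En/spm transposon protein",
                      "CACTA En/spm sub-class transposase"),
  "Helitron"      = c("putative transposon protein, helitron-like",
                      "rolling-circle transposable element helicase")
)

BACKGROUND_DESCRIPTIONS <- c(
  "ribosomal protein S8e", "ATP synthase beta subunit",
  "cytochrome P450 monooxygenase", "heat shock protein 70",
  "ubiquitin-conjugating enzyme", "photosystem II D1 protein",
  "MYB transcription factor", "cellulose synthase catalytic subunit",
  "aquaporin PIP2", "sucrose synthase", "beta-amylase precursor",
  "hypothetical protein")

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, p = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random open-reading-frame-like segment: ATG + (n_codons-2) stop-free
# codons + one stop; length = 3 * n_codons
random_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all_codons, STOP_CODONS)
  body <- sample(ok, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1))
}

# per-base substitution at the given rate (length-preserving)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(ch, collapse = "")
}

# perfect 18-bp palindromic (reverse-complement) block
random_palindrome <- function(len = 18L) {
  half <- random_dna(len %/% 2L)
  paste0(half, revcomp(half))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' define the study conditions under which the pipeline is validated:
#' 60 planted TEs spread over eight superfamilies plus 200 background
#' transcripts, over-dispersed negative-binomial counts, and a four-point
#' tenfold qPCR dilution series spanning 1e6-1e9 copies/ul.
#'
#' @param seed integer seed from which all generator randomness flows.
#' @param n_te integer count of planted TEs per superfamily; a scalar is
#'   recycled over the eight simulated superfamilies.
#' @param n_background count of non-TE background transcripts.
#' @param te_length_range (min, max) planted TE length in bp.
#' @param divergence per-base substitution rate between a planted TE and
#'   its superfamily reference element.
#' @param keyword_fraction fraction of planted TEs receiving a
#'   TE-keyword annotation (the rest are "hypothetical protein").
#' @param library_specs list of per-library specs: each a list with
#'   `library_id`, `total_reads`, and optionally `mean` (named per-TE
#'   expected counts; drawn log-normally when absent).
#' @param tissues character vector of tissue labels for DGE tag
#'   profiling.
#' @param tag_total nominal clean-tag total per tissue.
#' @param read_length read length in bp (>= 21).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param ct_noise_sd Gaussian noise sd on simulated Ct values.
#' @param curve_slope,curve_intercept standard-curve parameters
#'   (Ct = slope * log10(copies) + intercept); slope must be negative.
#' @param dilution standard concentrations, copies/ul.
#' @param reference_abundance copies/ul of the single-copy reference
#'   gene in the simulated genomic DNA sample.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 42L,
                       n_te = c(8L, 8L, 8L, 8L, 7L, 7L, 7L, 7L),
                       n_background = 200L,
                       te_length_range = c(800L, 3000L),
                       divergence = 0.10,
                       keyword_fraction = 0.8,
                       library_specs = NULL,
                       tissues = c("YL", "ML", "Stem", "FR", "ITR",
                                   "ETR", "HTR"),
                       tag_total = 2e5,
                       read_length = 50L,
                       dispersion = 0.1,
                       ct_noise_sd = 0.1,
                       curve_slope = -3.52,
                       curve_intercept = 49,
                       dilution = 10^(6:9),
                       reference_abundance = 2.57e7) {
  if (length(n_te) == 1L) n_te <- rep(n_te, length(SIM_SUPERFAMILIES))
  stopifnot(length(n_te) == length(SIM_SUPERFAMILIES))
  names(n_te) <- SIM_SUPERFAMILIES
  if (any(n_te < 0) || n_background < 0) stop("counts must be >= 0")
  if (read_length < 21) stop("read_length must be >= 21")
  if (curve_slope >= 0) stop("curve_slope must be negative")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  # a TE must host two termini (<= 300 bp each), a >= 450 nt ORF-like
  # segment and a CATG tag site
  if (te_length_range[2] < 800) {
    stop("te_length_range too small to host terminal repeats, an ",
         "ORF-like segment and a CATG tag site (max must be >= 800)")
  }
  if (is.null(library_specs)) {
    library_specs <- lapply(c("XS18_veg", "XS18_flower", "GS87_root",
                              "JS6_root"),
                            function(id) list(library_id = id,
                                              total_reads = 2e5))
  }
  structure(list(seed = as.integer(seed), n_te = n_te,
                 n_background = as.integer(n_background),
                 te_length_range = as.integer(te_length_range),
                 divergence = divergence,
                 keyword_fraction = keyword_fraction,
                 library_specs = library_specs, tissues = tissues,
                 tag_total = tag_total,
                 read_length = as.integer(read_length),
                 dispersion = dispersion, ct_noise_sd = ct_noise_sd,
                 curve_slope = curve_slope,
                 curve_intercept = curve_intercept, dilution = dilution,
                 reference_abundance = reference_abundance),
            class = "sim_config")
}

#' Generate the annotated transcript mixture with ground truth
#'
#' Builds one pristine reference element per simulated superfamily, then
#' plants `n_te` diverged copies of each among `n_background` random
#' background transcripts. Structural features follow the superfamily:
#' LTR superfamilies carry identical 150-300 bp direct terminal repeats,
#' TIR superfamilies 10-30 bp terminal inverted repeats, and Helitrons a
#' 3' CTAG immediately preceded by a perfect 18-bp palindromic block.
#' Every TE contains an internal ATG-to-stop ORF-like segment and at
#' least one CATG site with >= 17 downstream bases.
#'
#' @param config a [sim_config()].
#' @return list with elements `transcripts` (DNAStringSet, shuffled TE +
#'   background mixture), `annotations` (data.frame id/description/
#'   evalue), `reference` (DNAStringSet of labelled reference elements),
#'   `motifs` (DNAStringSet of sub-terminal motifs), and `truth` (list
#'   of ground-truth tables; `truth$te` has one row per planted TE).
#' @export
generate_te_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sf_all <- SIM_SUPERFAMILIES
  lookup <- SUPERFAMILY_TABLE[match(sf_all, SUPERFAMILY_TABLE$superfamily), ]

  # reference elements: termini + long internal spacers + reference ORF
  refs <- list(); ref_sf <- character(0); motifs <- character(0)
  spacerA <- list(); spacerB <- list()
  for (i in seq_along(sf_all)) {
    sf <- sf_all[i]
    spacerA[[sf]] <- random_dna(1200L)
    spacerB[[sf]] <- random_dna(900L)
    orf <- random_orf(200L)
    internal <- paste0(spacerA[[sf]], orf, spacerB[[sf]])
    el <- if (lookup$te_order[i] == "LTR") {
      ltr <- random_dna(200L)
      paste0(ltr, internal, ltr)
    } else if (lookup$te_order[i] == "TIR") {
      tir <- random_dna(20L)
      paste0(tir, internal, revcomp(tir))
    } else { # Helitron
      paste0(random_dna(30L), internal, random_palindrome(), "CTAG",
             random_dna(10L))
    }
    refs[[paste0("REF_", lookup$code[i], "_1")]] <- el
    ref_sf <- c(ref_sf, sf)
    # sub-terminal conserved motif: the 45 bp just inside the 5'
    # terminus (long enough that 70% similarity is discriminative
    # against chance matches in a 250 bp window)
    motifs <- c(motifs, substr(spacerA[[sf]], 1L, 45L))
  }
  reference <- Biostrings::DNAStringSet(unlist(refs))
  S4Vectors::mcols(reference)$description <-
    paste0("superfamily=", ref_sf)
  names(motifs) <- paste0("MOTIF_", lookup$code)
  motif_set <- Biostrings::DNAStringSet(motifs)
  S4Vectors::mcols(motif_set)$description <-
    paste0("superfamily=", sf_all)

  n_total_te <- sum(config$n_te)
  te_rows <- vector("list", n_total_te)
  te_seqs <- character(n_total_te)
  k <- 0L
  for (i in seq_along(sf_all)) {
    sf <- sf_all[i]
    for (j in seq_len(config$n_te[i])) {
      k <- k + 1L
      L <- sample(seq(config$te_length_range[1],
                      config$te_length_range[2]), 1)
      if (lookup$te_order[i] == "LTR") {
        term_len <- sample(150:min(300L, (L - 420L) %/% 2L), 1)
        left <- random_dna(term_len); right <- left
        tail_extra <- ""
      } else if (lookup$te_order[i] == "TIR") {
        term_len <- sample(10:30, 1)
        left <- random_dna(term_len); right <- revcomp(left)
        tail_extra <- ""
      } else { # Helitron: short head, palindrome+CTAG+tail at 3' end
        term_len <- 0L
        left <- ""; right <- ""
        tail_extra <- paste0(random_palindrome(), "CTAG", random_dna(8L))
      }
      # ORF sized so that >= 120 bp of reference-derived spacer remains
      hi_codons <- (L - 2L * nchar(left) - nchar(tail_extra) - 120L) %/% 3L
      orf_codons <- sample(100:max(100L, min(280L, hi_codons)), 1)
      orf <- random_orf(orf_codons)
      orf_len <- 3L * orf_codons
      fill <- L - 2L * nchar(left) - orf_len - nchar(tail_extra)
      fillA <- fill %/% 2L; fillB <- fill - fillA
      segA <- mutate_seq(substr(spacerA[[sf]], 1L, fillA),
                         config$divergence)
      segB <- mutate_seq(substr(spacerB[[sf]], 1L, fillB),
                         config$divergence)
      seq <- paste0(left, segA, orf, segB, tail_extra, right)
      # guarantee a CATG tag site (>= 17 downstream bases)
      pos <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
      if (!any(pos > 0 & pos + 20L <= nchar(seq))) {
        at <- nchar(left) + fillA + orf_len + 10L
        substr(seq, at, at + 3L) <- "CATG"
      }
      te_seqs[k] <- seq
      te_rows[[k]] <- data.frame(
        superfamily = sf, te_class = lookup$te_class[i],
        te_order = lookup$te_order[i], code = lookup$code[i],
        length = nchar(seq), term_len = term_len,
        orf_start = nchar(left) + nchar(segA) + 1L, orf_len = orf_len,
        hairpin_pos = if (sf == "Helitron")
          nchar(seq) - nchar(tail_extra) - nchar(right) + 1L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  te_truth <- if (length(te_rows)) {
    do.call(rbind, te_rows)
  } else {
    data.frame(superfamily = character(), te_class = character(),
               te_order = character(), code = character(),
               length = integer(), term_len = integer(),
               orf_start = integer(), orf_len = integer(),
               hairpin_pos = integer(), stringsAsFactors = FALSE)
  }

  bg_seqs <- vapply(seq_len(config$n_background),
                    function(i) random_dna(sample(300:2000, 1)),
                    character(1))

  # shuffle TEs and background together; ids hide the origin
  n_all <- n_total_te + config$n_background
  ord <- sample(n_all)
  all_seqs <- c(te_seqs, bg_seqs)[ord]
  is_te <- c(rep(TRUE, n_total_te), rep(FALSE, config$n_background))[ord]
  ids <- sprintf("TR_%05d", seq_len(n_all))

  # original TE m sits at shuffled position match(m, ord)
  te_idx_in_mix <- match(seq_len(n_total_te), ord)
  te_truth$id <- ids[te_idx_in_mix]
  te_truth <- te_truth[, c("id", setdiff(names(te_truth), "id")),
                       drop = FALSE]

  # annotations: keyword fraction of TEs get a superfamily description
  has_kw <- stats::runif(n_total_te) < config$keyword_fraction
  te_desc <- vapply(seq_len(n_total_te), function(m) {
    if (has_kw[m]) sample(TE_DESC_TEMPLATES[[te_truth$superfamily[m]]], 1)
    else "hypothetical protein"
  }, character(1))
  te_truth$has_keyword <- has_kw
  bg_desc <- sample(BACKGROUND_DESCRIPTIONS, config$n_background,
                    replace = TRUE)
  desc <- character(n_all)
  if (n_total_te > 0) desc[te_idx_in_mix] <- te_desc
  bg_pos <- setdiff(seq_len(n_all), te_idx_in_mix)
  if (length(bg_pos)) desc[bg_pos] <- bg_desc
  annotations <- data.frame(id = ids, description = desc,
                            evalue = 10^-stats::runif(n_all, 20, 100),
                            stringsAsFactors = FALSE)

  transcripts <- Biostrings::DNAStringSet(all_seqs)
  names(transcripts) <- ids
  S4Vectors::mcols(transcripts)$description <- desc

  # CATG tag sites (>= 17 downstream bases), computed on the mixture
  catg <- lapply(te_truth$id, function(id) {
    s <- as.character(transcripts[[id]])
    pos <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    pos <- pos[pos > 0 & pos + 20L <= nchar(s)]
    as.integer(pos)
  })
  names(catg) <- te_truth$id
  te_truth$n_catg <- lengths(catg)

  list(transcripts = transcripts, annotations = annotations,
       reference = reference, motifs = motif_set,
       truth = list(te = te_truth, catg_sites = catg,
                    background_ids = ids[!seq_len(n_all) %in% te_idx_in_mix]))
}

# draw negative-binomial counts (Poisson when dispersion == 0)
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate per-library read counts (and optional raw reads)
#'
#' Counts are drawn negative-binomially around per-TE expected
#' expressions; when a library spec does not provide means they are
#' drawn log-normally (a shared per-TE baseline times a per-library
#' factor). Raw reads, when requested, are exact substrings of their
#' source transcript at uniform start positions.
#'
#' @param config a [sim_config()].
#' @param sim output of [generate_te_library()].
#' @param raw_reads logical; also emit read sequences.
#' @return list with `counts` (TE x library integer matrix),
#'   `library_totals` (named numeric), `reads` (per-library
#'   DNAStringSet, if requested) and `read_truth` (data.frame read id /
#'   source TE).
#' @export
generate_read_counts <- function(config, sim, raw_reads = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$library_specs) == 0) stop("library_specs is empty")
  set.seed(config$seed + 1L)
  te <- sim$truth$te
  n_te <- nrow(te)
  baseline <- stats::rlnorm(n_te, meanlog = log(50), sdlog = 1)
  lib_ids <- vapply(config$library_specs, `[[`, character(1), "library_id")
  counts <- matrix(0L, n_te, length(lib_ids),
                   dimnames = list(te$id, lib_ids))
  totals <- numeric(length(lib_ids)); names(totals) <- lib_ids
  reads <- list(); read_truth <- list()
  for (j in seq_along(config$library_specs)) {
    spec <- config$library_specs[[j]]
    if (!is.null(spec$mean)) {
      unknown <- setdiff(names(spec$mean), te$id)
      if (length(unknown)) {
        stop("expected expression given for unknown TE id(s): ",
             paste(unknown, collapse = ", "))
      }
      mu <- rep(0, n_te); names(mu) <- te$id
      mu[names(spec$mean)] <- spec$mean
    } else {
      mu <- baseline * stats::rlnorm(n_te, 0, 0.25)
      # a slice of TEs silent per library, to exercise specificity calls
      mu[stats::runif(n_te) < 0.1] <- 0
    }
    cts <- rnb(n_te, mu, config$dispersion)
    cts[mu == 0] <- 0L
    counts[, j] <- as.integer(cts)
    totals[j] <- max(spec$total_reads, sum(cts))
    if (raw_reads) {
      src <- rep(te$id, counts[, j])
      sq <- vapply(src, function(id) {
        s <- as.character(sim$transcripts[[id]])
        if (nchar(s) <= config$read_length) return(s)
        st <- sample(nchar(s) - config$read_length + 1L, 1)
        substr(s, st, st + config$read_length - 1L)
      }, character(1), USE.NAMES = FALSE)
      rd <- Biostrings::DNAStringSet(sq)
      names(rd) <- sprintf("%s_read_%06d", lib_ids[j], seq_along(sq))
      reads[[lib_ids[j]]] <- rd
      read_truth[[lib_ids[j]]] <- data.frame(read_id = names(rd),
                                             source = src,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- list(counts = counts, library_totals = totals)
  if (raw_reads) {
    out$reads <- reads
    out$read_truth <- do.call(rbind, read_truth)
  }
  out
}

#' Generate per-tissue DGE tag counts
#'
#' Allocates each TE's negative-binomial tag total multinomially across
#' its extractable CATG 21-mers; TEs lacking a CATG site receive no
#' tags and are therefore undetectable by tag profiling.
#'
#' @param config a [sim_config()].
#' @param sim output of [generate_te_library()].
#' @param mean_tags optional tissue-named list of per-TE expected tag
#'   counts (named numeric); drawn log-normally when absent.
#' @return list with `tag_counts` (data.frame tag / te_id / offset and
#'   one count column per tissue), `tissue_totals` (named numeric) and
#'   `te_tag_truth` (TE x tissue matrix of realized tag totals).
#' @export
generate_dge_tags <- function(config, sim, mean_tags = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  te <- sim$truth$te
  sites <- sim$truth$catg_sites
  taggable <- te$id[te$n_catg > 0]
  catalog <- do.call(rbind, c(list(
    data.frame(tag = character(), te_id = character(),
               offset = integer(), stringsAsFactors = FALSE)),
    lapply(taggable, function(id) {
      s <- as.character(sim$transcripts[[id]])
      off <- sites[[id]]
      data.frame(tag = substring(s, off, off + 20L), te_id = id,
                 offset = off, stringsAsFactors = FALSE)
    })))
  catalog <- catalog[!duplicated(catalog[c("tag", "te_id")]), ,
                     drop = FALSE]
  baseline <- stats::rlnorm(length(taggable), log(40), 1)
  names(baseline) <- taggable
  te_mat <- matrix(0L, length(taggable), length(config$tissues),
                   dimnames = list(taggable, config$tissues))
  cnt <- matrix(0L, nrow(catalog), length(config$tissues),
                dimnames = list(NULL, config$tissues))
  for (tis in config$tissues) {
    if (!is.null(mean_tags) && !is.null(mean_tags[[tis]])) {
      mu <- rep(0, length(taggable)); names(mu) <- taggable
      mm <- mean_tags[[tis]]
      unknown <- setdiff(names(mm), te$id)
      if (length(unknown)) stop("unknown TE id(s): ",
                                paste(unknown, collapse = ", "))
      mu[intersect(names(mm), taggable)] <-
        mm[intersect(names(mm), taggable)]
    } else {
      mu <- baseline * stats::rlnorm(length(taggable), 0, 0.4)
      mu[stats::runif(length(taggable)) < 0.25] <- 0
    }
    tot <- rnb(length(taggable), mu, config$dispersion)
    tot[mu == 0] <- 0L
    te_mat[, tis] <- as.integer(tot)
    for (i in seq_along(taggable)) {
      if (tot[i] == 0) next
      rows <- which(catalog$te_id == taggable[i])
      alloc <- stats::rmultinom(1, tot[i], rep(1, length(rows)))[, 1]
      cnt[rows, tis] <- as.integer(alloc)
    }
  }
  tissue_totals <- pmax(config$tag_total, colSums(cnt))
  names(tissue_totals) <- config$tissues
  list(tag_counts = cbind(catalog, as.data.frame(cnt)),
       tissue_totals = tissue_totals, te_tag_truth = te_mat)
}

#' Generate a qPCR plate for one gene at a known copy number
#'
#' Standard Ct values follow Ct = slope * log10(copies) + intercept plus
#' Gaussian noise; the unknown sample's Ct is computed from the
#' reference-gene abundance times the true copy number through the
#' gene's own curve.
#'
#' @param config a [sim_config()].
#' @param true_copy_number integer >= 1, planted genomic copy number.
#' @param gene_id label for the plate.
#' @param slope,intercept optional per-gene curve overriding the config.
#' @param n_replicates Ct replicates per dilution level.
#' @return a [qpcr_plate()].
#' @export
generate_qpcr_plate <- function(config, true_copy_number,
                                gene_id = "gene", slope = NULL,
                                intercept = NULL, n_replicates = 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (true_copy_number < 1) stop("true_copy_number must be >= 1")
  slope <- slope %||% config$curve_slope
  intercept <- intercept %||% config$curve_intercept
  if (slope >= 0) stop("standard-curve slope must be negative")
  copies <- config$dilution
  ct <- lapply(copies, function(c0) {
    slope * log10(c0) + intercept +
      stats::rnorm(n_replicates, 0, config$ct_noise_sd)
  })
  # the unknown sample is run in the same number of replicate wells as
  # each standard level
  sample_abund <- config$reference_abundance * true_copy_number
  sample_ct <- slope * log10(sample_abund) + intercept +
    stats::rnorm(n_replicates, 0, config$ct_noise_sd)
  qpcr_plate(gene_id, copies, ct, sample_ct)
}
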