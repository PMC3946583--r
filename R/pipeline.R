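# End-to-end orchestration: simulate -> scan -> express -> dge -> qpcr
# -> compare, with a single JSON report aggregating the per-stage
# summaries.

#' Build and validate a pipeline run configuration
#'
#' Missing fields are defaulted (the thresholds default to the
#' pipeline's standard cut-offs: homology identity 70% at E <= 1e-10,
#' DE at p <= 0.05 and |log2FC| >= 1, detection at count >= 1, dedupe
#' at 95% global identity, introns at >= 40 bp); thresholds are
#' range-checked and all problems reported together.
#'
#' @param config named list of overrides (possibly empty): any of
#'   `seed`, `out_dir`, `min_identity`, `max_evalue`, `min_similarity`,
#'   `p_cut`, `lfc_cut`, `detect_min`, `identity_threshold`,
#'   `min_intron`, `sim` (a [sim_config()] or list of its arguments),
#'   and input paths `transcripts`, `annotations`, `reference`,
#'   `motifs` (all NULL = simulate).
#' @return validated config list with class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.null(config)) config <- list()
  defaults <- list(seed = 42L, out_dir = NULL, min_identity = 70,
                   max_evalue = 1e-10, min_similarity = 70,
                   p_cut = 0.05, lfc_cut = 1, detect_min = 1L,
                   identity_threshold = 0.95, min_intron = 40L,
                   transcripts = NULL, annotations = NULL,
                   reference = NULL, motifs = NULL, sim = NULL)
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  errs <- character(0)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown config field(s): ",
                           paste(unknown, collapse = ", ")))
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$min_identity > 0 && cfg$min_identity <= 100,
      "min_identity must be in (0, 100]")
  chk(cfg$min_similarity > 0 && cfg$min_similarity <= 100,
      "min_similarity must be in (0, 100]")
  chk(cfg$max_evalue > 0, "max_evalue must be > 0")
  chk(cfg$p_cut > 0 && cfg$p_cut <= 1, "p_cut must be in (0, 1]")
  chk(cfg$lfc_cut >= 0, "lfc_cut must be >= 0")
  chk(cfg$detect_min >= 1, "detect_min must be >= 1")
  chk(cfg$identity_threshold > 0 && cfg$identity_threshold <= 1,
      "identity_threshold must be in (0, 1]")
  chk(cfg$min_intron >= 1, "min_intron must be >= 1")
  simulate <- is.null(cfg$transcripts)
  if (!simulate) {
    for (f in c("transcripts", "annotations", "reference")) {
      if (is.null(cfg[[f]])) {
        errs <- c(errs, paste0("missing input path: ", f))
      } else if (!file.exists(cfg[[f]])) {
        errs <- c(errs, paste0(f, ": no such file: ", cfg[[f]]))
      }
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  if (is.null(cfg$sim)) {
    cfg$sim <- sim_config(seed = cfg$seed)
  } else if (!inherits(cfg$sim, "sim_config")) {
    cfg$sim <- do.call(sim_config,
                       utils::modifyList(list(seed = cfg$seed), cfg$sim))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file whose top-level keys are [validate_config()]
#'   fields.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' When no input paths are configured, the synthetic generator produces
#' the transcript mixture, read libraries, DGE tags and qPCR plates
#' under the config seed; otherwise the given files are read. Every
#' intermediate table is written under `out_dir` (when set) and an
#' aggregate report is returned (and written as JSON): TE counts by
#' superfamily, per-library expressed-TE counts and overlaps, the
#' breadth histogram, per-pair DETE/SETE counts, and the copy-number
#' table.
#'
#' @param config a `run_config` from [validate_config()] (or a raw
#'   list, validated on entry).
#' @return the report, a nested list; written to
#'   `<out_dir>/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  emit <- function(obj, fname, writer) {
    if (!is.null(out)) writer(obj, file.path(out, fname))
  }

  # ---- inputs ---------------------------------------------------------
  sim <- NULL
  if (is.null(config$transcripts)) {
    sim <- stage("simulate", {
      s <- generate_te_library(config$sim)
      emit(s$transcripts, "transcripts.fasta", write_fasta)
      emit(s$annotations, "annotations.tsv", write_annotation_table)
      emit(s$reference, "reference_tes.fasta", write_fasta)
      emit(s$motifs, "subterminal_motifs.fasta", write_fasta)
      s
    })
    transcripts <- sim$transcripts
    annotations <- sim$annotations
    reference <- sim$reference
    motifs <- sim$motifs
  } else {
    transcripts <- stage("read inputs", read_fasta(config$transcripts))
    annotations <- stage("read inputs",
                         read_annotation_table(config$annotations))
    reference <- stage("read inputs", read_fasta(config$reference))
    motifs <- if (!is.null(config$motifs)) {
      stage("read inputs", read_fasta(config$motifs))
    } else NULL
  }

  # ---- scan -----------------------------------------------------------
  scan <- stage("scan", te_scan(
    transcripts, annotations, reference, motifs,
    min_identity = config$min_identity, max_evalue = config$max_evalue,
    min_similarity = config$min_similarity,
    identity_threshold = config$identity_threshold))
  if (nrow(scan$tes)) {
    emit(scan$seqs, "tes.fasta", write_fasta)
    flat <- scan$tes
    flat$routes <- vapply(flat$routes, paste, character(1),
                          collapse = ",")
    flat$members <- vapply(flat$members, paste, character(1),
                           collapse = ",")
    emit(flat, "te_classification.tsv", function(x, p) {
      utils::write.table(x, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  sf_counts <- if (nrow(scan$tes)) {
    tab <- table(scan$tes$superfamily)
    as.list(stats::setNames(as.integer(tab), names(tab)))
  } else list()

  report <- list(
    n_te = nrow(scan$tes),
    n_class_I = if (nrow(scan$tes)) sum(scan$tes$te_class == "I") else 0L,
    n_class_II = if (nrow(scan$tes)) sum(scan$tes$te_class == "II") else 0L,
    superfamily_counts = sf_counts,
    keyword_hit_counts = as.list(scan$keyword_counts),
    n_long_orf = if (nrow(scan$tes))
      sum(scan$tes$longest_orf > 1000L) else 0L)

  # stages below need generated counts; with file inputs they are
  # skipped unless count tables are provided through sim
  if (is.null(sim)) {
    if (!is.null(out)) {
      jsonlite::write_json(report, file.path(out, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    return(report)
  }

  # ---- expression (read counts over TEs) ------------------------------
  expr <- stage("express", {
    rc <- generate_read_counts(config$sim, sim)
    # restrict to discovered TEs, renamed to their Ib_* names
    keep <- intersect(rownames(rc$counts), scan$tes$id)
    m <- rc$counts[keep, , drop = FALSE]
    rownames(m) <- scan$tes$name[match(keep, scan$tes$id)]
    emit(m, "te_read_counts.tsv", write_count_matrix)
    lens <- scan$tes$length[match(rownames(m), scan$tes$name)]
    rpkm_mat <- sapply(colnames(m), function(l) {
      rpkm(m[, l], lens, rc$library_totals[l])
    })
    rownames(rpkm_mat) <- rownames(m)
    emit(round(rpkm_mat, 4), "te_rpkm.tsv", write_count_matrix)
    list(counts = m, totals = rc$library_totals, rpkm = rpkm_mat)
  })
  detected <- lapply(colnames(expr$counts), function(l) {
    rownames(expr$counts)[expr$counts[, l] >= config$detect_min]
  })
  names(detected) <- colnames(expr$counts)
  overlaps <- list()
  libs <- colnames(expr$counts)
  for (i in seq_along(libs)) {
    for (j in seq_along(libs)) {
      if (i < j) {
        overlaps[[paste(libs[i], libs[j], sep = "_vs_")]] <-
          as.list(set_compare(detected[[i]], detected[[j]]))
      }
    }
  }
  report$expressed_per_library <- lapply(detected, length)
  report$library_overlaps <- overlaps

  # ---- DGE tag profiling over tissues ---------------------------------
  dge <- stage("dge", {
    tg <- generate_dge_tags(config$sim, sim)
    catalog <- tag_catalog(scan$seqs)
    # te-level count matrix over tissues, on discovered TEs
    tissues <- config$sim$tissues
    m <- matrix(0L, length(scan$seqs), length(tissues),
                dimnames = list(names(scan$seqs), tissues))
    for (tis in tissues) {
      te_expr <- tag_expression(
        data.frame(tag = tg$tag_counts$tag,
                   count = tg$tag_counts[[tis]]),
        catalog, tg$tissue_totals[tis])
      hit <- match(te_expr$te_id, rownames(m))
      m[hit[!is.na(hit)], tis] <- as.integer(
        te_expr$count[!is.na(hit)])
    }
    emit(m, "te_tag_counts.tsv", write_count_matrix)
    list(counts = m, totals = tg$tissue_totals,
         n_undetectable = length(attr(catalog, "undetectable")))
  })
  bs <- breadth_stats(dge$counts, config$detect_min)
  report$dge <- list(
    n_detected = bs$n_detected,
    n_undetectable = dge$n_undetectable,
    breadth = as.list(stats::setNames(bs$breadth$n_te,
                                      paste0("in_", bs$breadth$breadth))),
    breadth_percent = as.list(stats::setNames(bs$breadth$percent,
                                              paste0("in_",
                                                     bs$breadth$breadth))))
  tissues <- colnames(dge$counts)
  de_counts <- list(); sete_counts <- list()
  for (i in seq_along(tissues)) {
    for (j in seq_along(tissues)) {
      if (i < j) {
        key <- paste(tissues[i], tissues[j], sep = "_vs_")
        dt <- de_table(dge$counts, dge$totals,
                       c(tissues[i], tissues[j]),
                       config$p_cut, config$lfc_cut, config$detect_min)
        de_counts[[key]] <- list(up = sum(dt$status == "up"),
                                 down = sum(dt$status == "down"))
        sete_counts[[key]] <- list(
          a_only = sum(dt$specific == "A_only"),
          b_only = sum(dt$specific == "B_only"))
      }
    }
  }
  report$dete_counts <- de_counts
  report$sete_counts <- sete_counts

  # ---- qPCR copy number ----------------------------------------------
  qpcr <- stage("qpcr", {
    set.seed(config$sim$seed + 3L)
    true_copies <- c(1L, 2L, 3L, 2L, 1L)
    genes <- paste0("gene_", seq_along(true_copies))
    plates <- c(list(generate_qpcr_plate(config$sim, 1L, "S8e")),
                lapply(seq_along(genes), function(i) {
                  generate_qpcr_plate(config$sim, true_copies[i],
                                      genes[i],
                                      slope = config$sim$curve_slope *
                                        stats::runif(1, 0.95, 1.05))
                }))
    emit(plates, "qpcr_plates.tsv", write_qpcr_table)
    tab <- qpcr_copy_number(plates, reference = "S8e")
    tab$true_copies <- c(1L, true_copies)
    emit(tab, "copy_number.tsv", function(x, p) {
      utils::write.table(x, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    tab
  })
  report$copy_number <- lapply(seq_len(nrow(qpcr)), function(i) {
    list(gene = qpcr$gene[i], copy_number = qpcr$copy_number[i],
         true = qpcr$true_copies[i],
         efficiency = qpcr$efficiency[i])
  })

  # ---- clone comparison ----------------------------------------------
  compare <- stage("compare", {
    set.seed(config$sim$seed + 4L)
    rows <- list()
    # predicted CDS = a planted ORF; measured clone = CDS with point
    # differences, optionally with an intron inserted
    te_truth <- sim$truth$te
    pick <- if (nrow(te_truth)) {
      utils::head(order(-te_truth$orf_len), 3L)
    } else integer(0)
    for (i in seq_along(pick)) {
      tt <- te_truth[pick[i], ]
      s <- as.character(sim$transcripts[[tt$id]])
      cds <- substr(s, tt$orf_start, tt$orf_start + tt$orf_len - 1L)
      measured <- mutate_seq(cds, 0.005)
      if (i > 1) {
        at <- 3L * (nchar(cds) %/% 6L)
        measured <- paste0(substr(measured, 1, at),
                           random_dna(40L + 60L * i),
                           substr(measured, at + 1L, nchar(measured)))
      }
      rows[[i]] <- clone_comparison(tt$id, cds, measured,
                                    config$min_intron)
    }
    do.call(rbind, rows)
  })
  if (!is.null(compare)) {
    emit(compare, "clone_comparison.tsv", function(x, p) {
      utils::write.table(x, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  report$clone_comparison <- lapply(seq_len(NROW(compare)), function(i) {
    as.list(compare[i, ])
  })

  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}
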