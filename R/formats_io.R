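#' Read transcript sequences from a FASTA file
#'
#' Sequences are uppercased and U is mapped to T so that RNA-style input
#' is accepted; the result is validated against the {A,C,G,T,N}
#' alphabet. The part of the header before the first whitespace becomes
#' the sequence id; any remainder is kept as the per-sequence
#' `description` metadata column.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by id, with a
#'   `description` element metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out)$description <- character(0)
    return(out)
  }
  raw <- Biostrings::readBStringSet(path)
  chr <- toupper(as.character(raw))
  chr <- gsub("U", "T", chr, fixed = TRUE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("malformed FASTA header (empty id) at record ",
                           which(ids == "")[1])
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(chr) == 0)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(chr) == 0], collapse = ", "))
  }
  assert_dna_alphabet(chr, ids)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: ids (and, when present, the `description`
#' metadata column) are written back into the headers.
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  x <- seqs
  desc <- S4Vectors::mcols(seqs)$description
  if (!is.null(desc) && any(nzchar(desc))) {
    names(x) <- ifelse(nzchar(desc), paste(names(seqs), desc), names(seqs))
  }
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# shared TSV reader: tab-separated, "#" comments ignored, UTF-8, no quoting
read_tsv_raw <- function(path, header = FALSE, colClasses = NA) {
  utils::read.delim(path, header = header, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = colClasses, fileEncoding = "UTF-8",
                    blank.lines.skip = TRUE)
}

#' Read a per-transcript annotation table
#'
#' Headerless TSV with columns: transcript id, free-text description,
#' optional hit E-value. Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `id`, `description`, `evalue`
#'   (`NA` when absent).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(id = character(), description = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  df <- read_tsv_raw(path, colClasses = "character")
  if (ncol(df) < 2) stop("annotation table needs >= 2 columns: ", path)
  out <- data.frame(id = df[[1]], description = df[[2]],
                    evalue = if (ncol(df) >= 3) suppressWarnings(as.numeric(df[[3]])) else NA_real_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop("duplicate transcript id(s) in annotation table: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  out
}

#' Write an annotation table
#' @param annotations data.frame with columns `id`, `description`, `evalue`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  df <- annotations[, c("id", "description", "evalue")]
  df$evalue <- ifelse(is.na(df$evalue), "", format(df$evalue))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a count matrix (targets x libraries) from TSV
#'
#' First column holds target ids, remaining columns one library each;
#' the header row names the libraries.
#'
#' @param path path to the TSV.
#' @return integer matrix with target rownames and library colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_raw(path, header = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix to TSV
#' @param mat matrix with rownames (targets) and colnames (libraries).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a qPCR plate object
#'
#' One plate holds the dilution series of standards and the unknown
#' sample's Ct for a single gene.
#'
#' @param gene_id gene name.
#' @param copies numeric vector of standard concentrations (copies/ul),
#'   one per dilution level, all strictly positive.
#' @param ct list of numeric Ct replicate vectors, one per level.
#' @param sample_ct Ct of the unknown genomic-DNA sample.
#' @param reference_gene name of the single-copy reference gene.
#' @return an object of class `qpcr_plate`.
#' @export
qpcr_plate <- function(gene_id, copies, ct, sample_ct,
                       reference_gene = "S8e") {
  if (!is.list(ct)) ct <- lapply(seq_along(copies), function(i) ct[i])
  stopifnot(length(copies) == length(ct))
  if (any(copies <= 0)) stop("copies_per_ul must be strictly positive")
  if (length(unique(copies)) < 2) {
    stop("plate for ", gene_id, " needs >= 2 distinct standard concentrations")
  }
  if (any(unlist(ct) <= 0) || any(sample_ct <= 0)) {
    stop("all Ct values must be > 0")
  }
  structure(list(gene_id = gene_id, copies = as.numeric(copies),
                 ct = lapply(ct, as.numeric),
                 sample_ct = as.numeric(sample_ct),
                 reference_gene = reference_gene),
            class = "qpcr_plate")
}

#' @export
print.qpcr_plate <- function(x, ...) {
  cat("qPCR plate:", x$gene_id, "(reference:", x$reference_gene, ")\n")
  cat(sprintf("  %d standard levels, %s copies/ul; sample Ct %.2f\n",
              length(x$copies),
              paste(format(range(x$copies), digits = 3), collapse = " - "),
              mean(x$sample_ct)))
  invisible(x)
}

#' Read qPCR plates from a TSV file
#'
#' Expected columns: gene, standard copies/ul, one or more Ct replicate
#' columns, sample Ct, and optionally the reference gene name. One row
#' per dilution level; rows are grouped into one plate per gene.
#'
#' @param path path to the TSV (with header).
#' @return list of [qpcr_plate()] objects, one per gene.
#' @export
read_qpcr_table <- function(path) {
  df <- read_tsv_raw(path, header = TRUE)
  need <- c("gene", "copies_per_ul", "sample_ct")
  if (!all(need %in% names(df))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  ct_cols <- grep("^ct_rep", names(df), value = TRUE)
  if (length(ct_cols) == 0) stop("qPCR table has no ct_rep* columns")
  lapply(split(df, df$gene), function(g) {
    qpcr_plate(gene_id = g$gene[1],
               copies = g$copies_per_ul,
               ct = lapply(seq_len(nrow(g)), function(i) {
                 v <- as.numeric(g[i, ct_cols])
                 v[!is.na(v)]
               }),
               sample_ct = g$sample_ct[1],
               reference_gene = if ("reference_gene" %in% names(g))
                 g$reference_gene[1] else "S8e")
  })
}

#' Write qPCR plates to a TSV file
#' @param plates list of [qpcr_plate()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(plates, path) {
  if (inherits(plates, "qpcr_plate")) plates <- list(plates)
  nrep <- max(vapply(plates, function(p) max(lengths(p$ct)), 1L))
  rows <- lapply(plates, function(p) {
    ct <- t(vapply(p$ct, function(v) {
      c(v, rep(NA_real_, nrep - length(v)))
    }, numeric(nrep)))
    colnames(ct) <- paste0("ct_rep", seq_len(nrep))
    data.frame(gene = p$gene_id, copies_per_ul = p$copies, ct,
               sample_ct = mean(p$sample_ct),
               reference_gene = p$reference_gene,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
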