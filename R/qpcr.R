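# Real-time-PCR absolute quantification: plasmid standard copies,
# standard-curve fitting, amplification efficiency, sample
# quantification and copy number as a ratio to a single-copy reference.

#' Copies per microliter of a plasmid standard
#'
#' Standard double-stranded DNA formula: copies/ul =
#' conc * 6.022e23 / (length * 1e9 * 650), with concentration in ng/ul,
#' length in bp and 650 g/mol per bp.
#'
#' @param conc_ng_per_ul plasmid concentration, ng/ul (>= 0).
#' @param plasmid_length_bp plasmid length, bp (> 0).
#' @return copies per microliter.
#' @export
plasmid_copies <- function(conc_ng_per_ul, plasmid_length_bp) {
  if (any(plasmid_length_bp <= 0)) stop("plasmid length must be > 0")
  if (any(conc_ng_per_ul < 0)) stop("concentration must be >= 0")
  conc_ng_per_ul * 6.022e23 / (plasmid_length_bp * 1e9 * 650)
}

#' Fit a qPCR standard curve
#'
#' Replicate Ct values are averaged per dilution level, then mean Ct is
#' regressed on log10(copies) by ordinary least squares. The
#' amplification efficiency E = 10^(-1/slope) - 1 is attached.
#'
#' @param x a [qpcr_plate()], or a numeric vector of copies/ul when
#'   `ct` is given separately.
#' @param ct list of per-level Ct replicate vectors (or numeric vector
#'   of mean Cts), used when `x` is numeric.
#' @param gene_id label carried into the result.
#' @return object of class `standard_curve`: list with `gene_id`,
#'   `slope`, `intercept`, `r_squared`, `efficiency`, `n_levels`.
#' @export
fit_standard_curve <- function(x, ct = NULL, gene_id = NULL) {
  if (inherits(x, "qpcr_plate")) {
    copies <- x$copies; ct <- x$ct; gene_id <- gene_id %||% x$gene_id
  } else {
    copies <- as.numeric(x)
    gene_id <- gene_id %||% ""
  }
  if (!is.list(ct)) ct <- as.list(ct)
  if (length(unique(copies)) < 2) {
    stop("need >= 2 distinct standard concentrations")
  }
  mean_ct <- vapply(ct, mean, numeric(1))
  lx <- log10(copies)
  if (stats::var(lx) == 0) stop("zero variance in log10(copies)")
  fit <- stats::lm(mean_ct ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((mean_ct - mean(mean_ct))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  structure(list(gene_id = gene_id, slope = slope,
                 intercept = intercept, r_squared = r2,
                 efficiency = efficiency(slope),
                 n_levels = length(unique(copies))),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve %s: Ct = %.3f * log10(copies) + %.3f  (R2 = %.4f, E = %.2f)\n",
    x$gene_id, x$slope, x$intercept, x$r_squared,
    round_half_up(x$efficiency, 2)))
  invisible(x)
}

#' PCR amplification efficiency from a standard-curve slope
#'
#' E = 10^(-1/slope) - 1; a slope of -3.3219 (perfect doubling per
#' cycle) gives E = 1.
#'
#' @param slope standard-curve slope, must be negative.
#' @return efficiency E (0-1 scale; summaries print it to two
#'   decimals).
#' @export
efficiency <- function(slope) {
  if (any(slope >= 0)) stop("slope must be negative")
  10^(-1 / slope) - 1
}

#' Absolute quantification of a sample from a fitted curve
#'
#' copies/ul = 10^((sample_ct - intercept) / slope).
#'
#' @param sample_ct observed Ct of the unknown sample.
#' @param curve a `standard_curve`.
#' @return copies per microliter.
#' @export
absolute_quantify <- function(sample_ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((sample_ct - curve$intercept) / curve$slope)
}

#' Gene copy number as the ratio to a single-copy reference
#'
#' Rounded half-up to the nearest integer with a floor of 1.
#'
#' @param gene_abs absolute copies/ul of the gene (vectorized).
#' @param ref_abs absolute copies/ul of the single-copy reference.
#' @return integer copy number(s), >= 1.
#' @export
copy_ratio <- function(gene_abs, ref_abs) {
  if (any(gene_abs <= 0) || any(ref_abs <= 0)) {
    stop("absolute copy inputs must be positive")
  }
  pmax(1L, as.integer(floor(gene_abs / ref_abs + 0.5)))
}

#' Copy-number table from a set of qPCR plates
#'
#' Fits one standard curve per gene, quantifies each unknown sample
#' absolutely, and reports copy number relative to the reference gene's
#' plate.
#'
#' @param plates list of [qpcr_plate()] objects (one must be the
#'   reference gene).
#' @param reference reference gene name, default `"S8e"`.
#' @return data.frame with gene, slope, intercept, r_squared,
#'   efficiency (2 dp), absolute copies/ul, reference copies/ul, copy
#'   number.
#' @export
qpcr_copy_number <- function(plates, reference = "S8e") {
  if (inherits(plates, "qpcr_plate")) plates <- list(plates)
  genes <- vapply(plates, `[[`, character(1), "gene_id")
  if (!reference %in% genes) {
    stop("reference gene '", reference, "' has no plate")
  }
  curves <- lapply(plates, fit_standard_curve)
  abs_c <- vapply(seq_along(plates), function(i) {
    absolute_quantify(mean(plates[[i]]$sample_ct), curves[[i]])
  }, numeric(1))
  ref_abs <- abs_c[match(reference, genes)]
  data.frame(
    gene = genes,
    slope = vapply(curves, `[[`, numeric(1), "slope"),
    intercept = vapply(curves, `[[`, numeric(1), "intercept"),
    r_squared = vapply(curves, `[[`, numeric(1), "r_squared"),
    efficiency = round_half_up(
      vapply(curves, `[[`, numeric(1), "efficiency"), 2),
    absolute_copies = abs_c,
    reference_copies = ref_abs,
    copy_number = copy_ratio(abs_c, ref_abs),
    stringsAsFactors = FALSE)
}
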