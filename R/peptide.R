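#' SILAC peptide quality filter
#'
#' A peptide is kept when both heavy and light signal-to-noise are at
#' least 2, or when either one is at least 5.
#'
#' @param s2n_heavy,s2n_light signal-to-noise of the heavy and light
#'   channel (vectorised).
#' @return logical keep flag per peptide.
#' @examples
#' silac_peptide_filter(c(2, 4.9, 5), c(2, 0, 0))  # TRUE FALSE TRUE
#' @export
silac_peptide_filter <- function(s2n_heavy, s2n_light) {
  (s2n_heavy >= 2 & s2n_light >= 2) | pmax(s2n_heavy, s2n_light) >= 5
}

#' Denormalise TMT reporter intensities
#'
#' Reporter intensities exported per MS3 scan are normalised by the ion
#' accumulation time; multiplying them back by the scan's accumulation
#' time restores comparable absolute intensities.
#'
#' @param intensities numeric vector (one scan) or matrix (scans x
#'   channels).
#' @param accumulation_time scalar or per-scan vector (> 0).
#' @return denormalised intensities, same shape as the input.
#' @export
tmt_denormalize <- function(intensities, accumulation_time) {
  if (any(accumulation_time <= 0))
    stop("`accumulation_time` must be > 0", call. = FALSE)
  # matrix * per-scan vector recycles down columns, i.e. row-wise: each
  # scan's six channels share one accumulation time
  intensities * accumulation_time
}

#' Correct TMT reporter intensities for isotopic impurity
#'
#' Solves `M %*% x = observed` for the true channel intensities `x`,
#' where `M[i, j]` is the fraction of channel j's signal appearing in
#' channel i. Negative solutions are clipped to zero with a warning.
#'
#' @param intensities numeric vector (one scan) or matrix (scans x
#'   channels) of observed intensities.
#' @param impurity square impurity matrix (defaults to the identity, i.e.
#'   no correction, when no empirically derived matrix is supplied).
#' @return corrected intensities, same shape as the input.
#' @export
tmt_isotope_correct <- function(intensities, impurity = NULL) {
  vec <- !is.matrix(intensities)
  x <- if (vec) matrix(intensities, nrow = 1) else intensities
  if (is.null(impurity)) impurity <- diag(ncol(x))
  if (nrow(impurity) != ncol(x) || ncol(impurity) != ncol(x))
    stop("impurity matrix dimensions do not match channel count",
         call. = FALSE)
  if (abs(det(impurity)) < 1e-12)
    stop("impurity matrix is singular", call. = FALSE)
  corrected <- t(solve(impurity, t(x)))
  if (any(corrected < 0)) {
    warning("negative corrected intensities clipped to 0", call. = FALSE)
    corrected[corrected < 0] <- 0
  }
  dimnames(corrected) <- dimnames(x)
  if (vec) drop(corrected) else corrected
}

#' TMT turnover-experiment intensity filter
#'
#' Keeps scans whose denormalised reporter intensity is at least 20 in
#' the zero-timepoint channel and in at least four of the six channels.
#'
#' @param intensities scans x channels matrix of denormalised
#'   intensities.
#' @param zero_channel column index of the 0 s timepoint.
#' @param min_intensity intensity floor (20).
#' @param min_channels minimum number of channels at or above the floor.
#' @return logical keep flag per scan.
#' @export
tmt_turnover_filter <- function(intensities, zero_channel = 1L,
                                min_intensity = 20, min_channels = 4L) {
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = 1)
  intensities[, zero_channel] >= min_intensity &
    rowSums(intensities >= min_intensity) >= min_channels
}

#' Protein log2 ratio from SILAC peptides
#'
#' The protein ratio is the median of its peptides' log2 heavy/light
#' ratios.
#'
#' @param peptide_log2 numeric vector of peptide log2 ratios (already
#'   filtered).
#' @return scalar log2 ratio.
#' @export
silac_protein_ratio <- function(peptide_log2) {
  peptide_log2 <- peptide_log2[is.finite(peptide_log2)]
  if (!length(peptide_log2))
    stop("no quantified peptides for protein", call. = FALSE)
  stats::median(peptide_log2)
}

#' Protein log2 ratio from TMT peptides (intensity-weighted)
#'
#' The protein-level ratio is the ratio of the summed reporter
#' intensities of its peptides in the numerator and denominator channel,
#' log2-transformed. Summing first weights each peptide by its intensity.
#'
#' @param intensities peptides x channels matrix of (denormalised,
#'   impurity-corrected) intensities.
#' @param numerator_channel,denominator_channel column indices.
#' @return scalar log2 ratio.
#' @examples
#' m <- rbind(c(100, 50), c(300, 150))
#' tmt_protein_ratio(m, 1, 2)  # log2(400/200) = 1
#' @export
tmt_protein_ratio <- function(intensities, numerator_channel,
                              denominator_channel) {
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = 1)
  num <- sum(intensities[, numerator_channel])
  den <- sum(intensities[, denominator_channel])
  if (!is.finite(den) || den <= 0)
    stop("undefined ratio: denominator channel sum is not positive",
         call. = FALSE)
  log2(num / den)
}

#' Roll a SILAC peptide table up to protein log2 ratios
#'
#' Applies [silac_peptide_filter()] then takes the per-protein median of
#' peptide log2 ratios.
#'
#' @param peptides data.frame with columns `protein`, `s2n_heavy`,
#'   `s2n_light`, `ratio_hl` (heavy/light ratio on the linear scale), as
#'   produced by [generate_peptide_table()].
#' @return named numeric vector: log2 ratio per protein (proteins with no
#'   surviving peptide are absent).
#' @export
rollup_silac <- function(peptides) {
  need <- c("protein", "s2n_heavy", "s2n_light", "ratio_hl")
  if (!all(need %in% names(peptides)))
    stop("peptide table lacks columns: ",
         paste(setdiff(need, names(peptides)), collapse = ", "),
         call. = FALSE)
  keep <- silac_peptide_filter(peptides$s2n_heavy, peptides$s2n_light)
  kept <- peptides[keep, ]
  if (!nrow(kept)) return(setNames(numeric(), character()))
  l2 <- log2(kept$ratio_hl)
  out <- tapply(l2, kept$protein, stats::median)
  setNames(as.numeric(out), names(out))
}

#' Roll a TMT peptide table up to protein log2 ratios
#'
#' Denormalises intensities by accumulation time, applies the isotopic
#' impurity correction, optionally the turnover intensity filter, and
#' computes per-protein intensity-weighted ratios via
#' [tmt_protein_ratio()].
#'
#' @param peptides data.frame with columns `protein`, `i1`..`i6`
#'   (normalised intensities) and `accumulation_time`.
#' @param numerator_channel,denominator_channel channel indices; the
#'   denominator defaults to the wild-type reference channel 1.
#' @param impurity optional impurity matrix.
#' @param filter apply [tmt_turnover_filter()] with the denominator as
#'   zero channel.
#' @return named numeric vector: log2 ratio per protein.
#' @export
rollup_tmt <- function(peptides, numerator_channel = 2L,
                       denominator_channel = 1L, impurity = NULL,
                       filter = TRUE) {
  chan_cols <- grep("^i[0-9]+$", names(peptides), value = TRUE)
  if (!length(chan_cols) || !"accumulation_time" %in% names(peptides))
    stop("peptide table lacks TMT intensity/accumulation columns",
         call. = FALSE)
  x <- as.matrix(peptides[, chan_cols])
  x <- tmt_denormalize(x, peptides$accumulation_time)
  x <- tmt_isotope_correct(x, impurity)
  keep <- if (filter)
    tmt_turnover_filter(x, zero_channel = denominator_channel)
  else rep(TRUE, nrow(x))
  x <- x[keep, , drop = FALSE]
  prot <- peptides$protein[keep]
  if (!nrow(x)) return(setNames(numeric(), character()))
  ratios <- vapply(split(seq_len(nrow(x)), factor(prot, unique(prot))),
                   function(i) tmt_protein_ratio(x[i, , drop = FALSE],
                                                 numerator_channel,
                                                 denominator_channel),
                   numeric(1))
  ratios
}

#' Copy-number-aware recentering of log2-ratio columns
#'
#' Small differences in cell mixing shift whole ratio distributions; each
#' strain column is recentred so that the median log2 ratio of genes NOT
#' on that strain's duplicated chromosome is zero (most proteins are
#' assumed present 1:1). Duplicated genes are shifted by the same factor
#' so their excess relative to the background is preserved. Strains with
#' no duplicated chromosome (`NA`, e.g. wild-type/wild-type) are
#' recentred on all genes.
#'
#' @param m genes x strains matrix of log2 ratios.
#' @param annotation annotation data.frame (`gene`, `chromosome`).
#' @param strain_chromosomes named chromosome per strain; parsed from the
#'   column names by default.
#' @return recentred matrix with attribute `recenter_factors` (the
#'   per-strain subtracted medians).
#' @export
normalize_recenter <- function(m, annotation,
                               strain_chromosomes = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(strain_chromosomes))
    strain_chromosomes <- strain_chromosome(colnames(m))
  chrom <- setNames(annotation$chromosome, annotation$gene)[rownames(m)]
  factors <- setNames(numeric(ncol(m)), colnames(m))
  out <- m
  for (j in seq_len(ncol(m))) {
    dup <- strain_chromosomes[[colnames(m)[j]]]
    idx <- if (is.na(dup)) rep(TRUE, nrow(m)) else chrom != dup
    factors[j] <- stats::median(m[idx, j], na.rm = TRUE)
    out[, j] <- m[, j] - factors[j]
  }
  attr(out, "layer") <- attr(m, "layer")
  attr(out, "condition") <- attr(m, "condition")
  attr(out, "recenter_factors") <- factors
  out
}
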