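#' Weighted Pearson correlation
#'
#' Pearson correlation with per-observation weights used in the weighted
#' means and (co)variances. With binary weights this equals the ordinary
#' correlation computed on the retained subset.
#'
#' @param x,y numeric vectors.
#' @param w non-negative weights (default all 1). Pairs with missing
#'   values are dropped.
#' @return correlation in `[-1, 1]` (`NA` when a weighted variance is
#'   zero).
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  keep <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (sum(w) <= 0 || length(x) < 3)
    stop("need >= 3 effective (positively weighted) points", call. = FALSE)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Weight table down-weighting duplicated-chromosome measurements
#'
#' Builds a (gene x strain) weight matrix: `duplicated_weight`
#' (default 0) for measurements of genes on the strain's own duplicated
#' chromosome, 0 for missing cells, 1 elsewhere. Used so that the
#' trivially elevated duplicated block does not drive clustering.
#'
#' @param m genes x strains matrix.
#' @param annotation annotation data.frame (`gene`, `chromosome`).
#' @param strain_chromosomes named duplicated chromosome per strain
#'   (parsed from column names by default; `NA` = no duplication).
#' @param duplicated_weight weight for duplicated-chromosome cells.
#' @return numeric matrix shaped like `m` with entries in `[0, 1]`.
#' @export
weight_table <- function(m, annotation, strain_chromosomes = NULL,
                         duplicated_weight = 0) {
  if (is.null(strain_chromosomes))
    strain_chromosomes <- strain_chromosome(colnames(m))
  chrom <- setNames(annotation$chromosome, annotation$gene)[rownames(m)]
  w <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  for (strain in colnames(m)) {
    dup <- strain_chromosomes[[strain]]
    if (!is.na(dup)) w[chrom == dup & !is.na(chrom), strain] <- duplicated_weight
  }
  w[!is.finite(m)] <- 0
  w
}

# Pairwise weighted-Pearson matrix between rows of X; pair weight is the
# elementwise product of the two rows' weights. Pure matrix algebra so
# it scales to thousands of genes.
row_weighted_correlation <- function(X, W) {
  W[!is.finite(X)] <- 0
  X[!is.finite(X)] <- 0
  XW <- X * W
  X2W <- X * XW
  Sw <- W %*% t(W)
  Sx <- XW %*% t(W)
  Sy <- t(Sx)
  Sxy <- XW %*% t(XW)
  Sxx <- X2W %*% t(W)
  Syy <- t(Sxx)
  num <- Sxy - Sx * Sy / Sw
  den <- sqrt(pmax(Sxx - Sx^2 / Sw, 0) * pmax(Syy - Sy^2 / Sw, 0))
  R <- num / den
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  pmin(pmax(R, -1), 1)
}

#' Weighted hierarchical clustering of genes
#'
#' Agglomerative clustering of gene rows with distance
#' `1 - weighted_pearson` where each pair's weights are the product of
#' the two measurements' weights (WCluster-style: a weight table lets
#' individual measurements be discounted, e.g. zero weight for genes on
#' each strain's duplicated chromosome). Rows with fewer than `min_obs`
#' positively weighted observations are dropped and reported.
#'
#' @param m genes x strains matrix.
#' @param weights weight matrix shaped like `m` (default all 1 with 0 at
#'   missing cells).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param min_obs minimum positively weighted observations per row.
#' @return an `hclust` object over the retained genes, with attribute
#'   `dropped` naming excluded genes.
#' @export
weighted_hcluster <- function(m, weights = NULL, linkage = "average",
                              min_obs = 3L) {
  if (is.null(weights)) {
    weights <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    weights[!is.finite(m)] <- 0
  }
  eff <- rowSums(weights > 0 & is.finite(m))
  dropped <- rownames(m)[eff < min_obs]
  keep <- eff >= min_obs
  if (sum(keep) < 2)
    stop("fewer than 2 genes with enough weighted observations",
         call. = FALSE)
  X <- m[keep, , drop = FALSE]
  W <- weights[keep, , drop = FALSE]
  R <- row_weighted_correlation(X, W)
  d <- stats::as.dist(1 - R)
  hc <- stats::hclust(d, method = linkage)
  hc$labels <- rownames(X)
  attr(hc, "dropped") <- dropped
  hc
}

#' Extract the consistently upregulated signature
#'
#' Finds the gene set upregulated in every strain, the
#' aneuploidy-associated protein signature (APS) pattern. Two methods:
#' `"threshold"` keeps genes whose (positively weighted) value exceeds
#' `min_log2` in at least `min_strains` strains with no weighted strain
#' below, and whose mean is at least `mean_floor`; `"cluster"` cuts the
#' weighted dendrogram and picks the cluster (size >=
#' `min_cluster_size`) maximising the minimum per-strain cluster mean.
#'
#' @param m genes x strains matrix.
#' @param weights optional weight matrix (e.g. [weight_table()]).
#' @param min_log2 per-strain lower bound (exclusive) for the threshold
#'   method.
#' @param mean_floor minimum mean over weighted cells.
#' @param min_strains minimum number of positively weighted strains a
#'   gene must qualify in (default: all strains).
#' @param method `"threshold"` or `"cluster"`.
#' @param min_cluster_size,max_k cluster-method controls.
#' @param linkage linkage for the cluster method.
#' @param name signature name.
#' @return object of class `signature_set`: list with `name`, `genes`,
#'   `projection` (per-strain data.frame strain/mean/sem/n), `method`.
#' @export
extract_consistent_up_signature <- function(m, weights = NULL,
                                            min_log2 = 0,
                                            mean_floor = 0.2,
                                            min_strains = ncol(m),
                                            method = c("threshold",
                                                       "cluster"),
                                            min_cluster_size = 10L,
                                            max_k = 40L,
                                            linkage = "average",
                                            name = "APS") {
  method <- match.arg(method)
  if (ncol(m) < 2) stop("need >= 2 strains", call. = FALSE)
  if (is.null(weights)) {
    weights <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    weights[!is.finite(m)] <- 0
  }
  eff <- weights > 0 & is.finite(m)
  if (method == "threshold") {
    n_eff <- rowSums(eff)
    n_pass <- rowSums(eff & m > min_log2, na.rm = TRUE)
    mean_eff <- rowSums(ifelse(eff, m, 0), na.rm = TRUE) / pmax(n_eff, 1)
    qual <- n_pass == n_eff & n_eff >= min_strains & mean_eff >= mean_floor
    genes <- rownames(m)[qual]
  } else {
    hc <- weighted_hcluster(m, weights, linkage = linkage)
    best <- NULL; best_score <- -Inf
    for (k in 2:min(max_k, length(hc$labels) - 1)) {
      cl <- stats::cutree(hc, k = k)
      for (g in unique(cl)) {
        members <- hc$labels[cl == g]
        if (length(members) < min_cluster_size) next
        sub <- m[members, , drop = FALSE]
        wsub <- weights[members, , drop = FALSE]
        smeans <- colSums(ifelse(wsub > 0 & is.finite(sub), sub, 0)) /
          pmax(colSums(wsub > 0 & is.finite(sub)), 1)
        score <- min(smeans)
        if (score > best_score) { best_score <- score; best <- members }
      }
    }
    genes <- if (is.null(best)) character() else sort(best)
  }
  if (!length(genes))
    warning("no qualifying signature genes", call. = FALSE)
  projection <- if (length(genes)) signature_projection(m, genes) else
    data.frame(strain = colnames(m), mean = NA_real_, sem = NA_real_,
               n = 0L)
  structure(list(name = name, genes = genes, projection = projection,
                 method = method),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s': %d genes (%s method)\n", x$name,
              length(x$genes), x$method))
  if (length(x$genes))
    cat(sprintf("  per-strain mean %.3f to %.3f\n",
                min(x$projection$mean), max(x$projection$mean)))
  invisible(x)
}

#' Project a gene set onto strains
#'
#' Per-strain arithmetic mean and standard error of the set's rows
#' (missing values excluded), the intensity of a signature in each
#' strain.
#'
#' @param m genes x strains matrix.
#' @param genes gene set (must intersect the matrix rows).
#' @return data.frame with columns `strain`, `mean`, `sem`, `n`.
#' @export
signature_projection <- function(m, genes) {
  genes <- intersect(genes, rownames(m))
  if (!length(genes)) stop("gene set does not intersect matrix rows",
                           call. = FALSE)
  sub <- m[genes, , drop = FALSE]
  n <- colSums(is.finite(sub))
  mean_ <- colMeans(sub, na.rm = TRUE)
  sem <- apply(sub, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  data.frame(strain = colnames(m), mean = unname(mean_),
             sem = unname(sem), n = unname(n), stringsAsFactors = FALSE)
}

#' Correlate signature intensity with duplicated-chromosome size
#'
#' Pearson correlation (and least-squares line) between each strain's
#' signature intensity and the size of its duplicated chromosome.
#'
#' @param signature a `signature_set` or a named per-strain intensity
#'   vector.
#' @param chromosome_sizes named chromosome sizes (gene counts or bp).
#' @param strain_chromosomes named duplicated chromosome per strain
#'   (parsed from strain names by default).
#' @return list with `r`, `slope`, `intercept`, `n`, `data`
#'   (strain/size/intensity).
#' @export
intensity_size_correlation <- function(signature, chromosome_sizes,
                                       strain_chromosomes = NULL) {
  intensity <- if (inherits(signature, "signature_set"))
    setNames(signature$projection$mean, signature$projection$strain)
  else signature
  strains <- names(intensity)
  if (is.null(strain_chromosomes))
    strain_chromosomes <- strain_chromosome(strains)
  size <- as.numeric(chromosome_sizes[strain_chromosomes[strains]])
  keep <- is.finite(size) & is.finite(intensity)
  if (sum(keep) < 3) stop("need >= 3 strains", call. = FALSE)
  df <- data.frame(strain = strains[keep], size = size[keep],
                   intensity = unname(intensity[keep]),
                   stringsAsFactors = FALSE)
  fit <- stats::lm(intensity ~ size, data = df)
  list(r = stats::cor(df$size, df$intensity),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(df), data = df)
}

#' Bin genes by one matrix and compare the other, per strain
#'
#' Bins shared genes by their value in `matrix_a` into down
#' (`<= bounds[1]`), unchanged, and up (`>= bounds[2]`) categories, then
#' for each strain and bin reports the two means and a paired t test of
#' a vs b over the bin's genes. Used to ask whether a perturbation
#' (e.g. UBP6 loss) preferentially moves the most up- or down-regulated
#' proteins.
#'
#' @param matrix_a,matrix_b genes x strains matrices sharing genes and
#'   strains.
#' @param bounds down/up thresholds on `matrix_a` values (default
#'   `c(-0.4, 0.4)`).
#' @return data.frame with columns `strain`, `bin`, `n`, `mean_a`,
#'   `mean_b`, `mean_diff`, `p_value` (NA for bins with < 2 genes;
#'   1 when a and b are identical).
#' @export
bin_and_compare <- function(matrix_a, matrix_b, bounds = c(-0.4, 0.4)) {
  genes <- intersect(rownames(matrix_a), rownames(matrix_b))
  strains <- intersect(colnames(matrix_a), colnames(matrix_b))
  if (!length(genes) || !length(strains))
    stop("matrices share no genes or no strains", call. = FALSE)
  rows <- list()
  for (strain in strains) {
    a <- matrix_a[genes, strain]
    b <- matrix_b[genes, strain]
    keep <- is.finite(a) & is.finite(b)
    bin <- ifelse(a <= bounds[1], "down",
                  ifelse(a >= bounds[2], "up", "unchanged"))
    for (bn in c("down", "unchanged", "up")) {
      idx <- keep & bin == bn
      n <- sum(idx)
      if (n == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          strain = strain, bin = bn, n = 0L, mean_a = NA_real_,
          mean_b = NA_real_, mean_diff = NA_real_, p_value = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      d <- b[idx] - a[idx]
      p <- if (n < 2) NA_real_
      else if (stats::sd(d) == 0) { if (all(d == 0)) 1 else 0 }
      else stats::t.test(b[idx], a[idx], paired = TRUE)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        strain = strain, bin = bn, n = n, mean_a = mean(a[idx]),
        mean_b = mean(b[idx]), mean_diff = mean(d), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene turnover slopes from a short inhibition timecourse
#'
#' Least-squares slope of each gene's log2 ratio against time (seconds),
#' with per-chromosome mean slopes and an optional Welch contrast of an
#' attenuated gene group against the rest: attenuated duplicated genes
#' are the ones expected to accumulate when degradation is blocked.
#'
#' @param timecourse genes x timepoints matrix of log2 ratios.
#' @param timepoints times in seconds (default `c(0, 90, 300)`).
#' @param annotation optional annotation for per-chromosome averages.
#' @param attenuated optional attenuated gene set for the group
#'   contrast.
#' @param background genes forming the contrast's comparison group
#'   (default: all other genes in `timecourse`).
#' @return list with `slopes` (data.frame gene/slope/se),
#'   `chromosome_means` (or NULL), `contrast` (means, Welch p; or NULL).
#' @export
fit_turnover_slope <- function(timecourse, timepoints = c(0, 90, 300),
                               annotation = NULL, attenuated = NULL,
                               background = NULL) {
  if (length(timepoints) != ncol(timecourse))
    stop("`timepoints` must match the timecourse columns", call. = FALSE)
  if (length(timepoints) < 2)
    stop("need >= 2 timepoints", call. = FALSE)
  tc <- timepoints - mean(timepoints)
  sxx <- sum(tc^2)
  X <- timecourse
  complete <- rowSums(!is.finite(X)) == 0
  slope <- rep(NA_real_, nrow(X))
  se <- rep(NA_real_, nrow(X))
  if (any(complete)) {
    Xc <- X[complete, , drop = FALSE]
    sl <- drop(Xc %*% tc) / sxx
    fitted <- outer(sl, tc) + rowMeans(Xc)
    ss_res <- rowSums((Xc - fitted)^2)
    df_res <- length(timepoints) - 2
    se_c <- if (df_res > 0) sqrt(ss_res / df_res / sxx) else NA_real_
    slope[complete] <- sl
    se[complete] <- se_c
  }
  incomplete <- which(!complete)
  for (i in incomplete) {
    ok <- is.finite(X[i, ])
    if (sum(ok) < 2) next
    f <- stats::lm(X[i, ok] ~ timepoints[ok])
    slope[i] <- unname(stats::coef(f)[2])
    se[i] <- tryCatch(summary(f)$coefficients[2, 2],
                      error = function(e) NA_real_)
  }
  slopes <- data.frame(gene = rownames(X), slope = slope, se = se,
                       stringsAsFactors = FALSE)

  chromosome_means <- NULL
  if (!is.null(annotation)) {
    chrom <- setNames(annotation$chromosome, annotation$gene)[slopes$gene]
    ok <- is.finite(slopes$slope) & !is.na(chrom)
    agg <- tapply(slopes$slope[ok], chrom[ok], mean)
    chromosome_means <- data.frame(chromosome = names(agg),
                                   mean_slope = as.numeric(agg),
                                   stringsAsFactors = FALSE)
  }

  contrast <- NULL
  if (!is.null(attenuated)) {
    if (is.null(background)) background <- setdiff(slopes$gene, attenuated)
    a <- slopes$slope[slopes$gene %in% attenuated &
                        is.finite(slopes$slope)]
    b <- slopes$slope[slopes$gene %in% background &
                        is.finite(slopes$slope)]
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      contrast <- list(mean_attenuated = mean(a), mean_other = mean(b),
                       n_attenuated = length(a), n_other = length(b),
                       p_value = tt$p.value)
    }
  }
  list(slopes = slopes, chromosome_means = chromosome_means,
       contrast = contrast)
}
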