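#' Read a gene-by-strain log2-ratio matrix from TSV
#'
#' Expects a header row with a gene-ID column (first column) followed by
#' one column per strain. Empty cells and `"NA"` are read as missing
#' values, never as zeros; gene order is preserved.
#'
#' @param path TSV file.
#' @param layer layer tag attached to the result
#'   (`"protein"`/`"mRNA"`/`"footprint"`).
#' @param condition free-text condition tag.
#' @return numeric matrix (genes x strains) with rownames = gene IDs and
#'   attributes `layer`, `condition`.
#' @export
read_quant_matrix <- function(path, layer = "protein", condition = "") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  if (ncol(df) < 2)
    stop("quant matrix needs a gene column plus >= 1 strain column: ", path,
         call. = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    d <- which(duplicated(genes))[1]
    stop(sprintf("duplicate gene ID '%s' at row %d of %s",
                 genes[d], d, path), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell '%s' at gene '%s', strain '%s' in %s",
      vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
      colnames(vals)[bad[1, 2]], path), call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(vals))
  if (any(is.infinite(num)))
    stop("non-finite value in quant matrix: ", path, call. = FALSE)
  attr(num, "layer") <- layer
  attr(num, "condition") <- condition
  num
}

#' Write a quantification matrix to TSV
#'
#' Missing values are written as empty cells (the canonical form read
#' back by [read_quant_matrix()]).
#'
#' @param m genes x strains numeric matrix with rownames.
#' @param path output file.
#' @param digits significant digits used when printing values.
#' @export
write_quant_matrix <- function(m, path, digits = 8) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  out <- data.frame(gene = rownames(m),
                    signif(unclass(m), digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write gene annotation (gene, chromosome, ordinal position)
#'
#' The annotation TSV has columns `gene`, `chromosome`, `position`
#' (0-based ordinal along the chromosome). Ordinal positions must be
#' unique within a chromosome.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene`, `chromosome`, `position`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop("annotation must have columns gene, chromosome, position",
         call. = FALSE)
  df <- df[, need]
  df$chromosome <- as.character(df$chromosome)
  if (anyDuplicated(df$gene))
    stop("duplicate gene in annotation: ",
         df$gene[duplicated(df$gene)][1], call. = FALSE)
  dup <- duplicated(df[, c("chromosome", "position")])
  if (any(dup))
    stop("duplicate ordinal position within a chromosome: ",
         df$chromosome[dup][1], ":", df$position[dup][1], call. = FALSE)
  df
}

#' @rdname read_gene_annotation
#' @param annotation data.frame with columns `gene`, `chromosome`,
#'   `position`.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("gene", "chromosome", "position")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ingest annotation from a minimal BED/GFF3 subset
#'
#' Accepts 4+-column BED (chrom, start, end, name) or GFF3 (gene ID taken
#' from the `ID=` attribute) and converts bp starts to 0-based ordinal
#' positions within each chromosome.
#'
#' @param path BED or GFF3 file.
#' @return annotation data.frame (`gene`, `chromosome`, `position`) plus a
#'   `bp_size` attribute: named per-chromosome bp span.
#' @export
read_annotation_features <- function(path) {
  first <- readLines(path, n = 50)
  gff <- any(grepl("^##gff", first)) ||
    any(grepl("\t[^\t]*ID=", first))
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (gff) {
    if (ncol(raw) < 9) stop("malformed GFF3: ", path, call. = FALSE)
    ids <- sub(".*ID=([^;]+).*", "\\1", raw[[9]])
    df <- data.frame(chromosome = as.character(raw[[1]]),
                     start = as.numeric(raw[[4]]), gene = ids,
                     stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 4) stop("BED needs chrom, start, end, name: ", path,
                            call. = FALSE)
    df <- data.frame(chromosome = as.character(raw[[1]]),
                     start = as.numeric(raw[[2]]), gene = as.character(raw[[4]]),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$chromosome, df$start), ]
  pos <- unlist(lapply(split(seq_len(nrow(df)), df$chromosome),
                       function(i) seq_along(i) - 1L), use.names = FALSE)
  out <- data.frame(gene = df$gene, chromosome = df$chromosome,
                    position = pos[order(order(df$chromosome, df$start))],
                    stringsAsFactors = FALSE)
  out <- out[match(unique(df$gene), out$gene), ]
  rownames(out) <- NULL
  attr(out, "bp_size") <- tapply(df$start, df$chromosome, max)
  out
}

#' Read a protein-complex catalog from two-column TSV
#'
#' Column 1 = complex ID, column 2 = member gene. Duplicate
#' (complex, gene) rows are dropped with a warning; complexes with fewer
#' than two distinct members are rejected.
#'
#' @param path TSV file (header optional; detected by the first row).
#' @return named list of member-gene character vectors, with attribute
#'   `provenance` = `path`.
#' @export
read_complex_catalog <- function(path) {
  sets <- read_two_column_sets(path)
  sizes <- lengths(sets)
  if (any(sizes < 2))
    stop("singleton complex(es): ",
         paste(names(sets)[sizes < 2], collapse = ", "), call. = FALSE)
  attr(sets, "provenance") <- path
  sets
}

#' @rdname read_complex_catalog
#' @param catalog named list of member-gene vectors.
#' @export
write_complex_catalog <- function(catalog, path) {
  df <- data.frame(complex = rep(names(catalog), lengths(catalog)),
                   gene = unlist(catalog, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read named gene sets from two-column TSV (set ID, gene)
#'
#' @param path TSV file.
#' @return named list of gene vectors (insertion order preserved).
#' @export
read_gene_sets <- function(path) {
  read_two_column_sets(path)
}

#' @rdname read_gene_sets
#' @param sets named list of gene vectors.
#' @export
write_gene_sets <- function(sets, path) {
  df <- data.frame(set = rep(names(sets), lengths(sets)),
                   gene = unlist(sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_two_column_sets <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expected two columns in ", path, call. = FALSE)
  # tolerate an optional header row
  if (tolower(raw[1, 1]) %in% c("set", "complex", "id", "set_id",
                                "complex_id"))
    raw <- raw[-1, , drop = FALSE]
  key <- paste(raw[[1]], raw[[2]], sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (set, gene) rows dropped in ", path, call. = FALSE)
    raw <- raw[!duplicated(key), ]
  }
  ids <- unique(raw[[1]])
  sets <- split(raw[[2]], factor(raw[[1]], levels = ids))
  lapply(sets, as.character)
}

#' Pair two layers cell-by-cell
#'
#' Joins two quantification matrices of different layers on shared
#' (gene, strain) cells, keeping only pairs measured in both.
#'
#' @param a,b quantification matrices (attributes `layer` must differ).
#' @return data.frame with columns `gene`, `strain`, `value_a`,
#'   `value_b`; attribute `n_pairs` gives the pair count.
#' @export
merge_layers <- function(a, b) {
  la <- attr(a, "layer"); lb <- attr(b, "layer")
  if (!is.null(la) && !is.null(lb) && identical(la, lb))
    stop("`a` and `b` must be different layers", call. = FALSE)
  strains <- intersect(colnames(a), colnames(b))
  if (!length(strains))
    stop("no shared strains between layers", call. = FALSE)
  genes <- intersect(rownames(a), rownames(b))
  if (!length(genes)) {
    warning("no shared genes between layers; empty pairing", call. = FALSE)
    out <- data.frame(gene = character(), strain = character(),
                      value_a = numeric(), value_b = numeric())
    attr(out, "n_pairs") <- 0L
    return(out)
  }
  va <- a[genes, strains, drop = FALSE]
  vb <- b[genes, strains, drop = FALSE]
  keep <- is.finite(va) & is.finite(vb)
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(gene = genes[idx[, 1]], strain = strains[idx[, 2]],
                    value_a = va[keep], value_b = vb[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$strain, strains), match(out$gene, genes)), ]
  rownames(out) <- NULL
  attr(out, "n_pairs") <- nrow(out)
  out
}

#' Duplicated chromosome of each strain from its name
#'
#' Parses the `disome<roman>[_ubp6]` naming convention; strains that do
#' not match (e.g. wild-type/wild-type controls) map to `NA`.
#'
#' @param strains character vector of strain names.
#' @return named character vector of chromosome IDs (roman numerals).
#' @examples
#' strain_chromosome(c("disomeV", "disomeXIII_ubp6", "WT"))
#' @export
strain_chromosome <- function(strains) {
  out <- rep(NA_character_, length(strains))
  ok <- grepl("^disome[IVXLCDM]+([_,.].*)?$", strains)
  out[ok] <- sub("^disome([IVXLCDM]+).*$", "\\1", strains[ok])
  setNames(out, strains)
}
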