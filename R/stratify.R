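#' Coerce to an expression matrix
#'
#' Expression data are kept as a base numeric matrix, genes in rows and
#' samples in columns (log-scale values). Data frames whose first column
#' holds gene identifiers are coerced.
#'
#' @param x A numeric matrix with rownames (genes) and colnames (samples),
#'   or a data frame with gene identifiers in the first column.
#' @return A numeric matrix with unique rownames and colnames.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix or a data frame", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values", call. = FALSE)
  x
}

degenerate_condition <- function(msg) {
  structure(class = c("sigfalsify_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Stratify patients by the first principal component of a gene set
#'
#' Restricts the expression matrix to the given gene set, z-scores each
#' gene across samples (zero-variance genes dropped with a warning),
#' computes the first principal component of the samples in that gene
#' space by singular value decomposition, and splits the cohort into two
#' groups on the PC1 score. The sign of PC1 is fixed so that scores
#' correlate non-negatively with each sample's mean z-scored expression,
#' making `LOW`/`HIGH` interpretable as low/high expression of the set.
#'
#' @param expr Expression matrix (see [as_expression_matrix()]).
#' @param genes Character vector of gene identifiers; members absent from
#'   `expr` are dropped with a warning, at least two usable genes are
#'   required.
#' @param split `"median"` (groups by median score, ties to `LOW`) or
#'   `"sign"` (groups by the sign of the score, zero to `LOW`).
#' @return A tibble of class `stratification`: `sample`, `score`, `group`
#'   (factor `LOW`/`HIGH`), with attributes `method` and `genes_used`.
#' @export
pc1_stratify <- function(expr, genes, split = c("median", "sign")) {
  split <- match.arg(split)
  expr <- as_expression_matrix(expr)
  genes <- unique(as.character(genes))
  present <- genes[genes %in% rownames(expr)]
  if (length(present) < length(genes)) {
    warning(sprintf("%d gene(s) of the set absent from expression matrix",
                    length(genes) - length(present)), call. = FALSE)
  }
  if (ncol(expr) < 4) stop("need at least 4 samples", call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(sds == 0)),
            call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) < 2) {
    stop(degenerate_condition("fewer than 2 usable genes for PC1 stratification"))
  }
  z <- (sub - rowMeans(sub)) / sds
  # rows are centered, so columns of t(z) are centered: PC1 of the samples
  # is the leading right singular vector of z.
  sv <- svd(z, nu = 0, nv = 1)
  scores <- sv$v[, 1] * sv$d[1]
  msum <- colMeans(z)
  if (sum(scores * msum) < 0) scores <- -scores
  group <- switch(split,
    median = ifelse(scores <= stats::median(scores), "LOW", "HIGH"),
    sign   = ifelse(scores <= 0, "LOW", "HIGH")
  )
  if (length(unique(group)) < 2) {
    stop(degenerate_condition("degenerate stratification: one group is empty"))
  }
  out <- tibble::tibble(sample = colnames(expr),
                        score = scores,
                        group = factor(group, levels = c("LOW", "HIGH")))
  structure(out, class = c("stratification", class(out)),
            method = paste0("pc1_", split), genes_used = rownames(sub))
}

#' Sample a random surrogate gene set
#'
#' Uniform sample without replacement from the eligible pool; surrogate
#' sets drawn from the strong-regime pool share zero GO-BP terms with the
#' signature by construction. Deterministic for a fixed RNG state.
#'
#' @param eligible Character vector of eligible gene identifiers.
#' @param size Number of genes to draw (the signature size).
#' @return Character vector of `size` gene identifiers.
#' @export
random_gene_set <- function(eligible, size) {
  eligible <- as.character(eligible)
  size <- as.integer(size)
  if (size < 1) stop("size must be positive", call. = FALSE)
  if (size > length(eligible)) {
    stop(sprintf("requested %d genes from a pool of %d", size, length(eligible)),
         call. = FALSE)
  }
  if (size == length(eligible)) return(eligible)
  eligible[sample.int(length(eligible), size)]
}
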