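#' Gene signatures
#'
#' A signature is a named, ordered set of gene identifiers proposed as a
#' prognostic biomarker.
#'
#' @param genes Character vector of gene identifiers; duplicates are
#'   rejected.
#' @param name Signature label.
#' @return A list of class `signature` with elements `name` and `genes`.
#' @export
signature <- function(genes, name = "signature") {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("signature must contain at least one gene", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("signature contains duplicate genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(genes) | grepl("\\s", genes))) {
    stop("gene identifiers must be non-empty without whitespace", call. = FALSE)
  }
  structure(list(name = as.character(name)[1], genes = genes), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %s: %d genes\n", x$name, length(x$genes)))
  cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_signature <- function(x, name = "signature") {
  if (inherits(x, "signature")) return(x)
  signature(x, name = name)
}

#' Remove proliferation genes from the gene pool
#'
#' First step of the removal procedure: the proliferation gene list PG is
#' subtracted from the total pool G, giving G* = G \ PG. Proliferation
#' genes are removed because proliferation is prognostic in many cancers
#' regardless of signature membership and would confound the surrogate
#' comparison.
#'
#' @param pool Character vector of gene identifiers (the dataset's genes);
#'   input order is preserved, duplicates dropped.
#' @param pg Character vector of proliferation genes; entries absent from
#'   the pool are ignored (counted in a warning). May be empty, in which
#'   case a warning notes that no proliferation list was supplied.
#' @return Character vector G* = `pool` minus `pg`, in pool order.
#' @export
remove_proliferation <- function(pool, pg = character(0)) {
  pool <- unique(as.character(pool))
  if (length(pool) == 0) stop("gene pool is empty", call. = FALSE)
  pg <- unique(as.character(pg))
  if (length(pg) == 0) {
    warning("no proliferation gene list supplied; pool left unchanged", call. = FALSE)
    return(pool)
  }
  missing_n <- sum(!pg %in% pool)
  if (missing_n > 0) {
    warning(sprintf("%d proliferation gene(s) not found in pool", missing_n),
            call. = FALSE)
  }
  out <- setdiff(pool, pg)
  if (length(out) == 0) {
    stop("removing proliferation genes leaves an empty pool", call. = FALSE)
  }
  out
}

#' Removal set of a signature
#'
#' Maps the signature's genes to their GO-BP terms (the signature's
#' meaning), then maps those terms back to every gene annotated to any of
#' them. The result D is the set of genes sharing at least one BP term
#' with the signature; all annotated signature genes are contained in D.
#'
#' @param map An [annotation_map()].
#' @param bm A [signature()] or character vector of signature genes.
#' @return A list with `terms` (the signature's meaning) and `genes`
#'   (the removal set D).
#' @export
removal_set <- function(map, bm) {
  bm <- as_signature(bm)
  terms <- meaning_of_set(map, bm$genes)
  if (length(terms) == 0) {
    warning("signature '", bm$name,
            "' has no BP annotation; removal set is empty", call. = FALSE)
    return(list(terms = character(0), genes = character(0)))
  }
  genes <- sort(unique(map$gene[map$term %in% terms]))
  list(terms = terms, genes = genes)
}

removal_modes <- c("strong", "weak_ii", "weak_i")

#' Eligible gene pool under a removal regime
#'
#' Computes the pool G' from which surrogate gene sets are sampled, under
#' one of three regimes:
#' \describe{
#'   \item{`"weak_i"`}{sample from all of G* = G \ PG (signature genes may
#'     recur in surrogates);}
#'   \item{`"weak_ii"`}{sample from G* minus the signature genes;}
#'   \item{`"strong"`}{sample only from genes belonging to no GO-BP term
#'     that contains a signature gene: G' = G* \ (D U BM). Every eligible
#'     gene then has empty common meaning with the signature, so surrogate
#'     sets share zero BP terms with it.}
#' }
#' Unannotated genes satisfy the disjointness requirement vacuously and
#' remain eligible under the strong regime; their count is reported in the
#' provenance so users can see how much of the pool is annotation-dark.
#'
#' @param pool Character vector of dataset genes (G).
#' @param pg Proliferation genes to subtract first (may be empty).
#' @param map An [annotation_map()].
#' @param bm A [signature()] or character vector.
#' @param mode One of `"strong"`, `"weak_ii"`, `"weak_i"`.
#' @return A list of class `removal_result` with elements `mode`,
#'   `g_star`, `removal_terms`, `removed_genes` (D), `eligible` (G'),
#'   `signature`, and `provenance` (named integer counts).
#' @export
eligible_pool <- function(pool, pg = character(0), map, bm,
                          mode = c("strong", "weak_ii", "weak_i")) {
  mode <- match.arg(mode)
  bm <- as_signature(bm)
  pool <- unique(as.character(pool))
  g_star <- withCallingHandlers(
    remove_proliferation(pool, pg),
    warning = function(w) {
      if (length(pg) == 0) invokeRestart("muffleWarning")
    }
  )
  rs <- suppressWarnings(removal_set(map, bm))
  eligible <- switch(mode,
    weak_i  = g_star,
    weak_ii = setdiff(g_star, bm$genes),
    strong  = setdiff(g_star, union(rs$genes, bm$genes))
  )
  if (length(eligible) < length(bm$genes)) {
    stop(sprintf("eligible pool (%d genes) smaller than signature (%d genes)",
                 length(eligible), length(bm$genes)), call. = FALSE)
  }
  annotated <- unique(map$gene)
  structure(list(
    mode = mode,
    g_star = g_star,
    removal_terms = rs$terms,
    removed_genes = rs$genes,
    eligible = eligible,
    signature = bm,
    provenance = c(
      n_pool            = length(pool),
      n_pg_applied      = sum(unique(as.character(pg)) %in% pool),
      n_g_star          = length(g_star),
      n_removal_terms   = length(rs$terms),
      n_removed         = length(intersect(rs$genes, g_star)),
      n_eligible        = length(eligible),
      n_eligible_unannotated = sum(!eligible %in% annotated)
    )
  ), class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<removal_result> mode: %s | signature: %s (%d genes)\n",
              x$mode, x$signature$name, length(x$signature$genes)))
  cat(sprintf("  |G| = %d  ->  |G*| = %d (PG applied: %d)\n",
              p[["n_pool"]], p[["n_g_star"]], p[["n_pg_applied"]]))
  cat(sprintf("  signature meaning: %d BP terms; removal set |D ^ G*| = %d\n",
              p[["n_removal_terms"]], p[["n_removed"]]))
  cat(sprintf("  eligible |G'| = %d (%d unannotated)\n",
              p[["n_eligible"]], p[["n_eligible_unannotated"]]))
  invisible(x)
}

#' Tidy a removal result
#'
#' @param x A `removal_result`.
#' @param ... Unused.
#' @return One row per provenance quantity: `quantity`, `count`.
#' @export
tidy.removal_result <- function(x, ...) {
  tibble::tibble(quantity = names(x$provenance),
                 count = unname(as.integer(x$provenance)))
}

#' @rdname tidy.removal_result
#' @export
glance.removal_result <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$provenance))
  out$mode <- x$mode
  out$signature <- x$signature$name
  dplyr::relocate(out, "mode", "signature")
}
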