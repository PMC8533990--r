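#' Gene-to-GO annotation maps
#'
#' An `annotation_map` stores the binary relation between genes and Gene
#' Ontology biological-process (BP) terms as a tibble of distinct
#' (gene, term) pairs. Because a single pair table is kept, the gene-to-term
#' view and its transpose (term-to-gene) are consistent by construction.
#'
#' The in-memory constructor accepts any non-empty, whitespace-free tokens
#' for genes and terms so that toy and synthetic maps are easy to build;
#' the strict `GO:` + 7 digit pattern is enforced when parsing annotation
#' files (see [read_annotation()]).
#'
#' @param pairs A data frame with columns `gene` and `term`, one row per
#'   annotation. Duplicates are collapsed (set semantics).
#' @param propagated Logical flag recording whether ancestor propagation has
#'   been applied (see [propagate_ancestors()]).
#'
#' @return A tibble of class `annotation_map` with columns `gene` and
#'   `term`, plus a `propagated` attribute.
#' @examples
#' m <- annotation_map(data.frame(
#'   gene = c("gA", "gA", "gB"),
#'   term = c("GO:0000001", "GO:0000002", "GO:0000002")
#' ))
#' meaning_of_gene(m, "gA")
#' @export
annotation_map <- function(pairs, propagated = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("gene", "term") %in% names(pairs))) {
    stop("`pairs` must have columns `gene` and `term`", call. = FALSE)
  }
  pairs <- dplyr::distinct(pairs[, c("gene", "term")])
  pairs$gene <- as.character(pairs$gene)
  pairs$term <- as.character(pairs$term)
  bad <- !nzchar(pairs$gene) | grepl("\\s", pairs$gene) |
    !nzchar(pairs$term) | grepl("\\s", pairs$term)
  if (any(bad)) {
    stop("gene and term identifiers must be non-empty and contain no whitespace",
         call. = FALSE)
  }
  structure(pairs,
            class = c("annotation_map", class(tibble::tibble())),
            propagated = isTRUE(propagated))
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d annotations | %d genes | %d terms | propagated: %s\n",
              nrow(x), dplyr::n_distinct(x$gene), dplyr::n_distinct(x$term),
              attr(x, "propagated")))
  NextMethod()
  invisible(x)
}

go_term_pattern <- "^GO:[0-9]{7}$"

#' Biological-process root term
#'
#' The BP root (`GO:0008150`) annotates essentially every gene; it is
#' excluded from all term closures during ancestor propagation so that it
#' cannot empty the eligible pool.
#' @keywords internal
GO_BP_ROOT <- "GO:0008150"

#' Read a gene-to-GO annotation file
#'
#' Reads either a simple two-column TSV (gene, GO id; `#` comment lines
#' allowed) or a GAF 2.x file. For GAF input, only rows with aspect `"P"`
#' (biological process) are kept, rows whose qualifier contains `NOT` are
#' dropped, and the gene identifier is taken from the DB Object Symbol
#' column (column 3). All evidence codes are kept by default; set
#' `exclude_iea = TRUE` to drop electronically inferred (IEA) rows.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (sniff: lines starting `!` or >= 15 tab fields
#'   mean GAF), `"tsv"`, or `"gaf"`.
#' @param exclude_iea Drop GAF rows with evidence code IEA. Ignored for TSV.
#'
#' @return An [annotation_map()]. Genes absent from the file are simply not
#'   keys; callers treat missing genes as having empty meaning.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gaf"),
                            exclude_iea = FALSE) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("annotation file is empty: ", path, call. = FALSE)
  }
  if (format == "auto") {
    body <- lines[nzchar(lines) & !startsWith(lines, "#")]
    n_fields <- lengths(strsplit(utils::head(body, 50), "\t", fixed = TRUE))
    format <- if (any(startsWith(body, "!")) || any(n_fields >= 15)) "gaf" else "tsv"
  }
  if (format == "tsv") {
    keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    n <- lengths(fields)
    if (any(n < 2)) {
      stop(sprintf("line %d: expected two tab-separated columns", keep[which(n < 2)[1]]),
           call. = FALSE)
    }
    gene <- vapply(fields, `[[`, "", 1L)
    term <- vapply(fields, `[[`, "", 2L)
    bad <- !grepl(go_term_pattern, term)
    if (any(bad)) {
      stop(sprintf("line %d: malformed GO identifier '%s'",
                   keep[which(bad)[1]], term[which(bad)[1]]), call. = FALSE)
    }
    return(annotation_map(tibble::tibble(gene = gene, term = term)))
  }
  # GAF 2.x
  keep <- which(nzchar(lines) & !startsWith(lines, "!"))
  if (length(keep) == 0) stop("annotation file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 9)) {
    stop(sprintf("line %d: GAF row has %d columns (need >= 9)",
                 keep[which(n < 9)[1]], n[which(n < 9)[1]]), call. = FALSE)
  }
  gene      <- vapply(fields, `[[`, "", 3L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term      <- vapply(fields, `[[`, "", 5L)
  evidence  <- vapply(fields, function(f) if (length(f) >= 7) f[[7]] else "", "")
  aspect    <- vapply(fields, `[[`, "", 9L)
  bad <- !grepl(go_term_pattern, term)
  if (any(bad)) {
    stop(sprintf("line %d: malformed GO identifier '%s'",
                 keep[which(bad)[1]], term[which(bad)[1]]), call. = FALSE)
  }
  sel <- aspect == "P" & !grepl("(^|\\|)NOT(\\||$)", qualifier)
  if (exclude_iea) sel <- sel & evidence != "IEA"
  annotation_map(tibble::tibble(gene = gene[sel], term = term[sel]))
}

#' Read an OBO ontology as a parent relation
#'
#' Parses `[Term]` stanzas of an OBO 1.4 file, keeping `is_a` and
#' `relationship: part_of` edges. Obsolete terms are dropped.
#'
#' @param path Path to the `.obo` file.
#' @return A tibble with columns `child` and `parent`, one row per edge.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path)
  child <- character(0); parent <- character(0)
  cur <- NA_character_; in_term <- FALSE; obsolete <- FALSE
  flushable <- function() !is.na(cur) && !obsolete
  pend_c <- character(0); pend_p <- character(0)
  flush <- function() {
    if (flushable() && length(pend_p)) {
      child  <<- c(child, rep(cur, length(pend_p)))
      parent <<- c(parent, pend_p)
    }
    pend_p <<- character(0)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- NA_character_; obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    if (startsWith(ln, "is_obsolete: true")) obsolete <- TRUE
    if (startsWith(ln, "is_a:")) {
      pend_p <- c(pend_p, trimws(strsplit(sub("^is_a:", "", ln), "!", fixed = TRUE)[[1]][1]))
    }
    if (grepl("^relationship:\\s*part_of\\s", ln)) {
      tgt <- trimws(strsplit(sub("^relationship:\\s*part_of", "", ln), "!", fixed = TRUE)[[1]][1])
      pend_p <- c(pend_p, tgt)
    }
  }
  flush()
  dplyr::distinct(tibble::tibble(child = child, parent = parent))
}

#' Propagate annotations up the ontology
#'
#' Replaces each gene's term set by its closure under the ancestor relation
#' (`is_a` / `part_of`), excluding the BP root term `GO:0008150`. This is
#' the "true-path" reading of a GO annotation; it strictly enlarges each
#' gene's meaning and therefore the removal set of the strong regime.
#'
#' @param map An [annotation_map()].
#' @param ontology A parent relation as returned by [read_obo()]: a data
#'   frame with columns `child` and `parent`. Must be acyclic.
#' @return A new `annotation_map` with `propagated = TRUE`.
#' @export
propagate_ancestors <- function(map, ontology) {
  stopifnot(inherits(map, "annotation_map"))
  ontology <- tibble::as_tibble(ontology)
  stopifnot(all(c("child", "parent") %in% names(ontology)))
  anc <- ancestor_closure(ontology)
  extra <- dplyr::inner_join(
    tibble::as_tibble(map), anc, by = c(term = "child"),
    relationship = "many-to-many"
  )
  out <- dplyr::bind_rows(
    tibble::as_tibble(map),
    tibble::tibble(gene = extra$gene, term = extra$ancestor)
  )
  out <- dplyr::filter(out, .data$term != GO_BP_ROOT)
  annotation_map(out, propagated = TRUE)
}

# Transitive closure of the parent relation: tibble(child, ancestor).
# Fixed-point iteration; errors if a cycle is present.
ancestor_closure <- function(edges) {
  closure <- tibble::tibble(child = edges$child, ancestor = edges$parent)
  n_terms <- dplyr::n_distinct(c(edges$child, edges$parent))
  for (i in seq_len(n_terms + 1L)) {
    step <- dplyr::inner_join(closure, edges,
                              by = c(ancestor = "child"),
                              relationship = "many-to-many")
    step <- tibble::tibble(child = step$child, ancestor = step$parent)
    new_closure <- dplyr::distinct(dplyr::bind_rows(closure, step))
    if (nrow(new_closure) == nrow(closure)) {
      if (any(new_closure$child == new_closure$ancestor)) {
        stop("cycle detected in ontology parent relation", call. = FALSE)
      }
      return(new_closure)
    }
    closure <- new_closure
  }
  stop("cycle detected in ontology parent relation", call. = FALSE)
}

#' Biological meaning of a gene
#'
#' The meaning of a gene is the set of GO-BP terms annotating it. An
#' unannotated gene has empty meaning (it does not error): disjointness
#' with any signature is vacuously satisfied by such genes, and they must
#' remain in the eligible pool of the removal procedure.
#'
#' @param map An [annotation_map()].
#' @param gene A single gene identifier.
#' @return A sorted character vector of GO term identifiers (possibly
#'   length 0).
#' @export
meaning_of_gene <- function(map, gene) {
  stopifnot(inherits(map, "annotation_map"), length(gene) == 1L)
  sort(unique(map$term[map$gene == gene]))
}

#' Biological meaning of a gene set
#'
#' The meaning of a set of genes is the union of the meanings of its
#' members.
#'
#' @param map An [annotation_map()].
#' @param genes Character vector of gene identifiers (a set; duplicates
#'   are irrelevant). May be empty.
#' @return Sorted character vector of GO term identifiers.
#' @export
meaning_of_set <- function(map, genes) {
  stopifnot(inherits(map, "annotation_map"))
  sort(unique(map$term[map$gene %in% genes]))
}

#' Common biological meaning of two gene sets
#'
#' The intersection of the two sets' meanings; symmetric in its arguments.
#' The falsification procedure constructs surrogate gene sets whose common
#' meaning with the signature is empty.
#'
#' @param map An [annotation_map()].
#' @param s1,s2 Character vectors of gene identifiers.
#' @return Sorted character vector of shared GO term identifiers.
#' @export
common_meaning <- function(map, s1, s2) {
  intersect(meaning_of_set(map, s1), meaning_of_set(map, s2))
}

#' Genes annotated to a term
#'
#' Transpose lookup: all genes carrying a given GO term.
#'
#' @param map An [annotation_map()].
#' @param term A single GO term identifier.
#' @return Sorted character vector of gene identifiers.
#' @export
genes_of_term <- function(map, term) {
  stopifnot(inherits(map, "annotation_map"), length(term) == 1L)
  sort(unique(map$gene[map$term == term]))
}
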