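#' Read an expression matrix
#'
#' Tab- or comma-separated text (optionally gzipped): first column gene
#' identifiers, header row of sample identifiers, numeric values
#' (log-scale expression).
#'
#' @param path File path.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return A numeric matrix, genes x samples.
#' @export
read_expression <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_expression_matrix(as.data.frame(df))
}

#' Read a clinical survival table
#'
#' Header required; column names configurable for tables using different
#' labels.
#'
#' @param path File path (TSV or CSV, optionally gzipped).
#' @param sample_col,time_col,event_col Column names to use.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return A validated tibble with columns `sample`, `time`, `event`.
#' @export
read_clinical <- function(path, sample_col = "sample", time_col = "time",
                          event_col = "event", delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c(sample_col, time_col, event_col)
  if (!all(need %in% names(df))) {
    stop("clinical table lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  survival_records(tibble::tibble(sample = df[[sample_col]],
                                  time = df[[time_col]],
                                  event = df[[event_col]]))
}

#' Read gene signatures from a GMT file
#'
#' GMT: one signature per line, tab-separated fields `name`,
#' `description`, then the member genes.
#'
#' @param path File path.
#' @return A tibble with columns `name`, `description` and a list-column
#'   `genes`; use [get_signature()] to extract one as a [signature()].
#' @export
read_signatures_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file is empty: ", path, call. = FALSE)
  rows <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("line %d: GMT row needs name, description and >= 1 gene", i),
           call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      stop(sprintf("line %d: signature '%s' lists duplicate genes", i, f[1]),
           call. = FALSE)
    }
    tibble::tibble(name = f[1], description = f[2], genes = list(genes))
  })
  dplyr::bind_rows(rows)
}

#' Extract one signature from a GMT tibble
#'
#' @param gmt A tibble from [read_signatures_gmt()].
#' @param name Signature name; defaults to the first entry.
#' @return A [signature()].
#' @export
get_signature <- function(gmt, name = NULL) {
  if (is.null(name)) name <- gmt$name[1]
  i <- match(name, gmt$name)
  if (is.na(i)) stop("no signature named '", name, "' in GMT", call. = FALSE)
  signature(gmt$genes[[i]], name = name)
}

#' Read a plain gene list
#'
#' One gene per line; `#` comment lines and blank lines skipped. Used for
#' proliferation gene lists.
#'
#' @param path File path.
#' @return Character vector of gene identifiers (possibly empty).
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readr::read_lines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

config_keys <- c("expr", "clinical", "signature", "annotation", "ontology",
                 "pg", "out", "B", "alpha", "mode", "split", "seed",
                 "propagate")

#' Load a run configuration
#'
#' Reads a flat `key = value` file or a JSON object, applies overrides
#' (command-line flags take precedence over file values), and validates.
#' Defaults: `B = 1000`, `alpha = 0.05`, `mode = "strong"`,
#' `split = "median"`.
#'
#' @param path Config file path, or `NULL` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A list with the file-path entries plus a `config` element
#'   holding the [falsification_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    txt <- readr::read_lines(path)
    if (any(grepl("^\\s*\\{", txt))) {
      vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                 simplifyVector = TRUE)
    } else {
      kv <- txt[nzchar(trimws(txt)) & !startsWith(trimws(txt), "#")]
      for (ln in kv) {
        parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(parts) < 2) {
          stop("malformed config line (expected key = value): ", ln, call. = FALSE)
        }
        vals[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
      }
    }
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(config_keys, collapse = ", "), call. = FALSE)
  }
  num <- function(key, default) {
    v <- vals[[key]]
    if (is.null(v)) return(default)
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop("config field '", key, "' is not numeric: ", v,
                         call. = FALSE)
    out
  }
  cfg <- falsification_config(
    B = num("B", 1000L),
    alpha = num("alpha", 0.05),
    mode = if (is.null(vals$mode)) "strong" else as.character(vals$mode),
    split = if (is.null(vals$split)) "median" else as.character(vals$split),
    seed = if (is.null(vals$seed)) NULL else num("seed", NULL),
    propagate = isTRUE(as.logical(vals$propagate))
  )
  paths <- vals[intersect(names(vals),
                          c("expr", "clinical", "signature", "annotation",
                            "ontology", "pg", "out"))]
  for (k in setdiff(names(paths), "out")) {
    if (!file.exists(paths[[k]])) {
      stop("config field '", k, "' points to a missing file: ", paths[[k]],
           call. = FALSE)
    }
  }
  c(paths, list(config = cfg))
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a falsification report as JSON
#'
#' A versioned JSON document holding the full report: config echo, removal
#' provenance (the whole chain |G|, |PG|, |G*|, t, |D|, |G'|), the raw and
#' Bonferroni-adjusted surrogate p-values and the surrogate gene sets.
#' Optionally also writes a flat TSV of the surrogate p-values for
#' plotting.
#'
#' @param report A `falsification_report`.
#' @param path Output JSON path.
#' @param tsv_path Optional path for the surrogate p-value TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, tsv_path = NULL) {
  stopifnot(inherits(report, "falsification_report"))
  cfg <- report$config
  doc <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    config = list(B = cfg$B, alpha = cfg$alpha, mode = cfg$mode,
                  split = cfg$split, seed = cfg$seed,
                  propagate = cfg$propagate),
    signature = list(name = report$signature_name,
                     genes = report$signature_genes,
                     p = report$signature_p,
                     p_adj = report$signature_p_adj),
    removal = list(mode = report$removal$mode,
                   g_star = report$removal$g_star,
                   removal_terms = report$removal$removal_terms,
                   removed_genes = report$removal$removed_genes,
                   eligible = report$removal$eligible,
                   provenance = as.list(report$removal$provenance)),
    surrogate = list(p = report$surrogate$p,
                     statistic = report$surrogate$statistic,
                     p_adj = report$surrogate$p_adj,
                     significant = report$surrogate$significant,
                     genes = report$surrogate$genes),
    n_significant = report$n_significant,
    fraction_significant = report$fraction_significant,
    n_below_signature_p = report$n_below_signature_p,
    skipped = report$skipped
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(tsv_path)) {
    readr::write_tsv(report$surrogate[, c("draw", "p", "p_adj", "significant")],
                     tsv_path)
  }
  invisible(path)
}

#' Read a falsification report back from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return A `falsification_report` equal to the one written.
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) {
    stop("not a falsification report (no schema_version): ", path, call. = FALSE)
  }
  chr <- function(x) vapply(x, as.character, "")
  cfg <- falsification_config(
    B = doc$config$B, alpha = doc$config$alpha, mode = doc$config$mode,
    split = doc$config$split, seed = doc$config$seed,
    propagate = doc$config$propagate
  )
  bm <- signature(chr(doc$signature$genes), name = doc$signature$name)
  removal <- structure(list(
    mode = doc$removal$mode,
    g_star = chr(doc$removal$g_star),
    removal_terms = chr(doc$removal$removal_terms),
    removed_genes = chr(doc$removal$removed_genes),
    eligible = chr(doc$removal$eligible),
    signature = bm,
    provenance = vapply(doc$removal$provenance, as.integer, 1L)
  ), class = "removal_result")
  n_draws <- length(doc$surrogate$p)
  surrogate <- tibble::tibble(
    draw = seq_len(n_draws),
    p = vapply(doc$surrogate$p, as.numeric, 1),
    statistic = vapply(doc$surrogate$statistic, as.numeric, 1),
    genes = lapply(doc$surrogate$genes, chr),
    p_adj = vapply(doc$surrogate$p_adj, as.numeric, 1),
    significant = vapply(doc$surrogate$significant, isTRUE, TRUE)
  )
  structure(list(
    signature_name = doc$signature$name,
    signature_genes = chr(doc$signature$genes),
    signature_p = as.numeric(doc$signature$p),
    signature_p_adj = as.numeric(doc$signature$p_adj),
    surrogate = surrogate,
    n_significant = as.integer(doc$n_significant),
    fraction_significant = as.numeric(doc$fraction_significant),
    n_below_signature_p = as.integer(doc$n_below_signature_p),
    skipped = as.integer(doc$skipped),
    removal = removal,
    config = cfg
  ), class = "falsification_report")
}
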