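#' Configuration for a falsification run
#'
#' @param B Number of surrogate gene sets to draw (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param mode Removal regime, see [eligible_pool()].
#' @param split Stratification split rule, see [pc1_stratify()].
#' @param seed Integer RNG seed (or `NULL` to use the current RNG state).
#' @param propagate Whether annotation maps should be ancestor-propagated
#'   before use (acted on by the command-line driver; library callers
#'   propagate explicitly with [propagate_ancestors()]).
#' @return A list of class `falsification_config`.
#' @export
falsification_config <- function(B = 1000L, alpha = 0.05,
                                 mode = c("strong", "weak_ii", "weak_i"),
                                 split = c("median", "sign"),
                                 seed = NULL, propagate = FALSE) {
  mode <- match.arg(mode)
  split <- match.arg(split)
  B <- as.integer(B)
  if (is.na(B) || B < 1) stop("B must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(B = B, alpha = alpha, mode = mode, split = split,
                 seed = seed, propagate = isTRUE(propagate)),
            class = "falsification_config")
}

#' Prognostic task for one gene set
#'
#' Joins expression and clinical samples, stratifies the cohort by PC1 of
#' the gene set, and compares the two strata with the log-rank test. This
#' is the task each surrogate set must solve as well as the signature for
#' the signature's biological meaning to be called into question.
#'
#' @param expr Expression matrix (see [as_expression_matrix()]).
#' @param clinical Survival records (see [survival_records()]).
#' @param genes Gene set to evaluate.
#' @param split Split rule for [pc1_stratify()].
#' @return A list: `p_value`, `statistic`, `n_samples`, `degenerate`
#'   (logical), `reason` (NA or the degeneracy message). A degenerate
#'   stratification is reported as a tagged skip, not a p-value.
#' @export
run_prognostic_task <- function(expr, clinical, genes,
                                split = c("median", "sign")) {
  split <- match.arg(split)
  expr <- as_expression_matrix(expr)
  clinical <- survival_records(clinical)
  shared <- intersect(colnames(expr), clinical$sample)
  if (length(shared) == 0) {
    stop("expression and clinical tables share no samples", call. = FALSE)
  }
  if (length(shared) < 4) {
    stop("fewer than 4 samples shared between expression and clinical data",
         call. = FALSE)
  }
  expr <- expr[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample), ]
  strat <- tryCatch(
    suppressWarnings(pc1_stratify(expr, genes, split = split)),
    sigfalsify_degenerate = function(c) c
  )
  if (inherits(strat, "sigfalsify_degenerate")) {
    return(list(p_value = NA_real_, statistic = NA_real_,
                n_samples = length(shared), degenerate = TRUE,
                reason = conditionMessage(strat)))
  }
  lr <- logrank_test(clinical[strat$group == "LOW", ],
                     clinical[strat$group == "HIGH", ])
  list(p_value = lr$p_value, statistic = lr$statistic,
       n_samples = length(shared), degenerate = FALSE, reason = NA_character_)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests `B` and caps at 1; the
#' most conservative family-wise error correction. `B` may exceed the
#' number of p-values supplied (e.g. when correcting a single signature
#' p-value against the surrogate family size).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param B Number of tests; defaults to `length(p)`.
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni <- function(p, B = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, B * p)
}

#' Run the full falsification procedure
#'
#' Executes the gene removal procedure for the configured regime, draws
#' `B` surrogate gene sets of the signature's size from the eligible pool,
#' performs the prognostic task (PC1 stratification + log-rank) for the
#' signature and for every surrogate, applies the Bonferroni correction to
#' the surrogate p-values, and reports how many surrogates remain
#' significant at level `alpha`. If no surrogate matches the signature's
#' prognostic performance, the signature may carry biological meaning
#' worth discussing; if many do, its apparent biology is not supported.
#'
#' Degenerate draws (for example a zero-variance submatrix) are re-drawn
#' from the same RNG stream and counted in `skipped`; a retry cap of
#' `10 * B` total draws guards against pathological inputs. Under the
#' strong regime, disjointness of every emitted surrogate's meaning with
#' the signature's is asserted at run time.
#'
#' @param expr Expression matrix.
#' @param clinical Survival records.
#' @param map An [annotation_map()].
#' @param bm A [signature()] or character vector of signature genes.
#' @param config A [falsification_config()].
#' @param pool Gene pool G; defaults to the rownames of `expr`.
#' @param pg Proliferation gene list (may be empty; a note is emitted).
#' @return A list of class `falsification_report`; see
#'   [tidy.falsification_report()] and [glance.falsification_report()].
#' @export
falsification_run <- function(expr, clinical, map, bm,
                              config = falsification_config(),
                              pool = NULL, pg = character(0)) {
  stopifnot(inherits(config, "falsification_config"))
  expr <- as_expression_matrix(expr)
  clinical <- survival_records(clinical)
  bm <- as_signature(bm)
  if (is.null(pool)) pool <- rownames(expr)

  missing_bm <- setdiff(bm$genes, rownames(expr))
  if (length(missing_bm) > 0) {
    warning(sprintf("%d signature gene(s) absent from expression matrix; dropped",
                    length(missing_bm)), call. = FALSE)
    bm <- signature(setdiff(bm$genes, missing_bm), name = bm$name)
  }

  removal <- eligible_pool(pool, pg = pg, map = map, bm = bm,
                           mode = config$mode)
  m <- length(bm$genes)

  body <- function() {
    sig_task <- run_prognostic_task(expr, clinical, bm$genes,
                                    split = config$split)
    if (sig_task$degenerate) {
      stop("signature stratification is degenerate: ", sig_task$reason,
           call. = FALSE)
    }
    draws <- vector("list", config$B)
    skipped <- 0L
    skip_reasons <- character(0)
    i <- 0L; attempts <- 0L; cap <- 10L * config$B
    while (i < config$B) {
      if (attempts >= cap) {
        stop(sprintf("retry cap (%d draws) exceeded with %d valid surrogates; skip reasons: %s",
                     cap, i, paste(unique(skip_reasons), collapse = "; ")),
             call. = FALSE)
      }
      attempts <- attempts + 1L
      rgs <- random_gene_set(removal$eligible, m)
      if (config$mode == "strong" &&
          length(common_meaning(map, rgs, bm$genes)) != 0) {
        stop("internal error: surrogate set shares GO terms with the signature",
             call. = FALSE)
      }
      task <- run_prognostic_task(expr, clinical, rgs, split = config$split)
      if (task$degenerate) {
        skipped <- skipped + 1L
        skip_reasons <- c(skip_reasons, task$reason)
        next
      }
      i <- i + 1L
      draws[[i]] <- tibble::tibble(draw = i, p = task$p_value,
                                   statistic = task$statistic,
                                   genes = list(rgs))
    }
    list(sig_task = sig_task, draws = dplyr::bind_rows(draws),
         skipped = skipped)
  }
  res <- if (!is.null(config$seed)) withr::with_seed(config$seed, body()) else body()

  surrogate <- res$draws
  surrogate$p_adj <- bonferroni(surrogate$p, config$B)
  surrogate$significant <- surrogate$p_adj < config$alpha
  n_sig <- sum(surrogate$significant)

  structure(list(
    signature_name = bm$name,
    signature_genes = bm$genes,
    signature_p = res$sig_task$p_value,
    signature_p_adj = bonferroni(res$sig_task$p_value, config$B),
    surrogate = surrogate,
    n_significant = n_sig,
    fraction_significant = n_sig / config$B,
    n_below_signature_p = sum(surrogate$p <= res$sig_task$p_value),
    skipped = res$skipped,
    removal = removal,
    config = config
  ), class = "falsification_report")
}

#' @export
print.falsification_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<falsification_report> signature: %s (%d genes) | mode: %s | B = %d\n",
              x$signature_name, length(x$signature_genes), cfg$mode, cfg$B))
  cat(sprintf("  signature log-rank p = %.3g (Bonferroni vs B: %.3g)\n",
              x$signature_p, x$signature_p_adj))
  cat(sprintf("  surrogates significant at alpha = %g after Bonferroni: %d / %d (%.1f%%)\n",
              cfg$alpha, x$n_significant, cfg$B, 100 * x$fraction_significant))
  cat(sprintf("  surrogates with raw p <= signature p: %d | degenerate draws skipped: %d\n",
              x$n_below_signature_p, x$skipped))
  invisible(x)
}

#' Tidy a falsification report
#'
#' @param x A `falsification_report`.
#' @param ... Unused.
#' @return One row per surrogate draw: `draw`, `p`, `statistic`, `p_adj`,
#'   `significant`, `genes` (list-column).
#' @export
tidy.falsification_report <- function(x, ...) {
  x$surrogate
}

#' One-row summary of a falsification report
#'
#' @param x A `falsification_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.falsification_report <- function(x, ...) {
  tibble::tibble(
    signature = x$signature_name,
    mode = x$config$mode,
    B = x$config$B,
    alpha = x$config$alpha,
    signature_p = x$signature_p,
    signature_p_adj = x$signature_p_adj,
    n_significant = x$n_significant,
    fraction_significant = x$fraction_significant,
    n_below_signature_p = x$n_below_signature_p,
    skipped = x$skipped,
    n_eligible = unname(x$removal$provenance[["n_eligible"]])
  )
}

#' Plot the surrogate p-value distribution
#'
#' Histogram of the raw surrogate log-rank p-values on the -log10 scale,
#' with the signature's p-value and the Bonferroni threshold
#' `alpha / B` marked.
#'
#' @param object A `falsification_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.falsification_report <- function(object, ...) {
  df <- tibble::tibble(nlp = -log10(pmax(object$surrogate$p, 1e-300)))
  thr <- -log10(object$config$alpha / object$config$B)
  sig <- -log10(max(object$signature_p, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nlp)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = sig, colour = "red") +
    ggplot2::labs(
      x = expression(-log[10](p)),
      y = "surrogate gene sets",
      title = sprintf("%s: %d/%d surrogates significant after Bonferroni",
                      object$signature_name, object$n_significant,
                      object$config$B),
      subtitle = "dashed: Bonferroni threshold; red: signature p-value"
    ) +
    ggplot2::theme_minimal()
}
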