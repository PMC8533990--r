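#' Specification for a synthetic study
#'
#' Describes a fully synthetic cohort — expression, censored survival, a
#' designated signature, GO-BP annotation and a proliferation list — with
#' controllable prognostic structure. Three signal regimes are available:
#' \describe{
#'   \item{`"none"`}{survival is independent of expression (null);}
#'   \item{`"signature_only"`}{the hazard is driven by the standardized
#'     mean z-expression of the signature genes, which share a latent
#'     factor and carry dedicated GO terms held by no other gene — so the
#'     strong removal regime removes exactly the signature and surrogate
#'     sets are pure noise;}
#'   \item{`"latent_global"`}{one latent factor loads (with per-gene
#'     loadings) on a large fraction of genes including and beyond the
#'     signature and drives the hazard — the regime in which surrogate
#'     sets remain prognostic.}
#' }
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param n_terms Number of GO terms in the synthetic annotation.
#' @param terms_per_gene Poisson rate for the per-gene term count (the
#'   count is the rate-`terms_per_gene` Poisson truncated to >= 1).
#' @param frac_unannotated Fraction of genes with empty meaning.
#' @param signature_size Number of genes in the designated signature.
#' @param signal Signal regime, see Details.
#' @param effect Log-hazard scale of the prognostic factor (per standard
#'   deviation of the driver).
#' @param frac_affected For `"latent_global"`: fraction of genes loaded by
#'   the latent factor.
#' @param censor_rate Target fraction of right-censored samples.
#' @param baseline_hazard Exponential event rate (per study time unit).
#' @param n_proliferation Size of the synthetic proliferation gene list
#'   (drawn from non-signature genes; carries no survival signal).
#' @param seed Integer RNG seed, or `NULL`.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 1000L, n_samples = 200L, n_terms = 50L,
                       terms_per_gene = 2, frac_unannotated = 0.2,
                       signature_size = 20L,
                       signal = c("none", "signature_only", "latent_global"),
                       effect = 1.0, frac_affected = 0.5,
                       censor_rate = 0.3, baseline_hazard = 0.05,
                       n_proliferation = 10L, seed = NULL) {
  signal <- match.arg(signal)
  stopifnot(n_genes >= 1, n_samples >= 4, n_terms >= 1,
            terms_per_gene >= 0, frac_unannotated >= 0, frac_unannotated <= 1,
            signature_size >= 2, signature_size <= n_genes,
            effect >= 0, frac_affected >= 0, frac_affected <= 1,
            censor_rate >= 0, censor_rate < 1, baseline_hazard > 0,
            n_proliferation >= 0)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_terms = as.integer(n_terms), terms_per_gene = terms_per_gene,
    frac_unannotated = frac_unannotated,
    signature_size = as.integer(signature_size), signal = signal,
    effect = effect, frac_affected = frac_affected,
    censor_rate = censor_rate, baseline_hazard = baseline_hazard,
    n_proliferation = as.integer(n_proliferation), seed = seed
  ), class = "synth_spec")
}

synth_gene_ids <- function(n) sprintf("g%05d", seq_len(n))
synth_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

with_spec_seed <- function(spec, offset, code) {
  if (is.null(spec$seed)) return(code)
  withr::with_seed((spec$seed + offset) %% .Machine$integer.max, code)
}

# Poisson(rate) truncated to >= 1, capped at `cap`.
rtpois <- function(n, rate, cap) {
  p0 <- stats::ppois(0, rate)
  k <- stats::qpois(p0 + stats::runif(n) * (1 - p0), rate)
  pmin(pmax(k, 1L), cap)
}

#' Generate a synthetic GO-BP annotation map
#'
#' Each annotated gene draws a truncated-Poisson number of distinct terms
#' uniformly from the term pool; a `frac_unannotated` fraction of genes
#' gets an empty term set. Under the `"signature_only"` regime the
#' signature genes draw only from a small reserved block of terms that no
#' other gene may use, so the signature's removal set is exactly the
#' signature itself.
#'
#' @param spec A [synth_spec()].
#' @return An [annotation_map()].
#' @export
make_annotation <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- synth_gene_ids(spec$n_genes)
  terms <- synth_term_ids(spec$n_terms)
  sig_genes <- genes[seq_len(spec$signature_size)]
  with_spec_seed(spec, 1L, {
    private <- character(0)
    public <- terms
    if (spec$signal == "signature_only") {
      n_private <- min(max(2L, ceiling(spec$terms_per_gene)), spec$n_terms - 1L)
      private <- terms[seq_len(n_private)]
      public <- setdiff(terms, private)
    }
    unannotated <- sample(setdiff(genes, sig_genes),
                          size = min(round(spec$frac_unannotated * spec$n_genes),
                                     spec$n_genes - spec$signature_size))
    pairs <- purrr::map_dfr(genes, function(g) {
      if (g %in% unannotated) return(NULL)
      from <- if (spec$signal == "signature_only" && g %in% sig_genes) private else public
      k <- rtpois(1, spec$terms_per_gene, length(from))
      tibble::tibble(gene = g, term = sample(from, k))
    })
    annotation_map(pairs)
  })
}

#' Generate a synthetic cohort
#'
#' Expression is standard normal noise, with prognostic structure added
#' according to the spec's signal regime; survival times are exponential
#' with a proportional-hazards log-linear effect, and independent
#' exponential censoring whose rate is tuned (numerically, against the
#' realized per-sample hazards) so the expected censored fraction equals
#' `censor_rate`.
#'
#' @param spec A [synth_spec()].
#' @return A list with `expr` (genes x samples matrix), `clinical`
#'   (tibble: sample, time, event), `signature` (a [signature()]), and
#'   `truth` (the per-sample hazard driver, `NULL` under `"none"`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- synth_gene_ids(spec$n_genes)
  samples <- sprintf("s%04d", seq_len(spec$n_samples))
  sig_genes <- genes[seq_len(spec$signature_size)]
  with_spec_seed(spec, 2L, {
    expr <- matrix(stats::rnorm(spec$n_genes * spec$n_samples),
                   nrow = spec$n_genes, dimnames = list(genes, samples))
    driver <- NULL
    if (spec$signal == "signature_only") {
      u <- stats::rnorm(spec$n_samples)
      expr[sig_genes, ] <- expr[sig_genes, ] + rep(u, each = length(sig_genes))
      z <- t(scale(t(expr[sig_genes, , drop = FALSE])))
      driver <- as.numeric(scale(colMeans(z)))
    } else if (spec$signal == "latent_global") {
      u <- stats::rnorm(spec$n_samples)
      n_affected <- max(spec$signature_size,
                        round(spec$frac_affected * spec$n_genes))
      affected <- c(sig_genes,
                    sample(setdiff(genes, sig_genes),
                           n_affected - spec$signature_size))
      loadings <- stats::runif(length(affected), 0.5, 1.5)
      expr[affected, ] <- expr[affected, ] + loadings %o% u
      driver <- u
    }
    rate <- if (is.null(driver)) {
      rep(spec$baseline_hazard, spec$n_samples)
    } else {
      spec$baseline_hazard * exp(spec$effect * driver)
    }
    t_event <- stats::rexp(spec$n_samples, rate)
    if (spec$censor_rate > 0) {
      cr <- censoring_rate_for(rate, spec$censor_rate)
      t_cens <- stats::rexp(spec$n_samples, cr)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, spec$n_samples)
    }
    list(
      expr = expr,
      clinical = tibble::tibble(sample = samples, time = time, event = event),
      signature = signature(sig_genes, name = "SYNTH_SIG"),
      truth = driver
    )
  })
}

# Censoring rate mu with E[fraction censored] = mean_i mu/(rate_i + mu) = target.
censoring_rate_for <- function(rates, target) {
  f <- function(log_mu) mean(exp(log_mu) / (rates + exp(log_mu))) - target
  lo <- log(min(rates)) - 20; hi <- log(max(rates)) + 20
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing every input the falsification pipeline
#' needs: cohort, annotation, and a proliferation gene list (drawn from
#' non-signature genes, carrying no survival signal).
#'
#' @param spec A [synth_spec()].
#' @return A list: `expr`, `clinical`, `signature`, `map`, `pg`, `truth`,
#'   `spec`.
#' @export
make_synthetic_study <- function(spec) {
  cohort <- make_cohort(spec)
  map <- make_annotation(spec)
  pg <- with_spec_seed(spec, 3L, {
    candidates <- setdiff(rownames(cohort$expr), cohort$signature$genes)
    sample(candidates, min(spec$n_proliferation, length(candidates)))
  })
  c(cohort, list(map = map, pg = pg, spec = spec))
}

#' Write synthetic fixtures to disk
#'
#' Writes the study as plain-text files in the dialects the package's
#' readers accept: `expression.tsv` (gene column + one column per
#' sample), `clinical.tsv` (sample, time, event), `signature.gmt`,
#' `annotation.tsv` (gene, GO id) and `proliferation.txt` (one gene per
#' line).
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_synth_fixtures <- function(spec, dir) {
  study <- make_synthetic_study(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    signature = file.path(dir, "signature.gmt"),
    annotation = file.path(dir, "annotation.tsv"),
    proliferation = file.path(dir, "proliferation.txt")
  )
  expr_df <- tibble::as_tibble(study$expr, rownames = "gene")
  readr::write_tsv(expr_df, paths[["expression"]])
  readr::write_tsv(study$clinical, paths[["clinical"]])
  writeLines(paste(c(study$signature$name, "synthetic signature",
                     study$signature$genes), collapse = "\t"),
             paths[["signature"]])
  readr::write_tsv(tibble::as_tibble(study$map), paths[["annotation"]],
                   col_names = FALSE)
  writeLines(study$pg, paths[["proliferation"]])
  invisible(paths)
}
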