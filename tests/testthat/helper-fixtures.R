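# Shared fixture builders and brute-force oracles.

# Random toy annotation: each of n_genes genes independently annotated to
# each of n_terms terms with probability p. Returns the map plus the raw
# pair table for brute-force checks.
rand_annotation <- function(n_genes, n_terms, p = 0.1) {
  genes <- sprintf("tg%03d", seq_len(n_genes))
  terms <- sprintf("tt%03d", seq_len(n_terms))
  hit <- matrix(stats::runif(n_genes * n_terms) < p, n_genes, n_terms)
  idx <- which(hit, arr.ind = TRUE)
  pairs <- tibble::tibble(gene = genes[idx[, 1]], term = terms[idx[, 2]])
  list(map = annotation_map(pairs), pairs = pairs,
       genes = genes, terms = terms)
}

# Brute-force meaning of a gene set: scan the raw pair table.
bf_meaning <- function(pairs, genes) {
  sort(unique(pairs$term[pairs$gene %in% genes]))
}

# Brute-force removal set D: every gene sharing >= 1 term with the set.
bf_removal_genes <- function(pairs, bm_genes) {
  terms <- bf_meaning(pairs, bm_genes)
  sort(unique(pairs$gene[pairs$term %in% terms]))
}

# Simple exponential cohort for survival tests.
rand_survival <- function(n, rate = 0.1, censor = 0.3, prefix = "p") {
  t_ev <- stats::rexp(n, rate)
  t_cn <- stats::rexp(n, rate * censor / (1 - censor))
  tibble::tibble(sample = sprintf("%s%04d", prefix, seq_len(n)),
                 time = pmin(t_ev, t_cn),
                 event = as.integer(t_ev <= t_cn))
}

# survival::survdiff oracle for the two-group log-rank test.
oracle_logrank <- function(a, b) {
  df <- rbind(cbind(a, grp = "a"), cbind(b, grp = "b"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

three_gene_map <- function() {
  annotation_map(tibble::tibble(gene = c("gA", "gB", "gC"),
                                term = c("T1", "T1", "T2")))
}
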