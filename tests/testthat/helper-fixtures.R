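# Builders and an independent QC oracle used across the tests.

# Counts tibble from a plain matrix (probes x samples).
make_counts <- function(m, probes = rownames(m), samples = colnames(m)) {
  if (is.null(probes)) probes <- paste0("P", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  colnames(out) <- samples
  dplyr::bind_cols(tibble::tibble(probe_id = probes), out)
}

# A small panel: n_pos + n_neg controls and a block of genes, counts supplied
# column-wise or drawn Poisson around `gene_mean`.
make_panel_counts <- function(n_genes = 10, n_samples = 4, n_pos = 4, n_neg = 4,
                              gene_mean = 100, seed = 1) {
  set.seed(seed)
  probes <- c(paste0("POS", seq_len(n_pos)), paste0("ANT", seq_len(n_neg)),
              paste0("GENE", seq_len(n_genes)))
  m <- matrix(rpois((n_pos + n_neg + n_genes) * n_samples, gene_mean),
              nrow = n_pos + n_neg + n_genes,
              dimnames = list(probes, paste0("S", seq_len(n_samples))))
  make_counts(m)
}

# A sample column with exact control percentages: pos_pct/neg_pct percent of a
# `lib`-read library in the controls (split evenly), the rest in the genes.
exact_pct_column <- function(pos_pct, neg_pct, lib = 10000, n_pos = 4,
                             n_neg = 4, n_genes = 8) {
  pos_total <- round(pos_pct / 100 * lib)
  neg_total <- round(neg_pct / 100 * lib)
  stopifnot(abs(pos_total - pos_pct / 100 * lib) < 1e-6,
            abs(neg_total - neg_pct / 100 * lib) < 1e-6)
  gene_total <- lib - pos_total - neg_total
  c(rep(pos_total / n_pos, n_pos), rep(neg_total / n_neg, n_neg),
    rep(gene_total / n_genes, n_genes))
}

# Independent recomputation of the whole QC from first principles: explicit
# loops and textbook formulas only, no calls into the package's QC path.
oracle_qc <- function(counts, pos_ids, neg_ids,
                      pos_fail = 40, pos_alert = 10, neg_fail = 10, k = 2) {
  probes <- counts[[1]]
  samples <- colnames(counts)[-1]
  n <- length(samples)
  lib <- pos <- neg <- neg_mean <- numeric(n)
  for (s in seq_len(n)) {
    col <- counts[[s + 1]]
    lib[s] <- sum(col)
    pos[s] <- 100 * sum(col[probes %in% pos_ids]) / lib[s]
    neg[s] <- 100 * sum(col[probes %in% neg_ids]) / lib[s]
    cpm_neg <- col[probes %in% neg_ids] / lib[s] * 1e6
    neg_mean[s] <- sum(cpm_neg) / length(cpm_neg)
  }
  delta <- neg_mean - sum(neg_mean) / n
  delta_sd <- if (n >= 2) sqrt(sum((delta - sum(delta) / n)^2) / (n - 1)) else 0
  apply_dev <- n >= 3
  pos_flag <- neg_flag <- overall <- character(n)
  for (s in seq_len(n)) {
    pos_flag[s] <- if (pos[s] > pos_fail) "FAIL"
                   else if (pos[s] > pos_alert) "ALERT" else "PASS"
    neg_flag[s] <- if (neg[s] > neg_fail) "FAIL"
                   else if (apply_dev && abs(delta[s]) > k * delta_sd) "ALERT"
                   else "PASS"
    overall[s] <- if (pos_flag[s] == "FAIL" || neg_flag[s] == "FAIL") "FAIL"
                  else if (pos_flag[s] == "ALERT" || neg_flag[s] == "ALERT") "ALERT"
                  else "PASS"
  }
  list(sample_id = samples, library_size = lib, pos_pct = pos, neg_pct = neg,
       neg_mean_cpm = neg_mean, delta = delta, delta_sd = delta_sd,
       pos_flag = pos_flag, neg_flag = neg_flag, overall_flag = overall)
}

# Path to the installed CLI script.
cli_script <- function() {
  file.path(find.package("panelqc"), "exec", "panelqc")
}

# Run the CLI in a fresh Rscript process; returns list(status, stdout lines).
run_cli <- function(args) {
  out <- tempfile()
  status <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2("Rscript", c(cli_script(), args), stdout = out, stderr = out))
  list(status = status, output = readLines(out, warn = FALSE))
}
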