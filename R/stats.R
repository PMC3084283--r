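# Library statistics: Shannon diversity, read-count vs qPCR correlation,
# and the efficiency-corrected expression-ratio randomization test used for
# RNAi knockdown validation.

#' Shannon diversity of read counts
#'
#' `H' = -sum p_i log(p_i)` over categories with positive counts, with
#' `p_i = count_i / total`. Natural logarithm by default (the classical
#' convention); the base is a parameter.
#'
#' @param counts non-negative counts.
#' @param base logarithm base.
#' @return a `diversity_result`: `H_prime`, `S` (number of positive
#'   categories), `p_i`.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) fail("shannon_index needs at least one positive count")
  p <- counts / sum(counts)
  structure(list(H_prime = -sum(p * log(p, base = base)),
                 S = length(p), p_i = p),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Shannon H' = %.4f over %d categories (max %.4f)\n",
              x$H_prime, x$S, log(x$S)))
  invisible(x)
}

#' Correlate sequencing read counts with qPCR abundances
#'
#' Pearson correlation on the pairs whose read count reaches `min_reads`
#' (default 101: the "more than 100 reads" rule is strict), with two-sided
#' significance from `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param pairs data frame with columns `reads` and `qpcr` (e.g. copies per
#'   1000 copies of U6); an optional `gene` column is carried through.
#' @param min_reads inclusive read-count filter.
#' @return list `R`, `p`, `t`, `n_used`.
#' @export
correlate_reads_qpcr <- function(pairs, min_reads = 101) {
  keep <- pairs$reads >= min_reads
  x <- pairs$reads[keep]; y <- pairs$qpcr[keep]
  n <- length(x)
  if (n < 3) fail("fewer than 3 pairs after the read filter (%d)", n)
  if (var(x) == 0 || var(y) == 0) fail("zero variance in reads or qPCR values")
  R <- cor(x, y)
  t <- R * sqrt((n - 2) / max(1 - R^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t), df = n - 2)
  list(R = R, p = p, t = t, n_used = n)
}

#' Efficiency-corrected expression ratio with randomization test
#'
#' The relative expression of a target gene against a reference gene,
#' treated vs control, with per-gene amplification efficiencies:
#' `ratio = E_t^(mean Ct_t,control - mean Ct_t,treated) /
#'          E_r^(mean Ct_r,control - mean Ct_r,treated)`.
#' Significance comes from a pair-wise fixed-reallocation randomization
#' test: target and reference Cts stay paired within each sample while the
#' group labels are permuted (exhaustively when the number of label
#' reallocations does not exceed `n_randomizations`, otherwise sampled with
#' the given seed); the two-sided p-value is the fraction of reallocations
#' with `|log ratio|` at least the observed one.
#'
#' @param target,reference lists with numeric `control` and `treated` Ct
#'   vectors; target and reference replicates are paired by position.
#' @param E_target,E_reference amplification efficiencies in (1, 2].
#' @param n_randomizations maximum reallocations.
#' @param seed RNG seed for sampled reallocations.
#' @return an `expression_test`: `ratio`, `p_value`, `n_randomizations`,
#'   `exhaustive`, `seed`.
#' @export
rest_ratio_test <- function(target, reference, E_target = 2, E_reference = 2,
                            n_randomizations = 10000, seed = 1) {
  for (E in c(E_target, E_reference))
    if (E <= 1 || E > 2) fail("amplification efficiency must be in (1, 2]")
  tc <- target$control; tt <- target$treated
  rc <- reference$control; rt <- reference$treated
  if (length(tc) != length(rc) || length(tt) != length(rt))
    fail("target and reference replicates must pair within samples")
  if (length(tc) < 2 || length(tt) < 2) fail("need >= 2 replicates per group")
  n1 <- length(tc); n <- n1 + length(tt)
  t_all <- c(tc, tt); r_all <- c(rc, rt)
  log_ratio <- function(ctrl_idx) {
    trt_idx <- setdiff(seq_len(n), ctrl_idx)
    log(E_target) * (mean(t_all[ctrl_idx]) - mean(t_all[trt_idx])) -
      log(E_reference) * (mean(r_all[ctrl_idx]) - mean(r_all[trt_idx]))
  }
  obs <- log_ratio(seq_len(n1))
  n_total <- choose(n, n1)
  exhaustive <- n_total <= n_randomizations
  sel <- if (exhaustive) combn(n, n1) else
    with_seed(seed, replicate(n_randomizations, sample.int(n, n1)))
  K <- ncol(sel)
  ind <- matrix(0, K, n)
  ind[cbind(rep(seq_len(K), each = n1), as.vector(sel))] <- 1
  mc_t <- (ind %*% t_all) / n1; mt_t <- ((1 - ind) %*% t_all) / (n - n1)
  mc_r <- (ind %*% r_all) / n1; mt_r <- ((1 - ind) %*% r_all) / (n - n1)
  lr <- log(E_target) * (mc_t - mt_t) - log(E_reference) * (mc_r - mt_r)
  p <- mean(abs(lr) >= abs(obs) - 1e-12)
  structure(list(ratio = exp(obs), p_value = p, n_randomizations = K,
                 exhaustive = exhaustive, seed = seed),
            class = "expression_test")
}

#' @export
print.expression_test <- function(x, ...) {
  cat(sprintf("expression ratio %.4f, p = %.4g (%s, %d reallocations)\n",
              x$ratio, x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_randomizations))
  invisible(x)
}

#' Run rest_ratio_test from a Ct table
#'
#' @param ct_table data frame from [read_qpcr_table()].
#' @param gene target gene name.
#' @param reference_gene normalizer gene name (U6-like).
#' @inheritParams rest_ratio_test
#' @export
rest_from_table <- function(ct_table, gene, reference_gene = "U6",
                            E_target = 2, E_reference = 2,
                            n_randomizations = 10000, seed = 1) {
  pick <- function(g, grp) {
    d <- ct_table[ct_table$gene == g & ct_table$group == grp, ]
    d$Ct[order(d$replicate)]
  }
  rest_ratio_test(list(control = pick(gene, "control"),
                       treated = pick(gene, "treated")),
                  list(control = pick(reference_gene, "control"),
                       treated = pick(reference_gene, "treated")),
                  E_target, E_reference, n_randomizations, seed)
}

#' qPCR abundances relative to a reference gene
#'
#' Converts a Ct table (control group) to copies per 1000 copies of the
#' reference: `1000 * E^(mean Ct_ref - mean Ct_gene)`.
#'
#' @param ct_table data frame from [read_qpcr_table()].
#' @param reference_gene normalizer gene.
#' @param E amplification efficiency.
#' @param group which group to quantify.
#' @return data frame `gene`, `qpcr`.
#' @export
qpcr_abundance <- function(ct_table, reference_gene = "U6", E = 2,
                           group = "control") {
  d <- ct_table[ct_table$group == group, ]
  mean_ct <- tapply(d$Ct, d$gene, mean)
  if (!reference_gene %in% names(mean_ct))
    fail("reference gene %s not in table", reference_gene)
  genes <- setdiff(names(mean_ct), reference_gene)
  data.frame(gene = genes,
             qpcr = 1000 * E^(mean_ct[[reference_gene]] - unlist(mean_ct[genes])),
             row.names = NULL)
}

FIG_CATEGORIES <- c("known miRNA", "miRNA*", "conserved candidate",
                    "specific candidate", "other small RNAs", "unassigned")

status_to_category <- function(status) {
  map <- c(known = "known miRNA", star = "miRNA*",
           conserved_candidate = "conserved candidate",
           specific_candidate = "specific candidate",
           contaminant = "other small RNAs",
           artefact = "unassigned", unassigned = "unassigned")
  unname(map[status])
}

#' Compare library composition and diversity
#'
#' Per library, the read fraction falling in each class (known miRNA,
#' miRNA*, conserved candidate, specific candidate, other small RNAs --
#' structural, piRNA-like and endosymbiont sequences combined -- and
#' unassigned), plus the Shannon diversity of per-sequence read counts
#' within the known/conserved/specific classes.
#'
#' @param table an annotated [candidate_table()] carrying counts for every
#'   library to compare.
#' @param libraries library labels (default: all in the table).
#' @return list with `fractions` (category x library matrix) and
#'   `diversity` (class x library matrix of H').
#' @export
compare_libraries <- function(table, libraries = NULL) {
  libs <- libraries %||% attr(table, "libraries")
  if (length(libs) < 2) fail("need at least 2 libraries to compare")
  if (!all(libs %in% names(table))) fail("library column missing from table")
  if (!all(table$status %in% CANDIDATE_STATUS)) fail("category scheme mismatch")
  cats <- status_to_category(table$status)
  fractions <- sapply(libs, function(lib) {
    tot <- sum(table[[lib]])
    if (tot == 0) return(setNames(rep(0, length(FIG_CATEGORIES)), FIG_CATEGORIES))
    v <- tapply(table[[lib]], factor(cats, levels = FIG_CATEGORIES), sum,
                default = 0)
    v / tot
  })
  div_classes <- c(known = "known", conserved_candidate = "conserved",
                   specific_candidate = "specific")
  diversity <- sapply(libs, function(lib) {
    vapply(names(div_classes), function(st) {
      counts <- table[[lib]][table$status == st]
      counts <- counts[counts > 0]
      if (length(counts) == 0) return(NA_real_)
      shannon_index(counts)$H_prime
    }, 0)
  })
  rownames(diversity) <- unname(div_classes)
  list(fractions = fractions, diversity = diversity)
}
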