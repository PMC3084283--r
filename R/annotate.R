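# miRNA* detection against mature-masked hairpins, contaminant labeling, and
# the combined per-read annotation with fixed category precedence.

#' Mask the mature arm of hairpin references
#'
#' Replaces each mature interval (0-based half-open, from the reference set's
#' `mature_coords`) with `N`, so that reads matching the mature arm cannot
#' re-match during the miRNA* search. Masking is idempotent.
#'
#' @param hairpins a `reference_set` with `mature_coords`.
#' @return named list of `masked_hairpin` objects (`id`, `sequence`,
#'   `mature_interval`, `family`).
#' @export
mask_mature <- function(hairpins) {
  mc <- hairpins$mature_coords
  if (is.null(mc) || nrow(mc) == 0) fail("hairpin set has no mature_coords")
  out <- lapply(seq_len(nrow(mc)), function(i) {
    id <- mc$hairpin_id[i]
    seq <- hairpins$sequences$sequence[match(id, hairpins$sequences$id)]
    s <- mc$start[i]; e <- mc$end[i]
    if (s == 0 && e == nchar(seq)) warn("hairpin %s fully masked", id)
    masked <- paste0(substr(seq, 1, s),
                     strrep("N", e - s),
                     substr(seq, e + 1, nchar(seq)))
    structure(list(id = id, sequence = masked, mature_interval = c(s, e),
                   family = if ("family" %in% names(mc)) mc$family[i] else id),
              class = "masked_hairpin")
  })
  names(out) <- mc$hairpin_id
  out
}

#' Scan reads against masked hairpins for miRNA* sequences
#'
#' A star label requires the *full* read to align within a masked hairpin at
#' `min_identity` over at least `min_span` columns. `N` (the masked mature
#' region) matches nothing, so reads inside or straddling the mask fail the
#' identity threshold.
#'
#' @param reads a [read_set()].
#' @param masked_hairpins list from [mask_mature()].
#' @param min_identity identity threshold.
#' @param min_span minimum aligned columns.
#' @return data frame `id`, `category` (`star:<family>` or `unassigned`),
#'   `family`, `identity`, `coverage`.
#' @export
scan_star <- function(reads, masked_hairpins, min_identity = 0.90,
                      min_span = 16) {
  n <- nrow(reads)
  res <- data.frame(id = reads$id, category = rep("unassigned", n),
                    family = NA_character_, identity = 0, coverage = 0,
                    stringsAsFactors = FALSE)
  if (n == 0 || length(masked_hairpins) == 0) return(res)
  best_id <- rep(-1, n)
  for (h in masked_hairpins) {
    st <- align_stats(reads$sequence, h$sequence, type = "global-local")
    ok <- st$identity >= min_identity & st$columns >= min_span &
      st$identity > best_id + 1e-12
    if (any(ok)) {
      best_id[ok] <- st$identity[ok]
      res$category[ok] <- paste0("star:", h$family)
      res$family[ok] <- h$family
      res$identity[ok] <- st$identity[ok]
      res$coverage[ok] <- 1
    }
  }
  res
}

# exact-substring matcher: does >= min_coverage of each read occur verbatim
# (either strand) in the concatenated reference? Returns coverage attained
# (0 when no window matches).
exact_coverage <- function(seqs, ref_seqs, min_coverage = 0.95,
                           both_strands = TRUE) {
  if (length(ref_seqs) == 0 || length(seqs) == 0) return(numeric(length(seqs)))
  haystack <- paste(ref_seqs, collapse = "|")
  vapply(seqs, function(s) {
    L <- nchar(s)
    kmin <- as.integer(ceiling(min_coverage * L))
    variants <- if (both_strands) c(s, revcomp(s)) else s
    for (k in L:kmin) {
      for (v in variants) {
        wins <- substring(v, 1:(L - k + 1), k:L)
        if (any(vapply(wins, grepl, TRUE, x = haystack, fixed = TRUE)))
          return(k / L)
      }
    }
    0
  }, 0, USE.NAMES = FALSE)
}

CONTAMINANT_ORDER <- c("rRNA", "tRNA", "snRNA", "piRNA_transposon",
                       "endosymbiont")

#' Label contaminant reads against reference sets
#'
#' Reads matching a contaminant set at 100% identity over at least 95% of
#' their length (either strand) are labeled with that set's category. Reads
#' hitting several sets take the first category in the fixed precedence
#' order rRNA > tRNA > snRNA > piRNA_transposon > endosymbiont, mirroring
#' the removal of structural RNAs ahead of miRNA calling.
#'
#' @param reads a [read_set()].
#' @param reference_sets named list of `reference_set` objects (from
#'   [load_reference_sets()]).
#' @param min_identity required identity (1.00 = exact; lower values switch
#'   to local alignment).
#' @param min_coverage required fraction of the read length matched.
#' @return data frame `id`, `category`, `identity`, `coverage`.
#' @export
annotate_contaminants <- function(reads, reference_sets, min_identity = 1.00,
                                  min_coverage = 0.95) {
  n <- nrow(reads)
  res <- data.frame(id = reads$id, category = rep("unassigned", n),
                    identity = 0, coverage = 0, stringsAsFactors = FALSE)
  todo <- rep(TRUE, n)
  for (set_name in intersect(CONTAMINANT_ORDER, names(reference_sets))) {
    if (!any(todo)) break
    refs <- reference_sets[[set_name]]$sequences$sequence
    if (length(refs) == 0) next
    idx <- which(todo)
    if (min_identity >= 1) {
      cov <- exact_coverage(reads$sequence[idx], refs, min_coverage)
      hit <- cov >= min_coverage
      ident <- rep(1, length(idx))
    } else {
      cov <- numeric(length(idx)); ident <- numeric(length(idx))
      for (ref in refs) {
        st <- align_stats(reads$sequence[idx], ref)
        spans <- (st$a_end - st$a_start) / nchar(reads$sequence[idx])
        better <- st$identity >= min_identity & spans > cov
        cov[better] <- spans[better]
        ident[better] <- st$identity[better]
      }
      hit <- cov >= min_coverage
    }
    sel <- idx[hit]
    res$category[sel] <- set_name
    res$identity[sel] <- ident[hit]
    res$coverage[sel] <- cov[hit]
    todo[sel] <- FALSE
  }
  res
}

#' Full per-read annotation with fixed precedence
#'
#' Applies, in order: 36-nt U-rich-tail artefact flagging, contaminant
#' labeling, known-miRNA PSSM scanning, and miRNA* scanning against masked
#' hairpins. Every read receives exactly one category (possibly
#' `unassigned`).
#'
#' @param reads a [read_set()].
#' @param reference_sets named list of `reference_set`s (contaminants).
#' @param profiles PSSM profiles for known families (may be `NULL`).
#' @param masked_hairpins [mask_mature()] output (may be `NULL`).
#' @param min_identity_known,min_identity_star identity thresholds.
#' @param artefact_length read length treated as the artefact class when the
#'   3' tail is U-rich (`NA` disables).
#' @return data frame `id`, `sequence`, `category`, `identity`, `coverage`.
#' @export
annotate_reads <- function(reads, reference_sets = list(), profiles = NULL,
                           masked_hairpins = NULL,
                           min_identity_known = 0.90,
                           min_identity_star = 0.90,
                           artefact_length = 36) {
  n <- nrow(reads)
  out <- data.frame(id = reads$id, sequence = reads$sequence,
                    category = rep("unassigned", n), identity = NA_real_,
                    coverage = NA_real_, stringsAsFactors = FALSE)
  todo <- rep(TRUE, n)
  if (!is.na(artefact_length) && n > 0) {
    fl <- flag_low_complexity_tail(reads)
    art <- nchar(reads$sequence) == artefact_length & fl$flag
    out$category[art] <- "artefact"
    todo[art] <- FALSE
  }
  if (any(todo) && length(reference_sets) > 0) {
    sub <- as_read_set(as.data.frame(reads)[todo, , drop = FALSE], libraries(reads))
    cont <- annotate_contaminants(sub, reference_sets)
    hit <- cont$category != "unassigned"
    sel <- which(todo)[hit]
    out$category[sel] <- cont$category[hit]
    out$identity[sel] <- cont$identity[hit]
    out$coverage[sel] <- cont$coverage[hit]
    todo[sel] <- FALSE
  }
  if (any(todo) && length(profiles) > 0) {
    sub <- as_read_set(as.data.frame(reads)[todo, , drop = FALSE], libraries(reads))
    kn <- scan_profiles(sub, profiles, min_identity = min_identity_known)
    hit <- kn$category != "unassigned"
    sel <- which(todo)[hit]
    out$category[sel] <- kn$category[hit]
    out$identity[sel] <- kn$identity[hit]
    out$coverage[sel] <- kn$coverage[hit]
    todo[sel] <- FALSE
  }
  if (any(todo) && length(masked_hairpins) > 0) {
    sub <- as_read_set(as.data.frame(reads)[todo, , drop = FALSE], libraries(reads))
    st <- scan_star(sub, masked_hairpins, min_identity = min_identity_star)
    hit <- st$category != "unassigned"
    sel <- which(todo)[hit]
    out$category[sel] <- st$category[hit]
    out$identity[sel] <- st$identity[hit]
    out$coverage[sel] <- st$coverage[hit]
  }
  out
}
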