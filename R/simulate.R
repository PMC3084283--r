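# Ground-truthed synthetic small-RNA libraries: planted hairpin precursors
# with mature/star arms, power-law abundances, 5'/3' end heterogeneity with
# untemplated U/A 3' additions, 36-nt U-rich-tail artefact reads,
# contaminant fragments, and two library presets differing in composition.

random_seq <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# discrete power law on [xmin, xmax], pdf ~ x^-alpha (inverse-CDF sampling)
rpowerlaw <- function(n, alpha = 1.5, xmin = 1, xmax = 5e6) {
  u <- runif(n)
  b <- 1 - alpha
  pmax(xmin, round(((xmax^b - xmin^b) * u + xmin^b)^(1 / b)))
}

#' Simulation configuration
#'
#' Defaults define the study-like conditions: heavy-tailed per-locus
#' abundances, 5'/3' end heterogeneity with mostly-U untemplated 3'
#' additions, a 36-nt U-rich-tail artefact class, and trace contaminant
#' fragments. Per-library composition (artefact fraction, contaminant
#' fractions, per-family-tag abundance multipliers) comes from
#' [library_preset()].
#'
#' @param n_known,n_conserved,n_specific planted hairpins per family tag.
#' @param mature_len_weights named weights over mature lengths (nt).
#' @param loop_range,flank_range precursor loop and flank length ranges.
#' @param abundance_exponent,abundance_min,abundance_max discrete power law
#'   for per-hairpin base abundance (reads).
#' @param p_shift5,p_shift3 named probabilities over end shifts -2..+2.
#' @param p_untemplated probability of one untemplated 3' addition.
#' @param untemplated_weights base weights of the addition (U-heavy).
#' @param star_fraction star reads as a fraction of mature reads.
#' @param max_unique_artefacts cap on distinct artefact sequences emitted.
#' @return named list.
#' @export
sim_config <- function(n_known = 12, n_conserved = 8, n_specific = 16,
                       mature_len_weights = c(`21` = 0.15, `22` = 0.70, `23` = 0.15),
                       loop_range = c(8, 15), flank_range = c(3, 8),
                       abundance_exponent = 1.5, abundance_min = 150,
                       abundance_max = 5e4,
                       p_shift5 = c(`-2` = 0.03, `-1` = 0.12, `0` = 0.70,
                                    `1` = 0.12, `2` = 0.03),
                       p_shift3 = c(`-2` = 0.03, `-1` = 0.12, `0` = 0.70,
                                    `1` = 0.12, `2` = 0.03),
                       p_untemplated = 0.2,
                       untemplated_weights = c(T = 0.6, A = 0.3, C = 0.05, G = 0.05),
                       star_fraction = 0.5,
                       max_unique_artefacts = 5000,
                       force_mature_len = NULL) {
  stopifnot(abs(sum(p_shift5) - 1) < 1e-9, abs(sum(p_shift3) - 1) < 1e-9,
            p_untemplated >= 0, p_untemplated <= 1)
  as.list(environment())
}

#' Library composition presets
#'
#' `whole_body` is enriched in known miRNAs with a 13% 36-nt artefact load;
#' `ovary` is enriched in novel candidates (especially specific ones) with a
#' 22% artefact load. Contaminant loads mirror the trace piRNA-like /
#' endosymbiont levels of real libraries.
#'
#' @param preset `"whole_body"` or `"ovary"`.
#' @return list with `artefact_fraction`, `contaminant_fractions`,
#'   `multipliers` (per family tag).
#' @export
library_preset <- function(preset = c("whole_body", "ovary")) {
  preset <- match.arg(preset)
  if (preset == "whole_body") {
    list(name = preset,
         artefact_fraction = 0.13,
         contaminant_fractions = c(rRNA = 0.001, tRNA = 0.0005, snRNA = 0.0005,
                                   piRNA_transposon = 0.004, endosymbiont = 0.003),
         multipliers = c(known = 20, novel_conserved = 1, novel_specific = 0.5))
  } else {
    list(name = preset,
         artefact_fraction = 0.22,
         contaminant_fractions = c(rRNA = 0.001, tRNA = 0.0005, snRNA = 0.0005,
                                   piRNA_transposon = 0.002, endosymbiont = 0.002),
         multipliers = c(known = 1, novel_conserved = 10, novel_specific = 20))
  }
}

make_precursor <- function(mature, config) {
  loop_len <- sample(config$loop_range[1]:config$loop_range[2], 1)
  f5 <- sample(config$flank_range[1]:config$flank_range[2], 1)
  f3 <- sample(config$flank_range[1]:config$flank_range[2], 1)
  arm <- sample(c("5p", "3p"), 1)
  arm5 <- if (arm == "5p") mature else revcomp(mature)
  arm3 <- revcomp(arm5)
  seq <- paste0(random_seq(f5), arm5, random_seq(loop_len), arm3, random_seq(f3))
  L <- nchar(mature)
  a5 <- c(f5, f5 + L)                          # 0-based half-open
  a3 <- c(f5 + L + loop_len, f5 + L + loop_len + L)
  list(sequence = seq, arm = arm,
       mature_interval = if (arm == "5p") a5 else a3,
       star_interval = if (arm == "5p") a3 else a5)
}

#' Generate a planted hairpin set with references
#'
#' Builds precursors (60-100 nt inverted repeats with a loop) for three
#' family tags: `known:<name>` (with a miRBase-style family alignment and a
#' hairpin reference carrying mature coordinates), `novel_conserved` (the
#' mature also appears in the other-species sets) and `novel_specific`.
#' Every precursor is checked to fold with arm pairedness >= 0.8 under
#' [fold_hairpin()]; each hairpin gets a base abundance drawn from the
#' configured power law. Deterministic for a fixed seed. Also fabricates the
#' contaminant reference sets (rRNA, tRNA, snRNA, piRNA-like/transposon,
#' endosymbiont genome) and two other-species small-RNA sets.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `planted_hairpins` object: `hairpins` data frame, `families`
#'   (named list of aligned known-family sequences), `references` (named
#'   list of `reference_set`s incl. `hairpin` with mature coords and
#'   `species:*` sets), `config`, `seed`.
#' @export
generate_hairpin_set <- function(config = sim_config(), seed = 1) {
  with_seed(derive_seed(seed, 11), {
    lens <- as.integer(names(config$mature_len_weights))
    tags <- c(rep("known", config$n_known),
              rep("novel_conserved", config$n_conserved),
              rep("novel_specific", config$n_specific))
    ids <- c(sprintf("hp-kn%02d", seq_len(config$n_known)),
             sprintf("hp-nc%02d", seq_len(config$n_conserved)),
             sprintf("hp-ns%02d", seq_len(config$n_specific)))
    fams <- ifelse(tags == "known",
                   sprintf("mir-s%02d", cumsum(tags == "known")), NA)
    rows <- list()
    families <- list()
    for (k in seq_along(ids)) {
      L <- sample(lens, 1, prob = config$mature_len_weights)
      if (!is.null(config$force_mature_len)) L <- config$force_mature_len
      ok <- FALSE
      for (try in 1:25) {
        mature <- random_seq(L)
        pc <- make_precursor(mature, config)
        if (nchar(pc$sequence) < 40) next
        fold <- fold_hairpin(pc$sequence)
        if (!is.null(fold$arm5) && all(fold$pairedness >= 0.8)) { ok <- TRUE; break }
      }
      if (!ok) fail("could not generate a foldable precursor for %s", ids[k])
      if (tags[k] == "known") {
        variants <- vapply(1:2, function(v) {
          pos <- sample(L, 1)
          sub <- sample(setdiff(DNA_BASES, substr(mature, pos, pos)), 1)
          paste0(substr(mature, 1, pos - 1), sub,
                 substr(mature, pos + 1, L))
        }, "")
        families[[fams[k]]] <- c(mature, mature, variants)
      }
      rows[[k]] <- data.frame(
        id = ids[k], tag = tags[k], family = fams[k],
        sequence = pc$sequence, arm = pc$arm,
        mature = mature, star = revcomp(mature),
        mature_start = pc$mature_interval[1], mature_end = pc$mature_interval[2],
        star_start = pc$star_interval[1], star_end = pc$star_interval[2],
        base_abundance = rpowerlaw(1, config$abundance_exponent,
                                   config$abundance_min, config$abundance_max),
        stringsAsFactors = FALSE)
    }
    hp <- do.call(rbind, rows)
    known <- hp[hp$tag == "known", ]
    refs <- list(
      known_mature = reference_set("known_mature", known$family, known$mature),
      hairpin = reference_set(
        "hairpin", known$id, known$sequence,
        mature_coords = data.frame(hairpin_id = known$id,
                                   start = known$mature_start,
                                   end = known$mature_end,
                                   family = known$family)),
      rRNA = reference_set("rRNA", sprintf("rrna%d", 1:2),
                           vapply(1:2, function(i) random_seq(500), "")),
      tRNA = reference_set("tRNA", sprintf("trna%d", 1:5),
                           vapply(1:5, function(i) random_seq(75), "")),
      snRNA = reference_set("snRNA", sprintf("snrna%d", 1:3),
                            vapply(1:3, function(i) random_seq(150), "")),
      piRNA_transposon = reference_set("piRNA_transposon",
                                       sprintf("pitx%d", 1:4),
                                       vapply(1:4, function(i) random_seq(300), "")),
      endosymbiont = reference_set("endosymbiont", "blattabacterium_frag",
                                   random_seq(3000)))
    conserved <- hp[hp$tag == "novel_conserved", ]
    pick_a <- sample(c(TRUE, FALSE), nrow(conserved), replace = TRUE, prob = c(.7, .3))
    refs[["species:insectA"]] <- reference_set(
      "species:insectA",
      c(known$family, conserved$id[pick_a], sprintf("xa%d", 1:5)),
      c(known$mature, conserved$mature[pick_a],
        vapply(1:5, function(i) random_seq(22), "")))
    refs[["species:insectB"]] <- reference_set(
      "species:insectB",
      c(conserved$id[!pick_a], sprintf("xb%d", 1:5)),
      c(conserved$mature[!pick_a], vapply(1:5, function(i) random_seq(22), "")))
    structure(list(hairpins = hp, families = families, references = refs,
                   config = config, seed = seed),
              class = "planted_hairpins")
  })
}

#' @export
print.planted_hairpins <- function(x, ...) {
  cat(sprintf("planted_hairpins: %d hairpins (%s)\n", nrow(x$hairpins),
              paste(sprintf("%s: %d", names(table(x$hairpins$tag)),
                            table(x$hairpins$tag)), collapse = ", ")))
  invisible(x)
}

# emit end-heterogeneity variants of one arm interval; returns data frame
# sequence/count (counts multinomial over the variant space). The 3'-shift
# distribution is re-centered so that the modal emitted length is
# `center_len` (22 nt): 3' processing heterogeneity trims or extends toward
# the canonical miRNA length whatever the planted arm length.
emit_variants <- function(precursor, interval, n_reads, config,
                          center_len = 22) {
  if (n_reads <= 0) return(NULL)
  s5 <- as.integer(names(config$p_shift5))
  s3 <- as.integer(names(config$p_shift3)) +
    (center_len - (interval[2] - interval[1]))
  adds <- c("", names(config$untemplated_weights))
  p_add <- c(1 - config$p_untemplated,
             config$p_untemplated * config$untemplated_weights /
               sum(config$untemplated_weights))
  combos <- expand.grid(i5 = seq_along(s5), i3 = seq_along(s3),
                        ia = seq_along(adds))
  probs <- config$p_shift5[combos$i5] * config$p_shift3[combos$i3] *
    p_add[combos$ia]
  counts <- as.vector(rmultinom(1, n_reads, probs))
  keep <- counts > 0
  combos <- combos[keep, , drop = FALSE]; counts <- counts[keep]
  L <- nchar(precursor)
  vstart <- pmax(0, interval[1] + s5[combos$i5])
  vend <- pmin(L, interval[2] + s3[combos$i3])
  seqs <- paste0(substr(rep(precursor, nrow(combos)), vstart + 1, vend),
                 adds[combos$ia])
  agg <- rowsum(counts, seqs)
  data.frame(sequence = rownames(agg), count = agg[, 1],
             stringsAsFactors = FALSE)
}

#' Simulate one small-RNA library
#'
#' Draws reads for every planted hairpin (mature and star arms at the
#' configured ratio) under the abundance law scaled by the preset's
#' family-tag multipliers, applies 5'/3' end heterogeneity and untemplated
#' 3' additions, then mixes in 36-nt U-rich-tail artefact reads and
#' contaminant fragments at the preset fractions. Returns the collapsed
#' read set together with an exact truth manifest.
#'
#' @param hairpins a `planted_hairpins` object.
#' @param preset a [library_preset()] (or its name).
#' @param library library label for the counts.
#' @param seed integer seed.
#' @return list with `reads` (a [read_set()]) and `manifest` (data frame
#'   `sequence`, `origin`, `true_category`, `count`).
#' @export
simulate_library <- function(hairpins, preset = "whole_body",
                             library = "WB", seed = 1) {
  if (is.character(preset)) preset <- library_preset(preset)
  config <- hairpins$config
  with_seed(derive_seed(seed, 101 + sum(utf8ToInt(library))), {
    hp <- hairpins$hairpins
    rows <- list()
    for (k in seq_len(nrow(hp))) {
      mult <- preset$multipliers[[hp$tag[k]]]
      total <- round(hp$base_abundance[k] * mult * exp(rnorm(1, 0, 0.3)))
      if (total < 1) next
      m_reads <- round(total / (1 + config$star_fraction))
      s_reads <- total - m_reads
      cat_m <- switch(hp$tag[k], known = "known",
                      novel_conserved = "novel_conserved",
                      novel_specific = "novel_specific")
      vm <- emit_variants(hp$sequence[k], c(hp$mature_start[k], hp$mature_end[k]),
                          m_reads, config)
      if (!is.null(vm)) {
        vm$origin <- paste0(hp$id[k], ":mature")
        vm$true_category <- cat_m
        rows[[length(rows) + 1]] <- vm
      }
      vs <- emit_variants(hp$sequence[k], c(hp$star_start[k], hp$star_end[k]),
                          s_reads, config)
      if (!is.null(vs)) {
        vs$origin <- paste0(hp$id[k], ":star")
        vs$true_category <- paste0(cat_m, "_star")
        rows[[length(rows) + 1]] <- vs
      }
    }
    planted <- do.call(rbind, rows)
    n_planted <- sum(planted$count)
    f_art <- preset$artefact_fraction
    f_cont <- sum(preset$contaminant_fractions)
    denom <- 1 - f_art - f_cont
    # artefacts: 36-nt reads with a U-rich 3' decanucleotide, nearly all
    # singletons (capped unique sequences; excess reads pile on a few)
    n_art <- round(n_planted * f_art / denom)
    if (n_art > 0) {
      n_uniq <- min(config$max_unique_artefacts, n_art)
      seqs <- vapply(seq_len(n_uniq), function(i)
        paste0(random_seq(26),
               random_seq2(10, c(T = 0.6, A = 0.2, C = 0.1, G = 0.1))), "")
      counts <- rep(1, n_uniq)
      extra <- n_art - n_uniq
      if (extra > 0) {
        hot <- max(1, round(n_uniq * 0.01))
        counts[seq_len(hot)] <- counts[seq_len(hot)] +
          as.vector(rmultinom(1, extra, rep(1, hot)))
      }
      rows[[length(rows) + 1]] <- data.frame(
        sequence = seqs, count = counts, origin = "artefact",
        true_category = "artefact", stringsAsFactors = FALSE)
    }
    # contaminant fragments from the fabricated reference sets
    for (set in names(preset$contaminant_fractions)) {
      target <- round(n_planted * preset$contaminant_fractions[[set]] / denom)
      if (target <= 0) next
      refs <- hairpins$references[[set]]$sequences$sequence
      frs <- list(); got <- 0
      while (got < target) {
        ref <- refs[sample(length(refs), 1)]
        len <- sample(21:29, 1)
        if (nchar(ref) < len) next
        pos <- sample(nchar(ref) - len + 1, 1)
        cnt <- min(rpowerlaw(1, 2, 1, 80), target - got)
        frs[[length(frs) + 1]] <- data.frame(
          sequence = substr(ref, pos, pos + len - 1), count = cnt,
          origin = paste0("contaminant:", set), true_category = set,
          stringsAsFactors = FALSE)
        got <- got + cnt
      }
      rows[[length(rows) + 1]] <- do.call(rbind, frs)
    }
    all_rows <- do.call(rbind, rows)
    manifest <- aggregate(count ~ sequence + origin + true_category,
                          all_rows, sum)
    per_seq <- rowsum(all_rows$count, all_rows$sequence)
    reads <- read_set(id = sprintf("%s_s%06d", library, seq_len(nrow(per_seq))),
                      sequence = rownames(per_seq),
                      counts = matrix(per_seq[, 1], ncol = 1,
                                      dimnames = list(NULL, library)))
    list(reads = reads, manifest = manifest)
  })
}

# random sequence with base weights
random_seq2 <- function(n, weights) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights), collapse = "")
}

#' Generate a contig database embedding planted precursors
#'
#' Each novel precursor is embedded, as an exact substring, in a longer
#' contig with random flanks; decoy contigs are dinucleotide-preserving
#' shuffles of planted precursors (re-shuffled if a planted mature or star
#' survives as a substring), also flanked.
#'
#' @param hairpins a `planted_hairpins` object.
#' @param seed integer seed.
#' @param n_decoys number of decoy contigs.
#' @param flank_range contig flank lengths (nt).
#' @return list with `contigs` (data frame `id`, `sequence`) and `truth`
#'   (data frame `contig_id`, `hairpin_id`; decoys have `NA`).
#' @export
generate_contig_db <- function(hairpins, seed = 1, n_decoys = 10,
                               flank_range = c(10, 40)) {
  with_seed(derive_seed(seed, 301), {
    hp <- hairpins$hairpins
    novel <- hp[hp$tag != "known", ]
    planted_arms <- c(hp$mature, hp$star)
    embed <- function(seq) {
      f5 <- sample(flank_range[1]:flank_range[2], 1)
      f3 <- sample(flank_range[1]:flank_range[2], 1)
      total <- nchar(seq) + f5 + f3
      if (total > 200) { f5 <- min(f5, 20); f3 <- min(f3, 200 - nchar(seq) - f5) }
      paste0(random_seq(f5), seq, random_seq(max(0, f3)))
    }
    contigs <- data.frame(id = paste0("ctg_", novel$id),
                          sequence = vapply(novel$sequence, embed, "",
                                            USE.NAMES = FALSE),
                          stringsAsFactors = FALSE)
    truth <- data.frame(contig_id = contigs$id, hairpin_id = novel$id)
    if (n_decoys > 0) {
      dec <- vapply(seq_len(n_decoys), function(i) {
        src <- hp$sequence[sample(nrow(hp), 1)]
        for (try in 1:50) {
          sh <- dinuc_shuffle(src)
          hit <- any(vapply(planted_arms, function(a) grepl(a, sh, fixed = TRUE),
                            TRUE))
          if (!hit) return(embed(sh))
        }
        embed(paste(sample(strsplit(src, "")[[1]]), collapse = ""))
      }, "")
      contigs <- rbind(contigs,
                       data.frame(id = sprintf("ctg_decoy%02d", seq_len(n_decoys)),
                                  sequence = dec, stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(contig_id = sprintf("ctg_decoy%02d",
                                                           seq_len(n_decoys)),
                                       hairpin_id = NA_character_))
    }
    list(contigs = contigs, truth = truth)
  })
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random-walk shuffle on the dinucleotide transition multigraph (retrying
#' until a full-length walk is found), so the shuffled sequence keeps the
#' original dinucleotide composition.
#'
#' @param seq DNA sequence.
#' @param max_tries walk attempts before giving up (then a plain
#'   mononucleotide shuffle is returned).
#' @return shuffled sequence.
#' @export
dinuc_shuffle <- function(seq, max_tries = 50) {
  chars <- strsplit(as_dna(seq), "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  edges <- split(chars[-1], chars[-n])   # successor multiset per base
  for (try in seq_len(max_tries)) {
    pool <- lapply(edges, sample)
    out <- character(n)
    out[1] <- chars[1]
    ok <- TRUE
    for (i in 2:n) {
      nxt <- pool[[out[i - 1]]]
      if (length(nxt) == 0) { ok <- FALSE; break }
      out[i] <- nxt[1]
      pool[[out[i - 1]]] <- nxt[-1]
    }
    if (ok) return(paste(out, collapse = ""))
  }
  paste(sample(chars), collapse = "")
}

#' Simulate a qPCR Ct table from abundances
#'
#' Ct values follow `baseline - log_E(abundance) + N(0, noise_sd)`; the
#' treated group applies per-gene effect multipliers to the abundance (a
#' dicer-1-like knockdown halves every mature miRNA, for instance). A
#' U6-like reference gene with fixed abundance and effect 1 is always
#' included. Genes with non-positive abundance are skipped with a warning.
#'
#' @param abundances named numeric vector of per-gene abundances (reads).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param effects named multipliers applied in the treated group (default 1).
#' @param E amplification efficiency.
#' @param baseline Ct of one template copy.
#' @param n_replicates replicates per group.
#' @param reference_gene,reference_abundance the normalizer.
#' @param seed integer seed.
#' @return Ct table data frame (`gene`, `group`, `replicate`, `Ct`).
#' @export
simulate_qpcr <- function(abundances, noise_sd = 0.25, effects = NULL,
                          E = 2, baseline = 34, n_replicates = 3,
                          reference_gene = "U6", reference_abundance = 1e5,
                          seed = 1) {
  with_seed(derive_seed(seed, 401), {
    bad <- abundances <= 0 | !is.finite(abundances)
    if (any(bad)) {
      warn("skipping %d gene(s) with non-positive abundance", sum(bad))
      abundances <- abundances[!bad]
    }
    abundances <- c(abundances, setNames(reference_abundance, reference_gene))
    rows <- list()
    for (g in names(abundances)) {
      eff <- if (!is.null(effects) && g %in% names(effects)) effects[[g]] else 1
      for (grp in c("control", "treated")) {
        ab <- abundances[[g]] * if (grp == "treated") eff else 1
        ct <- baseline - log(ab) / log(E) + rnorm(n_replicates, 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, group = grp, replicate = seq_len(n_replicates), Ct = ct)
      }
    }
    do.call(rbind, rows)
  })
}
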