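test_that("hairpin generation is deterministic and self-consistently foldable", {
  cfg <- sim_config(n_known = 3, n_conserved = 2, n_specific = 2)
  hp1 <- generate_hairpin_set(cfg, seed = 7)
  hp2 <- generate_hairpin_set(cfg, seed = 7)
  expect_identical(hp1, hp2)
  hp3 <- generate_hairpin_set(cfg, seed = 8)
  expect_false(identical(hp1$hairpins$sequence, hp3$hairpins$sequence))

  for (k in seq_len(nrow(hp1$hairpins))) {
    f <- fold_hairpin(hp1$hairpins$sequence[k])
    expect_gte(min(f$pairedness), 0.8)
    L <- nchar(hp1$hairpins$sequence[k])
    expect_gte(L, 40); expect_lte(L, 120)
  }
  # mature and star on opposite, non-overlapping arms
  hp <- hp1$hairpins
  expect_true(all(hp$mature_end <= hp$star_start | hp$star_end <= hp$mature_start))
})

test_that("forcing the mature length fixes every planted interval", {
  cfg <- sim_config(n_known = 2, n_conserved = 1, n_specific = 1,
                    force_mature_len = 22)
  hp <- generate_hairpin_set(cfg, seed = 9)$hairpins
  expect_true(all(hp$mature_end - hp$mature_start == 22))
  expect_true(all(nchar(hp$mature) == 22))
})

test_that("simulated libraries are exact against their truth manifest", {
  cfg <- sim_config(n_known = 4, n_conserved = 2, n_specific = 4)
  hp <- generate_hairpin_set(cfg, seed = 10)
  sim <- simulate_library(hp, "whole_body", "WB", seed = 10)
  # conservation: manifest covers every emitted read exactly
  expect_equal(sum(sim$manifest$count), sum(total_counts(sim$reads)))
  man_by_seq <- tapply(sim$manifest$count, sim$manifest$sequence, sum)
  expect_equal(as.numeric(man_by_seq[sim$reads$sequence]), sim$reads$WB)
  # determinism
  sim2 <- simulate_library(hp, "whole_body", "WB", seed = 10)
  expect_identical(sim, sim2)
})

test_that("zero artefact fraction emits no 36-nt artefact reads", {
  cfg <- sim_config(n_known = 3, n_conserved = 1, n_specific = 1)
  hp <- generate_hairpin_set(cfg, seed = 11)
  preset <- library_preset("whole_body")
  preset$artefact_fraction <- 0
  sim <- simulate_library(hp, preset, "WB", seed = 11)
  expect_false(any(sim$manifest$true_category == "artefact"))
})

test_that("contig database embeds precursors exactly; decoys carry no planted arms", {
  cfg <- sim_config(n_known = 3, n_conserved = 2, n_specific = 3)
  hp <- generate_hairpin_set(cfg, seed = 12)
  db <- generate_contig_db(hp, seed = 12, n_decoys = 8)
  novel <- hp$hairpins[hp$hairpins$tag != "known", ]
  for (k in seq_len(nrow(novel))) {
    ctg <- db$contigs$sequence[db$contigs$id == paste0("ctg_", novel$id[k])]
    expect_true(grepl(novel$sequence[k], ctg, fixed = TRUE))
  }
  decoys <- db$contigs$sequence[is.na(db$truth$hairpin_id)]
  arms <- c(hp$hairpins$mature, hp$hairpins$star)
  for (d in decoys)
    expect_false(any(vapply(arms, grepl, TRUE, x = d, fixed = TRUE)))
  # determinism
  db2 <- generate_contig_db(hp, seed = 12, n_decoys = 8)
  expect_identical(db, db2)
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  withr::with_seed(13, {
    s <- random_dna(80)
    sh <- dinuc_shuffle(s)
    dinucs <- function(x) {
      ch <- strsplit(x, "")[[1]]
      sort(paste0(ch[-length(ch)], ch[-1]))
    }
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucs(sh), dinucs(s))
  })
})

test_that("a planted 2-fold knockdown is recovered by the randomization test", {
  ab <- c(m1 = 5000, m2 = 20000, m3 = 1000)
  qt <- simulate_qpcr(ab, noise_sd = 0, effects = c(m1 = 0.5, m2 = 0.5, m3 = 0.5),
                      n_replicates = 3, seed = 14)
  for (g in names(ab)) {
    et <- rest_from_table(qt, g, "U6")
    expect_equal(et$ratio, 0.5, tolerance = 1e-9)
  }
})

test_that("library presets shape the composition qualitatively", {
  cfg <- sim_config(n_known = 6, n_conserved = 3, n_specific = 6)
  hp <- generate_hairpin_set(cfg, seed = 15)
  wb <- simulate_library(hp, "whole_body", "WB", seed = 15)
  ov <- simulate_library(hp, "ovary", "Ov", seed = 15)
  frac <- function(man, cat) sum(man$count[startsWith(man$true_category, cat)]) /
    sum(man$count)
  # whole-body known-enriched; ovary candidate-enriched
  expect_gt(frac(wb$manifest, "known"), frac(wb$manifest, "novel"))
  expect_gt(frac(ov$manifest, "novel"), frac(ov$manifest, "known"))
})
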