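# Stage runner chaining the pipeline through on-disk artifacts, with a
# machine-readable run log and deterministic seeds.

PIPELINE_STAGES <- c("simulate", "preprocess", "cluster", "annotate",
                     "candidates", "precursors", "stats", "report")

#' Default pipeline configuration
#'
#' All thresholds of the pipeline stages with their defaults, the output
#' directory and the master seed. Any entry can be overridden.
#'
#' @param outdir artifact directory.
#' @param seed master seed; every stage derives its randomness from it.
#' @param ... overrides.
#' @return named list.
#' @export
pipeline_config <- function(outdir = "mirfree_run", seed = 1, ...) {
  cfg <- list(outdir = outdir, seed = seed,
              libraries = c("WB", "Ov"),
              presets = c("whole_body", "ovary"),
              min_length = 19, min_count = 6, max_ambiguous = 0,
              cluster_identity = 0.90, cluster_coverage = 0.80,
              known_identity = 0.90, star_identity = 0.90,
              contaminant_identity = 1.00, contaminant_coverage = 0.95,
              candidate_min_reads = 100,
              graph_identity = 0.90, graph_coverage = 0.95,
              q_threshold = 0.3,
              conservation_identity = 1.00, conservation_coverage = 0.95,
              map_identity = 1.00,
              qpcr_min_reads = 101,
              n_randomizations = 10000)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Write / read a read set as TSV
#'
#' Columns: `id`, `sequence`, then one count column per library. `#` lines
#' are comments.
#'
#' @param reads a [read_set()].
#' @param path TSV path.
#' @param header_comments optional comment lines.
#' @export
write_read_set <- function(reads, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments)) writeLines(paste0("# ", header_comments), con)
  write.table(as.data.frame(reads), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_set
#' @export
read_read_set <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  libs <- setdiff(names(df), c("id", "sequence"))
  read_set(df$id, df$sequence, as.matrix(df[, libs, drop = FALSE]))
}

art <- function(config, ...) file.path(config$outdir, ...)

need_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(structure(class = c("mirfree_missing_input", "error", "condition"),
                   list(message = sprintf("missing input: %s",
                                          paste(missing, collapse = ", ")),
                        call = NULL)))
  invisible(TRUE)
}

log_stage <- function(config, stage, params, counts, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  entry <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                seed = config$seed, params = params, counts = counts,
                input_md5 = as.list(tools::md5sum(inputs)))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(config$outdir, "run_log.jsonl"), append = TRUE, sep = "")
}

stage_simulate <- function(config) {
  dir.create(art(config, "refs"), recursive = TRUE, showWarnings = FALSE)
  hp <- generate_hairpin_set(sim_config(), seed = config$seed)
  # reference bundle
  refs <- hp$references
  conf_lines <- character()
  for (nm in names(refs)) {
    fn <- paste0(gsub(":", "_", nm), ".fa")
    write_fasta(refs[[nm]]$sequences$id, refs[[nm]]$sequences$sequence,
                art(config, "refs", fn))
    conf_lines <- c(conf_lines, sprintf("%s = %s", nm, fn))
  }
  mc <- refs$hairpin$mature_coords
  write.table(mc, art(config, "refs", "hairpin_coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  conf_lines <- c(conf_lines, "hairpin_coords = hairpin_coords.tsv")
  writeLines(conf_lines, art(config, "refs", "refsets.conf"))
  fam <- do.call(rbind, lapply(names(hp$families), function(f)
    data.frame(family = f, sequence = hp$families[[f]])))
  write.table(fam, art(config, "families.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # libraries
  for (i in seq_along(config$libraries)) {
    lib <- config$libraries[i]
    sim <- simulate_library(hp, preset = config$presets[i], library = lib,
                            seed = config$seed)
    write_fasta(sim$reads$id, sim$reads$sequence,
                art(config, sprintf("reads_%s.fasta", lib)),
                counts = sim$reads[[lib]])
    write.table(sim$manifest, art(config, sprintf("manifest_%s.tsv", lib)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # contigs
  db <- generate_contig_db(hp, seed = config$seed)
  write_fasta(db$contigs$id, db$contigs$sequence, art(config, "contigs.fasta"))
  write.table(db$truth, art(config, "contig_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # qPCR: per known family mature abundance per library, plus a knockdown
  # experiment halving every mature miRNA
  for (i in seq_along(config$libraries)) {
    lib <- config$libraries[i]
    man <- read.delim(art(config, sprintf("manifest_%s.tsv", lib)))
    kn <- man[man$true_category == "known", ]
    kn$hid <- sub(":.*$", "", kn$origin)
    ab <- tapply(kn$count, kn$hid, sum)
    fams <- hp$hairpins$family[match(names(ab), hp$hairpins$id)]
    abundances <- setNames(as.numeric(ab), fams)
    qt <- simulate_qpcr(abundances, seed = derive_seed(config$seed, i))
    write.table(qt, art(config, sprintf("qpcr_%s.tsv", lib)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (i == 1) {
      eff <- setNames(rep(0.5, length(abundances)), names(abundances))
      qk <- simulate_qpcr(abundances, effects = eff, n_replicates = 6,
                          seed = derive_seed(config$seed, 99))
      write.table(qk, art(config, "qpcr_knockdown.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  log_stage(config, "simulate", list(seed = config$seed),
            list(hairpins = nrow(hp$hairpins)))
  invisible(TRUE)
}

stage_preprocess <- function(config) {
  libs <- config$libraries
  need_inputs(art(config, sprintf("reads_%s.fasta", libs)))
  filtered <- list()
  for (lib in libs) {
    rs <- read_sequences(art(config, sprintf("reads_%s.fasta", lib)),
                         "fasta", library = lib)
    rs <- collapse_identical(rs)
    hist <- length_distribution(rs)
    write.table(as.data.frame(hist),
                art(config, sprintf("length_hist_%s.tsv", lib)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fr <- filter_reads(rs, filter_params(config$min_length, config$min_count,
                                         config$max_ambiguous))
    write.table(fr$report, art(config, sprintf("filter_report_%s.tsv", lib)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    filtered[[lib]] <- fr$kept
  }
  merged <- Reduce(merge_read_sets, filtered)
  write_read_set(merged, art(config, "reads_filtered.tsv"),
                 header_comments = sprintf("seed=%d", config$seed))
  log_stage(config, "preprocess", config[c("min_length", "min_count")],
            list(unique_sequences = nrow(merged),
                 reads = sum(total_counts(merged))),
            inputs = art(config, sprintf("reads_%s.fasta", libs)))
  invisible(TRUE)
}

stage_cluster <- function(config) {
  need_inputs(art(config, "reads_filtered.tsv"))
  reads <- read_read_set(art(config, "reads_filtered.tsv"))
  cl <- cluster_reads(reads, config$cluster_identity, config$cluster_coverage)
  write_cluster_table(cl, art(config, "clusters.tsv"),
                      header_comments = sprintf("seed=%d", config$seed))
  reps <- cluster_representatives(cl)
  write_read_set(reps, art(config, "representatives.tsv"),
                 header_comments = sprintf("seed=%d", config$seed))
  log_stage(config, "cluster",
            config[c("cluster_identity", "cluster_coverage")],
            list(clusters = length(cl$clusters)),
            inputs = art(config, "reads_filtered.tsv"))
  invisible(TRUE)
}

stage_annotate <- function(config) {
  need_inputs(c(art(config, "representatives.tsv"),
                art(config, "families.tsv"),
                art(config, "refs", "refsets.conf")))
  reps <- read_read_set(art(config, "representatives.tsv"))
  fam <- read.delim(art(config, "families.tsv"))
  profiles <- build_pssm_set(split(fam$sequence, fam$family))
  write_pssm_profiles(profiles, art(config, "pssm_profiles.tsv"))
  refs <- load_reference_sets(art(config, "refs", "refsets.conf"))
  masked <- mask_mature(refs$hairpin)
  ann <- annotate_reads(reps, refs, profiles, masked,
                        min_identity_known = config$known_identity,
                        min_identity_star = config$star_identity)
  write.table(ann, art(config, "annotation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage(config, "annotate", config[c("known_identity", "star_identity")],
            as.list(table(sub(":.*$", "", ann$category))))
  invisible(TRUE)
}

# map fine-grained annotation categories to candidate-table statuses
category_to_status <- function(category) {
  base <- sub(":.*$", "", category)
  ifelse(base == "known", "known",
    ifelse(base == "star", "star",
      ifelse(base %in% CONTAMINANT_ORDER, "contaminant",
        ifelse(base == "artefact", "artefact", "unassigned"))))
}

stage_candidates <- function(config) {
  need_inputs(c(art(config, "reads_filtered.tsv"), art(config, "clusters.tsv"),
                art(config, "annotation.tsv"),
                art(config, "refs", "refsets.conf")))
  reads <- read_read_set(art(config, "reads_filtered.tsv"))
  reps <- read_read_set(art(config, "representatives.tsv"))
  ann <- read.delim(art(config, "annotation.tsv"))
  # propagate each cluster representative's category to all its members:
  # the candidate network is built on the abundant *sequences*, not on the
  # cluster representatives, so variant clouds stay visible as components
  membership <- read.delim(art(config, "clusters.tsv"), comment.char = "#")
  rep_of <- with(membership,
                 setNames(member_id[is_representative][match(cluster_id,
                          cluster_id[is_representative])], member_id))
  member_ann <- data.frame(
    id = membership$member_id,
    category = ann$category[match(rep_of[membership$member_id], ann$id)])
  cand <- select_abundant(reads, member_ann,
                          min_reads = config$candidate_min_reads)
  graph <- build_similarity_graph(cand, config$graph_identity,
                                  config$graph_coverage)
  write_edge_list(graph, art(config, "edges.tsv"))
  def <- define_candidates(graph, q_threshold = config$q_threshold)
  comps <- connected_components(graph)
  comp_of <- integer(nrow(graph$nodes))
  for (i in seq_along(comps)) comp_of[comps[[i]]] <- i
  write.table(data.frame(node = graph$nodes$id, component = comp_of,
                         community = def$assignment),
              art(config, "partition.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  refs <- load_reference_sets(art(config, "refs", "refsets.conf"))
  species <- refs[startsWith(names(refs), "species:")]
  tab <- classify_conservation(def$table, species,
                               config$conservation_identity,
                               config$conservation_coverage)
  write_candidate_table(tab, art(config, "candidates.tsv"),
                        header_comments = sprintf("seed=%d", config$seed))
  summary <- data.frame(metric = c("n_components", "major_component_size",
                                   "Q_major", "n_modules_major",
                                   "n_candidates"),
                        value = c(def$n_components, def$major_component_size,
                                  def$Q_major, def$n_modules_major,
                                  nrow(tab)))
  write.table(summary, art(config, "network_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # full composition table: every cluster representative with its status;
  # representatives sitting in the candidate network inherit the
  # conserved/specific status of their community's representative
  status <- category_to_status(ann$category[match(reps$id, ann$id)])
  status_by_node <- setNames(
    tab$status[match(paste0("community", def$assignment), tab$cluster_id)],
    graph$nodes$id)
  in_cand <- reps$id %in% names(status_by_node)
  status[in_cand] <- status_by_node[reps$id[in_cand]]
  full <- candidate_table(reps$id, reps$sequence, status,
                          cluster_id = reps$id, counts = count_matrix(reps))
  write_candidate_table(full, art(config, "composition.tsv"),
                        header_comments = sprintf("seed=%d", config$seed))
  log_stage(config, "candidates",
            config[c("candidate_min_reads", "graph_identity",
                     "graph_coverage", "q_threshold")],
            list(candidates = nrow(tab), components = def$n_components))
  invisible(TRUE)
}

stage_precursors <- function(config) {
  need_inputs(c(art(config, "candidates.tsv"), art(config, "contigs.fasta")))
  tab <- read_candidate_table(art(config, "candidates.tsv"))
  contigs <- read_contigs(art(config, "contigs.fasta"))
  res <- find_precursors(tab, contigs, min_identity = config$map_identity)
  write.table(res$hits[, c("contig_id", "start", "end", "candidate_id",
                           "identity", "strand")],
              art(config, "hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$duplexes, art(config, "duplexes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage(config, "precursors", config["map_identity"],
            list(hits = nrow(res$hits), screened = length(res$screened),
                 duplexes = sum(res$duplexes$verdict == "duplex")))
  invisible(TRUE)
}

stage_stats <- function(config) {
  libs <- config$libraries
  need_inputs(c(art(config, "composition.tsv"), art(config, "annotation.tsv"),
                art(config, "representatives.tsv"),
                art(config, sprintf("qpcr_%s.tsv", libs[1]))))
  full <- read_candidate_table(art(config, "composition.tsv"))
  comp <- compare_libraries(full)
  write.table(data.frame(category = rownames(comp$fractions), comp$fractions),
              art(config, "composition_fractions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(class = rownames(comp$diversity), comp$diversity),
              art(config, "diversity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # reads vs qPCR per library
  ann <- read.delim(art(config, "annotation.tsv"))
  reps <- read_read_set(art(config, "representatives.tsv"))
  cors <- list()
  for (lib in libs) {
    qf <- art(config, sprintf("qpcr_%s.tsv", lib))
    if (!file.exists(qf)) next
    known <- ann[startsWith(ann$category, "known:"), ]
    fam_reads <- tapply(reps[[lib]][match(known$id, reps$id)],
                        sub("^known:", "", known$category), sum)
    qa <- qpcr_abundance(read_qpcr_table(qf))
    common <- intersect(names(fam_reads), qa$gene)
    pairs <- data.frame(gene = common, reads = as.numeric(fam_reads[common]),
                        qpcr = qa$qpcr[match(common, qa$gene)])
    ct <- tryCatch(correlate_reads_qpcr(pairs, min_reads = config$qpcr_min_reads),
                   error = function(e) NULL)
    if (!is.null(ct))
      cors[[lib]] <- data.frame(library = lib, R = ct$R, p = ct$p,
                                n_used = ct$n_used)
  }
  if (length(cors))
    write.table(do.call(rbind, cors), art(config, "correlation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  # knockdown randomization tests
  kf <- art(config, "qpcr_knockdown.tsv")
  if (file.exists(kf)) {
    qk <- read_qpcr_table(kf)
    genes <- setdiff(unique(qk$gene), "U6")
    kd <- do.call(rbind, lapply(genes, function(g) {
      et <- rest_from_table(qk, g, "U6",
                            n_randomizations = config$n_randomizations,
                            seed = derive_seed(config$seed, 7))
      data.frame(gene = g, ratio = et$ratio, p_value = et$p_value,
                 n_randomizations = et$n_randomizations)
    }))
    write.table(kd, art(config, "knockdown.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log_stage(config, "stats", config["qpcr_min_reads"], list())
  invisible(TRUE)
}

stage_report <- function(config) {
  need_inputs(art(config, "network_summary.tsv"))
  out <- list(seed = config$seed)
  summ <- read.delim(art(config, "network_summary.tsv"))
  out$network <- setNames(as.list(summ$value), summ$metric)
  for (f in c("correlation", "knockdown", "composition_fractions")) {
    p <- art(config, paste0(f, ".tsv"))
    if (file.exists(p)) out[[f]] <- read.delim(p)
  }
  dup <- art(config, "duplexes.tsv")
  if (file.exists(dup)) {
    d <- read.delim(dup)
    out$duplexes <- list(called = sum(d$verdict == "duplex"), total = nrow(d))
  }
  jsonlite::write_json(out, art(config, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage(config, "report", list(), list())
  invisible(TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `preprocess`, `cluster`, `annotate`, `candidates`,
#' `precursors`, `stats`, `report`. Each stage reads its declared input
#' artifacts from `config$outdir` (failing with a named missing path), writes
#' its outputs there, and appends a machine-readable entry (stage,
#' parameters, counts) to `run_log.jsonl`. Rerunning a later stage never
#' recomputes upstream artifacts.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @export
run_stage <- function(stage, config = pipeline_config()) {
  if (!stage %in% PIPELINE_STAGES)
    stop(structure(class = c("mirfree_usage", "error", "condition"),
                   list(message = sprintf("unknown stage '%s' (stages: %s)",
                                          stage,
                                          paste(PIPELINE_STAGES, collapse = ", ")),
                        call = NULL)))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = stage_simulate(config),
         preprocess = stage_preprocess(config),
         cluster = stage_cluster(config),
         annotate = stage_annotate(config),
         candidates = stage_candidates(config),
         precursors = stage_precursors(config),
         stats = stage_stats(config),
         report = stage_report(config))
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run, in order.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = PIPELINE_STAGES) {
  for (s in stages) run_stage(s, config)
  invisible(config$outdir)
}
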