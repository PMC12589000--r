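#' Configuration for the end-to-end design pipeline
#'
#' Bundles the stage configurations and the global seed. Every stochastic
#' stage derives its seed from `seed` so a configuration identifies one
#' reproducible run.
#'
#' @param seed Global integer seed.
#' @param candidate_spec A [candidate_generator_spec()] (or `NULL` to use a
#'   default synthetic table).
#' @param policy A [filter_policy()].
#' @param allele_world An `allele_world` (or `NULL` for a synthetic one).
#' @param mrl_spec An [mrl_generator_spec()] for the training library.
#' @param model_config An [mrl_model_config()].
#' @param embedding An [embedding_spec()].
#' @param blueprint A [construct_blueprint()].
#' @param pool_sources Named list of pool sources
#'   (see [build_candidate_pool()]); `NULL` for [reference_pool_sources()].
#' @param output_dir Directory for the report bundle, or `NULL` to skip
#'   writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            candidate_spec = NULL,
                            policy = filter_policy(),
                            allele_world = NULL,
                            mrl_spec = NULL,
                            model_config = NULL,
                            embedding = embedding_spec(),
                            blueprint = construct_blueprint(),
                            pool_sources = NULL,
                            output_dir = NULL) {
  if (is.null(candidate_spec))
    candidate_spec <- candidate_generator_spec(60L, pass_fraction = 0.4,
                                               seed = seed + 1L)
  if (is.null(allele_world))
    allele_world <- gen_allele_world(4L, 6L, 30L, seed = seed + 2L)
  if (is.null(mrl_spec))
    mrl_spec <- mrl_generator_spec(1500L, seed = seed + 3L)
  if (is.null(model_config))
    model_config <- mrl_model_config(filters = 24L, fc_hidden = 48L,
                                     epochs = 12L, learning_rate = 3e-3,
                                     seed = seed + 4L)
  if (is.null(pool_sources))
    pool_sources <- reference_pool_sources(seed = seed + 5L)
  structure(list(seed = as.integer(seed), candidate_spec = candidate_spec,
                 policy = policy, allele_world = allele_world,
                 mrl_spec = mrl_spec, model_config = model_config,
                 embedding = embedding, blueprint = blueprint,
                 pool_sources = pool_sources, output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full vaccine-design pipeline
#'
#' Executes the stages in design order — epitope filtering, population
#' coverage, 5'UTR model training and candidate ranking, construct assembly
#' (protein and mRNA), physicochemical profiling, codon metrics — and
#' returns a machine-readable report. Epitopes for the construct are the
#' packaged reference set ([reference_epitopes()]); the filtering stage
#' demonstrates the triage on the configured synthetic candidates. The run
#' is deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list report with one entry per stage; if
#'   `config$output_dir` is set, also written there as `report.json` plus a
#'   plain-text summary.
#' @export
run_design <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  report <- list(seed = config$seed)

  say("stage 1/6: epitope filtering")
  cands <- gen_epitope_candidates(config$candidate_spec, config$policy)
  fl <- filter_epitopes(cands, config$policy)
  sel <- summarize_selection(fl$retained)
  report$filtering <- list(n_candidates = nrow(cands),
                           n_retained = nrow(fl$retained),
                           per_class = as.list(sel$per_class))

  say("stage 2/6: population coverage")
  world <- config$allele_world
  regions <- unique(world$freq$region)
  cov_rows <- lapply(regions, function(rg) {
    cv <- compute_coverage(world, rg)
    data.frame(region = rg, coverage = 100 * cv$coverage,
               average_hit = cv$average_hit, pc90 = cv$pc90,
               stringsAsFactors = FALSE)
  })
  cov_tab <- do.call(rbind, cov_rows)
  cov_sum <- if (nrow(cov_tab) > 0) summarize_regions(cov_tab) else NULL
  report$coverage <- list(table = cov_tab, summary = cov_sum)

  say("stage 3/6: 5'UTR screening model")
  lib <- gen_mrl_library(config$mrl_spec)
  lib <- split_mrl_dataset(lib, seed = config$seed + 10L)
  model <- train_mrl_model(lib, config$model_config, config$embedding)
  pool <- build_candidate_pool(config$pool_sources)
  pool <- predict_mrl(model, pool)
  top <- rank_candidates(pool, 10L)
  report$utr <- list(best_epoch = model$best_epoch,
                     validation = model$best_metrics,
                     pool_size = nrow(pool),
                     top_candidates = top)

  say("stage 4/6: construct assembly")
  ep <- reference_epitopes()
  bp <- config$blueprint
  if (!nzchar(bp$utr5)) bp$utr5 <- top$sequence[1L]
  construct <- assemble_protein(bp,
                                ep$sequence[ep$epitope_class == "HTL"],
                                ep$sequence[ep$epitope_class == "LBL"],
                                ep$sequence[ep$epitope_class == "CTL"])
  construct <- assemble_mrna(construct)
  vreport <- validate_construct(construct)
  report$construct <- list(protein_length = nchar(construct$protein),
                           mrna_length = nchar(construct$mrna),
                           block_counts = as.list(construct$block_counts),
                           checks_passed = all(vreport$pass))

  say("stage 5/6: physicochemical profile")
  prof <- protein_profile(construct$protein)
  report$protein <- prof[c("length", "molecular_weight", "pI",
                           "instability_index", "aliphatic_index", "gravy",
                           "half_life_class")]

  say("stage 6/6: codon metrics")
  orf_max <- optimize_codons(construct$protein, mode = "max_cai")
  orf_gc <- optimize_codons(construct$protein, mode = "gc_balance")
  report$codon <- list(
    cai_max_cai = cai(orf_max),
    gc_max_cai = gc_content(orf_max),
    cai_gc_balance = cai(orf_gc),
    gc_gc_balance = gc_content(orf_gc),
    mrna_gc = gc_content(construct$mrna))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report(report),
               file.path(config$output_dir, "summary.txt"))
  }
  invisible(report)
}

render_report <- function(report) {
  c(sprintf("mevax design run (seed %d)", report$seed),
    sprintf("epitope filtering: %d/%d retained",
            report$filtering$n_retained, report$filtering$n_candidates),
    if (!is.null(report$coverage$summary))
      sprintf("coverage: mean %.2f%% (max %s, %.2f%%)",
              report$coverage$summary$mean_coverage,
              report$coverage$summary$max_region,
              report$coverage$summary$max_coverage),
    sprintf("UTR model: best epoch %d, validation R2 %.3f",
            report$utr$best_epoch, report$utr$validation$r2),
    sprintf("construct: %d aa / %d nt, checks %s",
            report$construct$protein_length, report$construct$mrna_length,
            if (report$construct$checks_passed) "passed" else "FAILED"),
    sprintf("protein: MW %.1f Da, pI %.2f, II %.2f, AI %.2f, GRAVY %.3f",
            report$protein$molecular_weight, report$protein$pI,
            report$protein$instability_index, report$protein$aliphatic_index,
            report$protein$gravy),
    sprintf("codon: CAI (max_cai) %.3f, GC (gc_balance) %.2f%%",
            report$codon$cai_max_cai, report$codon$gc_gc_balance))
}
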