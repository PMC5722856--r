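#' Run the analysis pipeline end to end or stage by stage
#'
#' Orchestrates the stages of the integrative analysis from a configuration
#' list (or YAML file): `simulate` (synthetic multi-omics inputs),
#' `methylome` (windowed differential test, ratio curve, DMRs, mDMRs,
#' isoDMBs), `isochores` (GC-track segmentation), `integrate` (expression
#' stats, subsets, MCW tests, DEGs, coherence), `overlap` (isoDMB vs
#' isochore and gene Jaccard tests) and `atac` (QC, DAIs, class fractions,
#' shared DAIs, H2 clustering); `all` runs everything in order. Each stage
#' derives its own RNG stream from the global seed and the stage name, so a
#' rerun with the same configuration reproduces the same artifacts, and
#' every output is listed in a machine-readable JSON manifest.
#'
#' @param config A list, path to a YAML file, or `NULL` for defaults.
#'   Recognized entries: `seed`, `outdir`, `dmr_alpha` (default 0.001),
#'   `deg_alpha` (0.05), `dai_alpha` (0.05), `n_perm` (10000), `p_grid`,
#'   plus any [sim_config()] field under `sim`.
#' @param stage One of `simulate`, `methylome`, `isochores`, `integrate`,
#'   `overlap`, `atac`, `all`.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Seed (overrides `config$seed`).
#' @return Invisibly, a list with the stage results and the manifest path.
#' @export
run_pipeline <- function(config = NULL,
                         stage = c("all", "simulate", "methylome",
                                   "isochores", "integrate", "overlap",
                                   "atac"),
                         outdir = NULL, seed = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$outdir)) config$outdir <- "isodmb_run"
  defaults <- list(dmr_alpha = 0.001, deg_alpha = 0.05, dai_alpha = 0.05,
                   n_perm = 10000, p_grid = c(0.1, 0.05, 0.01, 0.005, 0.001))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("dmr_alpha", "deg_alpha", "dai_alpha")) {
    a <- config[[nm]]
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      stop("config error: ", nm, " must lie in (0, 1)")
    }
  }
  if (config$n_perm < 100) stop("config error: n_perm must be >= 100")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, c(list(seed = config$seed),
                                config$sim %||% list()))
  stages <- if (stage == "all") c("simulate", "methylome", "isochores",
                                  "integrate", "overlap", "atac") else stage
  res <- list()
  manifest <- list(seed = config$seed, parameters = config[names(defaults)],
                   outputs = list())
  log_out <- function(stage, name, path) {
    manifest$outputs[[length(manifest$outputs) + 1L]] <<-
      list(stage = stage, name = name, path = path)
    path
  }
  od <- function(...) file.path(config$outdir, ...)

  sim <- NULL
  need_sim <- function() {
    if (is.null(sim)) {
      sim_path <- od("sim.rds_dir")
      sim <<- simulate_genome(scfg)
    }
    sim
  }

  for (st in stages) {
    if (st == "simulate") {
      sim <- need_sim()
      write_chrom_sizes(sim$layout, log_out(st, "chrom_sizes",
                                            od("chrom.sizes")))
      write_isochores_bed(sim$isochores,
                          log_out(st, "isochores_truth",
                                  od("truth_isochores.bed")))
      write_gene_table(sim$genes, log_out(st, "genes", od("genes.tsv")))
      utils::write.table(sim$truth_blocks,
                         log_out(st, "truth_blocks", od("truth_blocks.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      meth <- simulate_methylome(sim)
      write_count_matrix(meth, log_out(st, "methylome_counts",
                                       od("methylome_counts.tsv")))
      expr <- simulate_expression(sim)
      write_count_matrix(expr, log_out(st, "expression_counts",
                                       od("expression_counts.tsv")))
      utils::write.table(attr(expr, "truth"),
                         log_out(st, "truth_expression",
                                 od("truth_expression.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      atac <- simulate_atac(sim)
      for (g in atac$generations) {
        write_count_matrix(atac$counts[[g]],
                           log_out(st, paste0("atac_counts_", g),
                                   od(paste0("atac_counts_", g, ".tsv"))))
      }
      res$simulate <- list(sim = sim, methylome = meth, expression = expr,
                           atac = atac)
    } else if (st == "methylome") {
      sim <- need_sim()
      meth <- res$simulate$methylome %||% simulate_methylome(sim)
      grid <- attr(meth, "grid")
      diff <- diff_test(meth, control = "DMSO", treatment = "TBT")
      curve <- ratio_curve(diff, grid, sim$layout, p_grid = config$p_grid)
      utils::write.table(as.data.frame(curve),
                         log_out(st, "ratio_curve", od("ratio_curve.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dmrs <- call_dmrs(diff, grid, alpha = config$dmr_alpha)
      write_region_bed(dmrs, log_out(st, "dmrs", od("dmrs.bed")))
      mdmrs <- merge_mdmrs(dmrs)
      write_region_bed(mdmrs, log_out(st, "mdmrs", od("mdmrs.bed")))
      blocks <- build_isodmbs(dmrs)
      write_region_bed(blocks, log_out(st, "isodmbs", od("isodmbs.bed")))
      res$methylome <- list(diff = diff, curve = curve, dmrs = dmrs,
                            mdmrs = mdmrs, isodmbs = blocks, grid = grid)
    } else if (st == "isochores") {
      sim <- need_sim()
      iso <- segment_isochores(sim$gc_track)
      write_isochores_bed(iso, log_out(st, "isochores",
                                       od("isochores.bed")))
      res$isochores <- iso
    } else if (st == "integrate") {
      sim <- need_sim()
      if (is.null(res$methylome)) {
        stop("missing upstream artifact: run stage 'methylome' first")
      }
      expr <- res$simulate$expression %||% simulate_expression(sim)
      stats <- expression_stats(expr, genes = sim$genes,
                                control = "DMSO", treatment = "TBT")
      subsets <- assign_subsets(sim$genes, res$methylome$dmrs,
                                res$methylome$isodmbs, sim$layout)
      mcw <- list()
      for (ss in c("I", "II", "III")) {
        for (dir in c("hyper", "hypo")) {
          ids <- intersect(
            subsets$gene_id[subsets[[paste0(ss, "_", dir)]]],
            stats$gene_id)
          if (length(ids) == 0L) next
          for (sc in c("mean", "cv")) {
            key <- paste(ss, dir, sc, sep = "_")
            mcw[[key]] <- mcw_test(stats, ids, statistic = sc,
                                   n_perm = config$n_perm,
                                   seed = stage_seed(config$seed, key))
          }
        }
      }
      mcw_tab <- do.call(rbind, lapply(names(mcw), function(k) {
        m <- mcw[[k]]
        data.frame(test = k, n_genes = m$n_genes, bias = m$b_observed,
                   p_upper = m$p_upper, p_lower = m$p_lower)
      }))
      utils::write.table(mcw_tab, log_out(st, "mcw_tests",
                                          od("mcw_tests.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dge <- diff_test(expr, control = "DMSO", treatment = "TBT")
      degs <- call_degs(dge, alpha = config$deg_alpha)
      utils::write.table(degs, log_out(st, "degs", od("degs.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      coh <- coherence_test(res$methylome$isodmbs,
                            degs[degs$gene_id %in% stats$gene_id, ],
                            sim$genes, stats$gene_id,
                            n_perm = config$n_perm,
                            seed = stage_seed(config$seed, "coherence"))
      utils::write.table(coh$table, log_out(st, "coherence",
                                            od("coherence.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$integrate <- list(stats = stats, subsets = subsets, mcw = mcw,
                            degs = degs, coherence = coh)
    } else if (st == "overlap") {
      sim <- need_sim()
      if (is.null(res$methylome)) {
        stop("missing upstream artifact: run stage 'methylome' first")
      }
      blocks <- res$methylome$isodmbs
      tests <- list()
      for (dir in c("hyper", "hypo")) {
        q <- blocks[blocks$direction == dir, , drop = FALSE]
        if (nrow(q) == 0L) next
        tests[[paste0(dir, "_genes")]] <- overlap_mc_test(
          q, sim$genes, sim$layout, n = config$n_perm,
          seed = stage_seed(config$seed, paste0("ovl_genes_", dir)))
        gc_rich <- sim$isochores[sim$isochores$class %in%
                                   c("H1", "H2", "H3"), , drop = FALSE]
        tests[[paste0(dir, "_gc_rich")]] <- overlap_mc_test(
          q, gc_rich, sim$layout, n = config$n_perm,
          seed = stage_seed(config$seed, paste0("ovl_gc_", dir)))
      }
      tab <- do.call(rbind, lapply(names(tests), function(k) {
        t <- tests[[k]]
        data.frame(test = k, j_observed = t$j_observed,
                   null_mean = t$null_mean, null_sd = t$null_sd,
                   p_upper = t$p_upper, p_lower = t$p_lower)
      }))
      utils::write.table(tab, log_out(st, "overlap_tests",
                                      od("overlap_tests.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$overlap <- tests
    } else if (st == "atac") {
      sim <- need_sim()
      atac <- res$simulate$atac %||% simulate_atac(sim)
      grid <- NULL
      dais <- list()
      for (g in atac$generations) {
        cm <- atac$counts[[g]]
        qc <- qc_filter(cm, region_bp = sum(sim$isochores$end -
                                              sim$isochores$start))
        utils::write.table(qc$qc, log_out(st, paste0("atac_qc_", g),
                                          od(paste0("atac_qc_", g, ".tsv"))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dais[[g]] <- call_dais(qc$passed, sim$isochores,
                               alpha = config$dai_alpha,
                               control = "DMSO", treatment = "TBT",
                               generation = g)
        utils::write.table(as.data.frame(dais[[g]]),
                           log_out(st, paste0("dais_", g),
                                   od(paste0("dais_", g, ".tsv"))),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      fr <- dai_class_fractions(dais[[1]], n_perm = config$n_perm,
                                seed = stage_seed(config$seed, "daifrac"))
      utils::write.table(fr, log_out(st, "dai_class_fractions",
                                     od("dai_class_fractions.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sh <- shared_dais(dais[[1]], dais[[2]], n_perm = config$n_perm,
                        seed = stage_seed(config$seed, "daishared"))
      h2 <- which(sim$isochores$class == "H2")
      both <- count_matrix(
        cbind(atac$counts[[1]]$counts, atac$counts[[2]]$counts)[h2, ,
                                                                drop = FALSE],
        samples = rbind(atac$counts[[1]]$samples, atac$counts[[2]]$samples))
      clus <- tryCatch(cluster_samples(both), error = function(e) {
        warning("H2-guided clustering unavailable: ", conditionMessage(e))
        NULL
      })
      if (!is.null(clus)) {
        writeLines(clus$newick, log_out(st, "dendrogram",
                                        od("atac_h2_dendrogram.nwk")))
      }
      res$atac <- list(dais = dais, fractions = fr, shared = sh,
                       clustering = clus)
    }
  }
  manifest_path <- od("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest_path
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
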