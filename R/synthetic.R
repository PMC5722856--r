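#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every tunable of the simulator with defaults emulating the study
#' design the analysis targets: a small mammal-like genome segmented into
#' GC-homogeneous isochores, genes concentrated in GC-rich DNA, an MBD-seq
#' style windowed methylome with planted direction-consistent blocks (hyper
#' preferentially in AT-rich, hypo in GC-rich DNA), an RNA-seq transcriptome
#' with coordinated expression shifts for genes inside planted blocks, and
#' two "generations" of ATAC accessibility counts with treatment effects by
#' isochore class partially shared between generations.
#'
#' @param seed Integer seed fixing every draw.
#' @param n_chrom Number of chromosomes (default 3).
#' @param chrom_length Chromosome length in bp (default 5e6).
#' @param iso_mean_length Mean isochore segment length, exponential
#'   (default 3e5 bp; minimum 1e4, rounded to 1 kb).
#' @param class_probs Sampling probabilities of classes L1, L2, H1, H2, H3
#'   per segment.
#' @param class_gc Mean percent GC per class.
#' @param gc_sd Within-segment GC standard deviation across 1-kb bins.
#' @param gene_density_weights Relative per-bp gene density for L1..H3.
#' @param n_genes Number of genes (default 800).
#' @param gene_length_meanlog,gene_length_sdlog Lognormal gene length
#'   (median 10 kb).
#' @param n_blocks_per_chrom Planted methylation blocks per direction per
#'   chromosome (default 2).
#' @param block_length_range Planted block length range in bp (default
#'   500-800 kb: chromosome-domain scale, so blocks typically span several
#'   isochore segments around their anchor and the methylome change is
#'   global rather than locus-restricted).
#' @param block_class_pref Probability a block is anchored on a segment of
#'   its preferred class (hyper on L1/L2, hypo on H1/H2/H3).
#' @param mu_methyl Baseline NB mean per 100-bp methylome window (default
#'   10).
#' @param phi_methyl NB dispersion of methylome counts (variance
#'   mu + phi mu^2; default 0.1).
#' @param effect_size Methylation fold change inside planted blocks
#'   (treatment mean x effect inside hyper, / effect inside hypo; 1 = null).
#' @param n_rep_methyl Replicates per group for the methylome (default 4).
#' @param expr_meanlog,expr_sdlog Lognormal baseline expression counts.
#' @param phi_expr NB dispersion of expression counts (default 0.05).
#' @param expr_delta Planted |log2 fold change| for genes inside blocks
#'   (+ in hypo, - in hyper; default 1).
#' @param expr_pi Probability a gene inside a block receives the planted
#'   effect (default 0.6; 0 = null).
#' @param n_rep_expr Replicates per group for the transcriptome (default 4).
#' @param atac_rate Baseline ATAC reads per kb of isochore (default 5).
#' @param phi_atac NB dispersion of ATAC counts (default 0.01).
#' @param atac_effect_h,atac_effect_l Treatment multiplier for affected
#'   H2/H3 (default 0.7) and L1/L2 (default 1.3) isochores.
#' @param atac_affect_frac Fraction of candidate isochores affected per
#'   generation (default 0.6; 0 = null).
#' @param shared_fraction Fraction of each generation's affected isochores
#'   shared with the other generation (default 0.5).
#' @param n_rep_atac Replicates per group per generation (default 6).
#' @param atac_efficiency_range Uniform range of simulated in-region
#'   efficiency used to back out total read counts for QC.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 3,
                       chrom_length = 5e6,
                       iso_mean_length = 3e5,
                       class_probs = c(L1 = 0.18, L2 = 0.27, H1 = 0.25,
                                       H2 = 0.20, H3 = 0.10),
                       class_gc = c(L1 = 32, L2 = 39, H1 = 44, H2 = 49.5,
                                    H3 = 56),
                       gc_sd = 1.5,
                       gene_density_weights = c(L1 = 1, L2 = 2, H1 = 4,
                                                H2 = 6, H3 = 8),
                       n_genes = 800,
                       gene_length_meanlog = log(1e4),
                       gene_length_sdlog = 0.5,
                       n_blocks_per_chrom = 2,
                       block_length_range = c(5e5, 8e5),
                       block_class_pref = 0.85,
                       mu_methyl = 10,
                       phi_methyl = 0.1,
                       effect_size = 2.0,
                       n_rep_methyl = 4,
                       expr_meanlog = log(150),
                       expr_sdlog = 1,
                       phi_expr = 0.05,
                       expr_delta = 1,
                       expr_pi = 0.6,
                       n_rep_expr = 4,
                       atac_rate = 5,
                       phi_atac = 0.01,
                       atac_effect_h = 0.7,
                       atac_effect_l = 1.3,
                       atac_affect_frac = 0.6,
                       shared_fraction = 0.5,
                       n_rep_atac = 6,
                       atac_efficiency_range = c(0.4, 0.7)) {
  cfg <- as.list(environment())
  stopifnot(cfg$chrom_length > 0, cfg$iso_mean_length > 0,
            cfg$mu_methyl > 0, cfg$effect_size > 0,
            all(cfg$class_probs >= 0), sum(cfg$class_probs) > 0)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  cfg$class_probs <- cfg$class_probs / sum(cfg$class_probs)
  cls <- c("L1", "L2", "H1", "H2", "H3")
  if (is.null(names(cfg$class_probs))) names(cfg$class_probs) <- cls
  if (is.null(names(cfg$class_gc))) names(cfg$class_gc) <- cls
  if (is.null(names(cfg$gene_density_weights))) {
    names(cfg$gene_density_weights) <- cls
  }
  class(cfg) <- "sim_config"
  cfg
}

# Reproducible per-stage sub-seed so stages rerun independently; kept below
# 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 17477L +
    sum(utf8ToInt(stage)) * 131L
}

#' Simulate a genome: layout, isochores, GC track and gene annotation
#'
#' Isochore segments (exponential lengths, class-specific GC) tile each
#' chromosome; a noisy 1-kb GC track is drawn around the segment means;
#' genes with lognormal lengths are placed without overlap, with per-class
#' placement probability proportional to class footprint times the density
#' weight; planted methylation block coordinates are chosen inside
#' preferred-class segments without overlapping each other.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_genome`: `layout`, `isochores`
#'   (truth `isochore_set`), `gc_track` (1-kb bins), `genes`,
#'   `truth_blocks` (data frame `chrom`, `start`, `end`, `direction`),
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(stage_seed(config$seed, "genome"))
  classes <- names(config$class_probs)
  layout <- genome_layout(paste0("chr", seq_len(config$n_chrom)),
                          rep(config$chrom_length, config$n_chrom))
  segs <- list()
  for (ch in layout$chrom) {
    pos <- 0
    while (pos < config$chrom_length) {
      len <- max(1e4, round(stats::rexp(1, 1 / config$iso_mean_length) /
                              1000) * 1000)
      len <- min(len, config$chrom_length - pos)
      cls <- sample(classes, 1, prob = config$class_probs)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = pos + len,
        class = cls, stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  iso <- do.call(rbind, segs)
  # noisy per-kb GC around the class mean; segment mean GC recorded as truth
  gc_bins <- lapply(seq_len(nrow(iso)), function(i) {
    starts <- seq.int(iso$start[i], iso$end[i] - 1, by = 1000)
    gc <- stats::rnorm(length(starts), config$class_gc[[iso$class[i]]],
                       config$gc_sd)
    data.frame(chrom = iso$chrom[i], start = starts,
               end = pmin(starts + 1000, iso$end[i]),
               gc = pmin(100, pmax(0, gc)), stringsAsFactors = FALSE)
  })
  gc_track <- do.call(rbind, gc_bins)
  iso$gc <- vapply(seq_len(nrow(iso)), function(i) {
    mean(gc_track$gc[gc_track$chrom == iso$chrom[i] &
                       gc_track$start >= iso$start[i] &
                       gc_track$start < iso$end[i]])
  }, 0)
  iso <- classify_truth(iso)

  genes <- place_genes(iso, layout, config)
  blocks <- place_blocks(iso, config)
  structure(list(layout = layout, isochores = iso, gc_track = gc_track,
                 genes = genes, truth_blocks = blocks, config = config),
            class = "sim_genome")
}

# truth isochores keep their drawn class label (classification thresholds
# are tested separately on the realized GC)
classify_truth <- function(iso) {
  out <- iso[, c("chrom", "start", "end", "gc", "class")]
  class(out) <- c("isochore_set", "data.frame")
  out
}

place_genes <- function(iso, layout, config) {
  w <- config$gene_density_weights[iso$class] * (iso$end - iso$start)
  occupied <- lapply(layout$chrom, function(ch) {
    data.frame(start = numeric(0), end = numeric(0))
  })
  names(occupied) <- layout$chrom
  genes <- vector("list", config$n_genes)
  max_tries <- 200L * config$n_genes
  tries <- 0L
  placed <- 0L
  while (placed < config$n_genes) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("gene placement failed after ", max_tries,
           " attempts; lower n_genes or gene lengths")
    }
    len <- max(1000, round(stats::rlnorm(1, config$gene_length_meanlog,
                                         config$gene_length_sdlog)))
    i <- sample.int(nrow(iso), 1, prob = w)
    seg_len <- iso$end[i] - iso$start[i]
    if (len >= seg_len) next
    start <- iso$start[i] + floor(stats::runif(1) * (seg_len - len))
    end <- start + len
    occ <- occupied[[iso$chrom[i]]]
    if (nrow(occ) && any(start < occ$end & end > occ$start)) next
    occupied[[iso$chrom[i]]] <- rbind(occ, data.frame(start = start,
                                                      end = end))
    placed <- placed + 1L
    genes[[placed]] <- data.frame(
      chrom = iso$chrom[i], start = start, end = end,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes <- genes[order(match(genes$chrom, layout$chrom), genes$start), ]
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(nrow(genes))),
                      genes, stringsAsFactors = FALSE, row.names = NULL)
  genes$tss <- gene_tss(genes)
  genes
}

# Blocks are anchored on (centered over) a segment of the preferred class
# and may spill across neighboring segments: planted methylation domains are
# regional, larger than single isochores, but biased toward a base
# composition class.
place_blocks <- function(iso, config) {
  pref <- list(hyper = c("L1", "L2"), hypo = c("H1", "H2", "H3"))
  chrom_len <- tapply(iso$end, iso$chrom, max)
  blocks <- list()
  for (ch in unique(iso$chrom)) {
    occ <- data.frame(start = numeric(0), end = numeric(0))
    for (dir in c("hyper", "hypo")) {
      placed <- 0L
      tries <- 0L
      while (placed < config$n_blocks_per_chrom && tries < 2000L) {
        tries <- tries + 1L
        use_pref <- stats::runif(1) < config$block_class_pref
        cand <- iso[iso$chrom == ch &
                      (if (use_pref) iso$class %in% pref[[dir]] else TRUE), ,
                    drop = FALSE]
        if (nrow(cand) == 0L) next
        len <- round(stats::runif(1, config$block_length_range[1],
                                  config$block_length_range[2]) / 100) * 100
        i <- sample.int(nrow(cand), 1, prob = cand$end - cand$start)
        center <- (cand$start[i] + cand$end[i]) / 2
        start <- max(0, round((center - len / 2) / 100) * 100)
        end <- min(chrom_len[[ch]], start + len)
        if (nrow(occ) && any(start < occ$end & end > occ$start)) next
        occ <- rbind(occ, data.frame(start = start, end = end))
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom = ch, start = start, end = end, direction = dir,
          stringsAsFactors = FALSE)
        placed <- placed + 1L
      }
    }
  }
  out <- do.call(rbind, blocks)
  out[order(match(out$chrom, unique(iso$chrom)), out$start), , drop = FALSE]
}

# monotone GC -> coverage proxy shared by the methylome simulator
gc_coverage_factor <- function(gc) 0.5 + gc / 100

#' Simulate MBD-seq style windowed methylome counts
#'
#' Negative-binomial counts per 100-bp grid window and sample, with mean
#' `mu_methyl * g(GC)` where `g(GC) = 0.5 + GC/100` is a monotone CpG-density
#' proxy evaluated on the window's 1-kb GC bin. Treatment samples multiply
#' the mean by `effect_size` inside planted hyper blocks and divide by it
#' inside planted hypo blocks.
#'
#' @param sim A `sim_genome`.
#' @param config Defaults to `sim$config`.
#' @return A [count_matrix()] of windows (`w<index>`) x samples with groups
#'   DMSO (control) and TBT (treatment); attributes `grid` and
#'   `truth_blocks`.
#' @export
simulate_methylome <- function(sim, config = sim$config) {
  set.seed(stage_seed(config$seed, "methylome"))
  grid <- build_window_grid(sim$layout, width = 100)
  # GC of each window = GC of its containing 1-kb bin
  key_track <- paste0(sim$gc_track$chrom, ":", sim$gc_track$start %/% 1000)
  key_win <- paste0(grid$chrom, ":", grid$start %/% 1000)
  gc <- sim$gc_track$gc[match(key_win, key_track)]
  mu0 <- config$mu_methyl * gc_coverage_factor(gc)
  eff <- rep(1, nrow(grid))
  tb <- sim$truth_blocks
  if (!is.null(tb) && nrow(tb)) {
    gr_w <- intervals_to_gr(grid)
    for (dir in c("hyper", "hypo")) {
      sub <- tb[tb$direction == dir, , drop = FALSE]
      if (!nrow(sub)) next
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_w, intervals_to_gr(sub))))
      eff[hit] <- if (dir == "hyper") config$effect_size else
        1 / config$effect_size
    }
  }
  n <- config$n_rep_methyl
  size <- 1 / config$phi_methyl
  draw <- function(mu) stats::rnbinom(length(mu), size = size, mu = mu)
  ctrl <- vapply(seq_len(n), function(i) draw(mu0), numeric(nrow(grid)))
  trt <- vapply(seq_len(n), function(i) draw(mu0 * eff), numeric(nrow(grid)))
  m <- cbind(ctrl, trt)
  dimnames(m) <- list(paste0("w", grid$window),
                      c(paste0("DMSO_", seq_len(n)),
                        paste0("TBT_", seq_len(n))))
  out <- count_matrix(m, groups = rep(c("DMSO", "TBT"), each = n))
  attr(out, "grid") <- grid
  attr(out, "truth_blocks") <- tb
  out
}

#' Simulate RNA-seq style gene counts with coordinated planted effects
#'
#' Per-gene NB counts around a lognormal baseline. Genes whose body overlaps
#' a planted hypo block receive a `+expr_delta` log2 fold change in the
#' treatment group with probability `expr_pi`; genes in hyper blocks receive
#' `-expr_delta`; all other genes are unchanged.
#'
#' @param sim A `sim_genome`.
#' @param config Defaults to `sim$config`.
#' @return A [count_matrix()] of genes x samples (groups DMSO/TBT) with
#'   attribute `truth` (data frame `gene_id`, `block_direction`, `lfc`).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  set.seed(stage_seed(config$seed, "expression"))
  genes <- sim$genes
  base <- stats::rlnorm(nrow(genes), config$expr_meanlog, config$expr_sdlog)
  block_dir <- rep("none", nrow(genes))
  tb <- sim$truth_blocks
  if (!is.null(tb) && nrow(tb)) {
    gr_g <- genes_to_gr(genes)
    for (dir in c("hyper", "hypo")) {
      sub <- tb[tb$direction == dir, , drop = FALSE]
      if (!nrow(sub)) next
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_g, intervals_to_gr(sub))))
      block_dir[hit] <- dir
    }
  }
  lfc <- rep(0, nrow(genes))
  inside <- block_dir != "none"
  gets <- inside & stats::runif(nrow(genes)) < config$expr_pi
  lfc[gets & block_dir == "hypo"] <- config$expr_delta
  lfc[gets & block_dir == "hyper"] <- -config$expr_delta
  n <- config$n_rep_expr
  size <- 1 / config$phi_expr
  draw <- function(mu) stats::rnbinom(length(mu), size = size, mu = mu)
  ctrl <- vapply(seq_len(n), function(i) draw(base), numeric(nrow(genes)))
  trt <- vapply(seq_len(n), function(i) draw(base * 2^lfc),
                numeric(nrow(genes)))
  m <- cbind(ctrl, trt)
  dimnames(m) <- list(genes$gene_id,
                      c(paste0("DMSO_", seq_len(n)),
                        paste0("TBT_", seq_len(n))))
  out <- count_matrix(m, groups = rep(c("DMSO", "TBT"), each = n))
  attr(out, "truth") <- data.frame(gene_id = genes$gene_id,
                                   block_direction = block_dir, lfc = lfc,
                                   stringsAsFactors = FALSE)
  out
}

#' Simulate per-isochore ATAC accessibility counts for two generations
#'
#' Baseline NB mean proportional to isochore length (`atac_rate` reads/kb).
#' Per generation, a fraction of H2/H3 isochores has its treatment mean
#' multiplied by `atac_effect_h` (closing) and a fraction of L1/L2 isochores
#' by `atac_effect_l` (opening); the affected sets of the two generations
#' overlap by `shared_fraction`. Total sequenced reads per sample are backed
#' out from a uniform efficiency draw so QC filters can be exercised.
#'
#' @param sim A `sim_genome`.
#' @param config Defaults to `sim$config`.
#' @param generations Labels (default `c("F3", "F4")`).
#' @return List of class `sim_atac`: one [count_matrix()] per generation
#'   (isochores x samples, groups DMSO/TBT, sample metadata with
#'   `generation` and `total_reads`), plus `truth` (per generation the
#'   affected isochore indices) and `isochores`.
#' @export
simulate_atac <- function(sim, config = sim$config,
                          generations = c("F3", "F4")) {
  if (config$shared_fraction < 0 || config$shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  set.seed(stage_seed(config$seed, "atac"))
  iso <- sim$isochores
  mu0 <- config$atac_rate * (iso$end - iso$start) / 1000
  cand_h <- which(iso$class %in% c("H2", "H3"))
  cand_l <- which(iso$class %in% c("L1", "L2"))
  # affected sets drawn class by class, so every class carries its share of
  # the planted effect (and of the between-generation overlap)
  resample <- function(x, n) x[sample.int(length(x), min(n, length(x)))]
  pick_sets <- function(cand) {
    n_aff <- round(config$atac_affect_frac * length(cand))
    n_shared <- round(config$shared_fraction * n_aff)
    shared <- resample(cand, n_shared)
    rest <- setdiff(cand, shared)
    extra_a <- resample(rest, n_aff - length(shared))
    extra_b <- resample(setdiff(rest, extra_a), n_aff - length(shared))
    list(a = c(shared, extra_a), b = c(shared, extra_b))
  }
  per_class <- lapply(c("H2", "H3", "L1", "L2"), function(cl)
    pick_sets(which(iso$class == cl)))
  aff <- list(unlist(lapply(per_class, `[[`, "a")),
              unlist(lapply(per_class, `[[`, "b")))
  names(aff) <- generations
  n <- config$n_rep_atac
  size <- 1 / config$phi_atac
  out <- list()
  for (g in generations) {
    eff <- rep(1, nrow(iso))
    ha <- intersect(aff[[g]], cand_h)
    la <- intersect(aff[[g]], cand_l)
    eff[ha] <- config$atac_effect_h
    eff[la] <- config$atac_effect_l
    draw <- function(mult) vapply(seq_len(n), function(i)
      stats::rnbinom(nrow(iso), size = size, mu = mu0 * mult),
      numeric(nrow(iso)))
    m <- cbind(draw(rep(1, nrow(iso))), draw(eff))
    dimnames(m) <- list(paste0(iso$chrom, ":", iso$start, "-", iso$end),
                        paste0(g, "_", rep(c("DMSO", "TBT"), each = n),
                               "_", rep(seq_len(n), 2)))
    effc <- stats::runif(2 * n, config$atac_efficiency_range[1],
                         config$atac_efficiency_range[2])
    samples <- data.frame(
      sample = colnames(m),
      group = rep(c("DMSO", "TBT"), each = n),
      generation = g,
      total_reads = round(colSums(m) / effc),
      stringsAsFactors = FALSE)
    out[[g]] <- count_matrix(m, samples = samples)
  }
  structure(list(counts = out, truth = aff, isochores = iso,
                 generations = generations),
            class = "sim_atac")
}
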