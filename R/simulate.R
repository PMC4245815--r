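#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate a
#' lincRNA-like study design: catalogue-scale lincRNA gene geometry (about 2.9 exons per
#' gene, exon lengths around 400 bp, introns around 2.5 kb), a human-macaque
#' level of neutral divergence (0.07 substitutions/site split evenly over two
#' lineages), ESE bases evolving 15% slower than their surroundings, non-ESE
#' exonic sequence evolving at the intronic rate, transition bias kappa = 2,
#' slightly different GC targets per lineage (so the heterogeneity-corrected
#' distance has something to correct), a low indel rate, ESE planting decaying
#' with distance from the splice junction (targeting 30-40% flank density),
#' a 24-tissue expression table, and peak tracks whose density covaries with
#' intron density and activity status.
#'
#' @param n_genes number of genes.
#' @param mean_exons mean exon count (`1 + Poisson(mean_exons - 1)`).
#' @param exon_meanlog,exon_sdlog,exon_min,exon_max lognormal exon-length
#'   model (bp), clamped.
#' @param intron_meanlog,intron_sdlog,intron_min,intron_max intron-length
#'   model (bp), clamped.
#' @param frac_minus fraction of genes on the minus strand.
#' @param neutral_divergence expected substitutions/site on unconstrained
#'   sites, summed over both lineages.
#' @param ese_rate_multiplier,flank_nonese_multiplier,core_multiplier,intron_multiplier
#'   per-class rate multipliers (> 0) applied to the neutral divergence.
#' @param kappa transition/transversion rate bias.
#' @param gc_ancestral ancestral GC content.
#' @param gc_lineage length-2 vector of per-lineage GC targets biasing the
#'   substitution exchange matrix (reference lineage first).
#' @param indel_rate indel events per ancestral site.
#' @param indel_avoid_ese if `TRUE` (default) indels are never placed inside
#'   planted ESEs.
#' @param ese_hexamers [hexamer_set()] used for planting and scanning.
#' @param plant_p0,plant_decay planting probability per candidate hexamer
#'   start: `plant_p0 * exp(-(d - 1)/plant_decay)` with `d` the distance of
#'   the hexamer to its nearest splice junction.
#' @param flank_bp flank width used for the true site classes.
#' @param n_tissues number of tissues in the expression table.
#' @param expr_meanlog,expr_sdlog lognormal FPKM model for expressed
#'   gene-tissue pairs.
#' @param breadth_shape Beta parameters of per-gene expression breadth.
#' @param expr_rate_rho Gaussian-copula correlation planted between a gene's
#'   expression breadth and its true ESE density (0 = none).
#' @param cell_types cell types for peaks/activity labels.
#' @param activity_rate probability that a gene is active in a cell type.
#' @param chd1_base,chd1_active_slope,chd1_inactive_slope CHD1 peak intensity
#'   per bp: `base + slope * intron_density`, floored at 0, with the slope
#'   depending on activity status.
#' @param dhs_body_base,dhs_body_slope DHS intensity inside gene bodies.
#' @param dhs_flank_base,dhs_flank_amp,dhs_flank_decay DHS intensity in gene
#'   flanks: `base + amp * exp(-d/decay)` around active genes (`base` only
#'   around inactive ones), `d` = distance from the gene edge.
#' @param dhs_span bp of flank on each side receiving DHS peaks.
#' @param peak_width range (min, max) of simulated peak widths.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 500L, mean_exons = 2.9,
                       exon_meanlog = log(400), exon_sdlog = 0.45,
                       exon_min = 60L, exon_max = 3000L,
                       intron_meanlog = log(2500), intron_sdlog = 0.7,
                       intron_min = 150L, intron_max = 20000L,
                       frac_minus = 0.1,
                       neutral_divergence = 0.07,
                       ese_rate_multiplier = 0.85,
                       flank_nonese_multiplier = 1.0,
                       core_multiplier = 1.0,
                       intron_multiplier = 1.0,
                       kappa = 2, gc_ancestral = 0.35,
                       gc_lineage = c(0.33, 0.37),
                       indel_rate = 0.002, indel_avoid_ese = TRUE,
                       ese_hexamers = default_ese_hexamers(),
                       plant_p0 = 0.15, plant_decay = 50,
                       flank_bp = 70L,
                       n_tissues = 24L, expr_meanlog = 1, expr_sdlog = 1.2,
                       breadth_shape = c(1.2, 1.8), expr_rate_rho = 0,
                       cell_types = c("H1", "K562"), activity_rate = 0.3,
                       chd1_base = 3e-5, chd1_active_slope = 0.3,
                       chd1_inactive_slope = -0.02,
                       dhs_body_base = 3e-5, dhs_body_slope = 0.3,
                       dhs_flank_base = 1e-5, dhs_flank_amp = 6e-5,
                       dhs_flank_decay = 30000, dhs_span = 100000L,
                       peak_width = c(200L, 800L)) {
  cfg <- as.list(environment())
  mult <- c(cfg$ese_rate_multiplier, cfg$flank_nonese_multiplier,
            cfg$core_multiplier, cfg$intron_multiplier)
  if (any(mult <= 0)) stop("rate multipliers must be > 0")
  if (cfg$neutral_divergence < 0 || cfg$neutral_divergence >= 1)
    stop("neutral_divergence must be in [0, 1)")
  if (any(cfg$gc_lineage < 0 | cfg$gc_lineage > 1) ||
      cfg$gc_ancestral < 0 || cfg$gc_ancestral > 1)
    stop("GC contents must be in [0, 1]")
  if (cfg$exon_min < 1 || cfg$intron_min < 1) stop("lengths must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# draw iid bases at a given GC content (internal)
draw_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# substitute bases given kappa bias and a lineage GC target (internal)
mutate_bases <- function(b, kappa, gc) {
  bases <- c("A", "C", "G", "T")
  pi <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  out <- character(length(b))
  for (a in bases) {
    idx <- which(b == a)
    if (!length(idx)) next
    targets <- setdiff(bases, a)
    w <- pi[targets] * ifelse(targets == transition_of[[a]], kappa, 1)
    out[idx] <- sample(targets, length(idx), replace = TRUE, prob = w)
  }
  out
}

#' Simulate gene models with ancestral sequences and true site classes
#'
#' Draws exon/intron structures from the configured distributions, places the
#' genes along one synthetic chromosome with wide intergenic spacing, draws
#' ancestral sequence at the configured GC content, and plants ESE hexamers
#' in exons with probability decaying with distance from the nearest splice
#' junction. Every exonic site receives a true class (`ESE`, `flank`, or
#' `core`, using the midpoint-capped flank rule); intronic sites are class
#' `intron`. Planted hexamers never span a splice junction and never overlap
#' each other; exons shorter than a hexamer are skipped with a warning.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of class `"sim_genes"`: `genes` (list of [gene_model()]),
#'   `seqs` (per gene: `exon_seq`, `exon_block`, `exon_class`, `intron_seq`,
#'   `intron_block`, all in transcript orientation over ungapped ancestral =
#'   reference coordinates), `config`, and attribute `chrom_sizes`.
#' @export
simulate_gene_models <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_genes
  genes <- vector("list", n)
  seqs <- vector("list", n)
  cursor <- 0L
  chrom <- "chrS"
  warned_short <- FALSE
  for (i in seq_len(n)) {
    ne <- 1L + stats::rpois(1L, max(config$mean_exons - 1, 0))
    ex_len <- pmin(pmax(round(stats::rlnorm(ne, config$exon_meanlog,
                                            config$exon_sdlog)),
                        config$exon_min), config$exon_max)
    in_len <- if (ne > 1L)
      pmin(pmax(round(stats::rlnorm(ne - 1L, config$intron_meanlog,
                                    config$intron_sdlog)),
                config$intron_min), config$intron_max) else integer(0)
    strand <- if (stats::runif(1) < config$frac_minus) "-" else "+"
    cursor <- cursor + as.integer(round(stats::runif(1, 120000, 250000)))
    # genomic-order block lengths (transcript order reversed on minus strand)
    g_ex <- if (strand == "+") ex_len else rev(ex_len)
    g_in <- if (strand == "+") in_len else rev(in_len)
    starts <- integer(ne); ends <- integer(ne)
    pos <- cursor
    for (k in seq_len(ne)) {
      starts[k] <- pos; ends[k] <- pos + g_ex[k]
      pos <- ends[k] + if (k < ne) g_in[k] else 0L
    }
    gid <- sprintf("simg%04d", i)
    genes[[i]] <- gene_model(gid, chrom, cursor, ends[ne], strand,
                             cbind(starts, ends), biotype = "lincRNA")
    cursor <- ends[ne]
    # ancestral sequence + classes, transcript orientation
    exon_block <- rep(seq_len(ne), ex_len)
    exon_seq <- draw_bases(sum(ex_len), config$gc_ancestral)
    exon_class <- rep("core", sum(ex_len))
    offs <- c(0L, cumsum(ex_len))
    for (k in seq_len(ne)) {
      L <- ex_len[k]
      has5 <- k > 1L; has3 <- k < ne
      p <- seq_len(L)
      f5 <- if (has5 && has3) min(config$flank_bp, ceiling(L / 2))
            else if (has5) min(config$flank_bp, L) else 0L
      f3 <- if (has5 && has3) min(config$flank_bp, floor(L / 2))
            else if (has3) min(config$flank_bp, L) else 0L
      fl <- p <= f5 | p > L - f3
      exon_class[offs[k] + which(fl)] <- "flank"
      # ESE planting
      if (!(has5 || has3)) next
      if (L < 6L) {
        if (!warned_short) {
          warning("exon shorter than a hexamer: ESE planting skipped")
          warned_short <- TRUE
        }
        next
      }
      s <- seq_len(L - 5L)
      # candidate hexamers must lie entirely within a flank region
      d5 <- ifelse(has5 & s + 5L <= f5, s, Inf)
      d3 <- ifelse(has3 & s >= L - f3 + 1L, L - (s + 5L) + 1L, Inf)
      d <- pmin(d5, d3)
      accept <- which(stats::runif(length(s)) <
                        config$plant_p0 * exp(-(d - 1) / config$plant_decay))
      last_end <- 0L
      for (st in accept) {
        if (st <= last_end) next
        hx <- strsplit(sample(unclass(config$ese_hexamers), 1L), "")[[1L]]
        exon_seq[offs[k] + st:(st + 5L)] <- hx
        exon_class[offs[k] + st:(st + 5L)] <- "ESE"
        last_end <- st + 5L
      }
    }
    intron_block <- rep(seq_len(max(ne - 1L, 0L)), in_len)
    intron_seq <- draw_bases(sum(in_len), config$gc_ancestral)
    seqs[[i]] <- list(exon_seq = exon_seq, exon_block = exon_block,
                      exon_class = exon_class,
                      intron_seq = intron_seq, intron_block = intron_block)
  }
  structure(list(genes = genes, seqs = seqs, config = config),
            chrom_sizes = c(chrS = cursor + 150000L),
            class = "sim_genes")
}

# evolve one region (exon or intron array) into a gapped alignment pair;
# returns list(ref, oth, block) of equal-length character vectors (internal)
evolve_region <- function(anc, block, mult, config) {
  n <- length(anc)
  if (n == 0L) return(list(ref = character(0), oth = character(0),
                           block = integer(0)))
  t_lin <- config$neutral_divergence / 2
  ref <- anc; oth <- anc
  s1 <- which(stats::runif(n) < t_lin * mult)
  if (length(s1)) ref[s1] <- mutate_bases(anc[s1], config$kappa,
                                          config$gc_lineage[1L])
  s2 <- which(stats::runif(n) < t_lin * mult)
  if (length(s2)) oth[s2] <- mutate_bases(anc[s2], config$kappa,
                                          config$gc_lineage[2L])
  # indels: deletions in the other row, or insertions (other bases, ref gaps)
  n_ev <- stats::rpois(1L, config$indel_rate * n)
  ins_pos <- integer(0); ins_seq <- list()
  protected <- attr(anc, "ese") %||% rep(FALSE, n)
  for (e in seq_len(n_ev)) {
    len <- min(1L + stats::rgeom(1L, 0.5), 10L)
    pos <- sample.int(n, 1L)
    span <- pos:min(pos + len - 1L, n)
    if (config$indel_avoid_ese && any(protected[span])) next
    if (stats::runif(1) < 0.5) {
      oth[span] <- "-"
    } else {
      ins_pos <- c(ins_pos, pos)
      ins_seq <- c(ins_seq, list(draw_bases(len, config$gc_lineage[2L])))
    }
  }
  if (length(ins_pos)) {
    ord <- order(ins_pos)
    ins_pos <- ins_pos[ord]; ins_seq <- ins_seq[ord]
    pieces_r <- list(); pieces_o <- list(); pieces_b <- list()
    prev <- 0L
    for (j in seq_along(ins_pos)) {
      seg <- if (ins_pos[j] > prev) (prev + 1L):ins_pos[j] else integer(0)
      pieces_r[[length(pieces_r) + 1L]] <- ref[seg]
      pieces_o[[length(pieces_o) + 1L]] <- oth[seg]
      pieces_b[[length(pieces_b) + 1L]] <- block[seg]
      ins <- ins_seq[[j]]
      pieces_r[[length(pieces_r) + 1L]] <- rep("-", length(ins))
      pieces_o[[length(pieces_o) + 1L]] <- ins
      pieces_b[[length(pieces_b) + 1L]] <- rep(block[ins_pos[j]], length(ins))
      prev <- ins_pos[j]
    }
    if (prev < n) {
      seg <- (prev + 1L):n
      pieces_r[[length(pieces_r) + 1L]] <- ref[seg]
      pieces_o[[length(pieces_o) + 1L]] <- oth[seg]
      pieces_b[[length(pieces_b) + 1L]] <- block[seg]
    }
    ref <- unlist(pieces_r); oth <- unlist(pieces_o)
    block <- unlist(pieces_b)
  }
  list(ref = ref, oth = oth, block = block)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolve a gene's ancestral sequence into a pairwise alignment
#'
#' Two descendant sequences are produced from the ancestral sequence by
#' independent per-site substitution processes (one per lineage), each site's
#' substitution probability being `neutral_divergence/2` times its true class
#' multiplier, with transitions favoured `kappa`-fold and target bases biased
#' toward the lineage's GC target. Indels are inserted at `indel_rate` per
#' site as gap columns (deletions in the non-reference row, or insertions
#' carried by the non-reference row with gaps in the reference row, so the
#' reference's ungapped length always matches the gene model). The true
#' alignment is retained; there is no realignment step.
#'
#' @param sim a [simulate_gene_models()] result.
#' @param i gene index within `sim`.
#' @return list of [alignment_block()] objects (one per exon and intron).
#'   Uses the current RNG state; seed at the caller.
#' @export
evolve_pair <- function(sim, i) {
  gene <- sim$genes[[i]]; sq <- sim$seqs[[i]]; cfg <- sim$config
  mult_of <- c(ESE = cfg$ese_rate_multiplier,
               flank = cfg$flank_nonese_multiplier,
               core = cfg$core_multiplier)
  anc_e <- sq$exon_seq
  attr(anc_e, "ese") <- sq$exon_class == "ESE"
  ev_e <- evolve_region(anc_e, sq$exon_block, mult_of[sq$exon_class], cfg)
  ev_i <- evolve_region(sq$intron_seq, sq$intron_block,
                        rep(cfg$intron_multiplier, length(sq$intron_seq)),
                        cfg)
  blocks <- list()
  for (k in seq_len(n_exons(gene))) {
    sel <- ev_e$block == k
    blocks[[length(blocks) + 1L]] <- alignment_block(
      gene$gene_id, "exon", k,
      paste(ev_e$ref[sel], collapse = ""),
      paste(ev_e$oth[sel], collapse = ""))
  }
  for (k in seq_len(max(n_exons(gene) - 1L, 0L))) {
    sel <- ev_i$block == k
    blocks[[length(blocks) + 1L]] <- alignment_block(
      gene$gene_id, "intron", k,
      paste(ev_i$ref[sel], collapse = ""),
      paste(ev_i$oth[sel], collapse = ""))
  }
  blocks
}

#' Simulate stitched alignments for all genes
#'
#' @param sim a [simulate_gene_models()] result.
#' @param seed integer seed.
#' @return list with `alignments` (list of [stitch_blocks()] results, one per
#'   gene) and `truth` (per gene, the character vector of true exonic site
#'   classes over ungapped reference exon positions, transcript order).
#' @export
simulate_alignments <- function(sim, seed = 1L) {
  set.seed(seed)
  alns <- vector("list", length(sim$genes))
  truth <- vector("list", length(sim$genes))
  for (i in seq_along(sim$genes)) {
    blocks <- evolve_pair(sim, i)
    alns[[i]] <- stitch_blocks(blocks, sim$genes[[i]])
    truth[[i]] <- sim$seqs[[i]]$exon_class
  }
  list(alignments = alns, truth = truth)
}

#' Simulate a gene x tissue FPKM expression table
#'
#' Per gene, an expression breadth is drawn from a Beta distribution
#' (optionally rank-coupled, via a Gaussian copula, to the gene's true ESE
#' density so recovery tests can plant a breadth-rate association); each
#' tissue is expressed with that probability, and expressed entries draw
#' lognormal FPKM.
#'
#' @param sim a [simulate_gene_models()] result.
#' @param seed integer seed.
#' @return numeric matrix (genes x tissues) of FPKM >= 0, with gene ids as
#'   row names and tissue names `tissue01..`.
#' @export
simulate_expression <- function(sim, seed = 1L) {
  set.seed(seed)
  cfg <- sim$config
  n <- length(sim$genes); nt <- cfg$n_tissues
  z <- stats::rnorm(n)
  if (cfg$expr_rate_rho != 0) {
    score <- vapply(sim$seqs, function(s) mean(s$exon_class == "ESE"),
                    numeric(1))
    zs <- stats::qnorm(rank(score, ties.method = "average") / (n + 1))
    z <- cfg$expr_rate_rho * zs +
      sqrt(1 - cfg$expr_rate_rho^2) * z
  }
  breadth <- stats::qbeta(stats::pnorm(z), cfg$breadth_shape[1L],
                          cfg$breadth_shape[2L])
  expressed <- matrix(stats::runif(n * nt) < breadth, nrow = n)
  fpkm <- matrix(0, nrow = n, ncol = nt,
                 dimnames = list(vapply(sim$genes, `[[`, character(1),
                                        "gene_id"),
                                 sprintf("tissue%02d", seq_len(nt))))
  ne <- sum(expressed)
  fpkm[expressed] <- stats::rlnorm(ne, cfg$expr_meanlog, cfg$expr_sdlog)
  fpkm
}

# place n peaks uniformly in [lo, hi) (internal)
place_peaks <- function(n, lo, hi, width_range) {
  if (n == 0L || hi <= lo) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  w <- as.integer(round(stats::runif(n, width_range[1L], width_range[2L])))
  s <- as.integer(floor(stats::runif(n, lo, pmax(lo + 1, hi - w))))
  data.frame(start = s, end = s + w)
}

#' Simulate CHD1 and DHS peak tracks with activity labels
#'
#' Activity labels are drawn independently per cell type. CHD1 peaks are
#' placed in gene bodies with a per-bp intensity that rises linearly with
#' intron density for active genes (configured slope) and is flat or falling
#' for inactive genes. DHS peaks are placed both in gene bodies (same
#' structure) and in gene flanks, where their intensity decays exponentially
#' with distance from the edges of active genes.
#'
#' @param sim a [simulate_gene_models()] result.
#' @param seed integer seed.
#' @return list with `chd1` and `dhs` (named lists of [peak_track()] per cell
#'   type) and `labels` (data.frame `gene_id`, `cell_type`, `status`).
#' @export
simulate_peaks <- function(sim, seed = 1L) {
  set.seed(seed)
  cfg <- sim$config
  genes <- sim$genes
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  idens <- vapply(genes, intron_density, numeric(1))
  lens <- vapply(genes, unspliced_length, numeric(1))
  chd1 <- list(); dhs <- list(); labels <- list()
  for (ct in cfg$cell_types) {
    active <- stats::runif(length(genes)) < cfg$activity_rate
    labels[[ct]] <- data.frame(gene_id = ids, cell_type = ct,
                               status = ifelse(active, "active", "inactive"),
                               stringsAsFactors = FALSE)
    body_track <- function(base, slope_a, slope_i) {
      lam <- pmax(base + ifelse(active, slope_a, slope_i) * idens, 0)
      n_pk <- stats::rpois(length(genes), lam * lens)
      pieces <- lapply(seq_along(genes), function(i) {
        place_peaks(n_pk[i], genes[[i]]$start, genes[[i]]$end,
                    cfg$peak_width)
      })
      do.call(rbind, pieces)
    }
    chd_df <- body_track(cfg$chd1_base, cfg$chd1_active_slope,
                         cfg$chd1_inactive_slope)
    dhs_df <- body_track(cfg$dhs_body_base, cfg$dhs_body_slope, 0)
    # flank DHS: 10-kb strips out to dhs_span with decaying intensity
    strip <- 10000L
    nw <- as.integer(ceiling(cfg$dhs_span / strip))
    flank_pieces <- lapply(seq_along(genes), function(i) {
      g <- genes[[i]]
      out <- list()
      for (side in c(-1L, 1L)) {
        for (w in seq_len(nw)) {
          lo <- if (side < 0L) g$start - w * strip else
            g$end + (w - 1L) * strip
          hi <- lo + strip
          if (lo < 0L) next
          mid_d <- (w - 0.5) * strip
          lam <- cfg$dhs_flank_base + if (active[i])
            cfg$dhs_flank_amp * exp(-mid_d / cfg$dhs_flank_decay) else 0
          n_pk <- stats::rpois(1L, lam * strip)
          if (n_pk > 0L)
            out[[length(out) + 1L]] <- place_peaks(n_pk, lo, hi,
                                                   cfg$peak_width)
        }
      }
      if (length(out)) do.call(rbind, out) else NULL
    })
    dhs_df <- rbind(dhs_df, do.call(rbind, flank_pieces))
    chd1[[ct]] <- peak_track(rep(genes[[1L]]$chrom, nrow(chd_df)),
                             chd_df$start, chd_df$end)
    dhs[[ct]] <- peak_track(rep(genes[[1L]]$chrom, nrow(dhs_df)),
                            dhs_df$start, dhs_df$end)
  }
  list(chd1 = chd1, dhs = dhs, labels = do.call(rbind, labels))
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: gene models, diverged stitched alignments with
#' per-site truth, expression table, peak tracks and activity labels. Each
#' stage uses its own seed derived from `seed` so adding a stage never shifts
#' another stage's draws.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed.
#' @return list with `genes`, `seqs`, `alignments`, `truth`, `expression`,
#'   `peaks`, `config`, `chrom_sizes`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  sim <- simulate_gene_models(config, seed = seed)
  al <- simulate_alignments(sim, seed = seed + 1L)
  expr <- simulate_expression(sim, seed = seed + 2L)
  pk <- simulate_peaks(sim, seed = seed + 3L)
  list(genes = sim$genes, seqs = sim$seqs, alignments = al$alignments,
       truth = al$truth, expression = expr, peaks = pk, config = config,
       chrom_sizes = attr(sim, "chrom_sizes"))
}

#' Write a tiny deterministic fixture dataset
#'
#' Generates a six-gene dataset (fixed internal seed) in all the interchange
#' formats the package reads: BED12 gene models, paired gapped FASTA
#' alignments, an FPKM table, broadPeak tracks, activity labels and the
#' synthetic hexamer list. One gene is single-exon; one gene's alignment is
#' post-edited to carry an indel fraction of about 0.2 so it fails the
#' default 15% gap filter. Output is byte-identical across runs and machines.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
make_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_genes = 6L, mean_exons = 2.5,
                    exon_meanlog = log(120), exon_sdlog = 0.3,
                    exon_min = 40L, exon_max = 400L,
                    intron_meanlog = log(300), intron_sdlog = 0.3,
                    intron_min = 120L, intron_max = 800L,
                    n_tissues = 6L)
  sim <- simulate_gene_models(cfg, seed = 20140825 %% 2^20)
  # force gene 2 single-exon for the no-intron case
  if (n_exons(sim$genes[[2L]]) > 1L) {
    g <- sim$genes[[2L]]
    keep <- sim$seqs[[2L]]$exon_block == 1L
    first <- g$exons[exon_order(g)[1L], , drop = FALSE]
    sim$genes[[2L]] <- gene_model(g$gene_id, g$chrom, first[1L], first[2L],
                                  g$strand, first, g$biotype)
    sim$seqs[[2L]] <- list(exon_seq = sim$seqs[[2L]]$exon_seq[keep],
                           exon_block = sim$seqs[[2L]]$exon_block[keep],
                           exon_class = rep("core", sum(keep)),
                           intron_seq = character(0),
                           intron_block = integer(0))
  }
  set.seed(7L)
  blocks <- unlist(lapply(seq_along(sim$genes),
                          function(i) evolve_pair(sim, i)),
                   recursive = FALSE)
  # push gene 6 over the gap threshold: gap out 20% of its columns
  gid6 <- sim$genes[[6L]]$gene_id
  idx6 <- which(vapply(blocks, function(b) b$gene_id == gid6, logical(1)))
  tot_cols <- sum(vapply(blocks[idx6], function(b) nchar(b$seq_ref),
                         integer(1)))
  quota <- ceiling(0.2 * tot_cols)
  for (j in idx6) {
    if (quota <= 0L) break
    b <- blocks[[j]]
    o <- strsplit(b$seq_other, "")[[1L]]
    take <- min(quota, length(o))
    o[seq_len(take)] <- "-"
    quota <- quota - take
    blocks[[j]] <- alignment_block(b$gene_id, b$region_kind, b$ordinal,
                                   b$seq_ref, paste(o, collapse = ""))
  }
  expr <- simulate_expression(sim, seed = 11L)
  pk <- simulate_peaks(sim, seed = 13L)
  files <- c(bed = file.path(dir, "genes.bed"),
             ref = file.path(dir, "aln_ref.fa"),
             oth = file.path(dir, "aln_other.fa"),
             expr = file.path(dir, "expression.tsv"),
             chd1 = file.path(dir, "chd1_H1.broadPeak"),
             dhs = file.path(dir, "dhs_H1.broadPeak"),
             labels = file.path(dir, "activity_labels.tsv"),
             hexamers = file.path(dir, "synthetic_ese_hexamers.txt"))
  write_bed12(sim$genes, files[["bed"]])
  write_alignment_fasta(blocks, files[["ref"]], files[["oth"]])
  edf <- data.frame(gene_id = rownames(expr), round(expr, 4),
                    check.names = FALSE)
  utils::write.table(edf, files[["expr"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_peaks(pk$chd1$H1, files[["chd1"]])
  write_peaks(pk$dhs$H1, files[["dhs"]])
  utils::write.table(pk$labels, files[["labels"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(unclass(cfg$ese_hexamers), files[["hexamers"]])
  files
}
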