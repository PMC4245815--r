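#' Read a complete dataset from interchange files
#'
#' @param bed BED12 gene models.
#' @param aln_ref,aln_other paired gapped FASTA alignments (see
#'   [read_alignment_fasta()]).
#' @param expr optional FPKM TSV (`gene_id` + one column per tissue).
#' @param chd1,dhs optional broadPeak/BED peak tracks.
#' @param labels optional activity TSV (`gene_id`, `cell_type`, `status`).
#' @param hexamers optional hexamer list (defaults to
#'   [default_ese_hexamers()]).
#' @param biotype biotype assigned to the BED records.
#' @param cell_type cell type the peak tracks belong to.
#' @return list mirroring [simulate_dataset()] (without truth).
#' @export
read_dataset <- function(bed, aln_ref, aln_other, expr = NULL, chd1 = NULL,
                         dhs = NULL, labels = NULL, hexamers = NULL,
                         biotype = "lincRNA", cell_type = "H1") {
  genes <- read_bed12(bed, biotype = biotype)
  blocks <- read_alignment_fasta(aln_ref, aln_other)
  by_gene <- split(blocks, vapply(blocks, `[[`, character(1), "gene_id"))
  alns <- lapply(genes, function(g) {
    bl <- by_gene[[g$gene_id]]
    if (is.null(bl)) stop("no alignment blocks for gene '", g$gene_id, "'")
    stitch_blocks(bl, g)
  })
  expression <- NULL
  if (!is.null(expr)) {
    df <- utils::read.table(expr, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    expression <- as.matrix(df[, -1L, drop = FALSE])
    rownames(expression) <- df[[1L]]
  }
  lab <- if (!is.null(labels))
    utils::read.table(labels, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  list(genes = genes, alignments = alns, expression = expression,
       peaks = list(
         chd1 = if (!is.null(chd1))
           stats::setNames(list(read_peaks(chd1)), cell_type),
         dhs = if (!is.null(dhs))
           stats::setNames(list(read_peaks(dhs)), cell_type),
         labels = lab),
       hexamers = if (!is.null(hexamers)) read_hexamers(hexamers)
                  else default_ese_hexamers())
}

#' Median log rate ratios with signed-rank tests
#'
#' Medians of the defined per-gene natural-log rate ratios and one-sample
#' Wilcoxon signed-rank tests against 0. Genes with undefined (saturated or
#' filtered) ratios are excluded and counted.
#'
#' @param rates a [region_rates_table()] data.frame.
#' @return data.frame: `ratio`, `n`, `median`, `p_value`, `n_excluded`.
#' @export
summarize_medians <- function(rates) {
  cols <- c("log_ke_ki", "log_kef_kec", "log_kec_kic")
  out <- do.call(rbind, lapply(cols, function(cl) {
    v <- rates[[cl]]
    ok <- !is.na(v)
    if (!any(ok)) {
      return(data.frame(ratio = cl, n = 0L, median = NA_real_,
                        p_value = NA_real_, n_excluded = sum(!ok)))
    }
    p <- suppressWarnings(stats::wilcox.test(v[ok], mu = 0)$p.value)
    data.frame(ratio = cl, n = sum(ok), median = stats::median(v[ok]),
               p_value = p, n_excluded = sum(!ok))
  }))
  if (all(out$n == 0L)) warning("all log ratios undefined")
  out
}

# deterministic TSV writer (internal)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the pipeline end to end: data (simulated by default, or read
#' from files via [read_dataset()]), the indel-fraction gap filter, ESE
#' annotation, region partitioning, region-stratified rates with median
#' summaries, positional density and rate profiles with composition-matched
#' nulls, the predictor table with normal/partial correlation report, the
#' NMD stop-codon report, and the chromatin density analyses per cell type.
#' All randomness flows from `seed` through fixed per-stage substreams, so
#' repeated runs write byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root seed.
#' @param config a [sim_config()] used when `data` is NULL.
#' @param data optional [read_dataset()]/[simulate_dataset()] result.
#' @param gap_threshold indel-fraction filter (default 0.15).
#' @param flank_bp,intron_trim,min_concat region partition parameters.
#' @param dmin,dmax positional profile distance range.
#' @param null_draws composition-null draws per profile cell.
#' @param mc_iter Monte Carlo iterations for the activity label test.
#' @param n_shuffles shuffles for the NMD randomization.
#' @param fold_max_len 5' window for the folding proxy.
#' @return invisibly, a list with the main result tables and the manifest.
#' @export
run_all <- function(out_dir, seed = 1L, config = sim_config(), data = NULL,
                    gap_threshold = 0.15, flank_bp = 70L, intron_trim = 20L,
                    min_concat = 100L, dmin = 6L, dmax = 70L,
                    null_draws = 100L, mc_iter = 1000L, n_shuffles = 200L,
                    fold_max_len = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(data)
  if (simulated) data <- simulate_dataset(config, seed = seed)
  hex <- data$hexamers %||% config$ese_hexamers
  n_input <- length(data$genes)

  flt <- filter_by_gap(data$genes, data$alignments,
                       threshold = gap_threshold)
  write_tsv(flt$report, file.path(out_dir, "gap_filter.tsv"))
  genes <- flt$genes; alns <- flt$alignments

  masks <- lapply(alns, annotate_alignment_ese, hexamers = hex)
  parts <- lapply(seq_along(genes), function(i)
    partition_regions(genes[[i]], alns[[i]], flank_bp, intron_trim,
                      min_concat))
  rates <- region_rates_table(genes, alns, flank_bp, intron_trim, min_concat)
  write_tsv(rates, file.path(out_dir, "gene_rates.tsv"))
  med <- summarize_medians(rates)
  write_tsv(med, file.path(out_dir, "rate_ratio_medians.tsv"))

  dens_prof <- positional_density_profile(genes, alns, masks, dmin, dmax)
  write_tsv(dens_prof, file.path(out_dir, "ese_density_profile.tsv"))
  rate_prof <- positional_rate_profile(genes, alns, masks, dmin, dmax)
  pool <- exon_column_pool(alns)
  null_rates <- vapply(seq_len(nrow(rate_prof)), function(i) {
    if (rate_prof$class[i] != "ESE") return(NA_real_)
    d <- rate_prof$distance[i]
    comp <- composition_cell(genes, alns, masks, d, ese = TRUE)
    if (sum(comp) == 0L) return(NA_real_)
    composition_matched_null(comp, pool, n_draws = null_draws,
                             seed = seed + 17L + d)$rate
  }, numeric(1))
  rate_prof$null_rate <- null_rates
  write_tsv(rate_prof, file.path(out_dir, "rate_profile.tsv"))

  features <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    ese_density = vapply(seq_along(genes), function(i)
      ese_density(alns[[i]], masks[[i]]), numeric(1)),
    frac70 = vapply(seq_along(genes), function(i)
      frac70(genes[[i]], alns[[i]], flank_bp), numeric(1)),
    L_flank = vapply(parts, `[[`, integer(1), "L_flank"),
    L_core = vapply(parts, `[[`, integer(1), "L_core"),
    L_introncore = vapply(parts, `[[`, integer(1), "L_introncore"),
    passes = vapply(parts, `[[`, logical(1), "passes_min_length"),
    gc_content = vapply(alns, function(a) {
      ch <- aln_chars(a, "exon")
      mean(ch$ref[ch$ref != "-"] %in% c("G", "C"))
    }, numeric(1)),
    rna_stability = vapply(alns, folding_stability, numeric(1),
                           max_len = fold_max_len),
    stringsAsFactors = FALSE)
  write_tsv(features, file.path(out_dir, "gene_features.tsv"))

  report <- NULL
  if (!is.null(data$expression)) {
    es <- expression_summaries(data$expression)
    ptab <- merge(data.frame(gene_id = rates$gene_id,
                             evolutionary_rate = rates$K_exon),
                  merge(features, es, by = "gene_id"), by = "gene_id")
    write_tsv(ptab, file.path(out_dir, "predictor_table.tsv"))
    preds <- c("max_expr", "med_expr", "breadth", "rna_stability",
               "frac70", "ese_density", "gc_content")
    ok <- stats::complete.cases(ptab[, c("evolutionary_rate", preds)])
    if (sum(ok) >= length(preds) + 3L) {
      report <- correlation_report(ptab[ok, , drop = FALSE],
                                   response = "evolutionary_rate",
                                   predictors = preds)
      write_tsv(report, file.path(out_dir, "correlation_report.tsv"))
    }
  }

  exsq <- lapply(alns, exon_sequences)
  nmd1 <- penultimate_exon_paired_test(exsq)
  nmd2 <- two_exon_window_test(exsq)
  two_exon_first <- vapply(Filter(function(e) length(e) == 2L &&
                                    nchar(e[1L]) > 50L, exsq),
                           function(e) {
                             L <- nchar(e[1L])
                             substr(e[1L], 1L, L - 50L)
                           }, character(1))
  nmd_rows <- data.frame(
    statistic = c("penultimate_n", "penultimate_prop_5p_higher",
                  "penultimate_p", "two_exon_n", "two_exon_prop_outer_higher",
                  "two_exon_p", "outside_shadow_stop_free",
                  "outside_shadow_fewer3", "shuffled_stop_free",
                  "shuffled_fewer3"),
    value = c(nmd1$summary$n_informative, nmd1$summary$prop_5p_higher,
              nmd1$summary$p_value, nmd2$summary$n_informative,
              nmd2$summary$prop_outer_higher, nmd2$summary$p_value,
              if (length(two_exon_first)) {
                sf <- stop_free_fraction(two_exon_first)
                c(sf$frac_stop_free, sf$frac_fewer_than_3)
              } else c(NA, NA),
              if (length(two_exon_first)) {
                rx <- randomized_stop_free_expectation(
                  two_exon_first, n_shuffles = n_shuffles, seed = seed + 23L)
                c(rx$frac_stop_free, rx$frac_fewer_than_3)
              } else c(NA, NA)))
  write_tsv(nmd_rows, file.path(out_dir, "nmd_report.tsv"))

  chromatin <- NULL
  if (!is.null(data$peaks) && length(data$peaks$chd1)) {
    chromatin <- list()
    for (ct in names(data$peaks$chd1)) {
      lab <- data$peaks$labels
      lab_ct <- lab[lab$cell_type == ct, , drop = FALSE]
      dt <- density_table(data$genes, data$peaks$chd1[[ct]], lab_ct)
      act <- dt[!is.na(dt$status) & dt$status == "active", , drop = FALSE]
      inact <- dt[!is.na(dt$status) & dt$status == "inactive", , drop = FALSE]
      enough <- nrow(act) >= 3L && nrow(inact) >= 3L
      sp_a <- if (enough) spearman(act$peak_count_density,
                                   act$intron_density)
              else list(rho = NA_real_)
      sp_i <- if (enough) spearman(inact$peak_count_density,
                                   inact$intron_density)
              else list(rho = NA_real_)
      mc <- if (enough)
        monte_carlo_label_test(act$peak_count_density,
                               inact$peak_count_density,
                               n_iter = mc_iter, seed = seed + 31L)
      else list(p_value = NA_real_)
      dhs_prof <- flank_window_profile(data$genes, data$peaks$dhs[[ct]],
                                       lab_ct,
                                       chrom_sizes = data$chrom_sizes)
      chromatin[[ct]] <- list(density = dt, rho_active = sp_a$rho,
                              rho_inactive = sp_i$rho, mc_p = mc$p_value,
                              dhs_profile = dhs_prof)
      write_tsv(dt, file.path(out_dir, paste0("chd1_density_", ct, ".tsv")))
      write_tsv(dhs_prof, file.path(out_dir,
                                    paste0("dhs_flank_profile_", ct,
                                           ".tsv")))
      write_tsv(data.frame(statistic = c("rho_active", "rho_inactive",
                                         "mc_p"),
                           value = c(sp_a$rho, sp_i$rho, mc$p_value)),
                file.path(out_dir, paste0("chd1_summary_", ct, ".tsv")))
    }
  }

  manifest <- list(
    package = "lincsel",
    version = as.character(utils::packageVersion("lincsel")),
    seed = seed, simulated = simulated,
    gap_threshold = gap_threshold, flank_bp = flank_bp,
    intron_trim = intron_trim, min_concat = min_concat,
    n_genes_input = n_input, n_genes_after_gap_filter = length(genes),
    n_genes_passing_length_filter = sum(features$passes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(rates = rates, medians = med, features = features,
                 density_profile = dens_prof, rate_profile = rate_prof,
                 correlations = report, nmd = nmd_rows,
                 chromatin = chromatin, manifest = manifest))
}

# reference-base composition of the pooled (distance, class) profile cell
# (internal)
composition_cell <- function(genes, alns, masks, d, ese = TRUE) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in seq_along(genes)) {
    ann <- annotate_junction_distance(genes[[i]], alns[[i]])
    ch <- aln_chars(alns[[i]], "exon")
    sel <- ann$valid & !is.na(ann$distance) & ann$distance == d &
      ch$ref %in% bases & ch$oth %in% bases &
      (as.logical(masks[[i]]) == ese)
    if (any(sel)) {
      t <- table(factor(ch$ref[sel], levels = bases))
      comp <- comp + as.integer(t)
    }
  }
  comp
}
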