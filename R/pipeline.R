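#' Assemble a pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]: either `cohort_dir`
#' (a directory written by [write_cohort()]) or `synthetic` (a
#' [cohort_config()], generated on the fly), the thresholds of every stage
#' with their defaults, a mandatory master seed and an output directory.
#'
#' @param cohort_dir directory of cohort TSVs, or `NULL` to simulate.
#' @param synthetic a [cohort_config()] used when `cohort_dir` is `NULL`.
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are spawned with [derive_seed()].
#' @param min_cpm,min_fraction,n_gc_bins,log_offset,sd_threshold,min_batch_size,min_subtype_size
#'   preprocessing thresholds (see [preprocess_expression()]).
#' @param huber_c Huber tuning constant for deconvolution.
#' @param min_median_logcpm low-expression rule for panel genes.
#' @param r_threshold,fdr,cor_mode immune-correlation filter settings.
#' @param effect_variant `"weighted"` or `"unweighted"` relative effects.
#' @param effect_reference `"normal"` (anchor probabilities against the
#'   normal-tissue group of each cancer type) or `"pooled"` (anchor against
#'   the pooled within-type sample); see [subtype_effect_matrix()].
#' @param K_range candidate cluster numbers.
#' @param mhc_mutation_genes optional character vector for the mutation
#'   frequency analysis; defaults to the panel's MHC genes.
#' @param skip_deconvolution if `TRUE`, `fractions_file` (sample_id +
#'   cell-fraction columns, TSV) supplies the immune fractions instead of
#'   running the deconvolution stage.
#' @param fractions_file see `skip_deconvolution`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_dir = NULL,
                            synthetic = cohort_config(),
                            out_dir = "pipeline_out",
                            seed = 1L,
                            min_cpm = 1, min_fraction = 0.2,
                            n_gc_bins = 10L, log_offset = 0.25,
                            sd_threshold = 3, min_batch_size = 5L,
                            min_subtype_size = 10L,
                            huber_c = 1.345,
                            min_median_logcpm = 0,
                            r_threshold = 0.4, fdr = 0.05,
                            cor_mode = "positive",
                            effect_variant = "weighted",
                            effect_reference = "normal",
                            K_range = 2:5,
                            mhc_mutation_genes = NULL,
                            skip_deconvolution = FALSE,
                            fractions_file = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Reports unknown keys (with a nearest-known suggestion by edit distance),
#' missing paths and out-of-range thresholds. Never mutates state and never
#' raises: the return value is the report.
#'
#' @param config a [pipeline_config()] or plain named list.
#' @return data.frame with columns `key`, `problem` (empty when valid).
#' @export
validate_config <- function(config) {
  known <- names(formals(pipeline_config))
  issues <- list()
  add <- function(key, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(key = key, problem = problem,
                                                 stringsAsFactors = FALSE)
  }
  for (key in setdiff(names(config), known)) {
    dist <- utils::adist(key, known)
    add(key, sprintf("unknown key; did you mean '%s'?", known[which.min(dist)]))
  }
  g <- function(k) config[[k]]
  if (!is.null(g("cohort_dir")) && !dir.exists(g("cohort_dir"))) {
    add("cohort_dir", "path does not exist")
  }
  if (isTRUE(g("skip_deconvolution"))) {
    if (is.null(g("fractions_file"))) {
      add("fractions_file", "required when skip_deconvolution is TRUE")
    } else if (!file.exists(g("fractions_file"))) {
      add("fractions_file", "path does not exist")
    }
  }
  if (is.null(g("seed"))) add("seed", "a master seed is mandatory")
  rng <- list(r_threshold = c(0, 1), fdr = c(0, 1), min_fraction = c(1e-12, 1),
              min_cpm = c(1e-12, Inf), log_offset = c(1e-12, Inf),
              sd_threshold = c(0, Inf), huber_c = c(1e-12, Inf))
  for (k in names(rng)) {
    v <- g(k)
    if (!is.null(v) && (!is.numeric(v) || v < rng[[k]][1] || v > rng[[k]][2])) {
      add(k, sprintf("out of range [%g, %g]", rng[[k]][1], rng[[k]][2]))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(key = character(), problem = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: expression preprocessing (per cancer type) ->
#' methylation deconvolution -> panel selection (low-expression flag +
#' immune-correlation filter) -> relative effects -> MHC clustering ->
#' mutation summary -> pan-cancer correlation summary. Writes
#' `effects.tsv`, `bands.tsv`, `clusters.tsv`, `validity.tsv`,
#' `corr_summary.tsv`, `mutation_freq.tsv`, `heatmap_matrix.tsv`,
#' `panel_retained.tsv`, `fractions.tsv` and `run_log.txt` to
#' `config$out_dir`. On a stage error, already-written outputs are renamed
#' with a `.partial` suffix and the error reports the failing stage.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  rep <- validate_config(config)
  if (nrow(rep) > 0) {
    stopf("invalid configuration:\n%s",
          paste(sprintf("  %s: %s", rep$key, rep$problem), collapse = "\n"))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_lines <- c(sprintf("mhcprofiler %s", as.character(utils::packageVersion("mhcprofiler"))),
                 sprintf("R %s", getRversion()),
                 sprintf("master seed: %d", config$seed))
  par_keys <- setdiff(names(formals(pipeline_config)),
                      c("cohort_dir", "synthetic", "out_dir", "mhc_mutation_genes",
                        "fractions_file"))
  for (k in par_keys) {
    log_lines <- c(log_lines, sprintf("param %s = %s", k,
                                      paste(config[[k]], collapse = ",")))
  }
  emit <- function(writer, file) {
    path <- file.path(out_dir, file)
    writer(path)
    written <<- c(written, path)
  }
  stage <- "load"
  res <- tryCatch({
    ## ---- load / simulate -------------------------------------------------
    cohort <- if (!is.null(config$cohort_dir)) {
      read_cohort(config$cohort_dir)
    } else {
      syn <- config$synthetic
      syn$seed <- derive_seed(config$seed, "simulate")
      generate_cohort(syn)
    }
    md <- cohort$metadata
    types <- unique(md$cancer_type)
    log_lines <- c(log_lines, sprintf(
      "cohort: %d genes x %d samples, %d cancer types",
      nrow(cohort$counts), ncol(cohort$counts), length(types)))

    ## ---- stage 1: preprocessing per cancer type --------------------------
    stage <- "preprocess"
    expr_by_type <- list(); meta_rows <- list()
    for (ct in types) {
      sel <- md$sample_id[md$cancer_type == ct]
      pp <- preprocess_expression(
        cohort$counts[, sel, drop = FALSE], cohort$gc,
        md[md$sample_id %in% sel, , drop = FALSE],
        min_cpm = config$min_cpm, min_fraction = config$min_fraction,
        n_gc_bins = config$n_gc_bins, log_offset = config$log_offset,
        sd_threshold = config$sd_threshold,
        min_batch_size = config$min_batch_size,
        min_subtype_size = config$min_subtype_size)
      expr_by_type[[ct]] <- pp$expr
      meta_rows[[ct]] <- pp$metadata
      log_lines <- c(log_lines, paste0("[", ct, "] ", pp$log))
    }
    md <- do.call(rbind, meta_rows)
    rownames(md) <- NULL

    ## ---- stage 2: deconvolution ------------------------------------------
    stage <- "deconvolve"
    fractions <- if (isTRUE(config$skip_deconvolution)) {
      fd <- read_df_tsv(config$fractions_file)
      fr <- as.matrix(fd[, setdiff(names(fd), "sample_id"), drop = FALSE])
      rownames(fr) <- fd$sample_id
      fr
    } else {
      suppressWarnings(rpc_deconvolve(cohort$betas, cohort$reference,
                                      huber_c = config$huber_c))
    }
    immune <- fractions[, "immune"]
    emit(function(p) write_df_tsv(
      data.frame(sample_id = rownames(fractions), fractions,
                 check.names = FALSE), p), "fractions.tsv")
    log_lines <- c(log_lines, sprintf("deconvolution: %d samples, mean immune fraction %.3f",
                                      nrow(fractions), mean(immune)))

    ## ---- stage 3: panel selection ----------------------------------------
    stage <- "panel_selection"
    low_flagged <- flag_low_expressed_panel(expr_by_type, md, cohort$panel,
                                            config$min_median_logcpm)
    panel_expr <- cohort$panel[!cohort$panel$gene_id %in% low_flagged, ,
                               drop = FALSE]
    filt <- immune_correlation_filter(expr_by_type, immune, md, panel_expr,
                                      r_threshold = config$r_threshold,
                                      fdr = config$fdr,
                                      mode = config$cor_mode)
    retained <- filt$panel
    emit(function(p) write_df_tsv(retained, p), "panel_retained.tsv")
    log_lines <- c(log_lines, sprintf(
      "panel: %d genes; %d flagged low-expressed, %d immune-correlated, %d retained (%d MHC)",
      nrow(cohort$panel), length(low_flagged), length(filt$removed),
      nrow(retained), sum(retained$class == "MHC")))

    ## ---- stage 4: relative effects ---------------------------------------
    stage <- "relative_effects"
    tumor_ids <- md$sample_id[md$is_tumor == 1L]
    mutsum <- per_sample_mutation_burden(cohort$mutations,
                                         sample_ids = md$sample_id)
    tcell <- if (!is.null(cohort$truth$tcell)) {
      cohort$truth$tcell[md$sample_id, , drop = FALSE]
    } else {
      tl <- infer_tcell_levels(cohort$betas, cohort$tcell_reference,
                               huber_c = config$huber_c)
      colnames(tl) <- c("TCD4", "TCD8")
      tl[md$sample_id, , drop = FALSE]
    }
    extra <- cbind(MUTsum = mutsum[md$sample_id], tcell)
    rownames(extra) <- md$sample_id
    panel_by_type <- lapply(expr_by_type, function(e)
      e[intersect(retained$gene_id, rownames(e)), , drop = FALSE])
    eff <- subtype_effect_matrix(panel_by_type, extra, md,
                                 variant = config$effect_variant,
                                 reference = config$effect_reference)
    emit(function(p) write_matrix_tsv(eff$effects, p, "subtype"), "effects.tsv")
    emit(function(p) write_matrix_tsv(eff$bands, p, "subtype"), "bands.tsv")

    ## ---- stage 5: clustering ---------------------------------------------
    stage <- "clustering"
    mhc_genes <- retained$gene_id[retained$class == "MHC"]
    m <- eff$effects[, intersect(mhc_genes, colnames(eff$effects)),
                     drop = FALSE]
    clu <- cluster_mhc(m, K_range = config$K_range,
                       seed = derive_seed(config$seed, "cluster"))
    clusters_df <- data.frame(
      subtype = names(clu$result$consensus),
      consensus_cluster = unname(clu$result$consensus),
      mhc_class = unname(clu$result$subtype_class),
      mean_mhc_probability = rowMeans(m[names(clu$result$consensus), ,
                                        drop = FALSE]),
      stringsAsFactors = FALSE)
    emit(function(p) write_df_tsv(clusters_df, p), "clusters.tsv")
    emit(function(p) write_df_tsv(clu$validity, p), "validity.tsv")
    emit(function(p) write_matrix_tsv(clu$heatmap_matrix, p, "subtype"),
         "heatmap_matrix.tsv")
    log_lines <- c(log_lines, sprintf(
      "clustering: selected K = %d; class sizes: %s", clu$result$selected_K,
      paste(sprintf("%s=%d", names(table(clu$result$subtype_class)),
                    as.integer(table(clu$result$subtype_class))),
            collapse = ", ")))

    ## ---- stage 6: mutation summary ---------------------------------------
    stage <- "mutation_summary"
    mut_genes <- config$mhc_mutation_genes %||%
      cohort$panel$gene_id[cohort$panel$class == "MHC"]
    mut_freq <- suppressWarnings(
      mhc_mutation_frequency(cohort$mutations, mut_genes, md))
    emit(function(p) write_df_tsv(mut_freq, p), "mutation_freq.tsv")

    ## ---- stage 7: correlation summary ------------------------------------
    stage <- "correlation_summary"
    vars_by_type <- lapply(names(panel_by_type), function(ct) {
      e <- panel_by_type[[ct]]
      tum <- intersect(colnames(e), tumor_ids)
      rbind(e[, tum, drop = FALSE],
            TCD4 = extra[tum, "TCD4"], TCD8 = extra[tum, "TCD8"])
    })
    names(vars_by_type) <- names(panel_by_type)
    cs <- pan_cancer_correlation_summary(vars_by_type,
                                         r_threshold = config$r_threshold,
                                         fdr = config$fdr)
    emit(function(p) write_matrix_tsv(cs$summary, p, "variable"),
         "corr_summary.tsv")

    stage <- "finalize"
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    list(cohort = cohort, metadata = md, expr_by_type = expr_by_type,
         fractions = fractions, panel_retained = retained,
         low_flagged = low_flagged, filter_report = filt$report,
         effects = eff, clustering = clu, clusters = clusters_df,
         mutation_freq = mut_freq, corr_summary = cs$summary)
  }, error = function(e) {
    for (p in written) {
      if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
    }
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
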