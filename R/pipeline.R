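#' Configuration of an end-to-end pipeline run
#'
#' Bundles the synthetic-world configuration with every stage parameter.
#' Unknown parameter names are rejected.
#'
#' @param seed master seed; also seeds the synthetic config unless one is
#'   supplied.
#' @param synthetic a [synthetic_config()]; built from `seed` when `NULL`.
#' @param onco_mode oncohistone incorporation mode, `"H3.3"` or `"H3-like"`.
#' @param stages character vector of stages to run, a subset of
#'   `c("tracks", "domains", "clustering", "fit", "integration", "ploidy")`.
#' @param tau,min_bins,max_gap domain-calling parameters ([call_domains()]).
#' @param window smoothing window in bins ([smooth_track()]).
#' @param pseudocount log-ratio pseudocount ([normalize_input()]).
#' @param cluster_bin_size grid for the clustering stage (default 10 kb).
#' @param k clusters per partition ([cluster_bins()]).
#' @param degree dependency-model polynomial degree ([fit_dependency()]).
#' @param body_slots,flank_bp metagene parameters ([metagene()]).
#' @param n_perm permutations for the change correlation.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(seed = 1L, synthetic = NULL, onco_mode = "H3.3",
                       stages = c("tracks", "domains", "clustering", "fit",
                                  "integration", "ploidy"),
                       tau = 0, min_bins = 5L, max_gap = 2L, window = 5L,
                       pseudocount = 1, cluster_bin_size = 10000L, k = 6L,
                       degree = 7L, body_slots = 100L, flank_bp = 500,
                       n_perm = 199L) {
  known <- c("tracks", "domains", "clustering", "fit", "integration", "ploidy")
  if (!all(stages %in% known))
    config_error(sprintf("unknown stage(s): %s",
                         paste(setdiff(stages, known), collapse = ", ")))
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  if (!onco_mode %in% c("H3.3", "H3-like"))
    config_error("onco_mode must be 'H3.3' or 'H3-like'")
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 onco_mode = onco_mode, stages = stages, tau = tau,
                 min_bins = as.integer(min_bins),
                 max_gap = as.integer(max_gap), window = as.integer(window),
                 pseudocount = pseudocount,
                 cluster_bin_size = as.integer(cluster_bin_size),
                 k = as.integer(k), degree = as.integer(degree),
                 body_slots = as.integer(body_slots), flank_bp = flank_bp,
                 n_perm = as.integer(n_perm)),
            class = "RunConfig")
}

#' Build a RunConfig from a JSON file
#'
#' The JSON object may contain any [run_config()] argument plus a nested
#' `synthetic` object of [synthetic_config()] arguments.
#'
#' @param path JSON file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such config file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (!is.null(j$synthetic)) {
    bad <- setdiff(names(j$synthetic), names(formals(synthetic_config)))
    if (length(bad)) config_error(sprintf("unknown synthetic key(s): %s",
                                          paste(bad, collapse = ", ")))
    syn <- do.call(synthetic_config, j$synthetic)
    j$synthetic <- NULL
  }
  bad <- setdiff(names(j), names(formals(run_config)))
  if (length(bad)) config_error(sprintf("unknown config key(s): %s",
                                        paste(bad, collapse = ", ")))
  do.call(run_config, c(j, if (!is.null(syn)) list(synthetic = syn)))
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the stages in dependency order on a freshly generated synthetic
#' world: track generation, smoothing, domain classification, 10 kb
#' clustering (autosomes and X separately), dependency-model fitting at the
#' native bin size, expression integration, and DAPI ploidy calibration.
#' The report is fully deterministic for a fixed config (timestamps are
#' excluded); identical config + seed give identical reports.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the report is written to
#'   `report.json` there.
#' @return A `RunReport` list with one entry per executed stage, the log,
#'   seed and config hash.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  report <- list(package = "oncochrom",
                 version = as.character(utils::packageVersion("oncochrom")),
                 seed = config$seed,
                 config_hash = config_hash(rapply(unclass(config), identity,
                                                  how = "list")),
                 stages = list())
  if (length(config$stages) == 0L) {
    report$log <- log
    return(finish_report(report, out_dir))
  }

  syn <- config$synthetic
  assembly <- make_assembly(syn)
  wt <- simulate_wt_k27me3(assembly, syn)
  onco <- simulate_oncohistone(assembly, config$onco_mode, syn, wt)
  model <- dependency_model(syn$dependency)
  mut <- simulate_mut_k27me3(wt, onco, model, noise_sd = syn$mut_noise_sd,
                             seed = syn$seed)
  note("tracks: %d chromosomes, %d bins @ %d bp, mode %s",
       nrow(assembly), sum(assembly_bins(assembly, syn$bin_size)),
       syn$bin_size, config$onco_mode)
  if ("tracks" %in% config$stages) {
    report$stages$tracks <- list(
      n_bins = sum(assembly_bins(assembly, syn$bin_size)),
      bin_size = syn$bin_size, onco_mode = config$onco_mode,
      chromosome_summary = list(
        wt_k27me3 = chromosome_summary(wt),
        oncohistone = chromosome_summary(onco),
        mut_k27me3 = chromosome_summary(mut)))
  }

  if ("domains" %in% config$stages) {
    wts <- smooth_track(wt, config$window)
    muts <- smooth_track(mut, config$window)
    domains <- call_domains(wts, muts, tau = config$tau,
                            min_bins = config$min_bins,
                            max_gap = config$max_gap)
    dsum <- domain_summary(list(wt_k27me3 = wt, oncohistone = onco,
                                mut_k27me3 = mut), domains)
    note("domains: %d intervals, %d categories",
         nrow(domains$intervals), length(unique(domains$intervals$category)))
    report$stages$domains <- list(
      n_intervals = nrow(domains$intervals),
      category_bins = as.list(table(unlist(lapply(domains$bins,
                                                  as.character)))),
      summary = dsum)
  }

  if ("clustering" %in% config$stages) {
    wt10 <- rebin(wt, config$cluster_bin_size)
    onco10 <- rebin(onco, config$cluster_bin_size)
    mut10 <- rebin(mut, config$cluster_bin_size)
    cl <- list()
    for (part in c("autosomes", "X")) {
      cm <- build_matrix(wt10, onco10, mut10, partition = part)
      kk <- min(config$k, nrow(cm$matrix))
      bc <- cluster_bins(cm, k = kk)
      cl[[part]] <- list(k = kk, sizes = bc$sizes,
                         summary = cluster_summary(cm, bc))
      note("clustering/%s: %d bins -> %d clusters", part, nrow(cm$matrix), kk)
    }
    report$stages$clustering <- cl
  }

  if ("fit" %in% config$stages) {
    x <- track_values(wt); y <- track_values(onco); z <- track_values(mut)
    fit <- fit_dependency(x, y, z, degree = config$degree)
    gof <- goodness_of_fit(model, x, y, z)
    note("fit: n = %d, R^2 = %.4f", fit$n_bins, fit$r_squared)
    report$stages$fit <- list(
      coefficients = as.list(fit$coefficients),
      se = as.list(fit$se),
      r_squared = fit$r_squared, sse = fit$sse, n_bins = fit$n_bins,
      planted_model = list(r_squared = gof$r_squared, sse = gof$sse))
  }

  if ("integration" %in% config$stages) {
    genes <- simulate_gene_table(assembly, syn, wt, mut)
    genes <- de_filter(genes)
    genes <- assign_quintiles(genes)
    de <- genes[genes$de_status %in% c("up", "down"), , drop = FALSE]
    corr <- if (nrow(de) >= 3)
      correlate_changes(de$log2_fc, de$delta_k27me3,
                        n_perm = config$n_perm, seed = syn$seed)
    else list(spearman = NA_real_, pearson = NA_real_,
              p_permutation = NA_real_, n = nrow(de))
    qf <- if (nrow(de) > 0) quintile_fractions(genes) else NULL
    ov <- gene_set_overlap(de$id, genes$id[genes$germline_specific])
    profiles <- lapply(split(genes, genes$quintile), function(gq)
      metagene(mut, gq, group = as.character(gq$quintile[1]),
               body_slots = config$body_slots, flank_bp = config$flank_bp))
    note("integration: %d genes, %d DE, rho = %.3f",
         nrow(genes), nrow(de), corr$spearman)
    report$stages$integration <- list(
      n_genes = nrow(genes), n_de = nrow(de),
      n_up = sum(genes$de_status == "up"),
      n_down = sum(genes$de_status == "down"),
      change_correlation = corr,
      quintile_fractions = as.list(qf),
      germline_overlap = as.list(ov),
      quintile_body_means = lapply(profiles, function(p)
        mean(p$mean[p$zone == "body"])))
  }

  if ("ploidy" %in% config$stages) {
    dapi <- simulate_dapi(syn)
    cal <- calibrate_ploidy(dapi)
    contents <- data.frame(population = dapi$population,
                           content = estimate_content(dapi$intensity, cal))
    note("ploidy: %d nuclei, slope %.3f", nrow(dapi), cal$slope)
    report$stages$ploidy <- list(
      slope = cal$slope, intercept = cal$intercept,
      anchor_means = as.list(cal$anchor_means),
      relative_content = relative_content_report(contents))
  }

  report$log <- log
  finish_report(report, out_dir)
}

finish_report <- function(report, out_dir) {
  class(report) <- "RunReport"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      io_error(sprintf("cannot create %s", out_dir))
    writeLines(report_json(report), file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a run report to deterministic JSON
#'
#' @param report a `RunReport` from [run_pipeline()].
#' @return A JSON string (no timestamps; identical for identical runs).
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, dataframe = "columns",
                                na = "null", pretty = TRUE))
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport: seed %d, stages: %s\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
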