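# End-to-end orchestration: simulate (or load) inputs, scale the
# transect, fit reference clines and scan genes, run the climate
# association and quantitative-genetic models, scan the chloroplast
# alignment, and emit a machine-readable run report.

#' Default pipeline configuration
#'
#' @param seed Top-level seed; every stage derives its own substream.
#' @param output_dir Directory for all stage outputs.
#' @param simulate Generator settings (lists passed to
#'   [generate_hybrid_zone()], [generate_traits()], [generate_climate()],
#'   [generate_cp_alignment()]); set to `NULL` and supply `inputs`
#'   paths (`samples`, `ancestry`, `climate`, `traits`) to run on
#'   existing files.
#' @param scan Cline-scan settings (`n_starts`, `delta`).
#' @return A config list accepted by [run_all()].
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("cytocline_run_"),
                            simulate = list(
                              hybrid_zone = list(),
                              traits = list(beta_NxC = -0.11, V_block = 0.05,
                                            V_eps = 0.05),
                              climate = list(),
                              cp_alignment = list()),
                            scan = list(n_starts = 20, delta = 2.0)) {
  list(seed = seed, output_dir = output_dir, simulate = simulate,
       inputs = NULL, scan = scan)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order; a stage failure is recorded
#' in the report and only its downstream dependents are skipped.
#'
#' @param config A list from [pipeline_config()], or the path of a YAML
#'   file with the same structure.
#' @return A `run_report`: `config_hash`, `seed`, `stages` (status and
#'   wall time per stage), `summary` (gene tallies, reference cline
#'   parameters, climate slopes, heritability and interaction
#'   coefficients). Also written as `run_report.json` in the output
#'   directory.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed) || is.null(config$output_dir)) {
    stop_validation("config must provide seed and output_dir")
  }
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- list()
  summary <- list()
  env <- new.env()

  run_stage <- function(name, deps, fun) {
    failed_deps <- deps[vapply(deps, function(d) {
      !identical(stages[[d]]$status, "ok")
    }, logical(1))]
    if (length(failed_deps) > 0) {
      stages[[name]] <<- list(status = "skipped", wall_time = 0,
                              reason = paste("dependency failed:",
                                             paste(failed_deps, collapse = ", ")))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      fun()
      list(status = "ok")
    }, error = function(e) list(status = "failed",
                                reason = conditionMessage(e)))
    res$wall_time <- round(proc.time()[["elapsed"]] - t0, 3)
    stages[[name]] <<- res
  }

  run_stage("simulate", character(0), function() {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      hz <- generate_hybrid_zone(
        utils::modifyList(hybrid_zone_config(), sim$hybrid_zone %||% list()),
        seed = seed)
      cl <- generate_climate(sim$climate %||% list(), seed = seed,
                             sample_table = hz$samples)
      tr <- generate_traits(sim$traits %||% list(), seed = seed,
                            sample_table = hz$samples)
      cp <- generate_cp_alignment(sim$cp_alignment %||% list(), seed = seed)
      write_results(hz$samples, file.path(out_dir, "samples.tsv"), "TSV")
      write_ancestry_matrix(hz$ancestry, file.path(out_dir, "ancestry.tsv"))
      write_results(hz$annotations, file.path(out_dir, "annotations.tsv"), "TSV")
      write_results(cl$climate, file.path(out_dir, "climate.tsv"), "TSV")
      write_results(tr$traits, file.path(out_dir, "traits.tsv"), "TSV")
      writeLines(paste0(">", names(cp$sequences), "\n", cp$sequences),
                 file.path(out_dir, "cp_alignment.fasta"))
      env$samples <- hz$samples; env$ancestry <- hz$ancestry
      env$annotations <- hz$annotations; env$climate <- cl$climate
      env$traits <- tr$traits; env$cp_alignment <- cp
      env$truth <- list(hybrid_zone = hz$truth, climate = cl$truth,
                        traits = tr$truth, cp_alignment = cp$truth)
    } else {
      inp <- config$inputs
      env$samples <- read_sample_table(inp$samples)
      env$ancestry <- read_ancestry_matrix(inp$ancestry)
      env$annotations <- if (!is.null(inp$annotations_gff3)) {
        read_gene_annotations(inp$annotations_gff3, "GFF3")
      } else {
        read.delim(inp$annotations, stringsAsFactors = FALSE)
      }
      env$climate <- read_climate_table(inp$climate)
      env$traits <- read_trait_table(inp$traits)
      env$cp_alignment <- NULL
    }
  })

  run_stage("transect", "simulate", function() {
    env$transect <- scale_transect(env$samples)
    write_results(env$transect, file.path(out_dir, "transect.tsv"), "TSV")
  })

  run_stage("cointro_scan", c("simulate", "transect"), function() {
    props <- gene_ancestry_proportions(env$ancestry, env$annotations)
    props <- props[env$samples$sample_id, , drop = FALSE]
    scan <- cointro_scan(
      props, env$transect$distance_scaled,
      as.numeric(env$samples$chlorotype == "PT"),
      n_starts = config$scan$n_starts %||% 20,
      seed = child_seed(seed, "scan"),
      delta = config$scan$delta %||% 2.0)
    write_results(scan$verdicts, file.path(out_dir, "verdicts.tsv"), "TSV")
    jsonlite::write_json(scan$summary, file.path(out_dir, "scan_summary.json"),
                         auto_unbox = TRUE)
    summary$genes <<- scan$summary
    summary$reference_clines <<- list(
      chloroplast = list(center = scan$cp_ref$fit$spec$center,
                         width = scan$cp_ref$fit$spec$width,
                         center_ci = scan$cp_ref$center_ci,
                         width_ci = scan$cp_ref$width_ci),
      nuclear_mean = list(center = scan$nuc_ref$fit$spec$center,
                          width = scan$nuc_ref$fit$spec$width,
                          center_ci = scan$nuc_ref$center_ci,
                          width_ci = scan$nuc_ref$width_ci))
  })

  run_stage("climate_assoc", "simulate", function() {
    assoc <- climate_scan(env$samples, env$climate)
    write_results(assoc, file.path(out_dir, "climate_assoc.tsv"), "TSV")
    ok <- assoc$status == "ok"
    summary$climate_slopes <<- setNames(
      as.list(round(assoc$slope[ok], 6)),
      paste(assoc$contact_zone[ok], assoc$variable[ok], sep = ":"))
  })

  run_stage("quantgen", "simulate", function() {
    gardens <- unique(env$traits$garden)
    traits <- unique(env$traits$trait_name)
    h2 <- list()
    for (tr in traits) {
      for (g in gardens) {
        vc <- estimate_h2(env$traits, g, tr)
        h2[[paste(tr, g, sep = ":")]] <- round(vc$H2, 6)
      }
    }
    fits <- lapply(traits, function(tr) {
      fit_cytonuclear(env$traits, env$samples, tr)
    })
    names(fits) <- traits
    write_results(
      data.frame(trait = rep(traits, each = 4),
                 term = rep(c("beta_N", "beta_C", "beta_NxC", "beta_E"),
                            length(traits)),
                 estimate = unlist(lapply(fits, function(f) {
                   c(f$beta_N, f$beta_C, f$beta_NxC, f$beta_E)
                 }))),
      file.path(out_dir, "trait_model.tsv"), "TSV")
    summary$heritability <<- h2
    summary$interaction <<- lapply(fits, function(f) round(f$beta_NxC, 6))
  })

  run_stage("cpdiff", "simulate", function() {
    if (is.null(env$cp_alignment)) {
      return(invisible(NULL))  # no alignment provided in inputs mode
    }
    cp <- env$cp_alignment
    ids <- names(cp$sequences)
    fd <- find_fixed_differences(cp$sequences,
                                 grep("^PT", ids, value = TRUE),
                                 grep("^PB", ids, value = TRUE))
    fd <- classify_effect(fd, cp$cds, cp$reference)
    write_results(fd, file.path(out_dir, "fixed_differences.tsv"), "TSV")
    summary$cp_fixed_differences <<- list(
      total = nrow(fd), nonsynonymous = sum(fd$effect == "nonsynonymous"),
      synonymous = sum(fd$effect == "synonymous"),
      noncoding = sum(fd$effect == "noncoding"))
  })

  hash_cfg <- config
  hash_cfg$output_dir <- NULL  # identical runs in different dirs hash equal
  report <- structure(
    list(config_hash = rlang::hash(hash_cfg), seed = seed,
         stages = stages, summary = summary,
         any_failure = any(vapply(stages, function(s) {
           s$status == "failed"
         }, logical(1)))),
    class = "run_report")
  jsonlite::write_json(unclass(report), file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed=%d config=%s\n", x$seed, x$config_hash))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-14s %-8s %6.2fs%s\n", s, st$status, st$wall_time,
                if (!is.null(st$reason)) paste0("  (", st$reason, ")") else ""))
  }
  invisible(x)
}
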