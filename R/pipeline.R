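# Pipeline orchestration: resolved configs with recorded hashes, staged
# artifact writing, and end-to-end runs (reference estimation -> qMTA per
# treatment -> DEG overlap summaries).

#' Resolve a pipeline configuration
#'
#' Accepts a JSON file path or a list. Required fields: `model` (model
#' file), `expression` (FPKM TSV), `conditions` (sample-to-condition JSON),
#' `de` (named list: treated condition -> DE TSV), `outdir`. Optional:
#' `medium` (JSON), `measurements` (JSON), `untreated` (default
#' `"control"`), `seed` (default 1), and stage parameter lists `context`,
#' `reference` (`biomass_fraction`, `uniform_fallback`, `slack`,
#' `n_samples`, `thinning`), `qmta` (fields of [qmta_config()]). Every
#' default is materialized into the resolved config, which is written back
#' as `resolved_config.json` next to the outputs together with its hash, so
#' artifacts from different configurations are distinguishable.
#'
#' @param x path to a JSON config or a named list.
#' @return list of class `pipeline_config` (with `config_hash`).
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  req <- c("model", "expression", "conditions", "de", "outdir")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("config missing field(s): ", paste(miss, collapse = ", "))
  for (f in c("model", "expression", "conditions")) {
    if (!file.exists(cfg[[f]])) stop("config ", f, " file not found: ", cfg[[f]])
  }
  if (is.null(names(cfg$de)) || any(!nzchar(names(cfg$de)))) {
    stop("config 'de' must be a named list: condition -> DE table path")
  }
  for (p in unlist(cfg$de)) if (!file.exists(p)) stop("DE table not found: ", p)
  for (f in c("medium", "measurements")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config ", f, " file not found: ", cfg[[f]])
    }
  }
  cfg$untreated <- cfg$untreated %||% "control"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  ctx <- cfg$context %||% list()
  cfg$context <- list(fpkm_threshold = ctx$fpkm_threshold %||% 1,
                      biomass_fraction = ctx$biomass_fraction %||% 0.2,
                      de_fdr_threshold = ctx$de_fdr_threshold %||% 0.05,
                      biomass_reaction = ctx$biomass_reaction,
                      k_sd = ctx$k_sd %||% 2)
  ref <- cfg$reference %||% list()
  cfg$reference <- list(biomass_fraction = ref$biomass_fraction %||% 0.2,
                        uniform_fallback = ref$uniform_fallback %||% 1e-3,
                        slack = ref$slack %||% 0.01,
                        penalty_form = ref$penalty_form %||% "log2",
                        n_samples = ref$n_samples %||% 5000L,
                        thinning = ref$thinning %||% 100L,
                        n_warmup = ref$n_warmup %||% 100L)
  qm <- cfg$qmta %||% list()
  cfg$qmta <- list(p_th = qm$p_th %||% 0.25,
                   epsilon_ref = qm$epsilon_ref %||% 1e-6,
                   epsilon_fc = qm$epsilon_fc %||% 1e-6,
                   de_denom_squared = qm$de_denom_squared %||% TRUE,
                   ru_denom_squared = qm$ru_denom_squared %||% FALSE)
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

read_de_tsv <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "FDR")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop("DE table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(de$FC) && !is.null(de$log2FC)) de$FC <- 2^de$log2FC
  if (is.null(de$log2FC) && !is.null(de$FC)) de$log2FC <- log2(de$FC)
  de
}

read_measurements_json <- function(path) {
  if (is.null(path)) return(NULL)
  m <- jsonlite::fromJSON(path)
  if (length(m) == 0) return(NULL)
  as.data.frame(m, stringsAsFactors = FALSE)
}

read_medium_json <- function(path) {
  if (is.null(path)) return(NULL)
  m <- jsonlite::fromJSON(path)
  if (is.data.frame(m)) {
    medium_spec(stats::setNames(m$uptake, m$reaction),
                if (!is.null(m$secretion)) stats::setNames(m$secretion, m$reaction))
  } else {
    up <- vapply(m, function(e) as.numeric(e$uptake %||% 0), numeric(1))
    sec <- vapply(m, function(e) as.numeric(e$secretion %||% LP_BIG), numeric(1))
    medium_spec(stats::setNames(up, names(m)), stats::setNames(sec, names(m)))
  }
}

load_pipeline_inputs <- function(cfg) {
  list(model = load_model(cfg$model),
       profile = read_expression_tsv(cfg$expression, cfg$conditions),
       de_tables = lapply(cfg$de, read_de_tsv),
       medium = read_medium_json(cfg$medium),
       measurements = read_measurements_json(cfg$measurements))
}

build_pipeline_contexts <- function(cfg, inputs) {
  ctx_cfg <- context_config(fpkm_threshold = cfg$context$fpkm_threshold,
                            biomass_fraction = cfg$context$biomass_fraction,
                            de_fdr_threshold = cfg$context$de_fdr_threshold,
                            biomass_reaction = cfg$context$biomass_reaction,
                            k_sd = cfg$context$k_sd)
  build_context_model(inputs$model, inputs$profile, inputs$de_tables,
                      medium = inputs$medium,
                      measurements = inputs$measurements,
                      config = ctx_cfg, untreated = cfg$untreated)
}

#' Run the reference-flux stage of a configured pipeline
#'
#' Builds the control condition's context model, estimates the reference
#' flux distribution (expression-weighted minimization, 99%-optimum
#' restriction, hit-and-run sampling, sample mean) and writes
#' `reference/v_ref.tsv` plus a JSON sidecar carrying the penalty optimum,
#' slack, seed and config hash.
#'
#' @param config a [pipeline_config()] (or something coercible).
#' @return the `reference_result`, invisibly extended with `paths`.
#' @export
run_reference <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  inputs <- load_pipeline_inputs(cfg)
  contexts <- build_pipeline_contexts(cfg, inputs)
  control <- contexts$models[[cfg$untreated]]
  scores <- reaction_expression(control, inputs$profile, cfg$untreated)
  ref <- estimate_reference(
    control, scores,
    biomass_fraction = cfg$reference$biomass_fraction,
    uniform_fallback = cfg$reference$uniform_fallback,
    slack = cfg$reference$slack,
    penalty_form = cfg$reference$penalty_form,
    sampling = sampling_config(n_samples = cfg$reference$n_samples,
                               thinning = cfg$reference$thinning,
                               n_warmup = cfg$reference$n_warmup,
                               seed = cfg$seed))
  dir.create(file.path(cfg$outdir, "reference"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- c(v_ref = file.path(cfg$outdir, "reference", "v_ref.tsv"),
             sidecar = file.path(cfg$outdir, "reference", "reference.json"),
             provenance = file.path(cfg$outdir, "provenance.jsonl"),
             config = file.path(cfg$outdir, "resolved_config.json"))
  write_flux_tsv(ref$v_ref, control, paths[["v_ref"]])
  jsonlite::write_json(
    list(P_star = ref$fit$P_star, slack = ref$space$slack,
         biomass_floor = ref$fit$biomass_floor, seed = cfg$seed,
         n_samples = nrow(ref$samples), config_hash = cfg$config_hash),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  writeLines(vapply(contexts$provenance, function(rec) {
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1)), paths[["provenance"]])
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ref$paths <- paths
  ref$contexts <- contexts
  invisible(ref)
}

#' Run the qMTA stage for every treated condition
#'
#' Fits the quadratic transformation against the reference distribution on
#' each treatment's context model and writes, per condition, a result TSV
#' (`reaction`, `subsystem`, `v_ref`, `v_mta`, `log2fc`, `sign_flip`,
#' `direction`) and a JSON summary (objective decomposition, solver
#' status, config hash).
#'
#' @param config a [pipeline_config()].
#' @param reference the result of [run_reference()] (re-run when `NULL`).
#' @return named list of `qmta` fits, invisibly.
#' @export
run_qmta <- function(config, reference = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (is.null(reference)) reference <- run_reference(cfg)
  inputs <- load_pipeline_inputs(cfg)
  contexts <- reference$contexts %||% build_pipeline_contexts(cfg, inputs)
  qcfg <- qmta_config(p_th = cfg$qmta$p_th,
                      epsilon_ref = cfg$qmta$epsilon_ref,
                      epsilon_fc = cfg$qmta$epsilon_fc,
                      de_denom_squared = cfg$qmta$de_denom_squared,
                      ru_denom_squared = cfg$qmta$ru_denom_squared)
  fits <- list()
  for (cond in names(inputs$de_tables)) {
    mdl <- contexts$models[[cond]]
    vref <- reference$v_ref[mdl$reactions$id]
    fit <- qmta(mdl, vref, inputs$de_tables[[cond]],
                measurements = inputs$measurements, config = qcfg)
    if (fit$status != "optimal") {
      stop("qMTA stage failed for condition '", cond, "': ", fit$status)
    }
    rep <- pathway_report(fit)
    tab <- merge(fit$log2fc, rep[, c("reaction", "subsystem", "direction")],
                 by = "reaction", sort = FALSE)
    tab <- tab[order(tab$subsystem, tab$reaction),
               c("reaction", "subsystem", "v_ref", "v_mta", "log2fc",
                 "sign_flip", "direction")]
    out_tsv <- file.path(cfg$outdir, paste0("qmta_", cond, ".tsv"))
    utils::write.table(tab, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(condition = cond, objective = fit$objective,
           decomposition = as.list(fit$decomposition),
           status = fit$status, config_hash = cfg$config_hash),
      file.path(cfg$outdir, paste0("qmta_", cond, ".json")),
      auto_unbox = TRUE, digits = NA)
    fits[[cond]] <- fit
  }
  invisible(fits)
}

#' Run the whole pipeline
#'
#' Reference estimation, qMTA per treatment, pairwise DEG overlap
#' summaries between treatments, and a run report
#' (`report.json`). When a reference artifact with a matching config hash
#' already exists under `outdir`, the sampling stage is skipped and the
#' stored reference is reused; a hash mismatch (stale or corrupted cache)
#' triggers recomputation.
#'
#' @param config path to a JSON config or a list; see [pipeline_config()].
#' @return list of class `run_report`, invisibly.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  sidecar <- file.path(cfg$outdir, "reference", "reference.json")
  reference <- NULL
  if (file.exists(sidecar)) {
    side <- tryCatch(jsonlite::read_json(sidecar), error = function(e) NULL)
    if (!is.null(side) && identical(side$config_hash, cfg$config_hash)) {
      inputs <- load_pipeline_inputs(cfg)
      contexts <- build_pipeline_contexts(cfg, inputs)
      control <- contexts$models[[cfg$untreated]]
      vtab <- utils::read.delim(file.path(cfg$outdir, "reference", "v_ref.tsv"),
                                stringsAsFactors = FALSE)
      reference <- list(v_ref = flux_distribution(
        stats::setNames(vtab$flux, vtab$reaction_id), control),
        contexts = contexts, fit = list(P_star = side$P_star), cached = TRUE)
    }
  }
  if (is.null(reference)) reference <- run_reference(cfg)
  fits <- run_qmta(cfg, reference)
  venns <- list()
  conds <- names(cfg$de)
  if (length(conds) >= 2) {
    inputs2 <- lapply(cfg$de, read_de_tsv)
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i >= j) next
      a <- conds[i]; b <- conds[j]
      for (dir in c("up", "down")) {
        da <- filter_degs(ensure_pvalue(inputs2[[a]]))
        db <- filter_degs(ensure_pvalue(inputs2[[b]]))
        vs <- venn_overlap(da$gene[da$direction == dir],
                           db$gene[db$direction == dir], labels = c(a, b))
        key <- paste0(a, "_vs_", b, "_", dir)
        venns[[key]] <- vs
        jsonlite::write_json(unclass(vs),
                             file.path(cfg$outdir, paste0("venn_", key, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  report <- list(config_hash = cfg$config_hash, seed = cfg$seed,
                 reference = list(P_star = reference$fit$P_star,
                                  cached = isTRUE(reference$cached)),
                 conditions = conds,
                 qmta = lapply(fits, function(f) {
                   list(objective = f$objective, status = f$status)
                 }),
                 venn = lapply(venns, unclass))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(report = report, fits = fits, reference = reference,
                 venns = venns), class = "run_report")
}

ensure_pvalue <- function(de) {
  if (is.null(de$pvalue)) de$pvalue <- de$FDR
  de
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> conditions: ",
      paste(x$report$conditions, collapse = ", "), "\n", sep = "")
  for (cond in names(x$report$qmta)) {
    cat("  qMTA ", cond, ": objective ",
        format(x$report$qmta[[cond]]$objective, digits = 6), "\n", sep = "")
  }
  invisible(x)
}
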