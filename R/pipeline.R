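# One-config orchestration: QC -> relationship matrices -> sire-dam DHGLM
# -> genetic parameters -> masking cross-validation -> index selection.

#' Run configuration
#'
#' @param input either a fixture directory (from [write_fixture()]) via
#'   `fixture_dir`, or explicit `pedigree`/`genotypes`/`phenotypes` file
#'   paths, or an in-memory `"sim_dataset"` via `dataset`.
#' @param models data.frame (or list of lists) of model variants with
#'   columns `genetic_param`, `relationship`, `transform`; defaults to the
#'   animal-model evaluations on both relationship matrices and scales.
#' @param qc list of SNP QC thresholds (`call_rate_min`, `hwe_p_cutoff`,
#'   `maf_min`).
#' @param cv list with `k` (folds) and `seed`.
#' @param selection list with `b1`, `b2`, `proportion` for sire index
#'   selection on log-scale GEBV.
#' @param blend_weight weight on G when blending before inversion.
#' @param control a [dhglm_control()].
#' @param output_dir report directory.
#' @param seed master seed for the run.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input, models = NULL,
                       qc = list(call_rate_min = 0.90,
                                 hwe_p_cutoff = 1e-15, maf_min = 0.01),
                       cv = list(k = 10, seed = 1),
                       selection = list(b1 = 0.3, b2 = 0.7,
                                        proportion = 0.10),
                       blend_weight = 0.99,
                       control = dhglm_control(),
                       output_dir = NULL, seed = 1) {
  if (is.null(models))
    models <- expand.grid(genetic_param = "animal",
                          relationship = c("A", "H"),
                          transform = c("standardized", "log"),
                          stringsAsFactors = FALSE)
  structure(list(input = input, models = models, qc = qc, cv = cv,
                 selection = selection, blend_weight = blend_weight,
                 control = control, output_dir = output_dir,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(input = cfg$input)
  if (!is.null(cfg$models))
    args$models <- do.call(rbind,
                           lapply(cfg$models, as.data.frame))
  for (nm in c("qc", "cv", "selection", "blend_weight", "output_dir",
               "seed"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$control))
    args$control <- do.call(dhglm_control, cfg$control)
  do.call(run_config, args)
}

.load_input <- function(input) {
  if (inherits(input, "sim_dataset"))
    return(list(ped = input$ped, genotypes = input$genotypes,
                phenotypes = input$phenotypes))
  if (!is.null(input$dataset))
    return(.load_input(input$dataset))
  if (!is.null(input$fixture_dir)) {
    fx <- read_fixture(input$fixture_dir)
    return(list(ped = fx$ped, genotypes = fx$genotypes,
                phenotypes = fx$phenotypes))
  }
  if (is.null(input$pedigree) || is.null(input$phenotypes))
    stop("input must provide a dataset, fixture_dir, or pedigree + ",
         "phenotypes paths")
  phen <- utils::read.csv(input$phenotypes, stringsAsFactors = FALSE)
  list(ped = read_pedigree(input$pedigree),
       genotypes = if (!is.null(input$genotypes))
         read_genotypes(input$genotypes) else NULL,
       phenotypes = phen)
}

#' Run the full evaluation pipeline
#'
#' Executes SNP quality control, relationship-matrix construction,
#' sire-dam DHGLM variance-component estimation per relationship and
#' scale, derived genetic parameters, masking cross-validation of every
#' requested model variant (components always from the matching sire-dam
#' fit), and sire index selection. Reports are written to
#' `config$output_dir` when set.
#'
#' @param config a [run_config()].
#' @return list of class `"pipeline_result"`: `parameters` (per
#'   relationship x transform), `fits`, `crossval` (per variant),
#'   `selection`, `qc_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- .load_input(config$input)
  ped <- dat$ped
  phen <- dat$phenotypes
  models <- config$models
  need_h <- any(models$relationship == "H")
  if (need_h && is.null(dat$genotypes))
    stop("pipeline stage 'input': model variant requests H but no ",
         "genotypes were provided")
  qc_report <- NULL
  G <- NULL
  genotyped_ids <- character(0)
  if (!is.null(dat$genotypes)) {
    qc_out <- .stage("snp_qc", do.call(qc_snps, c(list(dat$genotypes),
                                                  config$qc)))
    qc_report <- qc_out$report
    scaled <- .stage("genomic_matrix", scale_genotypes(qc_out$genotypes))
    G <- build_genomic_relationship(scaled)
    genotyped_ids <- G$ids
    phen$genotyped <- phen$animal %in% genotyped_ids
  }
  # analysis-scale responses
  transforms <- unique(models$transform)
  responses <- list()
  specs_tr <- list()
  for (tr in transforms) {
    if (tr == "standardized") {
      st <- standardize(phen$weight)
      responses[[tr]] <- st$values
      specs_tr[[tr]] <- st$spec
    } else {
      specs_tr[[tr]] <- transform_spec("log")
      responses[[tr]] <- apply_transform(phen$weight, specs_tr[[tr]])
    }
  }
  # sire-dam variance components per relationship x transform
  fits <- list()
  params <- list()
  for (rel in unique(models$relationship)) {
    sd_spec <- model_spec("sire_dam", rel, "standardized")
    ev <- .stage(paste0("relationship_", rel),
                 evaluation_inverse(ped, sd_spec, G = G,
                                    genotyped_ids = genotyped_ids,
                                    blend_weight = config$blend_weight))
    for (tr in transforms) {
      key <- paste(rel, tr, sep = ".")
      ph <- phen
      ph$y <- responses[[tr]]
      fit <- .stage(paste0("dhglm_sire_dam_", key),
                    fit_dhglm(ph, ped,
                              model_spec("sire_dam", rel, tr),
                              ev$Kinv, control = config$control))
      fits[[key]] <- fit
      params[[key]] <- genetic_parameters(fit)
    }
  }
  # cross-validation per requested variant
  crossval <- list()
  blups <- list()
  for (i in seq_len(nrow(models))) {
    gp <- models$genetic_param[i]
    rel <- models$relationship[i]
    tr <- models$transform[i]
    key <- paste(gp, rel, tr, sep = ".")
    spec <- model_spec(gp, rel, tr)
    ev <- evaluation_inverse(ped, spec, G = G,
                             genotyped_ids = genotyped_ids,
                             blend_weight = config$blend_weight)
    ph <- phen
    ph$y <- responses[[tr]]
    vc <- fits[[paste(rel, tr, sep = ".")]]$varcomps
    full <- .stage(paste0("blup_full_", key),
                   predict_breeding_values(ph, ped, spec, ev$Kinv, vc,
                                           control = config$control))
    blups[[key]] <- full
    adj <- adjusted_phenotypes(full)
    plan <- make_folds(ph, k = config$cv$k, seed = config$cv$seed)
    crossval[[key]] <- .stage(paste0("crossval_", key),
                              run_crossval(ph, ped, spec, ev$Kinv, vc,
                                           plan, adj,
                                           control = config$control,
                                           full_fit = full))
  }
  # index selection of sires on log-scale GEBV when available
  sel <- NULL
  log_keys <- names(blups)[endsWith(names(blups), ".log")]
  if (length(log_keys)) {
    bl <- blups[[log_keys[length(log_keys)]]]
    sires <- unique(ped$sire[!is.na(ped$sire)])
    ebv <- animal_ebv(bl, ped, ids = sires)
    idx <- compute_index(stats::setNames(ebv$ebv_mean, ebv$animal),
                         stats::setNames(ebv$ebv_disp, ebv$animal),
                         b1 = config$selection$b1,
                         b2 = config$selection$b2)
    chosen <- truncation_select(idx, config$selection$proportion)
    sel <- list(index = idx, selected = chosen,
                gain = genetic_gain(chosen, ebv))
  }
  out <- structure(list(parameters = params, fits = fits,
                        crossval = crossval, blups = blups,
                        selection = sel, qc_report = qc_report,
                        transform_specs = specs_tr,
                        models = models, seed = config$seed),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) .write_reports(out, config)
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_reports <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_parameter_table(result$parameters,
                        file.path(config$output_dir, "parameters.csv"))
  cv_rows <- do.call(rbind, lapply(names(result$crossval), function(k) {
    s <- result$crossval[[k]]$summary
    data.frame(model = k, s)
  }))
  utils::write.csv(cv_rows, file.path(config$output_dir,
                                      "crossval_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  fold_rows <- do.call(rbind, lapply(names(result$crossval), function(k)
    data.frame(model = k, result$crossval[[k]]$per_fold)))
  utils::write.csv(fold_rows, file.path(config$output_dir,
                                        "crossval_folds.csv"),
                   row.names = FALSE, quote = FALSE)
  for (k in names(result$blups)) {
    b <- result$blups[[k]]
    ebv <- data.frame(id = names(b$ebv_mean),
                      ebv_mean = unname(b$ebv_mean),
                      ebv_disp = unname(b$ebv_disp))
    utils::write.csv(ebv,
                     file.path(config$output_dir,
                               paste0("ebv_", gsub("\\.", "_", k),
                                      ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(result$selection)) {
    utils::write.csv(
      data.frame(id = names(result$selection$index),
                 index = unname(result$selection$index),
                 selected = names(result$selection$index) %in%
                   result$selection$selected),
      file.path(config$output_dir, "selection.csv"),
      row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(
    lapply(result$transform_specs, function(sp) {
      sp <- unclass(sp)
      sp[!vapply(sp, is.null, logical(1))]
    }),
    file.path(config$output_dir, "transform_specs.yaml"))
  traces <- unlist(lapply(names(result$fits), function(k)
    paste0(k, " iter ", seq_along(result$fits[[k]]$loglik_trace),
           " logL ",
           formatC(result$fits[[k]]$loglik_trace, digits = 8,
                   format = "f"))))
  writeLines(traces, file.path(config$output_dir, "loglik_trace.log"))
  invisible(NULL)
}
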