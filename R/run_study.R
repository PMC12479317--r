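# Batch orchestration: YAML run configuration -> expanded estimand list ->
# pruning -> estimation -> joint / delta post-estimands -> FDR adjustment ->
# TSV results table. Per-estimand failures are recorded per row, never fatal
# to the batch.

#' Read and validate a YAML run configuration
#'
#' See the package README for the schema: a `cohort` block (paths and column
#' roles), a `study` block (one of the `phewas`, `gwas_lite` or `custom`
#' templates), estimator/learner settings, positivity threshold, `alpha`,
#' FDR scope, optional sieve-variance settings and seeds.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg$cohort), is.list(cfg$study))
  cfg$estimator <- cfg$estimator %||% "wtmle"
  cfg$folds <- cfg$folds %||% 3L
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$positivity_threshold <- cfg$positivity_threshold %||% 0.01
  if (cfg$positivity_threshold < 0 || cfg$positivity_threshold > 0.5)
    stop("positivity_threshold must be in [0, 0.5]", call. = FALSE)
  cfg$seed <- cfg$seed %||% 1L
  cfg$fdr_scope <- cfg$fdr_scope %||% "batch"
  cfg$learners <- cfg$learners %||% list(Q = "glm", g = "glm")
  tmpl <- cfg$study$template %||% "custom"
  if (!tmpl %in% c("phewas", "gwas_lite", "custom"))
    stop("study template must be one of phewas, gwas_lite, custom",
         call. = FALSE)
  cfg$study$template <- tmpl
  svp <- cfg$svp %||% list(enabled = FALSE)
  svp$enabled <- isTRUE(svp$enabled)
  svp$trigger_p <- svp$trigger_p %||% 0.07
  cfg$svp <- svp
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

learner_from_name <- function(name) {
  switch(name,
         constant = lrn_constant(),
         glm = lrn_glm(),
         glm_interactions = lrn_glm(interactions = TRUE),
         glmnet = lrn_glmnet(),
         boost = lrn_boost(),
         stack = lrn_stack(lrn_constant(), lrn_glm(), lrn_glmnet()),
         hal = lrn_hal(),
         stop("unknown learner '", name, "'", call. = FALSE))
}

# Expand the study template into a list of single-contrast estimands, each
# tagged with an id. phewas: one variant x many outcomes; gwas_lite: many
# variants x one outcome; custom: explicit list. For 3-level genotypes each
# variant contributes its single-allele-copy contrasts.
expand_study <- function(cfg, data) {
  co <- cfg$cohort
  confounders <- unlist(co$confounders)
  covariates <- unlist(co$covariates) %||% character()
  make_components <- function(outcome, variant) {
    lv <- levels(factor(as.character(data[[variant]])))
    pairs <- if (!is.null(cfg$study$contrasts)) {
      lapply(cfg$study$contrasts, function(p) as.character(p))
    } else {
      lapply(seq_len(length(lv) - 1L), function(i) lv[c(i, i + 1L)])
    }
    lapply(pairs, function(p) {
      spec <- ate(outcome, variant, p[1L], p[2L], confounders, covariates)
      attr(spec, "id") <- paste0(outcome, ":", variant, ":",
                                 p[1L], "->", p[2L])
      spec
    })
  }
  tmpl <- cfg$study$template
  if (tmpl == "phewas") {
    variant <- cfg$study$variant
    outcomes <- unlist(cfg$study$outcomes)
    specs <- unlist(lapply(outcomes, make_components, variant = variant),
                    recursive = FALSE)
  } else if (tmpl == "gwas_lite") {
    outcome <- cfg$study$outcome %||% co$outcome
    variants <- unlist(cfg$study$variants)
    specs <- unlist(lapply(variants, function(v)
      make_components(outcome, v)), recursive = FALSE)
  } else {
    specs <- lapply(cfg$study$estimands, function(e) {
      treatments <- unlist(e$treatments)
      spec <- if (length(treatments) == 1L)
        ate(e$outcome, treatments, as.character(e$baseline),
            as.character(e$target), confounders, covariates)
      else
        aie(e$outcome, treatments, as.character(unlist(e$baseline)),
            as.character(unlist(e$target)), confounders, covariates)
      attr(spec, "id") <- e$id %||%
        paste0(e$outcome, ":", paste(treatments, collapse = "x"))
      spec
    })
  }
  specs
}

record_row <- function(id, spec, rec = NULL, status = "ok") {
  contrast <- paste(vapply(spec$contrast, function(p)
    paste0(p[["baseline"]], "->", p[["target"]]), ""), collapse = ",")
  if (is.null(rec))
    return(data.frame(id = id, outcome = spec$outcome,
                      treatments = paste(spec$treatments, collapse = "x"),
                      contrast = contrast, estimator = NA, n = NA,
                      estimate = NA, se = NA, ci_low = NA, ci_high = NA,
                      p = NA, p_adj = NA, svp_sigma2 = NA, svp_tau0 = NA,
                      svp_p = NA, status = status))
  data.frame(id = id, outcome = spec$outcome,
             treatments = paste(spec$treatments, collapse = "x"),
             contrast = contrast, estimator = rec$estimator, n = rec$n,
             estimate = rec$psi, se = rec$se, ci_low = rec$ci[1L],
             ci_high = rec$ci[2L], p = rec$p, p_adj = NA,
             svp_sigma2 = NA, svp_tau0 = NA, svp_p = NA, status = status)
}

#' Run a configured batch study
#'
#' Expands the study template into single-contrast estimands, applies
#' positivity pruning, estimates every kept component, adjusts p-values
#' (Benjamini-Hochberg within the configured FDR scope) and, when enabled,
#' applies the sieve-plateau variance correction to rows whose iid p-value
#' falls below the trigger threshold. Deterministic given the configuration
#' and seeds.
#'
#' @param config A `run_config` (from [read_run_config()]), a path to a
#'   YAML file, or an equivalent list.
#' @param data Optional in-memory cohort data.frame (otherwise
#'   `config$cohort$path` is read).
#' @param grm Optional [compute_grm()] object for the SVP correction
#'   (otherwise `config$svp$grm_prefix` is read).
#' @return A `study_result`: `$table` (the results data.frame, also written
#'   to `output_dir` when set), `$records`, `$pruning`.
#' @export
run_study <- function(config, data = NULL, grm = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  co <- cfg$cohort
  if (is.null(data))
    data <- as.data.frame(data.table::fread(co$path, header = TRUE))
  specs <- expand_study(cfg, data)
  ids <- vapply(specs, attr, "", "id")
  pruning <- positivity_prune(data, specs, cfg$positivity_threshold)
  kept_ids <- ids[vapply(specs, function(s) any(vapply(
    pruning$kept, identical, TRUE, s)), TRUE)]
  q_learner <- learner_from_name(cfg$learners$Q %||% "glm")
  g_learner <- learner_from_name(cfg$learners$g %||% "glm")
  rows <- vector("list", length(specs))
  records <- vector("list", length(specs))
  names(records) <- ids
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (!ids[i] %in% kept_ids) {
      rows[[i]] <- record_row(ids[i], spec, status = "pruned")
      next
    }
    rec <- tryCatch(
      estimate_effect(spec, data, estimator = cfg$estimator,
                      q_learner = q_learner, g_learner = g_learner,
                      folds = cfg$folds, seed = cfg$seed,
                      alpha = cfg$alpha),
      genetmle_empty_support = function(e) e, error = function(e) e)
    if (inherits(rec, "error")) {
      rows[[i]] <- record_row(ids[i], spec,
                              status = paste0("failed: ",
                                              conditionMessage(rec)))
    } else {
      records[[ids[i]]] <- rec
      rows[[i]] <- record_row(ids[i], spec, rec)
    }
  }
  table <- do.call(rbind, rows)
  ok <- table$status == "ok"
  if (any(ok)) {
    scope <- if (identical(cfg$fdr_scope, "per_outcome"))
      table$outcome[ok] else rep("batch", sum(ok))
    adj <- stats::ave(table$p[ok], scope, FUN = bh_adjust)
    table$p_adj[ok] <- adj
  }
  if (cfg$svp$enabled) {
    if (is.null(grm) && !is.null(cfg$svp$grm_prefix))
      grm <- read_grm(cfg$svp$grm_prefix)
    if (is.null(grm)) stop("svp enabled but no GRM available", call. = FALSE)
    n_taus <- cfg$svp$taus %||% 100L
    for (i in which(ok & table$p < cfg$svp$trigger_p)) {
      rec <- records[[table$id[i]]]
      curve <- sieve_curve(rec$eif, grm,
                           taus = seq(0, 1, length.out = n_taus))
      crec <- corrected_inference(rec, curve)
      table$svp_sigma2[i] <- crec$sigma2
      table$svp_tau0[i] <- crec$tau0
      table$svp_p[i] <- crec$p
      records[[table$id[i]]] <- crec
    }
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(table, file.path(cfg$output_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(table = table, records = records, pruning = pruning,
                 config = cfg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>", nrow(x$table), "rows;",
      sum(x$table$status == "ok"), "estimated,",
      sum(x$table$status == "pruned"), "pruned\n")
  invisible(x)
}
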