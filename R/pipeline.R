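#' Read a pipeline configuration file
#'
#' YAML with sections: `seed`, `n_boot`, `alpha`, `policy`
#' (`percentile_cut`, `absolute_threshold`, `combine`), `atlas`
#' (`n_cortex`, `n_subcortex`), `consistency` (`n_replicates`, `mode`),
#' and `tracers` — either the string "default" (the built-in template
#' suite) or a list of template rows. Every analysis knob with a
#' documented default may be omitted.
#'
#' @param path YAML file path.
#' @return Config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

default_config <- function() {
  list(seed = 1L, n_boot = 10000L, alpha = 0.05,
       policy = list(percentile_cut = 5, absolute_threshold = 0.1,
                     combine = "and"),
       atlas = list(n_cortex = 100L, n_subcortex = 54L),
       consistency = list(n_replicates = 1L, mode = "original_vs_others"),
       tracers = "default")
}

merge_config <- function(cfg) {
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(cfg[[nm]])))
      base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' Run the full variability pipeline
#'
#' Orchestrates the end-to-end analysis over a set of tracer studies:
#' per-tracer [receptor_variability()] fits, spatial-consistency scoring
#' against each study's replicate maps, the cross-tracer
#' ratio-vs-consistency correlation per compartment, and cohort covariate
#' diagnostics. Studies may be supplied directly (a list of
#' `tracer_study`), or described by a config (path or list), in which case
#' the synthetic suite is generated. Per-tracer failures are caught and
#' reported, not fatal.
#'
#' @param x list of `tracer_study` objects, a config list, or a YAML path.
#' @param out_dir optional directory; when given, regional tables (TSV),
#'   the summary table and a JSON run manifest are written there.
#' @param ... config overrides (e.g. `seed`, `n_boot`) when `x` is a
#'   config or path.
#' @return An object of class `recvar_pipeline`: `fits`, `consistency`,
#'   `correlation` (per compartment), `diagnostics`, `summary`, `errors`,
#'   `config`.
#' @export
run_pipeline <- function(x = default_config(), out_dir = NULL, ...) {
  if (is.character(x) && length(x) == 1L) x <- read_pipeline_config(x)
  if (is.list(x) && length(x) && all(vapply(x, inherits, TRUE,
                                            "tracer_study"))) {
    studies <- x
    cfg <- merge_config(list(...))
  } else {
    cfg <- merge_config(utils::modifyList(as.list(x), list(...)))
    atlas <- synthetic_atlas(n_cortex = cfg$atlas$n_cortex,
                             n_subcortex = cfg$atlas$n_subcortex)
    templates <- if (identical(cfg$tracers, "default")) tracer_templates()
      else do.call(rbind, lapply(cfg$tracers, as.data.frame))
    if (is.null(templates) || nrow(templates) == 0L)
      stop("config names no tracer studies", call. = FALSE)
    studies <- make_tracer_suite(templates, atlas = atlas,
                                 seed = cfg$seed,
                                 n_replicates = cfg$consistency$n_replicates)
  }
  if (!length(studies))
    stop("no tracer studies to analyse", call. = FALSE)
  policy <- filter_policy(cfg$policy$percentile_cut,
                          cfg$policy$absolute_threshold,
                          cfg$policy$combine)

  errors <- list()
  fits <- stats::setNames(vector("list", length(studies)),
                          vapply(studies, study_id, ""))
  consistency <- list()
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    id <- study_id(st)
    fits[[i]] <- tryCatch(
      receptor_variability(st, policy = policy, n_boot = cfg$n_boot,
                           seed = cfg$seed, alpha = cfg$alpha),
      error = function(e) {
        errors[[id]] <<- paste("fit:", conditionMessage(e))
        NULL
      })
    others <- attr(st, "other_maps")
    if (!is.null(others) && length(others)) {
      consistency[[id]] <- tryCatch(
        mean_consistency(apply_exclusions(st$mean_map, st),
                         lapply(others, apply_exclusions, study = st),
                         receptor = st$receptor,
                         mode = cfg$consistency$mode),
        error = function(e) {
          errors[[id]] <<- paste("consistency:", conditionMessage(e))
          NULL
        })
    }
  }
  ok <- !vapply(fits, is.null, TRUE)
  summary_tab <- if (any(ok))
    do.call(rbind, lapply(fits[ok], summary)) else NULL
  if (!is.null(summary_tab)) rownames(summary_tab) <- NULL

  correlation <- list()
  cons_ids <- names(consistency)[!vapply(consistency, is.null, TRUE)]
  for (cm in c("cortex", "subcortex")) {
    ids <- intersect(names(fits)[ok], cons_ids)
    if (length(ids) >= 4L) {
      ratios <- vapply(ids, function(id)
        fits[[id]]$compartments[[cm]]$ratio %||% NA_real_, 0)
      cons <- vapply(ids, function(id)
        consistency[[id]]$mean_consistency, 0)
      correlation[[cm]] <- tryCatch(
        ratio_vs_consistency(ratios, cons, seed = derive_seed(cfg$seed, cm)),
        error = function(e) list(error = conditionMessage(e)))
    }
  }

  diagnostics <- if (sum(ok) >= 4L) {
    mean_cvs <- vapply(fits[ok], function(f) {
      v <- map_values(f$cv_map, valid_only = TRUE)
      if (length(v)) mean(v) else NA_real_
    }, 0)
    tryCatch(covariate_diagnostics(studies[ok], mean_cvs,
                                   seed = derive_seed(cfg$seed, "covar")),
             error = function(e) NULL)
  } else NULL

  res <- structure(
    list(fits = fits, consistency = consistency,
         correlation = correlation, diagnostics = diagnostics,
         summary = summary_tab, errors = errors, config = cfg,
         n_failed = sum(!ok)),
    class = "recvar_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$fits)) {
    f <- res$fits[[id]]
    if (is.null(f)) next
    fname <- file.path(out_dir, paste0(
      gsub("[^A-Za-z0-9._-]+", "_", id), "_cv.tsv"))
    maps <- list(mean = f$mean_map, std = f$std_map, cv = f$cv_map)
    if (!is.null(f$scaled_cv)) maps$scaled_cv <- f$scaled_cv
    write_regional_table(maps, fname)
  }
  if (!is.null(res$summary))
    utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NaN")
  manifest <- list(
    config = res$config,
    n_tracers = length(res$fits),
    n_failed = res$n_failed,
    errors = res$errors,
    correlation = lapply(res$correlation, function(z)
      z[setdiff(names(z), "null_r")]),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' One row per tracer and compartment with all variability statistics,
#' plus significant-tracer counts per compartment ("k/N": tracers whose
#' inter-regional CV significantly exceeds the bootstrap null). Tracers
#' whose statistics are NA in a compartment are excluded from that
#' denominator with a note.
#'
#' @param results a `recvar_pipeline`.
#' @return An object of class `recvar_summary`: `table` (data.frame) and
#'   `counts` (per-compartment list with `n_significant`, `n_tested`,
#'   `n_excluded`, `label`).
#' @export
report_summary <- function(results) {
  stopifnot(inherits(results, "recvar_pipeline"))
  tab <- results$summary
  if (is.null(tab)) stop("pipeline produced no successful fits", call. = FALSE)
  counts <- lapply(split(tab, tab$compartment), function(d) {
    tested <- !is.na(d$significant)
    list(n_significant = sum(d$significant[tested]),
         n_tested = sum(tested), n_excluded = sum(!tested),
         label = sprintf("%d/%d", sum(d$significant[tested]), sum(tested)))
  })
  structure(list(table = tab, counts = counts,
                 n_failed = results$n_failed),
            class = "recvar_summary")
}

#' @export
print.recvar_summary <- function(x, ...) {
  cat("Variability pipeline summary\n")
  for (cm in names(x$counts)) {
    ct <- x$counts[[cm]]
    cat(sprintf(
      "  %-9s %s tracers with inter-regional CV significantly > null%s\n",
      cm, ct$label,
      ifelse(ct$n_excluded > 0,
             sprintf("  (%d not estimable, excluded)", ct$n_excluded), "")))
  }
  if (x$n_failed > 0)
    cat("  ", x$n_failed, "tracer fit(s) failed\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
print.recvar_pipeline <- function(x, ...) {
  cat(sprintf("Variability pipeline: %d tracers (%d failed), seed %d\n",
              length(x$fits), x$n_failed, x$config$seed))
  for (cm in names(x$correlation)) {
    z <- x$correlation[[cm]]
    if (!is.null(z$r))
      cat(sprintf(
        "  %-9s ratio vs consistency: Spearman r = %.2f, perm p = %.3g\n",
        cm, z$r, z$p_perm))
  }
  if (!is.null(x$summary)) {
    sig <- stats::aggregate(significant ~ compartment, x$summary,
                            function(s) sprintf("%d/%d", sum(s), length(s)))
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %-9s significant tracers: %s\n",
                  sig$compartment[i], sig$significant[i]))
  }
  invisible(x)
}
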