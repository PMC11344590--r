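#' Validate and normalise a run configuration
#'
#' A configuration is a list (or a YAML/JSON file parsed into one) with:
#' \describe{
#'   \item{databases}{list of entries `label`, `path`, `format`
#'     (`"tsv"`/`"fasta"`), optional numeric `threshold` metadata label.
#'     Entries must be sorted by ascending threshold when thresholds are
#'     given.}
#'   \item{models}{list of entries `name` plus either `store` (embedding
#'     store path) or `score_matrix` (square TSV of pairwise scores, higher =
#'     more similar).}
#'   \item{levels}{subset of `c("superfamily", "fold")`.}
#'   \item{schemes}{subset of `c("weighted", "unweighted")`.}
#'   \item{output_dir}{directory for TSV/JSON outputs.}
#'   \item{seed}{integer; routed to every stage that draws random numbers.}
#'   \item{filters}{optional: `excluded_fold_ids`, `require_single_span`.}
#' }
#'
#' @param config A list or a path to a YAML file.
#' @return The validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!length(config$databases)) stopf("config needs at least one database")
  if (!length(config$models)) stopf("config needs at least one model source")
  config$levels <- match.arg(config$levels %||% "superfamily",
                             c("superfamily", "fold"), several.ok = TRUE)
  config$schemes <- match.arg(config$schemes %||% c("weighted", "unweighted"),
                              c("weighted", "unweighted"), several.ok = TRUE)
  config$seed <- as.integer(config$seed %||% 1L)
  config$filters <- config$filters %||% list()
  th <- vapply(config$databases, function(d) as.numeric(d$threshold %||% NA_real_), 1)
  if (all(!is.na(th)) && is.unsorted(th)) {
    stopf("database thresholds must be sorted ascending")
  }
  for (d in config$databases) {
    if (is.null(d$label) || is.null(d$path)) {
      stopf("each database entry needs `label` and `path`")
    }
    if (!file.exists(d$path)) stopf("database path '%s' does not exist", d$path)
  }
  for (m in config$models) {
    if (is.null(m$name)) stopf("each model entry needs `name`")
    src <- m$store %||% m$score_matrix
    if (is.null(src)) stopf("model '%s' needs `store` or `score_matrix`", m$name)
  }
  if (is.null(config$output_dir)) stopf("config needs `output_dir`")
  config
}

load_config_database <- function(entry, filters) {
  fmt <- entry$format %||% "tsv"
  db <- switch(fmt,
    tsv = read_annotation_table(entry$path,
                                identity_threshold_label = entry$threshold),
    fasta = read_astral_fasta(entry$path,
                              identity_threshold_label = entry$threshold),
    stopf("unknown database format '%s'", fmt))
  apply_preprocessing_filters(
    db,
    excluded_fold_ids = filters$excluded_fold_ids %||% character(),
    require_single_span = isTRUE(filters$require_single_span)
  )
}

read_score_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(tab)
}

#' Run the full retrieval evaluation described by a configuration
#'
#' Orchestrates reading and filtering each database, building query tasks at
#' each level, ranking with each model source, computing per-query metrics
#' and both aggregation schemes, and writing all outputs under
#' `output_dir`: one per-query metrics TSV per (database, model, level)
#' combination, a combined `aggregate.tsv`, a per-level Spearman agreement
#' matrix whenever two or more models succeed, and a `run_report.json` with
#' drop counts and per-combination status. A failure in one combination is
#' recorded and does not abort the others. Byte-identical outputs for a fixed
#' config and seed.
#'
#' @param config See [validate_run_config()].
#' @return A `RunReport` list (invisibly): `combinations` status data frame,
#'   `aggregates`, `agreement`, `dropped`, `config`.
#' @export
run_evaluation <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  agg_rows <- list()
  status_rows <- list()
  dropped <- list()
  agreement <- list()
  for (dbe in config$databases) {
    db <- tryCatch(load_config_database(dbe, config$filters), error = identity)
    if (inherits(db, "error")) {
      for (m in config$models) for (lv in config$levels) {
        status_rows[[length(status_rows) + 1L]] <- data.frame(
          database = dbe$label, model = m$name, level = lv, status = "failed",
          message = conditionMessage(db), stringsAsFactors = FALSE)
      }
      next
    }
    for (lv in config$levels) {
      tasks <- tryCatch(suppressWarnings(build_query_tasks(db, lv)),
                        error = identity)
      if (inherits(tasks, "error") || !length(tasks)) {
        msg <- if (inherits(tasks, "error")) conditionMessage(tasks)
               else "no retained queries"
        for (m in config$models) {
          status_rows[[length(status_rows) + 1L]] <- data.frame(
            database = dbe$label, model = m$name, level = lv,
            status = "failed", message = msg, stringsAsFactors = FALSE)
        }
        next
      }
      level_records <- list()
      for (m in config$models) {
        res <- tryCatch({
          records <- if (!is.null(m$store)) {
            store <- load_representation_store(m$store, pool_if_needed = TRUE)
            evaluate_model(tasks, store = store)
          } else {
            evaluate_model(tasks, score_matrix = read_score_matrix(m$score_matrix))
          }
          records
        }, error = identity)
        if (inherits(res, "error")) {
          status_rows[[length(status_rows) + 1L]] <- data.frame(
            database = dbe$label, model = m$name, level = lv,
            status = "failed", message = conditionMessage(res),
            stringsAsFactors = FALSE)
          next
        }
        key <- sprintf("%s_%s_%s", dbe$label, m$name, lv)
        utils::write.table(
          res, file.path(config$output_dir, sprintf("metrics_%s.tsv", key)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        drop_log <- attr(res, "drop_log")
        dropped[[key]] <- list(
          zero_positive_queries = length(attr(tasks, "dropped")),
          no_negative_queries = length(drop_log$no_negatives),
          degenerate_queries = length(drop_log$degenerate))
        for (sc in config$schemes) {
          agg <- aggregate_metrics(res, sc, lv)
          agg_rows[[length(agg_rows) + 1L]] <- data.frame(
            database = dbe$label, model = m$name, level = lv, scheme = sc,
            t(agg$overall), n_queries = nrow(res),
            n_groups = nrow(agg$per_group), stringsAsFactors = FALSE)
        }
        level_records[[m$name]] <- res
        status_rows[[length(status_rows) + 1L]] <- data.frame(
          database = dbe$label, model = m$name, level = lv, status = "ok",
          message = "", stringsAsFactors = FALSE)
      }
      if (length(level_records) >= 2L) {
        # undefined when some model's AUROC list is constant (zero rank
        # variance); the run still succeeds without the agreement table
        am <- tryCatch(agreement_matrix(level_records, lv), error = identity)
        if (!inherits(am, "error")) {
          akey <- sprintf("%s_%s", dbe$label, lv)
          agreement[[akey]] <- am
          utils::write.table(
            cbind(model = rownames(am), as.data.frame(unclass(am))),
            file.path(config$output_dir, sprintf("agreement_%s.tsv", akey)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  combos <- do.call(rbind, status_rows)
  aggregates <- if (length(agg_rows)) do.call(rbind, agg_rows) else NULL
  if (!is.null(aggregates)) {
    utils::write.table(aggregates, file.path(config$output_dir, "aggregate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(combinations = combos, aggregates = aggregates,
                 agreement = agreement, dropped = dropped,
                 config = config)
  class(report) <- "RunReport"
  jsonlite::write_json(
    list(seed = config$seed,
         combinations = combos,
         dropped = dropped),
    file.path(config$output_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (all(combos$status == "failed")) {
    stopf("all configured combinations failed; see run_report.json")
  }
  invisible(report)
}

#' Best- and worst-performing groups by mean AUROC
#'
#' Reproduces the report-table layout that lists, for one model, the `n`
#' Superfamilies (or Folds) with the highest and lowest mean AUROC among
#' groups with more than `min_queries` retained queries, together with the
#' average number of true labels per query (`mean_true`) and the number of
#' queries (`n_queries`).
#'
#' @param records A `QueryMetricRecord` data frame for one model.
#' @param n Number of groups per panel.
#' @param min_queries Groups with `n_queries <= min_queries` are omitted.
#' @param level Grouping level.
#' @return A data frame with columns `panel` (`"top"`/`"bottom"`),
#'   `group_id`, `auroc`, `mean_true`, `n_queries`; ties broken by group id.
#' @export
top_bottom_groups <- function(records, n = 5L, min_queries = 5L,
                              level = c("superfamily", "fold")) {
  level <- match.arg(level)
  agg <- aggregate_metrics(records, "weighted", level)$per_group
  agg <- agg[agg$n_queries > min_queries, , drop = FALSE]
  if (nrow(agg) == 0L) {
    warnf("no groups with more than %d queries", min_queries)
    return(data.frame(panel = character(), group_id = character(),
                      auroc = numeric(), mean_true = numeric(),
                      n_queries = integer(), stringsAsFactors = FALSE))
  }
  sel <- function(df, decreasing) {
    ord <- order(df$auroc, df$group_id,
                 decreasing = c(decreasing, FALSE), method = "radix")
    utils::head(df[ord, , drop = FALSE], n)
  }
  top <- sel(agg, TRUE); bottom <- sel(agg, FALSE)
  panel <- function(df, tag) {
    data.frame(panel = tag, group_id = df$group_id, auroc = df$auroc,
               mean_true = df$mean_n_pos, n_queries = df$n_queries,
               stringsAsFactors = FALSE)
  }
  out <- rbind(panel(top, "top"), panel(bottom, "bottom"))
  rownames(out) <- NULL
  out
}

#' Groups with the largest AUROC difference between two models
#'
#' For every group shared by both models, the difference of per-group mean
#' AUROC is computed; the returned table holds two panels sorted descending:
#' `a_minus_b` (groups where model A beats model B most) and `b_minus_a`.
#' Groups present in only one model are omitted and counted in
#' `attr(, "n_omitted")`.
#'
#' @param records_a,records_b `QueryMetricRecord` data frames for the two
#'   models.
#' @param n Number of groups per panel.
#' @param level Grouping level.
#' @return A data frame with columns `panel`, `group_id`, `auroc_a`,
#'   `auroc_b`, `delta`.
#' @export
model_delta_table <- function(records_a, records_b, n = 10L,
                              level = c("superfamily", "fold")) {
  level <- match.arg(level)
  ga <- aggregate_metrics(records_a, "weighted", level)$per_group
  gb <- aggregate_metrics(records_b, "weighted", level)$per_group
  shared <- intersect(ga$group_id, gb$group_id)
  if (!length(shared)) stopf("the two models share no groups")
  all_groups <- union(ga$group_id, gb$group_id)
  ga <- ga[match(shared, ga$group_id), ]
  gb <- gb[match(shared, gb$group_id), ]
  base <- data.frame(group_id = shared, auroc_a = ga$auroc, auroc_b = gb$auroc,
                     delta = ga$auroc - gb$auroc, stringsAsFactors = FALSE)
  pick <- function(df, decreasing) {
    ord <- order(df$delta, df$group_id,
                 decreasing = c(decreasing, FALSE), method = "radix")
    utils::head(df[ord, , drop = FALSE], n)
  }
  top <- pick(base, TRUE)
  bot <- pick(transform(base, delta = -base$delta), TRUE)
  out <- rbind(data.frame(panel = "a_minus_b", top),
               data.frame(panel = "b_minus_a", bot))
  rownames(out) <- NULL
  attr(out, "n_omitted") <- length(setdiff(all_groups, shared))
  out
}
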