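# Orchestration: one reproducible run tying cohort generation / loading,
# optional FC estimation, the full assortativity battery and the hemispheric
# permutation tests together, with all intermediate files written as plain
# TSV/JSON.

#' Configuration of a pipeline run
#'
#' @param mode `"simulate"` (generate a synthetic cohort and analyze it),
#'   `"analyze"` (load per-subject SC/FC matrices and a node table from
#'   `input_dir`), `"estimate"` (load time series, estimate FC, write it, no
#'   cohort statistics) or `"full"` (alias of `"simulate"`).
#' @param input_dir Directory of input files (analyze/estimate modes):
#'   `sub-*_sc.tsv`, `sub-*_fc.tsv` or `sub-*_ts.tsv`, plus `nodes.tsv`.
#' @param output_dir Where results are written; created if needed.
#' @param cohort A `cohort_spec` (simulate/full modes).
#' @param enet An `elastic_net_config` (estimate mode, or analyze mode with
#'   time-series inputs).
#' @param method Correlation variant for every assortativity statistic:
#'   `"pearson"` or `"spearman"`.
#' @param strength_scope Block statistics: `"block"` or `"global"` strengths.
#' @param sc_log_transform Log-transform (`log(1 + w)`) SC weights before
#'   analysis (display-style transform; default `FALSE`, raw streamline
#'   counts).
#' @param n_permutations,alpha Permutation draws and significance level for
#'   the hemispheric tests.
#' @param statistic Paired test statistic, `"median"` or `"mean"`.
#' @param seed Global seed; all per-subject and per-stage seeds are derived
#'   from it deterministically.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "analyze", "estimate", "full"),
                       input_dir = NULL, output_dir = NULL,
                       cohort = cohort_spec(),
                       enet = elastic_net_config(),
                       method = c("pearson", "spearman"),
                       strength_scope = c("block", "global"),
                       sc_log_transform = FALSE,
                       n_permutations = 10000L, alpha = 0.05,
                       statistic = c("median", "mean"),
                       seed = 1L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  strength_scope <- match.arg(strength_scope)
  statistic <- match.arg(statistic)
  structure(list(mode = mode, input_dir = input_dir, output_dir = output_dir,
                 cohort = cohort, enet = enet, method = method,
                 strength_scope = strength_scope,
                 sc_log_transform = sc_log_transform,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 statistic = statistic, seed = as.integer(seed)),
            class = "run_config")
}

# serializable view of a run_config (for config.yaml / report.json)
.config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$cohort <- unclass(out$cohort)
  out$enet <- unclass(out$enet)
  out
}

.val <- function(av) if (is_defined(av)) av$value else NA_real_

# all assortativity measures for one subject
.subject_measures <- function(mx, part, method, scope, subject_id) {
  rows <- list()
  add <- function(measure, rsn, hemisphere, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject = subject_id, measure = measure, rsn = rsn,
      hemisphere = hemisphere, value = value, stringsAsFactors = FALSE)
  }
  blk <- function(net, pt, r) {
    if (!r %in% pt$rsn) return(NA_real_)   # label absent: cell undefined
    .val(block_assortativity(net, pt, r, r, scope, method))
  }
  add("within_sc", "global", "both", .val(within_layer_assortativity(mx$sc, method)))
  add("within_fc", "global", "both", .val(within_layer_assortativity(mx$fc, method)))
  add("between", "global", "both", .val(between_layer_assortativity(mx, method = method)))
  for (r in RSN_LABELS) {
    add("within_sc", r, "both", blk(mx$sc, part, r))
    add("within_fc", r, "both", blk(mx$fc, part, r))
    nodes_r <- part$node_id[part$rsn == r]
    bt <- if (length(nodes_r) >= 3)
      .val(between_layer_assortativity(mx, nodes_r, method)) else NA_real_
    add("between", r, "both", bt)
  }
  for (side in c("L", "R")) {
    mxs <- hemisphere_split(mx, part, side)
    ps <- partition_side(part, side)
    add("within_sc", "global", side, .val(within_layer_assortativity(mxs$sc, method)))
    add("within_fc", "global", side, .val(within_layer_assortativity(mxs$fc, method)))
    add("between", "global", side,
        if (length(mxs$nodes) >= 3)
          .val(between_layer_assortativity(mxs, method = method)) else NA_real_)
    for (r in RSN_LABELS) {
      add("within_sc", r, side, blk(mxs$sc, ps, r))
      add("within_fc", r, side, blk(mxs$fc, ps, r))
      nodes_r <- ps$node_id[ps$rsn == r]
      bt <- if (length(nodes_r) >= 3)
        .val(between_layer_assortativity(mxs, nodes_r, method)) else NA_real_
      add("between", r, side, bt)
    }
  }
  do.call(rbind, rows)
}

# hemispheric L-vs-R permutation tests over all (measure, rsn) cells,
# Bonferroni-corrected as one family
.hemisphere_tests <- function(measures, n_permutations, statistic, seed) {
  fams <- unique(measures[measures$hemisphere == "L", c("measure", "rsn")])
  res <- NULL
  for (q in seq_len(nrow(fams))) {
    me <- fams$measure[q]; r <- fams$rsn[q]
    lv <- measures$value[measures$measure == me & measures$rsn == r &
                           measures$hemisphere == "L"]
    rv <- measures$value[measures$measure == me & measures$rsn == r &
                           measures$hemisphere == "R"]
    ps <- paired_sample(lv, rv)
    if (length(ps$left) < 2) {
      res <- rbind(res, data.frame(
        measure = me, rsn = r, observed_median_diff = NA_real_,
        p = NA_real_, p_adjusted = NA_real_, n_used = length(ps$left),
        n_excluded = ps$n_excluded,
        n_permutations = n_permutations, seed = seed))
      next
    }
    pt <- paired_permutation_test(ps, n_permutations,
                                  seed = .derive_seed(seed, 51L, q),
                                  statistic = statistic)
    res <- rbind(res, data.frame(
      measure = me, rsn = r, observed_median_diff = pt$observed_stat,
      p = pt$p_value, p_adjusted = NA_real_, n_used = pt$n_pairs,
      n_excluded = ps$n_excluded,
      n_permutations = n_permutations, seed = seed))
  }
  ok <- !is.na(res$p)
  res$p_adjusted[ok] <- bonferroni_adjust(res$p[ok])
  res
}

# load an analyze-mode cohort from input_dir
.load_cohort <- function(input_dir, enet, seed) {
  part <- read_partition_tsv(file.path(input_dir, "nodes.tsv"))
  sc_files <- sort(list.files(input_dir, "^sub-.*_sc\\.tsv$", full.names = TRUE))
  if (!length(sc_files)) stop("no sub-*_sc.tsv files in ", input_dir)
  subjects <- vector("list", length(sc_files))
  for (k in seq_along(sc_files)) {
    sc <- read_network_tsv(sc_files[k])
    fc_file <- sub("_sc\\.tsv$", "_fc.tsv", sc_files[k])
    ts_file <- sub("_sc\\.tsv$", "_ts.tsv", sc_files[k])
    if (file.exists(fc_file)) {
      fc <- read_network_tsv(fc_file)
    } else if (file.exists(ts_file)) {
      panel <- read_timeseries_tsv(ts_file)
      ecfg <- enet
      ecfg$seed <- .derive_seed(seed, 61L, k)
      fc <- estimate_fc(panel, ecfg)
    } else {
      stop("subject ", basename(sc_files[k]),
           ": no matching _fc.tsv or _ts.tsv found")
    }
    bad <- union(setdiff(sc$nodes, part$node_id),
                 setdiff(fc$nodes, sc$nodes))
    if (length(bad))
      stop("node ids mismatch between matrices and metadata: ",
           paste(utils::head(bad, 5), collapse = ", "))
    subjects[[k]] <- multiplex_pair(sc, fc)
  }
  part <- .check_partition(part, subjects[[1]]$nodes)
  list(subjects = subjects, partition = part)
}

#' Run the full multiplex assortativity pipeline
#'
#' Simulates (or loads) a cohort of coupled SC/FC networks, estimates FC from
#' time series where matrices are absent, computes every assortativity family
#' (global, per-RSN block, per-RSN between-layer, all repeated per
#' hemisphere), runs the paired L-vs-R permutation tests with Bonferroni
#' correction, and writes `results/assortativity.tsv`, `results/tests.tsv`,
#' `report.json` and `config.yaml` under `output_dir` (when set). Two runs
#' with identical config and seed produce identical payloads.
#'
#' @param cfg A `run_config`.
#' @param cohort Optional pre-built `mx_cohort` (overrides simulation; useful
#'   for injected-effect studies).
#' @return A `run_report` list: `config`, `measures` (tidy per-subject
#'   data.frame), `summaries` (cohort medians/MADs per cell), `tests`
#'   (hypothesis table), `achieved` (generator targets, simulate mode),
#'   `n_undefined`.
#' @export
run_full <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$mode %in% c("simulate", "full") && is.null(cohort)) {
    spec <- cfg$cohort
    spec$seed <- .derive_seed(cfg$seed, 1L)
    cohort_obj <- generate_cohort(spec)
  } else if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "mx_cohort"))
    cohort_obj <- cohort
  } else {
    if (is.null(cfg$input_dir)) stop("analyze/estimate modes need input_dir")
    loaded <- .load_cohort(cfg$input_dir, cfg$enet, cfg$seed)
    cohort_obj <- structure(list(subjects = loaded$subjects,
                                 partition = loaded$partition,
                                 spec = NULL, achieved = NULL),
                            class = "mx_cohort")
  }
  part <- cohort_obj$partition
  if (cfg$sc_log_transform) {
    for (k in seq_along(cohort_obj$subjects)) {
      mx <- cohort_obj$subjects[[k]]
      if (min(mx$sc$weights) < 0) stop("sc_log_transform needs nonnegative SC")
      sc <- weighted_network(log1p(mx$sc$weights), nodes = mx$sc$nodes)
      cohort_obj$subjects[[k]] <- multiplex_pair(sc, mx$fc)
    }
  }
  measures <- do.call(rbind, lapply(seq_along(cohort_obj$subjects), function(k)
    .subject_measures(cohort_obj$subjects[[k]], part, cfg$method,
                      cfg$strength_scope, k)))
  # cohort medians/MADs per (measure, rsn, hemisphere) cell
  cells <- unique(measures[, c("measure", "rsn", "hemisphere")])
  summaries <- do.call(rbind, lapply(seq_len(nrow(cells)), function(q) {
    sel <- measures$measure == cells$measure[q] &
      measures$rsn == cells$rsn[q] &
      measures$hemisphere == cells$hemisphere[q]
    v <- measures$value[sel]
    if (all(is.na(v))) {
      data.frame(cells[q, ], median = NA_real_, mad = NA_real_,
                 n_used = 0L, n_undefined = sum(is.na(v)))
    } else {
      s <- cohort_summary(v)
      data.frame(cells[q, ], median = s$median, mad = s$mad,
                 n_used = s$n_used, n_undefined = s$n_undefined)
    }
  }))
  rownames(summaries) <- NULL
  tests <- if (length(cohort_obj$subjects) >= 2) {
    .hemisphere_tests(measures, cfg$n_permutations, cfg$statistic, cfg$seed)
  } else NULL
  report <- list(config = .config_as_list(cfg),
                 measures = measures, summaries = summaries, tests = tests,
                 achieved = cohort_obj$achieved,
                 n_subjects = length(cohort_obj$subjects),
                 n_undefined = sum(is.na(measures$value)),
                 version = as.character(utils::packageVersion("mxassort")))
  class(report) <- "run_report"
  if (!is.null(cfg$output_dir)) {
    out <- cfg$output_dir
    dir.create(file.path(out, "results"), recursive = TRUE,
               showWarnings = FALSE)
    if (!is.null(cohort_obj$spec)) {
      write_cohort(cohort_obj, file.path(out, "subjects"))
    }
    utils::write.table(measures, file.path(out, "results", "assortativity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tests))
      utils::write.table(tests, file.path(out, "results", "tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(.config_as_list(cfg), file.path(out, "config.yaml"))
    jsonlite::write_json(
      list(config = .config_as_list(cfg), summaries = summaries,
           tests = tests, achieved = cohort_obj$achieved,
           n_subjects = report$n_subjects,
           n_undefined = report$n_undefined, version = report$version),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subjects, %d undefined cells\n",
              x$n_subjects, x$n_undefined))
  g <- x$summaries[x$summaries$rsn == "global" &
                     x$summaries$hemisphere == "both", ]
  for (q in seq_len(nrow(g)))
    cat(sprintf("  %-10s median %+0.4f (MAD %.4f, n = %d)\n",
                g$measure[q], g$median[q], g$mad[q], g$n_used[q]))
  if (!is.null(x$tests)) {
    sig <- sum(x$tests$p_adjusted < 0.05, na.rm = TRUE)
    cat(sprintf("  hemispheric tests: %d of %d significant at adjusted 0.05\n",
                sig, sum(!is.na(x$tests$p))))
  }
  invisible(x)
}
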