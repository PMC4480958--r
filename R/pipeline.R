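#' Configure an end-to-end analysis run
#'
#' Exactly one input mode must be set: file mode (`ssm_path`, optionally
#' `manifest_path`) or synthetic mode (`sim` = a preset name, a
#' `sim_config`, or a list of them).
#'
#' @param out_dir output directory (created if missing).
#' @param ssm_path ICGC-style SSM TSV (file mode).
#' @param manifest_path optional donor manifest TSV (file mode).
#' @param sim synthetic mode: preset label for [preset_panel()], a
#'   [sim_config()], or a list of configs.
#' @param include consequence include-list (default
#'   [exonic_consequences()]).
#' @param min_mutations,min_donors cancer-type filters applied before
#'   analysis (defaults 4 and 0: types with fewer than 4 detected
#'   mutations are excluded).
#' @param min_fit_donors donor floor for per-type curve fitting
#'   (default 50).
#' @param min_fit_points minimum usable points for curve fitting
#'   (default 4).
#' @param target_donor_fraction donor coverage target for the fit stage
#'   (default 0.95).
#' @param linkage clustering linkage (default `"average"`).
#' @param merge_national_projects strip country suffixes and pool
#'   national projects of the same tumor type (default TRUE).
#' @param seed integer seed controlling synthetic generation.
#' @param plots also render PDF figures of the curves, burden
#'   distributions and dendrogram (default FALSE; all tabular outputs are
#'   written regardless).
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, ssm_path = NULL, manifest_path = NULL,
                       sim = NULL, include = exonic_consequences(),
                       min_mutations = 4L, min_donors = 0L,
                       min_fit_donors = 50L, min_fit_points = 4L,
                       target_donor_fraction = 0.95, linkage = "average",
                       merge_national_projects = TRUE, seed = 1L,
                       plots = FALSE) {
  if (is.null(ssm_path) == is.null(sim)) {
    stop("exactly one of `ssm_path` (file mode) or `sim` (synthetic mode) must be set")
  }
  if (!is.null(ssm_path) && !file.exists(ssm_path)) {
    stop("SSM file not found: ", ssm_path)
  }
  stopifnot(target_donor_fraction > 0, target_donor_fraction < 1)
  structure(list(out_dir = out_dir, ssm_path = ssm_path,
                 manifest_path = manifest_path, sim = sim,
                 include = include,
                 min_mutations = as.integer(min_mutations),
                 min_donors = as.integer(min_donors),
                 min_fit_donors = as.integer(min_fit_donors),
                 min_fit_points = as.integer(min_fit_points),
                 target_donor_fraction = target_donor_fraction,
                 linkage = linkage,
                 merge_national_projects = isTRUE(merge_national_projects),
                 seed = as.integer(seed), plots = isTRUE(plots)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full recurrence analysis pipeline
#'
#' Executes ingest/generate, project merging, consequence and cancer-type
#' filtering, per-type and PanCancer recurrence summaries, coverage
#' curves, power-law fits with donor-coverage targets, burden summaries,
#' and cosine-similarity clustering, writing every artifact under
#' `config$out_dir`:
#' `table1.tsv` (per-type summary table), `summaries.tsv` (raw counts),
#' `curves.tsv`, `fits.tsv`, `burden.tsv`, `burden_summary.tsv`,
#' `gene_matrix.tsv`, `similarity.tsv`, `dendrogram.nwk`, and
#' `manifest.json` (config echo, package version, seed, and row/donor
#' counts after each stage). Output is deterministic given the config:
#' re-running produces byte-identical files. Any stage failure aborts
#' with the stage name; artifacts already written are preserved.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the catalog, summaries, curves, fits,
#'   burden tables, similarity matrix, dendrogram and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  note <- function(stage, catalog) {
    stage_counts[[stage]] <<- list(calls = nrow(catalog$calls),
                                   donors = nrow(catalog$roster),
                                   cancer_types = uniqueN(catalog$roster$cancer_type))
  }

  catalog <- run_stage("ingest", {
    if (!is.null(config$ssm_path)) {
      manifest <- if (!is.null(config$manifest_path)) {
        read_donor_manifest(config$manifest_path)
      }
      read_icgc_ssm(config$ssm_path, manifest = manifest)
    } else {
      sim <- config$sim
      if (is.character(sim)) sim <- preset_panel(sim)
      generate_catalog(sim, seed = config$seed)
    }
  })
  note("ingest", catalog)

  if (config$merge_national_projects) {
    catalog <- run_stage("merge_projects", merge_projects(catalog))
  }
  note("merge_projects", catalog)

  catalog <- run_stage("filter_consequences",
                       filter_consequences(catalog, config$include))
  note("filter_consequences", catalog)

  catalog <- run_stage("filter_cancer_types",
                       filter_cancer_types(catalog, config$min_mutations,
                                           config$min_donors))
  note("filter_cancer_types", catalog)

  summaries <- run_stage("recurrence", recurrence_summary_all(catalog))
  fwrite(summaries, file.path(config$out_dir, "summaries.tsv"), sep = "\t")
  fwrite(table1_report(summaries), file.path(config$out_dir, "table1.tsv"),
         sep = "\t", quote = FALSE)

  scopes <- c(sort(unique(catalog$roster$cancer_type)), "PanCancer")
  tables <- run_stage("recurrence", {
    ts <- lapply(scopes, function(s) suppressWarnings(recurrence_counts(catalog, s)))
    names(ts) <- scopes
    ts
  })
  curves <- run_stage("coverage_curves", {
    cs <- lapply(tables, function(tb) {
      if (nrow(tb$counts) == 0L) NULL else coverage_curve(tb, catalog$roster)
    })
    cs[!vapply(cs, is.null, TRUE)]
  })
  fwrite(rbindlist(curves), file.path(config$out_dir, "curves.tsv"),
         sep = "\t")

  roster_n <- catalog$roster[, .N, by = cancer_type]
  fits <- run_stage("coverage_fits", {
    rows <- lapply(names(curves), function(s) {
      n_don <- if (s == "PanCancer") sum(roster_n$N) else roster_n[cancer_type == s]$N
      if (s != "PanCancer" && n_don < config$min_fit_donors) return(NULL)
      pts <- donors_vs_mutations(curves[[s]])
      fit <- tryCatch(fit_coverage_model(pts, config$min_fit_points, scope = s),
                      error = function(e) NULL)
      est <- tryCatch(
        mutation_fraction_at_coverage(pts, fit, config$target_donor_fraction),
        error = function(e) list(mutation_fraction = NA_real_,
                                 method = "not-estimable"))
      data.table(scope = s,
                 amplitude = if (is.null(fit)) NA_real_ else fit$amplitude,
                 exponent = if (is.null(fit)) NA_real_ else fit$exponent,
                 n_points = if (is.null(fit)) 0L else fit$n_points,
                 rss = if (is.null(fit)) NA_real_ else fit$rss,
                 x_at_target = est$mutation_fraction,
                 method = est$method)
    })
    rbindlist(rows[!vapply(rows, is.null, TRUE)])
  })
  fwrite(fits, file.path(config$out_dir, "fits.tsv"), sep = "\t")

  burden <- run_stage("burden", donor_burden(catalog))
  bsum <- run_stage("burden", burden_summary(burden))
  fwrite(burden, file.path(config$out_dir, "burden.tsv"), sep = "\t")
  fwrite(bsum, file.path(config$out_dir, "burden_summary.tsv"), sep = "\t")

  sim_out <- run_stage("similarity", {
    res <- list(matrix = NULL, similarity = NULL, dendrogram = NULL,
                skipped = NULL)
    rec <- pan_recurrent_set(tables[["PanCancer"]])
    n_types <- uniqueN(catalog$roster$cancer_type)
    if (nrow(rec) == 0L || n_types < 2L) {
      res$skipped <- "fewer than 2 cancer types or no recurrent mutations"
    } else {
      gm <- gene_donor_matrix(catalog, rec)
      sm <- cosine_similarity_matrix(gm)
      hc <- hierarchical_dendrogram(sm, config$linkage)
      fwrite(data.table(cancer_type = rownames(gm), as.data.table(gm)),
             file.path(config$out_dir, "gene_matrix.tsv"), sep = "\t")
      fwrite(data.table(cancer_type = rownames(sm), as.data.table(sm)),
             file.path(config$out_dir, "similarity.tsv"), sep = "\t")
      writeLines(to_newick(hc), file.path(config$out_dir, "dendrogram.nwk"))
      res <- list(matrix = gm, similarity = sm, dendrogram = hc,
                  skipped = NULL)
    }
    res
  })

  if (config$plots) {
    run_stage("plots", render_plots(config$out_dir, curves, bsum,
                                    sim_out$dendrogram))
  }

  manifest <- list(
    package = "mutrecur",
    version = as.character(packageVersion("mutrecur")),
    seed = config$seed,
    config = config_echo(config),
    stage_counts = stage_counts,
    similarity_skipped = sim_out$skipped)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(catalog = catalog, summaries = summaries, curves = curves,
                 fits = fits, burden = burden, burden_summary = bsum,
                 similarity = sim_out, manifest = manifest))
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # implied by the manifest's own location
  if (!is.null(cfg$sim) && !is.character(cfg$sim)) {
    sims <- if (inherits(cfg$sim, "sim_config")) list(cfg$sim) else cfg$sim
    cfg$sim <- lapply(sims, function(s) {
      s <- unclass(s)
      s$consequence_probs <- as.list(s$consequence_probs)
      s
    })
  }
  cfg
}

#' Format the per-cancer summary table
#'
#' Renders recurrence summaries in the layout of published per-cancer
#' tables: one row per cancer type plus a final PanCancer row, counts
#' with thousands separators, and recurrence cells formatted as
#' `"count (pct%)"`.
#'
#' @param summaries data.table from [recurrence_summary_all()] (or a list
#'   of one-row summaries).
#' @return data.table with display-formatted character columns.
#' @export
table1_report <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- rbindlist(summaries)
  }
  summaries <- as.data.table(summaries)
  stopifnot(nrow(summaries) >= 1L)
  ord <- order(summaries$scope == "PanCancer", summaries$scope)
  summaries <- summaries[ord]
  big <- function(x) format(x, big.mark = ",", trim = TRUE, scientific = FALSE)
  data.table(
    `Cancer Type` = summaries$scope,
    Donors = big(summaries$donors),
    `Total Unique Mutations` = big(summaries$total_unique_mutations),
    `Total Recurrent Mutations` = sprintf(
      "%s (%s)", big(summaries$recurrent_mutations), summaries$recurrent_pct),
    `Donors with Recurrent Mutations` = sprintf(
      "%s (%s)", big(summaries$donors_with_recurrent),
      summaries$donors_with_recurrent_pct))
}

render_plots <- function(out_dir, curves, bsum, dendrogram) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off())
  all_curves <- rbindlist(curves)
  graphics::plot(NA, xlim = range(all_curves$k), ylim = c(0, 1), log = "x",
                 xlab = "mutation recurrence threshold k",
                 ylab = "fraction of somatic mutations",
                 main = "Recurrence CCD")
  for (cv in curves) {
    graphics::lines(cv$k, cv$mutation_fraction,
                    col = if (cv$scope[1L] == "PanCancer") "blue" else "red")
  }
  graphics::barplot(stats::setNames(log10(pmax(bsum$median, 0.5)),
                                    bsum$cancer_type),
                    las = 2, ylab = "log10 median per-donor burden",
                    main = "Exonic burden medians")
  if (!is.null(dendrogram)) {
    graphics::plot(dendrogram, xlab = "", sub = "",
                   main = "Cancer types by cosine similarity")
  }
  invisible(NULL)
}
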