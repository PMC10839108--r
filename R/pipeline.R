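# Pipeline runner and report -------------------------------------------------

#' Pipeline configuration
#'
#' @param input path to a cohort CSV, or `"synthetic"` to simulate the
#'   reference study design.
#' @param metadata optional farm-metadata CSV path.
#' @param stages subset of `c("summaries", "anova", "typology", "subsample")`.
#'   `summaries` is implied by the others and always run first.
#' @param out_dir output directory (created if absent).
#' @param seed single top-level seed; all stage randomness is fanned out
#'   from it and logged in the manifest.
#' @param k,consolidate typology options ([ward_hcpc()]).
#' @param sizes,percentiles,max_enumeration,mode,n_draws subsample options
#'   ([subsample_config()]).
#' @param schema,delim cohort reader options ([read_cohort()]).
#' @return list of class `hcc_pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", metadata = NULL,
                            stages = c("summaries", "anova", "typology",
                                       "subsample"),
                            out_dir = "hccvar-out", seed = 1L, k = "auto",
                            consolidate = FALSE, sizes = c(5L, 10L, 15L, 20L),
                            percentiles = c(5, 50, 95), max_enumeration = 2e6,
                            mode = "exact", n_draws = 10000L,
                            schema = c(farm_id = "farm_id",
                                       batch_id = "batch_id",
                                       pig_id = "pig_id", hcc = "hcc_pg_mg"),
                            delim = ",") {
  known <- c("summaries", "anova", "typology", "subsample")
  stages <- unique(match.arg(stages, known, several.ok = TRUE))
  if (length(stages) == 0) stop("stage list is empty")
  if (!identical(input, "synthetic") && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  if (!is.null(metadata) && !file.exists(metadata)) {
    stop("metadata file not found: ", metadata)
  }
  structure(list(input = input, metadata = metadata,
                 stages = union("summaries", stages), out_dir = out_dir,
                 seed = as.integer(seed), k = k, consolidate = consolidate,
                 sizes = sizes, percentiles = percentiles,
                 max_enumeration = max_enumeration, mode = mode,
                 n_draws = n_draws, schema = schema, delim = delim),
            class = "hcc_pipeline_config")
}

format_csv_num <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

write_artifact <- function(df, path) {
  df[] <- lapply(df, format_csv_num)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the HCC analysis pipeline
#'
#' Executes the requested stages in dependency order, writing table- and
#' figure-ready CSV artifacts plus a JSON manifest (file list with MD5
#' content hashes, resolved configuration, stage timings). Artifacts are
#' byte-identical across runs with the same config and inputs: numeric CSV
#' output is fixed at 6 significant digits.
#'
#' Artifacts: `batch_summaries.csv` (per-batch table), `fig1_histogram.csv`,
#' `fig3_mean_sd.csv` + `mean_sd_regression.json`; `anova_table.csv` (with
#' eta-squared percentages), `diagnostics.json`, `qq_plot.csv`,
#' `batch_comparisons.csv`; `active_matrix.csv`, `pca_eigenvalues.csv`,
#' `cluster_membership.csv`, `vtest.csv`; `subsample_percentiles.csv` and
#' `fig5_percentile_means.csv` (values also given in percent).
#'
#' @param config an [pipeline_config()].
#' @return list of class `hcc_manifest` (also written to `manifest.json`):
#'   `artifacts` (name, path, md5), `config`, `timings`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hcc_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  timings <- list()
  add <- function(name, path) {
    artifacts[[name]] <<- list(file = basename(path),
                               md5 = unname(tools::md5sum(path)))
  }
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  cohort <- if (identical(config$input, "synthetic")) {
    emulate_study_design(seed = config$seed)
  } else {
    read_cohort(config$input, schema = config$schema, delim = config$delim)
  }
  meta <- if (!is.null(config$metadata)) {
    read_farm_metadata(config$metadata, cohort = cohort)
  }

  out <- file.path(config$out_dir, "")
  sm <- NULL
  tick("summaries", {
    sm <- batch_summaries(cohort)
    add("batch_summaries", write_artifact(sm, paste0(out,
                                                     "batch_summaries.csv")))
    h <- hist(cohort$hcc, breaks = "Sturges", plot = FALSE)
    add("fig1_histogram",
        write_artifact(data.frame(bin_left = h$breaks[-length(h$breaks)],
                                  bin_right = h$breaks[-1], count = h$counts),
                       paste0(out, "fig1_histogram.csv")))
    add("fig3_mean_sd",
        write_artifact(sm[, c("farm_id", "batch_id", "mean", "sd")],
                       paste0(out, "fig3_mean_sd.csv")))
    reg <- mean_sd_regression(sm)
    jsonlite::write_json(lapply(reg, format_csv_num),
                         paste0(out, "mean_sd_regression.json"),
                         auto_unbox = TRUE, digits = NA)
    add("mean_sd_regression", paste0(out, "mean_sd_regression.json"))
  })

  if ("anova" %in% config$stages) tick("anova", {
    fit <- fit_two_way_anova(cohort)
    tab <- fit$table
    tab$eta_squared_pct <- 100 * tab$eta_squared
    add("anova_table", write_artifact(tab, paste0(out, "anova_table.csv")))
    diag <- residual_diagnostics(fit)
    jsonlite::write_json(list(shapiro = lapply(diag$shapiro, format_csv_num),
                              levene = lapply(diag$levene, format_csv_num),
                              flags = diag$flags),
                         paste0(out, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    add("diagnostics", paste0(out, "diagnostics.json"))
    add("qq_plot", write_artifact(diag$qq, paste0(out, "qq_plot.csv")))
    add("batch_comparisons",
        write_artifact(tukey_batch_comparisons(cohort),
                       paste0(out, "batch_comparisons.csv")))
  })

  typ <- NULL
  if ("typology" %in% config$stages) tick("typology", {
    typ <- farm_typology(sm, metadata = meta, k = config$k,
                         consolidate = config$consolidate)
    am <- data.frame(farm_id = rownames(typ$active), typ$active)
    add("active_matrix", write_artifact(am, paste0(out, "active_matrix.csv")))
    add("pca_eigenvalues",
        write_artifact(data.frame(component = seq_along(typ$pca$eigenvalues),
                                  eigenvalue = typ$pca$eigenvalues,
                                  variance_explained_pct =
                                    100 * typ$pca$variance_explained),
                       paste0(out, "pca_eigenvalues.csv")))
    add("cluster_membership",
        write_artifact(data.frame(farm_id = names(typ$labels),
                                  cluster = as.integer(typ$labels)),
                       paste0(out, "cluster_membership.csv")))
    vt <- typ$vtest_active
    if (!is.null(typ$vtest_supplementary)) {
      va <- typ$vtest_active[, c("variable", "cluster", "v", "p",
                                 "significant")]
      va$level <- NA_character_
      vs <- typ$vtest_supplementary[, c("variable", "level", "cluster", "v",
                                        "p", "significant")]
      vt <- rbind(va[, c("variable", "level", "cluster", "v", "p",
                         "significant")], vs)
    }
    add("vtest", write_artifact(vt, paste0(out, "vtest.csv")))
  })

  if ("subsample" %in% config$stages) tick("subsample", {
    sub <- run_subsample_study(cohort,
                               subsample_config(sizes = config$sizes,
                                                mode = config$mode,
                                                max_enumeration =
                                                  config$max_enumeration,
                                                n_draws = config$n_draws,
                                                seed = config$seed,
                                                percentiles =
                                                  config$percentiles))
    pb <- sub$per_batch
    pb$value_pct <- 100 * pb$value
    add("subsample_percentiles",
        write_artifact(pb, paste0(out, "subsample_percentiles.csv")))
    mn <- sub$means
    mn$value_pct <- 100 * mn$value
    add("fig5_percentile_means",
        write_artifact(mn, paste0(out, "fig5_percentile_means.csv")))
  })

  manifest <- structure(
    list(artifacts = artifacts,
         config = config[setdiff(names(config), "schema")],
         schema = as.list(config$schema),
         seed = config$seed, timings = timings,
         n_records = nrow(cohort)),
    class = "hcc_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest
}

#' Render a human-readable pipeline report
#'
#' Restates per-stage headline numbers from a completed run's artifacts.
#' Display rounding is one decimal (table style); the underlying CSVs keep
#' 6 significant digits. Missing artifacts are listed as absent and
#' rendering continues.
#'
#' @param manifest an `hcc_manifest` from [run_pipeline()], or the path of a
#'   `manifest.json`.
#' @param out_dir directory holding the artifacts (defaults to the config's).
#' @return character vector of report lines, invisibly also written to
#'   `report.md` in `out_dir`.
#' @export
render_report <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) {
    path <- manifest
    manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(out_dir)) out_dir <- dirname(path)
  }
  if (is.null(out_dir)) out_dir <- manifest$config$out_dir
  lines <- c("# HCC pipeline report", "",
             paste0("seed: ", manifest$seed),
             paste0("records: ", manifest$n_records), "")
  get_art <- function(name) {
    a <- manifest$artifacts[[name]]
    if (is.null(a)) return(NULL)
    f <- file.path(out_dir, a$file)
    if (!file.exists(f)) return(NULL)
    read.csv(f, check.names = FALSE)
  }
  absent <- character(0)

  sm <- get_art("batch_summaries")
  if (!is.null(sm)) {
    lines <- c(lines, "## Batch summaries",
               paste0("batches: ", nrow(sm),
                      "; batch means (pg/mg) range ",
                      round(min(sm$mean), 1), "-", round(max(sm$mean), 1),
                      "; CV range ", round(min(sm$cv), 2), "-",
                      round(max(sm$cv), 2)), "")
  } else absent <- c(absent, "batch_summaries")

  an <- get_art("anova_table")
  if (!is.null(an)) {
    lines <- c(lines, "## Variance partition (eta-squared, %)",
               paste0(an$term, ": ", round(an$eta_squared_pct, 1),
                      collapse = "; "), "")
  } else if ("anova" %in% manifest$config$stages) {
    absent <- c(absent, "anova_table")
  }

  cl <- get_art("cluster_membership")
  if (!is.null(cl)) {
    grp <- split(cl$farm_id, cl$cluster)
    lines <- c(lines, "## Farm typology",
               vapply(names(grp), function(g) {
                 paste0("cluster ", g, " (n = ", length(grp[[g]]), "): ",
                        paste(grp[[g]], collapse = ", "))
               }, ""), "")
  } else if ("typology" %in% manifest$config$stages) {
    absent <- c(absent, "cluster_membership")
  }

  mn <- get_art("fig5_percentile_means")
  if (!is.null(mn)) {
    lines <- c(lines, "## Subsample study (mean percentile across batches, %)")
    for (stat in unique(mn$statistic)) {
      sub <- mn[mn$statistic == stat, ]
      lines <- c(lines, paste0(stat, ":"),
                 vapply(unique(sub$j), function(jj) {
                   s <- sub[sub$j == jj, ]
                   paste0("  j = ", jj, ": ",
                          paste0("p", s$percentile, " = ",
                                 round(s$value_pct, 1), collapse = ", "))
                 }, ""))
    }
    lines <- c(lines, "")
  } else if ("subsample" %in% manifest$config$stages) {
    absent <- c(absent, "fig5_percentile_means")
  }

  if (length(absent) > 0) {
    lines <- c(lines, "## Missing artifacts",
               paste0("- ", absent), "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(lines)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `summaries`, `anova`, `typology`, `subsample`,
#' `all`. Each maps onto [pipeline_config()] flags; `simulate` writes a
#' synthetic cohort CSV and its ground truth instead of running analyses.
#' An executable wrapper is installed at `system.file("cli", "hccvar",
#' package = "hccvar")`.
#'
#' @param args character vector, default the command line.
#' @return exit status, invisibly (0 on success).
#' @export
hccvar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hccvar <simulate|summaries|anova|typology|subsample|all>",
    "[--input PATH|synthetic] [--metadata PATH] [--out DIR] [--seed N]",
    "[--k N|auto] [--sizes 5,10,15,20] [--percentiles 5,50,95]")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- list(
    optparse::make_option("--input", default = "synthetic"),
    optparse::make_option("--metadata", default = NULL, type = "character"),
    optparse::make_option("--out", default = "hccvar-out"),
    optparse::make_option("--seed", default = 1L, type = "integer"),
    optparse::make_option("--k", default = "auto"),
    optparse::make_option("--sizes", default = "5,10,15,20"),
    optparse::make_option("--percentiles", default = "5,50,95"))
  parsed <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                                 args = args[-1])
  num <- function(s) as.numeric(strsplit(s, ",")[[1]])

  if (cmd == "simulate") {
    cohort <- emulate_study_design(seed = parsed$seed)
    dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(parsed$out, "synthetic_cohort.csv"))
    message("wrote ", file.path(parsed$out, "synthetic_cohort.csv"),
            " (", nrow(cohort), " records)")
    return(invisible(0L))
  }
  stages <- switch(cmd,
                   summaries = "summaries",
                   anova = "anova",
                   typology = "typology",
                   subsample = "subsample",
                   all = c("summaries", "anova", "typology", "subsample"),
                   stop("unknown subcommand '", cmd, "'\n", usage))
  k <- if (identical(parsed$k, "auto")) "auto" else as.integer(parsed$k)
  config <- pipeline_config(input = parsed$input, metadata = parsed$metadata,
                            stages = stages, out_dir = parsed$out,
                            seed = parsed$seed, k = k,
                            sizes = num(parsed$sizes),
                            percentiles = num(parsed$percentiles))
  manifest <- run_pipeline(config)
  render_report(manifest)
  message("artifacts in ", parsed$out)
  invisible(0L)
}
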