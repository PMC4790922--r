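#' End-to-end run configuration
#'
#' @param synth a [synth_config()] (synthetic input source), or NULL when
#'   reading volumes from disk.
#' @param input_dir,covariates_csv NIfTI directory plus covariates CSV
#'   (columns `subject_id, group, icv, age, site, time_to_scan, low_3ms,
#'   diabetes`; volumes at `<subject_id>.nii.gz`) when `synth` is NULL.
#' @param directions comparisons to run: subset of `c("less", "greater")`
#'   (group of interest vs the other arm).
#' @param params an [odvba_params()] (the `direction` field is overridden
#'   per comparison).
#' @param scheme a [permutation_scheme()].
#' @param alpha uncorrected (trend) voxel threshold.
#' @param cluster_alpha cluster-wise FWE threshold.
#' @param exclusions character flags for sensitivity runs (subjects with any
#'   named flag TRUE are dropped), e.g. `c("low_3ms", "diabetes")`.
#' @param n_regions atlas regions for the report.
#' @param atlas_seed seed of the synthetic atlas.
#' @param output_dir where all stage artifacts are written.
#' @param protect_group include a protected group column in the nuisance fit.
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), input_dir = NULL,
                       covariates_csv = NULL,
                       directions = "less",
                       params = odvba_params(),
                       scheme = permutation_scheme(),
                       alpha = 0.05, cluster_alpha = 0.05,
                       exclusions = character(),
                       n_regions = 8, atlas_seed = 1L,
                       output_dir = tempfile("odvba_run_"),
                       protect_group = FALSE) {
  stopifnot(alpha > 0, alpha < 1, cluster_alpha > 0, cluster_alpha < 1,
            all(directions %in% c("less", "greater")))
  if (is.null(synth) && (is.null(input_dir) || is.null(covariates_csv)))
    stop("exactly one input source: synth config, or input_dir + covariates_csv")
  structure(list(synth = synth, input_dir = input_dir,
                 covariates_csv = covariates_csv, directions = directions,
                 params = params, scheme = scheme, alpha = alpha,
                 cluster_alpha = cluster_alpha, exclusions = exclusions,
                 n_regions = as.integer(n_regions),
                 atlas_seed = as.integer(atlas_seed),
                 output_dir = output_dir, protect_group = protect_group),
            class = "run_config")
}

#' Drop flagged subjects for sensitivity analyses
#'
#' @param cohort a `synth_cohort`.
#' @param exclusions character vector of logical flag columns in the
#'   covariates (e.g. `"low_3ms"`, `"diabetes"`); subjects with any named
#'   flag TRUE are removed.
#' @return the filtered cohort; counts of removed subjects per arm are in
#'   attribute `removed`.
#' @export
subgroup_filter <- function(cohort, exclusions) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (length(exclusions) == 0) return(cohort)
  missing <- setdiff(exclusions, names(cohort$covariates))
  if (length(missing) > 0)
    stop("unknown exclusion flag(s): ", paste(missing, collapse = ", "))
  flagged <- Reduce(`|`, lapply(exclusions, function(f)
    as.logical(cohort$covariates[[f]])))
  removed <- table(cohort$covariates$group[flagged])
  keep <- !flagged
  out <- cohort
  out$subjects <- cohort$subjects[keep]
  out$covariates <- cohort$covariates[keep, , drop = FALSE]
  rownames(out$covariates) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Write a cohort to disk (NIfTI volumes + covariates CSV)
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  for (s in cohort$subjects)
    write_volume(s$volume, file.path(dir, paste0(s$subject_id, ext)))
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  mask_img <- array(as.integer(cohort$mask), dim(cohort$mask))
  write_volume(mask_img, file.path(dir, paste0("mask", ext)),
               grid = cohort$grid)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' @param dir directory holding `covariates.csv`, `mask.nii(.gz)` and one
#'   volume per `subject_id`.
#' @return a `synth_cohort`-shaped object (without ground truth).
#' @export
read_cohort <- function(dir) {
  cov_df <- utils::read.csv(file.path(dir, "covariates.csv"),
                            stringsAsFactors = FALSE)
  mask_path <- c(file.path(dir, "mask.nii.gz"), file.path(dir, "mask.nii"))
  mask_path <- mask_path[file.exists(mask_path)][1]
  if (is.na(mask_path)) stop("no mask volume in ", dir)
  mv <- read_volume(mask_path)
  mask <- mv$values > 0.5
  grid <- mv$grid
  subjects <- lapply(seq_len(nrow(cov_df)), function(i) {
    sid <- cov_df$subject_id[i]
    p <- c(file.path(dir, paste0(sid, ".nii.gz")),
           file.path(dir, paste0(sid, ".nii")))
    p <- p[file.exists(p)][1]
    if (is.na(p)) stop("missing volume for subject ", sid)
    v <- read_volume(p)
    list(subject_id = sid, covariates = as.list(cov_df[i, -1]),
         volume = volume_map(v$values, grid, mask))
  })
  structure(list(subjects = subjects, grid = grid, mask = mask,
                 covariates = cov_df, truth = NULL, config = NULL),
            class = "synth_cohort")
}

#' Run the full pipeline
#'
#' Stages: generate/ingest -> sensitivity filter -> nuisance adjustment ->
#' ODVBA statistic map -> permutation inference with cluster-wise FWE ->
#' atlas-partitioned region report; run once per configured comparison
#' direction. All stage artifacts (NIfTI maps, CSV tables, JSON manifest)
#' are written under `config$output_dir`.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress lines.
#' @return the run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_time <- list()
  paths <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    stage_time[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  cohort <- clock("input", {
    if (!is.null(config$synth)) generate_cohort(config$synth)
    else read_cohort(config$input_dir)
  })
  say("input: %d subjects, %d mask voxels", length(cohort$subjects),
      sum(cohort$mask))

  if (length(config$exclusions) > 0) {
    cohort <- clock("filter", subgroup_filter(cohort, config$exclusions))
    say("filter: removed %s", paste(attr(cohort, "removed"), collapse = "/"))
  }

  design <- clock("design", build_design(cohort,
                                         protect_group = config$protect_group))
  model <- clock("adjust_fit", fit_nuisance(cohort, design))
  Xadj <- clock("adjust", residualize(cohort, model))
  utils::write.csv(cohort$covariates,
                   file.path(out_dir, "covariates_used.csv"),
                   row.names = FALSE)

  atlas <- clock("atlas", generate_atlas(cohort$mask, cohort$grid,
                                         config$n_regions,
                                         seed = config$atlas_seed))
  write_volume(array(as.numeric(atlas$labels), dim(atlas$labels)),
               file.path(out_dir, "atlas.nii.gz"), grid = cohort$grid)
  utils::write.csv(
    data.frame(label = as.integer(names(atlas$names)),
               name = unname(atlas$names), side = unname(atlas$sides)),
    file.path(out_dir, "atlas_labels.csv"), row.names = FALSE)

  labels <- cohort_labels(cohort)
  nbs <- clock("neighborhoods",
               build_neighborhoods(cohort$mask, cohort$grid, config$params))
  say("neighborhoods: %d", length(nbs$members))

  reports <- list()
  for (dir_ in config$directions) {
    params <- config$params
    params$direction <- dir_
    tag <- if (dir_ == "less") "lt" else "gt"
    comparison <- if (dir_ == "less") "treated<placebo" else "treated>placebo"

    pmap <- clock(paste0("infer_", tag), permutation_pvalues(
      Xadj, labels, params, config$scheme,
      cluster_alpha = config$alpha, connectivity = 26,
      mask = cohort$mask, grid = cohort$grid, nbs = nbs))
    say("infer %s: %d permutations", tag, pmap$n_perm)

    write_volume(pmap$stat$phi, file.path(out_dir, paste0("stat_", tag, ".nii.gz")),
                 grid = cohort$grid)
    write_volume(pmap$p, file.path(out_dir, paste0("p_", tag, ".nii.gz")),
                 grid = cohort$grid)
    write_volume(-log10(pmap$p), file.path(out_dir, paste0("neglog10p_", tag, ".nii.gz")),
                 grid = cohort$grid)
    sig <- threshold_map(pmap, config$alpha)
    write_volume(array(as.numeric(sig), dim(sig)),
                 file.path(out_dir, paste0("trend_mask_", tag, ".nii.gz")),
                 grid = cohort$grid)

    cl <- cluster_fwe(find_clusters(sig, pmap$connectivity),
                      pmap$null_max_sizes)
    cl_df <- if (length(cl) == 0)
      data.frame(id = integer(), size = integer(), corrected_p = numeric())
    else data.frame(id = vapply(cl, `[[`, 0L, "id"),
                    size = vapply(cl, function(x) as.integer(x$size), 0L),
                    corrected_p = vapply(cl, `[[`, 0, "corrected_p"))
    utils::write.csv(cl_df, file.path(out_dir, paste0("clusters_", tag, ".csv")),
                     row.names = FALSE)

    rep_df <- clock(paste0("report_", tag), make_report(
      pmap, atlas, Xadj, labels, alpha = config$alpha,
      cluster_alpha = config$cluster_alpha, comparison = comparison))
    utils::write.csv(rep_df, file.path(out_dir, paste0("report_", tag, ".csv")),
                     row.names = FALSE)
    reports[[dir_]] <- rep_df
    paths[[paste0("report_", tag)]] <- file.path(out_dir, paste0("report_", tag, ".csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("odvba")),
    r_version = as.character(getRversion()),
    seeds = list(synth = if (!is.null(config$synth)) config$synth$seed,
                 permutation = config$scheme$seed,
                 atlas = config$atlas_seed),
    n_subjects = length(cohort$subjects),
    n_mask_voxels = sum(cohort$mask),
    n_neighborhoods = length(nbs$members),
    n_perm = config$scheme$n_perm,
    directions = config$directions,
    alpha = config$alpha, cluster_alpha = config$cluster_alpha,
    exclusions = config$exclusions,
    output_dir = out_dir,
    stage_seconds = stage_time,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$reports <- reports
  invisible(manifest)
}

#' Read a flat key=value run-configuration file
#'
#' Minimal flat config format: one `key = value` per line, optional
#' `[section]` headers (folded into `section.key`), `#` comments. Values
#' are parsed as numbers, logicals or comma-separated vectors where
#' possible.
#'
#' @param path file path.
#' @return named list of settings.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  section <- ""
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(parsed))) out[[key]] <- parsed
    else if (all(toupper(parts) %in% c("TRUE", "FALSE")))
      out[[key]] <- as.logical(toupper(parts))
    else out[[key]] <- parts
  }
  out
}
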