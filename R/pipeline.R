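#' Build (or validate) a pipeline run configuration
#'
#' The configuration drives [run_pipeline()]: an input manifest (one row
#' per sample with the collagen and elastin stack paths and a group
#' label), the physical pitch, the masking rule, the orientation window,
#' the metric windows, the per-sample summary statistic, classifier
#' options, the global seed and the output directory. Every numeric
#' output of a run is traceable to the hash of this configuration.
#'
#' @param manifest data frame with columns `sample_id`, `collagen`,
#'   `elastin` (TIFF paths) and `label`; or a path to such a CSV.
#' @param outdir run output directory (created if needed).
#' @param pitch voxel pitch (um).
#' @param mask list: `method`, `param`, `denoise` (see [foreground_mask()]).
#' @param orientation list: `window_radius`, `conf_threshold`.
#' @param metrics list: `variance_radius`, `coverage_radius`,
#'   `trace_length` (um).
#' @param summary_statistic `"mean"` or `"median"`.
#' @param classify list: `feature_subset` (default all six), `lambda`.
#' @param embed list: `perplexity`.
#' @param simulate optional list for the `simulate` stage: `n_normal`,
#'   `n_scar`, `n_adjacent`, `shape`, `noise_sd`.
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing so partial reruns stay reproducible.
#' @param check_paths require manifest paths to exist (disable when the
#'   `simulate` stage will create them).
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest, outdir, pitch = default_pitch(),
                       mask = list(method = "fixed_fraction", param = 0.1,
                                   denoise = TRUE),
                       orientation = list(window_radius = 2,
                                          conf_threshold = 0.05),
                       metrics = list(variance_radius = 5,
                                      coverage_radius = 5,
                                      trace_length = 10),
                       summary_statistic = "mean",
                       classify = list(feature_subset = NULL, lambda = 1e-3),
                       embed = list(perplexity = NULL),
                       simulate = NULL, seed = 1, check_paths = TRUE) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  need <- c("sample_id", "collagen", "elastin", "label")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id)) stopf("duplicate sample ids")
  if (check_paths && is.null(simulate)) {
    paths <- c(manifest$collagen, manifest$elastin)
    bad <- paths[!file.exists(paths)]
    if (length(bad))
      stopf("manifest paths do not exist: %s", paste(head(bad, 3),
                                                     collapse = ", "))
  }
  cfg <- structure(list(manifest = manifest, outdir = outdir,
                        pitch = as.numeric(pitch), mask = mask,
                        orientation = orientation, metrics = metrics,
                        summary_statistic = summary_statistic,
                        classify = classify, embed = embed,
                        simulate = simulate, seed = as.integer(seed)),
                   class = "run_config")
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The manifest may be inline (list of rows) or a path to a CSV relative
#' to the config file.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @param check_paths require manifest paths to exist.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, check_paths = TRUE) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  man <- raw$manifest
  if (is.character(man) && length(man) == 1) {
    mp <- if (file.exists(man)) man else file.path(dirname(path), man)
    man <- read.csv(mp)
  } else if (!is.data.frame(man)) {
    man <- do.call(rbind, lapply(man, as.data.frame))
  }
  args <- raw[setdiff(names(raw), "manifest")]
  do.call(run_config, c(list(manifest = man), args,
                        list(check_paths = check_paths)))
}

# canonical JSON of the config (sorted names) hashed with md5; storage
# location is excluded so the same analysis hashes identically wherever
# its outputs land
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$outdir <- NULL
  x$manifest$collagen <- basename(x$manifest$collagen)
  x$manifest$elastin <- basename(x$manifest$elastin)
  x <- x[order(names(x))]
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

# derive a stage seed from the global seed by stable string hashing
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100003L) * 7919L + (h %% 7919L)
}

pipeline_stages <- function() {
  c("simulate", "orient", "metrics", "summarize", "classify", "embed",
    "report")
}

#' Run the analysis pipeline
#'
#' Orchestrates the full flow for a cohort of two-channel stacks: per
#' sample and channel, foreground masking and 3D orientation extraction;
#' the three metric fields (directional variance, waviness, local
#' coverage) written as float TIFFs; per-sample feature summaries into a
#' feature CSV; group statistics and discriminant classification with
#' subset search; a 2D sample embedding; and a JSON report. A run
#' manifest records the package version, the config hash and the seed.
#' Later stages reuse cached earlier outputs (keyed by a parameter hash)
#' and fail with a dependency error if a required upstream product is
#' missing. Reruns with an identical config and seed are byte-identical
#' for all CSV/JSON outputs.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate","orient","metrics","summarize","classify","embed","report")`.
#' @return The run directory, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config,
                         stages = c("orient", "metrics", "summarize",
                                    "classify", "embed", "report")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  out <- config$outdir
  for (d in c("", "stacks", "orient", "metrics"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  man <- config$manifest
  channels <- c("collagen", "elastin")

  if ("simulate" %in% stages) man <- stage_simulate(config, out)

  if ("orient" %in% stages) {
    for (i in seq_len(nrow(man))) for (ch in channels) {
      src <- man[[ch]][i]
      if (!file.exists(src))
        stopf("orient stage: missing input stack %s", src)
      dst <- file.path(out, "orient",
                       sprintf("%s_%s.tif", man$sample_id[i], ch))
      key <- paste(tools::md5sum(src), config$orientation$window_radius,
                   config$mask$method, config$mask$param, collapse = "_")
      if (cache_fresh(dst, key)) next
      stack <- read_stack(src, ch, config$pitch)
      msk <- foreground_mask(stack, config$mask$method, config$mask$param,
                             config$mask$denoise %||% TRUE)
      orient <- orientation_field(stack, config$orientation$window_radius,
                                  msk, config$orientation$conf_threshold)
      write_orientation_field(orient, dst)
      cache_stamp(dst, key)
    }
  }

  if ("metrics" %in% stages) {
    for (i in seq_len(nrow(man))) for (ch in channels) {
      osrc <- file.path(out, "orient",
                        sprintf("%s_%s.tif", man$sample_id[i], ch))
      if (!file.exists(osrc))
        stopf("metrics stage: missing orientation cache %s (run 'orient')",
              osrc)
      pm <- config$metrics
      key <- paste(tools::md5sum(osrc), pm$variance_radius,
                   pm$coverage_radius, pm$trace_length, collapse = "_")
      base <- file.path(out, "metrics",
                        sprintf("%s_%s", man$sample_id[i], ch))
      if (cache_fresh(paste0(base, "_variance.tif"), key)) next
      orient <- read_orientation_field(osrc)
      write_stack(directional_variance(orient, pm$variance_radius),
                  paste0(base, "_variance.tif"))
      write_stack(waviness(orient, pm$trace_length),
                  paste0(base, "_waviness.tif"))
      write_stack(local_coverage(orient, pm$coverage_radius),
                  paste0(base, "_coverage.tif"))
      cache_stamp(paste0(base, "_variance.tif"), key)
    }
  }

  if ("summarize" %in% stages) {
    rows <- lapply(seq_len(nrow(man)), function(i) {
      fields <- list()
      for (ch in channels) for (m in c("variance", "waviness", "coverage")) {
        f <- file.path(out, "metrics",
                       sprintf("%s_%s_%s.tif", man$sample_id[i], ch, m))
        if (!file.exists(f))
          stopf("summarize stage: missing metric cache %s (run 'metrics')", f)
        vox <- read_stack(f, pitch = config$pitch)$voxels
        fields[[paste(m, ch, sep = "_")]] <-
          metric_field(vox, m, params = list(from = f))
      }
      summarize_sample(fields, config$summary_statistic,
                       sample_id = man$sample_id[i], group = man$label[i])
    })
    features <- do.call(rbind, rows)
    write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
  }

  features_path <- file.path(out, "features.csv")
  if (any(c("classify", "embed", "report") %in% stages) &&
      !file.exists(features_path))
    stopf("missing feature table %s (run 'summarize' first)", features_path)

  if ("classify" %in% stages) {
    features <- read.csv(features_path)
    sub <- config$classify$feature_subset %||% feature_names()
    lam <- config$classify$lambda %||% 1e-3
    ld <- lda_classify(features, features$group, sub)
    res <- list(feature_subset = sub, oca = ld$oca, cvca = ld$cvca,
                confusion_cv = as.data.frame(ld$confusion$cv))
    if (length(unique(features$group)) == 2) {
      lr <- logistic_roc_auc(features, features$group, sub, lambda = lam)
      res$auc <- lr$auc
      write.csv(lr$roc, file.path(out, "roc.csv"), row.names = FALSE)
      ss <- subset_search(features, features$group, min_size = 4,
                          max_size = 6, lambda = lam)
      write.csv(as.data.frame(ss), file.path(out, "subset_table.csv"),
                row.names = FALSE, fileEncoding = "UTF-8")
    }
    jsonlite::write_json(res, file.path(out, "classification.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("embed" %in% stages) {
    features <- read.csv(features_path)
    emb <- visne_embed(features,
                       config$classify$feature_subset %||% feature_names(),
                       seed = stage_seed(config$seed, "embed"),
                       perplexity = config$embed$perplexity %||%
                         min(10, (nrow(features) - 1) %/% 3))
    write.csv(emb, file.path(out, "embedding.csv"), row.names = FALSE)
  }

  if ("report" %in% stages) {
    features <- read.csv(features_path)
    groups <- unique(features$group)
    tests <- lapply(feature_names(), function(m) {
      tst <- if (length(groups) == 2) two_group_test(features, m)
             else if (length(groups) == 3) three_group_anova_tukey(features, m)
             else NULL
      if (is.null(tst)) return(NULL)
      list(metric = m, test = tst$test, statistic = tst$statistic,
           p_value = tst$p_value, stars = tst$stars)
    })
    screen <- collinearity_screen(features)
    report <- list(n_samples = nrow(features),
                   groups = as.list(table(features$group)),
                   collinearity_flags = nrow(screen$flagged),
                   tests = Filter(Negate(is.null), tests))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(
    list(package = "fiberarch",
         version = as.character(utils::packageVersion("fiberarch")),
         config_hash = hash, seed = config$seed, stages = stages),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

cache_fresh <- function(path, key) {
  side <- paste0(path, ".cache")
  file.exists(path) && file.exists(side) && identical(readLines(side), key)
}

cache_stamp <- function(path, key) writeLines(key, paste0(path, ".cache"))

# simulate stage: synthesize two-channel stacks per manifest row into
# outdir/stacks and rewrite the manifest paths accordingly
stage_simulate <- function(config, out) {
  man <- config$manifest
  sim <- config$simulate %||% list()
  shape <- sim$shape %||% c(64, 64, 32)
  noise_sd <- sim$noise_sd %||% 4
  base_seed <- stage_seed(config$seed, "simulate")
  for (i in seq_len(nrow(man))) {
    for (ch in c("collagen", "elastin")) {
      dst <- file.path(out, "stacks",
                       sprintf("%s_%s.tif", man$sample_id[i], ch))
      if (!file.exists(dst)) {
        res <- simulate_tissue_stack(ch, man$label[i], shape, config$pitch,
                                     noise_sd = noise_sd,
                                     seed = base_seed + 31L * i +
                                       (ch == "elastin"),
                                     sample_id = man$sample_id[i])
        vox <- round(res$stack$voxels)
        vox[vox > 65535] <- 65535
        write_stack(intensity_stack(vox, config$pitch, ch,
                                    man$sample_id[i]), dst)
      }
      man[[ch]][i] <- dst
    }
  }
  write.csv(man, file.path(out, "manifest.csv"), row.names = FALSE)
  man
}

#' Build a synthetic-cohort manifest for the simulate stage
#'
#' @param n_normal,n_scar,n_adjacent samples per group.
#' @param outdir run directory the stacks will be generated into.
#' @return Manifest data frame with prospective stack paths.
#' @export
synthetic_manifest <- function(n_normal = 5, n_scar = 5, n_adjacent = 0,
                               outdir = ".") {
  grp <- c(rep("normal", n_normal), rep("scar", n_scar),
           rep("adjacent", n_adjacent))
  ids <- sprintf("%s%02d", grp, unlist(lapply(table(grp)[unique(grp)],
                                              seq_len)))
  data.frame(sample_id = ids,
             collagen = file.path(outdir, "stacks",
                                  paste0(ids, "_collagen.tif")),
             elastin = file.path(outdir, "stacks",
                                 paste0(ids, "_elastin.tif")),
             label = grp)
}
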