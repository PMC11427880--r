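#' Read a question corpus from CSV or JSONL
#'
#' Validates the record schema: columns `id`, `platform`, `title`,
#' `body` required (`date`, `topic`, `n_answers` optional and carried
#' through), ids nonempty and unique. Questions with identical
#' normalized text are reported in an attribute (`duplicates`) and a
#' warning but never dropped automatically.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"` (one JSON object per line);
#'   guessed from the file extension by default.
#' @return A data frame of question records with attribute
#'   `duplicates` (character vector of ids sharing text with an
#'   earlier record).
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = character(0))
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    cols <- unique(unlist(lapply(recs, names)))
    as.data.frame(stats::setNames(lapply(cols, function(cl) {
      vapply(recs, function(r) as.character(r[[cl]] %||% NA_character_),
             character(1))
    }), cols), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(c("id", "platform", "title", "body"), names(df))
  if (length(missing_cols)) {
    hq_stop("corpus is missing required column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "healthqq_schema_error")
  }
  if (any(!nzchar(df$id) | is.na(df$id))) {
    hq_stop("corpus contains empty record ids",
            class = "healthqq_schema_error")
  }
  dup_ids <- unique(df$id[duplicated(df$id)])
  if (length(dup_ids)) {
    hq_stop("duplicate record id(s): ",
            paste(utils::head(dup_ids, 10), collapse = ", "),
            class = "healthqq_schema_error")
  }
  norm <- tolower(hq_squish(paste(df$title, df$body)))
  dups <- df$id[duplicated(norm)]
  if (length(dups)) {
    warning(length(dups), " record(s) share identical normalized text ",
            "with an earlier record (reported, not dropped): ",
            paste(utils::head(dups, 5), collapse = ", "))
  }
  attr(df, "duplicates") <- dups
  df
}

#' Write a corpus to CSV or JSONL
#' @param corpus Data frame of question records.
#' @param path Output path.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(corpus, path, row.names = FALSE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      writeLines(jsonlite::toJSON(as.list(corpus[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Persist and restore a fitted quality model as JSON
#'
#' Stores centroids, standardizer, labels, seed and the SSE curve so a
#' fit can be re-applied to new questions without refitting.
#'
#' @param fit A `question_quality` object.
#' @param path JSON file path.
#' @return `write_quality_model`: `path` invisibly;
#'   `read_quality_model`: a list with a usable `hq_kmeans` in `$model`
#'   plus `$labels` and `$elbow`.
#' @export
write_quality_model <- function(fit, path) {
  hq_assert(inherits(fit, "question_quality"), "fit must be question_quality")
  m <- fit$model
  obj <- list(k = m$k, centers = m$centers,
              standardizer = m$standardizer,
              sse = m$sse, seed = m$seed, n_restarts = m$n_restarts,
              labels = as.list(fit$labels),
              elbow = fit$elbow)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_quality_model
#' @export
read_quality_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  model <- structure(list(
    k = obj$k, centers = as.matrix(obj$centers),
    standardizer = list(center = unlist(obj$standardizer$center),
                        scale = unlist(obj$standardizer$scale)),
    cluster = NULL, sse = obj$sse, seed = obj$seed,
    n_restarts = obj$n_restarts), class = "hq_kmeans")
  list(model = model,
       labels = stats::setNames(as.integer(unlist(obj$labels)),
                                names(obj$labels)),
       elbow = obj$elbow)
}

#' Pipeline configuration
#'
#' Collects the inputs and defaults of the reference pipeline: `k = 3`
#' quality clusters and a 10% per-cluster validation sample, seeds for
#' every random stage, and output locations. Accepts a YAML or JSON
#' config file; explicit arguments override file values.
#'
#' @param file Optional YAML/JSON configuration file.
#' @param ... Overrides: `input`, `ratings`, `consensus`, `codes`,
#'   `lexicon_dir`, `k`, `k_range`, `seed`, `sample_fraction`, `ridge`,
#'   `out_dir`, `n_per_platform` (for simulated input).
#' @return A validated list of class `hq_pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(input = NULL, ratings = NULL, consensus = NULL, codes = NULL,
              lexicon_dir = NULL, k = 3L, k_range = 1:8, seed = 1L,
              sample_fraction = 0.10, ridge = 0, out_dir = "healthqq_out")
  if (!is.null(file)) {
    loaded <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        hq_stop("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(file)
    } else {
      jsonlite::fromJSON(file)
    }
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (p in c("input", "ratings", "consensus", "codes", "lexicon_dir")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      hq_stop("configured path does not exist: ", p, " = ", cfg[[p]],
              class = "healthqq_config_error")
    }
  }
  hq_assert(cfg$sample_fraction > 0 && cfg$sample_fraction <= 1,
            "sample_fraction must be in (0, 1]")
  cfg$k <- as.integer(cfg$k)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "hq_pipeline_config")
}

#' Run the full quality-measurement pipeline
#'
#' Executes the stages in order -- read (or simulate) corpus,
#' featurize, cluster and label, stratified validation sample,
#' validation statistics (when ratings are supplied), determinant
#' regression (when codes are supplied) -- writing every artifact plus
#' a machine-readable run manifest to `out_dir`. All randomness flows
#' from the configured seed; rerunning an identical config reproduces
#' identical numeric outputs.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  hq_assert(inherits(config, "hq_pipeline_config"),
            "config must come from pipeline_config()")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[healthqq] stage: ", name)
    tryCatch(expr, error = function(e) {
      hq_stop("stage '", name, "' failed: ", conditionMessage(e),
              class = "healthqq_pipeline_error")
    })
  }

  planted <- NULL
  corpus <- stage("corpus", {
    if (is.null(config$input)) {
      sim <- generate_corpus(synthetic_spec(seed = config$seed))
      planted <- sim
      write_corpus(sim$corpus, file.path(out, "corpus.csv"))
      utils::write.csv(sim$codes, file.path(out, "codes.csv"),
                       row.names = FALSE)
      sim$corpus
    } else {
      read_corpus(config$input)
    }
  })
  message("[healthqq]   ", nrow(corpus), " records")

  lexicons <- if (is.null(config$lexicon_dir)) default_lexicons() else
    default_lexicons(config$lexicon_dir)

  fit <- stage("cluster", {
    question_quality(corpus, k = config$k, k_range = config$k_range,
                     seed = config$seed, lexicons = lexicons)
  })
  utils::write.csv(fit$features, file.path(out, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$assignments, file.path(out, "assignments.csv"),
                   row.names = FALSE)
  write_quality_model(fit, file.path(out, "model.json"))

  sample_ids <- stage("validation_sample", {
    ok <- !is.na(fit$assignments$quality)
    stratified_sample(fit$assignments[ok, ], config$sample_fraction,
                      seed = config$seed + 1L)
  })
  writeLines(sample_ids, file.path(out, "validation_sample.txt"))

  report <- list(n_records = nrow(corpus),
                 k = config$k,
                 advisory_elbow_k = fit$elbow$k %||% NA,
                 cluster_sizes = as.list(table(fit$assignments$quality)),
                 n_validation_sample = length(sample_ids))

  if (!is.null(config$ratings)) {
    val <- stage("validation", {
      ratings <- utils::read.csv(config$ratings, stringsAsFactors = FALSE)
      pk <- panel_kappa(ratings)
      consensus <- if (!is.null(config$consensus)) {
        cons <- utils::read.csv(config$consensus, stringsAsFactors = FALSE)
        stats::setNames(cons$rating, cons$record_id)
      } else {
        majority_consensus(ratings)
      }
      common <- intersect(names(consensus), fit$assignments$id)
      r <- rating_cluster_correlation(
        consensus[common],
        fit$assignments$quality[match(common, fit$assignments$id)])
      list(panel = pk, pearson_r = r)
    })
    report$mean_kappa <- val$panel$mean_kappa
    report$pearson_r <- val$pearson_r
  }

  regression <- NULL
  codes <- if (!is.null(config$codes)) {
    utils::read.csv(config$codes, stringsAsFactors = FALSE)
  } else if (!is.null(planted)) planted$codes
  if (!is.null(codes)) {
    regression <- stage("regression", {
      d <- merge(codes, fit$assignments[, c("id", "quality")], by = "id")
      d <- d[!is.na(d$quality), ]
      d$quality <- factor(d$quality, levels = 1:3,
                          labels = c("high", "average", "low"))
      d$quality <- droplevels(d$quality)
      preds <- setdiff(names(d), c("id", "platform", "quality"))
      fml <- stats::reformulate(preds, response = "quality")
      fit_multinomial(fml, d, reference = "high", ridge = config$ridge)
    })
    utils::write.csv(summary(regression)$coefficients,
                     file.path(out, "coefficients.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "healthqq",
    version = as.character(utils::packageVersion("healthqq")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    report = report)
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(manifest$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(out_dir = out, fit = fit, report = report,
                 regression = regression, sample_ids = sample_ids,
                 manifest = manifest))
}
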