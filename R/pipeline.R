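#' Run configuration for the end-to-end pipeline
#'
#' One serializable record holding every tunable of the workflow; the run
#' report embeds the exact configuration (all defaults made explicit) that
#' produced it, so no silent defaults exist.
#'
#' @param method Entropy measure: `"msampen"` or `"mfuzen"`.
#' @param M Per-channel embedding sizes (recycled to the channel count if
#'   a single value is given).
#' @param r Tolerance.
#' @param s Fuzzy power (required when `method = "mfuzen"`).
#' @param normalization Frequency-normalization mode, see
#'   [embedding_config()].
#' @param tau_max Largest scale factor of the multiscale profile.
#' @param crop_size Optional center-crop size (single integer or
#'   `c(H, W)`); `NULL` means no crop.
#' @param normalize Z-normalize each image before entropy (the standard
#'   preprocessing for database images; synthetic MIX validation runs on
#'   raw values).
#' @param train_frac,n_repeats,kernel Classification settings, see
#'   [make_splits()] and [evaluate_splits()].
#' @param seed Master seed for split randomness and synthetic generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(method = c("msampen", "mfuzen"), M = 2L, r = 0.02,
                       s = NULL, normalization = c("consistent", "literal"),
                       tau_max = 5L, crop_size = NULL, normalize = FALSE,
                       train_frac = 0.75, n_repeats = 5L,
                       kernel = c("radial", "linear"), seed = 1L) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  kernel <- match.arg(kernel)
  if (method == "mfuzen" && is.null(s)) {
    stop("config field `s` (fuzzy power) is required for method = \"mfuzen\"",
         call. = FALSE)
  }
  structure(list(method = method, M = as.integer(M), r = r, s = s,
                 normalization = normalization, tau_max = as.integer(tau_max),
                 crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size),
                 normalize = isTRUE(normalize), train_frac = train_frac,
                 n_repeats = as.integer(n_repeats), kernel = kernel,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Synthetic two-class (or k-class) MIX input specification
#'
#' Describes a set of MIX2D image classes for [run_pipeline()]: one class
#' per entry of `p`, `n_per_class` images each, with per-image seeds drawn
#' deterministically from the pipeline seed.
#'
#' @param p Named numeric vector of noise probabilities, one class per
#'   entry (names become class labels; unnamed entries get `p<value>`).
#' @param n_per_class Images per class.
#' @param shape Image dimensions `c(H, W)`.
#' @param q Channels per image (default 3).
#' @param shared_mask See [mix_params()].
#' @return A list of class `mix_spec`.
#' @export
mix_spec <- function(p, n_per_class = 50L, shape = c(50L, 50L), q = 3L,
                     shared_mask = FALSE) {
  if (is.null(names(p))) names(p) <- sprintf("p%g", p)
  structure(list(p = p, n_per_class = as.integer(n_per_class),
                 shape = as.integer(shape), q = as.integer(q),
                 shared_mask = isTRUE(shared_mask)),
            class = "mix_spec")
}

# Load a labeled image folder (one subfolder per class) as a list of
# mcimages plus labels.
load_image_folder <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  classes <- list.dirs(path, recursive = FALSE)
  if (length(classes) == 0L) {
    stop("input folder has no class subfolders: ", path, call. = FALSE)
  }
  images <- list(); labels <- character(0); ids <- character(0)
  for (cls in classes) {
    files <- list.files(cls, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    for (f in files) {
      images[[length(images) + 1L]] <- read_image(f)
      labels <- c(labels, basename(cls))
      ids <- c(ids, basename(f))
    }
  }
  if (length(images) == 0L) stop("no readable images under ", path, call. = FALSE)
  list(images = images, labels = labels, ids = ids)
}

generate_mix_set <- function(spec, seed) {
  total <- length(spec$p) * spec$n_per_class
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, total)
  images <- vector("list", total); labels <- character(total); ids <- character(total)
  t <- 0L
  for (ci in seq_along(spec$p)) {
    for (i in seq_len(spec$n_per_class)) {
      t <- t + 1L
      images[[t]] <- generate_mix2d(mix_params(
        p = spec$p[[ci]], shape = spec$shape, q = spec$q, seed = seeds[t],
        shared_mask = spec$shared_mask))
      labels[t] <- names(spec$p)[ci]
      ids[t] <- sprintf("%s_%03d", names(spec$p)[ci], i)
    }
  }
  list(images = images, labels = labels, ids = ids)
}

#' Write / read a feature CSV
#'
#' The on-disk exchange format between the multiscale and classification
#' stages: columns `sample_id`, `label`, `tau_1..tau_k`; undefined
#' entropies are empty cells.
#'
#' @param features Numeric matrix of profile values (rows = samples).
#' @param labels,ids Per-row class labels and sample identifiers.
#' @param path CSV path.
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` returns a list with `features`, `labels`, `ids`.
#' @export
write_features_csv <- function(features, labels, ids, path) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("tau_", seq_len(ncol(features)))
  }
  df <- data.frame(sample_id = ids, label = labels, features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("feature CSV must have sample_id and label columns", call. = FALSE)
  }
  feat <- as.matrix(df[, setdiff(names(df), c("sample_id", "label")),
                       drop = FALSE])
  list(features = feat, labels = df$label, ids = df$sample_id)
}

#' Run the full texture-classification pipeline
#'
#' End to end: load a labeled image folder (or generate a synthetic MIX
#' set) → optional center crop → optional z-normalization → multiscale
#' entropy profile per image → SVM evaluation over repeated stratified
#' splits.  Writes the feature CSV and a JSON report (embedding the full
#' configuration, per-stage counts and timings) under `out_dir` and is
#' byte-deterministic for a fixed configuration.
#'
#' @param config A [run_config()].
#' @param input Either a directory path (one subfolder per class,
#'   PNG/TIFF images) or a [mix_spec()].
#' @param out_dir Output directory (created if missing).  `NULL` skips
#'   writing files.
#' @return Invisibly, a list with `features`, `labels`, `ids`, `report`
#'   (a `classification_report`), `config` and the output `paths`.
#' @examples
#' \donttest{
#' cfg <- run_config(method = "msampen", M = 2, r = 0.02, tau_max = 3,
#'                   seed = 7)
#' spec <- mix_spec(c(low = 0.2, high = 0.8), n_per_class = 8,
#'                  shape = c(30, 30))
#' res <- run_pipeline(cfg, spec, out_dir = NULL)
#' res$report$mean_accuracy
#' }
#' @export
run_pipeline <- function(config, input, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()

  src <- if (inherits(input, "mix_spec")) {
    generate_mix_set(input, config$seed)
  } else if (is.character(input) && length(input) == 1L) {
    load_image_folder(input)
  } else {
    stop("`input` must be a directory path or a mix_spec", call. = FALSE)
  }
  timings["load_s"] <- proc.time()[["elapsed"]] - t0

  q <- dim(src$images[[1L]])[3L]
  M <- config$M
  if (length(M) == 1L) M <- rep(M, q)
  if (length(M) != q) {
    stop(sprintf("config field `M` has length %d but images have %d channel(s)",
                 length(config$M), q), call. = FALSE)
  }
  cfg <- embedding_config(M = M, r = config$r, s = config$s,
                          normalization = config$normalization)

  t1 <- proc.time()[["elapsed"]]
  prep <- lapply(src$images, function(im) {
    if (!is.null(config$crop_size)) im <- center_crop(im, config$crop_size)
    if (config$normalize) im <- normalize_image(im)
    im
  })
  timings["preprocess_s"] <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  profiles <- lapply(prep, multiscale_profile, cfg = cfg,
                     method = config$method, tau_max = config$tau_max)
  feat <- do.call(rbind, lapply(profiles, `[[`, "values"))
  colnames(feat) <- paste0("tau_", seq_len(config$tau_max))
  timings["entropy_s"] <- proc.time()[["elapsed"]] - t2

  t3 <- proc.time()[["elapsed"]]
  tab <- feature_table(feat, src$labels, src$ids)
  splits <- make_splits(tab, train_frac = config$train_frac,
                        n_repeats = config$n_repeats, seed = config$seed)
  report <- evaluate_splits(tab, splits, kernel = config$kernel)
  timings["classify_s"] <- proc.time()[["elapsed"]] - t3

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fcsv <- file.path(out_dir, "features.csv")
    write_features_csv(feat, src$labels, src$ids, fcsv)
    rjson <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      config = unclass(config),
      n_images = length(src$images),
      n_classes = length(unique(src$labels)),
      n_excluded_undefined = tab$n_excluded,
      split_accuracies_pct = report$accuracies,
      mean_accuracy_pct = report$mean_accuracy,
      classifier = report$classifier,
      timings_s = as.list(round(timings, 3))
    ), rjson, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    paths <- list(features = fcsv, report = rjson)
  }
  invisible(list(features = feat, labels = src$labels, ids = src$ids,
                 profiles = profiles, report = report, config = config,
                 paths = paths))
}
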