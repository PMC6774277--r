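#' @importFrom stats predict
NULL

# feature schema version; stored with every trained caller
FEATURE_SCHEMA_VERSION <- 1L
CALLER_FORMAT_VERSION <- 1L

feature_names <- function() {
  c("mismatch", "arrest", "single_jump_direct", "single_jump_delayed",
    "double_jump", "match_fraction_fwd", "match_fraction_rev",
    "fraction_as_G", "fraction_as_T", "fraction_as_C", "log10_cov",
    "prebase_A", "prebase_C", "prebase_G", "prebase_T")
}

#' Build the feature table for the modification caller
#'
#' Derives 15 numeric features per profile row, all computable from the row
#' alone: the five signature rates; the forward/reverse match fractions; the
#' fractions of reads showing G, T or C (relative to coverage — for the
#' adenosine rows that the m1A caller targets these are the misincorporation
#' fractions); `log10(cov + 1)`; and a one-hot encoding of the prebase over
#' A, C, G, T (a `-`/other prebase encodes as all zeros).
#'
#' When `labels` (known modified sites) are supplied, the returned table is
#' restricted to comparable rows: positives are the labelled positions and
#' negatives are the remaining rows whose reference base equals the modal
#' reference base of the positive set (comparing like with like). Labels
#' referencing positions absent from the profile are dropped with a warning.
#'
#' @param profile An `rt_profile` data.frame.
#' @param labels Optional data.frame with columns `ref_seg` and `pos` listing
#'   known modified sites.
#' @return A data.frame of features with attributes `ref_seg`/`pos` (row
#'   identity) and, when `labels` is given, a `label` attribute (factor with
#'   levels `unmodified`, `modified`).
#' @export
build_features <- function(profile, labels = NULL) {
  profile <- as.data.frame(profile)
  cm <- as.matrix(profile[count_cols])
  cov <- profile$cov
  i <- seq_len(nrow(profile))
  rb <- toupper(profile$refbase)
  safe <- function(x) ifelse(cov > 0, x / cov, 0)
  match_fwd <- safe(as.numeric(cm[cbind(i, match(rb, count_cols))]))
  match_rev <- safe(as.numeric(cm[cbind(i, match(tolower(rb), count_cols))]))
  pre <- toupper(profile$prebase)
  feats <- data.frame(
    mismatch = profile$mismatch,
    arrest = profile$arrest,
    single_jump_direct = profile$single_jump_direct,
    single_jump_delayed = profile$single_jump_delayed,
    double_jump = profile$double_jump,
    match_fraction_fwd = match_fwd,
    match_fraction_rev = match_rev,
    fraction_as_G = safe(cm[, "G"] + cm[, "g"]),
    fraction_as_T = safe(cm[, "T"] + cm[, "t"]),
    fraction_as_C = safe(cm[, "C"] + cm[, "c"]),
    log10_cov = log10(cov + 1),
    prebase_A = as.numeric(pre == "A"),
    prebase_C = as.numeric(pre == "C"),
    prebase_G = as.numeric(pre == "G"),
    prebase_T = as.numeric(pre == "T"))
  feats[is.na(feats)] <- 0

  ref_seg <- profile$ref_seg
  pos <- profile$pos
  if (!is.null(labels)) {
    stopifnot(all(c("ref_seg", "pos") %in% names(labels)))
    key <- paste(ref_seg, pos, sep = "\r")
    lkey <- unique(paste(labels$ref_seg, labels$pos, sep = "\r"))
    present <- lkey %in% key
    if (!all(present)) {
      warning(sum(!present), " label(s) reference positions absent from the ",
              "profile and were dropped")
      lkey <- lkey[present]
    }
    if (length(lkey) == 0L) {
      stop("no labelled positions present in the profile")
    }
    is_pos <- key %in% lkey
    modal_base <- names(sort(table(rb[is_pos]), decreasing = TRUE))[1L]
    keep <- is_pos | (!is_pos & rb == modal_base)
    feats <- feats[keep, , drop = FALSE]
    ref_seg <- ref_seg[keep]; pos <- pos[keep]
    attr(feats, "label") <- factor(
      ifelse(is_pos[keep], "modified", "unmodified"),
      levels = c("unmodified", "modified"))
  }
  rownames(feats) <- NULL
  attr(feats, "ref_seg") <- ref_seg
  attr(feats, "pos") <- pos
  attr(feats, "schema_version") <- FEATURE_SCHEMA_VERSION
  feats
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation; ties get midranks.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Logical (or coercible) positive-class indicator.
#' @return AUROC in `[0,1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes required to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment; returns integer fold per row
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train the balanced random-forest modification caller
#'
#' Fits a binary random-forest classifier on signature features. The majority
#' class is first randomly downsampled (seeded, without replacement) to a 1:1
#' class ratio — random forests otherwise bias toward the majority class,
#' producing false negatives for the rare modified class that the headline
#' scores need not reveal. Performance is estimated by repeated stratified
#' k-fold cross-validation on the balanced set: within each repeat the
#' out-of-fold probabilities are pooled into one AUROC, and the report gives
#' the per-repeat values with their mean and standard deviation. The final
#' model is refit on the full balanced set.
#'
#' @param features Feature table from [build_features()] (with its `label`
#'   attribute), or any data.frame with the same columns.
#' @param labels Optional explicit label factor/logical overriding the
#'   `label` attribute (`TRUE`/`"modified"` = positive).
#' @param n_trees Number of trees (default 500).
#' @param cv_folds Folds per repeat (default 5; must be >= 2).
#' @param cv_repeats Cross-validation repeats (default 10).
#' @param seed Integer seed governing downsampling, fold assignment and
#'   forest growth.
#' @return A `trained_caller` object: the fitted forest, the feature schema,
#'   the configuration and the CV report (`auroc_mean`, `auroc_sd`,
#'   `auroc_per_repeat`).
#' @export
train_caller <- function(features, labels = NULL, n_trees = 500L,
                         cv_folds = 5L, cv_repeats = 10L, seed = 1L) {
  if (is.null(labels)) labels <- attr(features, "label")
  if (is.null(labels)) stop("labels are required (none attached to features)")
  if (is.logical(labels)) {
    labels <- factor(ifelse(labels, "modified", "unmodified"),
                     levels = c("unmodified", "modified"))
  }
  labels <- factor(labels, levels = c("unmodified", "modified"))
  stopifnot(cv_folds >= 2L, cv_repeats >= 1L, n_trees >= 1L)
  x <- as.data.frame(features)[feature_names()]

  n_pos <- sum(labels == "modified")
  n_neg <- sum(labels == "unmodified")
  if (min(n_pos, n_neg) < cv_folds) {
    stop("only ", min(n_pos, n_neg), " instance(s) in the minority class; ",
         "at least ", cv_folds, " are required — a modification this rare ",
         "is not compatible with the available machine-learning process")
  }
  set.seed(seed)
  n_bal <- min(n_pos, n_neg)
  keep <- c(sample(which(labels == "modified"), n_bal),
            sample(which(labels == "unmodified"), n_bal))
  keep <- sort(keep)
  xb <- x[keep, , drop = FALSE]
  yb <- droplevels(labels[keep])
  yb <- factor(yb, levels = c("unmodified", "modified"))

  per_repeat <- numeric(cv_repeats)
  for (r in seq_len(cv_repeats)) {
    set.seed((seed + r) %% .Machine$integer.max)
    fold <- stratified_folds(yb, cv_folds)
    prob <- numeric(length(yb))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- randomForest::randomForest(xb[tr, , drop = FALSE], yb[tr],
                                        ntree = n_trees)
      prob[!tr] <- predict(fit, xb[!tr, , drop = FALSE],
                           type = "prob")[, "modified"]
    }
    per_repeat[r] <- auroc(prob, yb == "modified")
  }

  set.seed(seed)
  forest <- randomForest::randomForest(xb, yb, ntree = n_trees,
                                       importance = TRUE)
  structure(list(
    forest = forest,
    schema = list(features = feature_names(),
                  version = FEATURE_SCHEMA_VERSION),
    config = list(n_trees = as.integer(n_trees),
                  cv_folds = as.integer(cv_folds),
                  cv_repeats = as.integer(cv_repeats),
                  class_ratio = "1:1", seed = as.integer(seed)),
    cv_report = list(auroc_mean = mean(per_repeat),
                     auroc_sd = stats::sd(per_repeat),
                     auroc_per_repeat = per_repeat),
    n_balanced = 2L * n_bal),
    class = "trained_caller")
}

#' @export
print.trained_caller <- function(x, ...) {
  cat("trained_caller:", x$config$n_trees, "trees,",
      x$n_balanced, "balanced training rows\n")
  cat(sprintf("cv AUROC: %.4f +/- %.4f over %d x %d-fold\n",
              x$cv_report$auroc_mean,
              ifelse(is.na(x$cv_report$auroc_sd), 0, x$cv_report$auroc_sd),
              x$config$cv_repeats, x$config$cv_folds))
  invisible(x)
}

#' Predict modification status for profile positions
#'
#' Builds features for every row of the profile and scores them with a
#' trained caller. Calls use a fixed probability threshold of 0.5 (AUROC,
#' the training metric, is threshold-free).
#'
#' @param object A `trained_caller` from [train_caller()].
#' @param profile An `rt_profile` data.frame (or a prebuilt feature table
#'   from [build_features()]).
#' @param ... Unused.
#' @return A data.frame with `ref_seg`, `pos`, `probability` and `call`
#'   (logical).
#' @export
predict.trained_caller <- function(object, profile, ...) {
  if (is.data.frame(profile) && all(profile_cols %in% names(profile))) {
    feats <- build_features(profile)
  } else {
    feats <- profile
  }
  missing <- setdiff(object$schema$features, names(feats))
  if (length(missing) > 0L) {
    stop("feature schema mismatch; missing feature(s): ",
         paste(missing, collapse = ", "))
  }
  sv <- attr(feats, "schema_version")
  if (!is.null(sv) && sv != object$schema$version) {
    stop("feature schema version mismatch: model has ",
         object$schema$version, ", input has ", sv)
  }
  x <- as.data.frame(feats)[object$schema$features]
  if (nrow(x) == 0L) {
    return(data.frame(ref_seg = character(), pos = integer(),
                      probability = numeric(), call = logical(),
                      stringsAsFactors = FALSE))
  }
  prob <- as.numeric(predict(object$forest, x, type = "prob")[, "modified"])
  rs <- attr(feats, "ref_seg")
  pp <- attr(feats, "pos")
  data.frame(ref_seg = if (is.null(rs)) NA_character_ else rs,
             pos = if (is.null(pp)) NA_integer_ else pp,
             probability = prob,
             call = prob >= 0.5,
             stringsAsFactors = FALSE)
}

#' Save / load a trained caller
#'
#' The file embeds the feature schema, the training configuration, a format
#' version and the randomForest/package version strings; loading refuses a
#' file whose format or randomForest version does not match the running
#' installation, since forests are not portable across incompatible
#' versions. A round trip preserves predictions exactly.
#'
#' @param caller A `trained_caller`.
#' @param path File path.
#' @return `save_caller`: `path`, invisibly. `load_caller`: the
#'   `trained_caller`.
#' @export
save_caller <- function(caller, path) {
  stopifnot(inherits(caller, "trained_caller"))
  payload <- list(format_version = CALLER_FORMAT_VERSION,
                  rf_version = as.character(utils::packageVersion("randomForest")),
                  rtsig_version = as.character(utils::packageVersion("rtsig")),
                  caller = caller)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_caller
#' @export
load_caller <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("cannot read model file '",
                                               path, "': ", conditionMessage(e)))
  if (!is.list(payload) || is.null(payload$format_version) ||
      !inherits(payload$caller, "trained_caller")) {
    stop("'", path, "' is not a saved rtsig caller")
  }
  if (payload$format_version != CALLER_FORMAT_VERSION) {
    stop("model format version ", payload$format_version,
         " not supported (this build reads version ",
         CALLER_FORMAT_VERSION, ")")
  }
  rf_now <- as.character(utils::packageVersion("randomForest"))
  if (!identical(payload$rf_version, rf_now)) {
    stop("model was trained with randomForest ", payload$rf_version,
         " but ", rf_now, " is installed; refusing to load")
  }
  payload$caller
}
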