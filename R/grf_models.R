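# Feature construction, scaling, data splitting, random-forest training and
# permutation feature importance for vGRF regression.

#' Feature specification for vGRF models
#'
#' `"kinematics"`: the six lower-limb kinematic features plus the gait-cycle
#' percentage (7 inputs). `"c7"`: the same plus the C7 vertical acceleration
#' (8 inputs).
#'
#' @param name `"kinematics"` or `"c7"`.
#' @return list with `name` and the ordered `columns`.
#' @export
feature_spec <- function(name = c("c7", "kinematics")) {
  name <- match.arg(name)
  kin <- c("hip_angle", "knee_angle", "ankle_angle",
           "hip_velocity", "knee_velocity", "ankle_velocity")
  cols <- if (name == "c7") c(kin, "a_vert", "cycle_pct")
          else c(kin, "cycle_pct")
  list(name = name, columns = cols)
}

#' Build the model matrix and label vector from a cycle dataset
#'
#' @param dataset a `cycle_dataset` data frame (see [synchronize_cycles()]).
#' @param spec a [feature_spec()].
#' @return list with `X` (matrix, columns ordered by the spec), `y` (vGRF in
#'   BW) and `meta` (subject, speed, stride, cycle_pct).
#' @export
build_feature_table <- function(dataset, spec = feature_spec()) {
  missing <- setdiff(c(spec$columns, "vgrf"), names(dataset))
  if (length(missing))
    stop("dataset is missing columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(dataset[, spec$columns, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = dataset$vgrf,
       meta = dataset[, intersect(c("subject", "speed", "stride",
                                    "cycle_pct"), names(dataset))])
}

#' Min-max scaler fitted on training data
#'
#' Each column is mapped to `[0, 1]` using the training minimum and maximum;
#' the same affine map is applied to evaluation data (values may leave
#' `[0, 1]` and are not clipped).
#'
#' @param X training matrix.
#' @return object of class `minmax_scaler`.
#' @export
fit_scaler <- function(X) {
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  bad <- which(mx <= mn)
  if (length(bad))
    stop("constant feature column(s): ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "))
  structure(list(min = mn, max = mx), class = "minmax_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `minmax_scaler`.
#' @param inverse undo the scaling instead of applying it.
#' @export
apply_scaler <- function(scaler, X, inverse = FALSE) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  rng <- scaler$max - scaler$min
  if (inverse) sweep(sweep(X, 2, rng, "*"), 2, scaler$min, "+")
  else sweep(sweep(X, 2, scaler$min, "-"), 2, rng, "/")
}

#' Split a cycle dataset into train / validation / test partitions
#'
#' Rows of the held-out (`inter`) subjects form the test partition; the
#' remaining (`intra`) rows are split uniformly at random into training and
#' validation fractions.
#'
#' @param dataset a `cycle_dataset`.
#' @param inter_subjects subject ids held out entirely.
#' @param train_fraction fraction of intra rows used for training.
#' @param seed integer seed for the random split.
#' @return list of row-index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(dataset, inter_subjects, train_fraction = 0.8,
                       seed = 1) {
  subj <- dataset$subject
  if (length(unique(subj)) < 3) stop("need at least 3 subjects")
  test <- which(subj %in% inter_subjects)
  intra <- which(!subj %in% inter_subjects)
  if (length(intersect(test, intra)))
    stop("subject overlap between partitions")
  set.seed(seed)
  ntr <- round(train_fraction * length(intra))
  tr <- sort(sample(intra, ntr))
  list(train = tr, validation = sort(setdiff(intra, tr)), test = sort(test))
}

#' Random-forest configuration
#'
#' Defaults: 170 trees, maximum depth 35, minimum of 1 sample per leaf and 2
#' to split a node, and `floor(log2(p))` candidate features per split.
#'
#' @param n_trees,max_depth,min_samples_split,min_samples_leaf integers.
#' @param seed integer.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 170, max_depth = 35, min_samples_split = 2,
                      min_samples_leaf = 1, seed = 1) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_samples_split >= 2,
            min_samples_leaf >= 1)
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf, seed = seed),
            class = "rf_config")
}

#' Train the random-forest vGRF regressor
#'
#' @param X scaled feature matrix (see [fit_scaler()]).
#' @param y vGRF labels, BW.
#' @param config an [rf_config()].
#' @param ... further arguments passed to [ranger::ranger()] (e.g.
#'   `replace`, `sample.fraction` for small controlled fits).
#' @return object of class `grf_model` wrapping the fitted forest.
#' @export
train_grf_rf <- function(X, y, config = rf_config(), ...) {
  if (anyNA(X) || anyNA(y)) stop("NaN/NA in training data")
  if (length(y) == 0) stop("empty training data")
  dots <- list(...)
  mtry <- dots$mtry %||% max(1L, floor(log2(ncol(X))))
  dots$mtry <- NULL
  fit <- do.call(ranger::ranger, c(list(
    x = X, y = y,
    num.trees = config$n_trees,
    max.depth = config$max_depth,
    # ranger makes nodes of size <= min.node.size terminal, so "may split
    # nodes with >= min_samples_split samples" maps to min_samples_split - 1
    min.node.size = config$min_samples_split - 1,
    min.bucket = config$min_samples_leaf,
    mtry = mtry, seed = config$seed,
    num.threads = 1), dots))
  structure(list(kind = "rf", fit = fit, config = config,
                 features = colnames(X), mtry = mtry),
            class = "grf_model")
}

#' Predict vGRF from a fitted model
#'
#' @param object a `grf_model` (random forest or feedforward network).
#' @param newdata scaled feature matrix with the training column order.
#' @param ... unused.
#' @return numeric vector of vGRF predictions, BW (not clipped to >= 0).
#' @export
predict.grf_model <- function(object, newdata, ...) {
  if (!is.null(object$features) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$features))
    stop("feature columns do not match the training specification")
  if (object$kind == "rf") {
    stats::predict(object$fit, data = newdata,
                   num.threads = 1)$predictions
  } else {
    drop(fnn_forward(object$fit, newdata)$output)
  }
}

#' @export
print.grf_model <- function(x, ...) {
  if (x$kind == "rf") {
    cat(sprintf("<grf_model: random forest> %d trees, depth <= %d, mtry %d, %d features\n",
                x$config$n_trees, x$config$max_depth, x$mtry,
                length(x$features)))
  } else {
    cat(sprintf("<grf_model: feedforward net> %d hidden layers x %d units, %d features, %d epochs trained\n",
                x$config$hidden_layers, x$config$neurons, length(x$features),
                x$epochs_run))
  }
  invisible(x)
}

#' Permutation feature importance
#'
#' For each feature, the increase in prediction RMSE when that column is
#' randomly shuffled on the evaluation data, averaged over `repeats`
#' shuffles.
#'
#' @param model a fitted `grf_model`.
#' @param X evaluation feature matrix (scaled).
#' @param y evaluation labels, BW.
#' @param repeats number of shuffles per feature.
#' @param seed integer seed.
#' @return named numeric vector: mean RMSE increase per feature, BW.
#' @export
permutation_importance <- function(model, X, y, repeats = 5, seed = 1) {
  if (repeats < 1) stop("repeats must be >= 1")
  base <- sqrt(mean((predict(model, X) - y)^2))
  set.seed(seed)
  imp <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    inc <- numeric(repeats)
    for (r in seq_len(repeats)) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      inc[r] <- sqrt(mean((predict(model, Xp) - y)^2)) - base
    }
    imp[j] <- mean(inc)
  }
  names(imp) <- colnames(X)
  imp
}
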