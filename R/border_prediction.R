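#' Z-transform a feature matrix
#'
#' Standardises each column to mean 0 and unit standard deviation
#' (population convention, i.e. dividing by the root mean squared
#' deviation). Zero-variance columns are dropped with a warning.
#'
#' @param raw numeric matrix or data frame (rows = fragments, columns =
#'   markers).
#' @return A numeric matrix of Z-transformed signals.
#' @export
ztransform <- function(raw) {
  m <- as.matrix(raw)
  ctr <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2, ctr)^2))
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning("dropping zero-variance column(s): ",
            paste(if (!is.null(colnames(m))) colnames(m)[drop]
                  else which(drop), collapse = ", "))
    m <- m[, !drop, drop = FALSE]
    ctr <- ctr[!drop]; sds <- sds[!drop]
  }
  out <- sweep(sweep(m, 2, ctr), 2, sds, `/`)
  out
}

#' Label fragments by boundary membership
#'
#' A fragment containing a boundary center is labelled 1 (border-related);
#' all other fragments are labelled 0 (intra-domain).
#'
#' @param fragments a [fragment_map()].
#' @param centers a `boundary_set`.
#' @return Integer vector of 0/1 labels aligned to the fragment map rows.
#' @export
label_fragments <- function(fragments, centers) {
  labels <- integer(nrow(fragments))
  if (nrow(centers)) {
    idx <- locate_fragments(fragments, centers$chrom, centers$pos)
    labels[idx + 1L] <- 1L
  }
  labels
}

#' Mean track signal per fragment
#'
#' Marker signal for each fragment, computed as the mean of the track over
#' the fragment interval (uncovered stretches count as zero).
#'
#' @param tracks named list of [signal_track()] objects.
#' @param fragments a [fragment_map()].
#' @return Numeric matrix, one row per fragment, one column per track.
#' @export
fragment_signal_matrix <- function(tracks, fragments) {
  w <- fragments$end - fragments$start
  out <- vapply(tracks, function(tr) {
    Fint <- track_integrator(tr)
    (Fint(fragments$chrom, fragments$end) -
       Fint(fragments$chrom, fragments$start)) / w
  }, numeric(nrow(fragments)))
  colnames(out) <- names(tracks)
  out
}

#' Fit a logistic border-prediction model
#'
#' Maximum-likelihood logistic regression (log-odds linear in the features)
#' with a weak ridge penalty for numerical stability on separable data.
#' Rows are split at random into equally sized training and test halves;
#' the model is fitted on the training half and evaluated on the held-out
#' half. With `balance = TRUE` the negatives are first subsampled to match
#' the number of positives (border fragments are typically ~1% of
#' fragments).
#'
#' @param features numeric matrix (e.g. from [ztransform()]).
#' @param labels 0/1 vector aligned to the feature rows.
#' @param split_seed integer seed controlling the subsampling and the split.
#' @param balance subsample negatives to the positive count (default TRUE).
#' @param lambda ridge penalty (default 1e-3).
#' @return List with `weights` (including intercept), `train_idx`,
#'   `test_idx` (row indices into `features`), `scores` (held-out predicted
#'   probabilities), `test_labels`, `auc`, and `roc` (a [roc_auc()] result).
#' @export
fit_border_model <- function(features, labels, split_seed, balance = TRUE,
                             lambda = 1e-3) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  if (ncol(features) == 1)  # glmnet requires >= 2 columns
    features <- cbind(features, .const = 0)
  with_seed(split_seed, {
    rows <- seq_along(labels)
    if (balance) {
      pos <- which(labels == 1); neg <- which(labels == 0)
      n <- min(length(pos), length(neg))
      rows <- sort(c(sample(pos, n), sample(neg, n)))
    }
    rows <- sample(rows)                      # random order, then halve
    half <- floor(length(rows) / 2)
    train <- sort(rows[seq_len(half)])
    test <- sort(rows[-seq_len(half)])
    if (length(unique(labels[train])) < 2 ||
        length(unique(labels[test])) < 2)
      stop("train/test split lost a class; use more data or balance = TRUE")
    fit <- glmnet::glmnet(features[train, , drop = FALSE], labels[train],
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE, thresh = 1e-10)
    eta <- as.vector(cbind(1, features[test, , drop = FALSE]) %*%
                       as.matrix(stats::coef(fit)))
    scores <- 1 / (1 + exp(-eta))
    roc <- roc_auc(scores, labels[test])
    list(weights = as.vector(stats::coef(fit)),
         feature_names = colnames(features),
         train_idx = train, test_idx = test, scores = scores,
         test_labels = labels[test], auc = roc$auc, roc = roc)
  })
}

#' ROC curve and AUC as a rank statistic
#'
#' The AUC equals the Mann-Whitney U statistic normalised by `n1 * n0`;
#' tied scores contribute 1/2. The ROC curve is traced over the distinct
#' score thresholds.
#'
#' @param scores predicted scores or probabilities (higher = positive).
#' @param labels 0/1 class labels.
#' @return List with `thresholds`, `tpr`, `fpr` (monotone non-decreasing)
#'   and `auc` in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)                     # midranks handle ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1)
  fp <- cumsum(labels[o] == 0)
  keep <- !duplicated(scores[o], fromLast = TRUE)  # one point per threshold
  list(thresholds = scores[o][keep],
       tpr = c(0, tp[keep] / n1), fpr = c(0, fp[keep] / n0), auc = auc)
}
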