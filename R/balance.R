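#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest minority neighbors interpolated over
#'   (default 5, the technique's canonical choice).
#' @param seed Integer RNG seed.
#' @return Object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 1L) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1", call. = FALSE)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed), target = "balance"),
            class = "smote_config")
}

#' Balance a two-class dataset by synthetic minority oversampling
#'
#' Equalizes class counts by interpolating new minority-class points: each
#' synthetic point is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k` nearest minority neighbors of a randomly drawn
#' minority point `x_i` (Euclidean distance on standardized features;
#' interpolation happens on the original scale). All original rows are
#' returned unchanged, originals first. Columns whose observed values are all
#' 0/1 are treated as one-hot-encoded categories and synthetic values are
#' rounded to the nearest level.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Two-class vector aligned with `features`.
#' @param cfg A [smote_config()].
#' @return List with `features`, `labels`, `n_synthetic`, and
#'   `synthetic` (logical index of the synthetic rows).
#' @examples
#' x <- matrix(rnorm(60), ncol = 2)
#' y <- rep(c(1, 0), c(20, 10))
#' bal <- smote_balance(x, y, smote_config(k_neighbors = 3, seed = 1))
#' table(bal$labels)
#' @export
smote_balance <- function(features, labels, cfg = smote_config()) {
  stopifnot(inherits(cfg, "smote_config"))
  features <- as.matrix(features)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("smote_balance requires exactly two classes, got ", length(classes),
         call. = FALSE)
  }
  counts <- table(factor(labels, levels = classes))
  minority <- classes[which.min(counts)]
  m <- min(counts); M <- max(counts)
  n_syn <- as.integer(M - m)
  if (n_syn == 0L) {
    return(list(features = features, labels = labels, n_synthetic = 0L,
                synthetic = rep(FALSE, nrow(features))))
  }
  if (m <= cfg$k_neighbors) {
    stop(sprintf(
      "minority class has %d samples but k_neighbors = %d; lower k_neighbors below the minority count",
      m, cfg$k_neighbors), call. = FALSE)
  }
  min_idx <- which(labels == minority)
  x_min <- features[min_idx, , drop = FALSE]

  # neighbor search on standardized coordinates so no feature dominates
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  z_min <- sweep(sweep(x_min, 2, ctr), 2, scl, "/")
  d <- as.matrix(stats::dist(z_min))
  diag(d) <- Inf
  ord <- apply(d, 1, function(r) order(r)[seq_len(cfg$k_neighbors)])
  nn <- if (is.matrix(ord)) t(ord) else matrix(ord, ncol = 1L)

  set.seed(cfg$seed)
  base <- sample.int(m, n_syn, replace = TRUE)
  pick <- sample.int(cfg$k_neighbors, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  neigh <- nn[cbind(base, pick)]
  x_new <- x_min[base, , drop = FALSE] +
    u * (x_min[neigh, , drop = FALSE] - x_min[base, , drop = FALSE])

  onehot <- apply(features, 2, function(col) all(col %in% c(0, 1)))
  if (any(onehot)) x_new[, onehot] <- round(x_new[, onehot])
  rownames(x_new) <- if (is.null(rownames(features))) NULL
                     else sprintf("synthetic_%04d", seq_len(n_syn))

  list(features = rbind(features, x_new),
       labels = c(labels, rep(minority, n_syn)),
       n_synthetic = n_syn,
       synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, n_syn)))
}

#' Stratified train/holdout split
#'
#' Splits a table into a training part of exactly `round(train_fraction * n)`
#' rows and a holdout with the rest, stratified on a grouping variable
#' (largest-remainder apportionment keeps per-stratum shares as close to the
#' target fraction as integer counts allow).
#'
#' @param table `data.frame` to split.
#' @param train_fraction Fraction in (0, 1) assigned to training.
#' @param seed Integer RNG seed.
#' @param strata Column name to stratify on, or a vector aligned with rows;
#'   `NULL` for an unstratified split.
#' @return List with `train` and `holdout` data.frames.
#' @export
train_eval_split <- function(table, train_fraction = 0.9, seed = 1L,
                             strata = "progression_category") {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(table)
  target <- round(train_fraction * n)
  g <- if (is.null(strata)) rep(1L, n)
       else if (length(strata) == 1L && is.character(strata)) table[[strata]]
       else strata
  set.seed(seed)
  levs <- unique(g)
  ideal <- vapply(levs, function(l) train_fraction * sum(g == l), numeric(1))
  take <- floor(ideal)
  rem <- target - sum(take)
  if (rem > 0) {
    ord <- order(ideal - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  sizes <- vapply(levs, function(l) sum(g == l), numeric(1))
  if (any(take == 0 & sizes > 0) || any(take == sizes & sizes > 0)) {
    warning("a stratum is absent from the train or holdout part", call. = FALSE)
  }
  train_idx <- unlist(lapply(seq_along(levs), function(i) {
    idx <- which(g == levs[i])
    sample(idx, take[i])
  }))
  list(train = table[sort(train_idx), , drop = FALSE],
       holdout = table[setdiff(seq_len(n), train_idx), , drop = FALSE])
}
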