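# Cross-subject consistency, group mean networks and t-maps.

#' Collect subject component maps into a group array
#'
#' @param y_list list over subjects of M x L component matrices (or
#'   `ic_result` objects); rows are standardized to zero mean, unit
#'   variance.
#' @param subject_ids optional subject labels.
#' @return object of class `group_maps` holding an S x M x L array.
#' @export
group_maps <- function(y_list, subject_ids = NULL) {
  mats <- lapply(y_list, function(y) {
    v <- if (inherits(y, "ic_result")) y$Y else as.matrix(y)
    standardize_rows(v, on_constant = "zero")
  })
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == dims), logical(1))))
    stop_shape("subjects have inconsistent component-map dimensions")
  arr <- array(NA_real_, c(length(mats), dims[1], dims[2]))
  for (s in seq_along(mats)) arr[s, , ] <- mats[[s]]
  if (is.null(subject_ids)) subject_ids <- seq_along(mats)
  structure(list(maps = arr, subject_ids = subject_ids),
            class = "group_maps")
}

check_component <- function(maps, m) {
  M <- dim(maps$maps)[2]
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m > M)
    stop(sprintf("component index must lie in 1..%d", M), call. = FALSE)
  as.integer(m)
}

#' Group mean network of one component
#'
#' @param maps a [group_maps].
#' @param m component index.
#' @return length-L mean map across subjects.
#' @export
mean_network <- function(maps, m) {
  m <- check_component(maps, m)
  S <- dim(maps$maps)[1]
  colMeans(matrix(maps$maps[, m, ], nrow = S))
}

#' Cross-subject consistency of one component
#'
#' The average over subjects of the Pearson correlation between each
#' subject's map and the group mean map: a value of 1 means the cohort
#' shares one identical network, while independent noise maps average to
#' about zero.
#'
#' @param maps a [group_maps].
#' @param m component index.
#' @return scalar consistency in `[-1, 1]`.
#' @export
consistency <- function(maps, m) {
  m <- check_component(maps, m)
  mn <- mean_network(maps, m)
  if (sqrt(mean((mn - mean(mn))^2)) < 1e-300)
    stop("mean network has zero variance: consistency undefined",
         call. = FALSE)
  S <- dim(maps$maps)[1]
  mean(vapply(seq_len(S), function(s) safe_pearson(maps$maps[s, m, ], mn),
              numeric(1)))
}

#' Full consistency report
#'
#' @param maps a [group_maps].
#' @param threshold the similarity threshold the maps were extracted with
#'   (recorded in the report).
#' @return object of class `consistency_report`: per-component `k_per`,
#'   the S x M matrix `per_subject_rho` and the threshold.
#' @export
consistency_report <- function(maps, threshold = NA_real_) {
  S <- dim(maps$maps)[1]; M <- dim(maps$maps)[2]
  rho <- matrix(NA_real_, S, M)
  k_per <- numeric(M)
  for (m in seq_len(M)) {
    mn <- mean_network(maps, m)
    rho[, m] <- vapply(seq_len(S),
                       function(s) safe_pearson(maps$maps[s, m, ], mn),
                       numeric(1))
    k_per[m] <- mean(rho[, m])
  }
  structure(list(k_per = k_per, per_subject_rho = rho, threshold = threshold),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("<consistency_report> threshold = %s\n", format(x$threshold)))
  cat("  K_per:", paste(sprintf("%.3f", x$k_per), collapse = " "), "\n")
  invisible(x)
}

#' Write a consistency report as CSV
#'
#' Columns: component, threshold, k_per, then one column of per-subject
#' correlations per subject.
#'
#' @param report a `consistency_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_consistency_csv <- function(report, path) {
  S <- nrow(report$per_subject_rho)
  df <- data.frame(component = seq_along(report$k_per),
                   threshold = report$threshold,
                   k_per = report$k_per,
                   t(report$per_subject_rho))
  names(df)[-(1:3)] <- paste0("rho_subject_", seq_len(S))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' One-sample t-map of a component across subjects
#'
#' Per voxel, `t = mean / (sd / sqrt(S))` across the S subject maps with
#' `df = S - 1`. Voxels with zero variance get `+/-Inf` (nonzero mean) or 0
#' (zero mean).
#'
#' @param maps a [group_maps] with S >= 2 subjects.
#' @param m component index.
#' @return length-L vector of t-values.
#' @export
one_sample_tmap <- function(maps, m) {
  m <- check_component(maps, m)
  S <- dim(maps$maps)[1]
  if (S < 2L) stop("t-map needs at least 2 subjects", call. = FALSE)
  y <- matrix(maps$maps[, m, ], nrow = S)
  mu <- colMeans(y)
  sdv <- sqrt(colSums(sweep(y, 2, mu)^2) / (S - 1))
  tvals <- numeric(length(mu))
  zero <- sdv < 1e-300
  tvals[!zero] <- mu[!zero] / (sdv[!zero] / sqrt(S))
  tvals[zero & mu > 0] <- Inf
  tvals[zero & mu < 0] <- -Inf
  tvals
}

#' Critical t-value of a one-tailed test
#'
#' The upper quantile of Student's t distribution: the customary display
#' threshold p < 0.001 at df = 9 gives t = 4.30 (to two decimals).
#'
#' @param p one-tailed tail probability, in (0, 1).
#' @param df degrees of freedom, >= 1.
#' @return scalar threshold.
#' @export
critical_t <- function(p, df) {
  if (!is.numeric(p) || p <= 0 || p >= 1)
    stop("`p` must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(df) || df < 1)
    stop("`df` must be >= 1", call. = FALSE)
  qt(1 - p, df)
}

#' Threshold a map for display
#'
#' Values less than or equal to the cutoff are set to zero; values above
#' are kept. The customary display cutoffs for standardized intensity maps
#' are 2 and 1.5.
#'
#' @param map numeric vector or array.
#' @param z cutoff.
#' @return thresholded map of the same shape.
#' @export
threshold_map <- function(map, z) {
  map[map <= z] <- 0
  map
}
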