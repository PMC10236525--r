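#' Construct a cluster-randomized trial dataset
#'
#' Bundles individual-level CRT data into the container used by the model
#' fitting functions: one row per participant with a cluster identifier, a
#' cluster-level treatment indicator, a survival indicator, the outcome
#' (missing exactly where the participant did not survive — truncation by
#' death), and baseline covariates. A leading intercept column is added to the
#' design matrix automatically.
#'
#' @param data A data.frame with one row per participant.
#' @param covariates Character vector naming covariate columns in `data`.
#'   Defaults to every column other than the cluster/treatment/survival/outcome
#'   columns.
#' @param cluster,treatment,survival,outcome Names of the corresponding
#'   columns (defaults `"cluster"`, `"D"`, `"S"`, `"Y"`).
#' @return An object of class `crt_data`: a list with the validated
#'   data.frame (`df`), design matrix `X` (intercept first), integer cluster
#'   index per row, per-cluster treatment vector, and dimensions.
#' @export
crt_data <- function(data, covariates = NULL, cluster = "cluster",
                     treatment = "D", survival = "S", outcome = "Y") {
  stopifnot(is.data.frame(data), nrow(data) > 0L)
  needed <- c(cluster, treatment, survival, outcome)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), needed)
  }
  D <- data[[treatment]]
  S <- data[[survival]]
  Y <- data[[outcome]]
  if (!all(D %in% c(0, 1))) stop("treatment indicator must be 0/1")
  if (!all(S %in% c(0, 1))) stop("survival indicator must be 0/1")

  bad <- which(is.na(Y) != (S == 0))
  if (length(bad) > 0L) {
    stop(length(bad), " row(s) violate 'outcome observed iff survived' ",
         "(rows ", paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", ")")
  }

  cl <- factor(data[[cluster]])
  cluster_index <- as.integer(cl)
  I <- nlevels(cl)
  D_cluster <- vapply(split(D, cluster_index), function(d) {
    if (length(unique(d)) != 1L) {
      stop("treatment must be constant within cluster")
    }
    d[1L]
  }, numeric(1))

  X <- cbind(1, as.matrix(data[covariates]))
  storage.mode(X) <- "double"
  colnames(X) <- c("(Intercept)", covariates)
  if (!all(is.finite(X))) stop("covariates must be finite and non-missing")

  structure(list(
    df = data, X = X, Y = as.numeric(Y), S = as.integer(S),
    D = as.numeric(D), D_cluster = as.numeric(D_cluster),
    cluster = cluster_index, cluster_levels = levels(cl),
    covariates = covariates, n = nrow(data), I = I, p = ncol(X),
    n_i = as.integer(tabulate(cluster_index, I))
  ), class = "crt_data")
}

#' @export
print.crt_data <- function(x, ...) {
  cat("<crt_data> ", x$n, " participants in ", x$I, " clusters (",
      sum(x$D_cluster == 1), " treated)\n", sep = "")
  cat("  survivors: ", sum(x$S == 1), " (", sum(x$S == 0),
      " outcomes truncated by death)\n", sep = "")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write CRT datasets as delimited text
#'
#' `write_crt()` writes the participant table as comma-separated text with a
#' header; `read_crt()` reads such a file back into a [crt_data] object.
#' Truncated outcomes are stored as `NA`.
#'
#' @param data A [crt_data] object.
#' @param file Path to a CSV file.
#' @param ... Passed on to [crt_data()] (e.g. `covariates`).
#' @return `read_crt()` returns a [crt_data]; `write_crt()` returns `file`
#'   invisibly.
#' @export
write_crt <- function(data, file) {
  stopifnot(inherits(data, "crt_data"))
  utils::write.csv(data$df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_crt
#' @export
read_crt <- function(file, ...) {
  crt_data(utils::read.csv(file), ...)
}
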