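# Matrix and configuration I/O with domain validation.

.MODES <- c("expression", "methylation")
.STRATEGIES <- c("var", "cv", "svc", "dvc", "pwd", "rfdecd")

#' Construct a validated mixture matrix
#'
#' A mixture matrix holds the bulk observations `Y` (features x samples) for
#' one of the two supported data modes. Methylation beta-values must lie in
#' the closed interval \[0, 1\]; expression intensities must be non-negative.
#' Values exactly at a boundary are accepted.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param mode `"expression"` or `"methylation"`.
#' @return a numeric matrix of class `mixture_matrix` with a `mode` attribute.
#' @export
mixture_matrix <- function(values, mode = c("expression", "methylation")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("mixture matrix must have at least one feature and one sample")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate feature ID: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample ID: ", dup)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("missing or non-finite value at feature '",
         rownames(values)[bad[1L]], "', sample '", colnames(values)[bad[2L]],
         "' (imputation is out of scope; clean the input first)")
  }
  if (mode == "methylation" && (min(values) < 0 || max(values) > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1L, ]
    stop("methylation value outside [0, 1] at feature '",
         rownames(values)[bad[1L]], "', sample '", colnames(values)[bad[2L]],
         "': ", values[bad[1L], bad[2L]])
  }
  if (mode == "expression" && min(values) < 0) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value at feature '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'")
  }
  structure(values, mode = mode, class = c("mixture_matrix", "matrix", "array"))
}

#' @export
`[.mixture_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, mode = attr(x, "mode"),
                     class = c("mixture_matrix", "matrix", "array"))
  }
  out
}

#' Read a features x samples matrix from delimited text
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' Tab-separated by default; comma-separated when the file extension is
#' `.csv`. The returned matrix is validated for the requested mode
#' (see [mixture_matrix()]).
#'
#' @param path file path.
#' @param mode `"expression"` or `"methylation"`.
#' @param sep field separator; default chosen from the file extension.
#' @return a `mixture_matrix`, row/column order as on disk.
#' @export
read_matrix <- function(path, mode = c("expression", "methylation"),
                        sep = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(0))
  if (ncol(raw) < 2L) stop("expected feature-ID column plus >=1 sample column")
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(toupper(vals) %in% c("NA", "NAN")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric value '", vals[bad[1L, 1L], bad[1L, 2L]],
         "' at feature '", ids[bad[1L, 1L]], "', sample '",
         colnames(vals)[bad[1L, 2L]], "'")
  }
  rownames(num) <- ids
  mixture_matrix(num, mode)
}

#' Write a matrix (mixture, profiles or proportions) as TSV
#'
#' Writes full double precision (15 significant digits) so that a read/write
#' round trip is the identity. The first column carries the row IDs
#' (features, or cell-type labels for a proportion matrix).
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file path.
#' @param id_header header for the ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, id_header = "id") {
  if (is.null(dim(mat)) || nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("refusing to write an empty matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must carry row and column names")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(mat)), collapse = "\t"), con)
  body <- apply(format(mat, digits = 15, scientific = TRUE, trim = TRUE), 1L,
                paste, collapse = "\t")
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Build a run configuration
#'
#' Defaults follow the published protocol: feature-list size `m_target = 1000`
#' and `total_iter = 30` iterations, which suffice for ~4 cell types and ~100
#' samples; around 100 iterations are recommended for small studies (n <= 50)
#' or 6+ cell types.
#'
#' @param K number of cell types (>= 2).
#' @param mode `"expression"` or `"methylation"`.
#' @param strategy feature-selection strategy: one of `"var"`, `"cv"`,
#'   `"svc"`, `"dvc"`, `"pwd"`, `"rfdecd"`.
#' @param total_iter number of feature-selection iterations (>= 1).
#' @param m_target size of the selected feature list.
#' @param seed integer seed controlling all randomness of a run.
#' @param rmse_scope `"full"` (reconstruction error against the complete
#'   matrix, default) or `"subset"` (against the selected rows only).
#' @param tol convergence tolerance on the relative RMSE change per
#'   alternating sweep (scale-invariant).
#' @param max_iter maximum alternating sweeps per fit.
#' @param restarts random restarts per fit; the best (lowest-RMSE) is kept.
#' @return a list of class `run_config`.
#' @export
deconv_config <- function(K, mode = c("expression", "methylation"),
                          strategy = "rfdecd", total_iter = 30L,
                          m_target = 1000L, seed = 1L,
                          rmse_scope = c("full", "subset"),
                          tol = 1e-4, max_iter = 200L, restarts = 3L) {
  mode <- match.arg(mode)
  rmse_scope <- match.arg(rmse_scope)
  strategy <- tolower(strategy)
  if (!strategy %in% .STRATEGIES) {
    stop("unknown strategy '", strategy, "'; valid options: ",
         paste(.STRATEGIES, collapse = ", "))
  }
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be an integer >= 2")
  total_iter <- as.integer(total_iter)
  if (is.na(total_iter) || total_iter < 1L) stop("total_iter must be >= 1")
  m_target <- as.integer(m_target)
  if (is.na(m_target) || m_target < K) stop("m_target must be >= K")
  if (restarts < 1L) stop("restarts must be >= 1")
  structure(list(K = K, mode = mode, strategy = strategy,
                 total_iter = total_iter, m_target = m_target,
                 seed = as.integer(seed), rmse_scope = rmse_scope,
                 tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [deconv_config()]. Arguments passed through
#' `...` override the file (the command-line entry point uses this to let
#' flags win over the file).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   defaults only.
#' @param ... overrides forwarded to [deconv_config()].
#' @return a `run_config`.
#' @export
load_config <- function(path = NULL, ...) {
  file_args <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_args <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!is.list(file_args)) stop("config file must contain a mapping")
    known <- names(formals(deconv_config))
    unknown <- setdiff(names(file_args), known)
    if (length(unknown) > 0L) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
  }
  over <- list(...)
  file_args[names(over)] <- over
  do.call(deconv_config, file_args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Deconvolution run configuration\n")
  cat(sprintf("  K = %d cell types, mode = %s, strategy = %s\n",
              x$K, x$mode, x$strategy))
  cat(sprintf("  iterations = %d, feature-list size = %d, rmse scope = %s\n",
              x$total_iter, x$m_target, x$rmse_scope))
  cat(sprintf("  seed = %d, engine: tol %.1e, max %d sweeps, %d restarts\n",
              x$seed, x$tol, x$max_iter, x$restarts))
  invisible(x)
}
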