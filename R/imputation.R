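# Left-censored imputation: missing log2 intensities are replaced by
# draws from a narrow normal distribution placed below the observed
# distribution, modelling abundance under the detection limit.

#' Imputation parameters
#'
#' Missing values in label-free AP-MS are predominantly left-censored:
#' the protein was below the detection limit in that run.  They are
#' therefore replaced by draws from a normal distribution sitting in the
#' lower tail of the observed intensities rather than by anything
#' resembling the observed mean.
#'
#' @param downshift centre of the imputation distribution, expressed as
#'   a multiple of the observed standard deviation below the observed
#'   mean (`downshift_normal` mode).  The default 1.8, with `width` 0.3,
#'   is the Perseus community default for left-censored proteomics data.
#' @param width standard deviation of the imputation distribution as a
#'   multiple of the observed standard deviation; must be > 0.
#' @param scope `"per_sample"` (each sample column supplies its own
#'   observed mean/sd/min; the default, matching standard practice) or
#'   `"global"` (one set of moments for the whole matrix, for small
#'   designs).
#' @param mode `"downshift_normal"` draws from
#'   Normal(mean - downshift*sd, (width*sd)^2); `"min_centered"` draws
#'   from Normal(observed minimum, (width*sd)^2), centring the draws on
#'   the lowest detected intensity.
#' @param seed integer seed; identical seed + parameters + input give a
#'   bit-identical imputed matrix.
#' @return A list of class `impute_params`.
#' @export
impute_params <- function(downshift = 1.8, width = 0.3,
                          scope = c("per_sample", "global"),
                          mode = c("downshift_normal", "min_centered"),
                          seed = 1L) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  if (width <= 0) stop("width must be > 0")
  if (downshift < 0) stop("downshift must be >= 0")
  structure(list(downshift = downshift, width = width, scope = scope,
                 mode = mode, seed = as.integer(seed)),
            class = "impute_params")
}

#' Impute missing log2 intensities from a down-shifted normal
#'
#' Every missing cell is replaced by an independent draw from the
#' distribution described by `params`; observed cells are never touched.
#' Draws are generated from a per-cell standard-normal substream indexed
#' by the cell's position in the matrix, so which *other* cells happen to
#' be missing does not change the draw a given cell receives.
#'
#' @param table a log2-scale [protein_table()].
#' @param params an [impute_params()].
#' @return A list with `table` (complete, no missing cells) and
#'   `record`, an `imputation_record`: data frame of
#'   (`group_id`, `sample`, `imputed_value`) for every imputed cell plus
#'   a `scopes` attribute with the observed mean/sd/min used per scope.
#' @export
impute_missing <- function(table, params = impute_params()) {
  if (table$scale != "log2") stop("impute_missing expects a log2 table")
  v <- table$values
  miss <- is.na(v)

  # position-indexed standard normal draws: cell (i, j) always receives
  # z[i, j] regardless of the missingness pattern elsewhere
  z <- with_seed(params$seed,
                 matrix(stats::rnorm(length(v)), nrow = nrow(v)))

  scope_cols <- if (params$scope == "per_sample") {
    as.list(seq_len(ncol(v)))
  } else {
    list(seq_len(ncol(v)))
  }
  scope_names <- if (params$scope == "per_sample") colnames(v) else "global"

  scopes <- data.frame(scope = scope_names, mean = NA_real_, sd = NA_real_,
                       min = NA_real_, center = NA_real_, width = NA_real_,
                       n_imputed = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(scope_cols)) {
    cols <- scope_cols[[k]]
    m <- miss[, cols, drop = FALSE]
    if (!any(m)) next
    obs <- v[, cols, drop = FALSE][!m]
    if (length(obs) < 2L || stats::sd(obs) == 0) {
      stop("imputation scope '", scope_names[k],
           "' has fewer than 2 observed values or zero spread")
    }
    mu <- mean(obs)
    sdv <- stats::sd(obs)
    center <- if (params$mode == "downshift_normal") {
      mu - params$downshift * sdv
    } else {
      min(obs)
    }
    width <- params$width * sdv
    vv <- v[, cols, drop = FALSE]
    zz <- z[, cols, drop = FALSE]
    vv[m] <- center + width * zz[m]
    v[, cols] <- vv
    scopes[k, c("mean", "sd", "min", "center", "width")] <-
      c(mu, sdv, min(obs), center, width)
    scopes$n_imputed[k] <- sum(m)
  }

  cells <- which(miss, arr.ind = TRUE)
  record <- data.frame(
    group_id = table$records$group_id[cells[, 1L]],
    sample = colnames(v)[cells[, 2L]],
    imputed_value = v[miss],
    stringsAsFactors = FALSE
  )
  attr(record, "scopes") <- scopes
  class(record) <- c("imputation_record", class(record))

  list(table = protein_table(table$records, v, scale = "log2"),
       record = record)
}

#' Write an imputation record (one row per imputed cell)
#' @param record an `imputation_record` from [impute_missing()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputation_record <- function(record, path) {
  out <- data.frame(group_id = record$group_id, sample = record$sample,
                    imputed_value = sprintf("%.10g", record$imputed_value),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}
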