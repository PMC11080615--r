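#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds per-sample, per-locus DNA-methylation fractions
#' (beta values). Rows are samples, columns are CpG loci. Missing entries are
#' stored as `NA`; every observed value must lie in `[0, 1]` (0 = fully
#' unmethylated allele, 1 = fully methylated).
#'
#' @param values Numeric matrix, samples in rows and loci in columns, with
#'   `NA` for missing entries. Row names are sample identifiers and column
#'   names are CpG identifiers (conventionally `cg`-prefixed, not enforced).
#' @param sample_ids,locus_ids Optional character vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `beta_matrix`: a numeric matrix with unique
#'   row/column names and all observed values in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("cg", 1:4)))
#' beta_matrix(m)
beta_matrix <- function(values, sample_ids = NULL, locus_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x loci).", call. = FALSE)
  }
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(locus_ids)) colnames(values) <- locus_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and locus ids (colnames).",
         call. = FALSE)
  }
  validate_beta_matrix(structure(values, class = c("beta_matrix", "matrix")))
}

validate_beta_matrix <- function(bm) {
  sid <- rownames(bm)
  lid <- colnames(bm)
  if (anyDuplicated(sid)) {
    stop("Duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lid)) {
    stop("Duplicate locus ids: ",
         paste(unique(lid[duplicated(lid)]), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(bm) & (bm < 0 | bm > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("Beta values outside [0, 1] at locus ",
         paste(unique(lid[bad[, "col"]]), collapse = ", "),
         " (sample ", paste(unique(sid[bad[, "row"]]), collapse = ", "), ").",
         call. = FALSE)
  }
  bm
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix: %d samples x %d loci, %.1f%% missing>\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname beta_matrix
#' @param x Object to test or coerce.
#' @export
is_beta_matrix <- function(x) inherits(x, "beta_matrix")

#' Missingness mask of a beta matrix
#'
#' @param bm A [beta_matrix()].
#' @return Logical matrix, `TRUE` where the beta value is missing.
#' @export
missing_mask <- function(bm) {
  stopifnot(is_beta_matrix(bm))
  is.na(unclass(bm))
}

# ---- delimited-text I/O ----------------------------------------------------

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a GEO-series-matrix-style table: one header line of identifiers and
#' one identifier column, tab- or comma-delimited. Empty cells and `NA`
#' (case-insensitive) denote missing beta values.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"loci_as_rows"` (GEO convention: first column CpG ids,
#'   header sample ids) or `"samples_as_rows"`.
#' @param delim Field delimiter; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("loci_as_rows", "samples_as_rows"),
                             delim = guess_delim(path)) {
  orientation <- match.arg(orientation)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  if (ncol(tbl) < 2) stop("Expected an id column plus data columns in ", path,
                          call. = FALSE)
  ids <- as.character(tbl[[1]])
  cells <- as.matrix(tbl[, -1, drop = FALSE])
  miss <- is.na(cells) | trimws(cells) == "" | toupper(trimws(cells)) == "NA"
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(!miss & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "Non-numeric cell '%s' at row id '%s', column '%s' in %s.",
      cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(cells)[bad[1, 2]], path), call. = FALSE)
  }
  num[miss] <- NA_real_
  values <- matrix(num, nrow = nrow(cells),
                   dimnames = list(ids, colnames(cells)))
  if (orientation == "loci_as_rows") values <- t(values)
  beta_matrix(values)
}

#' Write a beta-value matrix to delimited text
#'
#' Missing entries are written as `NA`. The file round-trips through
#' [read_beta_matrix()] with identical ids, mask and values.
#'
#' @inheritParams read_beta_matrix
#' @param bm A [beta_matrix()].
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bm, path,
                              orientation = c("loci_as_rows", "samples_as_rows"),
                              delim = guess_delim(path)) {
  stopifnot(is_beta_matrix(bm))
  orientation <- match.arg(orientation)
  m <- unclass(bm)
  if (orientation == "loci_as_rows") m <- t(m)
  id_name <- if (orientation == "loci_as_rows") "cpg_id" else "sample_id"
  out <- tibble::as_tibble(m, rownames = id_name)
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Requires columns `sample_id` and `age`; `tissue`, `platform` and
#' `dataset_id` are kept when present and filled with `"unknown"` otherwise.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter (default inferred from the extension).
#' @return A tibble with columns `sample_id`, `age`, `tissue`, `platform`,
#'   `dataset_id`.
#' @export
read_sample_meta <- function(path, delim = guess_delim(path)) {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- setdiff(c("sample_id", "age"), names(tbl))
  if (length(need) > 0) {
    stop("Metadata table lacks required column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  as_sample_meta(tbl)
}

#' Coerce a data frame to the sample-metadata contract
#'
#' @param meta Data frame with at least `sample_id` and `age`.
#' @return A tibble with `sample_id`, `age` (>= 0 years), `tissue`,
#'   `platform`, `dataset_id`.
#' @export
as_sample_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("sample_id", "age") %in% names(meta))) {
    stop("`meta` needs `sample_id` and `age` columns.", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("Duplicate sample ids in metadata.", call. = FALSE)
  }
  if (any(!is.finite(meta$age)) || any(meta$age < 0)) {
    stop("Ages must be finite and non-negative (years).", call. = FALSE)
  }
  for (col in c("tissue", "platform", "dataset_id")) {
    if (!col %in% names(meta)) meta[[col]] <- "unknown"
  }
  dplyr::select(meta, "sample_id", "age", "tissue", "platform", "dataset_id",
                dplyr::everything())
}

#' Read or write a locus panel
#'
#' A locus panel is a plain-text file with one CpG identifier per line; its
#' order defines the model's input ordering, so the same panel file must be
#' used at training and prediction time.
#'
#' @param path File path.
#' @return `read_locus_panel()` returns a character vector of unique ids.
#' @export
read_locus_panel <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  if (length(ids) == 0) stop("Empty locus panel: ", path, call. = FALSE)
  if (anyDuplicated(ids)) stop("Duplicate ids in locus panel.", call. = FALSE)
  ids
}

#' @rdname read_locus_panel
#' @param panel Character vector of locus ids.
#' @export
write_locus_panel <- function(panel, path) {
  readr::write_lines(panel, path)
  invisible(path)
}

# ---- filtering, intersection, imputation -----------------------------------

#' Drop samples with too many missing beta values
#'
#' Removes every sample whose fraction of missing loci is strictly greater
#' than `max_missing_fraction` (the conventional array-QC rule: "more than
#' 50% missing" at the default threshold). Sample order is preserved.
#'
#' @param bm A [beta_matrix()].
#' @param max_missing_fraction Retention threshold in `[0, 1]`; a sample at
#'   exactly the threshold is kept.
#' @return A [beta_matrix()] with the offending samples removed (possibly
#'   zero rows).
#' @export
filter_samples_by_missingness <- function(bm, max_missing_fraction = 0.5) {
  stopifnot(is_beta_matrix(bm),
            is.numeric(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(bm))
  keep <- frac <= max_missing_fraction
  out <- unclass(bm)[keep, , drop = FALSE]
  structure(out, class = c("beta_matrix", "matrix"))
}

#' Restrict a beta matrix to a locus panel
#'
#' Reorders columns to the panel order. Panel loci absent from `bm` become
#' fully missing columns, so downstream imputation can fill them; a warning
#' is raised when more than 10% of the panel is absent.
#'
#' @param bm A [beta_matrix()].
#' @param panel Character vector of locus ids (see [read_locus_panel()]).
#' @return A [beta_matrix()] with `length(panel)` columns in panel order.
#' @export
intersect_loci <- function(bm, panel) {
  stopifnot(is_beta_matrix(bm), is.character(panel), length(panel) > 0)
  if (anyDuplicated(panel)) stop("Panel contains duplicate ids.", call. = FALSE)
  out <- matrix(NA_real_, nrow = nrow(bm), ncol = length(panel),
                dimnames = list(rownames(bm), panel))
  hit <- intersect(panel, colnames(bm))
  out[, hit] <- unclass(bm)[, hit, drop = FALSE]
  absent <- length(panel) - length(hit)
  if (absent > 0.1 * length(panel)) {
    warning(sprintf("%d of %d panel loci (%.1f%%) absent from the matrix.",
                    absent, length(panel), 100 * absent / length(panel)),
            call. = FALSE)
  }
  structure(out, class = c("beta_matrix", "matrix"))
}

#' Impute missing beta values by locus-wise linear regression
#'
#' For each locus with missing entries, fits an ordinary least-squares
#' regression of that locus on the `max_predictors` loci most correlated
#' with it (correlation over the samples where the target is observed) and
#' predicts the missing entries, clamping predictions to `[0, 1]`. Predictor
#' columns that are themselves incomplete enter the regression with their
#' missing entries provisionally filled by their observed mean, so the
#' procedure reduces to regression on fully observed loci whenever such loci
#' exist and degrades gracefully under scattered missingness. When the
#' regression is infeasible (fewer than two observed samples, or a singular
#' fit) the locus's observed mean is used; a locus observed in no sample is
#' filled with the global mean of all observed values.
#'
#' Observed values are never altered.
#'
#' @param bm A [beta_matrix()].
#' @param max_predictors Number of predictor loci per regression (default 5).
#' @return A fully observed [beta_matrix()] (no `NA` entries, provided at
#'   least one value anywhere was observed).
#' @export
impute_missing <- function(bm, max_predictors = 5L) {
  stopifnot(is_beta_matrix(bm), max_predictors >= 1)
  m <- unclass(bm)
  if (!anyNA(m)) return(bm)
  if (all(is.na(m))) stop("Cannot impute: no observed values at all.",
                          call. = FALSE)
  global_mean <- mean(m, na.rm = TRUE)
  targets <- which(colSums(is.na(m)) > 0)
  # provisional mean completion so incomplete loci can still serve as
  # predictors; loci with complete columns are unaffected
  prov <- m
  col_means <- colMeans(m, na.rm = TRUE)
  col_means[is.nan(col_means)] <- global_mean
  for (j in seq_len(ncol(prov))) {
    na_j <- is.na(prov[, j])
    if (any(na_j)) prov[na_j, j] <- col_means[j]
  }
  for (j in targets) {
    obs <- which(!is.na(m[, j]))
    mis <- which(is.na(m[, j]))
    filled <- NULL
    if (length(obs) == 0) {
      filled <- rep(global_mean, length(mis))
      message(sprintf("Locus %s observed in no sample; filled with global mean.",
                      colnames(m)[j]))
    } else if (length(obs) >= 2 && ncol(m) > 1) {
      y <- m[obs, j]
      cand <- setdiff(seq_len(ncol(m)), j)
      r <- suppressWarnings(stats::cor(prov[obs, cand, drop = FALSE], y))
      r[is.na(r)] <- 0
      k <- min(max_predictors, length(cand))
      pick <- cand[order(abs(r), decreasing = TRUE)[seq_len(k)]]
      X <- prov[, pick, drop = FALSE]
      fit <- tryCatch(
        stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), y),
        error = function(e) NULL)
      if (!is.null(fit)) {
        coefs <- fit$coefficients
        coefs[is.na(coefs)] <- 0  # collinear predictors dropped by pivoting
        if (all(is.finite(coefs))) {
          pred <- drop(cbind(1, X[mis, , drop = FALSE]) %*% coefs)
          filled <- pmin(1, pmax(0, pred))
        }
      }
    }
    if (is.null(filled)) filled <- rep(mean(m[obs, j]), length(mis))
    m[mis, j] <- filled
  }
  structure(m, class = c("beta_matrix", "matrix"))
}
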