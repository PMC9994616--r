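#' Read a site-by-species abundance matrix from CSV/TSV
#'
#' Expects a header row of species labels and a first column of site labels;
#' cells must be non-negative numbers. The separator is taken from the file
#' extension (.tsv/.txt = tab, otherwise comma). Near-integer values are
#' accepted when \code{round = TRUE}.
#'
#' @param path file path.
#' @param round round near-integer abundances to integers (default FALSE:
#'   non-integer cells are an error).
#' @return integer abundance matrix with dimnames.
#' @export
read_matrix <- function(path, round = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a site-label column plus species columns")
  sites <- as.character(df[[1L]])
  if (anyDuplicated(sites)) stop("duplicate site labels: ",
                                 paste(unique(sites[duplicated(sites)]),
                                       collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate species labels")
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)[1, ]
    stop("non-numeric cell at site '", sites[bad[1]], "', species '",
         colnames(m)[bad[2]], "'")
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at site '", sites[neg[1, 1]], "', species '",
         colnames(m)[neg[1, 2]], "'")
  if (round) m <- round(m)
  nonint <- which(m != round(m), arr.ind = TRUE)
  if (nrow(nonint))
    stop("non-integer abundance at site '", sites[nonint[1, 1]],
         "', species '", colnames(m)[nonint[1, 2]],
         "' (use round = TRUE for near-integer data)")
  storage.mode(m) <- "integer"
  rownames(m) <- sites
  m
}

#' Write a site-by-species matrix to CSV
#'
#' Inverse of [read_matrix()]: first column "site", then one column per
#' species.
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(site = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify one dataset and compute its property battery
#'
#' Runs the full single-dataset analysis: the abundance matrix is binarized
#' and the form of zeta decline classified from the first 10 orders
#' (falling back to [select_max_order()] with a warning when there are
#' fewer than 11 sites), and the community biodiversity properties with
#' their standardized effect sizes are computed on the abundances.
#'
#' @param x integer abundance matrix (sites x species).
#' @param dataset_id,study_id labels carried into the record.
#' @param n_orders orders for classification (default 10).
#' @param n_null null matrices per SES (default 999).
#' @param seed integer seed; if NULL, derived from \code{dataset_id}.
#' @param focal_rule passed to [community_properties()].
#' @return list of class \code{dataset_record} with \code{classification}
#'   (a \code{decline_fit}) and \code{properties} (a \code{property_set}).
#' @export
run_dataset <- function(x, dataset_id = "dataset", study_id = dataset_id,
                        n_orders = 10L, n_null = 999L, seed = NULL,
                        focal_rule = "top4") {
  m <- as.matrix(x)
  if (any(m < 0) || any(m != round(m)))
    stop("dataset '", dataset_id, "': abundances must be non-negative integers")
  if (is.null(seed)) seed <- derive_seed(dataset_id, 0L)
  cls <- if (nrow(m) <= n_orders) {
    warning("dataset '", dataset_id, "': fewer than ", n_orders + 1L,
            " sites; falling back to select_max_order()")
    fit_decline(m, n_orders = select_max_order(m))
  } else {
    fit_decline(m, n_orders = n_orders)
  }
  props <- community_properties(m, focal_rule = focal_rule, n_null = n_null,
                                seed = seed)
  structure(list(dataset_id = dataset_id, study_id = study_id,
                 n_sites = nrow(m), n_species = ncol(m),
                 classification = cls, properties = props, seed = seed),
            class = "dataset_record")
}

#' @export
print.dataset_record <- function(x, ...) {
  cat("Dataset ", x$dataset_id, " (study ", x$study_id, "): ",
      x$n_sites, " sites x ", x$n_species, " species\n", sep = "")
  cat("  form: ", x$classification$winner, " (wAIC exp ",
      round(x$classification$waic[["exponential"]], 3), ")\n", sep = "")
  invisible(x)
}

#' Tidy table of dataset records
#'
#' One row per dataset with the classification and all properties (raw and
#' SES), suitable for [compare_forms()] or export.
#'
#' @param records list of \code{dataset_record}s.
#' @return data frame.
#' @export
records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    p <- r$properties
    data.frame(
      dataset_id = r$dataset_id, study_id = r$study_id,
      n_sites = r$n_sites, n_species = r$n_species,
      form = r$classification$winner,
      waic_exponential = r$classification$waic[["exponential"]],
      ambiguous = r$classification$ambiguous,
      pie_pooled = p$pie_pooled, pie_sample_mean = p$pie_sample_mean,
      morisita_mean = p$morisita_mean, morisita_ses = p$morisita_ses$ses,
      spearman_mean = p$spearman_mean, spearman_ses = p$spearman_ses$ses,
      c_score = p$c_score, c_score_ses = p$c_score_ses$ses,
      singleton_proportion = p$singleton_proportion,
      matrix_fill = p$matrix_fill,
      stringsAsFactors = FALSE)
  }))
}

#' Compare a biodiversity property between the two forms of decline
#'
#' Logistic regression of the form of decline (exponential = 1, power = 0)
#' on one property, with a random intercept per study to absorb
#' non-independence of datasets from the same study (via
#' [lme4::glmer()]); falls back to a plain logistic model when every study
#' contributes a single dataset or the mixed fit fails. Complete separation
#' is flagged.
#'
#' @param records list of \code{dataset_record}s or a [records_table()]
#'   data frame.
#' @param property column name of the property to test (e.g.
#'   "morisita_ses").
#' @return list of class \code{comparison_result}: property, coefficient,
#'   se, z, p, model ("mixed-logistic" or "plain-logistic"), separation.
#' @export
compare_forms <- function(records, property) {
  tab <- if (is.data.frame(records)) records else records_table(records)
  if (!property %in% names(tab)) stop("unknown property: ", property)
  tab <- tab[is.finite(tab[[property]]), , drop = FALSE]
  if (length(unique(tab$form)) < 2L)
    stop("both forms of decline must be present")
  y <- as.integer(tab$form == "exponential")
  x <- tab[[property]]
  dat <- data.frame(y = y, x = x, study = factor(tab$study_id))
  mixed_ok <- any(duplicated(tab$study_id))
  fit <- NULL
  model <- "plain-logistic"
  if (mixed_ok) {
    fit <- tryCatch(
      suppressMessages(lme4::glmer(y ~ x + (1 | study), data = dat,
                                   family = stats::binomial)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) model <- "mixed-logistic"
  }
  if (is.null(fit)) {
    fit <- stats::glm(y ~ x, data = dat, family = stats::binomial)
  }
  cf <- summary(fit)$coefficients
  co <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  separation <- !is.finite(se) || se > 50 * max(abs(co), 1)
  if (separation) {
    # complete (or quasi-) separation: bias-reduced (Firth) logistic keeps
    # the estimate and its sign finite and interpretable
    fr <- firth_logistic(y, x)
    co <- fr$coefficient; se <- fr$se
    model <- "firth-logistic"
  }
  structure(list(property = property, coefficient = co, se = se,
                 z = co / se,
                 p = 2 * stats::pnorm(-abs(co / se)),
                 model = model, n = nrow(dat), separation = separation),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 3, ...) {
  cat(x$property, " (", x$model, ", n = ", x$n, "): coef = ",
      signif(x$coefficient, digits), " (SE ", signif(x$se, digits),
      "), z = ", signif(x$z, digits), ", p = ", signif(x$p, digits),
      if (x$separation) "  [separation]" else "", "\n", sep = "")
  invisible(x)
}

#' Test a contextual covariate against the form of decline
#'
#' Continuous covariates (e.g. extent, number of sites or species) are
#' tested by logistic regression of the form on the covariate; categorical
#' covariates (realm, kingdom, impact) by a chi-square test on the
#' form-by-level contingency table.
#'
#' @param records records list or [records_table()] data frame.
#' @param covariate column name in the table (or in \code{meta}).
#' @param meta optional data frame keyed by \code{dataset_id} supplying
#'   covariates not already in the table.
#' @return a \code{comparison_result} (continuous) or an \code{htest}
#'   (categorical).
#' @export
compare_context <- function(records, covariate, meta = NULL) {
  tab <- if (is.data.frame(records)) records else records_table(records)
  if (!is.null(meta)) {
    if (!"dataset_id" %in% names(meta)) stop("meta needs a dataset_id column")
    tab <- merge(tab, meta, by = "dataset_id", all.x = TRUE, sort = FALSE)
  }
  if (!covariate %in% names(tab)) stop("unknown covariate: ", covariate)
  v <- tab[[covariate]]
  ok <- !is.na(v)
  if (mean(ok) < 0.8)
    warning("covariate '", covariate, "' missing for more than 20% of records")
  tab <- tab[ok, , drop = FALSE]
  v <- v[ok]
  if (is.numeric(v)) {
    compare_forms(tab, covariate)
  } else {
    stats::chisq.test(table(tab$form, v))
  }
}

#' Run the batch pipeline over a collection of datasets
#'
#' Classifies every dataset, computes the property battery and returns the
#' records plus tidy table. Per-dataset seeds are derived by stable hashing
#' of the dataset id with the master seed, so the batch is reproducible and
#' insensitive to processing order.
#'
#' @param collection a \code{study_collection} from
#'   [generate_study_collection()], or a list whose elements have
#'   \code{matrix}, \code{dataset_id}, \code{study_id}.
#' @param n_null null matrices per SES (default 999).
#' @param seed master seed.
#' @param verbose log per-dataset progress to stderr.
#' @return list with \code{records} and \code{table}.
#' @export
run_pipeline <- function(collection, n_null = 999L, seed = 1L,
                         verbose = FALSE) {
  records <- lapply(collection, function(d) {
    if (verbose) message("dataset ", d$dataset_id)
    run_dataset(d$matrix, dataset_id = d$dataset_id, study_id = d$study_id,
                n_null = n_null, seed = derive_seed(d$dataset_id, seed))
  })
  list(records = records, table = records_table(records))
}

#' Write a pipeline report
#'
#' Writes the tidy per-dataset table as CSV and a JSON summary (counts per
#' form, per-property medians by form, seed) for reproducibility.
#'
#' @param records records list or the result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param seed master seed echoed into the summary.
#' @return invisibly, the paths written.
#' @export
write_report <- function(records, dir, seed = NULL) {
  if (!is.null(records$table)) {
    tab <- records$table
  } else {
    tab <- records_table(records)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  props <- c("pie_pooled", "pie_sample_mean", "morisita_ses", "spearman_ses",
             "c_score_ses", "singleton_proportion", "matrix_fill")
  med <- lapply(split(tab[props], tab$form), function(d)
    lapply(d, function(col) stats::median(col, na.rm = TRUE)))
  summary <- list(n_datasets = nrow(tab),
                  n_exponential = sum(tab$form == "exponential"),
                  n_power = sum(tab$form == "power"),
                  median_properties_by_form = med,
                  seed = seed)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}

# Firth's bias-reduced logistic regression for one covariate: Newton
# iterations on the Jeffreys-penalized score (hat-diagonal correction).
firth_logistic <- function(y, x, max_iter = 100L, tol = 1e-8) {
  X <- cbind(1, scale(x)[, 1])
  sx <- stats::sd(x)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    h <- rowSums((XW %*% solve(XtWX)) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- solve(XtWX, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(XtWX)))
  list(coefficient = beta[2] / sx, se = se[2] / sx)
}
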