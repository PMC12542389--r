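# CSV / YAML / JSON plumbing: record files, fixtures, result serialization
# and the dispatch behind the command-line entry point (inst/cli/survcalib).

.json_schema_version <- 1L

#' Read censored survival records from CSV
#'
#' Expects a header with columns \code{time}, \code{event} (0/1) and
#' \code{shat} (decimal in \eqn{[0, 1]}); an optional \code{id} column is
#' carried through.  Validation failures name the offending data row; missing
#' values are an error, never dropped.
#'
#' @param path path to the CSV file.
#' @return a data frame of validated records.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty sample")
  for (col in c("time", "event", "shat")) {
    if (!col %in% names(df)) stop(sprintf("missing column '%s'", col))
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d", col,
                   if (is.na(bad)) 1L else bad))
    }
    if (anyNA(df[[col]])) {
      stop(sprintf("missing value in column '%s', row %d", col,
                   which(is.na(df[[col]]))[1]))
    }
  }
  if (any(df$time < 0)) {
    stop(sprintf("negative time in row %d", which(df$time < 0)[1]))
  }
  if (!all(df$event %in% c(0, 1))) {
    stop(sprintf("event outside {0, 1} in row %d",
                 which(!df$event %in% c(0, 1))[1]))
  }
  if (any(df$shat < 0 | df$shat > 1)) {
    stop(sprintf("shat outside [0, 1] in row %d",
                 which(df$shat < 0 | df$shat > 1)[1]))
  }
  df
}

#' Write a dataset to CSV
#'
#' Plain-text writer for \code{\link{simulate_dataset}} output (or any record
#' data frame); round-trips through \code{\link{read_survival_csv}} to full
#' double precision.
#'
#' @param dataset a data frame with at least \code{time}, \code{event},
#'   \code{shat}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_survival_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a test result to JSON
#'
#' @param result a \code{"gof_test"} object.
#' @param path optional output file; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
gof_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "gof_test"))
  obj <- list(
    schema_version = .json_schema_version,
    method = if (grepl("^A-calibration", result$method)) "A" else "D",
    statistic = unname(result$statistic),
    df = unname(result$parameter),
    pvalue = result$p.value,
    observed = result$observed,
    expected = result$expected,
    K = result$K,
    a = result$a
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run a calibration test on a record file
#'
#' Dispatch used by the \code{test} subcommand of the command-line interface:
#' reads a CSV of records, builds the PIT sample, runs the requested test(s)
#' and serializes the results.
#'
#' @param input path to a record CSV (see \code{\link{read_survival_csv}}).
#' @param method \code{"A"}, \code{"D"} or \code{"both"}.
#' @param K number of partitioning intervals.
#' @param support optional support override for A-calibration.
#' @param output optional path for the JSON result; \code{NULL} prints to
#'   stdout.
#' @param quiet suppress the one-line INFO summary.
#' @return a list of \code{"gof_test"} objects, invisibly.
#' @export
run_test_command <- function(input, method = c("both", "A", "D"), K = 10,
                             support = NULL, output = NULL, quiet = FALSE) {
  method <- match.arg(method)
  records <- read_survival_csv(input)
  sample <- make_pit_sample(records)
  results <- list()
  if (method %in% c("A", "both")) {
    results$A <- a_calibration_test(sample, K = K, support = support)
  }
  if (method %in% c("D", "both")) {
    results$D <- d_calibration_test(sample, K = K)
  }
  json <- vapply(results, function(r) as.character(gof_result_json(r)), "")
  out <- sprintf("[%s]", paste(json, collapse = ","))
  if (!quiet) {
    for (r in results) {
      message(sprintf(
        "INFO n=%d events=%d K=%d a=%.4g statistic=%.4g df=%d p=%.4g",
        sample$n, sum(sample$events), r$K, r$a, r$statistic, r$parameter,
        r$p.value))
    }
  }
  if (is.null(output)) cat(out, "\n") else writeLines(out, output)
  invisible(results)
}

#' Write a deterministic test fixture to disk
#'
#' Simulates a dataset of a named kind and writes the record CSV plus a YAML
#' sidecar holding the generating configuration (truth, predictive model,
#' scheme, seed).  Identical calls produce byte-identical files.
#'
#' @param kind \code{"null_uncensored"} (no censoring, true model),
#'   \code{"null_censored"} (memoryless censoring at \code{q}, true model) or
#'   \code{"misspecified"} (shape misspecification \code{lambda}).
#' @param n number of subjects.
#' @param seed integer seed.
#' @param dir output directory.
#' @param q censoring fraction for the censored kinds.
#' @param lambda shape misspecification factor for \code{"misspecified"}.
#' @return paths of the files written, invisibly.
#' @export
make_fixture <- function(kind = c("null_uncensored", "null_censored",
                                  "misspecified"),
                         n = 100, seed = 1, dir = ".", q = 0.2,
                         lambda = 0.85) {
  kind <- match.arg(kind)
  truth <- weibull_spec()
  scheme <- if (kind == "null_uncensored") censoring_scheme("none")
            else calibrate_censoring("memoryless", truth, q)
  model <- if (kind == "misspecified") misspecify(truth, "shape", lambda)
           else truth
  ds <- simulate_dataset(n, truth, scheme, model = model, seed = seed)
  csv <- file.path(dir, sprintf("%s_n%d_seed%d.csv", kind, n, seed))
  side <- sub("\\.csv$", ".yaml", csv)
  write_survival_csv(ds, csv)
  cfg <- list(
    kind = kind, n = n, seed = seed,
    truth = list(alpha = truth$alpha, beta = truth$beta,
                 predictors = truth$predictors),
    model = list(alpha = model$alpha, beta = model$beta),
    scheme = list(kind = scheme$kind,
                  param = if (is.na(scheme$param)) NULL else scheme$param,
                  q = if (kind == "null_uncensored") 0 else q)
  )
  writeLines(yaml::as.yaml(cfg), side)
  invisible(c(csv = csv, yaml = side))
}

#' Plot power curves from a grid table
#'
#' Base-graphics rendering of rejection-rate curves for both tests against
#' the misspecification parameter, one panel per (scheme, n) combination,
#' with the nominal level as a dashed reference line.
#'
#' @param table a data frame from \code{\link{run_grid}}.
#' @param path optional PDF path; \code{NULL} draws on the current device.
#' @return the input table, invisibly.
#' @export
plot_power_curves <- function(table, path = NULL) {
  if (!is.null(path)) {
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
  }
  panels <- unique(table[, c("scheme", "n")])
  graphics::par(mfrow = c(1, nrow(panels)), mar = c(4, 4, 3, 1))
  for (i in seq_len(nrow(panels))) {
    sub <- table[table$scheme == panels$scheme[i] & table$n == panels$n[i], ]
    sub <- sub[order(sub$lambda), ]
    graphics::plot(sub$lambda, sub$power_A, type = "b", pch = 16,
                   ylim = c(0, 1), xlab = expression(lambda),
                   ylab = "rejection rate",
                   main = sprintf("%s, n = %d", panels$scheme[i],
                                  panels$n[i]))
    graphics::lines(sub$lambda, sub$power_D, type = "b", pch = 1, lty = 2)
    graphics::abline(h = unique(sub$level_A)[1], lty = 3)
    graphics::legend("bottomleft", c("A", "D"), pch = c(16, 1),
                     lty = c(1, 2), bty = "n")
  }
  invisible(table)
}
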